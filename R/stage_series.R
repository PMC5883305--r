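#' Simulate the meiotic prophase stage series
#'
#' Generates cell populations for the spermatogenesis stages around
#' meiotic entry and the WGBS observables of each: spermatogonia (Spg,
#' unreplicated, highly methylated), preleptotene (PL, mid-S-phase
#' mixture — the stage where passive dilution is underway), then
#' leptotene through pachytene (L, Z, P; fully replicated with
#' progressively more hemimethylated dyads restored by maintenance
#' methylation, earlier-replicating regions recovering first).
#'
#' With `replication_coupling = FALSE` a negative-control series is
#' produced instead: the same per-stage mean methylation trajectory is
#' imposed by uniform, replication-independent thinning of methylation,
#' with no relationship to replication timing.
#'
#' @param layout a `meth_layout`; `NULL` (default) builds [sim_layout()]
#'   with a seed derived from `seed`.
#' @param rt an `rt_track`; `NULL` builds [sim_rt_track()] on `layout`,
#'   seeded from `seed`.
#' @param params a [sim_params()] (`NULL` for defaults: `s0 = 0.86`
#'   outside CpG islands, `m = 0.3`, 60 cells); `s0` and `m` set the
#'   starting level and maintenance efficiency.
#' @param recovery named per-stage probabilities (cumulative, in `[0,1]`)
#'   that a hemimethylated dyad has been restored to `MM` by that stage.
#' @param rt_coupling amplitude of replication-timing grading of
#'   recovery (see [remethylate_population()]).
#' @param stages which stages to produce, in order.
#' @param replication_coupling simulate passive replication-coupled
#'   dilution (TRUE) or the uniform-demethylation control (FALSE).
#' @param wgbs additional arguments passed to [sample_wgbs()] as a list.
#' @param seed master seed; per-stage seeds are derived from it.
#' @return list of class `stage_series`: per stage, `pop` (the
#'   `dyad_pop`) and `wgbs` (calls + fragments); plus `layout`, `rt` and
#'   generation metadata. The whole object is a pure function of its
#'   arguments and `seed`.
#' @export
simulate_stage_series <- function(layout = NULL, rt = NULL, params = NULL,
                                  recovery = c(L = 0.5, Z = 0.75, P = 0.97,
                                               D = 0.98, Spz = 0.99),
                                  rt_coupling = 0.6,
                                  stages = c("Spg", "PL", "L", "Z", "P"),
                                  replication_coupling = TRUE,
                                  wgbs = list(depth = 8),
                                  seed = 1L) {
  check_prob(recovery, "recovery")
  default_inputs <- is.null(layout) && is.null(params)
  layout <- layout %||% sim_layout(seed = seed + 1L)
  rt <- rt %||% sim_rt_track(layout, seed = seed + 2L)
  if (default_inputs && !"DMR_maternal" %in% names(layout$annotation)) {
    ## maternal imprinted DMRs stay unmethylated on the paternal germline
    ## genome; paternal DMRs follow bulk methylation
    layout$annotation <- c(layout$annotation, imprinted_dmr_annotation(layout))
  }
  params <- params %||% sim_params(
    s0 = c(default = 0.86, CGI = 0.05,
           if (default_inputs) c(DMR_maternal = 0.02)),
    m = 0.3, n_cells = 60L, seed = seed
  )
  sample_stage <- function(pop, k) {
    do.call(sample_wgbs, c(list(pop = pop, seed = seed + 100L + k), wgbs))
  }
  out <- list()

  base_params <- params
  base_params$seed <- seed
  spg <- make_genome(base_params, rt, layout)

  if (replication_coupling) {
    k <- 0L
    for (st in stages) {
      k <- k + 1L
      pop <- switch(st,
        Spg = spg,
        PL = replicate_population(spg, rt, s_progress = default_s_progress,
                                  m = params$m, seed = seed + 10L),
        ## post-S stages: complete replication, then cumulative recovery
        {
          full <- replicate_population(spg, rt, s_progress = 1,
                                       m = params$m, seed = seed + 10L)
          if (!st %in% names(recovery)) mm_stop("no recovery level for stage ", st)
          rho <- recovery[[st]]
          remethylate_population(full, rho = rho, rt_coupling = rt_coupling,
                                 seed = seed + 20L + k)
        }
      )
      out[[st]] <- list(pop = pop, wgbs = sample_stage(pop, k))
    }
  } else {
    ## control: impose the same stage means by uniform strand thinning
    target <- stage_target_methylation(params, recovery)
    k <- 0L
    for (st in stages) {
      k <- k + 1L
      pop <- uniform_demethylate(spg, target_level = target[[st]],
                                 seed = seed + 30L + k)
      out[[st]] <- list(pop = pop, wgbs = sample_stage(pop, k))
    }
  }

  structure(list(stages = out, layout = layout, rt = rt,
                 meta = list(seed = seed, replication_coupling = replication_coupling,
                             recovery = recovery, rt_coupling = rt_coupling)),
            class = "stage_series")
}

#' Expected stage-mean strand methylation under the passive model
#'
#' Applies the closed-form dilution/recovery arithmetic per stage: Spg at
#' `s0`; PL at the S-progress-mixture expectation; post-S stages at full
#' replication with the stage's cumulative recovery of hemimethylated
#' dyads.
#'
#' @param params a [sim_params()].
#' @param recovery named per-stage recovery probabilities.
#' @return named numeric vector of expected strand-level methylation (for
#'   the non-CGI fraction of the genome).
#' @export
stage_target_methylation <- function(params,
                                     recovery = c(L = 0.5, Z = 0.75, P = 0.97,
                                                  D = 0.98, Spz = 0.99)) {
  s0 <- if (length(params$s0) > 1) unname(params$s0[["default"]]) else unname(params$s0)
  m <- params$m
  r_pl <- mean(c(0.25, 0.5, 0.9))
  post <- function(rho) s0 * ((1 + m) / 2 + (1 - m) / 2 * rho)
  c(Spg = s0,
    PL = expected_strand_methylation(s0, r_pl, m),
    vapply(recovery, post, numeric(1)))
}

## replication-independent control: thin methylated strand-CpGs uniformly
## (both strands independently) to reach a target strand-level methylation
uniform_demethylate <- function(pop, target_level, seed = 1L) {
  set.seed(seed)
  cur <- strand_methylation(pop)
  keep_p <- min(1, target_level / max(cur, 1e-12))
  thin <- function(mat) mat & (matrix(stats::runif(length(mat)), nrow(mat)) < keep_p)
  pop$top1 <- thin(pop$top1)
  pop$bot1 <- thin(pop$bot1)
  pop
}

#' Stage-wise summary table of a simulated series
#'
#' Genome-wide summaries per stage: median of 500-CpG bin means, overall
#' strand-level truth, and dyad-state proportions.
#'
#' @param series a `stage_series`.
#' @param bin_cpgs CpGs per bin for the median (default 500).
#' @return data.frame, one row per stage.
#' @export
stage_summary <- function(series, bin_cpgs = 500L) {
  do.call(rbind, lapply(names(series$stages), function(st) {
    s <- series$stages[[st]]
    merged <- merge_strands(s$wgbs$calls)
    bm <- bin_mean(merged, k = bin_cpgs)
    states <- dyad_state_counts(s$pop)
    data.frame(
      stage = st,
      median_bin_meth = stats::median(bm$mean_meth),
      truth_strand_meth = strand_methylation(s$pop),
      prop_hemi_duplexes = states[["hemi"]] / sum(states),
      stringsAsFactors = FALSE
    )
  }))
}
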
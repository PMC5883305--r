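#' Run the end-to-end workflow from a YAML config
#'
#' Executes the requested stages of the analysis —
#' `simulate` (stage-series generation + WGBS sampling),
#' `wgbs_summarize` (bins, windows, replicate correlation),
#' `dmr` (consecutive-stage block calling + intersection accounting),
#' `rt_corr` (replication-timing correlation series) and
#' `hairpin` (L1 hairpin simulation + dyad calling) — and writes their
#' tables plus a machine-readable JSON run report (seed, parameters,
#' drop counts) under `out_dir`. Identical config + seed reproduces
#' identical outputs.
#'
#' @param config path to a YAML file or an equivalent named list.
#'   Recognized top-level fields: `seed` (integer, required), `out_dir`,
#'   `steps` (subset of `c("simulate", "wgbs_summarize", "dmr",
#'   "rt_corr", "hairpin")`), and per-step parameter blocks `simulate:
#'   {n_cells, s0, m, cpgs_per_chrom}`, `dmr: {diff_cutoff, min_cpgs,
#'   max_gap, bandwidth}`, `hairpin: {n_molecules, hemi_frac, n_pairs,
#'   read_len, conv, err}`.
#' @return (invisibly) the run report list, also written as
#'   `report.json`.
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (!is.list(cfg)) mm_stop("config must be a YAML path or a list")
  if (is.null(cfg$seed)) mm_stop("config field 'seed' is required")
  seed <- as.integer(cfg$seed)
  out_dir <- cfg$out_dir %||% "meiometh_run"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  steps <- cfg$steps %||% c("simulate", "wgbs_summarize", "dmr", "rt_corr", "hairpin")
  known <- c("simulate", "wgbs_summarize", "dmr", "rt_corr", "hairpin")
  bad <- setdiff(steps, known)
  if (length(bad)) mm_stop("unknown steps: ", paste(bad, collapse = ", "))

  report <- list(seed = seed, steps = steps, outputs = list())
  note <- function(name, path) report$outputs[[name]] <<- path

  sim <- cfg$simulate %||% list()
  layout <- sim_layout(
    n_chrom = sim$n_chrom %||% 2,
    cpgs_per_chrom = sim$cpgs_per_chrom %||% 1500,
    seed = seed
  )
  rt <- sim_rt_track(layout, seed = seed + 1L)
  params <- sim_params(
    s0 = c(default = sim$s0 %||% 0.86, CGI = 0.05),
    m = sim$m %||% 0.3,
    n_cells = sim$n_cells %||% 40L,
    seed = seed
  )

  series <- NULL
  merged <- NULL
  if (any(c("simulate", "wgbs_summarize", "dmr", "rt_corr") %in% steps)) {
    series <- simulate_stage_series(layout, rt, params, seed = seed)
    merged <- lapply(series$stages, function(s) merge_strands(s$wgbs$calls))
    merged <- restrict_common(merged)$callsets
  }

  if ("simulate" %in% steps) {
    write_rt_bedgraph(rt, file.path(out_dir, "rt_track.bedGraph"))
    note("rt_track", file.path(out_dir, "rt_track.bedGraph"))
    for (st in names(series$stages)) {
      p <- file.path(out_dir, sprintf("%s.cov", st))
      write_bismark_cov(merged[[st]], p)
      note(paste0("cov_", st), p)
    }
    report$stage_summary <- stage_summary(series)
  }

  if ("wgbs_summarize" %in% steps) {
    summ <- do.call(rbind, lapply(names(merged), function(st) {
      bm <- bin_mean(merged[[st]], k = 500L)
      data.frame(stage = st, median_bin_meth = stats::median(bm$mean_meth))
    }))
    p <- file.path(out_dir, "stage_medians.tsv")
    utils::write.table(summ, p, sep = "\t", quote = FALSE, row.names = FALSE)
    note("stage_medians", p)
  }

  if ("dmr" %in% steps) {
    dmr_cfg <- cfg$dmr %||% list()
    sts <- names(merged)
    pairs <- Map(c, head(sts, -1), tail(sts, -1))
    blocks <- lapply(pairs, function(pr) {
      call_blocks(merged[[pr[1]]], merged[[pr[2]]],
                  diff_cutoff = dmr_cfg$diff_cutoff %||% 0.1,
                  min_cpgs = dmr_cfg$min_cpgs %||% 10L,
                  max_gap = dmr_cfg$max_gap %||% 2L,
                  bandwidth = dmr_cfg$bandwidth %||% 2L)
    })
    names(blocks) <- vapply(pairs, paste, character(1), collapse = "_")
    for (nm in names(blocks)) {
      p <- file.path(out_dir, sprintf("dmr_%s.bed", nm))
      write_blocks_bed(blocks[[nm]], p)
      note(paste0("dmr_", nm), p)
    }
    first <- blocks[[1]]
    report$dmr <- data.frame(
      comparison = names(blocks),
      n_blocks = vapply(blocks, nrow, numeric(1)),
      cpg_frac_hypo = vapply(blocks, function(b)
        cpg_proportions(b, merged[[1]])[["hypo"]], numeric(1)),
      frac_explained_by_first = vapply(blocks, function(b)
        intersect_fraction(first, b), numeric(1)),
      row.names = NULL
    )
  }

  if ("rt_corr" %in% steps) {
    windows <- lapply(merged, window_mean, width = 100000L)
    rc <- stage_correlation_series(windows, rt)
    p <- file.path(out_dir, "rt_correlation.tsv")
    utils::write.table(rc$series, p, sep = "\t", quote = FALSE, row.names = FALSE)
    note("rt_correlation", p)
    report$rt_sign_switch <- rc$sign_switch
  }

  if ("hairpin" %in% steps) {
    hp_cfg <- cfg$hairpin %||% list()
    cons <- l1_consensus()
    mols <- make_l1_population(hp_cfg$n_molecules %||% 2000,
                               consensus = cons,
                               hemi_frac = hp_cfg$hemi_frac %||% 0.04,
                               seed = seed + 50L)
    repl <- replicate_l1_population(mols, m = hp_cfg$m %||% 0, seed = seed + 51L)
    hp <- build_hairpin(cons$sequence, repl$top, repl$bottom)
    reads <- simulate_read_pairs(hp, n_pairs = hp_cfg$n_pairs %||% 5000,
                                 read_len = hp_cfg$read_len %||% 150L,
                                 conv = hp_cfg$conv %||% 1,
                                 err = hp_cfg$err %||% 0, seed = seed + 52L)
    res <- call_hairpin(reads$read1, reads$read2, cons)
    p <- file.path(out_dir, "hairpin_dyads.tsv")
    write_dyad_matrix(res$matrix, p)
    note("hairpin_dyads", p)
    p2 <- file.path(out_dir, "hairpin_summary.tsv")
    utils::write.table(res$summary$per_dyad, p2, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    note("hairpin_summary", p2)
    report$hairpin <- list(
      n_pairs = length(reads$read1),
      dropped = as.list(res$matrix$dropped),
      fully_unmethylated_fraction = res$summary$fully_unmethylated_fraction
    )
  }

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
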
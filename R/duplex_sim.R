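#' Simulation parameters for the duplex genome
#'
#' @param s0 initial strand-level methylation in `[0,1]`. Either a single
#'   number or a named vector with a `default` entry plus per-annotation
#'   overrides (e.g. `c(default = 0.86, CGI = 0.05)`); a CpG inside an
#'   annotated interval of a named class takes that class's value (later
#'   names win on overlap).
#' @param r replicated genome fraction in `[0,1]` (used by the closed-form
#'   expectation; the population simulator takes per-cell S-phase progress
#'   instead).
#' @param m maintenance-methylation efficiency in `[0,1]`: the probability
#'   that a CpG on the newly synthesized strand is methylated given its
#'   template-strand partner is methylated.
#' @param hemi_frac fraction of L1-like elements that start
#'   strand-coherently hemimethylated (top strand methylated, bottom not)
#'   rather than drawn from `s0`.
#' @param n_cells number of cells in the population.
#' @param seed integer seed; all randomness in the simulator flows from it.
#'
#' @return list of class `sim_params`.
#' @export
sim_params <- function(s0 = 0.86, r = 1, m = 0.3, hemi_frac = 0,
                       n_cells = 100L, seed = 1L) {
  check_prob(unname(s0), "s0"); check_prob(r, "r"); check_prob(m, "m")
  check_prob(hemi_frac, "hemi_frac")
  if (length(s0) > 1 && !("default" %in% names(s0))) {
    mm_stop("vector 's0' needs a 'default' entry")
  }
  if (n_cells < 1) mm_stop("n_cells must be positive")
  structure(list(s0 = s0, r = r, m = m, hemi_frac = hemi_frac,
                 n_cells = as.integer(n_cells), seed = as.integer(seed)),
            class = "sim_params")
}

## per-CpG initial strand-level methylation implied by s0 and annotations
cpg_s0 <- function(params, layout) {
  s0 <- params$s0
  n <- nrow(layout$cpgs)
  if (length(s0) == 1 && is.null(names(s0))) return(rep(unname(s0), n))
  p <- rep(unname(s0[["default"]]), n)
  for (cls in setdiff(names(s0), "default")) {
    iv <- layout$annotation[[cls]]
    if (is.null(iv)) mm_stop(sprintf("s0 names class '%s' absent from layout annotation", cls))
    hit <- !is.na(interval_index(layout$cpgs$chrom, layout$cpgs$pos, iv))
    p[hit] <- unname(s0[[cls]])
  }
  p
}

#' Create an unreplicated cell population of duplex genomes
#'
#' Each cell carries one duplex (two strands) per chromosome. Dyads are
#' drawn `MM` with probability `s0` and `UU` otherwise, so expected
#' strand-level methylation equals `s0`. A fixed set of
#' `round(hemi_frac * n_L1)` L1-like elements (chosen once per genome,
#' identically in every cell) is instead set strand-coherently
#' hemimethylated: every top-strand CpG of the element methylated, every
#' bottom-strand CpG unmethylated.
#'
#' @param params a [sim_params()] object.
#' @param rt an `rt_track` covering every CpG (validated here so that
#'   downstream replication is well defined).
#' @param layout a `meth_layout`.
#' @return object of class `dyad_pop`: logical matrices `top1`, `bot1`
#'   (cells x CpGs) for the parental duplex, `top2`, `bot2` for the
#'   daughter duplex created by replication (`NA` where unreplicated),
#'   `replicated` (logical matrix), `s_progress` per cell, plus the layout,
#'   rt track and params.
#' @export
make_genome <- function(params, rt, layout) {
  stopifnot(inherits(params, "sim_params"), inherits(layout, "meth_layout"))
  validate_rt_track(rt, layout)
  set.seed(params$seed)
  n <- nrow(layout$cpgs)
  nc <- params$n_cells

  p0 <- cpg_s0(params, layout)
  mm <- matrix(stats::runif(nc * n) < rep(p0, each = nc), nrow = nc)
  top1 <- mm
  bot1 <- mm

  hemi_elements <- integer(0)
  l1 <- layout$annotation$L1
  if (params$hemi_frac > 0 && !is.null(l1) && nrow(l1) > 0) {
    n_hemi <- round(params$hemi_frac * nrow(l1))
    hemi_elements <- sort(sample.int(nrow(l1), n_hemi))
    for (e in hemi_elements) {
      idx <- which(layout$cpgs$chrom == l1$chrom[e] &
                     layout$cpgs$pos >= l1$start[e] &
                     layout$cpgs$pos < l1$end[e])
      top1[, idx] <- TRUE
      bot1[, idx] <- FALSE
    }
  }

  na <- matrix(NA, nrow = nc, ncol = n)
  structure(list(
    layout = layout, rt = rt, params = params,
    top1 = top1, bot1 = bot1, top2 = na, bot2 = na,
    replicated = matrix(FALSE, nrow = nc, ncol = n),
    s_progress = rep(0, nc),
    hemi_elements = hemi_elements
  ), class = "dyad_pop")
}

#' @export
print.dyad_pop <- function(x, ...) {
  cat(sprintf(
    "dyad_pop: %d cells x %d CpG dyads; mean S-phase progress %.2f; strand-level methylation %.4f\n",
    nrow(x$top1), ncol(x$top1), mean(x$s_progress), strand_methylation(x)
  ))
  invisible(x)
}

## replication order: decreasing rt_value, ties by chrom then start
rt_replication_order <- function(rt) {
  order(-rt$rt_value, rt$chrom, rt$start)
}

#' Replicate a cell population in replication-timing order
#'
#' Each cell is assigned a fraction of S phase completed, and its
#' replication-timing domains are replicated in strictly decreasing
#' `rt_value` order (ties broken by genomic coordinate) until at least
#' that fraction of the genome's CpGs lies in replicated domains.
#' Replication is semiconservative: each replicated duplex is replaced by
#' two daughter duplexes that keep their template strand unchanged, while
#' each CpG on the newly synthesized strand is methylated with probability
#' `m` when its template partner is methylated and never otherwise
#' (passive dilution of methylation).
#'
#' @param pop an unreplicated `dyad_pop`.
#' @param rt replication-timing track; defaults to the one stored in `pop`.
#' @param s_progress S-phase progress per cell: a single number in `[0,1]`,
#'   a vector of length `n_cells`, or a function `f(n)` returning one value
#'   per cell. Default: equal mixture of 0.25 / 0.5 / 0.9 (early, mid and
#'   late S), the composition seen in replicating preleptotene cells.
#' @param m maintenance-methylation efficiency; defaults to `pop$params$m`.
#' @param seed integer seed.
#' @return the replicated `dyad_pop`.
#' @export
replicate_population <- function(pop, rt = pop$rt,
                                 s_progress = default_s_progress,
                                 m = pop$params$m, seed = pop$params$seed + 1L) {
  stopifnot(inherits(pop, "dyad_pop"))
  if (any(pop$replicated)) mm_stop("population already replicated")
  check_prob(m, "m")
  set.seed(seed)
  nc <- nrow(pop$top1); n <- ncol(pop$top1)

  sp <- if (is.function(s_progress)) s_progress(nc) else rep_len(s_progress, nc)
  check_prob(sp, "s_progress")

  ## map CpGs to rt intervals and order domains
  dom <- interval_index(pop$layout$cpgs$chrom, pop$layout$cpgs$pos, rt)
  ord <- rt_replication_order(rt)
  cpgs_per_dom <- tabulate(dom, nbins = nrow(rt))
  cum <- cumsum(cpgs_per_dom[ord])

  ## domains replicated for a given progress fraction: take domains in rt
  ## order while the replicated CpG count is still short of the target
  dom_rank <- match(seq_len(nrow(rt)), ord)
  for (cell in seq_len(nc)) {
    target <- sp[cell] * n
    if (target <= 0) next
    k <- findInterval(target, cum, left.open = TRUE) + 1L  # first k domains
    k <- min(k, nrow(rt))
    repl <- dom_rank[dom] <= k
    pop$replicated[cell, repl] <- TRUE
  }
  pop$s_progress <- sp

  ## semiconservative copy with maintenance efficiency m
  rep_idx <- which(pop$replicated)
  t1 <- pop$top1[rep_idx]; b1 <- pop$bot1[rep_idx]
  nrep <- length(rep_idx)
  new_bot1 <- t1 & (stats::runif(nrep) < m)  # daughter 1: template top1
  new_top2 <- b1 & (stats::runif(nrep) < m)  # daughter 2: template bot1
  pop$bot2[rep_idx] <- b1
  pop$top2[rep_idx] <- new_top2
  pop$bot1[rep_idx] <- new_bot1
  pop
}

#' Default preleptotene S-phase progress mixture
#'
#' Equal mixture over 0.25, 0.5 and 0.9 of S phase completed, echoing
#' EdU-labeling patterns of replicating preleptotene cells dominated by
#' middle and late S phase.
#' @param n number of cells.
#' @return numeric vector of length `n`.
#' @export
default_s_progress <- function(n) {
  sample(c(0.25, 0.5, 0.9), n, replace = TRUE)
}

#' Strand-level methylation of a population
#'
#' Per CpG site, the fraction of methylated strand copies across all
#' molecules of the population (an unreplicated dyad contributes 2
#' strands per cell, a replicated one 4). Site fractions are averaged
#' with equal weight per CpG — the quantity a coverage-normalized WGBS
#' measurement estimates — rather than pooled by strand count, which
#' during S phase would overweight already-replicated DNA.
#'
#' @param pop a `dyad_pop`.
#' @param by `"population"` (single number), `"cell"` (per-cell vector) or
#'   `"cpg"` (per-CpG vector).
#' @return numeric.
#' @export
strand_methylation <- function(pop, by = c("population", "cell", "cpg")) {
  by <- match.arg(by)
  r <- pop$replicated
  meth <- pop$top1 + pop$bot1 +
    ifelse(r, (pop$top2 & r) + (pop$bot2 & r), 0)
  tot <- 2 + 2 * r
  switch(by,
    population = mean(colSums(meth) / colSums(tot)),
    cell = rowMeans(meth / tot),
    cpg = colSums(meth) / colSums(tot)
  )
}

## per-dyad-duplex state counts (MM / hemi / UU) over all duplexes
dyad_state_counts <- function(pop) {
  rep_idx <- which(pop$replicated)
  s1 <- (pop$top1[rep_idx] + pop$bot1[rep_idx])
  s2 <- (pop$top2[rep_idx] + pop$bot2[rep_idx])
  ## duplexes: unreplicated parental + both daughters where replicated
  unrep <- table(factor((pop$top1 + pop$bot1)[!pop$replicated], levels = 0:2))
  repl <- table(factor(c(s1, s2), levels = 0:2))
  out <- as.integer(unrep + repl)
  stats::setNames(out, c("UU", "hemi", "MM"))
}

#' Closed-form expected strand-level methylation after replication
#'
#' For starting strand-level methylation `s0`, replicated genome fraction
#' `r` and maintenance efficiency `m`, the expected strand-level
#' methylation is `s0 * ((1 - r) + r * (1 + m) / 2)`: replicated DNA keeps
#' every template strand and regains a fraction `m` on new strands, so
#' with `m = 0` complete replication halves the starting level — the
#' theoretical maximum reduction of passive dilution.
#'
#' @param s0,r,m numbers in `[0,1]` (vectorized).
#' @return expected strand-level methylation.
#' @export
expected_strand_methylation <- function(s0, r, m) {
  check_prob(s0, "s0"); check_prob(r, "r"); check_prob(m, "m")
  s0 * ((1 - r) + r * (1 + m) / 2)
}

#' Remethylate hemimethylated dyads (maintenance recovery between stages)
#'
#' Converts hemimethylated dyads to fully methylated with a per-dyad
#' probability, modeling gradual DNMT1-mediated recovery after meiotic S
#' phase. With `rt_coupling > 0` the probability is graded by replication
#' timing (earlier-replicating regions, replicated longer ago, recover
#' more), producing the post-S reversal of the methylation-vs-timing
#' correlation.
#'
#' @param pop a `dyad_pop`.
#' @param rho baseline recovery probability in `[0,1]`.
#' @param rt_coupling additive modulation amplitude: per-CpG probability is
#'   `clamp(rho + rt_coupling * (rank(rt_value) - 0.5), 0, 1)` with ranks
#'   scaled to `[0, 1]`.
#' @param seed integer seed.
#' @return the modified `dyad_pop`.
#' @export
remethylate_population <- function(pop, rho, rt_coupling = 0, seed = 1L) {
  check_prob(rho, "rho")
  set.seed(seed)
  dom <- interval_index(pop$layout$cpgs$chrom, pop$layout$cpgs$pos, pop$rt)
  rt_rank <- (rank(pop$rt$rt_value) - 0.5) / nrow(pop$rt)  # in (0,1)
  p_cpg <- pmin(1, pmax(0, rho + rt_coupling * (rt_rank[dom] - 0.5)))
  nc <- nrow(pop$top1)
  pmat <- matrix(rep(p_cpg, each = nc), nrow = nc)

  fill <- function(top, bot, p) {
    hemi <- xor(top, bot)
    gain <- hemi & (matrix(stats::runif(length(top)), nrow = nrow(top)) < p)
    list(top = top | gain, bot = bot | gain)
  }
  d1 <- fill(pop$top1, pop$bot1, pmat)
  pop$top1 <- d1$top; pop$bot1 <- d1$bot
  rep_any <- which(pop$replicated)
  if (length(rep_any)) {
    t2 <- pop$top2; b2 <- pop$bot2
    hemi <- xor(t2, b2) & pop$replicated
    gain <- hemi & (matrix(stats::runif(length(t2)), nrow = nc) < pmat)
    gain[is.na(gain)] <- FALSE
    pop$top2 <- t2 | gain
    pop$bot2 <- b2 | gain
  }
  pop
}

#' Sample WGBS-style per-CpG calls and fragment coverage from a population
#'
#' Per CpG and strand, a Poisson number of reads (mean `depth`) samples
#' strand copies uniformly across all molecules of the population
#' (replicated regions expose twice the copies), and each sampled strand
#' state is reported through the bisulfite error model: a truly
#' unmethylated C appears methylated with probability `conv_fail`
#' (failed conversion) and a truly methylated C appears unmethylated with
#' probability `inapprop_conv` (inappropriate conversion). Separately,
#' fragment counts over fixed windows are drawn proportional to local DNA
#' content, so mid-S populations show reduced coverage over unreplicated
#' (late) domains.
#'
#' @param pop a `dyad_pop`.
#' @param depth mean reads per CpG per strand.
#' @param conv_fail,inapprop_conv error rates in `[0,1]`.
#' @param frag_window window width (bp) of the fragment-coverage track.
#' @param frag_depth mean fragments per window for unreplicated DNA.
#' @param seed integer seed.
#' @return list with `calls` (data.frame `chrom`, `pos`, `strand`,
#'   `n_meth`, `n_unmeth`; minus-strand records sit at `pos + 1`),
#'   `fragments` (data.frame `chrom`, `start`, `end`, `count`) and `meta`
#'   (seed and rates; every simulation artifact records its seed).
#' @export
sample_wgbs <- function(pop, depth = 5, conv_fail = 0.005, inapprop_conv = 0.005,
                        frag_window = 5000L, frag_depth = 50,
                        seed = pop$params$seed + 2L) {
  stopifnot(inherits(pop, "dyad_pop"))
  if (nrow(pop$top1) == 0) mm_stop("empty population")
  if (depth <= 0) mm_stop("depth must be positive")
  check_prob(conv_fail, "conv_fail"); check_prob(inapprop_conv, "inapprop_conv")
  set.seed(seed)
  n <- ncol(pop$top1); nc <- nrow(pop$top1)
  nrep <- colSums(pop$replicated)

  strand_p <- function(m1, m2) {
    extra <- colSums(m2 & pop$replicated, na.rm = TRUE)
    (colSums(m1) + extra) / (nc + nrep)
  }
  draw <- function(p) {
    nr <- stats::rpois(n, depth)
    true_m <- stats::rbinom(n, nr, p)
    obs_m <- stats::rbinom(n, true_m, 1 - inapprop_conv) +
      stats::rbinom(n, nr - true_m, conv_fail)
    list(m = obs_m, u = nr - obs_m)
  }
  top <- draw(strand_p(pop$top1, pop$top2))
  bot <- draw(strand_p(pop$bot1, pop$bot2))

  cp <- pop$layout$cpgs
  calls <- rbind(
    data.frame(chrom = cp$chrom, pos = cp$pos, strand = "+",
               n_meth = top$m, n_unmeth = top$u, stringsAsFactors = FALSE),
    data.frame(chrom = cp$chrom, pos = cp$pos + 1L, strand = "-",
               n_meth = bot$m, n_unmeth = bot$u, stringsAsFactors = FALSE)
  )
  calls <- calls[order(calls$chrom, calls$pos), ]
  rownames(calls) <- NULL

  ## fragment coverage ~ DNA content: 1 duplex per cell unreplicated, 2 replicated
  frag <- do.call(rbind, lapply(names(pop$layout$chrom_lengths), function(ch) {
    len <- pop$layout$chrom_lengths[[ch]]
    starts <- seq(0L, len - 1L, by = frag_window)
    in_ch <- cp$chrom == ch
    win_of_cpg <- findInterval(cp$pos[in_ch], starts)
    repl_frac <- vapply(seq_along(starts), function(w) {
      j <- which(win_of_cpg == w)
      if (!length(j)) return(0)
      mean(pop$replicated[, which(in_ch)[j], drop = FALSE])
    }, numeric(1))
    lam <- frag_depth * (1 + repl_frac)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + frag_window, len),
               count = stats::rpois(length(starts), lam),
               stringsAsFactors = FALSE)
  }))

  list(calls = calls, fragments = frag,
       meta = list(seed = seed, depth = depth, conv_fail = conv_fail,
                   inapprop_conv = inapprop_conv, frag_depth = frag_depth))
}

#' Dump per-molecule dyad truth states as TSV
#'
#' One row per (cell, duplex, CpG) in a compact wide format: columns
#' `cell`, `duplex`, then one column per CpG with symbols `MM`, `MU`,
#' `UM`, `UU`. Intended for oracle tests against external callers.
#'
#' @param pop a `dyad_pop`.
#' @param path output TSV path.
#' @export
write_dyad_truth <- function(pop, path) {
  code <- function(top, bot) {
    out <- matrix("UU", nrow = nrow(top), ncol = ncol(top))
    out[top & bot] <- "MM"
    out[top & !bot] <- "MU"
    out[!top & bot] <- "UM"
    out[is.na(top) | is.na(bot)] <- "."
    out
  }
  cp <- pop$layout$cpgs
  cols <- paste0(cp$chrom, ":", cp$pos)
  d1 <- as.data.frame(code(pop$top1, pop$bot1))
  d2 <- as.data.frame(code(pop$top2, pop$bot2))
  names(d1) <- names(d2) <- cols
  out <- rbind(
    cbind(cell = seq_len(nrow(d1)), duplex = 1L, d1),
    cbind(cell = seq_len(nrow(d2)), duplex = 2L, d2)
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
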
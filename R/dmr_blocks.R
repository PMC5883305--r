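#' Pool replicate call sets by count addition
#'
#' @param callsets list of merged dyad call data.frames over the same CpG
#'   universe (same chrom/start in the same order).
#' @return one merged data.frame with summed counts.
#' @export
pool_replicates <- function(callsets) {
  ref <- callsets[[1]]
  for (d in callsets[-1]) {
    if (!identical(d$chrom, ref$chrom) || !identical(d$start, ref$start)) {
      mm_stop("replicates must share one CpG universe; run restrict_common first")
    }
    ref$n_meth <- ref$n_meth + d$n_meth
    ref$n_unmeth <- ref$n_unmeth + d$n_unmeth
  }
  ref
}

#' Coverage-weighted kernel smoothing of per-CpG methylation
#'
#' Local weighted mean over a window of neighboring CpGs, with weights
#' proportional to kernel value times coverage, so poorly covered CpGs
#' borrow strength from their neighbors (a light-weight stand-in for
#' local-likelihood smoothing). Smoothing never crosses chromosome
#' boundaries and is deterministic given its inputs.
#'
#' @param calls merged dyad calls (`chrom`, `start`, `n_meth`,
#'   `n_unmeth`).
#' @param bandwidth halfwidth of the smoothing window in CpGs (window =
#'   `2 * bandwidth + 1`); `0` returns raw fractions.
#' @param kernel `"uniform"` or `"tricube"` taper over CpG index
#'   distance.
#' @return numeric vector of smoothed methylation fractions, one per
#'   input CpG (NA where the window has zero total coverage).
#' @export
smooth_methylation <- function(calls, bandwidth = 2L, kernel = c("uniform", "tricube")) {
  kernel <- match.arg(kernel)
  cov <- calls$n_meth + calls$n_unmeth
  frac <- ifelse(cov > 0, calls$n_meth / cov, 0)
  if (bandwidth == 0) return(ifelse(cov > 0, frac, NA_real_))
  k <- if (kernel == "uniform") {
    rep(1, 2 * bandwidth + 1)
  } else {
    d <- abs(seq(-bandwidth, bandwidth)) / (bandwidth + 0.5)
    (1 - d^3)^3
  }
  out <- rep(NA_real_, nrow(calls))
  for (ch in unique(calls$chrom)) {
    i <- which(calls$chrom == ch)
    w <- cov[i]
    num <- stats::filter(w * frac[i], k, sides = 2)
    den <- stats::filter(w, k, sides = 2)
    ## filter() leaves NA at the ends; fall back to truncated windows there
    edge <- which(is.na(num))
    for (e in edge) {
      lo <- max(1, e - bandwidth); hi <- min(length(i), e + bandwidth)
      kk <- k[(lo - e + bandwidth + 1):(hi - e + bandwidth + 1)]
      num[e] <- sum(kk * w[lo:hi] * frac[i][lo:hi])
      den[e] <- sum(kk * w[lo:hi])
    }
    out[i] <- ifelse(den > 0, as.numeric(num) / as.numeric(den), NA_real_)
  }
  out
}

#' Call large differentially methylated blocks between two stages
#'
#' Candidate blocks are maximal runs of CpGs whose smoothed difference
#' (`stage2 - stage1`) exceeds `diff_cutoff` in absolute value with a
#' consistent sign, tolerating up to `max_gap` consecutive sub-threshold
#' CpGs inside a run. Because kernel smoothing attenuates block edges,
#' candidate bounds are then refined outward on the raw differences
#' (extending while the raw signed difference stays beyond the cutoff).
#' Blocks with fewer than `min_cpgs` CpGs are discarded. The per-block
#' `mean_diff` is computed on raw fractions.
#'
#' @param calls_a,calls_b merged (replicate-pooled) dyad calls for the
#'   two stages over the identical CpG universe (restrict to commonly
#'   covered CpGs first; mismatched universes are refused).
#' @param diff_cutoff minimum absolute smoothed difference (default 0.1).
#' @param min_cpgs minimum CpGs per block (default 10).
#' @param max_gap maximum run of sub-threshold CpGs bridged inside a
#'   block (default 2).
#' @param bandwidth smoothing halfwidth in CpGs, passed to
#'   [smooth_methylation()].
#' @return data.frame of class `dmr_blocks`: `chrom`, `start`, `end`
#'   (0-based half-open), `n_cpgs`, `mean_diff`, `direction`
#'   (`hypo`/`hyper` for stage2 lower/higher than stage1); sorted and
#'   pairwise disjoint.
#' @export
call_blocks <- function(calls_a, calls_b, diff_cutoff = 0.1, min_cpgs = 10L,
                        max_gap = 2L, bandwidth = 2L) {
  if (!identical(calls_a$chrom, calls_b$chrom) ||
      !identical(calls_a$start, calls_b$start)) {
    mm_stop("stage call sets have unmatched CpG universes")
  }
  tol <- 1e-9
  sm_a <- smooth_methylation(calls_a, bandwidth)
  sm_b <- smooth_methylation(calls_b, bandwidth)
  diff_s <- sm_b - sm_a
  raw_a <- meth_fraction(calls_a)
  raw_b <- meth_fraction(calls_b)
  diff_r <- raw_b - raw_a

  blocks <- list()
  for (ch in unique(calls_a$chrom)) {
    i <- which(calls_a$chrom == ch)
    ds <- diff_s[i]; dr <- diff_r[i]
    pos <- calls_a$start[i]
    for (sgn in c(-1, 1)) {
      pass <- !is.na(ds) & sgn * ds >= diff_cutoff - tol
      if (!any(pass)) next
      ## merge passing runs separated by <= max_gap failing CpGs
      runs <- rle(pass)
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1L
      seg <- data.frame(s = starts[runs$values], e = ends[runs$values])
      merged <- seg[1, , drop = FALSE]
      if (nrow(seg) > 1) {
        for (j in 2:nrow(seg)) {
          if (seg$s[j] - merged$e[nrow(merged)] - 1L <= max_gap) {
            merged$e[nrow(merged)] <- seg$e[j]
          } else {
            merged <- rbind(merged, seg[j, ])
          }
        }
      }
      ## refine bounds on raw differences: trim smoothing spill-over at the
      ## edges, then extend while the raw signed difference stays past the
      ## cutoff
      raw_pass <- function(x) !is.na(dr[x]) && sgn * dr[x] >= diff_cutoff - tol
      drop_seg <- logical(nrow(merged))
      for (j in seq_len(nrow(merged))) {
        s <- merged$s[j]; e <- merged$e[j]
        while (s <= e && !raw_pass(s)) s <- s + 1L
        while (e >= s && !raw_pass(e)) e <- e - 1L
        if (s > e) { drop_seg[j] <- TRUE; next }
        while (s > 1 && raw_pass(s - 1)) s <- s - 1L
        while (e < length(i) && raw_pass(e + 1)) e <- e + 1L
        merged$s[j] <- s; merged$e[j] <- e
      }
      merged <- merged[!drop_seg, , drop = FALSE]
      if (!nrow(merged)) next
      ## refinement can make same-sign segments touch; re-merge overlaps
      keep <- merged[1, , drop = FALSE]
      if (nrow(merged) > 1) {
        for (j in 2:nrow(merged)) {
          if (merged$s[j] <= keep$e[nrow(keep)] + 1L) {
            keep$e[nrow(keep)] <- max(keep$e[nrow(keep)], merged$e[j])
          } else {
            keep <- rbind(keep, merged[j, ])
          }
        }
      }
      for (j in seq_len(nrow(keep))) {
        s <- keep$s[j]; e <- keep$e[j]
        n_cpg <- e - s + 1L
        if (n_cpg < min_cpgs) next
        blocks[[length(blocks) + 1L]] <- data.frame(
          chrom = ch, start = pos[s], end = pos[e] + 2L,
          n_cpgs = n_cpg, mean_diff = mean(dr[s:e], na.rm = TRUE),
          direction = if (sgn < 0) "hypo" else "hyper",
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- if (length(blocks)) do.call(rbind, blocks) else {
    data.frame(chrom = character(), start = integer(), end = integer(),
               n_cpgs = integer(), mean_diff = numeric(), direction = character(),
               stringsAsFactors = FALSE)
  }
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  ## opposite-sign blocks can abut but never overlap; same-sign runs are maximal
  class(out) <- c("dmr_blocks", "data.frame")
  out
}

#' Fraction of the CpG universe inside hypo-/hypermethylated blocks
#'
#' @param blocks a `dmr_blocks` data.frame.
#' @param universe merged dyad calls defining the evaluated CpGs.
#' @return named numeric: `hypo`, `hyper` fractions of universe CpGs.
#' @export
cpg_proportions <- function(blocks, universe) {
  frac_in <- function(b) {
    if (!nrow(b)) return(0)
    hit <- !is.na(interval_index(universe$chrom, universe$start, b))
    mean(hit)
  }
  c(hypo = frac_in(blocks[blocks$direction == "hypo", , drop = FALSE]),
    hyper = frac_in(blocks[blocks$direction == "hyper", , drop = FALSE]))
}

#' Fraction of one block set intersected by another
#'
#' Computes the fraction of `blocks_b` that overlap at least one block of
#' `blocks_a` (half-open interval semantics; any overlap of >= 1 bp
#' counts, each b-block counted once) — the normalization used when
#' attributing later-stage DMRs to the initial demethylation event.
#'
#' @param blocks_a,blocks_b interval data.frames (`chrom`, `start`,
#'   `end`).
#' @return a single fraction in `[0, 1]` (NA if `blocks_b` is empty).
#' @export
intersect_fraction <- function(blocks_a, blocks_b) {
  if (!nrow(blocks_b)) return(NA_real_)
  if (!nrow(blocks_a)) return(0)
  a <- GenomicRanges::GRanges(blocks_a$chrom,
                              IRanges::IRanges(blocks_a$start + 1L, blocks_a$end))
  b <- GenomicRanges::GRanges(blocks_b$chrom,
                              IRanges::IRanges(blocks_b$start + 1L, blocks_b$end))
  mean(IRanges::overlapsAny(b, a))
}

#' Fisher's exact test of DMR / differential-expression overlap
#'
#' Builds the 2x2 table of genes inside vs outside DMR blocks against
#' differentially expressed vs not, over a stated gene universe, and
#' tests association with the two-sided exact test.
#'
#' @param genes_in_blocks character vector of genes overlapping DMRs.
#' @param de_genes character vector of differentially expressed genes.
#' @param universe character vector of all genes considered.
#' @return list with `table` (2x2 matrix) and `p_value`.
#' @export
fisher_overlap <- function(genes_in_blocks, de_genes, universe) {
  universe <- unique(universe)
  in_dmr <- universe %in% genes_in_blocks
  de <- universe %in% de_genes
  tab <- matrix(c(sum(in_dmr & de), sum(in_dmr & !de),
                  sum(!in_dmr & de), sum(!in_dmr & !de)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("in_DMR", "out_DMR"), c("DE", "not_DE")))
  list(table = tab, p_value = stats::fisher.test(tab)$p.value)
}

#' Write DMR blocks as BED6+
#'
#' Columns: chrom, start, end, name (direction), score
#' (`|mean_diff| * 1000`, capped at 1000), strand (`.`), n_cpgs,
#' mean_diff.
#'
#' @param blocks a `dmr_blocks` data.frame.
#' @param path BED path.
#' @export
write_blocks_bed <- function(blocks, path) {
  df <- data.frame(
    chrom = blocks$chrom, start = blocks$start, end = blocks$end,
    name = blocks$direction,
    score = pmin(1000, round(abs(blocks$mean_diff) * 1000)),
    strand = ".", n_cpgs = blocks$n_cpgs, mean_diff = blocks$mean_diff
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
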
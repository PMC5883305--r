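#' Join methylation windows with replication-timing intervals
#'
#' Emits every overlapping (window, RT interval) pair with both values —
#' half-open overlap semantics, any overlap of at least 1 bp counts —
#' mirroring a `bedtools intersect -wa -wb` of the two tracks.
#'
#' @param meth_windows data.frame `chrom`, `start`, `end`, `mean_meth`
#'   (from [window_mean()]).
#' @param rt an `rt_track` data.frame.
#' @param late_threshold optional `rt_value` cutoff; only RT intervals
#'   with `rt_value < late_threshold` (late-replicating) are joined.
#' @return data.frame with window coordinates, `mean_meth`, RT interval
#'   coordinates and `rt_value`, one row per overlapping pair.
#' @export
overlay <- function(meth_windows, rt, late_threshold = NULL) {
  if (!is.null(late_threshold)) rt <- rt[rt$rt_value < late_threshold, , drop = FALSE]
  if (!nrow(meth_windows) || !nrow(rt)) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      mean_meth = numeric(), rt_start = integer(),
                      rt_end = integer(), rt_value = numeric()))
  }
  w <- GenomicRanges::GRanges(meth_windows$chrom,
                              IRanges::IRanges(meth_windows$start + 1L, meth_windows$end))
  r <- GenomicRanges::GRanges(rt$chrom, IRanges::IRanges(rt$start + 1L, rt$end))
  hits <- GenomicRanges::findOverlaps(w, r)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  data.frame(
    chrom = meth_windows$chrom[qi],
    start = meth_windows$start[qi], end = meth_windows$end[qi],
    mean_meth = meth_windows$mean_meth[qi],
    rt_start = rt$start[si], rt_end = rt$end[si], rt_value = rt$rt_value[si],
    stringsAsFactors = FALSE
  )
}

#' Per-stage correlation of window methylation with replication timing
#'
#' For each stage, Pearson r between 100-kb (or other) window methylation
#' and `rt_value` over windows overlapping late-replicating domains
#' (`rt_value` below `late_threshold`, default the track median). An
#' abrupt switch in the sign of r between the meiotic S-phase stage (PL)
#' and the following stage (L) is the genome-scale diagnostic of
#' replication-coupled demethylation: during S, still-unreplicated late
#' domains retain high methylation; once replicated, they are the least
#' recovered.
#'
#' @param stages named list of window data.frames (from
#'   [window_mean()]), in stage order (e.g. Spg, PL, L, Z, P, D, Spz).
#' @param rt an `rt_track`.
#' @param late_threshold `rt_value` cutoff defining late domains
#'   (default: median of the track).
#' @param switch_stages length-2 character vector naming the stages whose
#'   correlation signs are compared (default `c("PL", "L")`; falls back
#'   to the 2nd and 3rd stages when names are absent).
#' @param min_abs_r minimum `|r|` in both compared stages for a switch to
#'   count as prominent (default 0.3); two near-zero correlations of
#'   opposite sign are noise, not a directionality switch.
#' @return list of class `rt_correlation_series`: data.frame `series`
#'   (`stage`, `r`, `n_pairs`, `undefined`), `late_threshold`,
#'   `sign_switch` flag.
#' @export
stage_correlation_series <- function(stages, rt, late_threshold = NULL,
                                     switch_stages = c("PL", "L"),
                                     min_abs_r = 0.3) {
  late_threshold <- late_threshold %||% stats::median(rt$rt_value)
  series <- do.call(rbind, lapply(names(stages), function(st) {
    j <- overlay(stages[[st]], rt, late_threshold = late_threshold)
    j <- j[!is.na(j$mean_meth), , drop = FALSE]
    if (nrow(j) < 3 || stats::sd(j$mean_meth) == 0 || stats::sd(j$rt_value) == 0) {
      data.frame(stage = st, r = NA_real_, n_pairs = nrow(j), undefined = TRUE)
    } else {
      data.frame(stage = st, r = stats::cor(j$mean_meth, j$rt_value),
                 n_pairs = nrow(j), undefined = FALSE)
    }
  }))
  pick <- function(nm, fallback) {
    if (nm %in% series$stage) series$r[series$stage == nm] else series$r[fallback]
  }
  r1 <- pick(switch_stages[1], min(2, nrow(series)))
  r2 <- pick(switch_stages[2], min(3, nrow(series)))
  sign_switch <- isTRUE(!is.na(r1) && !is.na(r2) && sign(r1) * sign(r2) < 0 &&
                          abs(r1) >= min_abs_r && abs(r2) >= min_abs_r)
  structure(list(series = series, late_threshold = late_threshold,
                 sign_switch = sign_switch),
            class = "rt_correlation_series")
}

#' @export
print.rt_correlation_series <- function(x, ...) {
  cat(sprintf("rt_correlation_series (late: rt_value < %.3g); sign switch: %s\n",
              x$late_threshold, x$sign_switch))
  print(x$series, row.names = FALSE)
  invisible(x)
}
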
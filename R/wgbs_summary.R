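#' Clip methylation calls at M-bias-prone read cycles
#'
#' Removes per-read methylation evidence from the first cycles of each
#' mate (where 5' M-bias concentrates) and the last cycle(s) of both, the
#' standard remedy after inspecting M-bias plots. Defaults: first 6 nt of
#' read 1, first 10 nt of read 2, last 1 nt of both.
#'
#' @param calls data.frame of per-call records with columns
#'   `read_of_pair` (1 or 2), `cycle` (1-based position in the read) and
#'   `read_len`; other columns pass through.
#' @param clip5_r1,clip5_r2 cycles removed from the 5' end of read 1 / 2.
#' @param clip3 cycles removed from the 3' end of both reads.
#' @return the filtered data.frame.
#' @export
mbias_clip <- function(calls, clip5_r1 = 6L, clip5_r2 = 10L, clip3 = 1L) {
  need <- c("read_of_pair", "cycle", "read_len")
  miss <- setdiff(need, names(calls))
  if (length(miss)) {
    mm_stop("calls lack cycle metadata (missing: ", paste(miss, collapse = ", "), ")")
  }
  clip5 <- ifelse(calls$read_of_pair == 1L, clip5_r1, clip5_r2)
  keep <- calls$cycle > clip5 & calls$cycle <= calls$read_len - clip3
  calls[keep, , drop = FALSE]
}

#' Merge strand-specific CpG calls into dyad records
#'
#' A plus-strand record at position `p` and a minus-strand record at
#' `p + 1` (the paired C on the other strand) are summed into one dyad
#' record covering `[p, p + 2)`. Unpaired records become single-strand
#' dyads. Duplicate records for the same (chrom, pos, strand) indicate
#' input corruption and raise an error.
#'
#' @param calls data.frame with `chrom`, `pos` (0-based C position),
#'   `strand` (`+`/`-`), `n_meth`, `n_unmeth`.
#' @return data.frame with `chrom`, `start`, `end`, `n_meth`, `n_unmeth`
#'   keyed by dyad coordinate, sorted.
#' @export
merge_strands <- function(calls) {
  need <- c("chrom", "pos", "strand", "n_meth", "n_unmeth")
  if (!all(need %in% names(calls))) mm_stop("calls need ", paste(need, collapse = ", "))
  key <- paste(calls$chrom, calls$pos, calls$strand)
  if (anyDuplicated(key)) mm_stop("duplicate strand records at the same position: corrupted input")
  dyad_start <- ifelse(calls$strand == "-", calls$pos - 1L, calls$pos)
  agg <- stats::aggregate(
    calls[, c("n_meth", "n_unmeth")],
    by = list(chrom = calls$chrom, start = dyad_start),
    FUN = sum
  )
  agg <- agg[order(agg$chrom, agg$start), ]
  data.frame(chrom = agg$chrom, start = agg$start, end = agg$start + 2L,
             n_meth = agg$n_meth, n_unmeth = agg$n_unmeth,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Restrict samples to commonly covered CpGs
#'
#' Keeps exactly the dyads covered by at least one read in every sample
#' and reports the retained fraction per sample.
#'
#' @param callsets named list of merged dyad call data.frames (from
#'   [merge_strands()]).
#' @return list with `callsets` (filtered, common order) and `retained`
#'   (fraction of each sample's covered dyads kept).
#' @export
restrict_common <- function(callsets) {
  if (!length(callsets)) mm_stop("no callsets given")
  keys <- lapply(callsets, function(d) {
    covered <- d$n_meth + d$n_unmeth > 0
    paste(d$chrom[covered], d$start[covered])
  })
  common <- Reduce(intersect, keys)
  if (!length(common)) warning("no commonly covered CpGs; result is empty")
  out <- lapply(callsets, function(d) {
    d[match(common, paste(d$chrom, d$start)), , drop = FALSE]
  })
  out <- lapply(out, function(d) { rownames(d) <- NULL; d })
  list(callsets = out,
       retained = vapply(keys, function(k) length(common) / max(1L, length(k)), numeric(1)))
}

meth_fraction <- function(calls) calls$n_meth / (calls$n_meth + calls$n_unmeth)

#' Mean methylation in non-overlapping bins of k CpGs
#'
#' Bin i covers CpGs `[i*k, (i+1)*k)` in coordinate order within each
#' chromosome; the bin value is the mean of per-CpG methylation
#' fractions. A trailing bin with fewer than `k` CpGs is dropped and the
#' number of dropped CpGs recorded.
#'
#' @param calls merged dyad calls (from [merge_strands()]).
#' @param k CpGs per bin (paper-scale default 500).
#' @return data.frame `chrom`, `bin`, `n_cpgs`, `mean_meth`, with
#'   attribute `dropped_cpgs`.
#' @export
bin_mean <- function(calls, k = 500L) {
  if (k < 1) mm_stop("k must be >= 1")
  calls <- calls[order(calls$chrom, calls$start), ]
  frac <- meth_fraction(calls)
  dropped <- 0L
  out <- lapply(unique(calls$chrom), function(ch) {
    f <- frac[calls$chrom == ch]
    nb <- length(f) %/% k
    dropped <<- dropped + length(f) - nb * k
    if (nb == 0) return(NULL)
    idx <- rep(seq_len(nb), each = k)
    data.frame(chrom = ch, bin = seq_len(nb), n_cpgs = k,
               mean_meth = as.numeric(tapply(f[seq_len(nb * k)], idx, mean)),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  attr(res, "dropped_cpgs") <- dropped
  res
}

#' Mean methylation in fixed-width genomic windows
#'
#' Non-overlapping tiling from coordinate 0; window value is the mean of
#' per-CpG methylation fractions of dyads whose start falls in the
#' window. Windows without CpGs get `NA`.
#'
#' @param calls merged dyad calls.
#' @param width window width in bp (chromosome-trace default 100 kb).
#' @return data.frame `chrom`, `start`, `end`, `n_cpgs`, `mean_meth`.
#' @export
window_mean <- function(calls, width = 100000L) {
  if (width < 1) mm_stop("width must be positive")
  frac <- meth_fraction(calls)
  out <- lapply(unique(calls$chrom), function(ch) {
    in_ch <- calls$chrom == ch
    pos <- calls$start[in_ch]
    w <- pos %/% width
    wmax <- max(w)
    n <- tabulate(w + 1L, nbins = wmax + 1L)
    s <- rep(0, wmax + 1L)
    agg <- tapply(frac[in_ch], w, mean)
    s[as.integer(names(agg)) + 1L] <- agg
    data.frame(chrom = ch, start = (0:wmax) * width,
               end = (0:wmax + 1L) * width, n_cpgs = n,
               mean_meth = ifelse(n > 0, s, NA_real_),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Read-count coverage in fixed windows, normalized to the largest sample
#'
#' Re-tiles per-fragment (or per-window) counts into non-overlapping
#' windows and scales each sample by
#' `largest sample total / sample total`, so samples are comparable and
#' under-replicated regions stand out as reduced coverage.
#'
#' @param fragments named list of data.frames `chrom`, `start`, `end`,
#'   `count` (one per sample); a single data.frame is treated as one
#'   sample.
#' @param width window width in bp (default 5 kb). Counts are assigned to
#'   the window containing the fragment start.
#' @param normalize `"largest"` (default) or `"none"`.
#' @return named list of data.frames `chrom`, `start`, `end`, `count`,
#'   `norm_count`.
#' @export
coverage_windows <- function(fragments, width = 5000L, normalize = c("largest", "none")) {
  normalize <- match.arg(normalize)
  if (is.data.frame(fragments)) fragments <- list(sample = fragments)
  tiled <- lapply(fragments, function(fr) {
    out <- lapply(unique(fr$chrom), function(ch) {
      d <- fr[fr$chrom == ch, ]
      w <- d$start %/% width
      wmax <- max(w)
      cnt <- rep(0, wmax + 1L)
      agg <- tapply(d$count, w, sum)
      cnt[as.integer(names(agg)) + 1L] <- agg
      data.frame(chrom = ch, start = (0:wmax) * width,
                 end = (0:wmax + 1L) * width, count = cnt,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
  totals <- vapply(tiled, function(d) sum(d$count), numeric(1))
  scale <- if (normalize == "largest") max(totals) / pmax(totals, 1) else rep(1, length(tiled))
  Map(function(d, s) { d$norm_count <- d$count * s; d }, tiled, scale)
}

#' Aggregate methylation over annotated feature classes
#'
#' Per feature class, CpGs falling inside the class's intervals (a CpG in
#' two overlapping classes contributes to both) are taken in coordinate
#' order, chunked into consecutive non-overlapping groups of `chunk`
#' CpGs, and averaged; trailing partial chunks are dropped when
#' `drop_partial` (recorded per class).
#'
#' @param calls merged dyad calls.
#' @param annotation named list of interval data.frames (`chrom`,
#'   `start`, `end`), e.g. `layout$annotation` plus
#'   [imprinted_dmr_annotation()] sets.
#' @param chunk CpGs per aggregation chunk (default 100).
#' @param drop_partial drop trailing partial chunks (default TRUE).
#' @return list of class `feature_summary`: per class, the vector of
#'   chunk means; plus a `summary` data.frame (class, n_cpgs, n_chunks,
#'   mean, dropped_cpgs).
#' @export
feature_aggregate <- function(calls, annotation, chunk = 100L, drop_partial = TRUE) {
  frac <- meth_fraction(calls)
  chunks <- lapply(names(annotation), function(cls) {
    iv <- annotation[[cls]]
    hit <- !is.na(interval_index(calls$chrom, calls$start, iv))
    f <- frac[hit][order(calls$chrom[hit], calls$start[hit])]
    nb <- if (drop_partial) length(f) %/% chunk else ceiling(length(f) / chunk)
    if (nb == 0) return(list(means = numeric(0), n = length(f), dropped = length(f)))
    used <- if (drop_partial) nb * chunk else length(f)
    idx <- ceiling(seq_len(used) / chunk)
    list(means = as.numeric(tapply(f[seq_len(used)], idx, mean)),
         n = length(f), dropped = length(f) - used)
  })
  names(chunks) <- names(annotation)
  summary <- data.frame(
    class = names(annotation),
    n_cpgs = vapply(chunks, `[[`, numeric(1), "n"),
    n_chunks = vapply(chunks, function(x) length(x$means), numeric(1)),
    mean = vapply(chunks, function(x) if (length(x$means)) mean(x$means) else NA_real_, numeric(1)),
    dropped_cpgs = vapply(chunks, `[[`, numeric(1), "dropped"),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(chunks = lapply(chunks, `[[`, "means"), summary = summary),
            class = "feature_summary")
}

#' Pearson correlation between two binned replicates
#'
#' @param binned_a,binned_b numeric vectors (e.g. `mean_meth` of
#'   [bin_mean()] on two biological replicates) or data.frames carrying a
#'   `mean_meth` column.
#' @return Pearson r (complete pairs only).
#' @export
replicate_correlation <- function(binned_a, binned_b) {
  v <- function(x) if (is.data.frame(x)) x$mean_meth else x
  stats::cor(v(binned_a), v(binned_b), use = "complete.obs")
}

#' Read / write Bismark-style coverage files
#'
#' The Bismark coverage dialect is 1-based inclusive:
#' `chrom  start  end  %meth  count_methylated  count_unmethylated`.
#' Conversion to the package's 0-based half-open dyad records happens at
#' this boundary. Records in non-CpG context are not representable here;
#' callers filtering Bismark cytosine reports should drop CHG/CHH before
#' writing (non-CpG methylation is excluded from all summaries).
#'
#' @param calls merged dyad calls (`chrom`, `start`, `end`, `n_meth`,
#'   `n_unmeth`).
#' @param path coverage file path.
#' @rdname bismark_cov
#' @export
write_bismark_cov <- function(calls, path) {
  tot <- calls$n_meth + calls$n_unmeth
  df <- data.frame(
    chrom = calls$chrom,
    start = calls$start + 1L,  # 1-based inclusive
    end = calls$start + 1L,
    pct = ifelse(tot > 0, 100 * calls$n_meth / tot, 0),
    n_meth = calls$n_meth, n_unmeth = calls$n_unmeth
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname bismark_cov
#' @export
read_bismark_cov <- function(path) {
  df <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE,
                      col.names = c("chrom", "start", "end", "pct", "n_meth", "n_unmeth"),
                      colClasses = c("character", "integer", "integer",
                                     "numeric", "integer", "integer")),
    error = function(e) mm_stop("malformed coverage file '", path, "': ", conditionMessage(e))
  )
  data.frame(chrom = df$chrom, start = df$start - 1L, end = df$start + 1L,
             n_meth = df$n_meth, n_unmeth = df$n_unmeth,
             stringsAsFactors = FALSE)
}
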
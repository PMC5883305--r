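#' Align bisulfite reads to the consensus in collapsed alphabets
#'
#' Ungapped exhaustive scan of each read (and its reverse complement)
#' against the four bisulfite-converted strands of the consensus:
#' original top (OT), original bottom (OB), and their PCR complements
#' (CTOT, CTOB). In the reduced alphabet, consensus C positions accept
#' C or T on the OT/CTOT pairing and consensus G positions accept G or A
#' on the OB/CTOB pairing. The best placement wins if its mismatch count
#' is at most `max_mismatch`; a tie for best (across or within strand
#' classes) discards the read as ambiguous.
#'
#' At each consensus CpG the aligned base determines the methylation
#' call: C = methylated / T = unmethylated on top-reporting classes
#' (OT, CTOT), G = methylated / A = unmethylated on bottom-reporting
#' classes (OB, CTOB).
#'
#' @param reads character vector of read sequences.
#' @param consensus an [l1_consensus()].
#' @param max_mismatch maximum mismatches in the overlap (default 3).
#' @param min_overlap minimum read/consensus overlap in nt (default 20).
#' @return list of class `bis_alignments`: data.frame `aln` with columns
#'   `strand_class` (`OT`/`OB`/`CTOT`/`CTOB` or `NA`), `offset`,
#'   `mismatches`, `status` (`aligned`/`unaligned`/`ambiguous`), `strand`
#'   (`top`/`bottom` reported); and `calls`, a character matrix (reads x
#'   consensus CpGs) with entries `M`, `U` or `NA`.
#' @export
align_bisulfite <- function(reads, consensus, max_mismatch = 3L,
                            min_overlap = 20L) {
  stopifnot(inherits(consensus, "l1_consensus"))
  n <- length(reads)
  cons <- strsplit(consensus$sequence, "")[[1]]
  L <- length(cons)

  base_code <- function(x) {
    m <- match(strsplit(toupper(x), "")[[1]], c("A", "C", "G", "T")) - 1L
    m[is.na(m)] <- -1L
    m
  }
  enc <- function(seqs) {
    rl <- nchar(seqs)
    mat <- matrix(-1L, length(seqs), max(rl))
    for (i in seq_along(seqs)) mat[i, seq_len(rl[i])] <- base_code(seqs[i])
    list(q = mat, len = as.integer(rl))
  }

  ## acceptance tables: exact match everywhere, plus bisulfite collapse
  exact <- matrix(0L, L, 4)
  exact[cbind(seq_len(L), match(cons, c("A", "C", "G", "T")))] <- 1L
  acc_ct <- exact; acc_ct[cons == "C", 4] <- 1L  # C may read T
  acc_ga <- exact; acc_ga[cons == "G", 1] <- 1L  # G may read A

  fwd <- enc(reads)
  rev <- enc(revcomp(reads))

  ## mode table: query orientation x collapse -> strand class
  modes <- data.frame(
    class = c("OT", "CTOB", "CTOT", "OB"),
    orient = c("fwd", "fwd", "rev", "rev"),
    collapse = c("ct", "ga", "ct", "ga"),
    strand = c("top", "bottom", "top", "bottom"),
    stringsAsFactors = FALSE
  )
  res <- lapply(seq_len(nrow(modes)), function(k) {
    qq <- if (modes$orient[k] == "fwd") fwd else rev
    acc <- if (modes$collapse[k] == "ct") acc_ct else acc_ga
    .scan_mode(qq$q, qq$len, acc, as.integer(max_mismatch), as.integer(min_overlap))
  })

  mmx <- sapply(res, `[[`, "mismatch")
  offs <- sapply(res, `[[`, "offset")
  nbest <- sapply(res, `[[`, "n_best")
  if (n == 1) { mmx <- rbind(mmx); offs <- rbind(offs); nbest <- rbind(nbest) }

  best_mm <- apply(mmx, 1, min)
  aligned <- best_mm <= max_mismatch
  ties <- rowSums(nbest * (mmx == best_mm))
  ambiguous <- aligned & ties > 1
  winner <- apply(mmx, 1, which.min)

  status <- ifelse(!aligned, "unaligned", ifelse(ambiguous, "ambiguous", "aligned"))
  cls <- ifelse(status == "aligned", modes$class[winner], NA_character_)
  strand <- ifelse(status == "aligned", modes$strand[winner], NA_character_)
  offset <- ifelse(status == "aligned", offs[cbind(seq_len(n), winner)], NA_integer_)

  ## per-CpG methylation calls from the winning placement
  calls <- matrix(NA_character_, n, length(consensus$cpg_pos))
  for (i in which(status == "aligned")) {
    k <- winner[i]
    qq <- if (modes$orient[k] == "fwd") fwd else rev
    qlen <- qq$len[i]
    call_pos <- if (modes$collapse[k] == "ct") consensus$cpg_pos else consensus$cpg_pos + 1L
    j <- call_pos - offset[i]               # 0-based index into query
    ok <- j >= 0 & j < qlen
    b <- rep(NA_integer_, length(j))
    b[ok] <- qq$q[i, j[ok] + 1L]
    calls[i, ] <- if (modes$collapse[k] == "ct") {
      ifelse(b == 1L, "M", ifelse(b == 3L, "U", NA))
    } else {
      ifelse(b == 2L, "M", ifelse(b == 0L, "U", NA))
    }
  }

  structure(list(
    aln = data.frame(strand_class = cls, offset = offset,
                     mismatches = ifelse(aligned & !ambiguous, best_mm, NA_integer_),
                     status = status, strand = strand, stringsAsFactors = FALSE),
    calls = calls, cpg_pos = consensus$cpg_pos
  ), class = "bis_alignments")
}

#' Stitch read-pair alignments into dyad rows
#'
#' A pair contributes one row of the dyad matrix when its two reads align
#' to complementary strand classes — one reporting the top strand
#' (OT/CTOT) and one the bottom (OB/CTOB), which includes the
#' {read 1 OB + read 2 CTOT} and {read 2 OB + read 1 CTOT} pairings of a
#' hairpin library. At each consensus CpG the row holds the two-letter
#' dyad code (`MM`, `MU`, `UM`, `UU`; top strand first) or `.` when
#' either strand is uncalled. Pairs whose classes do not form a
#' complementary set are dropped and counted.
#'
#' @param aln1,aln2 `bis_alignments` of read 1 and read 2 (same order).
#' @return object of class `dyad_matrix`: character matrix (pairs kept x
#'   dyads), plus `dropped` counts by reason.
#' @export
stitch_dyads <- function(aln1, aln2) {
  stopifnot(nrow(aln1$aln) == nrow(aln2$aln))
  s1 <- aln1$aln$strand; s2 <- aln2$aln$strand
  ok1 <- aln1$aln$status == "aligned"; ok2 <- aln2$aln$status == "aligned"
  complementary <- ok1 & ok2 & s1 != s2
  keep <- which(complementary)

  top_calls <- ifelse(matrix(s1[keep] == "top", length(keep), ncol(aln1$calls)),
                      aln1$calls[keep, , drop = FALSE],
                      aln2$calls[keep, , drop = FALSE])
  bot_calls <- ifelse(matrix(s1[keep] == "bottom", length(keep), ncol(aln1$calls)),
                      aln1$calls[keep, , drop = FALSE],
                      aln2$calls[keep, , drop = FALSE])
  row <- matrix(".", length(keep), ncol(aln1$calls))
  both <- !is.na(top_calls) & !is.na(bot_calls)
  row[both] <- paste0(top_calls[both], bot_calls[both])

  amb <- aln1$aln$status == "ambiguous" | aln2$aln$status == "ambiguous"
  dropped <- c(
    unaligned = sum((!ok1 | !ok2) & !amb),
    ambiguous = sum(amb),
    non_complementary = sum(ok1 & ok2 & s1 == s2)
  )
  structure(list(matrix = row, kept = keep, cpg_pos = aln1$cpg_pos,
                 dropped = dropped),
            class = "dyad_matrix")
}

#' Summarize a dyad matrix into per-dyad state proportions
#'
#' Per dyad, counts rows by duplex state (`MM`, hemimethylated
#' `MU`/`UM`, `UU`) over fully informative rows. Reports, per dyad, the
#' hemimethylation proportion, the strand-level methylation including
#' hemimethylation `(2 nMM + nHemi) / (2 total)`, and the methylation
#' excluding hemimethylation `nMM / (nMM + nUU)` — the statistic that is
#' invariant under passive dilution. A read is fully unmethylated when
#' every assayed dyad is `UU` on both strands; the fraction of such reads
#' (over reads informative at all assayed dyads) is reported.
#'
#' @param dm a `dyad_matrix` (or plain character matrix of dyad codes).
#' @param assayed integer indices of the assayed dyad columns (default:
#'   all columns).
#' @return list of class `dyad_summary`: `per_dyad` data.frame (`n_MM`,
#'   `n_hemi`, `n_UU`, `prop_hemi`, `meth_incl_hemi`, `meth_excl_hemi`,
#'   `undefined` flag for dyads without informative rows),
#'   `fully_unmethylated_fraction`, `n_informative_reads`, `n_reads`.
#' @export
summarize_dyads <- function(dm, assayed = NULL) {
  mat <- if (inherits(dm, "dyad_matrix")) dm$matrix else dm
  if (!is.matrix(mat) || nrow(mat) == 0) mm_stop("empty dyad matrix")
  nd <- ncol(mat)
  assayed <- assayed %||% seq_len(nd)

  n_MM <- colSums(mat == "MM")
  n_hemi <- colSums(mat == "MU" | mat == "UM")
  n_UU <- colSums(mat == "UU")
  tot <- n_MM + n_hemi + n_UU
  per_dyad <- data.frame(
    dyad = seq_len(nd),
    n_MM = n_MM, n_hemi = n_hemi, n_UU = n_UU,
    prop_hemi = ifelse(tot > 0, n_hemi / tot, NA_real_),
    meth_incl_hemi = ifelse(tot > 0, (2 * n_MM + n_hemi) / (2 * tot), NA_real_),
    meth_excl_hemi = ifelse(n_MM + n_UU > 0, n_MM / (n_MM + n_UU), NA_real_),
    undefined = tot == 0
  )

  sub <- mat[, assayed, drop = FALSE]
  informative <- rowSums(sub == ".") == 0
  fully_unmeth <- informative & rowSums(sub == "UU") == length(assayed)
  structure(list(
    per_dyad = per_dyad,
    fully_unmethylated_fraction =
      if (any(informative)) sum(fully_unmeth) / sum(informative) else NA_real_,
    n_informative_reads = sum(informative),
    n_reads = nrow(mat),
    assayed = assayed
  ), class = "dyad_summary")
}

#' @export
print.dyad_summary <- function(x, ...) {
  cat(sprintf(
    "dyad_summary: %d reads (%d informative at %d assayed dyads); fully unmethylated %.3f%%\n",
    x$n_reads, x$n_informative_reads, length(x$assayed),
    100 * x$fully_unmethylated_fraction
  ))
  print(x$per_dyad, row.names = FALSE)
  invisible(x)
}

#' End-to-end hairpin caller
#'
#' Align both reads of each pair, stitch complementary alignments into
#' dyad rows and summarize. Convenience wrapper used by the pipeline.
#'
#' @param read1,read2 character vectors of the two reads per pair.
#' @param consensus an [l1_consensus()].
#' @param max_mismatch,min_overlap alignment parameters.
#' @param assayed assayed dyad columns for classification.
#' @return list with `alignments` (pair of `bis_alignments`), `matrix`
#'   (`dyad_matrix`) and `summary` (`dyad_summary`).
#' @export
call_hairpin <- function(read1, read2, consensus = l1_consensus(),
                         max_mismatch = 3L, min_overlap = 20L,
                         assayed = NULL) {
  a1 <- align_bisulfite(read1, consensus, max_mismatch, min_overlap)
  a2 <- align_bisulfite(read2, consensus, max_mismatch, min_overlap)
  dm <- stitch_dyads(a1, a2)
  list(alignments = list(a1, a2), matrix = dm,
       summary = summarize_dyads(dm, assayed = assayed))
}

#' Clip read 3' ends and drop short reads
#'
#' Light trimming in the spirit of adapter/quality trimming of amplicon
#' libraries: removes a fixed number of bases from the 3' end of each
#' read and discards pairs in which either mate falls below `min_len`.
#'
#' @param read1,read2 character vectors.
#' @param clip3 bases clipped from each 3' end (default 6).
#' @param min_len minimum retained length (default 100).
#' @return list with clipped `read1`, `read2` and logical `kept`.
#' @export
trim_reads <- function(read1, read2, clip3 = 6L, min_len = 100L) {
  cl <- function(x) substr(x, 1L, pmax(0L, nchar(x) - clip3))
  r1 <- cl(read1); r2 <- cl(read2)
  kept <- nchar(r1) >= min_len & nchar(r2) >= min_len
  list(read1 = r1[kept], read2 = r2[kept], kept = kept)
}

#' Write / read a dyad matrix as TSV
#'
#' One row per read pair, one column per consensus dyad, symbols
#' `MM`/`MU`/`UM`/`UU`/`.`.
#'
#' @param dm a `dyad_matrix`.
#' @param path TSV path.
#' @rdname dyad_matrix_io
#' @export
write_dyad_matrix <- function(dm, path) {
  df <- as.data.frame(dm$matrix, stringsAsFactors = FALSE)
  names(df) <- paste0("dyad_", dm$cpg_pos)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname dyad_matrix_io
#' @export
read_dyad_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  structure(list(
    matrix = as.matrix(df),
    cpg_pos = as.integer(sub("dyad_", "", names(df))),
    kept = seq_len(nrow(df)), dropped = c()
  ), class = "dyad_matrix")
}
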
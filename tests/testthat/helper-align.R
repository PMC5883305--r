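## independent brute-force bisulfite aligner used as oracle: plain R loops,
## no shared code with the package's scan
brute_align <- function(read, cons_seq, max_mismatch = 3, min_overlap = 20) {
  cons <- strsplit(toupper(cons_seq), "")[[1]]
  L <- length(cons)
  rc <- function(x) chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  match_base <- function(cb, qb, mode) {
    if (cb == qb) return(TRUE)
    if (mode == "ct" && cb == "C" && qb == "T") return(TRUE)
    if (mode == "ga" && cb == "G" && qb == "A") return(TRUE)
    FALSE
  }
  best <- list(mm = max_mismatch + 1, hits = 0, class = NA, offset = NA)
  combos <- list(OT = c("fwd", "ct"), CTOB = c("fwd", "ga"),
                 CTOT = c("rev", "ct"), OB = c("rev", "ga"))
  for (cl in names(combos)) {
    q <- if (combos[[cl]][1] == "fwd") toupper(read) else rc(toupper(read))
    qc <- strsplit(q, "")[[1]]
    lq <- length(qc)
    for (off in (-(lq - min_overlap)):(L - min_overlap)) {
      p0 <- max(0, -off); p1 <- min(lq, L - off)
      if (p1 - p0 < min_overlap) next
      mm <- 0
      for (p in (p0 + 1):p1) {
        if (!match_base(cons[off + p], qc[p], combos[[cl]][2])) mm <- mm + 1
      }
      if (mm <= max_mismatch) {
        if (mm < best$mm) best <- list(mm = mm, hits = 1, class = cl, offset = off)
        else if (mm == best$mm) best$hits <- best$hits + 1
      }
    }
  }
  best
}
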
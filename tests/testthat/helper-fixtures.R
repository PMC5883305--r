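## small fixtures shared across test files; all built in code

tiny_layout <- function(n_chrom = 1, cpgs_per_chrom = 200, spacing = 50L) {
  sim_layout(n_chrom = n_chrom, cpgs_per_chrom = cpgs_per_chrom,
             spacing = spacing, l1_per_chrom = 2, l1_cpgs = 5,
             cgi_per_chrom = 0, seed = 42)
}

## two equal-size domains per chromosome: first early, second late
two_domain_rt <- function(layout) {
  out <- do.call(rbind, lapply(names(layout$chrom_lengths), function(ch) {
    len <- layout$chrom_lengths[[ch]]
    data.frame(chrom = ch, start = c(0L, len %/% 2L), end = c(len %/% 2L, len),
               rt_value = c(2, -2), stringsAsFactors = FALSE)
  }))
  class(out) <- c("rt_track", "data.frame")
  out
}

## merged-dyad call set from explicit per-CpG fractions at fixed coverage
calls_from_fractions <- function(frac, coverage = 50L, chrom = "chr1", spacing = 100L) {
  n_m <- round(frac * coverage)
  data.frame(chrom = chrom, start = (seq_along(frac) - 1L) * spacing,
             end = (seq_along(frac) - 1L) * spacing + 2L,
             n_meth = n_m, n_unmeth = coverage - n_m,
             stringsAsFactors = FALSE)
}

## independent brute-force interval-overlap check (half-open, any bp)
overlaps_brute <- function(a, b) {
  vapply(seq_len(nrow(b)), function(j) {
    any(a$chrom == b$chrom[j] & a$start < b$end[j] & a$end > b$start[j])
  }, logical(1))
}
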
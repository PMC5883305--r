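test_that("consensus CpG scan equals an independent regular-expression count", {
  cons <- l1_consensus()
  s <- cons$sequence
  naive <- which(vapply(seq_len(nchar(s) - 1), function(i)
    substr(s, i, i + 1) == "CG", logical(1))) - 1L
  expect_identical(cons$cpg_pos, as.integer(naive))
  expect_gt(length(cons$cpg_pos), 0)
  ## scan handles overlapping-window edge cases
  expect_identical(scan_cpg("cgcgcg"), c(0L, 2L, 4L))
  expect_identical(scan_cpg("AAAA"), integer(0))
})

test_that("hairpin construction folds arms around the linker", {
  ## toy duplex with its single CpG dyad methylated on both strands
  hp <- build_hairpin("ACCGGT", top = matrix(TRUE, 1, 1),
                      bottom = matrix(TRUE, 1, 1),
                      enzyme_site = "ACCGGT", linker = "TTTT")
  expect_equal(hp$arm, "ACCGGT")
  s <- meiometh:::convert_hairpins(hp, conv = 1, seed = 1)
  ## both arms' CpG C survive conversion: ACCGGT -> ATCGGT, revcomp arm ACCGGT -> ATCGGT
  expect_equal(s, "ATCGGTTTTTATCGGT")

  ## hemimethylated dyad: top kept, bottom converted
  hp2 <- build_hairpin("ACCGGT", top = matrix(TRUE, 1, 1),
                       bottom = matrix(FALSE, 1, 1),
                       enzyme_site = "ACCGGT", linker = "TTTT")
  s2 <- meiometh:::convert_hairpins(hp2, conv = 1, seed = 1)
  expect_equal(s2, "ATCGGTTTTTATTGGT")

  ## element lacking the restriction site is excluded and counted
  hp3 <- build_hairpin("AAAACCCC", top = matrix(TRUE, 1, 0),
                       bottom = matrix(TRUE, 1, 0))
  expect_null(hp3$arm)
  expect_equal(hp3$n_excluded, 1L)
})

test_that("bisulfite conversion touches only unmethylated cytosines", {
  expect_equal(bisulfite_convert("CCGG", meth = FALSE, conv = 1), "TTGG")
  expect_equal(bisulfite_convert("CCGG", meth = c(1L), conv = 1), "TCGG")
  expect_equal(bisulfite_convert("ATGN", meth = FALSE, conv = 1), "ATGN")
  ## binomial oracle at conv = 0.99
  out <- bisulfite_convert(strrep("CA", 1000), meth = FALSE, conv = 0.99, seed = 3)
  n_conv <- lengths(regmatches(out, gregexpr("T", out)))
  expect_lt(abs(n_conv - 990), 3 * sqrt(1000 * 0.99 * 0.01))
})

test_that("error-free reads decode the exact arm sequences", {
  cons <- l1_consensus()
  mols <- make_l1_population(50, cons, hemi_frac = 0, meth_level = 1, seed = 4)
  hp <- build_hairpin(cons$sequence, mols$top, mols$bottom)
  reads <- simulate_read_pairs(hp, n_pairs = 40, read_len = 150, conv = 1,
                               err = 0, seed = 5)
  strands <- meiometh:::convert_hairpins(hp, conv = 1, seed = 5 + 1L)
  Ls <- nchar(strands[1])
  for (i in seq_len(5)) {
    s <- strands[reads$molecule[i]]
    fwd <- substr(s, 1, 150)
    rev <- meiometh:::revcomp(substr(s, Ls - 149, Ls))
    expect_true(setequal(c(reads$read1[i], reads$read2[i]), c(fwd, rev)))
  }
  expect_error(simulate_read_pairs(hp, n_pairs = 0), "positive")
})

test_that("alignment classifies converted consensus reads and flags ambiguity", {
  cons <- l1_consensus()
  ## all CpGs methylated, everything else converted -> OT at offset 0
  all_m <- bisulfite_convert(cons$sequence, meth = cons$cpg_pos, conv = 1)
  aln <- align_bisulfite(all_m, cons)
  expect_equal(aln$aln$strand_class, "OT")
  expect_equal(aln$aln$offset, 0L)
  expect_true(all(aln$calls == "M"))

  ## fully converted unmethylated read -> every dyad U
  all_u <- bisulfite_convert(cons$sequence, meth = FALSE, conv = 1)
  aln_u <- align_bisulfite(all_u, cons)
  expect_equal(aln_u$aln$status, "aligned")
  expect_true(all(aln_u$calls == "U"))

  ## the raw (unconverted) consensus matches OT and CTOB equally: ambiguous
  aln_amb <- align_bisulfite(cons$sequence, cons)
  expect_equal(aln_amb$aln$status, "ambiguous")

  ## garbage does not align
  aln_bad <- align_bisulfite(strrep("AT", 75), cons)
  expect_equal(aln_bad$aln$status, "unaligned")
})

test_that("alignment agrees with an exhaustive brute-force scorer", {
  set.seed(6)
  cons <- l1_consensus()
  mols <- make_l1_population(30, cons, hemi_frac = 0.3, meth_level = 0.7, seed = 7)
  hp <- build_hairpin(cons$sequence, mols$top, mols$bottom)
  reads <- simulate_read_pairs(hp, n_pairs = 13, read_len = 150, conv = 1,
                               err = 0.01, seed = 8)
  queries <- c(reads$read1, reads$read2)  # 26 reads
  got <- align_bisulfite(queries, cons)
  for (i in seq_along(queries)) {
    want <- brute_align(queries[i], cons$sequence)
    if (want$mm > 3) {
      expect_equal(got$aln$status[i], "unaligned")
    } else if (want$hits > 1) {
      expect_equal(got$aln$status[i], "ambiguous")
    } else {
      expect_equal(got$aln$strand_class[i], want$class)
      expect_equal(got$aln$offset[i], want$offset)
      expect_equal(got$aln$mismatches[i], want$mm)
    }
  }
})

test_that("stitched rows equal simulator truth exactly at zero error", {
  cons <- l1_consensus()
  mols <- make_l1_population(200, cons, hemi_frac = 0.1, meth_level = 0.8, seed = 9)
  repl <- replicate_l1_population(mols, m = 0.3, seed = 10)
  hp <- build_hairpin(cons$sequence, repl$top, repl$bottom)
  reads <- simulate_read_pairs(hp, n_pairs = 500, read_len = 150, conv = 1,
                               err = 0, seed = 11)
  res <- call_hairpin(reads$read1, reads$read2, cons)
  expect_equal(sum(res$matrix$dropped), 0)
  truth <- reads$truth[res$matrix$kept, , drop = FALSE]
  expect_identical(unname(res$matrix$matrix), unname(truth))
})

test_that("reads too short to span a dyad leave it missing", {
  cons <- l1_consensus()
  mols <- make_l1_population(10, cons, hemi_frac = 0, meth_level = 1, seed = 12)
  hp <- build_hairpin(cons$sequence, mols$top, mols$bottom)
  ## arm is 179 nt; 60-nt reads only reach consensus positions 0-59 from each
  ## end, so dyads past 59 are uncovered
  reads <- simulate_read_pairs(hp, n_pairs = 50, read_len = 60, conv = 1,
                               err = 0, seed = 13)
  res <- call_hairpin(reads$read1, reads$read2, cons, min_overlap = 20)
  far <- which(cons$cpg_pos >= 60)
  expect_gt(length(far), 0)
  expect_true(all(res$matrix$matrix[, far] == "."))
  near <- which(cons$cpg_pos < 59)
  expect_true(all(res$matrix$matrix[, near] != "."))
})

test_that("dyad summary arithmetic and fully-unmethylated classification", {
  mat <- rbind(
    matrix("MM", 6, 1), matrix(c("MU"), 1, 1), matrix("UM", 1, 1),
    matrix("UU", 2, 1)
  )
  s <- summarize_dyads(mat)
  expect_equal(s$per_dyad$prop_hemi, 0.2)
  expect_equal(s$per_dyad$meth_incl_hemi, 0.7)
  expect_equal(s$per_dyad$meth_excl_hemi, 0.75)
  expect_equal(s$fully_unmethylated_fraction, 0.2)

  all_mm <- matrix("MM", 5, 3)
  s2 <- summarize_dyads(all_mm)
  expect_true(all(s2$per_dyad$prop_hemi == 0))
  expect_true(all(s2$per_dyad$meth_incl_hemi == 1))
  expect_true(all(s2$per_dyad$meth_excl_hemi == 1))
  expect_equal(s2$fully_unmethylated_fraction, 0)

  ## dyad with no informative rows is flagged undefined
  s3 <- summarize_dyads(matrix(".", 3, 1))
  expect_true(s3$per_dyad$undefined)
  expect_true(is.na(s3$per_dyad$prop_hemi))
  expect_error(summarize_dyads(matrix(character(), 0, 2)), "empty")
})

test_that("one replication without maintenance drives hemimethylation to 1 and halves only the inclusive statistic", {
  cons <- l1_consensus()
  mols <- make_l1_population(2000, cons, hemi_frac = 0, meth_level = 1, seed = 14)
  hp0 <- build_hairpin(cons$sequence, mols$top, mols$bottom)
  r0 <- simulate_read_pairs(hp0, n_pairs = 3000, read_len = 150, conv = 1, err = 0, seed = 15)
  before <- call_hairpin(r0$read1, r0$read2, cons)$summary

  repl <- replicate_l1_population(mols, m = 0, seed = 16)
  hp1 <- build_hairpin(cons$sequence, repl$top, repl$bottom)
  r1 <- simulate_read_pairs(hp1, n_pairs = 3000, read_len = 150, conv = 1, err = 0, seed = 17)
  after <- call_hairpin(r1$read1, r1$read2, cons)$summary

  expect_true(all(after$per_dyad$prop_hemi == 1))
  ## inclusive methylation halves (1 -> 0.5); exclusive stays ~1 where defined
  expect_equal(after$per_dyad$meth_incl_hemi, rep(0.5, length(cons$cpg_pos)))
  expect_true(all(before$per_dyad$meth_incl_hemi == 1))
  expect_true(all(is.na(after$per_dyad$meth_excl_hemi) |
                    after$per_dyad$meth_excl_hemi == 1))
})

test_that("caller recovers dyad-state fractions under sequencing noise", {
  cons <- l1_consensus()
  mols <- make_l1_population(3000, cons, hemi_frac = 0.2, meth_level = 0.9, seed = 18)
  repl <- replicate_l1_population(mols, m = 0.5, seed = 19)
  hp <- build_hairpin(cons$sequence, repl$top, repl$bottom)
  n_pairs <- 8000
  reads <- simulate_read_pairs(hp, n_pairs = n_pairs, read_len = 150,
                               conv = 0.99, err = 0.005, seed = 20)
  res <- call_hairpin(reads$read1, reads$read2, cons)
  truth_hemi <- colMeans(xor(repl$top, repl$bottom))
  got_hemi <- res$summary$per_dyad$prop_hemi
  se <- sqrt(truth_hemi * (1 - truth_hemi) / res$summary$per_dyad$n_MM * 0 +
               truth_hemi * (1 - truth_hemi) / n_pairs)
  ## conversion failure (1%) inflates apparent methylation slightly; allow
  ## 3 SE plus the deterministic error-rate bias bound (~2 * 0.01)
  expect_true(all(abs(got_hemi - truth_hemi) < 3 * se + 0.02))
})

test_that("FASTQ round trip preserves reads and trimming drops short mates", {
  cons <- l1_consensus()
  mols <- make_l1_population(20, cons, seed = 21)
  hp <- build_hairpin(cons$sequence, mols$top, mols$bottom)
  reads <- simulate_read_pairs(hp, n_pairs = 25, read_len = 120, conv = 1,
                               err = 0, seed = 22)
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  on.exit(unlink(c(f1, f2)))
  write_hairpin_fastq(reads, f1, f2)
  back <- read_hairpin_fastq(f1, f2)
  expect_identical(back$read1, unname(reads$read1))
  expect_identical(back$read2, unname(reads$read2))

  tr <- trim_reads(back$read1, back$read2, clip3 = 6, min_len = 100)
  expect_true(all(nchar(tr$read1) == 114))
  tr2 <- trim_reads(back$read1, back$read2, clip3 = 30, min_len = 100)
  expect_equal(length(tr2$read1), 0)
})

test_that("excluding hemimethylation erases the dilution dip when maintenance is partial", {
  cons <- l1_consensus()
  mols <- make_l1_population(4000, cons, hemi_frac = 0, meth_level = 0.95, seed = 23)
  hp0 <- build_hairpin(cons$sequence, mols$top, mols$bottom)
  r0 <- simulate_read_pairs(hp0, n_pairs = 4000, read_len = 150, conv = 1, err = 0, seed = 24)
  before <- call_hairpin(r0$read1, r0$read2, cons)$summary

  repl <- replicate_l1_population(mols, m = 0.3, seed = 25)
  hp1 <- build_hairpin(cons$sequence, repl$top, repl$bottom)
  r1 <- simulate_read_pairs(hp1, n_pairs = 4000, read_len = 150, conv = 1, err = 0, seed = 26)
  after <- call_hairpin(r1$read1, r1$read2, cons)$summary

  incl_drop <- mean(before$per_dyad$meth_incl_hemi) - mean(after$per_dyad$meth_incl_hemi)
  excl_drop <- mean(before$per_dyad$meth_excl_hemi) - mean(after$per_dyad$meth_excl_hemi)
  ## dyad-fate enumeration: an MM dyad (p = 0.95) leaves an MM daughter
  ## dyad with probability m, else hemi; UU dyads persist, so
  ## excl_after = p*m / (p*m + (1 - p)) while incl_after = p*(1 + m)/2
  p <- 0.95; m <- 0.3
  expect_equal(mean(after$per_dyad$meth_incl_hemi), p * (1 + m) / 2,
               tolerance = 0.02)
  expect_equal(mean(after$per_dyad$meth_excl_hemi),
               p * m / (p * m + (1 - p)), tolerance = 0.04)
  ## the dip is mostly erased by exclusion: exclusive moves ~3x less
  expect_gt(incl_drop, 0.25)
  expect_lt(abs(excl_drop), incl_drop / 2)
})
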
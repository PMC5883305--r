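test_that("genome initialization matches the requested strand-level methylation", {
  lay <- tiny_layout()
  rt <- two_domain_rt(lay)

  sat <- make_genome(sim_params(s0 = 1, n_cells = 5, seed = 1), rt, lay)
  expect_true(all(sat$top1) && all(sat$bot1))
  expect_equal(strand_methylation(sat), 1.0)

  empty <- make_genome(sim_params(s0 = 0, n_cells = 5, seed = 1), rt, lay)
  expect_false(any(empty$top1) || any(empty$bot1))
  expect_equal(strand_methylation(empty), 0)

  ## binomial sampling oracle: n dyads at p = 0.9
  p <- sim_params(s0 = 0.9, n_cells = 200, seed = 1)
  pop <- make_genome(p, rt, lay)
  n_dyads <- 200 * nrow(lay$cpgs)
  se <- sqrt(0.9 * 0.1 / n_dyads)
  expect_lt(abs(strand_methylation(pop) - 0.9), 3 * se)
})

test_that("invalid simulation parameters are rejected", {
  expect_error(sim_params(s0 = 1.2), "\\[0, 1\\]")
  expect_error(sim_params(m = -0.1), "\\[0, 1\\]")
  expect_error(sim_params(s0 = c(0.9, CGI = 0.1)), "default")
  lay <- tiny_layout()
  bad_rt <- data.frame(chrom = "chr1", start = 0L, end = 10L, rt_value = 1)
  expect_error(make_genome(sim_params(n_cells = 2), bad_rt, lay), "cover")
})

test_that("full replication without maintenance halves methylation exactly", {
  lay <- tiny_layout()
  rt <- two_domain_rt(lay)
  pop <- make_genome(sim_params(s0 = 1, n_cells = 20, seed = 2), rt, lay)
  rep0 <- replicate_population(pop, rt, s_progress = 1, m = 0, seed = 3)
  expect_equal(strand_methylation(rep0), 0.5)
  ## every daughter duplex is strand-coherently hemimethylated:
  ## template strands stay methylated, new strands fully unmethylated
  expect_true(all(rep0$replicated))
  expect_true(all(rep0$top1) && !any(rep0$bot1))
  expect_true(all(rep0$bot2) && !any(rep0$top2))

  rep1 <- replicate_population(pop, rt, s_progress = 1, m = 1, seed = 3)
  expect_equal(strand_methylation(rep1), 1.0)

  expect_error(replicate_population(rep0, rt, s_progress = 1, m = 0),
               "already replicated")
  expect_error(replicate_population(pop, rt, s_progress = 1.4, m = 0),
               "\\[0, 1\\]")
})

test_that("half replication diluted the early domain only (hand enumeration)", {
  lay <- tiny_layout()
  rt <- two_domain_rt(lay)
  pop <- make_genome(sim_params(s0 = 1, n_cells = 10, seed = 4), rt, lay)
  half <- replicate_population(pop, rt, s_progress = 0.5, m = 0, seed = 5)
  m_cpg <- strand_methylation(half, by = "cpg")
  early <- lay$cpgs$pos < lay$chrom_lengths[[1]] / 2
  expect_equal(unique(m_cpg[early]), 0.5)
  expect_equal(unique(m_cpg[!early]), 1.0)
})

test_that("molecule count is conserved: two daughters per replicated duplex", {
  lay <- tiny_layout()
  rt <- two_domain_rt(lay)
  pop <- make_genome(sim_params(s0 = 0.8, n_cells = 30, seed = 6), rt, lay)
  repl <- replicate_population(pop, rt, s_progress = default_s_progress,
                               m = 0.5, seed = 7)
  ## daughter-duplex slots are populated exactly where replication happened
  expect_identical(!is.na(repl$top2), repl$replicated)
  expect_identical(!is.na(repl$bot2), repl$replicated)
  n_duplex <- sum(!repl$replicated) + 2 * sum(repl$replicated)
  expect_equal(n_duplex, length(repl$replicated) + sum(repl$replicated))
})

test_that("simulated dilution matches the closed form on an (s0, r, m) grid", {
  lay <- tiny_layout(cpgs_per_chrom = 400)
  rt <- two_domain_rt(lay)
  for (s0 in c(0.5, 1)) {
    for (r in c(0, 0.5, 1)) {
      for (m in c(0, 0.5)) {
        pop <- make_genome(sim_params(s0 = s0, n_cells = 50, seed = 8), rt, lay)
        repl <- replicate_population(pop, rt, s_progress = r, m = m, seed = 9)
        got <- strand_methylation(repl)
        want <- expected_strand_methylation(s0, r, m)
        per_cell <- strand_methylation(repl, by = "cell")
        mc_se <- stats::sd(per_cell) / sqrt(length(per_cell))
        expect_lt(abs(got - want), max(3 * mc_se, 1e-12) + 1e-12,
                  label = sprintf("|sim - closed form| at s0=%g r=%g m=%g", s0, r, m))
      }
    }
  }
})

test_that("closed-form dilution arithmetic", {
  expect_equal(expected_strand_methylation(1, 1, 0), 0.5)
  expect_equal(expected_strand_methylation(0.9, 0, 0.7), 0.9)
  expect_equal(expected_strand_methylation(0.8, 0.5, 0.5), 0.7)
  expect_error(expected_strand_methylation(1.1, 0, 0), "\\[0, 1\\]")
})

test_that("coherently hemimethylated elements yield fully unmethylated daughters at rate 1/2", {
  lay <- tiny_layout(cpgs_per_chrom = 300)
  rt <- two_domain_rt(lay)
  p <- sim_params(s0 = 1, hemi_frac = 0.5, n_cells = 10, seed = 10)
  pop <- make_genome(p, rt, lay)
  expect_gt(length(pop$hemi_elements), 0)
  l1 <- lay$annotation$L1[pop$hemi_elements, ]
  idx <- which(!is.na(meiometh:::interval_index(lay$cpgs$chrom, lay$cpgs$pos, l1)))
  expect_true(all(pop$top1[, idx]))
  expect_false(any(pop$bot1[, idx]))

  repl <- replicate_population(pop, rt, s_progress = 1, m = 0, seed = 11)
  ## daughter 1 (top template) hemimethylated; daughter 2 (bottom template) UU
  d1_uu <- !repl$top1[, idx] & !repl$bot1[, idx]
  d2_uu <- !repl$top2[, idx] & !repl$bot2[, idx]
  expect_equal(mean(rbind(d1_uu, d2_uu)), 0.5)
  expect_true(all(d2_uu))
})

test_that("WGBS sampling reproduces truth and the error model", {
  lay <- tiny_layout(cpgs_per_chrom = 400)
  rt <- two_domain_rt(lay)
  sat <- make_genome(sim_params(s0 = 1, n_cells = 10, seed = 12), rt, lay)
  w <- sample_wgbs(sat, depth = 10, conv_fail = 0, inapprop_conv = 0, seed = 13)
  m <- merge_strands(w$calls)
  covered <- m$n_meth + m$n_unmeth > 0
  expect_true(all(m$n_meth[covered] / (m$n_meth + m$n_unmeth)[covered] == 1))

  empty <- make_genome(sim_params(s0 = 0, n_cells = 10, seed = 12), rt, lay)
  w0 <- sample_wgbs(empty, depth = 20, conv_fail = 0.01, inapprop_conv = 0, seed = 14)
  frac <- sum(w0$calls$n_meth) / sum(w0$calls$n_meth + w0$calls$n_unmeth)
  n <- sum(w0$calls$n_meth + w0$calls$n_unmeth)
  expect_lt(abs(frac - 0.01), 3 * sqrt(0.01 * 0.99 / n))

  expect_error(sample_wgbs(sat, depth = 0), "positive")
})

test_that("mid-S fragment coverage is halved over unreplicated late domains", {
  lay <- tiny_layout(n_chrom = 2, cpgs_per_chrom = 2000, spacing = 100L)
  rt <- two_domain_rt(lay)
  pop <- make_genome(sim_params(s0 = 0.8, n_cells = 30, seed = 15), rt, lay)
  mid <- replicate_population(pop, rt, s_progress = 0.5, m = 0, seed = 16)
  w <- sample_wgbs(mid, depth = 2, frag_depth = 100, seed = 17)
  fr <- w$fragments
  late <- fr$start >= lay$chrom_lengths[[1]] / 2
  ratio <- mean(fr$count[late]) / mean(fr$count[!late])
  expect_lt(abs(ratio - 0.5), 0.05)
})

test_that("dyad truth TSV round-trips the population states", {
  lay <- tiny_layout(cpgs_per_chrom = 20)
  rt <- two_domain_rt(lay)
  pop <- make_genome(sim_params(s0 = 0.5, n_cells = 3, seed = 18), rt, lay)
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path))
  write_dyad_truth(pop, path)
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  expect_equal(nrow(tab), 2 * 3)
  d1 <- as.matrix(tab[tab$duplex == 1, -(1:2)])
  expect_equal(unname(d1 == "MM"), unname(pop$top1 & pop$bot1))
})
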
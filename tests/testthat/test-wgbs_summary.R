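test_that("M-bias clipping keeps exactly the interior cycles", {
  stream <- data.frame(read_of_pair = 1L, cycle = 1:100, read_len = 100L)
  out <- mbias_clip(stream)
  expect_equal(range(out$cycle), c(7, 99))

  expect_equal(nrow(mbias_clip(stream, 0, 0, 0)), 100)

  expect_error(mbias_clip(data.frame(cycle = 1)), "cycle metadata")

  ## randomized streams against an independent per-record filter
  set.seed(1)
  for (rep in 1:100) {
    n <- sample(5:60, 1)
    st <- data.frame(
      read_of_pair = sample(1:2, n, replace = TRUE),
      cycle = sample(1:120, n, replace = TRUE),
      read_len = sample(c(100L, 120L), n, replace = TRUE)
    )
    c1 <- sample(0:8, 1); c2 <- sample(0:12, 1); c3 <- sample(0:3, 1)
    got <- mbias_clip(st, c1, c2, c3)
    keep <- logical(n)
    for (i in seq_len(n)) {
      lo <- if (st$read_of_pair[i] == 1) c1 else c2
      keep[i] <- st$cycle[i] > lo && st$cycle[i] <= st$read_len[i] - c3
    }
    expect_equal(got, st[keep, , drop = FALSE])
  }
})

test_that("strand merging sums paired records and keeps singletons", {
  calls <- data.frame(
    chrom = "chr1", pos = c(10L, 11L, 50L),
    strand = c("+", "-", "+"),
    n_meth = c(5L, 3L, 5L), n_unmeth = c(1L, 1L, 1L)
  )
  m <- merge_strands(calls)
  expect_equal(m$n_meth[m$start == 10], 8)
  expect_equal(m$n_unmeth[m$start == 10], 2)
  expect_equal(m$end - m$start, c(2L, 2L))
  expect_equal(m$n_meth[m$start == 50], 5)

  dup <- rbind(calls, calls[1, ])
  expect_error(merge_strands(dup), "corrupted")
})

test_that("merged WGBS calls recover truth methylation at zero error", {
  lay <- tiny_layout(cpgs_per_chrom = 300)
  rt <- two_domain_rt(lay)
  pop <- make_genome(sim_params(s0 = 0.7, n_cells = 40, seed = 2), rt, lay)
  w <- sample_wgbs(pop, depth = 60, conv_fail = 0, inapprop_conv = 0, seed = 3)
  m <- merge_strands(w$calls)
  truth <- strand_methylation(pop, by = "cpg")
  got <- m$n_meth / (m$n_meth + m$n_unmeth)
  expect_lt(mean(abs(got - truth)), 0.05)
  expect_lt(abs(mean(got) - mean(truth)), 0.01)
})

test_that("common-CpG restriction is an exact coverage intersection", {
  mk <- function(starts, cov = 1L) {
    data.frame(chrom = "chr1", start = starts, end = starts + 2L,
               n_meth = cov, n_unmeth = 0L)
  }
  sets <- list(a = mk(c(0, 2, 4, 6)), b = mk(c(2, 4, 8)), c = mk(c(0, 2, 4)))
  res <- restrict_common(sets)
  expect_equal(res$callsets$a$start, c(2, 4))
  expect_equal(res$callsets$b$start, c(2, 4))
  expect_equal(res$retained[["b"]], 2 / 3)

  ## all covered -> identity
  same <- list(a = mk(c(0, 2)), b = mk(c(0, 2)))
  expect_equal(restrict_common(same)$callsets$a, same$a)

  ## an uncovered sample empties the result with a warning
  sets$d <- mk(c(100))
  expect_warning(res2 <- restrict_common(sets), "empty")
  expect_equal(nrow(res2$callsets$a), 0)

  ## randomized staggered coverage vs brute force
  set.seed(4)
  for (rep in 1:100) {
    pool <- seq(0, 60, by = 2)
    ss <- lapply(1:3, function(i) mk(sort(sample(pool, sample(5:20, 1)))))
    names(ss) <- c("x", "y", "z")
    keys <- Reduce(intersect, lapply(ss, function(d) d$start))
    got <- suppressWarnings(restrict_common(ss))
    expect_equal(sort(got$callsets$x$start), sort(keys))
  }
})

test_that("CpG-count bins average methylation fractions", {
  calls <- calls_from_fractions(c(1, 0.5, 0.5, 0))
  b <- bin_mean(calls, k = 2)
  expect_equal(b$mean_meth, c(0.75, 0.25))

  b1 <- bin_mean(calls, k = 1)
  expect_equal(b1$mean_meth, c(1, 0.5, 0.5, 0))

  const <- bin_mean(calls_from_fractions(rep(0.6, 10)), k = 3)
  expect_equal(const$mean_meth, rep(0.6, 3))
  expect_equal(attr(const, "dropped_cpgs"), 1L)
})

test_that("fixed-width windows match a brute-force tiling", {
  ## toy 10-kb chromosome, 5-kb windows
  calls <- calls_from_fractions(c(rep(1, 10), rep(0, 10)), spacing = 500L)
  w <- window_mean(calls, width = 5000L)
  expect_equal(nrow(w), 2)
  expect_equal(w$mean_meth, c(1, 0))

  set.seed(5)
  for (rep in 1:100) {
    n <- sample(10:80, 1)
    width <- sample(c(1000L, 2500L, 5000L), 1)
    pos <- sort(sample(0:19999, n))
    frac <- runif(n)
    calls <- data.frame(chrom = "chr1", start = pos, end = pos + 2L,
                        n_meth = round(frac * 100), n_unmeth = 100 - round(frac * 100))
    got <- window_mean(calls, width = width)
    f <- calls$n_meth / 100
    for (j in seq_len(nrow(got))) {
      in_w <- pos >= got$start[j] & pos < got$end[j]
      if (any(in_w)) expect_equal(got$mean_meth[j], mean(f[in_w]))
      else expect_true(is.na(got$mean_meth[j]))
    }
  }
})

test_that("coverage windows normalize to the largest data set", {
  fr <- function(counts) data.frame(chrom = "chr1",
                                    start = (seq_along(counts) - 1L) * 5000L,
                                    end = seq_along(counts) * 5000L,
                                    count = counts)
  cw <- coverage_windows(list(a = fr(c(10, 20)), b = fr(c(5, 10))), width = 5000L)
  expect_equal(cw$a$norm_count, c(10, 20))
  expect_equal(cw$b$norm_count, c(10, 20))  # scaled by 30/15

  same <- coverage_windows(list(a = fr(c(7, 7)), b = fr(c(7, 7))), width = 5000L)
  expect_equal(same$a$norm_count, same$a$count)
})

test_that("feature aggregation matches brute-force interval membership", {
  lay <- sim_layout(n_chrom = 2, cpgs_per_chrom = 500, spacing = 100L, seed = 6)
  rt <- two_domain_rt(lay)
  pop <- make_genome(sim_params(s0 = 0.8, n_cells = 10, seed = 7), rt, lay)
  w <- sample_wgbs(pop, depth = 10, conv_fail = 0, inapprop_conv = 0, seed = 8)
  calls <- merge_strands(w$calls)

  fs <- feature_aggregate(calls, lay$annotation, chunk = 50)
  expect_s3_class(fs$summary, "data.frame")

  ## membership oracle on 1,000 random CpGs: a CpG contributes to every
  ## class whose intervals contain it
  set.seed(9)
  idx <- sample(nrow(calls), 1000, replace = TRUE)
  for (cls in c("exon", "intron", "CGI", "L1")) {
    iv <- lay$annotation[[cls]]
    brute <- vapply(idx, function(i) {
      any(iv$chrom == calls$chrom[i] &
            iv$start <= calls$start[i] & calls$start[i] < iv$end)
    }, logical(1))
    pkg <- !is.na(meiometh:::interval_index(calls$chrom[idx], calls$start[idx], iv))
    expect_identical(pkg, brute)
    expect_equal(fs$summary$n_cpgs[fs$summary$class == cls],
                 sum(!is.na(meiometh:::interval_index(calls$chrom, calls$start, iv))))
  }
})

test_that("unmethylated CpG islands stay unmethylated through replication", {
  lay <- sim_layout(n_chrom = 1, cpgs_per_chrom = 800, spacing = 100L,
                    cgi_per_chrom = 4, seed = 10)
  rt <- two_domain_rt(lay)
  p <- sim_params(s0 = c(default = 0.9, CGI = 0.02), n_cells = 30, seed = 11)
  pop <- make_genome(p, rt, lay)
  repl <- replicate_population(pop, rt, s_progress = 1, m = 0, seed = 12)
  w <- sample_wgbs(repl, depth = 20, conv_fail = 0, inapprop_conv = 0, seed = 13)
  fs <- feature_aggregate(merge_strands(w$calls), lay$annotation["CGI"], chunk = 20)
  ## UU dyads have nothing to dilute: CGIs remain near zero after S phase
  expect_lt(fs$summary$mean, 0.03)
})

test_that("replicate correlation equals the textbook formula", {
  expect_equal(replicate_correlation(c(1, 2, 3), c(1, 2, 3)), 1.0)
  expect_equal(replicate_correlation(c(1, 2, 3), c(-1, -2, -3)), -1.0)
  set.seed(14)
  for (rep in 1:100) {
    a <- runif(sample(5:50, 1))
    b <- runif(length(a))
    textbook <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    expect_equal(replicate_correlation(a, b), textbook, tolerance = 1e-12)
  }
})

test_that("Bismark coverage files round-trip through the 1-based boundary", {
  calls <- calls_from_fractions(c(0, 0.25, 1), coverage = 8L)
  path <- tempfile(fileext = ".cov")
  on.exit(unlink(path))
  write_bismark_cov(calls, path)
  raw <- read.table(path, sep = "\t")
  expect_equal(raw$V2, calls$start + 1L)  # 1-based inclusive on disk
  back <- read_bismark_cov(path)
  expect_equal(back$start, calls$start)
  expect_equal(back$n_meth, calls$n_meth)
  expect_error(read_bismark_cov(textConnection("not a cov file")), "malformed")
})
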
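test_that("smoothing pools counts within the window", {
  # constant signal stays put
  cp <- cpg_table(pos = seq(0, 2000, by = 100), meth = 8, total = 10)
  s <- smooth_methylation(cp)
  expect_true(all(abs(s$mu_hat - 0.8) < 1e-12))
  # isolated CpG keeps its raw ratio
  cp2 <- cpg_table(pos = c(100, 5000), meth = c(3, 5), total = c(4, 10))
  s2 <- smooth_methylation(cp2)
  expect_equal(s2$mu_hat[1], 0.75)
  # hand-summed window of three CpGs
  cp3 <- cpg_table(pos = c(100, 150, 200), meth = c(8, 1, 6), total = 10)
  s3 <- smooth_methylation(cp3)
  expect_equal(s3$mu_hat[2], 15 / 30)
  # zero-coverage CpG with covered neighbours borrows their level
  cp4 <- cpg_table(pos = c(100, 150, 200), meth = c(8, 0, 6), total = c(10, 0, 10))
  expect_equal(smooth_methylation(cp4)$mu_hat[2], 14 / 20)
  expect_error(smooth_methylation(cp3[c(2, 1, 3)]), "sorted")
})

test_that("dispersion estimation: zero-variance, recovery, fallback", {
  # identical replicate proportions -> clipped floor
  M <- matrix(15L, 3, 4); Tt <- matrix(30L, 3, 4)
  expect_equal(estimate_dispersion(M, Tt, c(1, 1, 2, 2)), rep(1e-4, 3))
  # simulation at known phi = 0.1, coverage 30
  set.seed(11)
  n <- 5000
  mu <- rbeta(n, 8, 2)
  Tt <- matrix(rpois(n * 4, 30), n, 4)
  M <- matrix(0L, n, 4)
  for (j in 1:4) M[, j] <- rbb(n, Tt[, j], mu, 0.1)
  ph <- estimate_dispersion(M, Tt, c(1, 1, 2, 2))
  expect_gte(median(ph), 0.07)
  expect_lte(median(ph), 0.13)
  # single sample per group: one global value everywhere
  ph1 <- estimate_dispersion(M[, c(1, 3)], Tt[, c(1, 3)], c(1, 2))
  expect_equal(length(unique(ph1)), 1L)
})

test_that("Wald test matches hand evaluation and handles degeneracy", {
  # equal proportions
  w0 <- wald_test_cpg(5, 10, 10, 20, 0.05)
  expect_equal(w0$wald, 0)
  expect_equal(w0$p, 1)
  # hand-evaluated formula
  w <- wald_test_cpg(18, 20, 2, 20, 0)
  expect_equal(w$wald, 0.8 / sqrt(0.09 / 20 + 0.09 / 20), tolerance = 1e-12)
  expect_lt(w$p, 1e-15)
  # degenerate 0/20 vs 0/20
  wd <- wald_test_cpg(0, 20, 0, 20, 0.05)
  expect_equal(wd$wald, 0)
  expect_equal(wd$p, 1)
  # skipped when one side has no coverage
  expect_true(is.na(wald_test_cpg(5, 10, 0, 0, 0.05)$p))
})

test_that("Wald statistic is antisymmetric under group swap", {
  set.seed(3)
  t1 <- rpois(500, 25) + 1L; t2 <- rpois(500, 25) + 1L
  m1 <- rbinom(500, t1, 0.6); m2 <- rbinom(500, t2, 0.5)
  a <- wald_test_cpg(m1, t1, m2, t2, 0.05)
  b <- wald_test_cpg(m2, t2, m1, t1, 0.05)
  expect_equal(a$wald, -b$wald)
  expect_equal(a$p, b$p)
})

test_that("null Wald p-values are uniform (KS < 0.05)", {
  set.seed(42)
  n <- 10000
  mu <- rbeta(n, 26, 4)
  t1 <- rpois(n, 30); t2 <- rpois(n, 30)
  m1 <- rbb(n, t1, mu, 0.05); m2 <- rbb(n, t2, mu, 0.05)
  p <- wald_test_cpg(m1, t1, m2, t2, 0.05)$p
  ks <- suppressWarnings(stats::ks.test(p[!is.na(p)], "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

make_tests <- function(pos, sig, diff = 0.4, chrom = "chr1") {
  # per-CpG test table with clean raw counts behind each flag
  n <- length(pos)
  mu2 <- rep(0.85, n)
  mu1 <- ifelse(sig, 0.85 - diff, 0.85)
  data.table(chrom = chrom, pos = as.integer(pos),
             m1 = round(mu1 * 40), t1 = 40, m2 = round(mu2 * 40), t2 = 40,
             mu1 = mu1, mu2 = mu2, phi = 0.05,
             wald = ifelse(sig, -6, -0.5),
             p = ifelse(sig, 1e-9, 0.5))
}

test_that("call_dmrs assembles, trims and merges by the stated rules", {
  # 6 significant CpGs spanning 250 bp -> one DMR with 6 CpGs
  t1 <- make_tests(seq(1000, 1250, by = 50), sig = rep(TRUE, 6))
  d1 <- call_dmrs(t1)
  expect_equal(nrow(d1), 1L)
  expect_equal(d1$n_cpgs, 6L)
  expect_equal(d1$hypo_in, "group1")
  # 4 significant CpGs spanning 300 bp -> rejected by minCG
  t2 <- make_tests(seq(1000, 1300, by = 100), sig = rep(TRUE, 4))
  expect_equal(nrow(call_dmrs(t2)), 0L)
  # two qualifying regions separated by three insignificant CpGs:
  # a 40-bp inter-region gap merges, a 60-bp gap does not
  mk_two <- function(gap) {
    p1 <- seq(1000, 1250, by = 50)          # run 1 ends at 1250 (+2)
    p_insig <- c(1260, 1270, 1280)          # breaks the chain (> 2 insig)
    p2 <- seq(1252 + gap, 1502 + gap, by = 50)
    make_tests(c(p1, p_insig, p2),
               sig = c(rep(TRUE, 6), rep(FALSE, 3), rep(TRUE, 6)))
  }
  expect_equal(nrow(call_dmrs(mk_two(40))), 1L)
  expect_equal(nrow(call_dmrs(mk_two(60))), 2L)
  # empty input
  expect_equal(nrow(call_dmrs(make_tests(integer(0), logical(0)))), 0L)
})

test_that("call_dmrs output is sorted, non-overlapping, and monotone in
           the p threshold", {
  set.seed(21)
  pos <- sort(sample(1e5, 600))
  sig <- runif(600) < 0.3
  tt <- make_tests(pos, sig)
  tt[, p := ifelse(sig, 10^runif(.N, -12, -4), 10^runif(.N, -3, 0))]
  counts <- sapply(c(1e-7, 1e-5, 1e-3), function(th) {
    d <- call_dmrs(tt, dmr_params(p_threshold = th))
    if (nrow(d) > 1) {
      expect_true(all(d$start[-1] >= d$end[-nrow(d)] | d$chrom[-1] != d$chrom[-nrow(d)]))
    }
    nrow(d)
  })
  expect_true(all(diff(counts) >= 0))
})

test_that("call_dmrs equals the brute-force oracle on small fixtures", {
  set.seed(77)
  for (rep in 1:20) {
    n <- sample(10:50, 1)
    pos <- sort(sample(5000, n))
    sig <- runif(n) < 0.5
    diffs <- ifelse(sig, sample(c(-0.4, 0.4), n, replace = TRUE), 0)
    mu2 <- rep(0.6, n)
    mu1 <- mu2 + diffs
    tt <- data.table(chrom = "chr1", pos = as.integer(pos),
                     m1 = round(mu1 * 30), t1 = 30,
                     m2 = round(mu2 * 30), t2 = 30,
                     mu1 = mu1, mu2 = mu2, phi = 0.05,
                     wald = diffs * 10,
                     p = ifelse(sig, 1e-8, runif(n, 0.01, 1)))
    got <- call_dmrs(tt)[, .(chrom, start, end)]
    want <- oracle_call_dmrs(tt)
    expect_equal(got, want[, .(chrom, start, end)], ignore_attr = TRUE,
                 info = paste("fixture", rep))
  }
})

test_that("filter_dmrs enforces effect size and per-group coverage", {
  tt <- make_tests(seq(1000, 1450, by = 50), sig = rep(TRUE, 10))
  d <- call_dmrs(tt)
  expect_equal(nrow(filter_dmrs(d, tt)), 1L)
  # small effect removed
  d2 <- copy(d); d2$mean_diff <- -0.20
  expect_equal(nrow(filter_dmrs(d2, tt)), 0L)
  # insufficient covered CpGs in one group removed
  tt3 <- copy(tt); tt3[, t2 := c(rep(4L, 6), rep(40L, 4))]
  expect_equal(nrow(filter_dmrs(d, tt3)), 0L)
})

test_that("planted DMRs are recovered at effect 0.4, coverage 20", {
  cfg <- sim_config(seed = 1L)
  sim <- simulate_methylome(cfg)
  me <- sim$samples
  dmrs <- find_dmrs(me[grep("^pos_", names(me))], me[grep("^neg_", names(me))],
                    labels = c("pos", "neg"))
  rec <- overlap_recovery(dmrs, sim$truth$celltype_dmrs)
  expect_gte(rec$recall, 0.9)
  expect_gte(rec$precision, 0.9)
  expect_true(all(dmrs$hypo_in == "pos"))
})

test_that("empirical null curve separates signal from replicate noise", {
  cfg <- sim_config(seed = 2L, n_cpgs = 15000L, n_celltype_dmrs = 100L)
  sim <- simulate_methylome(cfg)
  me <- sim$samples
  curve <- empirical_null_curve(
    replicate_pairs = list(t0 = list(me$pos_t0_r1, me$pos_t0_r2)),
    condition_pairs = list(
      time = list(me$pos_t0_r1, me$pos_t4_r1),
      celltype = list(me$pos_t0_r1, me$neg_t0_r1)),
    p_thresholds = c(1e-3, 1e-5))
  nulls <- curve[type == "replicate_null"]
  times <- curve[comparison == "time"]
  cells <- curve[comparison == "celltype"]
  for (th in unique(curve$p_threshold)) {
    expect_lte(times[p_threshold == th, n_dmrs],
               2L * nulls[p_threshold == th, n_dmrs] + 1L)
  }
  expect_gte(cells[p_threshold == 1e-5, n_dmrs],
             10L * nulls[p_threshold == 1e-5, n_dmrs])
  expect_gte(cells[p_threshold == 1e-5, n_dmrs], 10L)
  # empty input -> empty table
  expect_equal(nrow(empirical_null_curve(list(), list())), 0L)
})

test_that("methylome summary computes global level and bins", {
  cp <- cpg_table(pos = c(100, 200), meth = c(10, 10), total = c(10, 10))
  s <- methylome_summary(cp)
  expect_equal(s$global, 1.0)
  expect_equal(unname(s$fractions["high"]), 1.0)
  cp2 <- cpg_table(pos = c(100, 200), meth = c(8, 1), total = c(10, 10))
  s2 <- methylome_summary(cp2)
  expect_equal(s2$global, 0.45)
  expect_equal(unname(s2$fractions), c(0.5, 0, 0.5))
  expect_equal(sum(s2$fractions), 1)
})

test_that("stability fraction counts stable regions and reports missing", {
  reg <- data.table(chrom = "chr1", start = seq(0, 9000, by = 1000),
                    end = seq(500, 9500, by = 1000))
  pos <- as.integer(unlist(lapply(reg$start, function(s) s + c(100, 300))))
  t0 <- cpg_table(pos = pos, meth = 16, total = 20)
  t4 <- copy(t0)
  expect_equal(stability_fraction(reg, t0, t4)$fraction_stable, 1.0)
  # one region shifted by 0.4
  t4b <- copy(t4); t4b[pos %in% c(100L, 300L), meth := 8L]
  expect_equal(stability_fraction(reg, t0, t4b)$fraction_stable, 0.9)
  # a region with no coverage at t4 leaves the denominator
  t4c <- t4[!(pos %in% c(1100L, 1300L))]
  sf <- stability_fraction(reg, t0, t4c)
  expect_equal(sf$n_missing, 1L)
  expect_equal(sf$n_evaluated, 9L)
})

test_that("aggregate_profile anchors at centers and flags missing bins", {
  reg <- data.table(chrom = "chr1", start = c(10000, 30000), end = c(10400, 30400))
  sig <- data.table(chrom = "chr1", pos = seq(0, 50000, by = 25), value = 0.8)
  pr <- aggregate_profile(reg, sig, flank = 5000, n_bins = 100)
  expect_equal(dim(pr$matrix), c(2L, 100L))
  expect_true(all(abs(pr$matrix - 0.8) < 1e-12))
  # step signal: 0 inside the interval, 1 outside
  sig2 <- copy(sig)
  sig2[, value := ifelse((pos >= 10000 & pos < 10400) |
                           (pos >= 30000 & pos < 30400), 0, 1)]
  pr2 <- aggregate_profile(reg, sig2, flank = 5000, n_bins = 100)
  expect_lt(mean(pr2$colmeans[49:52]), 0.2)
  expect_gt(mean(pr2$colmeans[c(1:10, 91:100)]), 0.95)
  # missing data excluded from column means
  sig3 <- sig[pos < 20000]
  pr3 <- aggregate_profile(reg, sig3, flank = 5000, n_bins = 100)
  expect_true(all(is.na(pr3$matrix[2, ])))
  expect_true(all(abs(pr3$colmeans - 0.8) < 1e-12))
})
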
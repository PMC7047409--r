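test_that("PWM scanning finds a planted consensus with minimal p", {
  pw <- toy_pwm("AAAAAGGGGG", name = "sharp")
  set.seed(12)
  seqs <- c(s1 = paste0(random_dna(40), "AAAAAGGGGG", random_dna(40)))
  h <- scan_pwm(seqs, pw, p_threshold = 1e-4)
  top <- h[which.max(score)]
  expect_equal(top$start, 40L)
  expect_equal(top$strand, "+")
  expect_equal(top$p, min(h$p))
  # reverse complement hits the minus strand with the identical score
  seqs_rc <- c(s1 = paste0(substr(seqs, 1, 40), revcomp("AAAAAGGGGG"),
                           substr(seqs, 51, 90)))
  h2 <- scan_pwm(seqs_rc, pw, p_threshold = 1e-4)
  top2 <- h2[which.max(score)]
  expect_equal(top2$strand, "-")
  expect_equal(top2$score, top$score)
  # sequence shorter than the motif: no hits, no error
  expect_equal(nrow(scan_pwm(c(tiny = "ACGT"), pw)), 0L)
})

test_that("DP score p-values match exhaustive 4-mer enumeration", {
  mat <- matrix(c(0.7, 0.1, 0.1, 0.1,
                  0.1, 0.6, 0.2, 0.1,
                  0.05, 0.05, 0.8, 0.1,
                  0.25, 0.25, 0.25, 0.25), 4, 4, byrow = TRUE,
                dimnames = list(NULL, c("A", "C", "G", "T")))
  bg <- c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)
  dist <- pwm_score_distribution(mat, bg, bin_bits = 0.01)
  lodds <- round(log2(sweep(mat, 2, bg, "/")) / 0.01)
  grid <- as.matrix(expand.grid(1:4, 1:4, 1:4, 1:4))
  sc_bin <- lodds[1, grid[, 1]] + lodds[2, grid[, 2]] +
    lodds[3, grid[, 3]] + lodds[4, grid[, 4]]
  pr <- bg[grid[, 1]] * bg[grid[, 2]] * bg[grid[, 3]] * bg[grid[, 4]]
  for (q in quantile(sc_bin, c(0.05, 0.3, 0.6, 0.9, 1))) {
    p_dp <- finregen:::pwm_tail_p(dist, q * 0.01)
    p_bf <- sum(pr[sc_bin >= q])
    expect_equal(p_dp, unname(p_bf), tolerance = 1e-12)
  }
})

test_that("binomial enrichment equals the exact tail sum", {
  # 50 of 100 targets hit at background rate 0.1
  targets <- data.table(chrom = "chr1",
                        start = seq(0L, 99000L, by = 1000L),
                        end = seq(0L, 99000L, by = 1000L) + 500L)
  bg <- data.table(chrom = "chr2",
                   start = seq(0L, 199000L, by = 1000L),
                   end = seq(0L, 199000L, by = 1000L) + 500L)
  hits <- rbind(
    data.table(chrom = "chr1", start = targets$start[1:50] + 10L,
               end = targets$start[1:50] + 20L, pwm = "m"),
    data.table(chrom = "chr2", start = bg$start[seq(1, 200, by = 10)] + 10L,
               end = bg$start[seq(1, 200, by = 10)] + 20L, pwm = "m"))
  en <- motif_enrichment(targets, bg, hits)
  expect_equal(en$n_target_with_hit, 50L)
  expect_equal(en$bg_rate, 0.1)
  oracle <- sum(vapply(50:100, function(k)
    choose(100, k) * 0.1^k * 0.9^(100 - k), numeric(1)))
  expect_lt(abs(en$p - oracle) / oracle, 1e-12)
  expect_lt(en$p, 1e-20)
  # equal rates -> no enrichment signal
  hits_null <- rbind(
    data.table(chrom = "chr1", start = targets$start[seq(1, 100, by = 10)] + 10L,
               end = targets$start[seq(1, 100, by = 10)] + 20L, pwm = "m"),
    data.table(chrom = "chr2", start = bg$start[seq(1, 200, by = 10)] + 10L,
               end = bg$start[seq(1, 200, by = 10)] + 20L, pwm = "m"))
  en0 <- motif_enrichment(targets, bg, hits_null)
  expect_gte(en0$p, 0.4)
})

test_that("footprint mixture model recovers planted bound sites", {
  set.seed(5)
  n <- 500; W <- 200; depl <- 0.7
  bound <- rep(c(TRUE, FALSE), each = n / 2)
  core <- 96:105
  rate_u <- rep(100 / W, W)
  rate_b <- rep(1.5 * 100 / W, W); rate_b[core] <- (1 - depl) * 1.5 * 100 / W
  X <- t(vapply(seq_len(n), function(i)
    rpois(W, if (bound[i]) rate_b else rate_u), numeric(W)))
  score <- rnorm(n, ifelse(bound, 12, 10), 2)
  cons <- pmin(pmax(rnorm(n, ifelse(bound, 0.6, 0.4), 0.2), 0), 1)
  fit <- fit_footprint_model(X, score, cons, seed = 1)
  expect_gte(mean((fit$posterior > 0.5) == bound), 0.9)
  expect_gte(mean(bound[fit$posterior > 0.95]), 0.95)
  expect_true(all(diff(fit$loglik) > -1e-6))
  expect_gt(fit$lambda_bound, fit$lambda_unbound)
  # same seed, same posteriors
  fit2 <- fit_footprint_model(X, score, cons, seed = 1)
  expect_identical(fit$posterior, fit2$posterior)
})

test_that("footprint model degenerate inputs behave as documented", {
  X <- matrix(3L, 40, 200)
  fit <- fit_footprint_model(X, rnorm(40), seed = 2)
  expect_lt(diff(range(fit$posterior)), 1e-6)
  expect_warning(fit_footprint_model(X[1:10, ], rnorm(10), seed = 2),
                 "fewer than 20")
})

test_that("upstream TF selection needs enrichment AND rising expression", {
  en <- data.table(pwm = c("m1", "m2", "m3"), p = c(1e-8, 0.5, 1e-8))
  expr <- matrix(c(10, 10, 10, 10,
                   10, 40, 40, 40,
                   10, 11, 10, 12), 3, 4, byrow = TRUE,
                 dimnames = list(c("gFlat", "gUp", "gMild"), c("0", "1", "2", "4")))
  tf_map <- data.table(pwm = c("m1", "m2", "m3"),
                       gene_id = c("gFlat", "gUp", "gMild"))
  sel <- select_upstream_tfs(en, expr, tf_map)
  # m1 enriched but flat -> out; m2 rising but not enriched -> out;
  # m3 enriched but only mildly rising -> out
  expect_equal(nrow(sel), 0L)
  en2 <- data.table(pwm = "m2", p = 1e-8)
  sel2 <- select_upstream_tfs(en2, expr, tf_map)
  expect_equal(sel2$gene_id, "gUp")
})

test_that("build_grn links bound sites in gained DARs to upregulated
           nearest genes", {
  genes <- data.table(gene_id = c("gTF", "gA", "gB"), chrom = "chr1",
                      tss = c(10000L, 50000L, 90000L))
  tfs <- data.table(pwm = "m1", gene_id = "gTF")
  dars <- data.table(chrom = "chr1", start = 54000L, end = 54400L)
  site_in <- data.table(chrom = "chr1", start = 54190L, end = 54200L, pwm = "m1")
  e1 <- build_grn(tfs, site_in, dars, genes, upregulated = "gA")
  expect_equal(nrow(e1), 1L)
  expect_equal(e1$tf, "gTF")
  expect_equal(e1$target, "gA")
  expect_equal(e1$type, "tf_target")
  # nearest gene not upregulated -> no edge
  expect_equal(nrow(build_grn(tfs, site_in, dars, genes, upregulated = "gB")), 0L)
  # site outside any gained DAR -> no edge
  site_out <- copy(site_in)[, `:=`(start = 80000L, end = 80010L)]
  expect_equal(nrow(build_grn(tfs, site_out, dars, genes, upregulated = "gA")), 0L)
  # autoregulation and input-order invariance
  dars2 <- rbind(dars, data.table(chrom = "chr1", start = 12000L, end = 12400L))
  sites2 <- rbind(site_in,
                  data.table(chrom = "chr1", start = 12190L, end = 12200L, pwm = "m1"))
  e2 <- build_grn(tfs, sites2, dars2, genes, upregulated = c("gA", "gTF"))
  expect_setequal(e2$type, c("auto", "tf_target"))
  e2b <- build_grn(tfs, sites2[2:1], dars2[2:1], genes,
                   upregulated = c("gTF", "gA"))
  expect_equal(e2, e2b)
})

test_that("target response comparison behaves like a paired signed-rank test", {
  set.seed(33)
  genes <- paste0("g", 1:200)
  wt <- setNames(rnorm(200, 2, 0.5), genes)
  mut <- wt
  mut[1:100] <- wt[1:100] * 0.5   # targets attenuated by 50%
  mut[101:200] <- wt[101:200] + rnorm(100, 0, 0.05)
  res <- compare_target_response(mut, wt, targets = genes[1:100],
                                 nontargets = genes[101:200])
  expect_lt(res$p_targets, 0.001)
  expect_gt(res$p_nontargets, 0.05)
  # identical fold changes -> p = 1
  same <- compare_target_response(wt, wt, genes[1:100], genes[101:200])
  expect_equal(same$p_targets, 1)
  # two-sided symmetry under swapping mutant and wildtype
  sw <- compare_target_response(wt, mut, genes[1:100], genes[101:200])
  expect_equal(res$p_targets, sw$p_targets)
})

test_that("gRNA score evaluates the printed formula exactly", {
  expect_equal(score_grna(strrep("G", 20), 1, 0), 72)
  expect_equal(score_grna(paste0(strrep("A", 10), strrep("T", 9), "T"), 0, 1), -30)
  expect_equal(score_grna(paste0(strrep("G", 5), strrep("C", 5), strrep("T", 9), "A"),
                          0.5, 0.5), 17)
  # monotone in GC, decreasing in relative position
  s_lowgc <- score_grna(paste0(strrep("A", 10), strrep("G", 10)), 0.5, 0.5)
  s_higc <- score_grna(paste0(strrep("C", 10), strrep("G", 10)), 0.5, 0.5)
  expect_gt(s_higc, s_lowgc)
  expect_gt(score_grna(strrep("G", 20), 0.5, 0.1),
            score_grna(strrep("G", 20), 0.5, 0.9))
  expect_error(score_grna("ACGT", 0.5, 0.5), "20-mer")
  expect_error(score_grna(strrep("N", 20), 0.5, 0.5), "A/C/G/T")
})
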
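mk_meth <- function(region, level, n = 5L, cov = 20L) {
  pos <- as.integer(seq(region$start + 10, region$end - 10, length.out = n))
  cpg_table(pos = pos, meth = round(level * cov), total = cov,
            chrom = region$chrom)
}

test_that("classify_enhancers applies criteria in the documented order", {
  genes <- data.table(gene_id = "g1", chrom = "chr1", tss = 100000L)
  dar <- function(center, dir = "gained")
    data.table(chrom = "chr1", start = center - 200L, end = center + 200L,
               direction = dir)
  # gained, 20 kb out, meth 0.3 stable -> candidate
  d1 <- dar(120000L)
  m0 <- mk_meth(d1, 0.3); m4 <- mk_meth(d1, 0.32)
  expect_equal(classify_enhancers(d1, m0, m4, genes)$class, "candidate")
  # hypermethylated at 0 dpa -> rejected
  expect_equal(classify_enhancers(d1, mk_meth(d1, 0.9), mk_meth(d1, 0.9), genes)$class,
               "rejected(hypermethylated)")
  # unstable methylation -> rejected
  expect_equal(classify_enhancers(d1, mk_meth(d1, 0.2), mk_meth(d1, 0.5), genes)$class,
               "rejected(meth_unstable)")
  # direction outranks everything else
  expect_equal(classify_enhancers(dar(120000L, "lost"), mk_meth(d1, 0.9),
                                  mk_meth(d1, 0.9), genes)$class,
               "rejected(not_gained)")
  # too close to a TSS outranks methylation
  d2 <- dar(101000L)
  expect_equal(classify_enhancers(d2, mk_meth(d2, 0.9), mk_meth(d2, 0.9), genes)$class,
               "rejected(too_close_to_tss)")
  # < 3 covered CpGs -> no_meth_data
  d3 <- dar(150000L)
  m03 <- mk_meth(d3, 0.3, n = 2L)
  expect_equal(classify_enhancers(d3, m03, m03, genes)$class,
               "rejected(no_meth_data)")
})

test_that("classify_enhancers is order-independent and idempotent", {
  genes <- data.table(gene_id = "g1", chrom = "chr1", tss = 100000L)
  set.seed(10)
  centers <- seq(110000L, 170000L, by = 5000L)
  dars <- data.table(chrom = "chr1", start = centers - 200L,
                     end = centers + 200L,
                     direction = sample(c("gained", "lost"), length(centers),
                                        replace = TRUE))
  meth <- rbindlist(lapply(seq_along(centers), function(i)
    mk_meth(dars[i], runif(1, 0.1, 0.9))))
  setkey(meth, chrom, pos)
  a <- classify_enhancers(dars, meth, meth, genes)
  b <- classify_enhancers(dars[sample(.N)], meth, meth, genes)[order(start)]
  expect_equal(a[order(start)]$class, b$class)
  # reasons partition the rejected set
  expect_true(all(grepl("^candidate$|^rejected\\(", a$class)))
})

test_that("hypomethylated fraction counts below-cutoff DARs", {
  dar <- data.table(chrom = "chr1",
                    start = seq(10000L, 100000L, by = 10000L) - 200L,
                    end = seq(10000L, 100000L, by = 10000L) + 200L)
  lev <- c(rep(0.2, 7), rep(0.8, 3))
  meth <- rbindlist(lapply(1:10, function(i) mk_meth(dar[i], lev[i])))
  setkey(meth, chrom, pos)
  hf <- hypomethylated_fraction(dar, meth)
  expect_equal(hf$fraction, 0.7)
  # all low
  meth2 <- rbindlist(lapply(1:10, function(i) mk_meth(dar[i], 0.2)))
  setkey(meth2, chrom, pos)
  expect_equal(hypomethylated_fraction(dar, meth2)$fraction, 1.0)
  # empty set -> missing
  expect_true(is.na(hypomethylated_fraction(dar[0], meth)$fraction))
})

test_that("assay tally partitions rows into candidates and controls", {
  rows <- read_assay_table()
  tl <- tally_assay_table(rows)
  expect_equal(tl$n_candidates + tl$n_negative_controls, nrow(rows))
  # single-row and empty cases
  one <- data.table(element = "x", dar_pos = TRUE, dar_neg = FALSE, egfp = TRUE)
  expect_equal(tally_assay_table(one),
               list(n_candidates = 1L, n_positive = 1L,
                    n_negative_controls = 0L, n_negative_positive = 0L))
  expect_equal(tally_assay_table(one[0])$n_candidates, 0L)
})

test_that("synthetic gained DARs classify as planted", {
  cfg <- sim_config(seed = 6L, n_cpgs = 12000L, n_genes = 60L, n_peaks = 80L,
                    n_celltype_dmrs = 20L, n_dars = 30L, n_de_genes = 15L,
                    n_grn_targets = 9L, n_unbound_sites_per_tf = 10L,
                    chrom_len = 400000L)
  sim <- simulate_all(cfg)
  me <- sim$methylome$samples
  pool2 <- function(a, b) {
    al <- align_cpgs(list(a, b))
    data.table(chrom = al$sites$chrom, pos = al$sites$pos,
               meth = rowSums(al$meth), total = rowSums(al$total))
  }
  m0 <- pool2(me$pos_t0_r1, me$pos_t0_r2)
  m4 <- pool2(me$pos_t4_r1, me$pos_t4_r2)
  gained <- sim$truth$dars[direction == "gained"]
  cls <- classify_enhancers(gained, m0, m4, sim$layout$genes)
  hypo <- gained$hypomethylated
  # hypomethylated distal gained DARs classify as candidates
  distal <- cls$distance_to_tss > 2000
  expect_gte(mean(cls$class[hypo & distal] == "candidate"), 0.95)
  # hypermethylated ones are rejected
  if (any(!hypo)) {
    expect_gte(mean(grepl("rejected", cls$class[!hypo])), 0.95)
  }
})
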
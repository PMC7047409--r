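test_that("Tn5 adjustment applies the +4/-5 offsets", {
  reads <- data.table(chrom = "chr1",
                      start = c(100L, 150L, 100L),
                      end = c(130L, 200L, 300L),
                      strand = c("+", "-", "."))
  ins <- adjust_tn5(reads)
  # + read at 100 -> 104; - read ending at 200 -> 195;
  # fragment (100, 300) -> both ends {104, 295}
  expect_setequal(ins$pos, c(104L, 195L, 104L, 295L))
  expect_equal(attr(ins, "library_size"), 4L)
})

test_that("Tn5 adjustment tallies skips and clips, conserving counts", {
  reads <- data.table(chrom = "chr1",
                      start = c(0L, 50L, 999998L),
                      end = c(30L, 80L, 999999L + 10L),
                      strand = c("-", NA, "."))
  ins <- adjust_tn5(reads, chrom_sizes = c(chr1 = 1000000L))
  expect_equal(attr(ins, "n_skipped"), 1L)
  expect_gte(attr(ins, "n_clipped"), 1L)
  # every non-skipped endpoint yields exactly one insertion
  expect_equal(nrow(ins), 1L + 2L)
})

test_that("peak calling finds a planted peak and controls false windows", {
  set.seed(5)
  sizes <- c(chr1 = 200000L)
  # uniform track: significant-window rate stays below the cutoff
  unif <- data.table(chrom = "chr1", pos = sort(sample(sizes, 2000L)))
  pk0 <- call_peaks(unif, sizes, p_cut = 0.01)
  n_windows <- length(seq(0, sizes - 200, by = 50))
  windows_in_peaks <- sum(pmax(pk0$end - pk0$start - 150, 0) / 50)
  expect_lte(windows_in_peaks / n_windows, 0.01)
  # single 300-bp region at 10x background, high depth
  n_bg <- 100000L
  bg <- data.table(chrom = "chr1", pos = sort(sample(sizes, n_bg, replace = TRUE)))
  rate <- n_bg / sizes
  hot <- data.table(chrom = "chr1",
                    pos = sort(sample(50000:50299, round(10 * rate * 300),
                                      replace = TRUE)))
  pk <- call_peaks(rbind(bg, hot)[order(pos)], sizes, p_cut = 1e-4)
  hit <- pk[start <= 50000 & end >= 50300]
  expect_equal(nrow(hit), 1L)
  expect_true(all(pk$summit >= pk$start & pk$summit < pk$end))
  if (nrow(pk) > 1) expect_true(all(pk$start[-1] >= pk$end[-nrow(pk)]))
})

test_that("reproducible peaks keep shared peaks only", {
  mkpeaks <- function(starts, enr) {
    data.table(chrom = "chr1", start = starts, end = starts + 400L,
               summit = starts + 200L, enrichment = enr)
  }
  set.seed(6)
  shared <- seq(10000L, by = 5000L, length.out = 100L)
  only1 <- seq(600000L, by = 5000L, length.out = 50L)
  enr <- runif(100, 2, 30)
  p1 <- mkpeaks(c(shared, only1), c(enr, runif(50, 2, 30)))
  p2 <- mkpeaks(shared + 50L, enr * runif(100, 0.8, 1.25))
  keep <- reproducible_peaks(p1, p2)
  expect_equal(sort(keep$start), sort(shared))
  # identical sets -> all kept; disjoint -> none
  expect_equal(nrow(reproducible_peaks(p1, p1)), nrow(p1))
  expect_equal(nrow(reproducible_peaks(mkpeaks(shared, enr),
                                       mkpeaks(shared + 2500L, enr))), 0L)
})

test_that("insertion counting uses half-open membership", {
  peaks <- data.table(chrom = "chr1", start = 100L, end = 200L)
  tr <- data.table(chrom = "chr1", pos = c(100L, 150L, 199L, 200L))
  mat <- count_insertions(peaks, list(a = tr, b = tr[0]))
  expect_equal(mat[1, "a"], 3L, ignore_attr = TRUE)
  expect_equal(mat[1, "b"], 0L, ignore_attr = TRUE)
  # total over peaks never exceeds the library
  set.seed(2)
  pk <- data.table(chrom = "chr1", start = seq(0L, 9000L, by = 1000L),
                   end = seq(400L, 9400L, by = 1000L))
  tr2 <- data.table(chrom = "chr1", pos = sort(sample(10000L, 500L)))
  m2 <- count_insertions(pk, list(s = tr2))
  expect_lte(sum(m2), nrow(tr2))
})

test_that("test_dars flips direction exactly under label swap", {
  set.seed(9)
  mat <- matrix(rnbinom(400 * 4, mu = 80, size = 20), 400, 4)
  mat[1:30, 3:4] <- rnbinom(60, mu = 320, size = 20)
  g <- factor(c("a", "a", "b", "b"), levels = c("a", "b"))
  g_sw <- factor(c("b", "b", "a", "a"), levels = c("a", "b"))
  d1 <- test_dars(mat, g, all_results = TRUE)
  d2 <- test_dars(mat[, c(3, 4, 1, 2)], g, all_results = TRUE)
  expect_equal(d1$log2_fold, -d2$log2_fold, tolerance = 1e-12)
  expect_equal(d1$p, d2$p, tolerance = 1e-12)
  expect_equal(d1$significant, d2$significant)
  flipped <- ifelse(d2$direction == "gained", "lost", "gained")
  expect_equal(d1$direction, flipped)
  # identical groups -> no DARs
  expect_equal(nrow(test_dars(cbind(mat[, 1:2], mat[, 1:2]), g)), 0L)
})

test_that("peak annotation classifies promoter, proximal, distal", {
  genes <- data.table(gene_id = c("g1", "g2"), chrom = "chr1",
                      tss = c(100000L, 140000L))
  mkpeak <- function(center) data.table(chrom = "chr1", start = center - 200L,
                                        end = center + 200L)
  peaks <- rbind(mkpeak(101000L),   # 1 kb -> promoter
                 mkpeak(106000L),   # 6 kb -> proximal
                 mkpeak(80000L),    # 20 kb -> distal
                 mkpeak(102000L),   # exactly 2 kb -> promoter (inclusive)
                 mkpeak(50000L))    # 50 kb -> distal
  ann <- annotate_peaks(peaks, genes)[order(start)]
  expect_equal(ann$annotation,
               c("distal", "distal", "promoter", "promoter", "proximal"))
  expect_equal(ann[start == 100800L, tss_distance], 1000)
})
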
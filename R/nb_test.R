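#' Median-of-ratios size factors
#'
#' For each sample, the factor is the median over features (restricted to
#' rows with all-positive counts) of the ratio of the count to the row
#' geometric mean.
#'
#' @param mat feature x sample count matrix.
#' @return numeric vector of per-sample size factors.
#' @export
size_factors <- function(mat) {
  mat <- as.matrix(mat)
  pos <- rowSums(mat > 0) == ncol(mat)
  if (!any(pos)) stop("no feature has all-positive counts; cannot estimate size factors")
  lg <- log(mat[pos, , drop = FALSE])
  gm <- rowMeans(lg)
  sf <- apply(exp(lg - gm), 2, median)
  setNames(sf, colnames(mat))
}

# Fit a simple mean-dispersion trend alpha(mu) = a0 + a1 / mu on binned
# means of the raw MoM estimates; returns a function of mu. Evaluation
# is clamped to the fitted mean range (no extrapolation), and when the
# means barely spread the trend degenerates to the global mean.
fit_dispersion_trend <- function(mu, alpha_raw) {
  ok <- is.finite(mu) & is.finite(alpha_raw) & mu > 0
  mu <- mu[ok]; alpha_raw <- alpha_raw[ok]
  flat <- function() {
    a <- max(mean(alpha_raw), 1e-8)
    function(m) rep(a, length(m))
  }
  if (length(mu) < 20) return(flat())
  qs <- unique(quantile(mu, probs = seq(0, 1, length.out = 21)))
  bins <- cut(mu, breaks = qs, include.lowest = TRUE)
  bm <- tapply(mu, bins, mean)
  ba <- tapply(alpha_raw, bins, mean)
  keep <- is.finite(bm) & is.finite(ba)
  if (sum(keep) < 3 || diff(range(bm[keep])) < 0.1 * mean(bm[keep])) return(flat())
  fit <- stats::lm(ba[keep] ~ I(1 / bm[keep]))
  a0 <- max(unname(coef(fit)[1]), 0)
  a1 <- max(unname(coef(fit)[2]), 0)
  lo <- min(bm[keep]); hi <- max(bm[keep])
  function(m) pmax(a0 + a1 / pmin(pmax(m, lo), hi), 1e-8)
}

#' Negative-binomial Wald test between two groups (shared engine)
#'
#' Counts are normalized by median-of-ratios size factors. Per-feature
#' NB dispersion is a method-of-moments estimate from within-group
#' replicate variation, shrunk halfway toward a fitted mean-dispersion
#' trend. The Wald statistic compares log group means with a delta-method
#' standard error; p-values are two-sided normal tails with
#' Benjamini-Hochberg FDR across features. This one engine backs both
#' differential accessibility and differential expression.
#'
#' @param mat feature x sample count matrix.
#' @param groups length-`ncol(mat)` factor with two levels; fold changes
#'   are level 2 over level 1.
#' @param prior_df prior degrees of freedom for dispersion moderation:
#'   the per-feature estimate is weighted `df / (df + prior_df)` against
#'   the trend (default 6), so with very few replicates the trend
#'   dominates and the test stays calibrated.
#' @return `data.table` with `id`, `base_mean`, `mean1`, `mean2`,
#'   `log2_fold`, `p`, `fdr`. Features with all-zero counts get `NA`
#'   p-values.
#' @export
nb_wald_test <- function(mat, groups, prior_df = 6) {
  mat <- as.matrix(mat)
  groups <- as.factor(groups)
  stopifnot(nlevels(groups) == 2L, ncol(mat) == length(groups))
  sf <- size_factors(mat)
  norm <- sweep(mat, 2, sf, "/")
  i1 <- which(groups == levels(groups)[1])
  i2 <- which(groups == levels(groups)[2])
  m1 <- rowMeans(norm[, i1, drop = FALSE])
  m2 <- rowMeans(norm[, i2, drop = FALSE])
  base_mean <- rowMeans(norm)
  # MoM dispersion from within-group variance of normalized counts:
  # Var(K/s) = mu/s + alpha mu^2
  pooled_var <- function(idx, m) {
    if (length(idx) < 2L) return(rep(NA_real_, nrow(mat)))
    rowSums((norm[, idx, drop = FALSE] - m)^2) / (length(idx) - 1L)
  }
  v1 <- pooled_var(i1, m1); v2 <- pooled_var(i2, m2)
  df1 <- max(length(i1) - 1L, 0L); df2 <- max(length(i2) - 1L, 0L)
  s2 <- (v1 * df1 + v2 * df2) / max(df1 + df2, 1L)
  # per-group moments: Var_g(K/s) = mu_g c + alpha mu_g^2, so the shot
  # noise and quadratic terms must use the group means, not the pooled
  # base mean (which biases alpha upward for truly changed features)
  cbar <- mean(1 / sf)
  shot <- cbar * (df1 * m1 + df2 * m2) / max(df1 + df2, 1L)
  quad <- (df1 * m1^2 + df2 * m2^2) / max(df1 + df2, 1L)
  alpha_raw <- pmax((s2 - shot) / pmax(quad, 1e-8), 0)
  trend <- fit_dispersion_trend(base_mean, alpha_raw)
  w <- (df1 + df2) / (df1 + df2 + prior_df)
  alpha <- pmin(pmax(w * alpha_raw + (1 - w) * trend(base_mean), 1e-8), 10)
  # delta-method variance of log group means (pseudocount 0.5 stabilizes
  # zero groups): Var(mean_j K_j/s_j) = (mu sum(1/s_j) + R alpha mu^2)/R^2
  vm1 <- (m1 * sum(1 / sf[i1]) + length(i1) * alpha * m1^2) / length(i1)^2
  vm2 <- (m2 * sum(1 / sf[i2]) + length(i2) * alpha * m2^2) / length(i2)^2
  a1 <- m1 + 0.5; a2 <- m2 + 0.5
  lfc <- log2(a2 / a1)
  se <- sqrt(vm1 / a1^2 + vm2 / a2^2)
  z <- (log(a2) - log(a1)) / pmax(se, 1e-12)
  p <- 2 * pnorm(-abs(z))
  allzero <- rowSums(mat) == 0
  p[allzero] <- NA_real_
  fdr <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  fdr[ok] <- p.adjust(p[ok], method = "BH")
  ids <- rownames(mat)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(mat)))
  data.table(id = ids, base_mean = base_mean, mean1 = m1, mean2 = m2,
             log2_fold = lfc, p = p, fdr = fdr)
}
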
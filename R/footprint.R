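#' Two-component mixture model for TF footprints
#'
#' Models the Tn5 insertion count vector of each motif-site window as a
#' mixture of a bound component (higher Poisson total-count rate, learned
#' multinomial positional profile with core depletion) and an unbound
#' component (lower rate, uniform profile). The per-site prior of being
#' bound is logistic in the motif score and a conservation score.
#' Parameters are fitted by EM (tolerance `1e-6` on the observed-data
#' log-likelihood, at most `max_iter` iterations) from a seeded
#' k-means-style initialization; the bound component is identified as
#' the one with the higher total-count rate. Missing conservation scores
#' are imputed with the track mean.
#'
#' @param counts site x position (window) insertion count matrix.
#' @param motif_score per-site motif log-odds scores.
#' @param conservation optional per-site conservation scores (`NA`s
#'   imputed).
#' @param posterior_cut posterior above which a site is called bound
#'   (default 0.95).
#' @param max_iter maximum EM iterations (default 200).
#' @param tol convergence tolerance on the log-likelihood (default 1e-6).
#' @param seed integer seed for the initialization (default 1).
#' @return list with `posterior` (per site), `bound` (logical,
#'   `posterior > posterior_cut`), `loglik` (trace, non-decreasing),
#'   `profile` (bound positional profile), `lambda_bound`,
#'   `lambda_unbound`, `prior_coef`, and `fitted` (FALSE when fewer than
#'   20 sites, in which case prior-only posteriors are returned with a
#'   warning).
#' @export
fit_footprint_model <- function(counts, motif_score,
                                conservation = NULL, posterior_cut = 0.95,
                                max_iter = 200L, tol = 1e-6, seed = 1L) {
  X <- as.matrix(counts)
  n <- nrow(X); W <- ncol(X)
  stopifnot(length(motif_score) == n)
  if (is.null(conservation)) conservation <- rep(0, n)
  cons <- conservation
  if (all(is.na(cons))) cons <- rep(0, n)
  cons[is.na(cons)] <- mean(cons, na.rm = TRUE)
  N <- rowSums(X)
  design <- cbind(1, scale_safe(motif_score), scale_safe(cons))
  if (n < 20L) {
    warning("fewer than 20 sites: returning prior-only posteriors")
    post <- rep(0.5, n)
    return(list(posterior = post, bound = post > posterior_cut,
                loglik = numeric(0), profile = rep(1 / W, W),
                lambda_bound = NA_real_, lambda_unbound = NA_real_,
                prior_coef = c(0, 0, 0), fitted = FALSE))
  }
  # seeded k-means-style init on (total count, core/flank contrast)
  set.seed(seed)
  core <- seq(floor(W / 2) - max(floor(W / 20), 1L),
              ceiling(W / 2) + max(floor(W / 20), 1L))
  core <- core[core >= 1 & core <= W]
  contrast <- rowMeans(X[, core, drop = FALSE]) /
    pmax(rowMeans(X[, -core, drop = FALSE]), 1e-6)
  feat <- cbind(scale_safe(N), scale_safe(contrast))
  km_assign <- simple_kmeans2(feat, seed = seed)
  z <- as.numeric(km_assign == which.max(tapply(N, km_assign, mean)))
  if (all(z == 0) || all(z == 1)) z <- rep(0.5, n)
  beta <- c(0, 0, 0)
  loglik <- numeric(0)
  ll_prev <- -Inf
  lp_unif <- -log(W)
  for (iter in seq_len(max_iter)) {
    # M-step
    lb <- sum(z * N) / max(sum(z), 1e-9)
    lu <- sum((1 - z) * N) / max(sum(1 - z), 1e-9)
    # identifiability: bound = higher total-count rate; relabel once at
    # the start so the EM ascent is not interrupted later
    if (iter == 1L && lb < lu) { z <- 1 - z; tmp <- lb; lb <- lu; lu <- tmp }
    prof <- colSums(X * z) + 0.5
    prof <- prof / sum(prof)
    beta <- fit_logistic_prior(design, z, beta)
    # E-step pieces (Poisson total + multinomial positions; the shared
    # multinomial coefficient cancels between components)
    eta <- drop(design %*% beta)
    lp_prior <- plogis(eta, log.p = TRUE)
    lp_prior0 <- plogis(-eta, log.p = TRUE)
    lb_ <- max(lb, 1e-9); lu_ <- max(lu, 1e-9)
    la <- N * log(lb_) - lb_ + drop(X %*% log(prof)) + lp_prior
    lo <- N * log(lu_) - lu_ + N * lp_unif + lp_prior0
    m <- pmax(la, lo)
    ll <- sum(m + log(exp(la - m) + exp(lo - m)))
    loglik <- c(loglik, ll)
    z <- 1 / (1 + exp(lo - la))
    if (is.finite(ll_prev) && abs(ll - ll_prev) < tol * (abs(ll_prev) + 1)) break
    ll_prev <- ll
  }
  list(posterior = z, bound = z > posterior_cut, loglik = loglik,
       profile = prof, lambda_bound = lb, lambda_unbound = lu,
       prior_coef = beta, fitted = TRUE)
}

scale_safe <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

# Deterministic 2-means on a feature matrix: initialized at the extreme
# points along the first feature, a few Lloyd iterations.
simple_kmeans2 <- function(feat, seed = 1L, iters = 10L) {
  f <- as.matrix(feat)
  c1 <- f[which.min(f[, 1]), , drop = FALSE]
  c2 <- f[which.max(f[, 1]), , drop = FALSE]
  assign <- rep(1L, nrow(f))
  for (i in seq_len(iters)) {
    d1 <- rowSums(sweep(f, 2, c1, "-")^2)
    d2 <- rowSums(sweep(f, 2, c2, "-")^2)
    new_assign <- ifelse(d2 < d1, 2L, 1L)
    if (identical(new_assign, assign) && i > 1L) break
    assign <- new_assign
    if (any(assign == 1L)) c1 <- colMeans(f[assign == 1L, , drop = FALSE])
    if (any(assign == 2L)) c2 <- colMeans(f[assign == 2L, , drop = FALSE])
  }
  assign
}

# Weighted logistic regression M-step for the site prior; falls back to
# the previous coefficients if IRLS fails.
fit_logistic_prior <- function(design, z, beta_prev) {
  z <- pmin(pmax(z, 1e-6), 1 - 1e-6)
  fit <- tryCatch(
    suppressWarnings(glm.fit(design, z, family = binomial())),
    error = function(e) NULL)
  if (is.null(fit) || !all(is.finite(coef(fit)))) return(beta_prev)
  cf <- coef(fit)
  # cap the linear scale so the prior cannot collapse to 0/1
  pmin(pmax(cf, -8), 8)
}
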
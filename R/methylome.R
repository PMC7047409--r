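#' Moving-window smoothing of CpG methylation
#'
#' Estimates the local methylation level of each CpG as the pooled ratio
#' `sum(meth) / sum(total)` over all CpGs within `window_bp / 2` on either
#' side. An isolated CpG (no covered neighbour in the window) keeps its
#' raw ratio; a CpG with `total = 0` and no covered neighbour gets
#' `mu_hat = NA` (flagged missing). The window sums are also returned:
#' they are the effective counts used by the region-level Wald test, and
#' `sum_tt = sum(total * (total - 1))` over the window carries the
#' dispersion scaling for pooled independent CpGs.
#'
#' @param cpgs `data.table` with `chrom`, `pos`, `meth`, `total`, sorted
#'   by (`chrom`, `pos`).
#' @param window_bp full window width in bp (default 500).
#' @param tt optional per-CpG sum of `t_r (t_r - 1)` over the
#'   independent beta-binomial draws making up `total` (one term per
#'   sample when replicate counts were pooled); defaults to
#'   `total * (total - 1)`, i.e. a single draw per CpG.
#' @return the input with columns `mu_hat`, `m_win`, `t_win`, `sum_tt`
#'   added.
#' @export
smooth_methylation <- function(cpgs, window_bp = 500, tt = NULL) {
  dt <- as.data.table(cpgs)
  if (is.null(tt)) tt <- as.numeric(dt$total) * (as.numeric(dt$total) - 1)
  dt[, .tt_draw := tt]
  if (is.unsorted(dt$chrom) && !identical(order(dt$chrom, dt$pos), seq_len(nrow(dt))))
    stop("cpgs must be sorted by (chrom, pos)")
  if (any(dt[, is.unsorted(pos), by = chrom]$V1))
    stop("cpgs must be sorted by (chrom, pos)")
  half <- window_bp / 2
  smooth_one <- function(pos, meth, total, ttd) {
    lo <- findInterval(pos - half - 0.5, pos) + 1L
    hi <- findInterval(pos + half + 0.5, pos)
    cm <- c(0, cumsum(as.numeric(meth)))
    ct <- c(0, cumsum(as.numeric(total)))
    ctt <- c(0, cumsum(ttd))
    m_win <- cm[hi + 1L] - cm[lo]
    t_win <- ct[hi + 1L] - ct[lo]
    sum_tt <- ctt[hi + 1L] - ctt[lo]
    mu <- ifelse(t_win > 0, m_win / t_win, NA_real_)
    list(mu_hat = mu, m_win = m_win, t_win = t_win, sum_tt = sum_tt)
  }
  dt[, c("mu_hat", "m_win", "t_win", "sum_tt") :=
       smooth_one(pos, meth, total, .tt_draw), by = chrom]
  dt[, .tt_draw := NULL]
  dt[]
}

#' Method-of-moments beta-binomial dispersion per CpG
#'
#' With replicates, a per-CpG raw estimate is formed from within-group
#' replicate variation of methylation proportions and shrunk toward the
#' genome-wide (trimmed-mean) dispersion with weight
#' `coverage / (coverage + 50)`. With a single sample per group, the
#' genome-wide estimate is derived from local spatial variation: squared
#' residuals of raw ratios around the smoothed mean, solved for `phi`
#' under the beta-binomial variance
#' `mu (1 - mu) (1 / t + phi (1 - 1 / t))`. Estimates are clipped to
#' `[1e-4, 0.5]`.
#'
#' @param meth_mat,total_mat CpG x sample matrices of methylated and total
#'   counts (rows aligned across samples).
#' @param groups integer or factor of length `ncol(meth_mat)` with two
#'   levels assigning samples to groups.
#' @param mu_hat optional per-CpG smoothed means (pooled over samples);
#'   computed from pooled raw ratios when missing. Used by the
#'   single-sample fallback.
#' @return numeric vector of per-CpG `phi` estimates.
#' @export
estimate_dispersion <- function(meth_mat, total_mat, groups, mu_hat = NULL) {
  meth_mat <- as.matrix(meth_mat); total_mat <- as.matrix(total_mat)
  groups <- as.factor(groups)
  stopifnot(nlevels(groups) == 2L, ncol(meth_mat) == length(groups))
  n <- nrow(meth_mat)
  clip <- function(x) pmin(pmax(x, 1e-4), 0.5)
  reps <- table(groups)
  if (all(reps >= 2L)) {
    ss <- numeric(n); df <- numeric(n); bsum <- numeric(n); dsum <- numeric(n)
    for (g in levels(groups)) {
      idx <- which(groups == g)
      Tm <- total_mat[, idx, drop = FALSE]
      P <- meth_mat[, idx, drop = FALSE] / ifelse(Tm > 0, Tm, NA)
      r <- rowSums(!is.na(P))
      mu <- rowSums(meth_mat[, idx, drop = FALSE]) / pmax(rowSums(Tm), 1)
      res2 <- rowSums((P - mu)^2, na.rm = TRUE)
      ss <- ss + res2
      df <- df + pmax(r - 1, 0)
      v <- mu * (1 - mu)
      inv_t <- rowMeans(ifelse(Tm > 0, 1 / Tm, NA), na.rm = TRUE)
      bsum <- bsum + v * inv_t * pmax(r - 1, 0)
      dsum <- dsum + v * (1 - inv_t) * pmax(r - 1, 0)
    }
    ok <- df > 0 & dsum > 0
    s2 <- ifelse(ok, ss / pmax(df, 1), NA)
    b <- ifelse(ok, bsum / pmax(df, 1), NA)
    d <- ifelse(ok, dsum / pmax(df, 1), NA)
    phi_raw <- pmax((s2 - b) / d, 0)
    # genome-wide target: trimmed mean of the unbiased raw estimates
    usable <- ok & is.finite(phi_raw)
    phi_global <- if (any(usable)) mean(phi_raw[usable], trim = 0.05) else 1e-3
    cov_mean <- rowMeans(total_mat)
    w <- cov_mean / (cov_mean + 50)
    phi <- ifelse(usable, w * phi_raw + (1 - w) * phi_global, phi_global)
    return(clip(phi))
  }
  # single sample per group: global estimate from local spatial
  # variation. When no smoothed mean is supplied, a +/- 5-row moving
  # average of the pooled ratios stands in; since the reference mean
  # includes the CpG itself, residual variance is deflated by (1 - 1/w)
  # and the estimate is corrected accordingly.
  m_pool <- rowSums(meth_mat); t_pool <- rowSums(total_mat)
  p_raw <- ifelse(t_pool > 0, m_pool / t_pool, NA)
  noise_corr <- 1
  if (is.null(mu_hat)) {
    w <- 11
    k <- rep(1 / w, w)
    padded <- stats::filter(ifelse(is.na(p_raw), mean(p_raw, na.rm = TRUE), p_raw), k)
    mu_hat <- as.numeric(padded)
    noise_corr <- w / (w - 1)
  }
  v <- mu_hat * (1 - mu_hat)
  use <- is.finite(p_raw) & is.finite(mu_hat) & is.finite(v) &
    v > 0.05 & t_pool >= 5
  if (!any(use)) return(rep(1e-3, n))
  r2 <- (p_raw[use] - mu_hat[use])^2 / v[use] * noise_corr
  inv_t <- 1 / t_pool[use]
  phi_global <- (mean(r2) - mean(inv_t)) / (1 - mean(inv_t))
  rep(clip(phi_global), n)
}

#' Beta-binomial Wald test for a methylation difference at one CpG
#'
#' Group methylation levels are `mu_i = m_i / t_i` (or supplied smoothed
#' means) and the variance of each is
#' `mu_i (1 - mu_i) (1 + (t_i - 1) phi_i) / t_i`. The statistic is
#' `wald = (mu1 - mu2) / sqrt(var1 + var2)` with an epsilon floor (1e-8)
#' on the pooled variance so degenerate proportions (0/t vs 0/t) yield
#' `wald = 0, p = 1`. `p` is the two-sided standard-normal tail. A side
#' with `t = 0` yields a skipped test (`p = NA`). All arguments are
#' vectorized.
#'
#' @param m1,t1,m2,t2 methylated and total counts per group.
#' @param phi dispersion for group 1 (and group 2 unless `phi2` given).
#' @param phi2 optional dispersion for group 2.
#' @param mu1,mu2 optional externally estimated (smoothed) group means.
#' @return `data.table` with `mu1`, `mu2`, `phi`, `wald`, `p`.
#' @export
wald_test_cpg <- function(m1, t1, m2, t2, phi, phi2 = phi,
                          mu1 = NULL, mu2 = NULL) {
  if (is.null(mu1)) mu1 <- ifelse(t1 > 0, m1 / t1, NA_real_)
  if (is.null(mu2)) mu2 <- ifelse(t2 > 0, m2 / t2, NA_real_)
  var1 <- mu1 * (1 - mu1) * (1 + (t1 - 1) * phi) / pmax(t1, 1)
  var2 <- mu2 * (1 - mu2) * (1 + (t2 - 1) * phi2) / pmax(t2, 1)
  v <- pmax(var1 + var2, 1e-8)
  wald <- (mu1 - mu2) / sqrt(v)
  wald[mu1 == mu2] <- 0
  p <- 2 * pnorm(-abs(wald))
  skip <- t1 <= 0 | t2 <= 0
  wald[skip] <- NA_real_; p[skip] <- NA_real_
  data.table(mu1 = mu1, mu2 = mu2, phi = (phi + phi2) / 2, wald = wald, p = p)
}

#' Default DMR-calling parameters
#'
#' Region assembly uses `delta = 0, minlen = 200, minCG = 5,
#' dis_merge = 50, pct_sig = 0.5` with a default per-CpG significance
#' threshold of `p < 1e-5`; final filtering requires a mean methylation
#' difference above 0.25 and at least 5 CpGs covered by at least 5 reads
#' in both groups.
#'
#' @param ... overrides for any parameter.
#' @return named list of parameters.
#' @export
dmr_params <- function(...) {
  p <- list(delta = 0, minlen = 200, minCG = 5L, dis_merge = 50,
            pct_sig = 0.5, p_threshold = 1e-5, min_mean_diff = 0.25,
            min_covered_cpgs = 5L, min_cov = 5L,
            smooth_window = 500, max_insig_run = 2L, max_gap = 300)
  over <- list(...)
  unknown <- setdiff(names(over), names(p))
  if (length(unknown)) stop("unknown dmr parameter(s): ", paste(unknown, collapse = ", "))
  p[names(over)] <- over
  stopifnot(p$pct_sig > 0, p$pct_sig <= 1, p$minlen > 0, p$minCG > 0,
            p$p_threshold > 0, p$dis_merge >= 0)
  p
}

#' Per-CpG differential methylation tests between two sample groups
#'
#' The full testing chain: align CpGs across samples, pool counts within
#' groups, smooth each group, estimate dispersion, and run the Wald test
#' per CpG using the smoothed (window-pooled) counts. Because a window
#' pools independent CpGs, the effective dispersion of the pooled counts
#' is rescaled as `phi_eff = phi * sum(t_j (t_j - 1)) / (T (T - 1))`,
#' which is exact for CpGs sharing the window mean.
#'
#' @param group1,group2 lists of per-sample CpG `data.table`s
#'   (`chrom`, `pos`, `meth`, `total`).
#' @param params parameter list from [dmr_params()].
#' @return `data.table` with per-CpG positions, raw pooled counts per
#'   group, smoothed means, `phi`, `wald` and `p`, sorted by position.
#' @export
dml_test <- function(group1, group2, params = dmr_params()) {
  aligned <- align_cpgs(c(group1, group2))
  g <- factor(rep(c(1L, 2L), c(length(group1), length(group2))))
  M <- aligned$meth; Tt <- aligned$total
  key <- aligned$sites
  pool <- function(idx) {
    dt <- copy(key)
    dt[, meth := rowSums(M[, idx, drop = FALSE])]
    dt[, total := rowSums(Tt[, idx, drop = FALSE])]
    dt
  }
  # per-sample t (t - 1) sums: pooled replicate counts are sums of
  # independent beta-binomial draws, so the overdispersion term scales
  # with the per-sample totals, not the pooled total
  tt_of <- function(idx) {
    Tg <- Tt[, idx, drop = FALSE]
    rowSums(Tg * (Tg - 1))
  }
  s1 <- smooth_methylation(pool(which(g == 1L)), params$smooth_window,
                           tt = tt_of(which(g == 1L)))
  s2 <- smooth_methylation(pool(which(g == 2L)), params$smooth_window,
                           tt = tt_of(which(g == 2L)))
  phi <- estimate_dispersion(M, Tt, g,
                             mu_hat = (s1$m_win + s2$m_win) / pmax(s1$t_win + s2$t_win, 1))
  # the test runs on window-pooled counts, so the dispersion is averaged
  # over the same window (per-CpG 2-df estimates are far too noisy)
  phi <- smooth_in_window(key$chrom, key$pos, phi, params$smooth_window)
  phi_eff <- function(s) ifelse(s$t_win > 1, phi * s$sum_tt / (s$t_win * (s$t_win - 1)), phi)
  wt <- wald_test_cpg(s1$m_win, s1$t_win, s2$m_win, s2$t_win,
                      phi = phi_eff(s1), phi2 = phi_eff(s2))
  out <- data.table(chrom = key$chrom, pos = key$pos,
                    m1 = s1$meth, t1 = s1$total, m2 = s2$meth, t2 = s2$total,
                    mu1 = wt$mu1, mu2 = wt$mu2, phi = phi,
                    wald = wt$wald, p = wt$p)
  setorder(out, chrom, pos)
  out[]
}

# moving-window mean of a per-CpG quantity (same geometry as
# smooth_methylation)
smooth_in_window <- function(chrom, pos, x, window_bp = 500) {
  half <- window_bp / 2
  out <- numeric(length(x))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    p <- pos[idx]
    lo <- findInterval(p - half - 0.5, p) + 1L
    hi <- findInterval(p + half + 0.5, p)
    cx <- c(0, cumsum(x[idx]))
    out[idx] <- (cx[hi + 1L] - cx[lo]) / (hi - lo + 1L)
  }
  out
}

#' Align per-sample CpG tables on the union of positions
#'
#' @param samples list of CpG `data.table`s.
#' @return list with `sites` (`chrom`, `pos`) and `meth` / `total`
#'   matrices (CpG x sample; absent positions get 0 counts).
#' @export
align_cpgs <- function(samples) {
  sites <- unique(rbindlist(lapply(samples, function(s) s[, .(chrom, pos)])))
  setkey(sites, chrom, pos)
  M <- matrix(0, nrow(sites), length(samples))
  Tt <- matrix(0, nrow(sites), length(samples))
  for (j in seq_along(samples)) {
    s <- as.data.table(samples[[j]])
    idx <- sites[s[, .(chrom, pos)], on = c("chrom", "pos"), which = TRUE]
    M[idx, j] <- s$meth
    Tt[idx, j] <- s$total
  }
  list(sites = sites, meth = M, total = Tt)
}

#' Assemble candidate differentially methylated regions from per-CpG tests
#'
#' Significant CpGs (`p < p_threshold`, same sign of difference) are
#' chained into runs; a run is broken when more than `max_insig_run`
#' consecutive CpGs are insignificant or the gap between adjacent CpGs
#' exceeds `max_gap` bp. A candidate region spans the first to last
#' significant CpG of its run and is kept when its length is at least
#' `minlen`, it contains at least `minCG` CpGs, and the fraction of
#' significant CpGs is at least `pct_sig`. Surviving regions of the same
#' sign separated by at most `dis_merge` bp are merged, and the mean
#' difference is recomputed over all CpGs of the final region from the
#' raw pooled counts.
#'
#' @param tests per-CpG test table from [dml_test()] (requires `chrom`,
#'   `pos`, `p`, `mu1`, `mu2`, and for mean recomputation `m1`, `t1`,
#'   `m2`, `t2`; `wald` feeds the area statistic).
#' @param params parameter list from [dmr_params()].
#' @param labels length-2 character vector naming the two groups (used
#'   for `hypo_in`).
#' @return `data.table` of regions: `chrom`, `start`, `end`, `n_cpgs`,
#'   `n_sig`, `mean_diff` (group1 - group2), `hypo_in`, `area_stat`,
#'   sorted and non-overlapping.
#' @export
call_dmrs <- function(tests, params = dmr_params(),
                      labels = c("group1", "group2")) {
  dt <- as.data.table(tests)
  if (nrow(dt) == 0L) return(empty_dmr_table())
  setorder(dt, chrom, pos)
  if (!"wald" %in% names(dt)) dt[, wald := 0]
  dt[, diffm := mu1 - mu2]
  dt[, sig := !is.na(p) & p < params$p_threshold & !is.na(diffm)]
  regions <- list()
  for (ch in unique(dt$chrom)) {
    d <- dt[chrom == ch]
    sig_idx <- which(d$sig)
    if (!length(sig_idx)) next
    # chain significant CpGs into runs
    run_start <- sig_idx[1]; prev <- sig_idx[1]
    runs <- list()
    if (length(sig_idx) > 1L) {
      for (i in sig_idx[-1]) {
        n_between <- i - prev - 1L
        gap_ok <- all(diff(d$pos[prev:i]) <= params$max_gap)
        same_sign <- sign(d$diffm[i]) == sign(d$diffm[prev])
        if (n_between <= params$max_insig_run && gap_ok && same_sign) {
          prev <- i
        } else {
          runs[[length(runs) + 1L]] <- c(run_start, prev)
          run_start <- i; prev <- i
        }
      }
    }
    runs[[length(runs) + 1L]] <- c(run_start, prev)
    for (r in runs) {
      i1 <- r[1]; i2 <- r[2]
      n_all <- i2 - i1 + 1L
      n_sig <- sum(d$sig[i1:i2])
      len <- d$pos[i2] + 2L - d$pos[i1]  # dyad occupies pos .. pos+1
      if (len >= params$minlen && n_all >= params$minCG &&
          n_sig / n_all >= params$pct_sig) {
        regions[[length(regions) + 1L]] <-
          data.table(chrom = ch, start = d$pos[i1], end = d$pos[i2] + 2L,
                     sign = sign(sum(d$diffm[i1:i2], na.rm = TRUE)))
      }
    }
  }
  if (!length(regions)) return(empty_dmr_table())
  reg <- rbindlist(regions)
  # trim region boundaries: drop flanking CpGs whose raw per-CpG
  # difference is small or of the wrong sign -- they are significant
  # only because the smoothing window bleeds across the region edge.
  # Region thresholds are re-applied afterwards.
  dt[, rawdiff := ifelse(t1 > 0 & t2 > 0, m1 / pmax(t1, 1) - m2 / pmax(t2, 1), NA_real_)]
  trim <- params$min_mean_diff
  trimmed <- vector("list", nrow(reg))
  for (k in seq_len(nrow(reg))) {
    d <- dt[chrom == reg$chrom[k] & pos >= reg$start[k] & pos < reg$end[k]]
    keepable <- !is.na(d$rawdiff) & sign(d$rawdiff) == reg$sign[k] &
      abs(d$rawdiff) >= trim
    if (!any(keepable)) next
    i1 <- which(keepable)[1]; i2 <- tail(which(keepable), 1)
    n_all <- i2 - i1 + 1L
    n_sig <- sum(d$sig[i1:i2])
    len <- d$pos[i2] + 2L - d$pos[i1]
    if (len >= params$minlen && n_all >= params$minCG &&
        n_sig / n_all >= params$pct_sig) {
      trimmed[[k]] <- data.table(chrom = reg$chrom[k], start = d$pos[i1],
                                 end = d$pos[i2] + 2L, sign = reg$sign[k])
    }
  }
  trimmed <- trimmed[!vapply(trimmed, is.null, logical(1))]
  if (!length(trimmed)) return(empty_dmr_table())
  reg <- rbindlist(trimmed)
  setorder(reg, chrom, start)
  # merge same-sign regions separated by <= dis_merge
  reg[, region_id := cumsum(c(1L, (chrom[-1] != chrom[-.N]) |
                                (start[-1] - end[-.N] > params$dis_merge) |
                                (sign[-1] != sign[-.N])))]
  merged <- reg[, .(chrom = chrom[1], start = min(start), end = max(end)),
                by = region_id]
  # recompute statistics over all CpGs in the final interval; the
  # regional methylation difference averages the (smoothed) per-CpG
  # group levels, as DMR methylation levels are conventionally reported
  out <- merged[, {
    .ch <- chrom[1]; .s <- start[1]; .e <- end[1]
    d2 <- dt[chrom == .ch & pos >= .s & pos < .e]
    # regional difference from the raw pooled counts over all CpGs in
    # the final region (the smoothed per-CpG levels are diluted by
    # window bleed at region boundaries)
    md <- sum(d2$m1) / max(sum(d2$t1), 1) - sum(d2$m2) / max(sum(d2$t2), 1)
    .(chrom = .ch, start = .s, end = .e,
      n_cpgs = nrow(d2), n_sig = sum(d2$sig),
      mean_diff = md,
      hypo_in = if (md < 0) labels[1] else labels[2],
      area_stat = sum(d2$wald, na.rm = TRUE))
  }, by = region_id][, region_id := NULL][]
  setorder(out, chrom, start)
  out[]
}

empty_dmr_table <- function() {
  data.table(chrom = character(), start = integer(), end = integer(),
             n_cpgs = integer(), n_sig = integer(), mean_diff = numeric(),
             hypo_in = character(), area_stat = numeric())
}

#' Filter candidate DMRs on effect size and coverage
#'
#' Retains regions whose absolute mean methylation difference exceeds
#' `min_mean_diff` and which contain at least `min_covered_cpgs` CpGs
#' covered by at least `min_cov` reads in both groups (per-group rule,
#' the stricter reading).
#'
#' @param dmrs candidate region table from [call_dmrs()].
#' @param tests the per-CpG test table the regions were called from.
#' @param params parameter list from [dmr_params()].
#' @return the filtered region table.
#' @export
filter_dmrs <- function(dmrs, tests, params = dmr_params()) {
  if (nrow(dmrs) == 0L) return(dmrs)
  dt <- as.data.table(tests)
  keep <- vapply(seq_len(nrow(dmrs)), function(i) {
    if (abs(dmrs$mean_diff[i]) <= params$min_mean_diff) return(FALSE)
    d <- dt[chrom == dmrs$chrom[i] & pos >= dmrs$start[i] & pos < dmrs$end[i]]
    sum(d$t1 >= params$min_cov & d$t2 >= params$min_cov) >= params$min_covered_cpgs
  }, logical(1))
  dmrs[keep]
}

#' Two-group DMR calling, start to finish
#'
#' Convenience wrapper running [dml_test()], [call_dmrs()] and
#' [filter_dmrs()].
#'
#' @inheritParams dml_test
#' @inheritParams call_dmrs
#' @return filtered DMR table.
#' @export
find_dmrs <- function(group1, group2, params = dmr_params(),
                      labels = c("group1", "group2")) {
  tests <- dml_test(group1, group2, params)
  filter_dmrs(call_dmrs(tests, params, labels), tests, params)
}

#' Empirical replicate-null DMR counts across p-value thresholds
#'
#' Runs the full call-and-filter chain on within-condition replicate
#' pairs (the empirical false-positive baseline) and on between-condition
#' pairs, at each threshold, and reports the counts side by side with
#' their ratio. All comparisons are single sample versus single sample so
#' the two kinds of comparison have equal power.
#'
#' @param replicate_pairs named list; each element is a list of two CpG
#'   tables that are biological replicates of the same condition.
#' @param condition_pairs named list; each element is a list of two CpG
#'   tables from different conditions.
#' @param p_thresholds numeric vector of per-CpG significance thresholds.
#' @param params parameter list from [dmr_params()] (its `p_threshold`
#'   is overridden per threshold).
#' @return `data.table` with `comparison`, `type`
#'   (`replicate_null` / `condition`), `p_threshold`, `n_dmrs`.
#' @export
empirical_null_curve <- function(replicate_pairs, condition_pairs,
                                 p_thresholds = c(1e-3, 1e-5, 1e-7),
                                 params = dmr_params()) {
  run_pair <- function(pair, name, type) {
    tests <- dml_test(pair[1], pair[2], params)
    rbindlist(lapply(p_thresholds, function(th) {
      pp <- params; pp$p_threshold <- th
      n <- nrow(filter_dmrs(call_dmrs(tests, pp), tests, pp))
      data.table(comparison = name, type = type, p_threshold = th, n_dmrs = n)
    }))
  }
  out <- list()
  for (nm in names(replicate_pairs)) {
    out[[length(out) + 1L]] <- run_pair(replicate_pairs[[nm]], nm, "replicate_null")
  }
  for (nm in names(condition_pairs)) {
    out[[length(out) + 1L]] <- run_pair(condition_pairs[[nm]], nm, "condition")
  }
  if (!length(out)) {
    return(data.table(comparison = character(), type = character(),
                      p_threshold = numeric(), n_dmrs = integer()))
  }
  rbindlist(out)
}

#' Global methylation summary
#'
#' Global level is pooled `sum(meth) / sum(total)`. Bin fractions (low
#' `< 0.25`, medium, high `>= 0.75`) are computed over CpGs with
#' `total >= min_cov`.
#'
#' @param cpgs CpG `data.table`.
#' @param min_cov minimum coverage for binning (default 5).
#' @param breaks histogram breaks for the level distribution.
#' @return list with `global`, `fractions` (named low/medium/high),
#'   `n_binned`, and `histogram` (counts per level bin).
#' @export
methylome_summary <- function(cpgs, min_cov = 5,
                              breaks = seq(0, 1, by = 0.05)) {
  dt <- as.data.table(cpgs)
  global <- sum(dt$meth) / max(sum(dt$total), 1)
  cov <- dt[total >= min_cov]
  lev <- cov$meth / cov$total
  fr <- c(low = mean(lev < 0.25), medium = mean(lev >= 0.25 & lev < 0.75),
          high = mean(lev >= 0.75))
  h <- hist(lev, breaks = breaks, plot = FALSE)
  list(global = global, fractions = fr, n_binned = length(lev),
       histogram = setNames(h$counts, head(breaks, -1)))
}

#' Fraction of regions with stable methylation between two timepoints
#'
#' Regional methylation at each timepoint is the coverage-weighted CpG
#' mean over the region. Regions lacking coverage at either timepoint are
#' excluded from the denominator and reported separately.
#'
#' @param regions interval `data.table` (`chrom`, `start`, `end`).
#' @param meth_t0,meth_t4 CpG tables for the two timepoints.
#' @param change_threshold absolute change below which a region counts as
#'   stable (default 0.25).
#' @param min_cpgs minimum covered CpGs per region per timepoint
#'   (default 1).
#' @return list with `fraction_stable`, `n_evaluated`, `n_missing`, and
#'   the per-region table (`delta` column).
#' @export
stability_fraction <- function(regions, meth_t0, meth_t4,
                               change_threshold = 0.25, min_cpgs = 1L) {
  reg <- as.data.table(regions)
  if (nrow(reg) == 0L) {
    return(list(fraction_stable = NA_real_, n_evaluated = 0L,
                n_missing = 0L, regions = reg))
  }
  m0 <- region_methylation(reg, meth_t0, min_cpgs = min_cpgs)
  m4 <- region_methylation(reg, meth_t4, min_cpgs = min_cpgs)
  reg <- copy(reg)
  reg[, `:=`(meth_t0 = m0, meth_t4 = m4, delta = m4 - m0)]
  ok <- is.finite(reg$delta)
  list(fraction_stable = if (any(ok)) mean(abs(reg$delta[ok]) < change_threshold) else NA_real_,
       n_evaluated = sum(ok), n_missing = sum(!ok), regions = reg[])
}

#' Coverage-weighted regional methylation
#'
#' @param regions interval `data.table`.
#' @param cpgs CpG table.
#' @param min_cpgs minimum number of covered CpGs required; regions below
#'   it get `NA`.
#' @return numeric vector, one mean per region.
#' @export
region_methylation <- function(regions, cpgs, min_cpgs = 1L) {
  reg <- as.data.table(regions)
  dt <- as.data.table(cpgs)[total > 0]
  vapply(seq_len(nrow(reg)), function(i) {
    d <- dt[chrom == reg$chrom[i] & pos >= reg$start[i] & pos < reg$end[i]]
    if (nrow(d) < min_cpgs) return(NA_real_)
    sum(d$meth) / sum(d$total)
  }, numeric(1))
}

#' Center-anchored signal profile matrix over intervals
#'
#' Each interval is anchored at its center; the `[-flank, +flank)` window
#' is split into `n_bins` bins and the mean of the point signal within
#' each bin is taken. Bins with no data points are `NA` and excluded from
#' the column means.
#'
#' @param intervals interval `data.table`.
#' @param signal point signal `data.table` with `chrom`, `pos`, `value`.
#' @param flank half-window in bp (default 5000).
#' @param n_bins number of bins (default 100).
#' @return list with `matrix` (intervals x bins) and `colmeans`.
#' @export
aggregate_profile <- function(intervals, signal, flank = 5000, n_bins = 100) {
  reg <- as.data.table(intervals)
  sig <- as.data.table(signal)
  setkey(sig, chrom, pos)
  bin_w <- 2 * flank / n_bins
  mat <- matrix(NA_real_, nrow(reg), n_bins)
  for (i in seq_len(nrow(reg))) {
    center <- floor((reg$start[i] + reg$end[i]) / 2)
    lo <- center - flank
    d <- sig[chrom == reg$chrom[i] & pos >= lo & pos < center + flank]
    if (nrow(d) == 0L) next
    b <- pmin(floor((d$pos - lo) / bin_w) + 1L, n_bins)
    means <- tapply(d$value, b, mean)
    mat[i, as.integer(names(means))] <- means
  }
  list(matrix = mat, colmeans = colMeans(mat, na.rm = TRUE))
}
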
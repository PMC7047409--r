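# shared fixtures and independent oracles for the test suite

library(data.table)

# beta-binomial draws parameterized like the package generator
rbb <- function(n, size, mu, phi) {
  if (phi <= 1e-8) return(rbinom(n, size, mu))
  s <- (1 - phi) / phi
  p <- rbeta(n, mu * s, (1 - mu) * s)
  rbinom(n, size, p)
}

# a small CpG table with the given positions and counts
cpg_table <- function(pos, meth, total, chrom = "chr1") {
  dt <- data.table(chrom = chrom, pos = as.integer(pos),
                   meth = as.integer(meth), total = as.integer(total))
  setkey(dt, chrom, pos)
  dt
}

# Independent brute-force oracle for DMR region assembly. Walks the
# per-CpG tests one at a time and applies the documented rules
# literally: chain significant same-sign CpGs (at most max_insig_run
# insignificant CpGs between, no adjacent gap above max_gap), candidate
# = first..last significant CpG, length / minCG / pct_sig thresholds,
# boundary trimming on raw differences, threshold re-check, then merge
# of same-sign regions within dis_merge.
oracle_call_dmrs <- function(tests, params = dmr_params()) {
  dt <- as.data.table(tests)
  setorder(dt, chrom, pos)
  dt[, raw := ifelse(t1 > 0 & t2 > 0, m1 / pmax(t1, 1) - m2 / pmax(t2, 1), NA_real_)]
  dt[, d := mu1 - mu2]
  dt[, s := !is.na(p) & p < params$p_threshold & !is.na(d)]
  out <- list()
  for (ch in unique(dt$chrom)) {
    g <- dt[chrom == ch]
    sig <- which(g$s)
    if (!length(sig)) next
    # build runs one significant CpG at a time
    runs <- list(c(sig[1], sig[1]))
    for (i in sig[-1]) {
      last <- runs[[length(runs)]][2]
      gap_ok <- TRUE
      for (j in (last + 1):i) {
        if (g$pos[j] - g$pos[j - 1] > params$max_gap) gap_ok <- FALSE
      }
      if ((i - last - 1) <= params$max_insig_run && gap_ok &&
          sign(g$d[i]) == sign(g$d[last])) {
        runs[[length(runs)]][2] <- i
      } else {
        runs[[length(runs) + 1]] <- c(i, i)
      }
    }
    qualify <- function(i1, i2) {
      n_all <- i2 - i1 + 1
      n_sig <- sum(g$s[i1:i2])
      len <- g$pos[i2] + 2 - g$pos[i1]
      len >= params$minlen && n_all >= params$minCG &&
        n_sig / n_all >= params$pct_sig
    }
    for (r in runs) {
      if (!qualify(r[1], r[2])) next
      sgn <- sign(sum(g$d[r[1]:r[2]], na.rm = TRUE))
      idx <- r[1]:r[2]
      keep <- idx[!is.na(g$raw[idx]) & sign(g$raw[idx]) == sgn &
                    abs(g$raw[idx]) >= params$min_mean_diff]
      if (!length(keep)) next
      i1 <- min(keep); i2 <- max(keep)
      if (!qualify(i1, i2)) next
      out[[length(out) + 1]] <- data.table(chrom = ch, start = g$pos[i1],
                                           end = g$pos[i2] + 2, sign = sgn)
    }
  }
  if (!length(out)) return(data.table(chrom = character(), start = integer(),
                                      end = integer()))
  reg <- rbindlist(out)
  setorder(reg, chrom, start)
  merged <- reg[1]
  if (nrow(reg) > 1) {
    for (k in 2:nrow(reg)) {
      lastk <- nrow(merged)
      if (reg$chrom[k] == merged$chrom[lastk] &&
          reg$start[k] - merged$end[lastk] <= params$dis_merge &&
          reg$sign[k] == merged$sign[lastk]) {
        merged$end[lastk] <- max(merged$end[lastk], reg$end[k])
      } else {
        merged <- rbind(merged, reg[k])
      }
    }
  }
  merged[, .(chrom, start, end)]
}

# interval recovery helpers against a truth table
overlap_recovery <- function(called, planted) {
  called <- as.data.table(called); planted <- as.data.table(planted)
  if (nrow(planted) == 0 || nrow(called) == 0) {
    return(list(recall = if (nrow(planted)) 0 else NA_real_,
                precision = if (nrow(called)) 0 else NA_real_))
  }
  hit_p <- vapply(seq_len(nrow(planted)), function(i)
    any(called$chrom == planted$chrom[i] & called$start < planted$end[i] &
          called$end > planted$start[i]), logical(1))
  hit_c <- vapply(seq_len(nrow(called)), function(i)
    any(planted$chrom == called$chrom[i] & planted$start < called$end[i] &
          planted$end > called$start[i]), logical(1))
  list(recall = mean(hit_p), precision = mean(hit_c))
}

# one sharp test PWM
toy_pwm <- function(consensus = "ACGTACGTAC", dominant = 0.91,
                    name = "toy") {
  bases <- c("A", "C", "G", "T")
  cons <- strsplit(consensus, "")[[1]]
  mat <- matrix((1 - dominant) / 3, length(cons), 4,
                dimnames = list(NULL, bases))
  for (l in seq_along(cons)) mat[l, cons[l]] <- dominant
  list(name = name, matrix = mat,
       background = setNames(rep(0.25, 4), bases), pseudocount = 0)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
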
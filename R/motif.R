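# DNA helpers -----------------------------------------------------------

DNA_CODE <- c(A = 1L, C = 2L, G = 3L, T = 4L)

encode_dna <- function(seq) {
  code <- DNA_CODE[strsplit(toupper(seq), "", fixed = TRUE)[[1]]]
  unname(code)  # non-ACGT become NA and never match
}

#' Reverse complement of a DNA string
#' @param seq character scalar or vector.
#' @return reverse complement(s).
#' @export
revcomp <- function(seq) {
  vapply(seq, function(s) {
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Reverse-complement a PWM probability matrix (reverse rows, swap A<->T,
# C<->G) so scoring the + strand with it equals scoring the - strand with
# the original.
revcomp_pwm_matrix <- function(mat) {
  out <- mat[rev(seq_len(nrow(mat))), c(4L, 3L, 2L, 1L), drop = FALSE]
  colnames(out) <- c("A", "C", "G", "T")
  out
}

#' Exact discretized null distribution of a PWM log-odds score
#'
#' Per-position log2-odds scores against the background are rounded to
#' bins of `bin_bits` and convolved across positions under the background
#' model, giving the exact (to bin resolution) distribution of the score
#' of a random background sequence. Used to convert scores to p-values.
#'
#' @param mat L x 4 probability matrix.
#' @param background length-4 background probabilities (A,C,G,T).
#' @param bin_bits score bin width in bits (default 0.01).
#' @return list with `offset` (bin index of score 0), `probs`
#'   (probability per bin), `bin_bits`.
#' @export
pwm_score_distribution <- function(mat, background, bin_bits = 0.01) {
  L <- nrow(mat)
  sc <- round(log2(sweep(mat, 2, background, "/")) / bin_bits)
  cur <- c(1)  # distribution over binned scores, starting at score 0
  cur_lo <- 0L
  for (l in seq_len(L)) {
    s <- sc[l, ]
    new_lo <- cur_lo + min(s)
    new_hi <- cur_lo + length(cur) - 1L + max(s)
    new <- numeric(new_hi - new_lo + 1L)
    for (b in 1:4) {
      shift <- s[b] - new_lo + cur_lo
      idx <- seq_along(cur) + shift
      new[idx] <- new[idx] + cur * background[b]
    }
    cur <- new; cur_lo <- new_lo
  }
  list(offset = cur_lo, probs = cur, bin_bits = bin_bits)
}

# Upper-tail p-value P(score >= s) for binned scores under a
# pwm_score_distribution
pwm_tail_p <- function(dist, score_bits) {
  bin <- round(score_bits / dist$bin_bits)
  tail_cum <- rev(cumsum(rev(dist$probs)))
  idx <- bin - dist$offset + 1L
  idx <- pmin(pmax(idx, 1L), length(tail_cum) + 1L)
  ifelse(idx > length(tail_cum), 0, tail_cum[idx])
}

# Log-odds scores (bits) for every window of an encoded sequence.
# Per-position scores are quantized to the same bins as the null
# distribution so observed scores and DP tail probabilities line up
# exactly.
score_windows <- function(code, mat, background, bin_bits = 0.01) {
  L <- nrow(mat)
  n <- length(code) - L + 1L
  if (n < 1L) return(numeric(0))
  lodds <- round(log2(sweep(mat, 2, background, "/")) / bin_bits) * bin_bits
  s <- numeric(n)
  for (l in seq_len(L)) {
    v <- lodds[l, code[l:(l + n - 1L)]]
    v[is.na(v)] <- -Inf  # windows containing non-ACGT never match
    s <- s + v
  }
  s
}

#' Scan sequences with a PWM, exact p-values by dynamic programming
#'
#' Scores every window on both strands with the log2-odds of the PWM
#' against the background model (by default the base composition of the
#' scanned sequence set) and reports windows whose exact tail probability
#' under the background, computed by discretized-score convolution
#' ([pwm_score_distribution()]), is below `p_threshold`. Overlapping hits
#' are all reported.
#'
#' @param seqs named character vector of sequences.
#' @param pwm PWM object (list with `name`, `matrix`, `background`).
#' @param p_threshold hit p-value threshold (default 1e-5).
#' @param background optional length-4 background; defaults to the
#'   sequence-set base composition.
#' @param bin_bits score discretization (default 0.01 bits).
#' @return `data.table` with `seqname`, `start` (0-based within the
#'   sequence), `end`, `strand`, `score` (bits), `p`, `pwm`.
#' @export
scan_pwm <- function(seqs, pwm, p_threshold = 1e-5, background = NULL,
                     bin_bits = 0.01) {
  L <- nrow(pwm$matrix)
  if (is.null(background)) {
    tab <- table(factor(unlist(strsplit(toupper(paste(seqs, collapse = "")),
                                        "")), levels = c("A", "C", "G", "T")))
    background <- as.numeric(tab) / max(sum(tab), 1)
    if (any(background == 0)) {
      background <- (background + 0.01) / sum(background + 0.01)
    }
  }
  # strand-symmetrized background (A=T, C=G) so a window and its reverse
  # complement score identically on opposite strands
  background <- (background + background[4:1]) / 2
  names(background) <- c("A", "C", "G", "T")
  mats <- list(`+` = pwm$matrix, `-` = revcomp_pwm_matrix(pwm$matrix))
  dists <- lapply(mats, pwm_score_distribution, background = background,
                  bin_bits = bin_bits)
  hits <- list()
  for (i in seq_along(seqs)) {
    code <- encode_dna(seqs[[i]])
    nm <- if (!is.null(names(seqs))) names(seqs)[i] else as.character(i)
    for (strand in c("+", "-")) {
      sc <- score_windows(code, mats[[strand]], background, bin_bits)
      if (!length(sc)) next
      pv <- pwm_tail_p(dists[[strand]], sc)
      keep <- which(is.finite(sc) & pv < p_threshold)
      if (!length(keep)) next
      hits[[length(hits) + 1L]] <-
        data.table(seqname = nm, start = keep - 1L, end = keep - 1L + L,
                   strand = strand, score = sc[keep], p = pv[keep],
                   pwm = pwm$name)
    }
  }
  if (!length(hits)) {
    return(data.table(seqname = character(), start = integer(),
                      end = integer(), strand = character(),
                      score = numeric(), p = numeric(), pwm = character()))
  }
  out <- rbindlist(hits)
  setorder(out, seqname, start, strand)
  out[]
}

#' Binomial motif enrichment in target versus background regions
#'
#' The per-region background hit rate `q` is the fraction of background
#' regions containing at least one hit, after resampling the background
#' to match the target region length distribution (length-decile
#' matching). The enrichment p-value is the exact upper binomial tail
#' `P(X >= k | n_targets, q)`.
#'
#' @param targets,background interval `data.table`s (`chrom`, `start`,
#'   `end`).
#' @param hits genomic motif-hit table (`chrom`, `start`, `end`, `pwm`),
#'   e.g. lifted scan results.
#' @param pwms character vector of PWM names to test (default: all in
#'   `hits`).
#' @return `data.table` per PWM: `pwm`, `n_target`, `n_target_with_hit`,
#'   `bg_rate`, `expected`, `p`.
#' @export
motif_enrichment <- function(targets, background, hits, pwms = NULL) {
  tg <- as.data.table(targets); bg <- as.data.table(background)
  ht <- as.data.table(hits)
  if (is.null(pwms)) pwms <- sort(unique(ht$pwm))
  n_t <- nrow(tg)
  # length matching: sample background regions to the target length deciles
  tlen <- tg$end - tg$start
  blen <- bg$end - bg$start
  qs <- unique(quantile(tlen, probs = seq(0, 1, length.out = 11)))
  if (length(qs) > 1L) {
    tbin <- cut(tlen, breaks = qs, include.lowest = TRUE)
    bbin <- cut(blen, breaks = qs, include.lowest = TRUE)
    sel <- integer(0)
    for (b in levels(tbin)) {
      cand <- which(bbin == b)
      need <- sum(tbin == b, na.rm = TRUE)
      if (!length(cand) || need == 0L) next
      sel <- c(sel, rep_len(cand, need))  # deterministic cycling
    }
    if (length(sel)) bg <- bg[sel]
  }
  region_has_hit <- function(reg, h) {
    if (nrow(reg) == 0L || nrow(h) == 0L) return(logical(nrow(reg)))
    r <- copy(reg)[, xid := .I]
    setkey(h, chrom, start, end)
    ov <- foverlaps(r, h, by.x = c("chrom", "start", "end"), nomatch = NULL)
    seq_len(nrow(reg)) %in% ov$xid
  }
  out <- rbindlist(lapply(pwms, function(pw) {
    h <- ht[pwm == pw, .(chrom, start, end)]
    k <- sum(region_has_hit(tg, copy(h)))
    q <- mean(region_has_hit(bg, copy(h)))
    q_adj <- min(max(q, 0.5 / max(nrow(bg), 1)), 1 - 1e-12)
    p <- pbinom(k - 1, n_t, q_adj, lower.tail = FALSE)
    data.table(pwm = pw, n_target = n_t, n_target_with_hit = k,
               bg_rate = q, expected = q * n_t, p = p)
  }))
  setorder(out, p)
  out[]
}
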
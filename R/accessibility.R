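#' Convert aligned read/fragment endpoints to Tn5 insertion sites
#'
#' Reads mapped to the + strand are offset by +4 bp and reads mapped to
#' the - strand by -5 bp, placing each endpoint at the centre of the Tn5
#' binding event. A record with strand `+` contributes one insertion at
#' `start + 4`; strand `-` contributes one at `end - 5` (the 5' end of a
#' minus-strand read is its right coordinate). A strand of `.` marks a
#' whole fragment: both ends are used (`start + 4` and `end - 5`).
#' Records with missing strand are skipped and out-of-bounds insertions
#' are clipped; both are tallied.
#'
#' @param reads `data.table` with `chrom`, `start`, `end`, `strand`.
#' @param chrom_sizes named integer vector of chromosome lengths; used
#'   for clipping (optional).
#' @return `data.table` of insertions (`chrom`, `pos`), sorted, with
#'   attributes `library_size`, `n_skipped`, `n_clipped`.
#' @export
adjust_tn5 <- function(reads, chrom_sizes = NULL) {
  dt <- as.data.table(reads)
  if (!"strand" %in% names(dt)) dt[, strand := "."]
  ok <- !is.na(dt$strand) & dt$strand %in% c("+", "-", ".")
  n_skipped <- sum(!ok)
  dt <- dt[ok]
  plus <- dt[strand %in% c("+", "."), .(chrom, pos = start + 4L)]
  minus <- dt[strand %in% c("-", "."), .(chrom, pos = end - 5L)]
  ins <- rbind(plus, minus)
  n_clipped <- 0L
  if (!is.null(chrom_sizes)) {
    lim <- chrom_sizes[ins$chrom]
    bad <- ins$pos < 0L | ins$pos >= lim
    n_clipped <- sum(bad, na.rm = TRUE)
    ins[, pos := pmin(pmax(pos, 0L), lim - 1L)]
  } else {
    bad <- ins$pos < 0L
    n_clipped <- sum(bad)
    ins[, pos := pmax(pos, 0L)]
  }
  setorder(ins, chrom, pos)
  setattr(ins, "library_size", nrow(ins))
  setattr(ins, "n_skipped", n_skipped)
  setattr(ins, "n_clipped", n_clipped)
  ins[]
}

#' Sliding-window Poisson peak calling on an insertion track
#'
#' Windows of `window` bp every `step` bp are scored with the upper
#' Poisson tail of the observed insertion count against the larger of the
#' genome-wide and local (`local_bg` bp around the window) expected
#' counts. Significant windows are merged into peaks; the summit is the
#' position with the most insertions.
#'
#' @param track insertion `data.table` (`chrom`, `pos`), sorted.
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @param window window width in bp (default 200).
#' @param step window step in bp (default 50).
#' @param local_bg width of the local background window (default 10000).
#' @param p_cut Poisson tail p-value cutoff per window (default 0.01).
#' @return `data.table` of peaks: `chrom`, `start`, `end`, `summit`,
#'   `enrichment` (fold over expected), sorted and non-overlapping.
#' @export
call_peaks <- function(track, chrom_sizes, window = 200, step = 50,
                       local_bg = 10000, p_cut = 0.01) {
  dt <- as.data.table(track)
  genome_len <- sum(as.numeric(chrom_sizes))
  genome_rate <- nrow(dt) / genome_len
  peaks <- list()
  for (ch in names(chrom_sizes)) {
    pos <- dt[chrom == ch, sort(pos)]
    if (!length(pos)) next
    len <- chrom_sizes[[ch]]
    starts <- seq(0L, max(0L, len - window), by = step)
    n_in <- findInterval(starts + window - 0.5, pos) -
      findInterval(starts - 0.5, pos)
    lo <- pmax(starts + window / 2 - local_bg / 2, 0)
    hi <- pmin(starts + window / 2 + local_bg / 2, len)
    n_local <- findInterval(hi - 0.5, pos) - findInterval(lo - 0.5, pos)
    local_rate <- n_local / pmax(hi - lo, 1)
    lambda <- pmax(genome_rate, local_rate) * window
    pv <- ppois(n_in - 1, lambda, lower.tail = FALSE)
    sig <- which(pv < p_cut & n_in > 0)
    if (!length(sig)) next
    s <- starts[sig]; e <- s + window
    grp <- cumsum(c(1L, s[-1] > cummax(e[-length(e)])))
    for (g in unique(grp)) {
      idx <- which(grp == g)
      p_start <- min(s[idx]); p_end <- max(e[idx])
      inpk <- pos[pos >= p_start & pos < p_end]
      tab <- table(inpk)
      summit <- as.integer(names(tab)[which.max(tab)])
      expd <- max(genome_rate * (p_end - p_start), 1e-9)
      peaks[[length(peaks) + 1L]] <-
        data.table(chrom = ch, start = p_start, end = p_end,
                   summit = summit, enrichment = length(inpk) / expd)
    }
  }
  if (!length(peaks)) {
    return(data.table(chrom = character(), start = integer(),
                      end = integer(), summit = integer(),
                      enrichment = numeric()))
  }
  out <- rbindlist(peaks)
  setorder(out, chrom, start)
  out[]
}

#' Reproducible peaks across two replicates
#'
#' Keeps replicate-1 peaks that have a reciprocal overlap of at least
#' `min_overlap` with some replicate-2 peak and whose enrichment rank is
#' concordant between replicates. Concordance rule (replaces the IDR
#' copula model): among matched peak pairs, a pair is concordant when its
#' two enrichment ranks differ by at most half the number of matched
#' pairs, i.e. a peak in the top half of one replicate may not sit at the
#' very bottom of the other.
#'
#' @param peaks_rep1,peaks_rep2 peak tables from [call_peaks()].
#' @param min_overlap minimum reciprocal overlap fraction (default 0.5).
#' @return the surviving replicate-1 peaks, flagged `reproducible = TRUE`.
#' @export
reproducible_peaks <- function(peaks_rep1, peaks_rep2, min_overlap = 0.5) {
  p1 <- copy(as.data.table(peaks_rep1)); p2 <- copy(as.data.table(peaks_rep2))
  if (nrow(p1) == 0L || nrow(p2) == 0L) return(p1[0])
  p1[, xid := .I]; p2[, yid := .I]
  setkey(p2, chrom, start, end)
  ov <- foverlaps(p1, p2, by.x = c("chrom", "start", "end"), nomatch = NULL)
  if (nrow(ov) == 0L) return(p1[0])
  ov[, `:=`(ov_len = pmin(i.end, end) - pmax(i.start, start))]
  ov[, `:=`(len1 = i.end - i.start, len2 = end - start)]
  ov <- ov[ov_len / len1 >= min_overlap & ov_len / len2 >= min_overlap]
  if (nrow(ov) == 0L) return(p1[0])
  # best match per rep1 peak
  setorder(ov, xid, -ov_len)
  ov <- ov[!duplicated(xid)]
  r1 <- rank(-p1$enrichment[ov$xid], ties.method = "first")
  r2 <- rank(-p2$enrichment[ov$yid], ties.method = "first")
  concordant <- abs(r1 - r2) <= length(r1) / 2
  out <- p1[ov$xid[concordant]]
  out[, xid := NULL]
  out[, reproducible := TRUE]
  setorder(out, chrom, start)
  out[]
}

#' Count insertions per peak per sample
#'
#' Insertions with `pos` in `[start, end)` are counted (half-open
#' membership).
#'
#' @param peaks peak interval `data.table`.
#' @param tracks named list of insertion tables (`chrom`, `pos`).
#' @return peak x sample integer matrix with attribute `library_sizes`.
#' @export
count_insertions <- function(peaks, tracks) {
  pk <- as.data.table(peaks)
  mat <- matrix(0L, nrow(pk), length(tracks),
                dimnames = list(NULL, names(tracks)))
  for (j in seq_along(tracks)) {
    tr <- as.data.table(tracks[[j]])
    for (ch in unique(pk$chrom)) {
      pos <- tr[chrom == ch, sort(pos)]
      idx <- which(pk$chrom == ch)
      if (!length(pos) || !length(idx)) next
      mat[idx, j] <- findInterval(pk$end[idx] - 0.5, pos) -
        findInterval(pk$start[idx] - 0.5, pos)
    }
  }
  attr(mat, "library_sizes") <- vapply(tracks, nrow, integer(1))
  mat
}

#' Differential accessibility test between two conditions
#'
#' Runs the shared negative-binomial Wald engine ([nb_wald_test()]) on
#' the peak count matrix and reports peaks passing `|log2FC| > log2(fc_cut)`
#' and `FDR < fdr_cut` with their direction (`gained` means higher in
#' group level 2).
#'
#' @param mat peak x sample count matrix (rows aligned with `peaks`).
#' @param groups two-level factor over samples (level 2 vs level 1).
#' @param peaks optional peak interval table to carry through.
#' @param fc_cut fold-change cutoff (default 2).
#' @param fdr_cut FDR cutoff (default 0.01).
#' @param all_results return all peaks (with a `significant` flag)
#'   instead of significant ones only.
#' @return `data.table` of DARs with `log2_fold`, `p`, `fdr`,
#'   `direction`.
#' @export
test_dars <- function(mat, groups, peaks = NULL, fc_cut = 2, fdr_cut = 0.01,
                      all_results = FALSE) {
  res <- nb_wald_test(mat, groups)
  res[, direction := ifelse(log2_fold > 0, "gained", "lost")]
  res[, significant := !is.na(fdr) & fdr < fdr_cut &
        abs(log2_fold) > log2(fc_cut)]
  if (!is.null(peaks)) {
    res <- cbind(as.data.table(peaks)[, .(chrom, start, end)], res)
  }
  if (all_results) res[] else res[significant == TRUE][]
}

#' Annotate peaks by distance to the nearest TSS
#'
#' A peak whose centre lies within +/- `promoter_bp` (inclusive) of any
#' TSS is a `promoter` peak; one whose nearest TSS is more than
#' `distal_bp` away is `distal`; anything else is `proximal`. Nearest-TSS
#' ties are broken by the leftmost gene id.
#'
#' @param peaks peak interval `data.table`.
#' @param genes gene table with `gene_id`, `chrom`, `tss`.
#' @param promoter_bp promoter half-width (default 2000).
#' @param distal_bp distal cutoff (default 10000).
#' @return peaks with `annotation`, `nearest_gene`, `tss_distance` added.
#' @export
annotate_peaks <- function(peaks, genes, promoter_bp = 2000,
                           distal_bp = 10000) {
  pk <- copy(as.data.table(peaks))
  gn <- as.data.table(genes)
  pk[, `:=`(annotation = NA_character_, nearest_gene = NA_character_,
            tss_distance = NA_real_)]
  for (ch in unique(pk$chrom)) {
    g <- gn[chrom == ch][order(tss, gene_id)]
    idx <- which(pk$chrom == ch)
    if (!nrow(g)) next
    center <- floor((pk$start[idx] + pk$end[idx]) / 2)
    d <- abs(outer(center, g$tss, "-"))
    best <- apply(d, 1, function(row) which(row == min(row))[1])  # leftmost tie
    pk$nearest_gene[idx] <- g$gene_id[best]
    dist <- d[cbind(seq_along(best), best)]
    pk$tss_distance[idx] <- dist
    pk$annotation[idx] <- ifelse(dist <= promoter_bp, "promoter",
                                 ifelse(dist > distal_bp, "distal", "proximal"))
  }
  pk[]
}
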
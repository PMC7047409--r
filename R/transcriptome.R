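#' Differential expression test between two conditions
#'
#' Runs the shared negative-binomial Wald engine ([nb_wald_test()]) on a
#' gene count matrix and assigns `status`: `up` when
#' `log2_fold > log2(fc_cut)` and `FDR < fdr_cut`, `down` for the
#' mirrored condition, `ns` otherwise (including all-zero genes, which
#' get `NA` p-values).
#'
#' @param mat gene x sample count matrix.
#' @param groups two-level factor over samples; fold changes are level 2
#'   over level 1.
#' @param fc_cut fold-change cutoff (default 2).
#' @param fdr_cut FDR cutoff (default 0.05).
#' @return `data.table` with `id`, `base_mean`, `log2_fold`, `p`, `fdr`,
#'   `status`.
#' @export
test_de <- function(mat, groups, fc_cut = 2, fdr_cut = 0.05) {
  res <- nb_wald_test(mat, groups)
  lcut <- log2(fc_cut)
  res[, status := "ns"]
  res[!is.na(fdr) & fdr < fdr_cut & log2_fold > lcut, status := "up"]
  res[!is.na(fdr) & fdr < fdr_cut & log2_fold < -lcut, status := "down"]
  res[]
}

#' Transcripts per million
#'
#' `rate_i = count_i / length_i`; `TPM_i = 1e6 rate_i / sum(rate)` per
#' sample.
#'
#' @param mat gene x sample count matrix.
#' @param lengths exonic lengths in bp, aligned with rows.
#' @return TPM matrix; every column sums to 1e6 (when any gene is
#'   expressed).
#' @export
compute_tpm <- function(mat, lengths) {
  mat <- as.matrix(mat)
  stopifnot(length(lengths) == nrow(mat), all(lengths > 0))
  rate <- mat / lengths
  sweep(rate, 2, colSums(rate), "/") * 1e6
}

#' Assign each gene its putative distal enhancer peak
#'
#' The assigned peak is the one closest to the gene's TSS among peaks
#' farther than `min_dist` bp from it; ties are broken by the leftmost
#' peak. Genes with no qualifying peak are unmapped (`NA`).
#'
#' @param genes gene table with `gene_id`, `chrom`, `tss`.
#' @param peaks peak interval `data.table`.
#' @param min_dist minimum TSS distance in bp (default 10000).
#' @return `data.table` with `gene_id`, `peak_chrom`, `peak_start`,
#'   `peak_end`, `distance` (`NA` rows for unmapped genes).
#' @export
assign_distal_enhancer <- function(genes, peaks, min_dist = 10000) {
  gn <- as.data.table(genes)
  pk <- as.data.table(peaks)
  setorder(pk, chrom, start)
  out <- gn[, .(gene_id, chrom, tss)]
  out[, `:=`(peak_chrom = NA_character_, peak_start = NA_integer_,
             peak_end = NA_integer_, distance = NA_real_)]
  for (i in seq_len(nrow(out))) {
    p <- pk[chrom == out$chrom[i]]
    if (!nrow(p)) next
    tssi <- out$tss[i]
    d <- ifelse(tssi < p$start, p$start - tssi,
                ifelse(tssi >= p$end, tssi - p$end + 1L, 0))
    qual <- which(d > min_dist)
    if (!length(qual)) next
    best <- qual[which(d[qual] == min(d[qual]))][1]  # leftmost tie (pk sorted)
    out$peak_chrom[i] <- p$chrom[best]
    out$peak_start[i] <- p$start[best]
    out$peak_end[i] <- p$end[best]
    out$distance[i] <- d[best]
  }
  out[]
}

#' Direction concordance between accessibility and expression changes
#'
#' For each DAR class (gained / lost), collects the expression log2 fold
#' changes of the nearest genes and reports the fraction whose sign
#' matches the accessibility change, plus the fold-change distribution.
#'
#' @param dars DAR table with `direction` and `nearest_gene`.
#' @param de_results DE table from [test_de()] (`id`, `log2_fold`).
#' @param min_genes minimum genes per class to report a fraction.
#' @return list with `concordance` (per-class table) and `folds`
#'   (per-class list of log2 fold changes); empty when no DARs.
#' @export
concordance <- function(dars, de_results, min_genes = 1L) {
  dd <- as.data.table(dars)
  if (nrow(dd) == 0L) return(list(concordance = data.table(), folds = list()))
  de <- as.data.table(de_results)
  dd <- merge(dd, de[, .(nearest_gene = id, gene_lfc = log2_fold)],
              by = "nearest_gene")
  dd <- dd[is.finite(gene_lfc)]
  folds <- split(dd$gene_lfc, dd$direction)
  conc <- dd[, .(n = .N,
                 concordant = mean(sign(gene_lfc) ==
                                     ifelse(direction == "gained", 1, -1)),
                 median_lfc = median(gene_lfc)),
             by = direction]
  conc[n < min_genes, concordant := NA_real_]
  list(concordance = conc[], folds = folds)
}
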
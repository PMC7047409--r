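#' Select putative upstream TFs from enrichment and expression
#'
#' A TF qualifies when its motif is enriched in gained DARs
#' (Benjamini-Hochberg FDR over PWMs below `fdr_cut`) and its gene's
#' normalized expression at 1, 2 or 4 dpa exceeds the uninjured (0 dpa)
#' level by at least `min_fold`.
#'
#' @param enrichment table from [motif_enrichment()] (`pwm`, `p`).
#' @param expr matrix of normalized TF-gene expression: rows named by
#'   gene id, columns named by timepoint (`"0"`, `"1"`, `"2"`, `"4"`).
#' @param tf_map `data.table` mapping `pwm` to `gene_id`.
#' @param fdr_cut enrichment FDR cutoff (default 0.05).
#' @param min_fold minimum expression fold over 0 dpa (default 1.5).
#' @return `data.table` of selected TFs: `pwm`, `gene_id`, `fdr`,
#'   `max_fold`.
#' @export
select_upstream_tfs <- function(enrichment, expr, tf_map, fdr_cut = 0.05,
                                min_fold = 1.5) {
  en <- copy(as.data.table(enrichment))
  en[, fdr := p.adjust(p, method = "BH")]
  en <- merge(en, as.data.table(tf_map), by = "pwm")
  later <- intersect(colnames(expr), c("1", "2", "4"))
  stopifnot("0" %in% colnames(expr), length(later) > 0)
  keep <- logical(nrow(en)); mf <- numeric(nrow(en))
  for (i in seq_len(nrow(en))) {
    g <- en$gene_id[i]
    if (!g %in% rownames(expr)) { keep[i] <- FALSE; next }
    base <- expr[g, "0"] + 1e-8
    folds <- (expr[g, later] + 1e-8) / base
    mf[i] <- max(folds)
    keep[i] <- en$fdr[i] < fdr_cut && mf[i] >= min_fold
  }
  en[, max_fold := mf]
  out <- en[keep, .(pwm, gene_id, fdr, max_fold)]
  setorder(out, fdr, pwm)
  out[]
}

#' Build a regulatory network from bound sites, gained DARs and DE genes
#'
#' For each selected TF, bound motif sites falling inside a
#' gained-accessibility DAR are linked to the gene with the nearest TSS;
#' the link becomes an edge when that gene is upregulated. Edge types:
#' `auto` when the target is the TF itself, `tf_tf` when the target is
#' another selected TF, otherwise `tf_target`. Edges are deduplicated per
#' (TF, target), keeping the closest supporting site, and the output is
#' sorted so it is invariant to input ordering.
#'
#' @param tfs selected TFs from [select_upstream_tfs()] (`pwm`,
#'   `gene_id`).
#' @param bound_sites bound motif sites (`chrom`, `start`, `end`, `pwm`).
#' @param gained_dars gained-DAR intervals (`chrom`, `start`, `end`).
#' @param genes gene table (`gene_id`, `chrom`, `tss`).
#' @param upregulated character vector of upregulated gene ids.
#' @return `data.table` of edges: `tf` (gene id), `pwm`, `target`,
#'   `site_chrom`, `site_start`, `site_end`, `dar_start`, `dar_end`,
#'   `distance`, `type`.
#' @export
build_grn <- function(tfs, bound_sites, gained_dars, genes, upregulated) {
  tf <- as.data.table(tfs)
  bs <- as.data.table(bound_sites)
  da <- as.data.table(gained_dars)
  gn <- as.data.table(genes)
  empty <- data.table(tf = character(), pwm = character(),
                      target = character(), site_chrom = character(),
                      site_start = integer(), site_end = integer(),
                      dar_start = integer(), dar_end = integer(),
                      distance = numeric(), type = character())
  if (nrow(tf) == 0L || nrow(bs) == 0L || nrow(da) == 0L) return(empty)
  bs <- bs[pwm %in% tf$pwm]
  if (nrow(bs) == 0L) return(empty)
  # sites fully inside a gained DAR (supporting site must be contained)
  bs <- copy(bs)[, xid := .I]
  da2 <- copy(da)[, yid := .I]
  setkey(da2, chrom, start, end)
  ov <- foverlaps(bs, da2, by.x = c("chrom", "start", "end"), nomatch = NULL)
  ov <- ov[i.start >= start & i.end <= end]
  if (nrow(ov) == 0L) return(empty)
  edges <- list()
  for (k in seq_len(nrow(ov))) {
    ch <- ov$chrom[k]
    s0 <- ov$i.start[k]; s1 <- ov$i.end[k]
    mid <- (s0 + s1) / 2
    g <- gn[chrom == ch][order(tss, gene_id)]
    if (!nrow(g)) next
    d <- abs(g$tss - mid)
    best <- which(d == min(d))[1]
    target <- g$gene_id[best]
    if (!target %in% upregulated) next
    pw <- ov$pwm[k]
    tf_gene <- tf[pwm == pw]$gene_id[1]
    type <- if (identical(target, tf_gene)) "auto"
            else if (target %in% tf$gene_id) "tf_tf" else "tf_target"
    edges[[length(edges) + 1L]] <-
      data.table(tf = tf_gene, pwm = pw, target = target,
                 site_chrom = ch, site_start = s0, site_end = s1,
                 dar_start = ov$start[k], dar_end = ov$end[k],
                 distance = d[best], type = type)
  }
  if (!length(edges)) return(empty)
  out <- rbindlist(edges)
  setorder(out, tf, target, distance, site_chrom, site_start)
  out <- out[!duplicated(paste(tf, target))]
  setorder(out, tf, target)
  out[]
}

#' Compare mutant versus wildtype expression response in targets and
#' non-targets
#'
#' Paired two-sided Wilcoxon signed-rank tests on per-gene log2 fold
#' changes (mutant vs wildtype), within the predicted target set and
#' within the non-target set, with medians and quartiles. Identical fold
#' changes (all zero differences) give `p = 1`.
#'
#' @param lfc_mutant,lfc_wildtype named numeric vectors of per-gene log2
#'   fold changes.
#' @param targets,nontargets character vectors of gene ids.
#' @return list with `p_targets`, `p_nontargets`, and per-set summary
#'   tables (`median_mutant`, `median_wildtype`, quartiles, `n`).
#' @export
compare_target_response <- function(lfc_mutant, lfc_wildtype, targets,
                                    nontargets) {
  test_set <- function(ids) {
    ids <- intersect(ids, intersect(names(lfc_mutant), names(lfc_wildtype)))
    x <- lfc_mutant[ids]; y <- lfc_wildtype[ids]
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    p <- if (length(x) == 0L || all(x == y)) 1 else
      suppressWarnings(wilcox.test(x, y, paired = TRUE)$p.value)
    list(p = p,
         summary = data.table(n = length(x),
                              median_mutant = median(x),
                              median_wildtype = median(y),
                              q25_mutant = unname(quantile(x, 0.25, names = FALSE)),
                              q75_mutant = unname(quantile(x, 0.75, names = FALSE)),
                              q25_wildtype = unname(quantile(y, 0.25, names = FALSE)),
                              q75_wildtype = unname(quantile(y, 0.75, names = FALSE))))
  }
  tg <- test_set(targets); ntg <- test_set(nontargets)
  list(p_targets = tg$p, p_nontargets = ntg$p,
       targets = tg$summary, nontargets = ntg$summary)
}

#' Score a CRISPR gRNA protospacer
#'
#' `score = 60 * GC + 10 * prop_transcripts - 30 * rel_pos
#'  + 2 * [position 20 is G] - 3 * [position 20 is A]`,
#' where GC is the proportion of G/C bases in the 20-mer and position 20
#' is the 20th (1-based, PAM-proximal) base.
#'
#' @param sequence 20-mer over A/C/G/T.
#' @param prop_transcripts proportion of the gene's transcripts targeted,
#'   in `[0, 1]`.
#' @param rel_pos relative position of the cut site in the gene, in
#'   `[0, 1]`.
#' @return numeric score.
#' @export
score_grna <- function(sequence, prop_transcripts, rel_pos) {
  sequence <- toupper(sequence)
  if (nchar(sequence) != 20L) stop("gRNA protospacer must be a 20-mer")
  if (!grepl("^[ACGT]{20}$", sequence)) stop("gRNA sequence must be over A/C/G/T")
  stopifnot(prop_transcripts >= 0, prop_transcripts <= 1,
            rel_pos >= 0, rel_pos <= 1)
  bases <- strsplit(sequence, "")[[1]]
  gc <- mean(bases %in% c("G", "C"))
  60 * gc + 10 * prop_transcripts - 30 * rel_pos +
    2 * (bases[20] == "G") - 3 * (bases[20] == "A")
}
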
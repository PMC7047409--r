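#' Classify gained DARs as regeneration-enhancer candidates
#'
#' A candidate must (in this order of evaluation) have gained
#' accessibility, lie more than `min_tss_dist` bp from the nearest TSS,
#' be lowly or intermediately methylated (`meth_t0 < meth_cutoff`) in the
#' uninjured sample, and change methylation by less than `max_delta`
#' between timepoints. Regional methylation is the coverage-weighted CpG
#' mean over the DAR; a DAR with fewer than `min_cpgs` covered CpGs is
#' `rejected(no_meth_data)` (evaluated after the direction and distance
#' criteria, before the methylation ones can be read). Every rejection
#' carries the first failed criterion so reasons partition the rejected
#' set.
#'
#' @param dars DAR table with `chrom`, `start`, `end`, `direction`.
#' @param meth_t0,meth_t4 CpG tables for 0 dpa and 4 dpa.
#' @param genes gene table with `gene_id`, `chrom`, `tss`.
#' @param meth_cutoff uninjured methylation cutoff (default 0.6).
#' @param max_delta maximum absolute methylation change (default 0.25).
#' @param min_tss_dist minimum distance to any TSS in bp (default 2000;
#'   the candidate-nomination cutoff, distinct from the 10-kb "distal"
#'   annotation class).
#' @param min_cpgs minimum covered CpGs for regional methylation
#'   (default 3).
#' @return `data.table` with the DAR columns plus `meth_t0`, `meth_t4`,
#'   `delta_meth`, `distance_to_tss`, `class`
#'   (`candidate` or `rejected(<reason>)`).
#' @export
classify_enhancers <- function(dars, meth_t0, meth_t4, genes,
                               meth_cutoff = 0.6, max_delta = 0.25,
                               min_tss_dist = 2000, min_cpgs = 3L) {
  dd <- copy(as.data.table(dars))
  if (nrow(dd) == 0L) {
    dd[, `:=`(meth_t0 = numeric(), meth_t4 = numeric(),
              delta_meth = numeric(), distance_to_tss = numeric(),
              class = character())]
    return(dd[])
  }
  ann <- annotate_peaks(dd, genes, promoter_bp = min_tss_dist)
  m0 <- region_methylation(dd, meth_t0, min_cpgs = min_cpgs)
  m4 <- region_methylation(dd, meth_t4, min_cpgs = min_cpgs)
  dd[, `:=`(meth_t0 = m0, meth_t4 = m4, delta_meth = m4 - m0,
            distance_to_tss = ann$tss_distance)]
  cls <- character(nrow(dd))
  for (i in seq_len(nrow(dd))) {
    cls[i] <- if (!identical(dd$direction[i], "gained")) {
      "rejected(not_gained)"
    } else if (is.finite(dd$distance_to_tss[i]) &&
               dd$distance_to_tss[i] <= min_tss_dist) {
      "rejected(too_close_to_tss)"
    } else if (!is.finite(dd$meth_t0[i]) || !is.finite(dd$meth_t4[i])) {
      "rejected(no_meth_data)"
    } else if (dd$meth_t0[i] >= meth_cutoff) {
      "rejected(hypermethylated)"
    } else if (abs(dd$delta_meth[i]) >= max_delta) {
      "rejected(meth_unstable)"
    } else {
      "candidate"
    }
  }
  dd[, class := cls]
  dd[]
}

#' Fraction of gained DARs hypomethylated before injury
#'
#' @param dars gained-DAR interval table.
#' @param meth_t0 CpG table of the uninjured sample.
#' @param cutoff methylation cutoff (default 0.6).
#' @param min_cpgs minimum covered CpGs per DAR (default 3).
#' @return list with `fraction` (`NA` when no DAR could be evaluated),
#'   `n_evaluated`, `n_missing`.
#' @export
hypomethylated_fraction <- function(dars, meth_t0, cutoff = 0.6,
                                    min_cpgs = 3L) {
  dd <- as.data.table(dars)
  if (nrow(dd) == 0L) {
    return(list(fraction = NA_real_, n_evaluated = 0L, n_missing = 0L))
  }
  m0 <- region_methylation(dd, meth_t0, min_cpgs = min_cpgs)
  ok <- is.finite(m0)
  list(fraction = if (any(ok)) mean(m0[ok] < cutoff) else NA_real_,
       n_evaluated = sum(ok), n_missing = sum(!ok))
}

#' Read the packaged enhancer reporter-assay table
#'
#' A transcription of the published table of tested elements: element
#' name, whether the element was a DAR in sp7+ cells, in sp7- cells, and
#' whether EGFP reporter expression was observed in the regenerating fin.
#'
#' @param path TSV path; defaults to the copy shipped with the package.
#' @return `data.table` with `element`, `dar_pos`, `dar_neg`, `egfp`
#'   (logical columns).
#' @export
read_assay_table <- function(path = system.file("extdata",
                                                "enhancer_assay_table.tsv",
                                                package = "finregen")) {
  dt <- fread(path, sep = "\t", header = TRUE,
              colClasses = list(character = "element"))
  for (col in c("dar_pos", "dar_neg", "egfp")) {
    dt[[col]] <- dt[[col]] %in% c("Yes", "TRUE", "+", "yes", "true")
  }
  dt
}

#' Tally the enhancer reporter-assay table
#'
#' A row is a candidate when the element was a DAR in either cell type,
#' and a negative control otherwise; positives are rows with EGFP
#' expression.
#'
#' @param rows table from [read_assay_table()].
#' @return list with `n_candidates`, `n_positive` (EGFP+ candidates),
#'   `n_negative_controls`, `n_negative_positive` (EGFP+ negative
#'   controls).
#' @export
tally_assay_table <- function(rows) {
  dt <- as.data.table(rows)
  if (nrow(dt) == 0L) {
    return(list(n_candidates = 0L, n_positive = 0L,
                n_negative_controls = 0L, n_negative_positive = 0L))
  }
  cand <- dt$dar_pos | dt$dar_neg
  list(n_candidates = sum(cand),
       n_positive = sum(cand & dt$egfp),
       n_negative_controls = sum(!cand),
       n_negative_positive = sum(!cand & dt$egfp))
}
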
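#' Validate a pipeline configuration
#'
#' Configurations are JSON objects with optional blocks `sim`
#' (simulation fields, see [sim_config()]), `dmr` (DMR-calling fields,
#' see [dmr_params()]), `dar` (`fc_cut`, `fdr_cut`), `de` (`fc_cut`,
#' `fdr_cut`), `enhancer` (`meth_cutoff`, `max_delta`, `min_tss_dist`,
#' `min_cpgs`), `grn` (`fdr_cut`, `min_fold`, `posterior_cut`), plus
#' top-level `seed` and `outdir`. Unknown keys anywhere are rejected
#' with the offending field named; a missing seed is defaulted to 1 with
#' a warning.
#'
#' @param x path to a JSON file, or an already-parsed list.
#' @return validated configuration list (class `pipeline_config`).
#' @export
validate_config <- function(x) {
  cfg <- if (is.character(x)) jsonlite::read_json(x, simplifyVector = TRUE) else x
  if (is.null(cfg)) cfg <- list()
  known_top <- c("seed", "outdir", "sim", "dmr", "dar", "de", "enhancer", "grn")
  unknown <- setdiff(names(cfg), known_top)
  if (length(unknown)) stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  if (is.null(cfg$seed)) {
    warning("config: missing seed, defaulting to 1")
    cfg$seed <- 1L
  }
  cfg$seed <- as.integer(cfg$seed)
  sim_args <- as.list(cfg$sim %||% list())
  cfg$sim_config <- do.call(sim_config, c(list(seed = cfg$seed), sim_args))
  cfg$dmr_params <- do.call(dmr_params, as.list(cfg$dmr %||% list()))
  check_block <- function(block, allowed, name) {
    block <- as.list(block %||% list())
    unknown <- setdiff(names(block), names(allowed))
    if (length(unknown)) stop(sprintf("unknown config field(s) in %s: %s",
                                      name, paste(unknown, collapse = ", ")))
    allowed[names(block)] <- block
    allowed
  }
  cfg$dar <- check_block(cfg$dar, list(fc_cut = 2, fdr_cut = 0.01), "dar")
  cfg$de <- check_block(cfg$de, list(fc_cut = 2, fdr_cut = 0.05), "de")
  cfg$enhancer <- check_block(cfg$enhancer,
                              list(meth_cutoff = 0.6, max_delta = 0.25,
                                   min_tss_dist = 2000, min_cpgs = 3L),
                              "enhancer")
  cfg$grn <- check_block(cfg$grn,
                         list(fdr_cut = 0.05, min_fold = 1.5,
                              posterior_cut = 0.95, scan_p = 1e-5),
                         "grn")
  stopifnot(cfg$dar$fc_cut > 1, cfg$de$fc_cut > 1,
            cfg$enhancer$meth_cutoff > 0, cfg$enhancer$meth_cutoff <= 1,
            cfg$grn$posterior_cut > 0, cfg$grn$posterior_cut < 1)
  class(cfg) <- "pipeline_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pipeline_log <- function(stage, msg, ...) {
  message(sprintf("[%s] level=info %s", stage, sprintf(msg, ...)))
}

#' Run the full synthetic-data pipeline
#'
#' Simulates a multi-omics dataset under the configuration, then runs
#' every analysis stage in order: DMR calling with the empirical
#' replicate-null curve, differential accessibility (4 dpa vs 0 dpa in
#' the sorted-positive cells), differential expression, regeneration-
#' enhancer classification, and footprint-based network construction.
#' Deterministic given `config$seed`; each stage logs record counts.
#'
#' @param config a `pipeline_config` from [validate_config()], or a list
#'   coercible to one.
#' @param outdir optional directory: when given, the simulation inputs
#'   and all result tables are written there.
#' @return a result bundle: `dmrs` (cell-type), `null_curve`,
#'   `stability`, `dars`, `de`, `enhancers`, `hypo_fraction`,
#'   `concordance`, `edges`, `tfs`, `truth`, `recovery`.
#' @export
run_pipeline <- function(config = validate_config(list(seed = 1L)),
                         outdir = NULL) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  sim <- simulate_all(config$sim_config)
  if (!is.null(outdir)) write_simulation(sim, outdir)
  me <- sim$methylome$samples
  pipeline_log("simulate", "samples=%d cpgs=%d peaks=%d genes=%d",
               length(me), nrow(sim$layout$cpg_sites),
               nrow(sim$atac$peaks), nrow(sim$layout$genes))

  # --- methylome ---------------------------------------------------
  pp <- config$dmr_params
  # cell-type comparison pools both timepoints (lineage methylation is
  # stable across regeneration, so all samples of a cell type inform it)
  dmrs_ct <- find_dmrs(me[grep("^pos_", names(me), value = TRUE)],
                       me[grep("^neg_", names(me), value = TRUE)],
                       pp, labels = c("pos", "neg"))
  null_curve <- empirical_null_curve(
    replicate_pairs = list(
      pos_t0 = list(me$pos_t0_r1, me$pos_t0_r2),
      pos_t4 = list(me$pos_t4_r1, me$pos_t4_r2)),
    condition_pairs = list(
      pos_t0_vs_t4 = list(me$pos_t0_r1, me$pos_t4_r1),
      pos_vs_neg_t0 = list(me$pos_t0_r1, me$neg_t0_r1)),
    p_thresholds = c(1e-3, 1e-5, 1e-7), params = pp)
  pool2 <- function(a, b) {
    al <- align_cpgs(list(a, b))
    data.table(chrom = al$sites$chrom, pos = al$sites$pos,
               meth = rowSums(al$meth), total = rowSums(al$total))
  }
  stab <- stability_fraction(dmrs_ct,
                             pool2(me$pos_t0_r1, me$pos_t0_r2),
                             pool2(me$pos_t4_r1, me$pos_t4_r2))
  pipeline_log("methylome", "celltype_dmrs=%d stable_fraction=%.3f",
               nrow(dmrs_ct), stab$fraction_stable)

  # --- accessibility ----------------------------------------------
  tr <- sim$atac$tracks
  pos_samples <- c("pos_t0_r1", "pos_t0_r2", "pos_t4_r1", "pos_t4_r2")
  counts <- count_insertions(sim$atac$peaks, tr[pos_samples])
  groups <- factor(c("t0", "t0", "t4", "t4"), levels = c("t0", "t4"))
  dars <- test_dars(counts, groups, peaks = sim$atac$peaks,
                    fc_cut = config$dar$fc_cut, fdr_cut = config$dar$fdr_cut)
  dars <- annotate_peaks(dars, sim$layout$genes)
  pipeline_log("accessibility", "peaks=%d dars=%d gained=%d",
               nrow(sim$atac$peaks), nrow(dars),
               sum(dars$direction == "gained"))

  # --- transcriptome ----------------------------------------------
  cnt <- sim$rnaseq$counts
  rna_groups <- factor(ifelse(grepl("^t4_", colnames(cnt)), "t4", "other"),
                       levels = c("other", "t4"))
  de0 <- cnt[, grepl("^t0_|^t4_", colnames(cnt)), drop = FALSE]
  de_groups <- factor(ifelse(grepl("^t4_", colnames(de0)), "t4", "t0"),
                      levels = c("t0", "t4"))
  de <- test_de(de0, de_groups, fc_cut = config$de$fc_cut,
                fdr_cut = config$de$fdr_cut)
  conc <- concordance(dars, de)
  pipeline_log("transcriptome", "genes=%d up=%d down=%d",
               nrow(de), sum(de$status == "up"), sum(de$status == "down"))

  # --- enhancer integration ---------------------------------------
  meth0 <- pool2(me$pos_t0_r1, me$pos_t0_r2)
  meth4 <- pool2(me$pos_t4_r1, me$pos_t4_r2)
  gained <- dars[direction == "gained"]
  enh <- classify_enhancers(gained, meth0, meth4, sim$layout$genes,
                            meth_cutoff = config$enhancer$meth_cutoff,
                            max_delta = config$enhancer$max_delta,
                            min_tss_dist = config$enhancer$min_tss_dist,
                            min_cpgs = config$enhancer$min_cpgs)
  hypo <- hypomethylated_fraction(gained, meth0,
                                  cutoff = config$enhancer$meth_cutoff,
                                  min_cpgs = config$enhancer$min_cpgs)
  pipeline_log("enhancers", "gained=%d candidates=%d hypo_fraction=%.3f",
               nrow(gained), sum(enh$class == "candidate"),
               hypo$fraction %||% NA_real_)

  # --- regulatory network -----------------------------------------
  grn_out <- run_grn_stage(sim, dars, de, config)
  pipeline_log("grn", "tfs=%d edges=%d", nrow(grn_out$tfs), nrow(grn_out$edges))

  recovery <- list(
    dmr = recovery_stats(dmrs_ct, sim$truth$celltype_dmrs),
    dar = recovery_stats(dars, sim$truth$dars),
    de = {
      called <- de[status == "up"]$id
      truthset <- sim$truth$de_genes$gene_id
      list(recall = if (length(truthset)) mean(truthset %in% called) else NA_real_,
           precision = if (length(called)) mean(called %in% truthset) else NA_real_)
    },
    edges = {
      called <- paste(grn_out$edges$tf, grn_out$edges$target)
      truthset <- paste(sim$truth$edges$tf, sim$truth$edges$target)
      list(recall = if (length(truthset)) mean(truthset %in% called) else NA_real_,
           precision = if (length(called)) mean(called %in% truthset) else NA_real_)
    })

  bundle <- list(dmrs = dmrs_ct, null_curve = null_curve, stability = stab,
                 dars = dars, de = de, enhancers = enh,
                 hypo_fraction = hypo, concordance = conc,
                 edges = grn_out$edges, tfs = grn_out$tfs,
                 footprints = grn_out$footprints,
                 truth = sim$truth, recovery = recovery)
  if (!is.null(outdir)) {
    fwrite(dmrs_ct, file.path(outdir, "dmrs.tsv"), sep = "\t")
    fwrite(null_curve, file.path(outdir, "dmr_null_curve.tsv"), sep = "\t")
    fwrite(dars, file.path(outdir, "dars.tsv"), sep = "\t")
    fwrite(de, file.path(outdir, "de.tsv"), sep = "\t")
    fwrite(enh, file.path(outdir, "enhancer_candidates.tsv"), sep = "\t")
    fwrite(grn_out$edges, file.path(outdir, "grn_edges.tsv"), sep = "\t")
    jsonlite::write_json(recovery, file.path(outdir, "recovery.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  bundle
}

# interval recovery: recall = planted regions overlapped by a call;
# precision = calls overlapping a planted region
recovery_stats <- function(called, planted) {
  called <- as.data.table(called); planted <- as.data.table(planted)
  if (nrow(planted) == 0L || nrow(called) == 0L) {
    return(list(recall = if (nrow(planted)) 0 else NA_real_,
                precision = if (nrow(called)) 0 else NA_real_))
  }
  ca <- copy(called)[, .(chrom, start, end)][, xid := .I]
  pl <- copy(planted)[, .(chrom, start, end)][, yid := .I]
  setkey(pl, chrom, start, end)
  ov <- foverlaps(ca, pl, by.x = c("chrom", "start", "end"), nomatch = NULL)
  list(recall = length(unique(ov$yid)) / nrow(pl),
       precision = length(unique(ov$xid)) / nrow(ca))
}

# footprint + GRN stage on a simulation result (shared by run_pipeline
# and the end-to-end tests): scans the whole simulated genome for motif
# instances (as genome-wide motif scanning does), tests enrichment in
# gained DARs against non-DAR peaks, fits the footprint model per PWM on
# 4 dpa insertions over all instances, selects upstream TFs and
# assembles edges.
run_grn_stage <- function(sim, dars, de, config) {
  grn_cfg <- config$grn
  genome <- sim$genome$genome
  gained <- as.data.table(dars)[direction == "gained", .(chrom, start, end)]
  peaks <- sim$atac$peaks
  dar_ids <- as.data.table(dars)
  nonDar <- peaks[!mapply(function(ch, s, e)
    any(dar_ids$chrom == ch & dar_ids$start < e & dar_ids$end > s),
    peaks$chrom, peaks$start, peaks$end), .(chrom, start, end)]
  pwms <- sim$genome$pwms
  ins4 <- rbind(sim$atac$tracks$pos_t4_r1, sim$atac$tracks$pos_t4_r2)
  setorder(ins4, chrom, pos)
  all_bound <- list(); enrich <- list(); fits <- list()
  for (pw in pwms) {
    h <- scan_pwm(genome, pw, p_threshold = grn_cfg$scan_p)
    hits <- data.table(chrom = h$seqname, start = h$start, end = h$end,
                       pwm = h$pwm, score = h$score)
    enrich[[pw$name]] <- motif_enrichment(gained, nonDar, hits,
                                          pwms = pw$name)
    if (nrow(hits) == 0L) next
    win <- footprint_windows(hits, ins4, width = 200L)
    fit <- fit_footprint_model(win, hits$score,
                               posterior_cut = grn_cfg$posterior_cut,
                               seed = config$seed)
    fits[[pw$name]] <- fit
    bd <- hits[fit$bound]
    if (nrow(bd)) all_bound[[pw$name]] <- bd
  }
  enrich <- rbindlist(enrich)
  bound_sites <- if (length(all_bound)) rbindlist(all_bound) else
    data.table(chrom = character(), start = integer(), end = integer(),
               pwm = character(), score = numeric())
  # TF expression by timepoint (normalized means)
  cnt <- sim$rnaseq$counts
  sf <- size_factors(cnt)
  norm <- sweep(cnt, 2, sf, "/")
  tps <- sub("^t(\\d+)_.*$", "\\1", colnames(norm))
  expr <- sapply(sort(unique(as.integer(tps))), function(tp)
    rowMeans(norm[, tps == as.character(tp), drop = FALSE]))
  colnames(expr) <- sort(unique(as.integer(tps)))
  tfs <- select_upstream_tfs(enrich, expr, sim$truth$tf_map,
                             fdr_cut = grn_cfg$fdr_cut,
                             min_fold = grn_cfg$min_fold)
  up <- de[status == "up"]$id
  edges <- build_grn(tfs, bound_sites, gained, sim$layout$genes, up)
  list(edges = edges, tfs = tfs, enrichment = enrich,
       footprints = fits, bound_sites = bound_sites)
}

#' Insertion count vectors in windows around motif sites
#'
#' Counts insertions per bp in a `width`-bp window centred on each motif
#' site midpoint.
#'
#' @param sites motif-site intervals (`chrom`, `start`, `end`).
#' @param track insertion table (`chrom`, `pos`), sorted.
#' @param width window width in bp (default 200).
#' @return sites x width count matrix.
#' @export
footprint_windows <- function(sites, track, width = 200L) {
  st <- as.data.table(sites)
  tr <- as.data.table(track)
  out <- matrix(0L, nrow(st), width)
  half <- floor(width / 2)
  for (ch in unique(st$chrom)) {
    pos <- tr[chrom == ch, sort(pos)]
    idx <- which(st$chrom == ch)
    for (i in idx) {
      mid <- floor((st$start[i] + st$end[i]) / 2)
      lo <- mid - half
      inw <- pos[pos >= lo & pos < lo + width]
      if (length(inw)) {
        tb <- tabulate(inw - lo + 1L, nbins = width)
        out[i, ] <- tb
      }
    }
  }
  out
}
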
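# Beta-binomial draw parameterized by (mean mu, dispersion phi) with
# phi = 1 / (a + b + 1); phi -> 0 degenerates to binomial.
rbetabinom <- function(n, size, mu, phi) {
  mu <- pmin(pmax(mu, 1e-6), 1 - 1e-6)
  if (phi <= 1e-8) return(rbinom(n, size, mu))
  s <- (1 - phi) / phi  # a + b
  p <- rbeta(n, mu * s, (1 - mu) * s)
  rbinom(n, size, p)
}

methylome_sample_grid <- function(config) {
  CJ(celltype = config$celltypes, timepoint = c(0L, 4L),
     rep = seq_len(config$n_reps), sorted = FALSE)
}

#' Simulate per-sample CpG methylation tables
#'
#' Generates 2 cell types x 2 timepoints (0 and 4 dpa) x `n_reps`
#' replicates of strand-collapsed CpG records. Background methylation is
#' bimodal (high mode near 0.87, low mode at promoters); planted
#' cell-type DMRs lower the positive cell type's mean by `dmr_effect` at
#' both timepoints (stable across regeneration); optional time DMRs
#' lower the 4 dpa mean in the positive cell type. Coverage is Poisson
#' (`mean_coverage`) and counts are beta-binomial with dispersion
#' `dispersion_phi`; replicates share true means.
#'
#' @param config a [sim_config()].
#' @param layout optional precomputed [sim_layout()].
#' @return list with `samples` (named list of CpG tables,
#'   `"<celltype>_t<dpa>_r<rep>"`), `truth` (`celltype_dmrs`,
#'   `time_dmrs` interval tables with true means), and `cpg_sites`.
#' @export
simulate_methylome <- function(config, layout = NULL) {
  if (is.null(layout)) layout <- sim_layout(config)
  cfg <- config
  set.seed(cfg$seed + 1L)
  grid <- methylome_sample_grid(cfg)
  n_cpg <- nrow(layout$cpg_sites)
  samples <- vector("list", nrow(grid))
  names(samples) <- sprintf("%s_t%d_r%d", grid$celltype, grid$timepoint, grid$rep)
  for (i in seq_len(nrow(grid))) {
    mu <- if (grid$celltype[i] == "pos") layout$mu_pos else layout$mu_neg
    if (grid$timepoint[i] == 4L && grid$celltype[i] == "pos" &&
        length(layout$time_shift_idx)) {
      mu <- copy(mu)
      mu[layout$time_shift_idx] <- pmax(
        layout$base_dmr_mu - cfg$dmr_effect, 0)
    }
    total <- rpois(n_cpg, cfg$mean_coverage)
    meth <- integer(n_cpg)
    nz <- total > 0
    meth[nz] <- rbetabinom(sum(nz), total[nz], mu[nz], cfg$dispersion_phi)
    samples[[i]] <- data.table(chrom = layout$cpg_sites$chrom,
                               pos = layout$cpg_sites$pos,
                               meth = meth, total = total)
    setkey(samples[[i]], chrom, pos)
  }
  truth_ct <- copy(layout$celltype_dmrs)
  if (nrow(truth_ct)) {
    truth_ct[, `:=`(hypo_in = "pos",
                    mean_pos = layout$base_dmr_mu - cfg$dmr_effect,
                    mean_neg = layout$base_dmr_mu)]
  }
  truth_tm <- copy(layout$time_dmrs)
  if (nrow(truth_tm)) {
    truth_tm[, `:=`(hypo_in = "t4",
                    mean_t0 = layout$base_dmr_mu,
                    mean_t4 = layout$base_dmr_mu - cfg$dmr_effect)]
  }
  list(samples = samples,
       truth = list(celltype_dmrs = truth_ct, time_dmrs = truth_tm),
       cpg_sites = layout$cpg_sites)
}

#' Simulate Tn5 insertion tracks with peaks, DARs and footprints
#'
#' Insertions are placed by an inhomogeneous Poisson process: a uniform
#' background (`bg_insertion_rate` per bp), peak regions with mean
#' `peak_mean_insertions` per sample, planted gained (lost) DARs whose
#' 4 dpa rate in the positive cell type is multiplied (divided) by
#' `dar_fold`, and bound motif sites that superimpose a trapezoid
#' footprint: 50-bp flanks at 1.5x the local peak rate and a motif core
#' thinned to `(1 - footprint_depletion)` of the flank rate.
#'
#' @inheritParams simulate_methylome
#' @return list with `tracks` (named list of insertion tables),
#'   `peaks`, and `truth` (`dars`, `sites`).
#' @export
simulate_atac <- function(config, layout = NULL) {
  if (is.null(layout)) layout <- sim_layout(config)
  cfg <- config
  set.seed(cfg$seed + 2L)
  grid <- methylome_sample_grid(cfg)
  peaks <- layout$peaks
  dars <- layout$dars
  sites <- layout$sites
  tracks <- vector("list", nrow(grid))
  names(tracks) <- sprintf("%s_t%d_r%d", grid$celltype, grid$timepoint, grid$rep)
  peak_rate <- cfg$peak_mean_insertions / cfg$peak_width
  for (i in seq_len(nrow(grid))) {
    ct <- grid$celltype[i]; tp <- grid$timepoint[i]
    parts <- list()
    # background
    for (ch in layout$chroms) {
      n_bg <- rpois(1, cfg$bg_insertion_rate * cfg$chrom_len)
      parts[[length(parts) + 1L]] <-
        data.table(chrom = ch,
                   pos = as.integer(floor(runif(n_bg, 0, cfg$chrom_len))))
    }
    # peaks (with DAR modulation in the positive cells at 4 dpa)
    mult <- rep(1, nrow(peaks))
    if (tp == 4L && ct == "pos" && nrow(dars)) {
      m <- match(peaks$peak_id, dars$peak_id)
      hit <- !is.na(m)
      mult[hit] <- ifelse(dars$direction[m[hit]] == "gained",
                          cfg$dar_fold, 1 / cfg$dar_fold)
    }
    # linked enhancer peaks carry no signal before regeneration
    closed <- peaks$placement == "linked_enhancer" & !(tp == 4L & ct == "pos")
    mult[closed] <- 0.1
    n_pk <- rpois(nrow(peaks), cfg$peak_mean_insertions * mult)
    pk_pos <- lapply(which(n_pk > 0), function(k)
      data.table(chrom = peaks$chrom[k],
                 pos = as.integer(floor(runif(n_pk[k], peaks$start[k], peaks$end[k])))))
    parts <- c(parts, pk_pos)
    ins <- rbindlist(parts)
    # footprints at bound sites, active in positive cells at 4 dpa
    if (nrow(sites)) {
      active <- sites[bound == TRUE]
      if (tp == 4L && ct == "pos" && nrow(active)) {
        local_rate <- peak_rate * cfg$dar_fold  # bound sites sit in gained DARs
        flank_rate <- 1.5 * local_rate
        core_rate <- (1 - cfg$footprint_depletion) * flank_rate
        for (k in seq_len(nrow(active))) {
          s0 <- active$start[k]; s1 <- active$end[k]
          # thin or boost the core toward core_rate (current ~ local_rate)
          in_core <- ins$chrom == active$chrom[k] & ins$pos >= s0 & ins$pos < s1
          keep_p <- min(core_rate / local_rate, 1)
          drop <- which(in_core)[runif(sum(in_core)) > keep_p]
          if (length(drop)) ins <- ins[-drop]
          extra_core <- max(core_rate - local_rate, 0) * (s1 - s0)
          n_ec <- rpois(1, extra_core)
          # flanks: add the excess over the local rate
          n_fl <- rpois(2, (flank_rate - local_rate) * 50)
          add <- data.table(
            chrom = active$chrom[k],
            pos = as.integer(c(
              if (n_ec > 0) floor(runif(n_ec, s0, s1)),
              if (n_fl[1] > 0) floor(runif(n_fl[1], s0 - 50, s0)),
              if (n_fl[2] > 0) floor(runif(n_fl[2], s1, s1 + 50)))))
          if (nrow(add)) ins <- rbind(ins, add)
        }
      }
    }
    ins[, pos := pmin(pmax(pos, 0L), cfg$chrom_len - 1L)]
    setorder(ins, chrom, pos)
    setattr(ins, "library_size", nrow(ins))
    tracks[[i]] <- ins
  }
  list(tracks = tracks, peaks = copy(peaks),
       truth = list(dars = copy(dars), sites = copy(sites)))
}

#' Simulate a gene-level RNA count matrix over the regeneration course
#'
#' Negative-binomial counts (dispersion `nb_dispersion`) for the
#' positive cell type at 0/1/2/4 dpa with `n_reps` replicates. Planted
#' DE genes are induced `de_fold`-fold at 4 dpa; designated TF genes
#' rise `de_fold`-fold from 1 dpa on (early activation); every planted
#' regulatory edge's target is a DE gene whose linked gained DAR carries
#' the TF's bound motif site.
#'
#' @inheritParams simulate_methylome
#' @return list with `counts` (genes x samples, columns
#'   `t<dpa>_r<rep>`), `gene_lengths`, and `truth` (`de_genes`,
#'   `tf_genes`, `edges`).
#' @export
simulate_rnaseq <- function(config, layout = NULL) {
  if (is.null(layout)) layout <- sim_layout(config)
  cfg <- config
  set.seed(cfg$seed + 3L)
  genes <- layout$genes
  base <- stats::rlnorm(nrow(genes), log(cfg$rna_base_mean), 0.6)
  grid <- CJ(timepoint = cfg$timepoints, rep = seq_len(cfg$n_reps), sorted = FALSE)
  cn <- sprintf("t%d_r%d", grid$timepoint, grid$rep)
  counts <- matrix(0, nrow(genes), nrow(grid),
                   dimnames = list(genes$gene_id, cn))
  is_de <- genes$gene_id %in% layout$de_genes
  is_tf <- genes$gene_id %in% layout$tf_genes
  for (j in seq_len(nrow(grid))) {
    tp <- grid$timepoint[j]
    mu <- base
    if (cfg$de_fold > 1) {
      if (tp == 4L) mu[is_de] <- mu[is_de] * cfg$de_fold
      if (tp >= 1L) mu[is_tf] <- mu[is_tf] * cfg$de_fold
    }
    counts[, j] <- rnbinom(length(mu), mu = mu, size = 1 / cfg$nb_dispersion)
  }
  truth_de <- if (cfg$de_fold > 1) {
    data.table(gene_id = c(layout$de_genes, layout$tf_genes),
               log2_fold = log2(cfg$de_fold),
               is_tf = c(rep(FALSE, length(layout$de_genes)),
                         rep(TRUE, length(layout$tf_genes))))
  } else data.table(gene_id = character(), log2_fold = numeric(),
                    is_tf = logical())
  edges <- if (length(layout$targets)) {
    data.table(tf = layout$target_tf,
               pwm = layout$tf_map$pwm[match(layout$target_tf, layout$tf_map$gene_id)],
               target = layout$targets)
  } else data.table(tf = character(), pwm = character(), target = character())
  list(counts = counts, gene_lengths = setNames(genes$exonic_length, genes$gene_id),
       truth = list(de_genes = truth_de, tf_genes = layout$tf_genes,
                    edges = edges))
}

#' Simulate the genome sequence, annotation, PWMs and motif instances
#'
#' Random sequence per chromosome with the exact consensus of each TF's
#' PWM planted at every truth motif site (bound and unbound) and a `CG`
#' dinucleotide written at every simulated CpG position (outside motif
#' windows). Gene TSSs are positioned so that each planted
#' enhancer-gene nearest-TSS link holds.
#'
#' @inheritParams simulate_methylome
#' @return list with `genome` (named character), `genes` (GTF-ready
#'   table), `pwms`, `sites` (motif-instance table), `chrom_sizes`.
#' @export
simulate_genome <- function(config, layout = NULL) {
  if (is.null(layout)) layout <- sim_layout(config)
  cfg <- config
  set.seed(cfg$seed + 4L)
  bases <- c("A", "C", "G", "T")
  genome <- list()
  for (ch in layout$chroms) {
    v <- sample(bases, cfg$chrom_len, replace = TRUE)
    # CpG dinucleotides at simulated CpG positions
    cp <- layout$cpg_sites[chrom == ch, pos]
    v[cp + 1L] <- "C"; v[cp + 2L] <- "G"
    # plant motif consensi (after CpGs so instances stay exact)
    st <- layout$sites[chrom == ch]
    if (nrow(st)) {
      for (k in seq_len(nrow(st))) {
        cons <- strsplit(layout$consensi[match(st$pwm[k], vapply(layout$pwms, `[[`, "", "name"))], "")[[1]]
        v[(st$start[k] + 1L):(st$start[k] + cfg$motif_length)] <- cons
      }
    }
    genome[[ch]] <- paste(v, collapse = "")
  }
  list(genome = unlist(genome), genes = copy(layout$genes),
       pwms = layout$pwms, sites = copy(layout$sites),
       chrom_sizes = layout$chrom_sizes)
}

#' Run every generator under one configuration
#'
#' @param config a [sim_config()].
#' @return list with `layout`, `methylome`, `atac`, `rnaseq`, `genome`
#'   and a consolidated `truth` ledger sufficient to score recovery of
#'   every planted element.
#' @export
simulate_all <- function(config) {
  layout <- sim_layout(config)
  me <- simulate_methylome(config, layout)
  at <- simulate_atac(config, layout)
  rn <- simulate_rnaseq(config, layout)
  ge <- simulate_genome(config, layout)
  truth <- list(celltype_dmrs = me$truth$celltype_dmrs,
                time_dmrs = me$truth$time_dmrs,
                dars = at$truth$dars,
                sites = at$truth$sites,
                de_genes = rn$truth$de_genes,
                tf_genes = rn$truth$tf_genes,
                edges = rn$truth$edges,
                tf_map = layout$tf_map)
  list(layout = layout, methylome = me, atac = at, rnaseq = rn,
       genome = ge, truth = truth)
}

#' Write a simulation to disk in the pipeline's input formats
#'
#' methylC files per methylome sample, insertion BED per ATAC sample,
#' peaks BED, gene annotation GTF, genome FASTA, MEME-like PWM file,
#' motif-instance BED, RNA count TSV, and `truth.json`.
#'
#' @param sim result of [simulate_all()].
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(sim$methylome$samples)) {
    write_methylc(sim$methylome$samples[[nm]],
                  file.path(outdir, paste0("meth_", nm, ".methylc")))
  }
  for (nm in names(sim$atac$tracks)) {
    tr <- sim$atac$tracks[[nm]]
    fwrite(tr[, .(chrom, pos, end = pos + 1L)],
           file.path(outdir, paste0("insertions_", nm, ".bed")),
           sep = "\t", col.names = FALSE)
  }
  write_bed(sim$atac$peaks[, .(chrom, start, end, name = peak_id)],
            file.path(outdir, "peaks.bed"))
  gn <- sim$genome$genes
  gtf <- sprintf(
    "%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; gene_name \"%s\";",
    gn$chrom, pmin(gn$start, gn$end - 1L) + 1L, pmax(gn$end, gn$start + 1L),
    gn$strand, gn$gene_id, gn$gene_id)
  writeLines(gtf, file.path(outdir, "genes.gtf"))
  write_fasta(sim$genome$genome, file.path(outdir, "genome.fa"))
  write_pwm(sim$genome$pwms, file.path(outdir, "motifs.meme"))
  if (nrow(sim$truth$sites)) {
    write_bed(sim$truth$sites[, .(chrom, start, end, name = pwm)],
              file.path(outdir, "motif_sites.bed"))
  }
  write_counts(sim$rnaseq$counts, file.path(outdir, "rna_counts.tsv"))
  truth <- lapply(sim$truth, function(x) if (is.data.table(x)) as.data.frame(x) else x)
  jsonlite::write_json(truth, file.path(outdir, "truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
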
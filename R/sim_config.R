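#' Simulation configuration
#'
#' Defaults encode the data regime of sorted-cell fin-regeneration
#' multi-omics: a small two-chromosome genome dense enough in CpGs,
#' genes and peaks to exercise every pipeline stage; bimodal CpG
#' methylation with a high mode near 80 percent global mCG/CG;
#' cell-type hypoDMRs of effect 0.4 stable across timepoints and no
#' time DMRs (the central negative result); 4-fold planted
#' differential accessibility and expression with beta-binomial /
#' negative-binomial noise; and three TF motifs with bound footprint
#' sites (core depletion 0.7) wired into a TF-to-target network.
#'
#' @param seed integer RNG seed.
#' @param ... overrides for any field; unknown fields are rejected.
#' @return validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    n_chroms = 2L,
    chrom_len = 1000000L,
    n_cpgs = 30000L,
    n_genes = 150L,
    n_peaks = 260L,
    n_celltype_dmrs = 200L,
    n_time_dmrs = 0L,
    dmr_effect = 0.4,
    cpgs_per_dmr = 10L,
    mean_coverage = 20,
    dispersion_phi = 0.05,
    n_dars = 60L,
    dar_fold = 4,
    n_de_genes = 40L,
    de_fold = 4,
    nb_dispersion = 0.05,
    n_footprint_motifs = 3L,
    n_grn_targets = 20L,
    n_unbound_sites_per_tf = 40L,
    footprint_depletion = 0.7,
    motif_length = 10L,
    n_reps = 2L,
    timepoints = c(0L, 1L, 2L, 4L),
    celltypes = c("pos", "neg"),
    peak_width = 400L,
    peak_mean_insertions = 100,
    bg_insertion_rate = 0.002,
    hypometh_dar_fraction = 0.85,
    rna_base_mean = 100,
    promoter_halfwidth = 600L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown sim_config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  cnt <- c("n_chroms", "chrom_len", "n_cpgs", "n_genes", "n_peaks",
           "n_celltype_dmrs", "n_time_dmrs", "n_dars", "n_de_genes",
           "n_footprint_motifs", "n_grn_targets", "n_reps")
  for (f in cnt) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0) stop("sim_config: ", f, " must be a non-negative count")
  }
  if (!(cfg$dmr_effect > 0 && cfg$dmr_effect <= 1) && cfg$n_celltype_dmrs > 0) {
    if (cfg$dmr_effect != 0) stop("sim_config: dmr_effect must lie in (0, 1] (or 0 to plant nothing)")
  }
  if (cfg$dar_fold < 1 || cfg$de_fold < 1) stop("sim_config: dar_fold and de_fold must be >= 1")
  if (cfg$footprint_depletion < 0 || cfg$footprint_depletion > 1)
    stop("sim_config: footprint_depletion must lie in [0, 1]")
  if (cfg$dispersion_phi <= 0 || cfg$dispersion_phi >= 1)
    stop("sim_config: dispersion_phi must lie in (0, 1)")
  # planted elements must fit inside the simulated genome
  genome_len <- cfg$n_chroms * cfg$chrom_len
  need_cpgs <- cfg$cpgs_per_dmr * (cfg$n_celltype_dmrs + cfg$n_time_dmrs)
  if (need_cpgs > cfg$n_cpgs / 2)
    stop("sim_config: planted DMRs would use more than half of all CpGs; enlarge n_cpgs")
  if ((cfg$n_peaks + cfg$n_grn_targets) * (cfg$peak_width + 2000) > genome_len)
    stop("sim_config: peaks do not fit in the genome; enlarge chrom_len")
  if (cfg$n_dars > cfg$n_peaks) stop("sim_config: n_dars exceeds n_peaks")
  if (cfg$n_grn_targets > cfg$n_de_genes)
    stop("sim_config: n_grn_targets exceeds n_de_genes")
  if (cfg$n_de_genes + cfg$n_footprint_motifs > cfg$n_genes)
    stop("sim_config: DE genes plus TF genes exceed n_genes")
  invisible(cfg)
}

#' Deterministic shared layout of the simulated world
#'
#' All placement decisions (chromosomes, gene TSSs, CpG positions, peak
#' intervals, planted DMR runs, DARs, enhancer-target links, motif
#' consensus sequences and sites, DE/TF gene assignments, per-CpG true
#' methylation means) are drawn here under `config$seed`, so every
#' `simulate_*` generator sees the same world and the truth ledger is
#' consistent across assays.
#'
#' @param config a [sim_config()] object.
#' @return a list describing the layout (used by the generators and
#'   condensed into the truth ledger).
#' @export
sim_layout <- function(config) {
  cfg <- config
  set.seed(cfg$seed)
  chroms <- paste0("chr", seq_len(cfg$n_chroms))
  chrom_sizes <- setNames(rep(cfg$chrom_len, cfg$n_chroms), chroms)

  # genes on a jittered grid, alternating strand
  genes_per_chrom <- diff(floor(seq(0, cfg$n_genes, length.out = cfg$n_chroms + 1)))
  genes <- list()
  gi <- 0L
  for (ci in seq_along(chroms)) {
    ng <- genes_per_chrom[ci]
    if (ng == 0L) next
    spacing <- cfg$chrom_len / (ng + 1)
    tss <- round(seq_len(ng) * spacing + runif(ng, -500, 500))
    tss <- pmin(pmax(tss, 2000L), cfg$chrom_len - 4000L)
    genes[[ci]] <- data.table(
      gene_id = sprintf("g%03d", gi + seq_len(ng)),
      chrom = chroms[ci], tss = as.integer(tss),
      strand = rep(c("+", "-"), length.out = ng),
      exonic_length = 1500L)
    gi <- gi + ng
  }
  genes <- rbindlist(genes)
  genes[, `:=`(start = ifelse(strand == "+", tss, tss - 1999L),
               end = ifelse(strand == "+", tss + 2000L, tss + 1L))]

  # TF and DE gene assignment
  tf_idx <- seq_len(cfg$n_footprint_motifs)
  tf_genes <- genes$gene_id[tf_idx]
  de_pool <- setdiff(genes$gene_id, tf_genes)
  de_genes <- sort(sample(de_pool, cfg$n_de_genes))
  targets <- if (cfg$n_grn_targets > 0) sort(sample(de_genes, cfg$n_grn_targets)) else character(0)
  target_tf <- if (length(targets)) tf_genes[((seq_along(targets) - 1L) %% length(tf_genes)) + 1L] else character(0)

  # motif consensi and PWMs (length L, dominant probability 0.9)
  bases <- c("A", "C", "G", "T")
  consensi <- vapply(seq_len(cfg$n_footprint_motifs), function(i)
    paste(sample(bases, cfg$motif_length, replace = TRUE), collapse = ""),
    character(1))
  pwm_names <- sprintf("TF%d_motif", seq_len(cfg$n_footprint_motifs))
  pwms <- lapply(seq_along(consensi), function(i) {
    cons <- strsplit(consensi[i], "")[[1]]
    mat <- matrix(0.1 / 3, cfg$motif_length, 4, dimnames = list(NULL, bases))
    for (l in seq_along(cons)) mat[l, cons[l]] <- 0.9
    list(name = pwm_names[i], matrix = mat,
         background = setNames(rep(0.25, 4), bases), pseudocount = 0)
  })
  tf_map <- data.table(pwm = pwm_names, gene_id = tf_genes)

  # enhancer DARs linked to targets: distal (> 2 kb) on the gene's
  # downstream side, close enough that the target owns the nearest TSS
  linked <- data.table()
  if (length(targets)) {
    tg <- genes[match(targets, gene_id)]
    offset <- round(runif(length(targets), 3000, 4500))
    center <- ifelse(tg$strand == "+", tg$tss + offset, tg$tss - offset)
    center <- pmin(pmax(center, cfg$peak_width), cfg$chrom_len - cfg$peak_width)
    linked <- data.table(chrom = tg$chrom,
                         start = as.integer(center - cfg$peak_width / 2),
                         end = as.integer(center + cfg$peak_width / 2),
                         target = targets, tf_gene = target_tf,
                         pwm = tf_map$pwm[match(target_tf, tf_map$gene_id)])
  }

  # ordinary peaks: ~26% at promoters, the rest on a shuffled candidate
  # grid away from genes and linked enhancers
  n_prom <- round(0.26 * cfg$n_peaks)
  prom_genes <- genes[sample(.N, min(n_prom, .N))]
  prom_peaks <- data.table(chrom = prom_genes$chrom,
                           start = as.integer(prom_genes$tss - cfg$peak_width / 2),
                           end = as.integer(prom_genes$tss + cfg$peak_width / 2),
                           placement = "promoter")
  grid <- rbindlist(lapply(chroms, function(ch)
    data.table(chrom = ch,
               center = seq(3000L, cfg$chrom_len - 3000L, by = 2500L))))
  avoid <- rbind(genes[, .(chrom, lo = tss - 1500L, hi = tss + 1500L)],
                 if (nrow(linked)) linked[, .(chrom, lo = start - 1500L, hi = end + 1500L)])
  bad <- rep(FALSE, nrow(grid))
  for (i in seq_len(nrow(avoid))) {
    bad <- bad | (grid$chrom == avoid$chrom[i] &
                    grid$center >= avoid$lo[i] & grid$center <= avoid$hi[i])
  }
  grid <- grid[!bad][sample(.N)]
  n_other <- cfg$n_peaks - nrow(prom_peaks)
  if (n_other > nrow(grid)) stop("sim_layout: not enough space for peaks; enlarge chrom_len")
  other_peaks <- grid[seq_len(n_other),
                      .(chrom, start = as.integer(center - cfg$peak_width / 2),
                        end = as.integer(center + cfg$peak_width / 2),
                        placement = "background")]
  peaks <- rbind(prom_peaks, other_peaks)
  if (nrow(linked)) {
    peaks <- rbind(peaks, linked[, .(chrom, start, end, placement = "linked_enhancer")])
  }
  setorder(peaks, chrom, start)
  peaks[, peak_id := sprintf("peak%04d", .I)]

  # DARs: all linked enhancers gain; the remainder sampled from
  # non-promoter ordinary peaks, half gained half lost
  dars <- peaks[placement == "linked_enhancer",
                .(peak_id, chrom, start, end, direction = "gained")]
  n_more <- max(cfg$n_dars - nrow(dars), 0L)
  cand <- peaks[placement == "background"]
  if (n_more > nrow(cand)) stop("sim_layout: n_dars exceeds available non-promoter peaks")
  if (cfg$dar_fold > 1 && n_more > 0) {
    pick <- cand[sample(.N, n_more)]
    dir <- rep(c("gained", "lost"), length.out = n_more)
    dars <- rbind(dars, pick[, .(peak_id, chrom, start, end, direction = dir)])
  }
  if (cfg$dar_fold <= 1) dars <- dars[0]
  setorder(dars, chrom, start)

  # motif sites: one bound site at the centre of each linked DAR
  # (bound at 4 dpa in the sorted-positive cells), plus unbound
  # consensus instances inside non-DAR background peaks
  bound_sites <- data.table()
  if (nrow(linked)) {
    lc <- peaks[placement == "linked_enhancer"]
    lc <- merge(lc, linked[, .(chrom, start, end, target, tf_gene, pwm)],
                by = c("chrom", "start", "end"))
    mid <- floor((lc$start + lc$end) / 2)
    bound_sites <- data.table(chrom = lc$chrom,
                              start = as.integer(mid - floor(cfg$motif_length / 2)),
                              end = as.integer(mid - floor(cfg$motif_length / 2) + cfg$motif_length),
                              pwm = lc$pwm, bound = TRUE,
                              target = lc$target, tf_gene = lc$tf_gene,
                              peak_id = lc$peak_id)
  }
  # unbound instances are scattered across the genome (as genome-wide
  # motif scans find them), away from peaks, genes and planted DMRs, so
  # motifs stay enriched in gained DARs while the footprint model sees a
  # large unbound class
  n_unb <- cfg$n_unbound_sites_per_tf * cfg$n_footprint_motifs
  unbound_sites <- data.table()
  if (n_unb > 0) {
    ugrid <- rbindlist(lapply(chroms, function(ch)
      data.table(chrom = ch,
                 start = seq(1000L, cfg$chrom_len - 1000L, by = 1700L))))
    bad <- rep(FALSE, nrow(ugrid))
    avoid2 <- rbind(peaks[, .(chrom, lo = start - 600L, hi = end + 600L)],
                    genes[, .(chrom, lo = tss - 1200L, hi = tss + 1200L)])
    for (i in seq_len(nrow(avoid2))) {
      bad <- bad | (ugrid$chrom == avoid2$chrom[i] &
                      ugrid$start >= avoid2$lo[i] & ugrid$start <= avoid2$hi[i])
    }
    ugrid <- ugrid[!bad][sample(.N)]
    if (n_unb > nrow(ugrid)) stop("sim_layout: not enough space for unbound motif sites")
    rows <- ugrid[seq_len(n_unb)]
    unbound_sites <- data.table(chrom = rows$chrom,
                                start = rows$start,
                                end = rows$start + cfg$motif_length,
                                pwm = rep(pwm_names, each = cfg$n_unbound_sites_per_tf),
                                bound = FALSE, target = NA_character_,
                                tf_gene = NA_character_, peak_id = NA_character_)
  }
  sites <- rbind(bound_sites, unbound_sites)
  if (nrow(sites)) setorder(sites, chrom, start)

  # CpG positions: uniform random, deduplicated, sorted. Every planted
  # DAR additionally carries at least four evenly spaced CpGs so its
  # regional methylation is always measurable (regeneration enhancers
  # are CpG-bearing elements).
  cpgs_per_chrom <- diff(floor(seq(0, cfg$n_cpgs, length.out = cfg$n_chroms + 1)))
  cpg_sites <- rbindlist(lapply(seq_along(chroms), function(ci) {
    pos <- sort(sample(seq(100L, cfg$chrom_len - 100L, by = 2L),
                       cpgs_per_chrom[ci]))
    data.table(chrom = chroms[ci], pos = pos)
  }))
  if (nrow(dars)) {
    anchors <- dars[, .(chrom,
                        pos = as.integer(2L * floor((start + (end - start) *
                                                       c(0.2, 0.4, 0.6, 0.8)) / 2))),
                    by = .(peak_id)][, .(chrom, pos)]
    cpg_sites <- unique(rbind(cpg_sites, anchors))
  }
  setkey(cpg_sites, chrom, pos)

  # per-CpG true methylation means
  n_cpg <- nrow(cpg_sites)
  mu <- rbeta(n_cpg, 26, 4)                      # high mode, mean ~0.87
  in_prom <- overlaps_point(cpg_sites,
                            genes[, .(chrom, lo = tss - cfg$promoter_halfwidth,
                                      hi = tss + cfg$promoter_halfwidth)])
  mu[in_prom] <- rbeta(sum(in_prom), 2, 18)      # promoter low mode, mean 0.1
  # hypomethylated gained DARs (stable over time): regeneration
  # enhancers are preset lowly methylated before injury
  gained <- dars[direction == "gained"]
  if (nrow(gained)) {
    is_linked <- gained$peak_id %in% peaks[placement == "linked_enhancer"]$peak_id
    hypo <- is_linked | (runif(nrow(gained)) < cfg$hypometh_dar_fraction)
    hypo_reg <- gained[hypo]
    if (nrow(hypo_reg)) {
      in_hypo <- overlaps_point(cpg_sites,
                                hypo_reg[, .(chrom, lo = start, hi = end - 1L)])
      mu[in_hypo] <- rbeta(sum(in_hypo), 6, 14)  # mean 0.3
    }
    dars[, hypomethylated := FALSE]
    dars[direction == "gained", hypomethylated := hypo]
  } else {
    dars[, hypomethylated := logical(0)]
  }

  # planted cell-type DMR runs: cpgs_per_dmr consecutive CpGs spanning
  # 250-900 bp, outside promoters, peaks and DARs, non-overlapping
  excl <- rbind(genes[, .(chrom, lo = tss - 1600L, hi = tss + 1600L)],
                peaks[, .(chrom, lo = start - 200L, hi = end + 200L)])
  free <- !overlaps_point(cpg_sites, excl)
  n_ct <- if (cfg$dmr_effect > 0) cfg$n_celltype_dmrs else 0L
  n_tm <- if (cfg$dmr_effect > 0) cfg$n_time_dmrs else 0L
  dmr_runs <- pick_cpg_runs(cpg_sites, free, cfg$cpgs_per_dmr, n_ct + n_tm,
                            span_range = c(250, 900))
  if (nrow(dmr_runs) < n_ct + n_tm)
    stop("sim_layout: could not place all requested DMR runs; enlarge n_cpgs or chrom_len")
  ct_runs <- dmr_runs[seq_len(n_ct)]
  tm_runs <- dmr_runs[n_ct + seq_len(n_tm)]

  base_dmr_mu <- max(0.85, cfg$dmr_effect)
  mu_pos <- mu; mu_neg <- mu
  dmr_cpg_idx <- integer(0)
  if (nrow(ct_runs) && cfg$dmr_effect > 0) {
    for (i in seq_len(nrow(ct_runs))) {
      idx <- ct_runs$first_idx[i]:ct_runs$last_idx[i]
      mu_neg[idx] <- base_dmr_mu
      mu_pos[idx] <- base_dmr_mu - cfg$dmr_effect
      dmr_cpg_idx <- c(dmr_cpg_idx, idx)
    }
  }
  # time DMRs: methylation loss at 4 dpa in the positive cell type
  time_shift_idx <- integer(0)
  if (nrow(tm_runs) && cfg$dmr_effect > 0) {
    for (i in seq_len(nrow(tm_runs))) {
      idx <- tm_runs$first_idx[i]:tm_runs$last_idx[i]
      mu_pos[idx] <- base_dmr_mu
      mu_neg[idx] <- base_dmr_mu
      time_shift_idx <- c(time_shift_idx, idx)
    }
  }

  list(config = cfg, chroms = chroms, chrom_sizes = chrom_sizes,
       genes = genes, peaks = peaks, dars = dars,
       tf_map = tf_map, pwms = pwms, consensi = consensi,
       de_genes = de_genes, tf_genes = tf_genes,
       targets = targets, target_tf = target_tf, linked = linked,
       sites = sites, cpg_sites = cpg_sites,
       mu_pos = mu_pos, mu_neg = mu_neg,
       base_dmr_mu = base_dmr_mu,
       celltype_dmrs = run_intervals(cpg_sites, ct_runs),
       time_dmrs = run_intervals(cpg_sites, tm_runs),
       time_shift_idx = time_shift_idx)
}

# TRUE for each point row (chrom, pos) falling in any (chrom, lo, hi)
# interval (closed)
overlaps_point <- function(points, intervals) {
  out <- rep(FALSE, nrow(points))
  if (is.null(intervals) || nrow(intervals) == 0L) return(out)
  for (ch in unique(intervals$chrom)) {
    iv <- intervals[chrom == ch]
    idx <- which(points$chrom == ch)
    if (!length(idx)) next
    o <- order(iv$lo)
    lo <- iv$lo[o]; hi <- cummax(iv$hi[o])
    k <- findInterval(points$pos[idx], lo)
    out[idx] <- k > 0 & points$pos[idx] <= hi[pmax(k, 1)]
  }
  out
}

# pick n non-overlapping runs of `k` consecutive eligible CpGs whose
# genomic span falls in span_range; deterministic given the RNG state
pick_cpg_runs <- function(cpg_sites, eligible, k, n, span_range) {
  if (n == 0L) {
    return(data.table(first_idx = integer(), last_idx = integer()))
  }
  pos <- cpg_sites$pos; ch <- cpg_sites$chrom
  n_cpg <- length(pos)
  starts <- seq_len(n_cpg - k + 1L)
  ok <- vapply(starts, function(i) {
    j <- i + k - 1L
    all(eligible[i:j]) && ch[i] == ch[j] &&
      (pos[j] - pos[i]) >= span_range[1] && (pos[j] - pos[i]) <= span_range[2]
  }, logical(1))
  cand <- starts[ok]
  cand <- cand[sample(length(cand))]
  chosen <- integer(0)
  used <- rep(FALSE, n_cpg)
  for (i in cand) {
    j <- i + k - 1L
    lo <- max(i - k, 1L); hi <- min(j + k, n_cpg)  # keep a CpG-run gap
    if (any(used[lo:hi])) next
    chosen <- c(chosen, i)
    used[i:j] <- TRUE
    if (length(chosen) == n) break
  }
  data.table(first_idx = chosen, last_idx = chosen + k - 1L)
}

run_intervals <- function(cpg_sites, runs) {
  if (nrow(runs) == 0L) {
    return(data.table(chrom = character(), start = integer(),
                      end = integer(), n_cpgs = integer()))
  }
  data.table(chrom = cpg_sites$chrom[runs$first_idx],
             start = cpg_sites$pos[runs$first_idx],
             end = cpg_sites$pos[runs$last_idx] + 2L,
             n_cpgs = runs$last_idx - runs$first_idx + 1L)
}
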
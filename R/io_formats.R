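#' Read a methylC-dialect per-cytosine methylation file
#'
#' The accepted dialect is fixed: tab-separated columns
#' `chrom, start (0-based), end (= start + 1), context, ratio, strand,
#' coverage`. Only `CG` context rows are retained. Methylated read counts
#' are reconstructed as `round(ratio * coverage)` and the two symmetric
#' strands of a CpG dyad (`+` at `pos`, `-` at `pos + 1`) are collapsed
#' into a single record anchored at the `+`-strand cytosine, summing both
#' counts. Strand-collapsing doubles effective coverage and matches
#' per-CpG (rather than per-cytosine) reporting.
#'
#' @param path path to a methylC text file.
#' @return a `data.table` with columns `chrom`, `pos` (0-based position of
#'   the + strand C of the dyad), `meth`, `total`, sorted by
#'   (`chrom`, `pos`).
#' @export
read_methylc <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.table(chrom = character(), pos = integer(),
                      meth = integer(), total = integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != 7L)
  if (length(bad)) {
    stop(sprintf("malformed methylC line %d in '%s': expected 7 tab-separated fields, got %d",
                 bad[1], path, nf[bad[1]]))
  }
  m <- matrix(unlist(fields), ncol = 7L, byrow = TRUE)
  dt <- data.table(chrom = m[, 1], start = as.integer(m[, 2]),
                   end = as.integer(m[, 3]), context = m[, 4],
                   ratio = as.numeric(m[, 5]), strand = m[, 6],
                   coverage = as.integer(m[, 7]))
  bad <- which(is.na(dt$start) | is.na(dt$ratio) | is.na(dt$coverage))
  if (length(bad)) stop(sprintf("malformed methylC line %d in '%s': non-numeric field", bad[1], path))
  bad <- which(dt$ratio < 0 | dt$ratio > 1)
  if (length(bad)) stop(sprintf("methylC line %d in '%s': ratio %g outside [0,1]", bad[1], path, dt$ratio[bad[1]]))
  dt <- dt[context == "CG"]
  # anchor the dyad at the + strand cytosine
  dt[, dyad := ifelse(strand == "-", start - 1L, start)]
  dt[, meth := as.integer(round(ratio * coverage))]
  out <- dt[, .(meth = sum(meth), total = sum(coverage)), by = .(chrom, dyad)]
  setnames(out, "dyad", "pos")
  setkey(out, chrom, pos)
  out[]
}

#' Write CpG records as a methylC-dialect file
#'
#' Each strand-collapsed dyad record is written as one `+`-strand `CG` line
#' with `ratio = meth / total` (full precision, so reading the file back
#' reproduces the counts exactly) and `coverage = total`.
#'
#' @param cpgs `data.table` with `chrom`, `pos`, `meth`, `total`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_methylc <- function(cpgs, path) {
  stopifnot(all(c("chrom", "pos", "meth", "total") %in% names(cpgs)))
  ratio <- ifelse(cpgs$total > 0, cpgs$meth / cpgs$total, 0)
  lines <- sprintf("%s\t%d\t%d\tCG\t%s\t+\t%d",
                   cpgs$chrom, cpgs$pos, cpgs$pos + 1L,
                   format(ratio, digits = 12, trim = TRUE, scientific = FALSE),
                   cpgs$total)
  writeLines(lines, path)
  invisible(path)
}

#' Read genomic intervals from BED, bedGraph or GTF
#'
#' BED input is taken as 0-based half-open and passed through; bedGraph
#' adds a `score` column from its fourth field. GTF (1-based, closed) is
#' converted on read to 0-based half-open; only `gene` feature rows are
#' kept and each yields its `gene_id` (and `gene_name` when present) plus
#' a strand-aware TSS: `start` for `+` genes, `end - 1` (0-based) for `-`
#' genes. Output is sorted by (`chrom`, `start`), stably.
#'
#' @param path input path.
#' @param format one of `"BED"`, `"bedGraph"`, `"GTF"`.
#' @return a `data.table` of intervals: `chrom`, `start`, `end`, plus
#'   `name`, `score`, `strand` when present (BED), `score` (bedGraph), or
#'   `gene_id`, `gene_name`, `strand`, `tss` (GTF).
#' @export
read_intervals <- function(path, format = c("BED", "bedGraph", "GTF")) {
  format <- match.arg(format)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (format == "GTF") lines <- lines[!startsWith(lines, "track")]
  if (length(lines) == 0L) {
    return(data.table(chrom = character(), start = integer(), end = integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (format == "GTF") {
    nf <- lengths(fields)
    bad <- which(nf < 9L)
    if (length(bad)) stop(sprintf("malformed GTF line %d in '%s'", bad[1], path))
    m <- vapply(fields, function(f) f[1:9], character(9))
    dt <- data.table(chrom = m[1, ], feature = m[3, ],
                     start = as.integer(m[4, ]) - 1L, end = as.integer(m[5, ]),
                     strand = m[7, ], attr = m[9, ])
    bad <- which(dt$end <= dt$start)
    if (length(bad)) stop(sprintf("GTF line %d in '%s': end <= start at %s:%d",
                                  bad[1], path, dt$chrom[bad[1]], dt$start[bad[1]]))
    dt <- dt[feature == "gene"]
    extract_attr <- function(attr, key) {
      pat <- paste0(key, "[ =]+\"?([^\";]+)\"?")
      m <- regmatches(attr, regexec(pat, attr))
      vapply(m, function(x) if (length(x) >= 2) x[2] else NA_character_, character(1))
    }
    dt[, gene_id := extract_attr(attr, "gene_id")]
    dt[, gene_name := extract_attr(attr, "gene_name")]
    dt[, tss := ifelse(strand == "-", end - 1L, start)]
    dt[, c("feature", "attr") := NULL]
    setorder(dt, chrom, start)
    return(dt[])
  }
  ncol_min <- if (format == "bedGraph") 4L else 3L
  nf <- lengths(fields)
  bad <- which(nf < ncol_min)
  if (length(bad)) stop(sprintf("malformed %s line %d in '%s'", format, bad[1], path))
  chrom <- vapply(fields, `[`, character(1), 1L)
  start <- as.integer(vapply(fields, `[`, character(1), 2L))
  end <- as.integer(vapply(fields, `[`, character(1), 3L))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) stop(sprintf("malformed %s line %d in '%s': non-numeric coordinate", format, bad[1], path))
  bad <- which(end <= start | start < 0L)
  if (length(bad)) stop(sprintf("%s line %d in '%s': invalid interval %s:%d-%d",
                                format, bad[1], path, chrom[bad[1]], start[bad[1]], end[bad[1]]))
  dt <- data.table(chrom = chrom, start = start, end = end)
  if (format == "bedGraph") {
    dt[, score := as.numeric(vapply(fields, `[`, character(1), 4L))]
  } else {
    if (all(nf >= 4L)) dt[, name := vapply(fields, `[`, character(1), 4L)]
    if (all(nf >= 5L)) dt[, score := as.numeric(vapply(fields, `[`, character(1), 5L))]
    if (all(nf >= 6L)) dt[, strand := vapply(fields, `[`, character(1), 6L)]
  }
  setorder(dt, chrom, start)
  dt[]
}

#' Write intervals as BED
#'
#' Writes `chrom`, `start`, `end` plus any of `name`, `score`, `strand`
#' and further numeric columns named in `extra` (as BED6+ columns).
#'
#' @param intervals interval `data.table`.
#' @param path output path.
#' @param extra character vector of additional columns to append.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path, extra = character()) {
  dt <- copy(as.data.table(intervals))
  opt <- c("name", "score", "strand")
  # BED columns are positional: pad any gap up to the last one needed
  last <- max(c(0L, which(opt %in% names(dt))), if (length(extra)) 3L else 0L)
  for (col in head(opt, last)) {
    if (!col %in% names(dt)) dt[[col]] <- if (col == "score") 0 else "."
  }
  cols <- c("chrom", "start", "end", head(opt, last), extra)
  fwrite(dt[, cols, with = FALSE], path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read position weight matrices from MEME-like text
#'
#' Parses `MOTIF <name>` blocks each followed by a
#' `letter-probability matrix:` header line and `w` rows of 4 probabilities
#' (A, C, G, T). A `Background letter frequencies` line, when present,
#' supplies the background; otherwise the background is uniform. Each row
#' has `pseudocount` added and is renormalized to sum to 1.
#'
#' @param path path to the motif file.
#' @param pseudocount value added to each probability before
#'   renormalization (default 0.01).
#' @return a list of PWM objects; each is a list with `name`,
#'   `matrix` (L x 4, columns A,C,G,T), `background` (length 4) and
#'   `pseudocount`.
#' @export
read_pwm <- function(path, pseudocount = 0.01) {
  lines <- trimws(readLines(path))
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  bg_idx <- grep("^Background letter frequencies", lines)
  if (length(bg_idx)) {
    toks <- strsplit(lines[bg_idx[1] + 1L], "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(toks))
    lett <- toks[is.na(vals)]
    vals <- vals[!is.na(vals)]
    if (length(vals) == 4L) bg[lett[seq_len(4)]] <- vals
  }
  motif_idx <- grep("^MOTIF\\b", lines)
  if (!length(motif_idx)) stop(sprintf("no MOTIF blocks found in '%s'", path))
  pwms <- vector("list", length(motif_idx))
  for (k in seq_along(motif_idx)) {
    i <- motif_idx[k]
    name <- strsplit(lines[i], "\\s+")[[1]][2]
    j <- i + 1L
    while (j <= length(lines) && !grepl("^letter-probability matrix", lines[j])) j <- j + 1L
    if (j > length(lines)) stop(sprintf("motif '%s' in '%s' has no letter-probability matrix", name, path))
    w <- suppressWarnings(as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[j])))
    rows <- list(); j <- j + 1L
    while (j <= length(lines) && nzchar(lines[j]) &&
           grepl("^[-0-9.eE+ \t]+$", lines[j])) {
      rows[[length(rows) + 1L]] <- as.numeric(strsplit(lines[j], "\\s+")[[1]])
      j <- j + 1L
    }
    mat <- do.call(rbind, rows)
    if (!is.na(w) && nrow(mat) > w) mat <- mat[seq_len(w), , drop = FALSE]
    if (is.null(mat) || ncol(mat) != 4L) stop(sprintf("motif '%s' in '%s': matrix rows must have 4 columns", name, path))
    if (nrow(mat) < 4L) stop(sprintf("motif '%s' in '%s': motif length %d < 4", name, path, nrow(mat)))
    if (any(rowSums(mat) <= 0)) stop(sprintf("motif '%s' in '%s': row sums to 0", name, path))
    mat <- mat + pseudocount
    mat <- mat / rowSums(mat)
    colnames(mat) <- c("A", "C", "G", "T")
    pwms[[k]] <- list(name = name, matrix = mat, background = bg,
                      pseudocount = pseudocount)
  }
  pwms
}

#' Write PWMs as MEME-like text
#'
#' @param pwms list of PWM objects as returned by [read_pwm()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pwm <- function(pwms, path) {
  out <- c("MEME version 4", "", "ALPHABET= ACGT", "",
           "Background letter frequencies",
           paste(sprintf("%s %.5f", c("A", "C", "G", "T"),
                         pwms[[1]]$background), collapse = " "), "")
  for (p in pwms) {
    out <- c(out,
             paste("MOTIF", p$name),
             sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                     nrow(p$matrix)),
             apply(p$matrix, 1, function(r) paste(sprintf("%.6f", r), collapse = " ")),
             "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#' @param path FASTA path.
#' @return named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(x)), names(x))
}

#' Write named sequences to FASTA
#' @param seqs named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a gene-by-sample count matrix from TSV
#'
#' First column holds gene ids, header row holds sample names.
#' @param path TSV path.
#' @return numeric matrix with gene rownames and sample colnames.
#' @export
read_counts <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE)
  mat <- as.matrix(dt[, -1, with = FALSE])
  rownames(mat) <- as.character(dt[[1]])
  storage.mode(mat) <- "double"
  mat
}

#' Write a count matrix to TSV
#' @param mat matrix with rownames (genes) and colnames (samples).
#' @param path output path.
#' @param id_col name of the id column (default "gene_id").
#' @return `path`, invisibly.
#' @export
write_counts <- function(mat, path, id_col = "gene_id") {
  dt <- data.table(id = rownames(mat))
  setnames(dt, "id", id_col)
  dt <- cbind(dt, as.data.table(mat))
  fwrite(dt, path, sep = "\t")
  invisible(path)
}
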
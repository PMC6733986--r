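#' Write a count matrix as a MatrixMarket triplet
#'
#' CellRanger-style triplet: `matrix.mtx`, `genes.tsv` (one id per line),
#' `barcodes.tsv`.
#'
#' @param counts genes x cells matrix.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_counts_mtx <- function(counts, dir) {
  .check_count_matrix(counts)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read a MatrixMarket triplet count matrix
#'
#' @param dir directory holding `matrix.mtx`, `genes.tsv`, `barcodes.tsv`.
#' @return genes x cells integer matrix.
#' @export
read_counts_mtx <- function(dir) {
  m <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
  storage.mode(m) <- "integer"
  dimnames(m) <- list(readLines(file.path(dir, "genes.tsv")),
                      readLines(file.path(dir, "barcodes.tsv")))
  m
}

#' Write / read a dense genes x cells TSV count matrix
#'
#' @param counts genes x cells matrix.
#' @param file path of the TSV (gene ids in the first column).
#' @return `file` invisibly / the matrix.
#' @export
write_counts_tsv <- function(counts, file) {
  utils::write.table(data.frame(gene = rownames(counts), counts,
                                check.names = FALSE),
                     file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(file) {
  df <- utils::read.delim(file, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write / read a bulk expression matrix with a sample-annotation sidecar
#'
#' @param bulk a `bulk_expression` object.
#' @param file expression TSV path; the sidecar (columns sample_id,
#'   cell_type) is written next to it with suffix `.samples.tsv`.
#' @return `file` invisibly / a `bulk_expression`.
#' @export
write_bulk_tsv <- function(bulk, file) {
  stopifnot(inherits(bulk, "bulk_expression"))
  utils::write.table(data.frame(feature = rownames(bulk$values),
                                gene = bulk$feature_to_gene[
                                  rownames(bulk$values)],
                                bulk$values, check.names = FALSE),
                     file, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample_id = names(bulk$sample_group),
                                cell_type = unname(bulk$sample_group)),
                     paste0(file, ".samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_bulk_tsv
#' @export
read_bulk_tsv <- function(file) {
  df <- utils::read.delim(file, check.names = FALSE)
  ann <- utils::read.delim(paste0(file, ".samples.tsv"))
  v <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(v) <- df$feature
  structure(list(values = v,
                 sample_group = stats::setNames(ann$cell_type,
                                                ann$sample_id),
                 feature_to_gene = stats::setNames(df$gene, df$feature)),
            class = "bulk_expression")
}

#' Write / read super-enhancer regions as BED6 plus FASTA
#'
#' One BED6 file per state (`se_BK.bed`, `se_DK.bed`; 0-based half-open,
#' name = region id, score 0, strand '.') and one FASTA keyed by region
#' id. Requires the Biostrings package for FASTA handling.
#'
#' @param se an `se_region_set`.
#' @param dir output directory.
#' @return `dir` invisibly / an `se_region_set`.
#' @export
write_se_regions <- function(se, dir) {
  stopifnot(inherits(se, "se_region_set"))
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("Biostrings is required for FASTA output", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  r <- se$regions
  for (st in unique(r$state)) {
    sub <- r[r$state == st, , drop = FALSE]
    utils::write.table(data.frame(sub$chrom, sub$start, sub$end, sub$id,
                                  0L, "."),
                       file.path(dir, paste0("se_", st, ".bed")),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(se$sequences),
    file.path(dir, "se_sequences.fasta"))
  invisible(dir)
}

#' @rdname write_se_regions
#' @export
read_se_regions <- function(dir) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("Biostrings is required for FASTA input", call. = FALSE)
  beds <- list.files(dir, pattern = "^se_.*\\.bed$", full.names = TRUE)
  regions <- do.call(rbind, lapply(beds, function(f) {
    st <- sub("^se_(.*)\\.bed$", "\\1", basename(f))
    b <- utils::read.delim(f, header = FALSE,
                           col.names = c("chrom", "start", "end", "id",
                                         "score", "strand"))
    data.frame(chrom = b$chrom, start = b$start, end = b$end, id = b$id,
               state = st, stringsAsFactors = FALSE)
  }))
  seqs <- Biostrings::readDNAStringSet(file.path(dir, "se_sequences.fasta"))
  structure(list(regions = regions,
                 sequences = stats::setNames(as.character(seqs),
                                             names(seqs))),
            class = "se_region_set")
}

#' Write / read motifs in JASPAR 2016 PFM text format
#'
#' `>id name` header followed by four `A|C|G|T [ counts ]` rows.
#'
#' @param motifs named list of [pwm()] objects.
#' @param file path.
#' @return `file` invisibly / a named list of [pwm()] objects.
#' @export
write_jaspar <- function(motifs, file) {
  lines <- unlist(lapply(motifs, function(m) {
    c(paste0(">", m$name, " ", m$name),
      vapply(c("A", "C", "G", "T"), function(b)
        paste0(b, "  [ ", paste(format(m$counts[b, ]), collapse = " "),
               " ]"), character(1)))
  }))
  writeLines(lines, file)
  invisible(file)
}

#' @rdname write_jaspar
#' @export
read_jaspar <- function(file) {
  lines <- readLines(file)
  heads <- grep("^>", lines)
  motifs <- lapply(heads, function(h) {
    nm <- strsplit(sub("^>\\s*", "", lines[h]), "\\s+")[[1]][1]
    vals <- lapply(lines[h + 1:4], function(r) {
      stripped <- sub("^\\s*[ACGT]", "", r)
      as.numeric(regmatches(stripped,
                            gregexpr("[0-9.]+", stripped))[[1]])
    })
    counts <- do.call(rbind, vals)
    rownames(counts) <- c("A", "C", "G", "T")
    pwm(nm, counts)
  })
  stats::setNames(motifs, vapply(motifs, `[[`, character(1), "name"))
}

#' Read motifs in MEME minimal format
#'
#' Parses `MOTIF` blocks with `letter-probability matrix` sections
#' (columns A, C, G, T).
#'
#' @param file path.
#' @return Named list of [pwm()] objects (probability matrices).
#' @export
read_meme <- function(file) {
  lines <- readLines(file)
  starts <- grep("^MOTIF", lines)
  motifs <- lapply(starts, function(s) {
    nm <- strsplit(lines[s], "\\s+")[[1]][2]
    lp <- grep("letter-probability matrix", lines)
    lp <- lp[lp > s][1]
    w <- as.integer(sub(".*w=\\s*([0-9]+).*", "\\1", lines[lp]))
    rows <- lines[lp + seq_len(w)]
    probs <- t(vapply(rows, function(r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]]), numeric(4)))
    counts <- t(probs)
    rownames(counts) <- c("A", "C", "G", "T")
    pwm(nm, counts)
  })
  stats::setNames(motifs, vapply(motifs, `[[`, character(1), "name"))
}

#' Read / write GMT gene-set files
#'
#' @param file path; GMT rows are `set_name<TAB>description<TAB>genes...`.
#' @param sets named list of character vectors.
#' @return Named list of gene sets / `file` invisibly.
#' @export
read_gmt <- function(file) {
  rows <- strsplit(readLines(file), "\t", fixed = TRUE)
  stats::setNames(lapply(rows, function(r) r[-(1:2)]),
                  vapply(rows, `[[`, character(1), 1L))
}

#' @rdname read_gmt
#' @export
write_gmt <- function(sets, file) {
  writeLines(vapply(names(sets), function(nm)
    paste(c(nm, nm, sets[[nm]]), collapse = "\t"), character(1)), file)
  invisible(file)
}

#' Write planted truth as JSON
#'
#' @param truth a `planted_truth`.
#' @param file path.
#' @return `file` invisibly.
#' @export
write_truth_json <- function(truth, file) {
  out <- truth
  out$log2_profile <- NULL
  class(out) <- NULL
  jsonlite::write_json(out, file, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(file)
}

#' Write all synthetic inputs of a simulation to a directory
#'
#' Counts as MatrixMarket triplet and dense TSV, the bulk matrix with its
#' sample sidecar, the super-enhancer BED/FASTA pair, motifs as JASPAR
#' PFM text, and the planted truth as JSON.
#'
#' @param sim a [simulate_all()] result.
#' @param dir output directory.
#' @return `dir` invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_counts_mtx(sim$counts, file.path(dir, "counts"))
  write_counts_tsv(sim$counts, file.path(dir, "counts.tsv"))
  write_bulk_tsv(sim$bulk, file.path(dir, "bulk.tsv"))
  write_se_regions(sim$se, file.path(dir, "se"))
  write_jaspar(sim$motifs, file.path(dir, "motifs.pfm"))
  write_truth_json(sim$truth, file.path(dir, "truth.json"))
  invisible(dir)
}
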
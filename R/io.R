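#' Read a back-splice junction (BSJ) table
#'
#' BSJ files use a BED-dialect TSV: columns `chrom`, `start`, `end`,
#' `strand`, then one supporting-read count column per sample. On-disk
#' coordinates are 0-based half-open and converted to the package's
#' internal 1-based inclusive convention on read.
#'
#' @param path Path to the TSV (with header).
#' @param n_samples Expected number of per-sample count columns.
#' @return A data.frame of class `bsj_table` with columns `circ_id`,
#'   `chrom`, `start`, `end`, `strand` and one integer count column per
#'   sample. `circ_id` is `chrom:start-end(strand)` in internal
#'   coordinates.
#' @export
read_bsj_table <- function(path, n_samples) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- read.delim(path, header = TRUE, sep = "\t",
                  stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(d) != 4L + n_samples)
    stop("BSJ table has ", ncol(d), " columns; expected ",
         4L + n_samples, " (chrom,start,end,strand + ", n_samples,
         " sample counts)")
  names(d)[1:4] <- c("chrom", "start", "end", "strand")
  if (nrow(d) == 0L) {
    d$circ_id <- character(0)
    return(structure(d[c("circ_id", names(d)[names(d) != "circ_id"])],
                     class = c("bsj_table", "data.frame")))
  }
  counts <- as.matrix(d[, -(1:4), drop = FALSE])
  storage.mode(counts) <- "integer"
  if (anyNA(counts)) stop("non-integer count in BSJ table")
  if (any(counts < 0L)) stop("negative supporting-read count in BSJ table")
  ## BED 0-based half-open -> 1-based inclusive
  d$start <- as.integer(d$start) + 1L
  d$end <- as.integer(d$end)
  if (any(d$start >= d$end))
    stop("BSJ with start >= end after coordinate conversion")
  if (!all(d$strand %in% c("+", "-")))
    stop("BSJ strand must be '+' or '-'")
  out <- data.frame(
    circ_id = sprintf("%s:%d-%d(%s)", d$chrom, d$start, d$end, d$strand),
    d[, 1:4], counts, stringsAsFactors = FALSE, check.names = FALSE)
  structure(out, class = c("bsj_table", "data.frame"))
}

#' Write a BSJ table (BED-dialect coordinates)
#'
#' Inverse of [read_bsj_table()]; internal 1-based inclusive coordinates
#' are written 0-based half-open.
#'
#' @param bsj A `bsj_table` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bsj_table <- function(bsj, path) {
  d <- as.data.frame(bsj)
  d$circ_id <- NULL
  d$start <- d$start - 1L
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract the per-sample count matrix from a BSJ table
#'
#' @param bsj A `bsj_table` data.frame.
#' @return Integer matrix, one row per junction (rownames = `circ_id`),
#'   one column per sample.
#' @export
bsj_counts <- function(bsj) {
  cn <- setdiff(names(bsj), c("circ_id", "chrom", "start", "end", "strand"))
  m <- as.matrix(as.data.frame(bsj)[, cn, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- bsj$circ_id
  m
}

#' Read a count matrix with library sizes
#'
#' TSV with a feature-id first column and one column per sample. Library
#' sizes (per-sample total reads, the normalization denominators) are
#' mandatory: either a row whose feature id is `library_size`, or a
#' two-column sidecar TSV (`sample`, `library_size`) given via
#' `lib_sizes_path`. Library sizes are sequencing-run totals and are never
#' recomputed from column sums.
#'
#' @param path Path to the count TSV.
#' @param lib_sizes_path Optional sidecar path.
#' @return List with `counts` (integer matrix, features x samples) and
#'   `lib_sizes` (named numeric vector aligned with the columns).
#' @export
read_count_matrix <- function(path, lib_sizes_path = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- read.delim(path, header = TRUE, sep = "\t",
                  stringsAsFactors = FALSE, check.names = FALSE)
  ids <- d[[1]]
  m <- as.matrix(d[, -1, drop = FALSE])
  lib_row <- which(ids == "library_size")
  if (length(lib_row) == 1L) {
    lib_sizes <- as.numeric(m[lib_row, ])
    m <- m[-lib_row, , drop = FALSE]
    ids <- ids[-lib_row]
  } else if (!is.null(lib_sizes_path)) {
    ls <- read.delim(lib_sizes_path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
    i <- match(colnames(m), ls[[1]])
    if (anyNA(i)) stop("sidecar library sizes missing sample: ",
                       colnames(m)[which(is.na(i))[1]])
    lib_sizes <- as.numeric(ls[[2]][i])
  } else {
    stop("count matrix lacks library sizes (no 'library_size' row and no ",
         "sidecar); normalization is undefined without them")
  }
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicated feature id: ", dup[1])
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  names(lib_sizes) <- colnames(m)
  list(counts = m, lib_sizes = lib_sizes)
}

#' Write a count matrix with an embedded library-size row
#'
#' @param counts Integer matrix, features x samples.
#' @param lib_sizes Numeric vector, one per sample.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(counts, lib_sizes, path) {
  stopifnot(length(lib_sizes) == ncol(counts))
  d <- data.frame(feature_id = c("library_size", rownames(counts)),
                  rbind(as.numeric(lib_sizes), counts),
                  stringsAsFactors = FALSE, check.names = FALSE)
  colnames(d) <- c("feature_id", colnames(counts))
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a known-circRNA coordinate list
#'
#' A catalogue-style TSV with columns `chrom`, `start`, `end`, `strand`
#' in 1-based inclusive coordinates, used to separate novel circRNAs from
#' previously reported ones.
#'
#' @param path Path to the TSV (with header).
#' @return data.frame with the four columns.
#' @export
read_known_circs <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- read.delim(path, header = TRUE, sep = "\t",
                  stringsAsFactors = FALSE)
  names(d)[1:4] <- c("chrom", "start", "end", "strand")
  d$start <- as.integer(d$start)
  d$end <- as.integer(d$end)
  d
}

#' @rdname read_known_circs
#' @param known data.frame with columns `chrom`, `start`, `end`, `strand`.
#' @export
write_known_circs <- function(known, path) {
  write.table(known[, c("chrom", "start", "end", "strand")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a sponge network
#'
#' Writes circRNA-miRNA-mRNA triplets either as a Cytoscape-loadable SIF
#' edge list (two `targets` edges per triplet, miRNA->circRNA and
#' miRNA->mRNA, deduplicated) or as a TSV with one row per triplet
#' including scores and correlations.
#'
#' @param triplets A triplet data.frame from [assemble_triplets()].
#' @param path Output path.
#' @param format `"sif"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(triplets, path, format = c("tsv", "sif")) {
  format <- match.arg(format)
  if (format == "sif") {
    if (nrow(triplets) == 0L) {
      writeLines(character(0), path)
      return(invisible(path))
    }
    edges <- unique(rbind(
      data.frame(source = triplets$mirna_id, rel = "targets",
                 target = triplets$circ_id, stringsAsFactors = FALSE),
      data.frame(source = triplets$mirna_id, rel = "targets",
                 target = triplets$mrna_id, stringsAsFactors = FALSE)))
    writeLines(sprintf("%s\t%s\t%s", edges$source, edges$rel,
                       edges$target), path)
  } else {
    write.table(as.data.frame(triplets), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}

#' Re-import a triplet TSV written by [write_network()]
#'
#' @param path Path to a TSV network export.
#' @return Triplet data.frame.
#' @export
read_network_tsv <- function(path) {
  d <- read.delim(path, header = TRUE, sep = "\t",
                  stringsAsFactors = FALSE)
  structure(d, class = c("triplet_set", "data.frame"))
}
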
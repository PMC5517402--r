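#' Genome annotation container
#'
#' Holds the chromosome table, gene table and (per-gene, non-overlapping)
#' exon table used for back-splice junction classification and sequence
#' extraction. Coordinates are 1-based inclusive.
#'
#' @param chromosomes data.frame with columns `id`, `length` and optionally
#'   `organelle` (one of `"nuclear"`, `"chloroplast"`, `"mitochondria"`).
#' @param genes data.frame with columns `gene_id`, `chrom`, `strand`
#'   (`"+"`/`"-"`), `start`, `end`.
#' @param exons data.frame with columns `gene_id`, `start`, `end`. Exons of
#'   one gene must be non-overlapping; they are sorted by coordinate and
#'   given ordinals 1..k internally. Chromosome and strand are inherited
#'   from the gene.
#' @param organelle_map named character vector mapping chromosome ids to
#'   organelle tags; chromosomes not named are `"nuclear"`. Ignored when
#'   `chromosomes` already carries an `organelle` column.
#'
#' @return An object of class `genome_annotation`: a list with elements
#'   `chromosomes`, `genes`, `exons` (the exon table gains `chrom`,
#'   `strand` and `ordinal` columns).
#' @export
genome_annotation <- function(chromosomes, genes, exons,
                              organelle_map = default_organelle_map()) {
  stopifnot(is.data.frame(chromosomes), is.data.frame(genes),
            is.data.frame(exons))
  chromosomes <- as.data.frame(chromosomes, stringsAsFactors = FALSE)
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  exons <- as.data.frame(exons, stringsAsFactors = FALSE)

  if (!"organelle" %in% names(chromosomes)) {
    chromosomes$organelle <- ifelse(
      chromosomes$id %in% names(organelle_map),
      unname(organelle_map[match(chromosomes$id, names(organelle_map))]),
      "nuclear")
    chromosomes$organelle[is.na(chromosomes$organelle)] <- "nuclear"
  }
  if (anyDuplicated(chromosomes$id))
    stop("duplicated chromosome id in annotation")
  if (anyDuplicated(genes$gene_id))
    stop("duplicated gene id in annotation")

  ## attach gene context to exons, sort, assign ordinals
  gi <- match(exons$gene_id, genes$gene_id)
  if (anyNA(gi))
    stop("exon refers to unknown gene: ",
         exons$gene_id[which(is.na(gi))[1]])
  exons$chrom <- genes$chrom[gi]
  exons$strand <- genes$strand[gi]
  ord <- order(exons$gene_id, exons$start)
  exons <- exons[ord, , drop = FALSE]
  exons$ordinal <- stats::ave(exons$start, exons$gene_id,
                              FUN = seq_along)
  rownames(exons) <- NULL

  ann <- structure(
    list(chromosomes = chromosomes, genes = genes, exons = exons),
    class = "genome_annotation")
  validate_annotation(ann)
  ann
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation:",
      nrow(x$chromosomes), "chromosome(s),",
      nrow(x$genes), "gene(s),",
      nrow(x$exons), "exon(s)\n")
  org <- table(x$chromosomes$organelle)
  cat("  chromosomes:",
      paste(sprintf("%s (%s, %d bp)", x$chromosomes$id,
                    x$chromosomes$organelle, x$chromosomes$length),
            collapse = ", "), "\n")
  invisible(x)
}

#' Default chromosome-id to organelle map
#'
#' TAIR-style naming: `ChrC` is the chloroplast and `ChrM` the
#' mitochondrial genome. Override when the assembly uses other ids.
#' @return Named character vector.
#' @export
default_organelle_map <- function() {
  c(ChrC = "chloroplast", ChrM = "mitochondria")
}

validate_annotation <- function(ann) {
  chrs <- ann$chromosomes
  genes <- ann$genes
  exons <- ann$exons
  ci <- match(genes$chrom, chrs$id)
  if (anyNA(ci))
    stop("gene on unknown chromosome: ", genes$chrom[which(is.na(ci))[1]])
  bad <- genes$start < 1 | genes$end > chrs$length[ci] |
    genes$start > genes$end
  if (any(bad))
    stop("gene outside chromosome bounds: ", genes$gene_id[which(bad)[1]])
  gi <- match(exons$gene_id, genes$gene_id)
  bad <- exons$start < genes$start[gi] | exons$end > genes$end[gi] |
    exons$start > exons$end
  if (any(bad))
    stop("exon outside gene span for gene ",
         exons$gene_id[which(bad)[1]])
  ## non-overlap within each gene (exons already sorted by start)
  by_gene <- split(seq_len(nrow(exons)), exons$gene_id)
  for (idx in by_gene) {
    if (length(idx) > 1L) {
      s <- exons$start[idx]; e <- exons$end[idx]
      if (any(s[-1L] <= e[-length(e)]))
        stop("overlapping exons in gene ", exons$gene_id[idx[1]])
    }
  }
  invisible(ann)
}

#' Read a GFF3 genome annotation
#'
#' Parses a GFF3 file (via [rtracklayer::import()]) into a
#' [genome_annotation()] object. `##` pragma lines are honored:
#' `##sequence-region` records define chromosome lengths; when absent, a
#' chromosome's length falls back to the largest feature end on it. Exons
#' may name a gene directly as `Parent` or an mRNA whose own `Parent` is a
#' gene; exons of multiple isoforms are collapsed to their per-gene union
#' so the stored exon set is non-overlapping.
#'
#' @param path Path to a GFF3 file (1-based inclusive coordinates).
#' @param organelle_map Named character vector mapping chromosome ids to
#'   organelle tags (default [default_organelle_map()]).
#' @return A [genome_annotation()] object.
#' @export
read_gff3 <- function(path, organelle_map = default_organelle_map()) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)

  ## light pre-scan so malformed lines are reported with their number
  seqregions <- list()
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (ln == "" || startsWith(ln, "#")) {
      if (startsWith(ln, "##sequence-region")) {
        f <- strsplit(trimws(ln), "[ \t]+")[[1]]
        if (length(f) >= 4L)
          seqregions[[f[2]]] <- as.integer(f[4])
      }
      next
    }
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) != 9L)
      stop("malformed GFF3 line ", i, ": expected 9 tab-separated fields")
    if (is.na(suppressWarnings(as.integer(f[4]))) ||
        is.na(suppressWarnings(as.integer(f[5]))))
      stop("malformed GFF3 line ", i, ": non-numeric coordinates")
  }

  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  ids <- if (!is.null(gr$ID)) as.character(gr$ID) else rep(NA_character_,
                                                           length(gr))
  parents <- if (!is.null(gr$Parent)) gr$Parent else
    S4Vectors::SplitDataFrameList()

  is_gene <- type == "gene"
  genes <- data.frame(
    gene_id = ids[is_gene],
    chrom = as.character(GenomicRanges::seqnames(gr))[is_gene],
    strand = as.character(GenomicRanges::strand(gr))[is_gene],
    start = GenomicRanges::start(gr)[is_gene],
    end = GenomicRanges::end(gr)[is_gene],
    stringsAsFactors = FALSE)
  if (nrow(genes) == 0L) stop("GFF3 contains no gene features")
  if (anyNA(genes$gene_id)) stop("gene feature without ID attribute")

  ## map any feature id to its feature row, for parent resolution
  id_type <- setNames(type, ids)
  id_parent <- setNames(rep(NA_character_, length(gr)), ids)
  plen <- lengths(parents)
  has_par <- which(plen > 0L)
  first_par <- vapply(as.list(parents[has_par]), `[`, character(1), 1L)
  id_parent[ids[has_par]] <- first_par

  resolve_gene <- function(pid) {
    seen <- character(0)
    while (!is.na(pid) && !pid %in% seen) {
      if (!is.na(id_type[pid]) && identical(unname(id_type[pid]), "gene"))
        return(pid)
      seen <- c(seen, pid)
      pid <- if (pid %in% names(id_parent)) id_parent[[pid]] else
        NA_character_
    }
    NA_character_
  }

  is_exon <- which(type == "exon")
  if (length(is_exon) == 0L) stop("GFF3 contains no exon features")
  exon_par <- character(length(is_exon))
  for (k in seq_along(is_exon)) {
    i <- is_exon[k]
    if (plen[i] == 0L)
      stop("exon without a Parent attribute at ",
           as.character(GenomicRanges::seqnames(gr))[i], ":",
           GenomicRanges::start(gr)[i])
    g <- resolve_gene(parents[[i]][1L])
    if (is.na(g))
      stop("exon whose Parent does not resolve to a gene: ",
           parents[[i]][1L])
    exon_par[k] <- g
  }

  exons_raw <- data.frame(
    gene_id = exon_par,
    start = GenomicRanges::start(gr)[is_exon],
    end = GenomicRanges::end(gr)[is_exon],
    stringsAsFactors = FALSE)
  ## collapse isoforms: per-gene exon union
  exons <- do.call(rbind, lapply(split(exons_raw, exons_raw$gene_id),
                                 function(d) {
    r <- IRanges::reduce(IRanges::IRanges(d$start, d$end))
    data.frame(gene_id = d$gene_id[1],
               start = IRanges::start(r), end = IRanges::end(r),
               stringsAsFactors = FALSE)
  }))
  rownames(exons) <- NULL

  chrom_ids <- unique(c(names(seqregions),
                        as.character(GenomicRanges::seqnames(gr))))
  chrom_len <- vapply(chrom_ids, function(id) {
    if (!is.null(seqregions[[id]])) return(as.integer(seqregions[[id]]))
    sel <- as.character(GenomicRanges::seqnames(gr)) == id
    as.integer(max(GenomicRanges::end(gr)[sel]))
  }, integer(1))
  chromosomes <- data.frame(id = chrom_ids, length = unname(chrom_len),
                            stringsAsFactors = FALSE)

  genome_annotation(chromosomes, genes, exons,
                    organelle_map = organelle_map)
}

#' Write a genome_annotation as GFF3
#'
#' Emits `##sequence-region` pragmas plus one `gene` line and its `exon`
#' children per gene. Used by the synthetic-data generator; the output
#' round-trips through [read_gff3()].
#'
#' @param ann A [genome_annotation()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(ann, path) {
  stopifnot(inherits(ann, "genome_annotation"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(sprintf("##sequence-region %s 1 %d",
                     ann$chromosomes$id, ann$chromosomes$length), con)
  g <- ann$genes
  e <- ann$exons
  out <- character(0)
  for (i in seq_len(nrow(g))) {
    out <- c(out, sprintf("%s\tcircleaf\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                          g$chrom[i], g$start[i], g$end[i], g$strand[i],
                          g$gene_id[i]))
    ei <- e[e$gene_id == g$gene_id[i], , drop = FALSE]
    out <- c(out, sprintf(
      "%s\tcircleaf\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
      ei$chrom, ei$start, ei$end, ei$strand, ei$gene_id, ei$ordinal,
      ei$gene_id))
  }
  writeLines(out, con)
  invisible(path)
}
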
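CIRC_CATEGORIES <- c("EXONIC_BOTH_BOUNDARY", "EXONIC_BOTH_INTERNAL",
                     "EXONIC_ONE_BOUNDARY", "INTRONIC", "INTERGENIC",
                     "AMBIGUOUS")

## round-half-up to `digits` decimals (printed-table convention; R's
## round() goes half-to-even)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

## percentages to one decimal by largest-remainder allocation, so a
## printed column sums to exactly 100.0 (the convention behind summary
## tables whose rows partition the total)
largest_remainder_pct <- function(counts, total) {
  if (total == 0) return(setNames(rep(NA_real_, length(counts)),
                                  names(counts)))
  raw <- 1000 * counts / total          # tenths of a percent
  base <- floor(raw)
  short <- 1000L - sum(base)
  if (short > 0) {
    ## break remainder ties toward the larger count, then table order
    ord <- order(raw - base, counts, -seq_along(counts),
                 decreasing = TRUE)
    base[ord[seq_len(short)]] <- base[ord[seq_len(short)]] + 1
  }
  setNames(base / 10, names(counts))
}

#' Classify one back-splice junction against the annotation
#'
#' A back-splice junction (BSJ) has two genomic breakpoints, `start`
#' (upstream, A) and `end` (downstream, B), both 1-based inclusive. A
#' breakpoint *hits* an exon when it lies inside the exon interval; it is
#' *boundary-matched* when it is within `boundary_tolerance` nucleotides
#' of the appropriate exon edge — the acceptor edge for the
#' transcript-upstream breakpoint and the donor edge for the
#' transcript-downstream one, which on either strand amounts to comparing
#' A with the start edge and B with the end edge of the exon it hits
#' (the donor/acceptor labels mirror on the minus strand).
#'
#' Categories: if both breakpoints hit exons of one strand-matched gene,
#' the junction is exonic — `EXONIC_BOTH_BOUNDARY` (both matched),
#' `EXONIC_BOTH_INTERNAL` (neither), `EXONIC_ONE_BOUNDARY` (exactly one).
#' Both breakpoints inside one strand-matched gene but in introns gives
#' `INTRONIC`; neither breakpoint inside any gene gives `INTERGENIC`;
#' every other configuration (different genes, one genic one intergenic,
#' strand mismatch, exon/intron mix, host-gene tie) is `AMBIGUOUS`.
#' When several strand-matched genes could host the junction, the gene
#' whose span overlaps `[start, end]` the most wins; an exact tie is
#' `AMBIGUOUS`.
#'
#' @param junction List or one-row data.frame with `chrom`, `start`,
#'   `end`, `strand`.
#' @param ann A [genome_annotation()] object.
#' @param boundary_tolerance Max distance (nt) from an exon edge still
#'   counted as boundary-matched (default 0, i.e. exact).
#' @return List with `chrom`, `start`, `end`, `strand`, `category`,
#'   `host_gene` (NA unless exonic), `exon_span` (host-gene exons
#'   overlapping the junction interval), `organelle`.
#' @export
classify_bsj <- function(junction, ann, boundary_tolerance = 0L) {
  chrom <- as.character(junction$chrom)
  A <- as.integer(junction$start)
  B <- as.integer(junction$end)
  strand <- as.character(junction$strand)
  ci <- match(chrom, ann$chromosomes$id)
  if (is.na(ci)) stop("unknown chromosome: ", chrom)
  stopifnot(A < B)
  organelle <- ann$chromosomes$organelle[ci]

  res <- function(category, host = NA_character_, span = 0L) {
    list(chrom = chrom, start = A, end = B, strand = strand,
         category = category, host_gene = host, exon_span = span,
         organelle = organelle)
  }

  g <- ann$genes
  e <- ann$exons
  on_chrom_gene <- g$chrom == chrom
  ## intergenic test ignores strand: inside any gene span at all?
  a_in_any <- on_chrom_gene & g$start <= A & A <= g$end
  b_in_any <- on_chrom_gene & g$start <= B & B <= g$end
  if (!any(a_in_any) && !any(b_in_any)) return(res("INTERGENIC"))

  sm <- which(on_chrom_gene & g$strand == strand)
  if (length(sm)) {
    ex <- e[e$gene_id %in% g$gene_id[sm], , drop = FALSE]
    a_hit <- ex$start <= A & A <= ex$end
    b_hit <- ex$start <= B & B <= ex$end
    cand <- intersect(unique(ex$gene_id[a_hit]), unique(ex$gene_id[b_hit]))
    if (length(cand)) {
      host <- cand
      if (length(cand) > 1L) {
        gi <- match(cand, g$gene_id)
        ov <- pmin(g$end[gi], B) - pmax(g$start[gi], A) + 1L
        best <- ov == max(ov)
        if (sum(best) > 1L) return(res("AMBIGUOUS"))
        host <- cand[best]
      }
      hx <- ex[ex$gene_id == host, , drop = FALSE]
      exa <- hx[hx$start <= A & A <= hx$end, , drop = FALSE]
      exb <- hx[hx$start <= B & B <= hx$end, , drop = FALSE]
      a_matched <- abs(A - exa$start[1]) <= boundary_tolerance
      b_matched <- abs(B - exb$end[1]) <= boundary_tolerance
      category <- if (a_matched && b_matched) "EXONIC_BOTH_BOUNDARY"
        else if (!a_matched && !b_matched) "EXONIC_BOTH_INTERNAL"
        else "EXONIC_ONE_BOUNDARY"
      span <- sum(hx$start <= B & hx$end >= A)
      return(res(category, host, as.integer(span)))
    }
    ## both breakpoints inside one strand-matched gene, neither in an exon
    span_genes <- sm[g$start[sm] <= A & B <= g$end[sm]]
    for (i in span_genes) {
      gx <- e[e$gene_id == g$gene_id[i], , drop = FALSE]
      a_ex <- any(gx$start <= A & A <= gx$end)
      b_ex <- any(gx$start <= B & B <= gx$end)
      if (!a_ex && !b_ex) return(res("INTRONIC"))
    }
  }
  res("AMBIGUOUS")
}

#' Classify every junction of a BSJ table
#'
#' Vector wrapper around [classify_bsj()].
#'
#' @param bsj A `bsj_table` data.frame (see [read_bsj_table()]) or any
#'   data.frame with `chrom`, `start`, `end`, `strand`.
#' @inheritParams classify_bsj
#' @return A `circ_records` data.frame: `circ_id`, coordinates, strand,
#'   `category`, `host_gene`, `exon_span`, `organelle`, `is_novel`
#'   (NA until [flag_novel()] is applied).
#' @export
classify_junctions <- function(bsj, ann, boundary_tolerance = 0L) {
  rows <- lapply(seq_len(nrow(bsj)), function(i)
    classify_bsj(bsj[i, ], ann, boundary_tolerance))
  out <- data.frame(
    circ_id = if ("circ_id" %in% names(bsj)) bsj$circ_id else
      sprintf("%s:%d-%d(%s)", bsj$chrom, bsj$start, bsj$end, bsj$strand),
    chrom = vapply(rows, `[[`, character(1), "chrom"),
    start = vapply(rows, `[[`, integer(1), "start"),
    end = vapply(rows, `[[`, integer(1), "end"),
    strand = vapply(rows, `[[`, character(1), "strand"),
    category = vapply(rows, `[[`, character(1), "category"),
    host_gene = vapply(rows, `[[`, character(1), "host_gene"),
    exon_span = vapply(rows, `[[`, integer(1), "exon_span"),
    organelle = vapply(rows, `[[`, character(1), "organelle"),
    is_novel = NA, stringsAsFactors = FALSE)
  structure(out, class = c("circ_records", "data.frame"))
}

#' Summarize circRNA classes (printed-table style)
#'
#' Aggregates classified circRNA records into per-category counts and
#' percentages (one decimal, round-half-up), the exonic subtotal and
#' within-exonic shares, an exon-span histogram, organelle counts and
#' novelty counts.
#'
#' @param records A `circ_records` data.frame from [classify_junctions()].
#' @return Object of class `class_summary`.
#' @export
summarize_classes <- function(records) {
  n <- nrow(records)
  cat_counts <- setNames(integer(length(CIRC_CATEGORIES)), CIRC_CATEGORIES)
  if (n > 0) {
    tb <- table(factor(records$category, levels = CIRC_CATEGORIES))
    cat_counts[] <- as.integer(tb)
  }
  exonic_cats <- c("EXONIC_BOTH_BOUNDARY", "EXONIC_BOTH_INTERNAL",
                   "EXONIC_ONE_BOUNDARY")
  exonic_total <- sum(cat_counts[exonic_cats])
  pct <- largest_remainder_pct(cat_counts, n)
  out <- list(
    total = n,
    counts = cat_counts,
    percentages = pct,
    exonic_total = exonic_total,
    ## the exonic subtotal percentage is the sum of its printed rows
    exonic_percentage = if (n > 0) sum(pct[exonic_cats]) else NA_real_,
    percent_of_exonic = largest_remainder_pct(cat_counts[exonic_cats],
                                              exonic_total),
    exon_span_histogram = if (n > 0)
      table(records$exon_span[records$category %in% exonic_cats]) else
      table(integer(0)),
    organelle_counts = if (n > 0) table(records$organelle) else
      table(character(0)),
    novelty_counts = c(novel = sum(records$is_novel %in% TRUE),
                       known = sum(records$is_novel %in% FALSE),
                       unknown = sum(is.na(records$is_novel))))
  structure(out, class = "class_summary")
}

#' @export
print.class_summary <- function(x, ...) {
  cat("circRNA classification summary —", x$total, "junction(s)\n")
  if (x$total == 0) return(invisible(x))
  for (cc in names(x$counts))
    cat(sprintf("  %-22s %4d  (%.1f%%)\n", cc, x$counts[[cc]],
                x$percentages[[cc]]))
  cat(sprintf("  exonic subtotal        %4d  (%.1f%%)\n",
              x$exonic_total, x$exonic_percentage))
  if (x$novelty_counts[["unknown"]] < x$total)
    cat("  novel:", x$novelty_counts[["novel"]], " known:",
        x$novelty_counts[["known"]], "\n")
  invisible(x)
}

#' Flag novel circRNAs against a known-coordinate catalogue
#'
#' A record is known when some catalogue entry matches its chromosome and
#' strand with both breakpoints within `slack` nucleotides; otherwise it
#' is novel.
#'
#' @param records A `circ_records` data.frame.
#' @param known data.frame with `chrom`, `start`, `end`, `strand`
#'   (1-based inclusive; see [read_known_circs()]).
#' @param slack Maximum per-breakpoint coordinate difference (default 0).
#' @return `records` with `is_novel` filled in.
#' @export
flag_novel <- function(records, known, slack = 0L) {
  if (nrow(records) == 0L) return(records)
  if (is.null(known) || nrow(known) == 0L) {
    records$is_novel <- TRUE
    return(records)
  }
  records$is_novel <- vapply(seq_len(nrow(records)), function(i) {
    !any(known$chrom == records$chrom[i] &
           known$strand == records$strand[i] &
           abs(known$start - records$start[i]) <= slack &
           abs(known$end - records$end[i]) <= slack)
  }, logical(1))
  records
}

#' Extract the circular sequence of a circRNA
#'
#' For an exonic record, host-gene exon sub-sequences overlapping the
#' junction interval are clipped to it and spliced together; intronic and
#' intergenic records use the plain genomic interval. Minus-strand
#' records are reverse-complemented. The junction-spanning window — the
#' last `k - 1` bases followed by the first `k - 1` bases of the circular
#' sequence — is returned alongside, so target sites crossing the
#' back-splice junction can be scanned.
#'
#' @param record One classified record (list or one-row data.frame with
#'   `chrom`, `start`, `end`, `strand`, `category`, `host_gene`).
#' @param genome A [Biostrings::DNAStringSet] keyed by chromosome id.
#' @param ann A [genome_annotation()] object.
#' @param junction_window_k Window parameter `k` (typically the miRNA
#'   length); the junction window has `2*(k - 1)` bases.
#' @return List with `sequence` and `junction_window` (character).
#' @export
extract_circ_sequence <- function(record, genome, ann,
                                  junction_window_k = 22L) {
  chrom <- as.character(record$chrom)
  if (!chrom %in% names(genome))
    stop("no genome sequence for chromosome ", chrom)
  chrseq <- genome[[chrom]]
  s <- as.integer(record$start); e <- as.integer(record$end)
  if (e > length(chrseq))
    stop("record span exceeds chromosome length for ", chrom)
  exonic <- !is.na(record$category) &&
    record$category %in% c("EXONIC_BOTH_BOUNDARY", "EXONIC_BOTH_INTERNAL",
                           "EXONIC_ONE_BOUNDARY")
  if (exonic) {
    hx <- ann$exons[ann$exons$gene_id == record$host_gene, , drop = FALSE]
    hx <- hx[hx$start <= e & hx$end >= s, , drop = FALSE]
    hx <- hx[order(hx$start), , drop = FALSE]
    pieces <- Biostrings::DNAStringSet(lapply(seq_len(nrow(hx)), function(i)
      Biostrings::subseq(chrseq, max(hx$start[i], s), min(hx$end[i], e))))
    seq <- Biostrings::DNAString(paste(as.character(pieces), collapse = ""))
  } else {
    seq <- Biostrings::subseq(chrseq, s, e)
  }
  if (record$strand == "-")
    seq <- Biostrings::reverseComplement(seq)
  seq <- as.character(seq)
  L <- nchar(seq)
  k <- as.integer(junction_window_k)
  w <- min(k - 1L, L)
  window <- paste0(substr(seq, L - w + 1L, L), substr(seq, 1L, w))
  list(sequence = seq, junction_window = window)
}
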
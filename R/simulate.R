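## run code under a temporary RNG seed, restoring caller state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

## regular gene models: n_exons exons of exon_len separated by intron_len
make_genes <- function(gene_ids, chroms, starts, strands, n_exons,
                       exon_len, intron_len) {
  step <- exon_len + intron_len
  genes <- data.frame(
    gene_id = gene_ids, chrom = chroms, strand = strands,
    start = starts,
    end = starts + n_exons * exon_len + (n_exons - 1L) * intron_len - 1L,
    stringsAsFactors = FALSE)
  exons <- do.call(rbind, lapply(seq_along(gene_ids), function(i) {
    s <- starts[i] + (seq_len(n_exons[i]) - 1L) * step[i]
    data.frame(gene_id = gene_ids[i], start = s,
               end = s + exon_len[i] - 1L, stringsAsFactors = FALSE)
  }))
  list(genes = genes, exons = exons)
}

## breakpoints of one circRNA given its host-gene geometry and category;
## the circRNA starts at host exon `first_exon` and spans `span` exons
circ_coords <- function(category, gene_start, span, exon_len,
                        intron_len, first_exon = 1L) {
  e1s <- gene_start + (first_exon - 1L) * (exon_len + intron_len)
  e_last_end <- e1s + (span - 1L) * (exon_len + intron_len) +
    exon_len - 1L
  switch(category,
         EXONIC_BOTH_BOUNDARY = c(e1s, e_last_end),
         EXONIC_BOTH_INTERNAL = c(e1s + 10L, e_last_end - 10L),
         EXONIC_ONE_BOUNDARY = c(e1s, e_last_end - 10L),
         stop("not an exonic category: ", category))
}

#' Simulate one negative-binomial time course
#'
#' Draws counts for one feature over the time-point grid from a
#' negative-binomial distribution around a logistic (or flat) mean
#' trajectory. For `"logistic_up"` the mean rises from `baseline` to a
#' plateau chosen so the expected pseudocounted expression ratio is
#' exactly `fold` (`mu_hi + 1 = fold * (baseline + 1)`); for
#' `"logistic_down"` it falls from `baseline` to the level a `fold`-fold
#' drop implies on the same scale.
#'
#' @param shape `"flat"`, `"logistic_up"` or `"logistic_down"`.
#' @param days Time-point grid (day labels).
#' @param baseline Mean at the flat end of the trajectory (the low end
#'   for `up`, the high end for `down`).
#' @param fold Planted fold change on the pseudocounted scale.
#' @param midpoint,scale Logistic midpoint (day) and width (days).
#' @param anchor_day When set, the logistic is renormalized between
#'   `anchor_day` and the last day so the mean equals `baseline` at the
#'   anchor and the full planted level at the course end — the planted
#'   contrast against a reference at `anchor_day` is then exactly `fold`
#'   regardless of where the raw logistic puts those days. Days before
#'   the anchor stay at `baseline`.
#' @param dispersion Negative-binomial dispersion (`size = 1/dispersion`;
#'   0 gives Poisson draws).
#' @return Integer count vector with the mean trajectory attached as
#'   attribute `mu`.
#' @export
sim_time_course <- function(shape = c("flat", "logistic_up",
                                      "logistic_down"),
                            days = seq(4, 30, by = 2), baseline = 1,
                            fold = 4, midpoint = 20, scale = 1,
                            anchor_day = NULL, dispersion = 0.05) {
  shape <- match.arg(shape)
  s <- stats::plogis((days - midpoint) / scale)
  if (!is.null(anchor_day)) {
    s0 <- stats::plogis((anchor_day - midpoint) / scale)
    s1 <- stats::plogis((max(days) - midpoint) / scale)
    s <- pmax(0, (s - s0) / (s1 - s0))
  }
  mu <- switch(shape,
    flat = rep(baseline, length(days)),
    logistic_up = {
      hi <- fold * (baseline + 1) - 1
      baseline + (hi - baseline) * s
    },
    logistic_down = {
      lo <- max((baseline + 1) / fold - 1, 0)
      baseline - (baseline - lo) * s
    })
  counts <- if (dispersion > 0)
    rnbinom(length(mu), mu = mu, size = 1 / dispersion)
  else stats::rpois(length(mu), mu)
  structure(as.integer(counts), mu = mu)
}

#' Parameters for the synthetic dataset generator
#'
#' Defaults describe a desk-scale stand-in for a leaf lifespan total
#' RNA-seq course: 14 samples at 2-day intervals, two nuclear
#' chromosomes plus a chloroplast and a mitochondrial genome, mostly
#' exonic circRNAs in the observed category mixture, senescence-stage
#' differential expression that is predominantly upward, and miRNAs
#' anti-correlated with their planted targets. Planted up-regulated
#' circRNAs rise from a near-zero baseline — circRNA supporting reads
#' are sparse, most circRNAs being seen in very few samples — while
#' down-regulated ones fall from a moderately expressed baseline.
#'
#' @param seed RNG seed; identical parameters and seed give
#'   byte-identical outputs.
#' @param n_genes Nuclear protein-coding genes (split over the nuclear
#'   chromosomes).
#' @param n_circ Number of circRNAs.
#' @param category_mix Named proportions over the four circRNA
#'   categories; must sum to 1.
#' @param frac_de Fraction of circRNAs planted differentially expressed
#'   (in the senescence stage by default).
#' @param frac_up Fraction of planted DE circRNAs that are up-regulated
#'   toward senescence.
#' @param fold Planted fold change (pseudocounted scale).
#' @param dispersion Negative-binomial dispersion of counts.
#' @param n_mirna,mirna_length miRNA count and length.
#' @param frac_planted_targets Fraction of miRNAs given a planted,
#'   anti-correlated mRNA and circRNA target.
#' @param ... Overrides for the remaining defaults (chromosome lengths,
#'   gene geometry, baselines, library sizes, logistic midpoint/scale,
#'   known-list makeup); see the source for the full list.
#' @return List of class `sim_params`.
#' @export
sim_params <- function(seed = 1L, n_genes = 30L, n_circ = 40L,
                       category_mix = c(EXONIC_BOTH_BOUNDARY = 134,
                                        EXONIC_BOTH_INTERNAL = 8,
                                        EXONIC_ONE_BOUNDARY = 16,
                                        INTERGENIC = 10) / 168,
                       frac_de = 0.3, frac_up = 0.85, fold = 4,
                       dispersion = 0.05, n_mirna = 5L,
                       mirna_length = 21L,
                       frac_planted_targets = 0.6, ...) {
  p <- list(
    seed = as.integer(seed),
    nuclear_chroms = c(Chr1 = 120000L, Chr2 = 120000L),
    chloroplast_length = 30000L, mito_length = 15000L,
    n_genes = as.integer(n_genes),
    exons_per_gene = 7L, exon_length = 150L, intron_length = 100L,
    gene_spacing = 850L,
    n_circ = as.integer(n_circ), category_mix = category_mix,
    max_exon_span = 5L,
    frac_de = frac_de, frac_up = frac_up, fold = fold,
    de_stage = "M-to-S",
    circ_baseline = 0.5, de_up_baseline = 0.1, de_down_baseline = 10,
    dispersion = dispersion,
    logistic_midpoint = 20, logistic_scale = 1,
    gene_baseline = 20, frac_gene_de = 0.3,
    n_mirna = as.integer(n_mirna),
    mirna_length = as.integer(mirna_length),
    mirna_baseline = 100,
    ## planted miRNAs decline gradually over the whole course (the
    ## anti-correlation partner of a senescence-up target)
    mirna_midpoint = 17, mirna_scale = 4,
    frac_planted_targets = frac_planted_targets,
    lib_size = 2e7,
    known_fraction = 0.6, n_known_decoys = 5L,
    cfg = stage_config())
  dots <- list(...)
  bad <- setdiff(names(dots), names(p))
  if (length(bad)) stop("unknown sim parameter(s): ",
                        paste(bad, collapse = ", "))
  p[names(dots)] <- dots
  if (abs(sum(p$category_mix) - 1) > 1e-8)
    stop("category_mix must sum to 1")
  if (any(unlist(p[c("n_genes", "n_circ", "n_mirna")]) < 0))
    stop("counts must be non-negative")
  structure(p, class = "sim_params")
}

## split n into integer category counts proportional to mix
apportion <- function(n, mix) {
  raw <- mix * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  setNames(as.integer(base), names(mix))
}

#' Generate a synthetic leaf lifespan dataset
#'
#' Produces every input the pipeline consumes — genome annotation and
#' sequence, BSJ table with per-sample supporting reads, gene and miRNA
#' count matrices with library sizes, miRNA sequences and a known-circRNA
#' list — with the internal consistency the analysis assumes: BSJ
#' coordinates honor their planted category against the emitted
#' annotation, planted miRNA sites are exact complements embedded in
#' their targets (strand-aware, so the spliced transcript carries the
#' complement), planted DE circRNAs follow logistic trajectories over
#' the 14 time points, and counts are negative-binomial around the
#' means. The same seed reproduces the dataset exactly.
#'
#' @param params A [sim_params()] object.
#' @param dir Optional directory; when given, all files are written there
#'   (`genome.fa`, `annotation.gff3`, `bsj.tsv`, `gene_counts.tsv`,
#'   `mirna_counts.tsv`, `mirna.fa`, `known_circs.tsv`).
#' @return List with the in-memory objects (`annotation`, `genome`,
#'   `bsj`, `gene_counts`, `mirna_counts`, library sizes, `mirna_seqs`,
#'   `known`, `cfg`) and a `truth` list recording what was planted.
#' @export
simulate_dataset <- function(params = sim_params(), dir = NULL) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  with_seed(p$seed, {
    days <- p$cfg$days
    n_days <- length(days)
    day_cols <- paste0("day_", days)

    ## ---- genome layout ------------------------------------------------
    gene_len <- p$exons_per_gene * p$exon_length +
      (p$exons_per_gene - 1L) * p$intron_length
    step <- gene_len + p$gene_spacing
    n_chrom <- length(p$nuclear_chroms)
    per_chrom <- apportion(p$n_genes, rep(1 / n_chrom, n_chrom))
    capacity <- (p$nuclear_chroms - 1000L) %/% step
    if (any(per_chrom > capacity))
      stop("infeasible parameters: genes do not fit on the nuclear ",
           "chromosomes")
    if (p$exon_length < p$mirna_length + 30L)
      stop("infeasible parameters: exons too short to embed miRNA sites")

    gene_ids <- sprintf("g%03d", seq_len(p$n_genes))
    chrom_of <- rep(names(p$nuclear_chroms), per_chrom)
    idx_on <- unlist(lapply(per_chrom, seq_len), use.names = FALSE)
    starts <- 501L + (idx_on - 1L) * step
    strands <- rep(c("+", "-"), length.out = p$n_genes)
    gm <- make_genes(gene_ids, chrom_of, starts, strands,
                     rep(p$exons_per_gene, p$n_genes),
                     rep(p$exon_length, p$n_genes),
                     rep(p$intron_length, p$n_genes))
    chromosomes <- data.frame(
      id = c(names(p$nuclear_chroms), "ChrC", "ChrM"),
      length = c(unname(p$nuclear_chroms), p$chloroplast_length,
                 p$mito_length),
      stringsAsFactors = FALSE)
    ann <- genome_annotation(chromosomes, gm$genes, gm$exons)

    ## ---- circRNA placement -------------------------------------------
    n_cat <- apportion(p$n_circ, p$category_mix)
    categories <- rep(names(n_cat), n_cat)
    n_exonic <- p$n_circ - n_cat[["INTERGENIC"]]
    if (n_exonic > 0 && p$n_genes == 0)
      stop("infeasible parameters: exonic circRNAs but no genes")
    max_span <- min(p$max_exon_span, p$exons_per_gene)
    c_chrom <- character(p$n_circ); c_start <- integer(p$n_circ)
    c_end <- integer(p$n_circ); c_strand <- character(p$n_circ)
    c_host <- rep(NA_character_, p$n_circ)
    ei <- 0L; ii <- 0L
    for (k in seq_len(p$n_circ)) {
      if (categories[k] == "INTERGENIC") {
        ii <- ii + 1L
        if (ii %% 3L == 1L) {         # some arise from the plastid
          s <- sample.int(p$chloroplast_length - 600L, 1L)
          c_chrom[k] <- "ChrC"; c_start[k] <- s; c_end[k] <- s + 300L
          c_strand[k] <- "+"
        } else {                      # nuclear gene desert (gene gap)
          g <- gm$genes[sample.int(p$n_genes, 1L), ]
          c_chrom[k] <- g$chrom
          c_start[k] <- g$end + 200L; c_end[k] <- g$end + 500L
          c_strand[k] <- "+"
        }
      } else {
        ei <- ei + 1L
        g <- gm$genes[((ei - 1L) %% p$n_genes) + 1L, ]
        ## when circRNAs outnumber genes, later rounds start at a deeper
        ## exon so coordinates stay unique (alternative back-splicing)
        a <- (ei - 1L) %/% p$n_genes + 1L
        if (a + 1L > p$exons_per_gene)
          stop("infeasible parameters: too many circRNAs per gene")
        span <- sample.int(min(max_span, p$exons_per_gene - a + 1L), 1L)
        xy <- circ_coords(categories[k], g$start, span, p$exon_length,
                          p$intron_length, first_exon = a)
        c_chrom[k] <- g$chrom; c_start[k] <- xy[1]; c_end[k] <- xy[2]
        c_strand[k] <- g$strand; c_host[k] <- g$gene_id
      }
    }
    circ <- data.frame(chrom = c_chrom, start = c_start, end = c_end,
                       strand = c_strand, category = categories,
                       host = c_host, stringsAsFactors = FALSE)
    circ$circ_id <- sprintf("%s:%d-%d(%s)", circ$chrom, circ$start,
                            circ$end, circ$strand)

    ## ---- planted circRNA expression ----------------------------------
    exonic_rows <- which(circ$category != "INTERGENIC")
    n_de <- round(p$frac_de * p$n_circ)
    de_rows <- head(exonic_rows, n_de)
    n_up <- round(p$frac_up * length(de_rows))
    de_dir <- rep(c("up", "down"), c(n_up, length(de_rows) - n_up))
    circ_counts <- matrix(0L, nrow = p$n_circ, ncol = n_days,
                          dimnames = list(circ$circ_id, day_cols))
    de_ref <- p$cfg$stages[[p$de_stage]]$ref
    for (i in seq_len(p$n_circ)) {
      circ_counts[i, ] <- if (i %in% de_rows) {
        dirn <- de_dir[match(i, de_rows)]
        sim_time_course(
          if (dirn == "up") "logistic_up" else "logistic_down",
          days = days,
          baseline = if (dirn == "up") p$de_up_baseline else
            p$de_down_baseline,
          fold = p$fold, midpoint = p$logistic_midpoint,
          scale = p$logistic_scale, anchor_day = de_ref,
          dispersion = p$dispersion)
      } else {
        sim_time_course("flat", days = days, baseline = p$circ_baseline,
                        dispersion = p$dispersion)
      }
    }

    ## ---- gene expression (head of the table is planted up-DE) --------
    n_gde <- round(p$frac_gene_de * p$n_genes)
    gene_counts <- matrix(0L, nrow = p$n_genes, ncol = n_days,
                          dimnames = list(gene_ids, day_cols))
    for (i in seq_len(p$n_genes)) {
      gene_counts[i, ] <- if (i <= n_gde)
        sim_time_course("logistic_up", days = days,
                        baseline = p$gene_baseline, fold = p$fold,
                        midpoint = p$logistic_midpoint,
                        scale = p$logistic_scale, anchor_day = de_ref,
                        dispersion = p$dispersion)
      else sim_time_course("flat", days = days,
                           baseline = p$gene_baseline,
                           dispersion = p$dispersion)
    }

    ## ---- miRNAs, planted targets, genome sequence --------------------
    mirna_ids <- sprintf("mir%02d", seq_len(p$n_mirna))
    mirna_seqs <- setNames(
      vapply(seq_len(max(p$n_mirna, 0L)),
             function(i) random_dna(p$mirna_length), character(1)),
      mirna_ids)
    n_planted <- round(p$frac_planted_targets * p$n_mirna)
    up_circ_rows <- de_rows[de_dir == "up"]

    genome_chr <- lapply(setNames(as.list(chromosomes$length),
                                  chromosomes$id),
                         random_dna)
    ## embed `site` so the transcript (strand-aware) carries the exact
    ## complement of the miRNA
    plant <- function(chrom, pos, strand, mir) {
      site <- if (strand == "+") revcomp_chr(mir) else mir
      stopifnot(pos + nchar(site) - 1L <= nchar(genome_chr[[chrom]]))
      substr(genome_chr[[chrom]], pos, pos + nchar(site) - 1L) <<- site
    }

    planted_map <- NULL
    mirna_counts <- matrix(0L, nrow = p$n_mirna, ncol = n_days,
                           dimnames = list(mirna_ids, day_cols))
    for (i in seq_len(p$n_mirna)) {
      is_planted <- i <= n_planted
      mirna_counts[i, ] <- if (is_planted)
        sim_time_course("logistic_down", days = days,
                        baseline = p$mirna_baseline, fold = p$fold,
                        midpoint = p$mirna_midpoint,
                        scale = p$mirna_scale,
                        dispersion = p$dispersion)
      else sim_time_course("flat", days = days,
                           baseline = p$mirna_baseline,
                           dispersion = p$dispersion)
      if (!is_planted) next
      ## up-DE genes and planted sites coincide at the head of the gene
      ## table; stagger offsets so several miRNAs never overwrite a site
      layer <- (i - 1L) %/% max(n_gde, 1L)
      tg <- gene_ids[((i - 1L) %% max(n_gde, 1L)) + 1L]
      grow <- gm$genes[gm$genes$gene_id == tg, ]
      plant(grow$chrom, grow$start + 10L + layer * (p$mirna_length + 4L),
            grow$strand, mirna_seqs[[i]])
      tc <- NA_character_
      if (length(up_circ_rows)) {
        clayer <- (i - 1L) %/% length(up_circ_rows)
        cr <- circ[up_circ_rows[((i - 1L) %% length(up_circ_rows)) + 1L], ]
        off <- 20L + clayer * (p$mirna_length + 4L)
        ## the site must sit wholly inside the circRNA's first exon so
        ## splicing does not break it
        if (off + p$mirna_length <= p$exon_length - 12L &&
            cr$start + off + p$mirna_length <= cr$end) {
          plant(cr$chrom, cr$start + off, cr$strand, mirna_seqs[[i]])
          tc <- cr$circ_id
        }
      }
      planted_map <- rbind(planted_map, data.frame(
        mirna_id = mirna_ids[i], target_gene = tg, target_circ = tc,
        stringsAsFactors = FALSE))
    }
    genome <- Biostrings::DNAStringSet(unlist(genome_chr))

    ## ---- known-circRNA list ------------------------------------------
    n_known <- round(p$known_fraction * p$n_circ)
    known_rows <- sort(sample.int(p$n_circ, n_known))
    known <- circ[known_rows, c("chrom", "start", "end", "strand")]
    if (p$n_known_decoys > 0) {
      dstart <- sample.int(10000L, p$n_known_decoys) + 100L
      known <- rbind(known, data.frame(
        chrom = "ChrM", start = dstart, end = dstart + 250L,
        strand = "+", stringsAsFactors = FALSE))
    }
    rownames(known) <- NULL

    bsj <- data.frame(circ_id = circ$circ_id,
                      circ[, c("chrom", "start", "end", "strand")],
                      circ_counts, stringsAsFactors = FALSE,
                      check.names = FALSE)
    rownames(bsj) <- NULL
    bsj <- structure(bsj, class = c("bsj_table", "data.frame"))
    lib <- rep(p$lib_size, n_days)

    out <- list(
      params = p, cfg = p$cfg, annotation = ann, genome = genome,
      bsj = bsj, circ_lib_sizes = lib,
      gene_counts = gene_counts, gene_lib_sizes = lib,
      mirna_counts = mirna_counts, mirna_lib_sizes = lib,
      mirna_seqs = mirna_seqs, known = known,
      truth = list(
        categories = setNames(circ$category, circ$circ_id),
        hosts = setNames(circ$host, circ$circ_id),
        de_circ = data.frame(circ_id = circ$circ_id[de_rows],
                             direction = de_dir,
                             stringsAsFactors = FALSE),
        de_stage = p$de_stage,
        de_genes = gene_ids[seq_len(n_gde)],
        planted_targets = planted_map,
        known_rows = known_rows))
    if (!is.null(dir)) write_sim_dataset(out, dir)
    out
  })
}

## write every simulated input in its on-disk format
write_sim_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(sim$genome, file.path(dir, "genome.fa"))
  write_gff3(sim$annotation, file.path(dir, "annotation.gff3"))
  write_bsj_table(sim$bsj, file.path(dir, "bsj.tsv"))
  ## library sizes of the BSJ assay travel in a sidecar (the BSJ table
  ## itself has no feature-id column to host a library_size row)
  write.table(
    data.frame(sample = colnames(bsj_counts(sim$bsj)),
               library_size = sim$circ_lib_sizes),
    file.path(dir, "bsj.tsv.libsizes"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  write_count_matrix(sim$gene_counts, sim$gene_lib_sizes,
                     file.path(dir, "gene_counts.tsv"))
  write_count_matrix(sim$mirna_counts, sim$mirna_lib_sizes,
                     file.path(dir, "mirna_counts.tsv"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(sim$mirna_seqs),
    file.path(dir, "mirna.fa"))
  write_known_circs(sim$known, file.path(dir, "known_circs.tsv"))
  invisible(dir)
}
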
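#' Spliced transcript sequence of a gene
#'
#' Concatenates the gene's exon sequences in genomic order and
#' reverse-complements the result for minus-strand genes.
#'
#' @param gene_id Gene identifier.
#' @param genome A [Biostrings::DNAStringSet] keyed by chromosome id.
#' @param ann A [genome_annotation()] object.
#' @return Character transcript sequence.
#' @export
extract_transcript_sequence <- function(gene_id, genome, ann) {
  gi <- match(gene_id, ann$genes$gene_id)
  if (is.na(gi)) stop("unknown gene: ", gene_id)
  g <- ann$genes[gi, ]
  ex <- ann$exons[ann$exons$gene_id == gene_id, , drop = FALSE]
  ex <- ex[order(ex$start), , drop = FALSE]
  chrseq <- genome[[g$chrom]]
  pieces <- vapply(seq_len(nrow(ex)), function(i)
    as.character(Biostrings::subseq(chrseq, ex$start[i], ex$end[i])),
    character(1))
  seq <- paste(pieces, collapse = "")
  if (g$strand == "-") seq <- revcomp_chr(seq)
  seq
}

#' Pipeline configuration
#'
#' Collects input paths and all thresholds for [run_pipeline()]. Every
#' referenced path must exist; a missing one aborts naming the path.
#'
#' @param gff3,genome_fa,bsj,gene_counts,mirna_counts,mirna_fa Input
#'   paths (annotation, genome FASTA, BSJ TSV, count TSVs, miRNA FASTA).
#' @param known Optional known-circRNA TSV.
#' @param out_dir Optional output directory for stage files.
#' @param cfg A [stage_config()].
#' @param fc_threshold DE `|log2FC|` threshold (default 2).
#' @param min_samples Retained-set detection minimum (default 2).
#' @param boundary_tolerance,slack Classification/novelty tolerances (nt).
#' @param cutoffs Target score cutoffs per molecule kind.
#' @param rho_max Anti-correlation ceiling.
#' @param gates Triplet fold-change gates.
#' @param junction_window_k Junction window parameter for circular scans.
#' @param organelle_map Chromosome-id to organelle map.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(gff3, genome_fa, bsj, gene_counts,
                            mirna_counts, mirna_fa, known = NULL,
                            out_dir = NULL, cfg = stage_config(),
                            fc_threshold = 2, min_samples = 2L,
                            boundary_tolerance = 0L, slack = 0L,
                            cutoffs = c(mRNA = 4, circRNA = 4.5),
                            rho_max = -0.5,
                            gates = c(mirna = 1, circ = 2, mrna = 2),
                            junction_window_k = 22L,
                            organelle_map = default_organelle_map()) {
  paths <- c(gff3 = gff3, genome_fa = genome_fa, bsj = bsj,
             gene_counts = gene_counts, mirna_counts = mirna_counts,
             mirna_fa = mirna_fa,
             if (!is.null(known)) c(known = known))
  for (nm in names(paths))
    if (!file.exists(paths[[nm]]))
      stop("missing input file (", nm, "): ", paths[[nm]])
  structure(list(paths = as.list(paths), out_dir = out_dir, cfg = cfg,
                 fc_threshold = fc_threshold, min_samples = min_samples,
                 boundary_tolerance = boundary_tolerance, slack = slack,
                 cutoffs = cutoffs, rho_max = rho_max, gates = gates,
                 junction_window_k = junction_window_k,
                 organelle_map = organelle_map),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML maps the arguments of [pipeline_config()]; unknown keys are
#' rejected. Relative paths are resolved against the YAML file's
#' directory.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  path_keys <- c("gff3", "genome_fa", "bsj", "gene_counts",
                 "mirna_counts", "mirna_fa", "known", "out_dir")
  for (k in intersect(path_keys, names(y)))
    if (!grepl("^(/|[A-Za-z]:)", y[[k]])) y[[k]] <- file.path(base, y[[k]])
  known_args <- names(formals(pipeline_config))
  bad <- setdiff(names(y), known_args)
  if (length(bad)) stop("unknown config key(s): ",
                        paste(bad, collapse = ", "))
  for (k in c("cutoffs", "gates")) if (k %in% names(y))
    y[[k]] <- unlist(y[[k]])
  do.call(pipeline_config, y)
}

## load every input of a pipeline_config into the in-memory layout that
## simulate_dataset()/make_benchmark_fixture() return
load_pipeline_inputs <- function(config) {
  n_samples <- length(config$cfg$days)
  bsj <- read_bsj_table(config$paths$bsj, n_samples)
  ## BSJ library sizes ride in a sidecar next to the table
  side <- paste0(config$paths$bsj, ".libsizes")
  if (!file.exists(side))
    stop("missing BSJ library-size sidecar: ", side)
  ls_tab <- read.delim(side, header = TRUE, sep = "\t",
                       stringsAsFactors = FALSE)
  gene <- read_count_matrix(config$paths$gene_counts)
  mirna <- read_count_matrix(config$paths$mirna_counts)
  mirna_fa <- Biostrings::readDNAStringSet(config$paths$mirna_fa)
  list(
    cfg = config$cfg,
    annotation = read_gff3(config$paths$gff3, config$organelle_map),
    genome = Biostrings::readDNAStringSet(config$paths$genome_fa),
    bsj = bsj,
    circ_lib_sizes = as.numeric(ls_tab[[2]]),
    gene_counts = gene$counts, gene_lib_sizes = gene$lib_sizes,
    mirna_counts = mirna$counts, mirna_lib_sizes = mirna$lib_sizes,
    mirna_seqs = setNames(as.character(mirna_fa), names(mirna_fa)),
    known = if (!is.null(config$paths$known))
      read_known_circs(config$paths$known) else NULL)
}

#' Run the whole circRNA pipeline
#'
#' Executes classification, quantification, target prediction and
#' network assembly end to end and writes stage outputs plus a summary
#' report. `run_pipeline()` starts from a [pipeline_config()] (files on
#' disk); [run_pipeline_data()] starts from the in-memory object list
#' that [simulate_dataset()] and [make_benchmark_fixture()] return. Both are
#' deterministic: the same inputs give identical outputs.
#'
#' @param config A `pipeline_config`.
#' @return Object of class `circleaf_report`; see [run_pipeline_data()].
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  data <- pipeline_stage("load_inputs", load_pipeline_inputs(config))
  run_pipeline_data(
    data, out_dir = config$out_dir,
    fc_threshold = config$fc_threshold,
    min_samples = config$min_samples,
    boundary_tolerance = config$boundary_tolerance,
    slack = config$slack, cutoffs = config$cutoffs,
    rho_max = config$rho_max, gates = config$gates,
    junction_window_k = config$junction_window_k)
}

## run one stage, aborting with its name on failure
pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' @rdname run_pipeline
#' @param data List with `cfg`, `annotation`, `genome`, `bsj`,
#'   `circ_lib_sizes`, `gene_counts`, `gene_lib_sizes`, `mirna_counts`,
#'   `mirna_lib_sizes`, `mirna_seqs` and optionally `known`.
#' @param out_dir Optional output directory.
#' @inheritParams pipeline_config
#' @export
run_pipeline_data <- function(data, out_dir = NULL, fc_threshold = 2,
                              min_samples = 2L, boundary_tolerance = 0L,
                              slack = 0L,
                              cutoffs = c(mRNA = 4, circRNA = 4.5),
                              rho_max = -0.5,
                              gates = c(mirna = 1, circ = 2, mrna = 2),
                              junction_window_k = 22L) {
  cfg <- data$cfg
  stages <- names(cfg$stages)

  ## ---- classify ------------------------------------------------------
  records <- pipeline_stage("classify", {
    r <- classify_junctions(data$bsj, data$annotation,
                            boundary_tolerance)
    flag_novel(r, data$known, slack)
  })
  class_summary <- summarize_classes(records)
  host_map <- records[records$category %in%
                        c("EXONIC_BOTH_BOUNDARY", "EXONIC_BOTH_INTERNAL",
                          "EXONIC_ONE_BOUNDARY"),
                      c("circ_id", "host_gene")]
  names(host_map) <- c("circ_id", "gene_id")

  ## ---- quantify ------------------------------------------------------
  q <- pipeline_stage("quantify", {
    circ_counts <- bsj_counts(data$bsj)
    circ_expr <- normalize_expression(circ_counts, data$circ_lib_sizes)
    detection <- detection_summary(circ_counts, cfg, min_samples)
    kept <- detection$retained
    kept_expr <- normalize_expression(
      circ_counts[kept, , drop = FALSE], data$circ_lib_sizes)
    gene_expr <- normalize_expression(data$gene_counts,
                                      data$gene_lib_sizes)
    mirna_expr <- normalize_expression(data$mirna_counts,
                                       data$mirna_lib_sizes)
    fcs <- function(expr) lapply(setNames(stages, stages), function(s)
      log2_fold_changes(expr, cfg, s))
    circ_fc <- fcs(kept_expr); gene_fc <- fcs(gene_expr)
    mirna_fc <- fcs(mirna_expr)
    des <- function(fc) do.call(rbind, lapply(fc, call_de,
                                              threshold = fc_threshold))
    list(circ_expr = circ_expr, kept_expr = kept_expr,
         gene_expr = gene_expr, mirna_expr = mirna_expr,
         detection = detection, circ_fc = circ_fc, gene_fc = gene_fc,
         mirna_fc = mirna_fc, circ_de = des(circ_fc),
         gene_de = des(gene_fc), mirna_de = des(mirna_fc))
  })

  concordance <- pipeline_stage("host_concordance",
    suppressMessages(host_concordance(q$circ_de, q$gene_de, q$kept_expr,
                                      q$gene_expr, host_map)))

  ## ---- targets: scan stage-gated molecules ---------------------------
  tg <- pipeline_stage("targets", {
    gated <- function(fc_list, gate)
      unique(unlist(lapply(fc_list, function(fc)
        rownames(fc)[apply(abs(fc), 1, max) >= gate])))
    mir_ids <- gated(q$mirna_fc, gates[["mirna"]])
    circ_ids <- gated(q$circ_fc, gates[["circ"]])
    mrna_ids <- gated(q$gene_fc, gates[["mrna"]])
    circ_seqs <- setNames(vapply(circ_ids, function(id) {
      rec <- records[records$circ_id == id, ]
      extract_circ_sequence(rec, data$genome, data$annotation,
                            junction_window_k)$sequence
    }, character(1)), circ_ids)
    mrna_seqs <- setNames(vapply(mrna_ids, function(id)
      extract_transcript_sequence(id, data$genome, data$annotation),
      character(1)), mrna_ids)
    mir_seqs <- data$mirna_seqs[mir_ids]
    circ_hits <- anticorrelation_filter(
      predict_targets(mir_seqs, circ_seqs, "circRNA", cutoffs),
      q$mirna_expr, q$kept_expr, rho_max)
    mrna_hits <- anticorrelation_filter(
      predict_targets(mir_seqs, mrna_seqs, "mRNA", cutoffs),
      q$mirna_expr, q$gene_expr, rho_max)
    list(circ_hits = circ_hits, mrna_hits = mrna_hits)
  })

  ## ---- network -------------------------------------------------------
  triplets <- pipeline_stage("network",
    lapply(setNames(stages, stages), function(s)
      assemble_triplets(tg$circ_hits, tg$mrna_hits, q$circ_fc[[s]],
                        q$gene_fc[[s]], q$mirna_fc[[s]], s, gates)))
  stats <- network_stats(triplets)

  report <- structure(list(
    records = records, class_summary = class_summary,
    detection = q$detection, quantification = q,
    concordance = concordance, hits = tg, triplets = triplets,
    network_stats = stats, host_map = host_map),
    class = "circleaf_report")

  if (!is.null(out_dir)) write_pipeline_outputs(report, out_dir)
  report
}

write_pipeline_outputs <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write.table(as.data.frame(report$records),
              file.path(out_dir, "records.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(report$quantification$circ_de,
              file.path(out_dir, "de_circ.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  det <- report$detection
  write.table(data.frame(circ_id = names(det$detection),
                         n_samples_detected = unname(det$detection),
                         retained = names(det$detection) %in%
                           det$retained),
              file.path(out_dir, "detection.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (s in names(report$triplets)) {
    safe <- gsub("[^A-Za-z0-9]+", "_", s)
    write_network(report$triplets[[s]],
                  file.path(out_dir, paste0("network_", safe, ".tsv")),
                  "tsv")
    write_network(report$triplets[[s]],
                  file.path(out_dir, paste0("network_", safe, ".sif")),
                  "sif")
  }
  capture <- utils::capture.output(print(report))
  writeLines(capture, file.path(out_dir, "report.txt"))
  invisible(out_dir)
}

#' @export
print.circleaf_report <- function(x, ...) {
  cat("== circRNA lifespan pipeline report ==\n\n")
  print(x$class_summary)
  cat("\n")
  print(x$detection)
  de <- x$quantification$circ_de
  de <- de[de$is_de, , drop = FALSE]
  cat("\nDE circRNAs (|log2FC| threshold met):\n")
  for (s in unique(x$quantification$circ_de$stage)) {
    d <- de[de$stage == s, ]
    cat(sprintf("  %-8s %3d DE (%d up, %d down)\n", s, nrow(d),
                sum(d$direction == "up"), sum(d$direction == "down")))
  }
  both <- Reduce(intersect, split(de$feature_id, de$stage))
  cat("  DE in both stages:", length(both), "\n")
  cat("\nHost concordance (up circRNAs with up host transcript):\n")
  pc <- x$concordance$per_stage
  for (i in seq_len(nrow(pc)))
    cat(sprintf("  %-8s %d/%d\n", pc$stage[i], pc$n_concordant[i],
                pc$n_up_circ[i]))
  cat("\n")
  print(x$network_stats)
  invisible(x)
}
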
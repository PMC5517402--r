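#' Time-course stage configuration
#'
#' The default layout mirrors a leaf lifespan course: 14 samples at 2-day
#' intervals from day 4 to day 30, split into a growth-to-maturation
#' window (`G-to-M`, days 4-18, reference day 4) and a
#' maturation-to-senescence window (`M-to-S`, days 16-30, reference day
#' 16). Days 16 and 18 belong to both windows; each stage uses its own
#' reference day for fold changes.
#'
#' @param days Ordered numeric vector of time-point labels (days); one
#'   sample per day.
#' @param stages Named list; each stage is `list(days = <member days>,
#'   ref = <reference day>)`.
#' @return Object of class `stage_config`.
#' @export
stage_config <- function(days = seq(4, 30, by = 2),
                         stages = list(
                           "G-to-M" = list(days = seq(4, 18, by = 2),
                                           ref = 4),
                           "M-to-S" = list(days = seq(16, 30, by = 2),
                                           ref = 16))) {
  stopifnot(is.numeric(days), length(days) >= 2, !anyDuplicated(days))
  for (nm in names(stages)) {
    st <- stages[[nm]]
    if (!all(st$days %in% days))
      stop("stage ", nm, " contains days outside the time course")
    if (!st$ref %in% st$days)
      stop("reference day of stage ", nm, " is not a member day")
  }
  structure(list(days = days, stages = stages), class = "stage_config")
}

#' @export
print.stage_config <- function(x, ...) {
  cat("stage_config:", length(x$days), "time points (days",
      paste(range(x$days), collapse = "-"), ")\n")
  for (nm in names(x$stages))
    cat(sprintf("  %-8s days %s (reference day %s)\n", nm,
                paste(range(x$stages[[nm]]$days), collapse = "-"),
                x$stages[[nm]]$ref))
  invisible(x)
}

## column indices of a stage's days (matrices carry one column per day,
## in time-course order)
stage_cols <- function(cfg, stage) {
  st <- cfg$stages[[stage]]
  if (is.null(st)) stop("unknown stage: ", stage)
  match(st$days, cfg$days)
}

#' Normalize counts to pseudocounted reads-per-million
#'
#' `E[f, s] = (n[f, s] + 1) / N[s] * 1e6`, where `N[s]` is the sample's
#' library size (total reads of the sequencing run, not a column sum).
#' The pseudocount keeps every value positive so log fold changes are
#' always defined; the per-million scale cancels in every fold change.
#'
#' @param counts Integer matrix, features x samples.
#' @param lib_sizes Numeric vector of per-sample total reads (> 0).
#' @return Object of class `expression_matrix`: list with `counts`,
#'   `lib_sizes`, `E` (the normalized matrix).
#' @export
normalize_expression <- function(counts, lib_sizes) {
  counts <- as.matrix(counts)
  if (length(lib_sizes) != ncol(counts))
    stop("library sizes (", length(lib_sizes),
         ") do not match sample count (", ncol(counts), ")")
  if (any(lib_sizes <= 0)) stop("library sizes must be positive")
  if (any(counts < 0)) stop("negative counts")
  E <- sweep(counts + 1, 2, lib_sizes, "/") * 1e6
  structure(list(counts = counts, lib_sizes = as.numeric(lib_sizes),
                 E = E),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$counts), "feature(s) x",
      ncol(x$counts), "sample(s); E = (n+1)/N * 1e6\n")
  invisible(x)
}

#' Stage-wise log2 fold-change profiles
#'
#' For each non-reference day `t` of the stage,
#' `FC[f, t] = log2(E[f, t] / E[f, ref])`. Always defined because the
#' normalization keeps `E > 0`.
#'
#' @param expr An `expression_matrix` from [normalize_expression()].
#' @param cfg A [stage_config()].
#' @param stage Stage name.
#' @return Numeric matrix features x non-reference days; column names are
#'   the day labels. Attributes `stage` and `ref_day` record the window.
#' @export
log2_fold_changes <- function(expr, cfg, stage) {
  stopifnot(inherits(expr, "expression_matrix"))
  cols <- stage_cols(cfg, stage)
  st <- cfg$stages[[stage]]
  ref_col <- match(st$ref, cfg$days)
  non_ref <- cols[st$days != st$ref]
  fc <- log2(expr$E[, non_ref, drop = FALSE] / expr$E[, ref_col])
  colnames(fc) <- paste0("day_", st$days[st$days != st$ref])
  attr(fc, "stage") <- stage
  attr(fc, "ref_day") <- st$ref
  fc
}

#' Call differential expression from fold-change profiles
#'
#' A feature is differentially expressed (DE) when some stage day reaches
#' `|log2FC| >= threshold` (inclusive; the default 2 is a 4-fold change).
#' The direction is the sign of the fold change at the day of maximum
#' `|log2FC|`; an exact tie across days resolves to the latest day.
#' Set `final_day_only = TRUE` to require the threshold at the last stage
#' day instead of any day.
#'
#' @param fc Fold-change matrix from [log2_fold_changes()].
#' @param threshold Inclusive `|log2FC|` cutoff (default 2).
#' @param final_day_only Gate on the final stage day only (default FALSE).
#' @return data.frame with `feature_id`, `stage`, `max_abs_fc`,
#'   `direction` (`"up"`/`"down"`), `is_de`.
#' @export
call_de <- function(fc, threshold = 2, final_day_only = FALSE) {
  fc_eval <- if (final_day_only) fc[, ncol(fc), drop = FALSE] else fc
  max_abs <- apply(abs(fc_eval), 1, max)
  dir <- vapply(seq_len(nrow(fc_eval)), function(i) {
    r <- fc_eval[i, ]
    j <- max(which(abs(r) == max(abs(r))))  # tie -> latest day
    if (r[j] >= 0) "up" else "down"
  }, character(1))
  data.frame(feature_id = rownames(fc),
             stage = attr(fc, "stage") %||% NA_character_,
             max_abs_fc = unname(max_abs),
             direction = dir,
             is_de = unname(max_abs >= threshold),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Detection frequencies, retained set and stage membership
#'
#' A feature is *detected* in a sample when it has at least `min_reads`
#' supporting reads (default 1; the minimal assumption). Reports the
#' per-feature detection count, its histogram, the retained set
#' (detection in at least `min_samples` samples, the precondition for DE
#' analysis), per-stage detected sets (detected on any stage day; days
#' shared between windows count toward both stages) and the stage Venn.
#' The overlap excluding the shared days is reported alongside, so their
#' contribution is visible.
#'
#' @param counts Integer matrix, features x samples (columns in
#'   time-course order).
#' @param cfg A [stage_config()].
#' @param min_samples Minimum samples for the retained set (default 2).
#' @param min_reads Reads needed to call a feature detected (default 1).
#' @return Object of class `detection_summary`.
#' @export
detection_summary <- function(counts, cfg, min_samples = 2L,
                              min_reads = 1L) {
  counts <- as.matrix(counts)
  det <- counts >= min_reads
  n_det <- rowSums(det)
  stage_names <- names(cfg$stages)
  sets <- lapply(stage_names, function(nm)
    rownames(counts)[rowSums(det[, stage_cols(cfg, nm), drop = FALSE]) > 0])
  names(sets) <- stage_names
  shared_days <- Reduce(intersect, lapply(cfg$stages, `[[`, "days"))
  sets_excl <- lapply(stage_names, function(nm) {
    dd <- setdiff(cfg$stages[[nm]]$days, shared_days)
    rownames(counts)[rowSums(det[, match(dd, cfg$days), drop = FALSE]) > 0]
  })
  names(sets_excl) <- stage_names
  venn <- function(ss) {
    inter <- Reduce(intersect, ss)
    un <- Reduce(union, ss)
    c(setNames(lengths(ss), names(ss)),
      intersection = length(inter), union = length(un))
  }
  structure(list(
    n_features = nrow(counts),
    detection = setNames(as.integer(n_det), rownames(counts)),
    histogram = table(factor(n_det, levels = 0:ncol(counts))),
    retained = rownames(counts)[n_det >= min_samples],
    min_samples = min_samples,
    stage_sets = sets,
    venn = venn(sets),
    shared_days = shared_days,
    stage_sets_excluding_shared = sets_excl,
    venn_excluding_shared = venn(sets_excl)),
    class = "detection_summary")
}

#' @export
print.detection_summary <- function(x, ...) {
  n <- x$n_features
  singles <- sum(x$detection == 1)
  cat("detection_summary:", n, "feature(s)\n")
  cat(sprintf("  detected in exactly 1 sample: %d (%.1f%%)\n",
              singles, round_half_up(100 * singles / n, 1)))
  cat(sprintf("  retained (>= %d samples): %d\n", x$min_samples,
              length(x$retained)))
  v <- x$venn
  cat("  stage sets:",
      paste(sprintf("%s = %d", names(v)[seq_along(x$stage_sets)],
                    v[seq_along(x$stage_sets)]), collapse = ", "),
      sprintf("; intersection %d, union %d\n", v[["intersection"]],
              v[["union"]]))
  invisible(x)
}

#' Host-gene concordance of up-regulated circRNAs
#'
#' For each stage, counts how many up-regulated DE circRNAs have a host
#' gene whose linear transcript is itself up-regulated DE in the same
#' stage (gene DE called with the same normalization and threshold), and
#' reports per-pair Spearman correlations between circRNA and host
#' normalized profiles over the full time course. circRNAs without a host
#' gene (non-exonic) are skipped and listed.
#'
#' @param circ_de data.frame of circRNA DE calls (rows from [call_de()],
#'   possibly several stages row-bound).
#' @param gene_de data.frame of gene DE calls, same shape.
#' @param circ_expr,gene_expr `expression_matrix` objects for circRNAs
#'   and genes over the same samples.
#' @param host_map data.frame with columns `circ_id`, `gene_id` (exonic
#'   records only), or a named character vector (names = circ ids).
#' @return List with `per_stage` (stage, up-circ count, concordant count,
#'   fraction), `pairs` (circ, host, Spearman rho) and `skipped`.
#' @export
host_concordance <- function(circ_de, gene_de, circ_expr, gene_expr,
                             host_map) {
  if (!is.data.frame(host_map))
    host_map <- data.frame(circ_id = names(host_map),
                           gene_id = unname(host_map),
                           stringsAsFactors = FALSE)
  stages <- unique(circ_de$stage)
  per_stage <- do.call(rbind, lapply(stages, function(stg) {
    up <- circ_de$feature_id[circ_de$stage == stg & circ_de$is_de &
                               circ_de$direction == "up"]
    hosts <- host_map$gene_id[match(up, host_map$circ_id)]
    gene_up <- gene_de$feature_id[gene_de$stage == stg & gene_de$is_de &
                                    gene_de$direction == "up"]
    conc <- sum(!is.na(hosts) & hosts %in% gene_up)
    data.frame(stage = stg, n_up_circ = length(up),
               n_concordant = conc,
               fraction = if (length(up)) conc / length(up) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  with_host <- host_map[host_map$circ_id %in% rownames(circ_expr$E) &
                          host_map$gene_id %in% rownames(gene_expr$E), ,
                        drop = FALSE]
  skipped <- setdiff(rownames(circ_expr$E), host_map$circ_id)
  if (length(skipped))
    message(length(skipped),
            " circRNA(s) without a host gene skipped in concordance")
  pairs <- data.frame(
    circ_id = with_host$circ_id, gene_id = with_host$gene_id,
    rho = vapply(seq_len(nrow(with_host)), function(i)
      spearman_rho(circ_expr$E[with_host$circ_id[i], ],
                   gene_expr$E[with_host$gene_id[i], ]), numeric(1)),
    stringsAsFactors = FALSE)
  list(per_stage = per_stage, pairs = pairs, skipped = skipped)
}
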
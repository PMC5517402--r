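#' Assemble circRNA-miRNA-mRNA triplets for one stage
#'
#' A triplet joins a miRNA to one circRNA and one mRNA it targets, with
#' all three molecules passing their stage fold-change gates: `|log2FC|`
#' at least 1 for the miRNA (2-fold) and at least 2 (4-fold) for the
#' circRNA and the mRNA, at any day within the stage, each molecule gated
#' independently. Hit lists are expected to be anti-correlation-filtered
#' already ([anticorrelation_filter()]); rows with a `passed` column set
#' to `FALSE` are dropped. The result is deduplicated and sorted by
#' (circRNA, miRNA, mRNA).
#'
#' @param circ_hits Filtered miRNA->circRNA hits.
#' @param mrna_hits Filtered miRNA->mRNA hits.
#' @param circ_fc,mrna_fc,mirna_fc Stage fold-change matrices from
#'   [log2_fold_changes()] for the same stage.
#' @param stage Stage name recorded on the triplets.
#' @param gates Named numeric `|log2FC|` gates (defaults `mirna = 1`,
#'   `circ = 2`, `mrna = 2`).
#' @return data.frame of class `triplet_set`: `circ_id`, `mirna_id`,
#'   `mrna_id`, `stage`, scores and correlations of both hits.
#' @export
assemble_triplets <- function(circ_hits, mrna_hits, circ_fc, mrna_fc,
                              mirna_fc, stage,
                              gates = c(mirna = 1, circ = 2, mrna = 2)) {
  gated <- function(fc, gate)
    rownames(fc)[apply(abs(fc), 1, max) >= gate]
  ok_circ <- gated(circ_fc, gates[["circ"]])
  ok_mrna <- gated(mrna_fc, gates[["mrna"]])
  ok_mirna <- gated(mirna_fc, gates[["mirna"]])

  keep <- function(h) {
    if (!nrow(h)) return(h)
    if ("passed" %in% names(h)) h <- h[h$passed, , drop = FALSE]
    h
  }
  ch <- keep(circ_hits)
  mh <- keep(mrna_hits)
  ch <- ch[ch$mirna_id %in% ok_mirna & ch$target_id %in% ok_circ, ,
           drop = FALSE]
  mh <- mh[mh$mirna_id %in% ok_mirna & mh$target_id %in% ok_mrna, ,
           drop = FALSE]

  empty <- data.frame(circ_id = character(0), mirna_id = character(0),
                      mrna_id = character(0), stage = character(0),
                      circ_score = numeric(0), mrna_score = numeric(0),
                      rho_mirna_circ = numeric(0),
                      rho_mirna_mrna = numeric(0),
                      stringsAsFactors = FALSE)
  if (!nrow(ch) || !nrow(mh))
    return(structure(empty, class = c("triplet_set", "data.frame")))

  tr <- merge(
    data.frame(mirna_id = ch$mirna_id, circ_id = ch$target_id,
               circ_score = ch$score,
               rho_mirna_circ = if ("rho" %in% names(ch)) ch$rho else
                 NA_real_, stringsAsFactors = FALSE),
    data.frame(mirna_id = mh$mirna_id, mrna_id = mh$target_id,
               mrna_score = mh$score,
               rho_mirna_mrna = if ("rho" %in% names(mh)) mh$rho else
                 NA_real_, stringsAsFactors = FALSE),
    by = "mirna_id")
  tr$stage <- stage
  tr <- tr[, c("circ_id", "mirna_id", "mrna_id", "stage", "circ_score",
               "mrna_score", "rho_mirna_circ", "rho_mirna_mrna")]
  tr <- unique(tr)
  tr <- tr[order(tr$circ_id, tr$mirna_id, tr$mrna_id), , drop = FALSE]
  rownames(tr) <- NULL
  structure(tr, class = c("triplet_set", "data.frame"))
}

#' Summary statistics of a sponge network
#'
#' @param triplets One triplet set, or a named list of per-stage sets.
#' @return List with per-stage triplet counts, node counts by molecule
#'   type and the miRNA degree distribution (distinct targets per miRNA).
#' @export
network_stats <- function(triplets) {
  if (is.data.frame(triplets)) triplets <- list(all = triplets)
  per_stage <- vapply(triplets, nrow, integer(1))
  one <- function(tr) {
    list(n_triplets = nrow(tr),
         n_circ = length(unique(tr$circ_id)),
         n_mirna = length(unique(tr$mirna_id)),
         n_mrna = length(unique(tr$mrna_id)),
         mirna_degree = if (nrow(tr)) vapply(
           split(tr, tr$mirna_id),
           function(d) length(unique(d$circ_id)) +
             length(unique(d$mrna_id)), integer(1)) else
           setNames(integer(0), character(0)))
  }
  structure(list(triplet_counts = per_stage,
                 stages = lapply(triplets, one)),
            class = "network_stats")
}

#' @export
print.network_stats <- function(x, ...) {
  cat("sponge network:\n")
  for (nm in names(x$stages)) {
    s <- x$stages[[nm]]
    cat(sprintf(
      "  %-8s %4d triplet(s): %d circRNA(s), %d miRNA(s), %d mRNA(s)\n",
      nm, s$n_triplets, s$n_circ, s$n_mirna, s$n_mrna))
  }
  invisible(x)
}
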
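## sequence -> integer codes (A=1, C=2, G=3, T/U=4); errors on anything else
encode_seq <- function(x, what = "sequence") {
  x <- chartr("u", "t", tolower(x))
  v <- strsplit(x, "", fixed = TRUE)[[1]]
  code <- match(v, c("a", "c", "g", "t"))
  if (anyNA(code))
    stop("non-nucleotide character in ", what, ": ",
         v[which(is.na(code))[1]])
  code
}

## penalty lookup: rows = miRNA base, cols = target base (A,C,G,T).
## Watson-Crick pair -> 0; G:U wobble (miRNA G : target U, or miRNA U :
## target G) -> wobble penalty; otherwise mismatch penalty.
penalty_matrix <- function(wobble = 0.5, mismatch = 1) {
  P <- matrix(mismatch, 4, 4)
  P[cbind(1:4, 4:1)] <- 0          # A:T, C:G, G:C, T:A
  P[3, 4] <- wobble                # G : U
  P[4, 3] <- wobble                # U : G
  P
}

#' Penalty score of one miRNA/target window alignment
#'
#' Gapless plant-style penalty scoring. The target window is read 3'->5'
#' against the miRNA 5'->3', so miRNA position `i` pairs with window base
#' `m - i + 1`. Watson-Crick pairs cost 0, G:U wobbles 0.5, mismatches 1,
#' and every penalty is doubled in the seed region (miRNA positions
#' `seed_start`..`seed_end`, default 2-13). A score of 0 therefore means
#' perfect complementarity over the whole miRNA.
#'
#' @param mirna_seq miRNA sequence 5'->3' (RNA or DNA alphabet).
#' @param target_window Target subsequence 5'->3', same length as the
#'   miRNA.
#' @param seed_start,seed_end Seed region bounds (miRNA positions,
#'   inclusive).
#' @param wobble,mismatch Base penalties before seed doubling.
#' @return Numeric penalty score `S >= 0`.
#' @export
score_window <- function(mirna_seq, target_window, seed_start = 2L,
                         seed_end = 13L, wobble = 0.5, mismatch = 1) {
  mir <- encode_seq(mirna_seq, "miRNA")
  win <- encode_seq(target_window, "target window")
  if (length(mir) != length(win))
    stop("target window length (", length(win),
         ") must equal miRNA length (", length(mir), ")")
  m <- length(mir)
  P <- penalty_matrix(wobble, mismatch)
  wt <- ifelse(seq_len(m) >= seed_start & seq_len(m) <= seed_end, 2, 1)
  pen <- P[cbind(mir, win[m:1])]   # miRNA i pairs window m - i + 1
  sum(wt * pen)
}

## alignment glyphs per miRNA position: | = Watson-Crick, o = wobble,
## . = mismatch
alignment_string <- function(mir, win, P) {
  m <- length(mir)
  pen <- P[cbind(mir, win[m:1])]
  paste(ifelse(pen == 0, "|", ifelse(pen < 1, "o", ".")), collapse = "")
}

#' Scan a target sequence for the best miRNA site
#'
#' Slides a window of miRNA length over the target and returns the
#' minimum-penalty window. For circular targets the scan continues across
#' the junction: windows wrapping from the 3' end back into the 5' end
#' are included and flagged `junction_spanning`. Ties resolve to the
#' smallest start coordinate, linear windows before junction-spanning
#' ones.
#'
#' @param mirna_seq miRNA sequence 5'->3'.
#' @param target_seq Target sequence 5'->3'.
#' @param circular Scan junction-spanning windows too (default FALSE).
#' @inheritParams score_window
#' @return One-row data.frame with `start` (1-based on the target),
#'   `junction_spanning`, `score`, `alignment`, or `NULL` when the target
#'   is shorter than the miRNA (a message is emitted).
#' @export
scan_target <- function(mirna_seq, target_seq, circular = FALSE,
                        seed_start = 2L, seed_end = 13L, wobble = 0.5,
                        mismatch = 1) {
  mir <- encode_seq(mirna_seq, "miRNA")
  tgt <- encode_seq(target_seq, "target")
  m <- length(mir)
  L <- length(tgt)
  if (L < m) {
    message("target shorter than miRNA (", L, " < ", m, "); no hit")
    return(NULL)
  }
  ext <- if (circular) c(tgt, tgt[seq_len(m - 1L)]) else tgt
  n_win <- length(ext) - m + 1L
  P <- penalty_matrix(wobble, mismatch)
  wt <- ifelse(seq_len(m) >= seed_start & seq_len(m) <= seed_end, 2, 1)
  a <- mir[m:1]                    # reversed miRNA: a[j] pairs window j
  aw <- wt[m:1]
  scores <- numeric(n_win)
  for (j in seq_len(m))
    scores <- scores + aw[j] * P[a[j], ext[j:(j + n_win - 1L)]]
  best <- which.min(scores)        # ties -> smallest start (linear first)
  win <- ext[best:(best + m - 1L)]
  data.frame(start = as.integer(best),
             junction_spanning = best > L - m + 1L,
             score = scores[best],
             alignment = alignment_string(mir, win, P),
             stringsAsFactors = FALSE)
}

#' Predict miRNA targets under per-molecule score cutoffs
#'
#' Scans every (miRNA, target) pair with [scan_target()] and keeps the
#' best hit per pair when its penalty score is at or below the cutoff for
#' the target's molecule type (defaults: 4 for mRNA, 4.5 for circRNA;
#' both inclusive). circRNA targets are scanned circularly.
#'
#' @param mirnas Named character vector (or `DNAStringSet`/`RNAStringSet`)
#'   of miRNA sequences.
#' @param targets Named character vector (or `XStringSet`) of target
#'   sequences.
#' @param target_kind Either one of `"mRNA"`/`"circRNA"` for all targets,
#'   or a vector parallel to `targets`.
#' @param cutoffs Named numeric, inclusive score cutoffs per kind.
#' @inheritParams score_window
#' @return data.frame of retained hits: `mirna_id`, `target_id`, `kind`,
#'   `start`, `junction_spanning`, `score`, `alignment`.
#' @export
predict_targets <- function(mirnas, targets, target_kind = "mRNA",
                            cutoffs = c(mRNA = 4, circRNA = 4.5),
                            seed_start = 2L, seed_end = 13L,
                            wobble = 0.5, mismatch = 1) {
  if (methods::is(mirnas, "XStringSet"))
    mirnas <- setNames(as.character(mirnas), names(mirnas))
  if (methods::is(targets, "XStringSet"))
    targets <- setNames(as.character(targets), names(targets))
  if (length(target_kind) == 1L)
    target_kind <- rep(target_kind, length(targets))
  stopifnot(length(target_kind) == length(targets),
            all(target_kind %in% names(cutoffs)))
  hits <- list()
  for (mi in seq_along(mirnas)) {
    for (ti in seq_along(targets)) {
      h <- scan_target(mirnas[[mi]], targets[[ti]],
                       circular = target_kind[ti] == "circRNA",
                       seed_start = seed_start, seed_end = seed_end,
                       wobble = wobble, mismatch = mismatch)
      if (is.null(h) || h$score > cutoffs[[target_kind[ti]]]) next
      hits[[length(hits) + 1L]] <- data.frame(
        mirna_id = names(mirnas)[mi], target_id = names(targets)[ti],
        kind = target_kind[ti], h, stringsAsFactors = FALSE)
    }
  }
  if (!length(hits))
    return(data.frame(mirna_id = character(0), target_id = character(0),
                      kind = character(0), start = integer(0),
                      junction_spanning = logical(0), score = numeric(0),
                      alignment = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties (via
#' [stats::cor()][stats::cor]). Returns `NA` when either vector is
#' constant, where the coefficient is undefined.
#'
#' @param x,y Equal-length numeric vectors, length >= 3.
#' @return rho in \[-1, 1\], or `NA_real_` when undefined.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    return(NA_real_)
  unname(stats::cor(x, y, method = "spearman"))
}

## profile lookup that tolerates expression_matrix or plain matrix
expr_profile <- function(expr, id) {
  E <- if (inherits(expr, "expression_matrix")) expr$E else expr
  if (!id %in% rownames(E)) return(NULL)
  E[id, ]
}

#' Filter target hits by miRNA anti-correlation
#'
#' A sponge interaction is only plausible when the miRNA and its target
#' are anti-correlated in expression. Each hit passes when the Spearman
#' correlation between the miRNA and target normalized profiles over the
#' full time course is at or below `rho_max` (default -0.5, inclusive).
#' Hits with an undefined correlation (constant profile) or a missing
#' profile fail and are noted.
#'
#' @param hits data.frame from [predict_targets()].
#' @param mirna_expr,target_expr `expression_matrix` objects (or plain
#'   matrices of normalized profiles) keyed by feature id.
#' @param rho_max Inclusive correlation ceiling (default -0.5).
#' @return `hits` with added `rho` and `passed` columns.
#' @export
anticorrelation_filter <- function(hits, mirna_expr, target_expr,
                                   rho_max = -0.5) {
  if (nrow(hits) == 0L) {
    hits$rho <- numeric(0); hits$passed <- logical(0)
    return(hits)
  }
  rho <- vapply(seq_len(nrow(hits)), function(i) {
    xm <- expr_profile(mirna_expr, hits$mirna_id[i])
    xt <- expr_profile(target_expr, hits$target_id[i])
    if (is.null(xm) || is.null(xt)) {
      message("missing expression profile for hit ", hits$mirna_id[i],
              " -> ", hits$target_id[i], "; hit fails the filter")
      return(NA_real_)
    }
    spearman_rho(xm, xt)
  }, numeric(1))
  hits$rho <- rho
  hits$passed <- !is.na(rho) & rho <= rho_max
  hits
}
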
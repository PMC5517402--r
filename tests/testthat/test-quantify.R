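mk_counts <- function(rows, ids = sprintf("f%02d", seq_along(rows))) {
  m <- do.call(rbind, rows)
  dimnames(m) <- list(ids, paste0("day_", seq(4, 30, 2)))
  m
}

test_that("pseudocounted per-million normalization is exact", {
  m <- matrix(c(0L, 3L, 15L), 1)
  e <- normalize_expression(m, c(1e6, 1e6, 2e6))
  expect_equal(as.numeric(e$E), c(1, 4, 8))
  expect_error(normalize_expression(m, c(1e6, 0, 1e6)), "positive")
  expect_error(normalize_expression(m, c(1e6, 1e6)), "match")
})

test_that("stage fold changes use each stage's own reference day", {
  cfg <- stage_config()
  counts <- mk_counts(list(rep(7L, 14), c(3L, 15L, rep(3L, 12))))
  expr <- normalize_expression(counts, rep(1e6, 14))
  fc_g <- log2_fold_changes(expr, cfg, "G-to-M")
  expect_equal(dim(fc_g), c(2L, 7L))
  expect_equal(unname(fc_g[1, ]), rep(0, 7))        # constant profile
  expect_equal(unname(fc_g[1 + 1, "day_6"]), 2)     # 16/4 -> +2
  fc_m <- log2_fold_changes(expr, cfg, "M-to-S")
  expect_equal(attr(fc_m, "ref_day"), 16)
  expect_equal(colnames(fc_m)[1], "day_18")
  # antisymmetry: swapping reference and target negates the fold change
  counts2 <- mk_counts(list(c(15L, 3L, rep(15L, 12))))
  fc2 <- log2_fold_changes(normalize_expression(counts2, rep(1e6, 14)),
                           cfg, "G-to-M")
  expect_equal(unname(fc2[1, "day_6"]), -2)
})

test_that("DE calls are inclusive at the threshold and break ties late", {
  cfg <- stage_config()
  fc <- matrix(c(2, 0, 0, 0, 0, 0, 0,
                 1.9, 0, 0, 0, 0, 0, 0,
                 0, 0, 0, 0, 2.5, 0, -2.5),
               nrow = 3, byrow = TRUE,
               dimnames = list(c("at", "below", "tie"),
                               paste0("day_", seq(6, 18, 2))))
  attr(fc, "stage") <- "G-to-M"
  de <- call_de(fc, threshold = 2)
  expect_equal(de$is_de, c(TRUE, FALSE, TRUE))
  # |FC| tie between +2.5 (day 14) and -2.5 (day 18): the later day wins
  expect_equal(de$direction[de$feature_id == "tie"], "down")
  # final-day-only mode gates on the last stage day
  de2 <- call_de(fc, threshold = 2, final_day_only = TRUE)
  expect_equal(de2$is_de, c(FALSE, FALSE, TRUE))
})

test_that("fold changes are invariant to library-size scaling", {
  withr::with_seed(42L, {
    counts <- matrix(rpois(5 * 14, 20), 5,
                     dimnames = list(sprintf("f%d", 1:5),
                                     paste0("day_", seq(4, 30, 2))))
    lib <- runif(14, 1e6, 2e6)
    cfg <- stage_config()
    fc1 <- log2_fold_changes(normalize_expression(counts, lib), cfg,
                             "M-to-S")
    fc2 <- log2_fold_changes(normalize_expression(counts, lib * 3.7),
                             cfg, "M-to-S")
    expect_equal(fc1, fc2)
  })
})

test_that("planting 4*(n_ref+1)-1 reads forces a fold change of exactly 2", {
  cfg <- stage_config()
  counts <- mk_counts(list(rep(5L, 14)))
  counts[1, "day_24"] <- 4L * (counts[1, "day_16"] + 1L) - 1L
  fc <- log2_fold_changes(normalize_expression(counts, rep(1e6, 14)),
                          cfg, "M-to-S")
  expect_equal(unname(fc[1, "day_24"]), 2)
  expect_true(call_de(fc)$is_de)
})

test_that("detection summary counts, retains and stages features", {
  cfg <- stage_config()
  counts <- mk_counts(list(
    rep(0L, 14),                       # never detected
    c(1L, rep(0L, 13)),                # G-window singleton
    c(rep(0L, 6), 2L, rep(0L, 7)),     # day-16 singleton: both stages
    rep(1L, 14)))                      # everywhere
  det <- detection_summary(counts, cfg, min_samples = 2)
  expect_equal(unname(det$detection), c(0L, 1L, 1L, 14L))
  expect_equal(det$retained, "f04")
  expect_setequal(det$stage_sets[["G-to-M"]], c("f02", "f03", "f04"))
  expect_setequal(det$stage_sets[["M-to-S"]], c("f03", "f04"))
  v <- det$venn
  expect_equal(unname(v[["intersection"]]), 2L)
  expect_equal(unname(v[["union"]]), 3L)
  # without the shared days 16/18 the day-16 singleton is in neither set
  expect_setequal(det$stage_sets_excluding_shared[["M-to-S"]], "f04")

  # Venn identity holds on random detection matrices
  withr::with_seed(9L, {
    for (i in 1:20) {
      m <- matrix(rbinom(30 * 14, 1, 0.2), 30,
                  dimnames = list(sprintf("r%02d", 1:30),
                                  paste0("day_", seq(4, 30, 2))))
      d <- detection_summary(m, cfg)
      vv <- d$venn
      expect_equal(vv[["G-to-M"]] + vv[["M-to-S"]] -
                     vv[["intersection"]], unname(vv[["union"]]))
    }
  })
})

test_that("adding reads never shrinks the retained set", {
  cfg <- stage_config()
  withr::with_seed(3L, {
    m <- matrix(rpois(20 * 14, 0.4), 20,
                dimnames = list(sprintf("r%02d", 1:20),
                                paste0("day_", seq(4, 30, 2))))
    before <- detection_summary(m, cfg)$retained
    m2 <- m
    m2[sample(length(m2), 30)] <- m2[sample(length(m2), 30)] + 2L
    after <- detection_summary(m2, cfg)$retained
    expect_true(all(before %in% after))
  })
})

test_that("host concordance counts up-up pairs and reports correlations", {
  cfg <- stage_config()
  up <- c(1L, 1L, 1L, 1L, 1L, 1L, 1L, 2L, 4L, 8L, 16L, 16L, 16L, 16L)
  flat <- rep(5L, 14)
  strict_up <- c(1:7, 20L, 40L, 60L, 80L, 100L, 120L, 140L)
  strict_down <- seq(140L, 10L, by = -10L)
  circ_counts <- mk_counts(list(up, up, strict_up), c("c1", "c2", "c3"))
  gene_counts <- mk_counts(list(up, flat, strict_down),
                           c("g1", "g2", "g3"))
  ce <- normalize_expression(circ_counts, rep(1e6, 14))
  ge <- normalize_expression(gene_counts, rep(1e6, 14))
  cd <- call_de(log2_fold_changes(ce, cfg, "M-to-S"))
  gd <- call_de(log2_fold_changes(ge, cfg, "M-to-S"))
  hm <- data.frame(circ_id = c("c1", "c2", "c3"),
                   gene_id = c("g1", "g2", "g3"))
  hc <- host_concordance(cd, gd, ce, ge, hm)
  st <- hc$per_stage[hc$per_stage$stage == "M-to-S", ]
  expect_equal(st$n_up_circ, 3L)
  expect_equal(st$n_concordant, 1L)   # only g1 rises with its circRNA
  expect_equal(st$fraction, 1 / 3)
  # identical profiles correlate perfectly; mirrored ones perfectly
  # negatively
  expect_equal(hc$pairs$rho[hc$pairs$circ_id == "c1"], 1)
  expect_equal(hc$pairs$rho[hc$pairs$circ_id == "c3"], -1)
})

test_that("stage configuration validates its windows", {
  expect_error(stage_config(stages = list(S = list(days = c(4, 99),
                                                   ref = 4))),
               "outside")
  expect_error(stage_config(stages = list(S = list(days = c(4, 6),
                                                   ref = 8))),
               "reference")
})
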
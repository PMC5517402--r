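test_that("window scoring follows the penalty rules", {
  mir <- "UGACCUAUGAAUUGACAGCCA"          # 21 nt, RNA alphabet
  site <- revcomp(chartr("U", "T", mir))  # perfect complement
  expect_equal(score_window(mir, site), 0)

  # a mismatch at miRNA position 5 sits in the seed: penalty 1 * 2
  s5 <- site
  pos <- nchar(site) - 5 + 1              # target base pairing position 5
  bad <- setdiff(c("A", "C", "G", "T"),
                 c(substr(site, pos, pos),
                   chartr("ACGT", "TGCA", substr(chartr("U", "T", mir),
                                                 5, 5)),
                   if (substr(chartr("U", "T", mir), 5, 5) %in%
                       c("G", "T"))
                     chartr("GT", "TG", substr(chartr("U", "T", mir),
                                               5, 5))))[1]
  substr(s5, pos, pos) <- bad
  expect_equal(score_window(mir, s5), 2)

  # same mutation outside the seed costs the base penalty: the doubling
  # rule means seed and non-seed versions differ by exactly 1
  mir2 <- paste(rep("A", 21), collapse = "")
  site2 <- paste(rep("T", 21), collapse = "")
  seed_mut <- site2; substr(seed_mut, 21 - 5 + 1, 21 - 5 + 1) <- "C"
  non_seed <- site2; substr(non_seed, 21 - 15 + 1, 21 - 15 + 1) <- "C"
  expect_equal(score_window(mir2, seed_mut) -
                 score_window(mir2, non_seed), 1)

  # G:U wobble at position 15 (non-seed): 0.5
  mirg <- paste(c(rep("A", 14), "G", rep("A", 6)), collapse = "")
  # position 15 pairs target base 21-15+1 = 7; complement C -> T = wobble
  sg <- revcomp(mirg)
  substr(sg, 7, 7) <- "T"
  expect_equal(score_window(mirg, sg), 0.5)

  expect_error(score_window("ACGU", "ACG"), "length")
  expect_error(score_window("ACNU", "ACGU"), "non-nucleotide")
  # T and U are interchangeable on input
  expect_equal(score_window("ACGU", revcomp("ACGT")),
               score_window("ACGT", revcomp("ACGT")))
})

test_that("scores are monotone under added mismatches", {
  withr::with_seed(5L, {
    mir <- rand_seq(21)
    site <- revcomp(mir)
    s_prev <- score_window(mir, site)
    mutated <- site
    for (pos in sample(21, 10)) {
      old <- substr(mutated, pos, pos)
      substr(mutated, pos, pos) <- setdiff(c("A", "C", "G", "T"), old)[1]
      s_new <- score_window(mir, mutated)
      expect_gte(s_new, s_prev)
      s_prev <- s_new
    }
  })
})

test_that("target scanning finds embedded and junction-spanning sites", {
  withr::with_seed(21L, {
    mir <- rand_seq(21)
    target <- paste0(rand_seq(80), revcomp(mir), rand_seq(60))
    hit <- scan_target(mir, target)
    expect_equal(hit$score, 0)
    expect_equal(hit$start, 81L)
    expect_false(hit$junction_spanning)

    # a site split across the circular junction: last 10 nt + first 11 nt
    site <- revcomp(mir)
    circ <- paste0(substr(site, 11, 21), rand_seq(100),
                   substr(site, 1, 10))
    lin <- scan_target(mir, circ, circular = FALSE)
    expect_gt(lin$score, 0)
    wrap <- scan_target(mir, circ, circular = TRUE)
    expect_equal(wrap$score, 0)
    expect_true(wrap$junction_spanning)
    expect_equal(wrap$start, 112L)     # L - 10 + 1

    # shorter targets than the miRNA yield no hit
    expect_message(h <- scan_target(mir, rand_seq(10)), "shorter")
    expect_null(h)
  })
})

test_that("scanning agrees with brute-force enumeration", {
  withr::with_seed(31L, {
    for (i in 1:25) {
      mir <- rand_seq(21)
      target <- rand_seq(sample(50:200, 1))
      circular <- i %% 2 == 0
      got <- scan_target(mir, target, circular = circular)
      want <- oracle_scan(mir, target, circular = circular)
      expect_equal(got$score, want$score)
      expect_equal(got$start, want$start)
      expect_equal(got$junction_spanning, want$junction_spanning)
    }
  })
})

test_that("per-kind cutoffs are inclusive", {
  withr::with_seed(8L, {
    mir <- c(m1 = rand_seq(21))
    perfect <- revcomp(mir)
    # four non-seed mismatches -> S = 4.0 exactly; one more wobble-free
    # mismatch would overshoot, so add a non-seed wobble for S = 4.5
    s4 <- perfect
    for (pos in 1:4) {              # target positions 1..4 pair miRNA 18..21
      old <- substr(s4, pos, pos)
      comp <- chartr("ACGT", "TGCA", substr(mir, 21 - pos + 1, 21 - pos + 1))
      repl <- setdiff(c("A", "C", "G", "T"),
                      c(old, comp,
                        if (substr(mir, 21 - pos + 1, 21 - pos + 1) %in%
                            c("G", "T"))
                          chartr("GT", "TG",
                                 substr(mir, 21 - pos + 1, 21 - pos + 1))))[1]
      substr(s4, pos, pos) <- repl
    }
    expect_equal(score_window(mir[[1]], s4), 4)

    tg <- c(t1 = paste0(rand_seq(30), s4, rand_seq(30)))
    hit_mrna <- predict_targets(mir, tg, "mRNA")
    expect_equal(nrow(hit_mrna), 1L)    # S = 4.0 retained (inclusive)

    # push to S = 4.5 with a non-seed wobble at miRNA position 16 when
    # possible, otherwise a mismatch for S = 5; test both gates
    mir_g <- c(m2 = paste0(substr(mir, 1, 15), "G", substr(mir, 17, 21)))
    s45 <- revcomp(mir_g)
    for (pos in 1:4) {
      old <- substr(s45, pos, pos)
      comp <- chartr("ACGT", "TGCA",
                     substr(mir_g, 21 - pos + 1, 21 - pos + 1))
      repl <- setdiff(c("A", "C", "G", "T"),
                      c(old, comp,
                        if (substr(mir_g, 21 - pos + 1, 21 - pos + 1) %in%
                            c("G", "T"))
                          chartr("GT", "TG",
                                 substr(mir_g, 21 - pos + 1,
                                        21 - pos + 1))))[1]
      substr(s45, pos, pos) <- repl
    }
    substr(s45, 6, 6) <- "T"            # G:U wobble at miRNA position 16
    expect_equal(score_window(mir_g[[1]], s45), 4.5)
    tg45 <- c(t2 = paste0(rand_seq(30), s45, rand_seq(30)))
    expect_equal(nrow(predict_targets(mir_g, tg45, "mRNA")), 0L)
    expect_equal(nrow(predict_targets(mir_g, tg45, "circRNA")), 1L)

    expect_equal(nrow(predict_targets(character(0), tg, "mRNA")), 0L)
  })
})

test_that("spearman_rho matches hand ranking and flags degeneracy", {
  expect_equal(spearman_rho(1:10, 1:10), 1)
  expect_equal(spearman_rho(1:10, 10:1), -1)
  expect_error(spearman_rho(1:2, 1:2), "3")
  expect_error(spearman_rho(1:3, 1:4), "length")
  expect_true(is.na(spearman_rho(rep(2, 5), 1:5)))
  withr::with_seed(13L, {
    for (i in 1:20) {
      x <- sample(1:4, 6, replace = TRUE)
      y <- sample(1:4, 6, replace = TRUE)
      if (length(unique(x)) == 1 || length(unique(y)) == 1) next
      expect_equal(spearman_rho(x, y), oracle_spearman(x, y))
    }
  })
  # invariance under strictly monotone transforms
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  y <- c(2, 7, 1, 8, 2.8, 1.8)
  expect_equal(spearman_rho(exp(x), y^3), spearman_rho(x, y))
})

test_that("the anti-correlation filter is inclusive, strict and idempotent",
{
  hits <- data.frame(
    mirna_id = c("m1", "m1", "m2"),
    target_id = c("tA", "tB", "tC"), kind = "mRNA",
    start = 1L, junction_spanning = FALSE, score = 0,
    alignment = "", stringsAsFactors = FALSE)
  prof <- rbind(m1 = c(1, 2, 3), m2 = c(2, 2, 2),
                tA = c(3, 1, 2),           # rho(m1, tA) = -0.5 exactly
                tB = c(1, 3, 2),           # rho(m1, tB) = +0.5
                tC = c(1, 2, 3))
  out <- suppressMessages(
    anticorrelation_filter(hits, prof, prof, rho_max = -0.5))
  expect_equal(out$rho[1], -0.5)
  expect_true(out$passed[1])               # -0.5 passes (inclusive)
  expect_false(out$passed[2])              # above the ceiling fails
  expect_false(out$passed[3])              # constant miRNA: undefined rho
  expect_true(is.na(out$rho[3]))

  # idempotent: filtering a filtered set changes nothing
  out2 <- suppressMessages(
    anticorrelation_filter(out, prof, prof, rho_max = -0.5))
  expect_equal(out2, out)

  # missing profiles fail the hit with a message
  expect_message(
    miss <- anticorrelation_filter(hits[2, ], prof[c("m1", "tA"), ],
                                   prof[c("m1", "tA"), ]),
    "missing")
  expect_false(miss$passed)
})
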
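small_params <- function(seed = 1L, ...) {
  sim_params(seed = seed, n_circ = 20L, n_genes = 10L,
             nuclear_chroms = c(Chr1 = 60000L, Chr2 = 60000L), ...)
}

test_that("the generator is deterministic in its seed", {
  a <- simulate_dataset(small_params(seed = 4L))
  b <- simulate_dataset(small_params(seed = 4L))
  expect_identical(a$bsj, b$bsj)
  expect_identical(a$gene_counts, b$gene_counts)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$mirna_seqs, b$mirna_seqs)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_dataset(small_params(seed = 4L), dir = d1)
  simulate_dataset(small_params(seed = 4L), dir = d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     info = f)

  c2 <- simulate_dataset(small_params(seed = 5L))
  expect_false(identical(as.character(a$genome),
                         as.character(c2$genome)))
})

test_that("emitted files round-trip through the readers", {
  d <- withr::local_tempdir()
  sim <- simulate_dataset(small_params(seed = 2L), dir = d)
  bsj <- read_bsj_table(file.path(d, "bsj.tsv"),
                        n_samples = length(sim$cfg$days))
  expect_equal(as.data.frame(bsj), as.data.frame(sim$bsj))
  gc <- read_count_matrix(file.path(d, "gene_counts.tsv"))
  expect_equal(gc$counts, sim$gene_counts)
  expect_equal(unname(gc$lib_sizes), sim$gene_lib_sizes)
  ann <- read_gff3(file.path(d, "annotation.gff3"))
  expect_equal(ann$genes, sim$annotation$genes)
  fa <- Biostrings::readDNAStringSet(file.path(d, "mirna.fa"))
  expect_equal(as.character(fa), sim$mirna_seqs)
  known <- read_known_circs(file.path(d, "known_circs.tsv"))
  expect_equal(known, sim$known)
})

test_that("planted categories are recovered by classification", {
  sim <- simulate_dataset(small_params(seed = 3L))
  rec <- classify_junctions(sim$bsj, sim$annotation)
  expect_equal(rec$category, unname(sim$truth$categories))
  expect_equal(rec$host_gene[!is.na(rec$host_gene)],
               unname(sim$truth$hosts[!is.na(sim$truth$hosts)]))

  # an all-boundary mixture comes back 100% boundary-matched
  pure <- simulate_dataset(small_params(
    seed = 6L, category_mix = c(EXONIC_BOTH_BOUNDARY = 1,
                                EXONIC_BOTH_INTERNAL = 0,
                                EXONIC_ONE_BOUNDARY = 0,
                                INTERGENIC = 0)))
  recp <- classify_junctions(pure$bsj, pure$annotation)
  expect_true(all(recp$category == "EXONIC_BOTH_BOUNDARY"))
})

test_that("planted miRNA sites are perfect hits in their targets", {
  sim <- simulate_dataset(small_params(seed = 9L))
  rec <- classify_junctions(sim$bsj, sim$annotation)
  pm <- sim$truth$planted_targets
  expect_gt(nrow(pm), 0L)
  for (i in seq_len(nrow(pm))) {
    mrna <- extract_transcript_sequence(pm$target_gene[i], sim$genome,
                                        sim$annotation)
    expect_equal(scan_target(sim$mirna_seqs[[pm$mirna_id[i]]],
                             mrna)$score, 0)
    if (!is.na(pm$target_circ[i])) {
      crec <- rec[rec$circ_id == pm$target_circ[i], ]
      cs <- extract_circ_sequence(crec, sim$genome, sim$annotation)
      expect_equal(scan_target(sim$mirna_seqs[[pm$mirna_id[i]]],
                               cs$sequence, circular = TRUE)$score, 0)
    }
  }
})

test_that("planted trajectories honor the declared fold at the reference",
{
  tc <- sim_time_course("logistic_up", baseline = 0.1, fold = 4,
                        anchor_day = 16, dispersion = 0)
  mu <- attr(tc, "mu")
  days <- seq(4, 30, 2)
  expect_equal(mu[days == 16], 0.1)
  expect_equal((mu[days == 30] + 1) / (mu[days == 16] + 1), 4)
  expect_true(all(mu[days < 16] == 0.1))

  td <- sim_time_course("logistic_down", baseline = 10, fold = 4,
                        anchor_day = 16, dispersion = 0)
  mud <- attr(td, "mu")
  expect_equal((mud[days == 16] + 1) / (mud[days == 30] + 1), 4)
})

test_that("infeasible parameters fail before emission", {
  expect_error(simulate_dataset(sim_params(
    n_genes = 500L, nuclear_chroms = c(Chr1 = 30000L, Chr2 = 30000L))),
    "infeasible")
  expect_error(simulate_dataset(small_params(exon_length = 40L)),
    "infeasible")
  expect_error(sim_params(category_mix = c(EXONIC_BOTH_BOUNDARY = 0.5,
                                           EXONIC_BOTH_INTERNAL = 0.2,
                                           EXONIC_ONE_BOUNDARY = 0.2,
                                           INTERGENIC = 0.2)),
               "sum to 1")
  expect_error(sim_params(bogus_knob = 3), "unknown")
})
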
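jx <- function(chrom, start, end, strand = "+")
  list(chrom = chrom, start = start, end = end, strand = strand)

test_that("exon-boundary breakpoints give the boundary-matched category", {
  ann <- toy_annotation()
  # exon2 start to exon4 end of gA (exons at 1401-1600 and 2201-2400)
  r <- classify_bsj(jx("Chr1", 1401L, 2400L), ann)
  expect_equal(r$category, "EXONIC_BOTH_BOUNDARY")
  expect_equal(r$host_gene, "gA")
  expect_equal(r$exon_span, 3L)
})

test_that("gene-free scaffolds and intron pairs classify as expected", {
  ann <- toy_annotation()
  r <- classify_bsj(jx("scaffold1", 100L, 900L), ann)
  expect_equal(r$category, "INTERGENIC")
  expect_equal(r$exon_span, 0L)
  expect_true(is.na(r$host_gene))

  # both breakpoints in gA introns (1201-1400 and 1601-1800)
  r2 <- classify_bsj(jx("Chr1", 1250L, 1700L), ann)
  expect_equal(r2$category, "INTRONIC")
})

test_that("single off-boundary breakpoints and tolerance behave", {
  ann <- toy_annotation()
  # one breakpoint at exon edge, the other 7 nt inside an exon
  r <- classify_bsj(jx("Chr1", 1401L, 2393L), ann)
  expect_equal(r$category, "EXONIC_ONE_BOUNDARY")
  expect_equal(r$category, oracle_classify(jx("Chr1", 1401L, 2393L), ann))

  # with tolerance 0 both-boundary needs exact equality at both edges
  expect_equal(classify_bsj(jx("Chr1", 1402L, 2400L), ann)$category,
               "EXONIC_ONE_BOUNDARY")
  # a 7-nt offset is forgiven at tolerance 7 but not 6
  expect_equal(classify_bsj(jx("Chr1", 1401L, 2393L), ann,
                            boundary_tolerance = 7L)$category,
               "EXONIC_BOTH_BOUNDARY")
  expect_equal(classify_bsj(jx("Chr1", 1401L, 2393L), ann,
                            boundary_tolerance = 6L)$category,
               "EXONIC_ONE_BOUNDARY")
})

test_that("strand mismatches and cross-gene junctions are ambiguous", {
  ann <- toy_annotation()
  # both breakpoints in gB exons but on the wrong strand
  expect_equal(classify_bsj(jx("Chr1", 5001L, 6999L, "+"), ann)$category,
               "AMBIGUOUS")
  expect_equal(classify_bsj(jx("Chr1", 5001L, 6999L, "-"), ann)$category,
               "EXONIC_BOTH_BOUNDARY")
  # one breakpoint in gA, one in gB (different genes)
  expect_equal(classify_bsj(jx("Chr1", 1100L, 5100L, "+"), ann)$category,
               "AMBIGUOUS")
  # unknown chromosome errors
  expect_error(classify_bsj(jx("Chr9", 10L, 90L), ann), "chromosome")
})

test_that("classification matches the exhaustive oracle on random junctions",
{
  withr::with_seed(11L, {
    for (rep in 1:5) {
      ann <- random_toy_annotation()
      L <- ann$chromosomes$length[1]
      for (i in 1:40) {
        s <- sample.int(L - 500L, 1)
        e <- s + sample.int(400L, 1)
        j <- jx("ChrR", s, e, sample(c("+", "-"), 1))
        expect_equal(classify_bsj(j, ann)$category,
                     oracle_classify(j, ann))
      }
    }
  })
})

test_that("class summaries reproduce printed-table arithmetic", {
  cats <- rep(c("EXONIC_BOTH_BOUNDARY", "EXONIC_BOTH_INTERNAL",
                "EXONIC_ONE_BOUNDARY", "INTERGENIC"),
              c(134, 8, 16, 10))
  rec <- data.frame(circ_id = sprintf("c%03d", seq_along(cats)),
                    category = cats, exon_span = 1L,
                    organelle = "nuclear", is_novel = NA)
  cs <- summarize_classes(rec)
  expect_equal(unname(cs$percentages[1:6]),
               c(79.8, 4.8, 9.5, 0, 5.9, 0))
  expect_equal(cs$exonic_total, 158L)
  expect_equal(cs$exonic_percentage, 94.1)
  expect_equal(unname(cs$percent_of_exonic), c(84.8, 5.1, 10.1))
  expect_equal(sum(cs$counts), 168L)
  # percentages are a partition of 100 by construction
  expect_equal(sum(cs$percentages), 100)

  one <- summarize_classes(rec[rec$category == "INTERGENIC", ][1, ])
  expect_equal(unname(one$percentages[["INTERGENIC"]]), 100.0)

  empty <- summarize_classes(rec[0, ])
  expect_equal(empty$total, 0L)
  expect_true(all(is.na(empty$percentages)))
})

test_that("novelty flagging honors slack and empty catalogues", {
  rec <- data.frame(circ_id = c("a", "b"), chrom = "Chr1",
                    start = c(100L, 500L), end = c(300L, 900L),
                    strand = "+", is_novel = NA,
                    stringsAsFactors = FALSE)
  known <- data.frame(chrom = "Chr1", start = 101L, end = 299L,
                      strand = "+", stringsAsFactors = FALSE)
  expect_equal(flag_novel(rec, known, slack = 0L)$is_novel,
               c(TRUE, TRUE))
  expect_equal(flag_novel(rec, known, slack = 2L)$is_novel,
               c(FALSE, TRUE))
  # strand must match even within slack
  known$strand <- "-"
  expect_equal(flag_novel(rec, known, slack = 5L)$is_novel,
               c(TRUE, TRUE))
  expect_true(all(flag_novel(rec, known[0, ])$is_novel))
})

test_that("circular sequence extraction splices and wraps correctly", {
  ann <- toy_annotation()
  genome <- toy_genome(ann)
  chr1 <- as.character(genome[["Chr1"]])

  # single-exon circRNA equals the genomic substring
  rec <- list(chrom = "Chr1", start = 1001L, end = 1200L, strand = "+",
              category = "EXONIC_BOTH_BOUNDARY", host_gene = "gA")
  ext <- extract_circ_sequence(rec, genome, ann)
  expect_equal(nchar(ext$sequence), 200L)
  expect_equal(ext$sequence, substr(chr1, 1001, 1200))

  # the intron between exon1 and exon2 is spliced out
  rec2 <- list(chrom = "Chr1", start = 1001L, end = 1600L, strand = "+",
               category = "EXONIC_BOTH_BOUNDARY", host_gene = "gA")
  ext2 <- extract_circ_sequence(rec2, genome, ann)
  expect_equal(ext2$sequence,
               paste0(substr(chr1, 1001, 1200), substr(chr1, 1401, 1600)))

  # junction window is last k-1 plus first k-1 bases
  ext3 <- extract_circ_sequence(rec, genome, ann, junction_window_k = 22L)
  expect_equal(nchar(ext3$junction_window), 42L)
  expect_equal(ext3$junction_window,
               paste0(substr(ext3$sequence, 180, 200),
                      substr(ext3$sequence, 1, 21)))

  # minus strand is reverse-complemented
  recm <- list(chrom = "Chr1", start = 5001L, end = 5300L, strand = "-",
               category = "EXONIC_BOTH_BOUNDARY", host_gene = "gB")
  extm <- extract_circ_sequence(recm, genome, ann)
  expect_equal(extm$sequence, revcomp(substr(chr1, 5001, 5300)))

  # spans beyond the chromosome error out
  bad <- list(chrom = "scaffold1", start = 2900L, end = 3200L,
              strand = "+", category = "INTERGENIC",
              host_gene = NA_character_)
  expect_error(extract_circ_sequence(bad, genome, ann), "exceeds")
})
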
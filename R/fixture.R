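#' Deterministic benchmark fixture
#'
#' Builds, by explicit construction rather than sampling, a small dataset
#' whose summary statistics jointly realize the benchmark constraints of
#' the leaf lifespan setting it emulates: 168 circRNAs in categories
#' 134/8/16/10 (exact-boundary / internal / one-boundary / intergenic),
#' 3 of the 10 intergenic circRNAs on the chloroplast genome and none on
#' the mitochondrial one, a known-coordinate list leaving exactly 40
#' novel circRNAs, 142 of the 158 exonic records spanning 1-5 host
#' exons, a detection profile with 104 single-sample circRNAs, 7 seen in
#' more than 10 samples and 64 retained in at least two, stage detection
#' sets of 66 and 144 with 42 shared, 6 and 35 differentially expressed
#' circRNAs per stage (5+1 and 34+1 up/down, 3 shared), 9 of the 34
#' senescence-up circRNAs with an up-regulated host transcript, and a
#' sponge network of 20 and 220 triplets per stage.
#'
#' Library sizes are equal within each assay, so fold changes reflect the
#' counts exactly; every planted miRNA site is a perfect complement
#' embedded in an exon covered by its target circRNA or transcript. The
#' construction is seeded internally and returns identical objects on
#' every call.
#'
#' @param dir Optional directory; when given, all input files are written
#'   in their on-disk formats (same layout as [simulate_dataset()]).
#' @return List with the same elements as [simulate_dataset()] plus a
#'   `truth` list recording roles, planted DE calls, concordant hosts and
#'   the planted network.
#' @export
make_benchmark_fixture <- function(dir = NULL) {
  with_seed(168L, {
    days <- seq(4, 30, by = 2)
    day_cols <- paste0("day_", days)
    exon_len <- 150L; intron_len <- 100L; n_exons <- 7L
    gene_len <- n_exons * exon_len + (n_exons - 1L) * intron_len # 1650
    step <- 2500L

    ## ---- gene grid: 158 hosts + 22 senescence mRNA targets (t) +
    ## ---- 5 growth mRNA targets (u) -----------------------------------
    n_genes <- 185L
    gene_ids <- sprintf("g%03d", 1:n_genes)
    on_chr1 <- 1:93
    chrom_of <- ifelse(seq_len(n_genes) %in% on_chr1, "Chr1", "Chr2")
    pos_on <- c(seq_along(on_chr1), seq_len(n_genes - length(on_chr1)))
    starts <- 1001L + (pos_on - 1L) * step
    ## genes carrying planted sites stay on the plus strand; the rest
    ## alternate
    site_genes <- c(8:20, 159:185)
    strands <- ifelse(seq_len(n_genes) %in% site_genes, "+",
                      c("+", "-")[(seq_len(n_genes) %% 2L) + 1L])
    gm <- make_genes(gene_ids, chrom_of, starts, strands,
                     rep(n_exons, n_genes), rep(exon_len, n_genes),
                     rep(intron_len, n_genes))
    chromosomes <- data.frame(
      id = c("Chr1", "Chr2", "ChrC", "ChrM"),
      length = c(250000L, 250000L, 20000L, 10000L),
      stringsAsFactors = FALSE)
    ann <- genome_annotation(chromosomes, gm$genes, gm$exons)

    ## ---- circRNA roles (expression classes) --------------------------
    n_circ <- 168L
    role <- character(n_circ)
    role[1:7] <- "high"            # detected in >10 samples
    role[8:10] <- "both_shared_up" # DE up in both stages
    role[11:20] <- "both_net_up"   # senescence-up, sponge-network circ
    role[21:22] <- "both_flat"
    role[23:24] <- "g_up"; role[25] <- "g_down"
    role[26:32] <- "a_flat"
    role[33:48] <- "b_up"          # senescence-up (B-window only)
    role[49:64] <- "b_flat"
    role[65:78] <- "a_single"
    role[79:98] <- "shared_single" # single detection on a shared day
    role[99:168] <- "b_single"

    category <- rep("EXONIC_BOTH_BOUNDARY", n_circ)
    category[65:72] <- "EXONIC_BOTH_INTERNAL"
    category[79:94] <- "EXONIC_ONE_BOUNDARY"
    category[99:108] <- "INTERGENIC"

    ## exon spans: 142 exonic records span 1-5 exons, 16 span 6-7
    exonic_idx <- which(category != "INTERGENIC")
    span <- integer(n_circ)
    long_idx <- 109:124
    span[long_idx] <- rep(c(6L, 7L), c(10L, 6L))
    small_idx <- setdiff(exonic_idx, long_idx)
    span[small_idx] <- rep(1:5, c(40L, 35L, 30L, 22L, 15L))

    host <- rep(NA_character_, n_circ)
    host[exonic_idx] <- gene_ids[seq_along(exonic_idx)]

    c_chrom <- character(n_circ); c_start <- integer(n_circ)
    c_end <- integer(n_circ); c_strand <- character(n_circ)
    for (k in exonic_idx) {
      g <- gm$genes[match(host[k], gm$genes$gene_id), ]
      xy <- circ_coords(category[k], g$start, span[k], exon_len,
                        intron_len)
      c_chrom[k] <- g$chrom; c_start[k] <- xy[1]; c_end[k] <- xy[2]
      c_strand[k] <- g$strand
    }
    ## 3 chloroplast intergenic circRNAs, 7 in nuclear gene deserts
    chloro <- data.frame(start = c(2001L, 5001L, 8001L),
                         end = c(2301L, 5401L, 8501L))
    for (j in 1:3) {
      k <- 98L + j
      c_chrom[k] <- "ChrC"; c_start[k] <- chloro$start[j]
      c_end[k] <- chloro$end[j]; c_strand[k] <- "+"
    }
    gap_hosts <- c("g030", "g045", "g060", "g120", "g135", "g150",
                   "g165")
    for (j in seq_along(gap_hosts)) {
      k <- 101L + j
      g <- gm$genes[match(gap_hosts[j], gm$genes$gene_id), ]
      c_chrom[k] <- g$chrom; c_start[k] <- g$end + 200L
      c_end[k] <- g$end + 500L; c_strand[k] <- "+"
    }
    circ_id <- sprintf("%s:%d-%d(%s)", c_chrom, c_start, c_end, c_strand)

    ## ---- circRNA supporting-read counts ------------------------------
    counts <- matrix(0L, nrow = n_circ, ncol = 14,
                     dimnames = list(circ_id, day_cols))
    zeros <- integer(14)
    sing <- function(sample, count) { v <- zeros; v[sample] <- count; v }
    j_high_up <- 0L; j_shared <- 0L; j_net <- 0L; j_bup <- 0L
    a_pairs <- list(c(1L, 2L), c(2L, 3L), c(3L, 4L), c(4L, 5L),
                    c(5L, 6L), c(1L, 6L), c(2L, 5L))
    b_pairs <- list(c(9L, 10L), c(10L, 11L), c(11L, 12L), c(12L, 13L),
                    c(13L, 14L), c(9L, 14L), c(10L, 13L), c(11L, 14L))
    for (k in seq_len(n_circ)) {
      counts[k, ] <- switch(role[k],
        high = if (k == 1L)
          c(3L, 2L, 1L, 2L, 1L, 2L, 7L, 2L, 1L, 1L, 2L, 1L, 1L, 1L)
        else if (k <= 6L) {
          j_high_up <- j_high_up + 1L
          P <- 11L + j_high_up
          c(1L, 1L, 1L, 1L, 1L, 2L, 2L, 3L, 5L, 9L, P, P, P, P)
        } else rep(c(1L, 2L), 7),
        both_shared_up = {
          j_shared <- j_shared + 1L
          Q <- 7L + j_shared
          c(0L, 0L, 0L, 3L, 0L, 0L, 1L, 2L, 3L, 5L, Q, Q, Q, Q)
        },
        both_net_up = {
          j_net <- j_net + 1L
          R <- 9L + j_net
          c(0L, 0L, 0L, 0L, 0L, 1L, 1L, 2L, 3L, 5L, 8L, R, R, R)
        },
        both_flat = if (k == 21L)
          c(1L, 0L, 0L, 0L, 0L, 0L, 1L, 0L, 0L, 0L, 0L, 0L, 0L, 2L)
        else
          c(2L, 0L, 0L, 0L, 0L, 0L, 2L, 0L, 0L, 0L, 0L, 0L, 0L, 1L),
        g_up = if (k == 23L)
          c(0L, 3L, 3L, zeros[1:11])
        else c(0L, 0L, 4L, 4L, zeros[1:10]),
        g_down = c(7L, 1L, zeros[1:12]),
        a_flat = {
          pr <- a_pairs[[k - 25L]]
          v <- zeros; v[pr] <- c(1L, 2L)[(k %% 2L) + 1L]; v
        },
        b_up = {
          j_bup <- j_bup + 1L
          S <- 6L + j_bup
          c(zeros[1:8], 1L, 2L, 4L, S, S, S)
        },
        b_flat = {
          pr <- b_pairs[[((k - 49L) %% 8L) + 1L]]
          v <- zeros; v[pr] <- c(1L, 2L)[(k %% 2L) + 1L]; v
        },
        a_single = sing(((k - 65L) %% 6L) + 1L, ((k - 65L) %% 2L) + 1L),
        shared_single = sing(7L + (k %% 2L), ((k %% 4L) < 2L) + 1L),
        b_single = sing(9L + ((k - 99L) %% 6L), ((k - 99L) %% 2L) + 1L))
    }

    ## ---- gene expression ---------------------------------------------
    up_gene_profile <- c(10L, 11L, 12L, 13L, 14L, 15L, 16L, 17L, 30L,
                         50L, 80L, 120L, 160L, 200L)
    u_gene_profile <- c(3L, 3L, 6L, rep(15L, 11))
    ## 9 concordant hosts: the hosts of the 5 high senescence-up
    ## circRNAs and of 4 senescence-up B-window circRNAs
    concordant_hosts <- c(host[2:6], host[33:36])
    t_genes <- gene_ids[159:180]
    u_genes <- gene_ids[181:185]
    gene_counts <- matrix(0L, nrow = n_genes, ncol = 14,
                          dimnames = list(gene_ids, day_cols))
    for (i in seq_len(n_genes)) {
      gid <- gene_ids[i]
      gene_counts[i, ] <-
        if (gid %in% concordant_hosts) up_gene_profile
        else if (gid %in% t_genes)
          up_gene_profile + c(rep(0L, 13), i %% 7L)
        else if (gid %in% u_genes) u_gene_profile
        else 19L + ((i + seq_len(14L)) %% 3L)   # flat, well inside gates
    }

    ## ---- miRNAs ------------------------------------------------------
    mirna_ids <- c("mirA", "mirB", "mirC", "mirD", "mirE")
    mirna_counts <- rbind(
      mirA = c(80L, 60L, 40L, rep(25L, 11)),
      mirB = c(200L, 190L, 180L, 170L, 160L, 150L, 140L, 130L, 120L,
               100L, 80L, 60L, 40L, 20L),
      mirC = c(90L, 70L, 50L, rep(30L, 11)),
      mirD = rep(50L, 14),
      mirE = rep(c(50L, 51L), 7))
    colnames(mirna_counts) <- day_cols
    mirna_seqs <- setNames(
      vapply(1:5, function(i) random_dna(21L), character(1)), mirna_ids)

    ## ---- genome with planted sites -----------------------------------
    genome_chr <- lapply(setNames(as.list(chromosomes$length),
                                  chromosomes$id), random_dna)
    plant <- function(gene_id, exon_ord, offset, mir) {
      g <- gm$genes[match(gene_id, gm$genes$gene_id), ]
      pos <- g$start + (exon_ord - 1L) * (exon_len + intron_len) + offset
      site <- revcomp_chr(mir)     # all site genes are plus-strand
      substr(genome_chr[[g$chrom]], pos,
             pos + nchar(site) - 1L) <<- site
    }
    for (g in u_genes) { plant(g, 1L, 10L, mirna_seqs[["mirA"]])
                         plant(g, 2L, 10L, mirna_seqs[["mirC"]]) }
    for (g in t_genes) plant(g, 1L, 10L, mirna_seqs[["mirB"]])
    plant(host[8], 1L, 20L, mirna_seqs[["mirA"]])    # shared-up circ 1
    plant(host[8], 1L, 60L, mirna_seqs[["mirC"]])
    plant(host[9], 1L, 20L, mirna_seqs[["mirA"]])
    plant(host[10], 1L, 20L, mirna_seqs[["mirA"]])
    for (k in 11:20) plant(host[k], 1L, 20L, mirna_seqs[["mirB"]])
    genome <- Biostrings::DNAStringSet(unlist(genome_chr))

    ## ---- known-circRNA catalogue: everything but the first 40 --------
    known <- data.frame(chrom = c_chrom[41:168], start = c_start[41:168],
                        end = c_end[41:168], strand = c_strand[41:168],
                        stringsAsFactors = FALSE)
    decoy_start <- c(501L, 1201L, 1901L, 2601L, 3301L)
    known <- rbind(known, data.frame(
      chrom = "ChrM", start = decoy_start, end = decoy_start + 250L,
      strand = "+", stringsAsFactors = FALSE))
    rownames(known) <- NULL

    ## ---- planted truth -----------------------------------------------
    de_circ <- rbind(
      data.frame(circ_id = circ_id[c(23, 24, 8:10)], stage = "G-to-M",
                 direction = "up", stringsAsFactors = FALSE),
      data.frame(circ_id = circ_id[25], stage = "G-to-M",
                 direction = "down", stringsAsFactors = FALSE),
      data.frame(circ_id = circ_id[c(2:6, 8:20, 33:48)],
                 stage = "M-to-S", direction = "up",
                 stringsAsFactors = FALSE),
      data.frame(circ_id = circ_id[1], stage = "M-to-S",
                 direction = "down", stringsAsFactors = FALSE))

    bsj <- data.frame(circ_id = circ_id,
                      chrom = c_chrom, start = c_start, end = c_end,
                      strand = c_strand, counts,
                      stringsAsFactors = FALSE, check.names = FALSE)
    rownames(bsj) <- NULL
    bsj <- structure(bsj, class = c("bsj_table", "data.frame"))

    out <- list(
      cfg = stage_config(), annotation = ann, genome = genome,
      bsj = bsj, circ_lib_sizes = rep(2e7, 14),
      gene_counts = gene_counts, gene_lib_sizes = rep(3e7, 14),
      mirna_counts = mirna_counts, mirna_lib_sizes = rep(1e7, 14),
      mirna_seqs = mirna_seqs, known = known,
      truth = list(
        roles = data.frame(circ_id = circ_id, role = role,
                           category = category, host = host,
                           exon_span = span, stringsAsFactors = FALSE),
        hosts = setNames(host, circ_id),
        de_circ = de_circ,
        concordant_hosts = concordant_hosts,
        network = list(
          g_mirnas = c("mirA", "mirC"),
          m_mirna = "mirB",
          g_circ = circ_id[8:10], m_circ = circ_id[11:20],
          g_mrna = u_genes, m_mrna = t_genes,
          n_triplets = c("G-to-M" = 20L, "M-to-S" = 220L))))
    if (!is.null(dir)) write_sim_dataset(out, dir)
    out
  })
}
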
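# toy data builders and the independent brute-force oracles used to
# cross-check the vectorized implementations

toy_annotation <- function() {
  chromosomes <- data.frame(
    id = c("Chr1", "Chr2", "ChrC", "scaffold1"),
    length = c(10000L, 10000L, 5000L, 3000L),
    stringsAsFactors = FALSE)
  genes <- data.frame(
    gene_id = c("gA", "gB", "gC"),
    chrom = c("Chr1", "Chr1", "Chr2"),
    strand = c("+", "-", "+"),
    start = c(1001L, 5001L, 2001L),
    end = c(2999L, 6999L, 3999L),
    stringsAsFactors = FALSE)
  # gA: 5 exons of 200 nt, introns 200 nt: 1001-1200, 1401-1600, ...
  exA <- data.frame(gene_id = "gA", start = 1001L + (0:4) * 400L,
                    end = 1200L + (0:4) * 400L)
  exB <- data.frame(gene_id = "gB", start = c(5001L, 5801L, 6500L),
                    end = c(5300L, 6100L, 6999L))
  exC <- data.frame(gene_id = "gC", start = c(2001L, 2501L),
                    end = c(2300L, 2800L))
  genome_annotation(chromosomes, genes, rbind(exA, exB, exC))
}

toy_genome <- function(ann, seed = 7L) {
  withr::with_seed(seed, {
    Biostrings::DNAStringSet(vapply(
      setNames(ann$chromosomes$length, ann$chromosomes$id),
      function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                        collapse = ""),
      character(1)))
  })
}

# a random annotation with irregular exon structure, for oracle
# equivalence tests
random_toy_annotation <- function(n_genes = 6L) {
  chrom_len <- 60000L
  chromosomes <- data.frame(id = "ChrR", length = chrom_len,
                            stringsAsFactors = FALSE)
  pos <- 200L
  genes <- NULL; exons <- NULL
  for (i in seq_len(n_genes)) {
    n_ex <- sample(1:6, 1)
    ex_len <- sample(40:250, n_ex, replace = TRUE)
    gaps <- sample(30:200, n_ex, replace = TRUE)
    s <- pos + cumsum(gaps) + c(0L, cumsum(ex_len))[seq_len(n_ex)]
    e <- s + ex_len - 1L
    gid <- sprintf("rg%02d", i)
    genes <- rbind(genes, data.frame(
      gene_id = gid, chrom = "ChrR",
      strand = sample(c("+", "-"), 1),
      start = s[1], end = e[n_ex], stringsAsFactors = FALSE))
    exons <- rbind(exons, data.frame(gene_id = gid, start = s, end = e,
                                     stringsAsFactors = FALSE))
    pos <- e[n_ex] + sample(100:600, 1)
  }
  genome_annotation(chromosomes, genes, exons)
}

# ---- independent classification oracle: exhaustive per-exon testing ----
oracle_classify <- function(junction, ann, tol = 0L) {
  A <- junction$start; B <- junction$end
  chrom <- junction$chrom; strand <- junction$strand
  genes <- ann$genes[ann$genes$chrom == chrom, , drop = FALSE]

  in_any_gene <- function(x) {
    any(genes$start <= x & x <= genes$end)
  }
  if (!in_any_gene(A) && !in_any_gene(B)) return("INTERGENIC")

  sm <- genes[genes$strand == strand, , drop = FALSE]
  hosts <- character(0); a_match <- logical(0); b_match <- logical(0)
  for (g in sm$gene_id) {
    ex <- ann$exons[ann$exons$gene_id == g, , drop = FALSE]
    a_hit <- FALSE; b_hit <- FALSE; am <- FALSE; bm <- FALSE
    for (j in seq_len(nrow(ex))) {
      if (ex$start[j] <= A && A <= ex$end[j]) {
        a_hit <- TRUE; am <- abs(A - ex$start[j]) <= tol
      }
      if (ex$start[j] <= B && B <= ex$end[j]) {
        b_hit <- TRUE; bm <- abs(B - ex$end[j]) <= tol
      }
    }
    if (a_hit && b_hit) {
      hosts <- c(hosts, g); a_match <- c(a_match, am)
      b_match <- c(b_match, bm)
    }
  }
  if (length(hosts) >= 1) {
    if (length(hosts) > 1) {
      gi <- match(hosts, sm$gene_id)
      ov <- pmin(sm$end[gi], B) - pmax(sm$start[gi], A) + 1L
      if (sum(ov == max(ov)) > 1) return("AMBIGUOUS")
      pick <- which.max(ov)
      a_match <- a_match[pick]; b_match <- b_match[pick]
    }
    n_m <- a_match[1] + b_match[1]
    return(c("EXONIC_BOTH_INTERNAL", "EXONIC_ONE_BOUNDARY",
             "EXONIC_BOTH_BOUNDARY")[n_m + 1])
  }
  for (g in sm$gene_id) {
    gi <- match(g, sm$gene_id)
    if (sm$start[gi] <= A && B <= sm$end[gi]) {
      ex <- ann$exons[ann$exons$gene_id == g, , drop = FALSE]
      a_ex <- any(ex$start <= A & A <= ex$end)
      b_ex <- any(ex$start <= B & B <= ex$end)
      if (!a_ex && !b_ex) return("INTRONIC")
    }
  }
  "AMBIGUOUS"
}

# ---- independent target-scoring oracle: positionwise loop -------------
oracle_score <- function(mirna, window, seed = c(2L, 13L)) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", U = "A")
  m <- toupper(chartr("u", "t", mirna))
  w <- toupper(chartr("u", "t", window))
  mv <- strsplit(m, "")[[1]]; wv <- strsplit(w, "")[[1]]
  n <- length(mv); s <- 0
  for (i in seq_len(n)) {
    t_base <- wv[n - i + 1]
    pen <- if (comp[[mv[i]]] == t_base) 0
      else if ((mv[i] == "G" && t_base == "T") ||
               (mv[i] == "T" && t_base == "G")) 0.5
      else 1
    if (i >= seed[1] && i <= seed[2]) pen <- 2 * pen
    s <- s + pen
  }
  s
}

oracle_scan <- function(mirna, target, circular = FALSE) {
  m <- nchar(mirna); L <- nchar(target)
  ext <- if (circular) paste0(target, substr(target, 1, m - 1)) else
    target
  n_win <- nchar(ext) - m + 1
  scores <- vapply(seq_len(n_win), function(s)
    oracle_score(mirna, substr(ext, s, s + m - 1)), numeric(1))
  best <- which.min(scores)
  list(start = best, score = scores[best],
       junction_spanning = best > L - m + 1)
}

# ---- hand-rank Spearman oracle ----------------------------------------
oracle_spearman <- function(x, y) {
  rank_avg <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v))
      r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    r
  }
  rx <- rank_avg(x); ry <- rank_avg(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# random complement-free-ish sequence utilities for scan tests
rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")
revcomp <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
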
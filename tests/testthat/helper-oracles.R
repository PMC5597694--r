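# Independent brute-force oracles and tiny fixtures, built in code.

# O(m^2 L) all-pairs Hamming oracle with pairwise deletion, written
# deliberately naively and independently of pairwise_pi()
pi_oracle <- function(seqs) {
  m <- length(seqs)
  chars <- lapply(toupper(seqs), function(s) strsplit(s, "")[[1]])
  vals <- c()
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    a <- chars[[i]]; b <- chars[[j]]
    ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
    if (!any(ok)) next
    vals <- c(vals, sum(a[ok] != b[ok]) / sum(ok))
  }
  mean(vals)
}

random_seqs <- function(m, L, gap_prob = 0, amb_prob = 0) {
  alpha <- c("A", "C", "G", "T")
  vapply(seq_len(m), function(i) {
    x <- sample(alpha, L, replace = TRUE)
    r <- runif(L)
    x[r < gap_prob] <- "-"
    x[r >= gap_prob & r < gap_prob + amb_prob] <- "N"
    paste(x, collapse = "")
  }, character(1))
}

toy_model <- function() {
  gene_model(data.frame(label = c("E1", "I1", "E2"),
                        kind = c("exon", "intron", "exon"),
                        length = c(4L, 3L, 3L)), locus = "toy")
}

# small in-frame model for CDS/translation tests: exons total 12 bp
frame_model <- function() {
  gene_model(data.frame(label = c("E1", "I1", "E2"),
                        kind = c("exon", "intron", "exon"),
                        length = c(6L, 4L, 6L)), locus = "frame")
}

# seq_matrix built directly from per-individual sequence pairs
manual_matrix <- function(seq_pairs, taxon = "t", prefix = "ind") {
  structure(list(seq = unlist(seq_pairs, use.names = FALSE),
                 individual = rep(sprintf("%s%02d", prefix,
                                          seq_along(seq_pairs)), each = 2L),
                 taxon = taxon, locus = "manual", regions = "manual"),
            class = "seq_matrix")
}

# one null dataset: two groups of n individuals drawn from a single pool
null_groups <- function(seed, n = 10, model = NULL, K = 12) {
  if (is.null(model)) model <- pan_gene_model("B")
  rates <- default_region_rates(model, "AB")
  pool <- generate_pool(model, K, rates, seed = seed)
  sg1 <- sample_genotypes(pool, n, "g1", seed = derive_seed(seed, "g1"))
  sg2 <- sample_genotypes(pool, n, "g2", freqs = sg1$freqs,
                          seed = derive_seed(seed, "g2"), prefix = "g2")
  gt <- genotype_table(rbind(as.data.frame(sg1$genotypes),
                             as.data.frame(sg2$genotypes)))
  list(g1 = build_matrix(gt, pool$sequences, pool$locus, model, taxa = "g1"),
       g2 = build_matrix(gt, pool$sequences, pool$locus, model, taxa = "g2"))
}

# two-pool dataset at a given diversity ratio (shared ancestral alignment)
ratio_groups <- function(seed, ratio, n = 10, K = 12) {
  model <- pan_gene_model("B")
  rates <- default_region_rates(model, "AB")
  anc <- panmhc:::make_ancestral(model, seed = derive_seed(seed, "anc"))
  p1 <- generate_pool(model, K, rates, seed = derive_seed(seed, "p1"),
                      locus = "Hi-B", ancestral = anc)
  p2 <- generate_pool(model, K, rates, seed = derive_seed(seed, "p2"),
                      locus = "Lo-B", ancestral = anc, diversity_scale = ratio)
  sg1 <- sample_genotypes(p1, n, "hi", seed = derive_seed(seed, "ghi"))
  sg2 <- sample_genotypes(p2, n, "lo", seed = derive_seed(seed, "glo"))
  gt <- genotype_table(rbind(as.data.frame(sg1$genotypes),
                             as.data.frame(sg2$genotypes)))
  seqs <- c(p1$sequences, p2$sequences)
  list(g1 = build_matrix(gt, seqs, "Hi-B", model, taxa = "hi"),
       g2 = build_matrix(gt, seqs, "Lo-B", model, taxa = "lo"))
}
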
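# Small in-code fixtures shared across test files.

# A hand-sized alignment: 10-site region, ancestor all "A", explicit variants.
# `rows` is a named list of character vectors over the variant positions.
tiny_alignment <- function(rows, pos, clusters, region_len = 10,
                           hq = rep(TRUE, region_len), region_start = 101L) {
  mat <- do.call(rbind, rows)
  rownames(mat) <- names(rows)
  hap_alignment(mat, pos = pos, chrom = "chrT",
                ancestor_full = rep("A", region_len),
                region_start = region_start, hq_mask = hq,
                meta = tibble::tibble(haplotype = names(rows),
                                      cluster = clusters))
}

# Random additive (ultrametric-free) tree with integer branch lengths and its
# exact patristic distance matrix.
random_additive_case <- function(n_taxa, seed) {
  set.seed(seed)
  tr <- ape::rtree(n_taxa, br = function(n) sample(1:9, n, replace = TRUE))
  list(tree = tr, d = cophenetic(tr))
}

# Alignment matrix with two clean clusters separated by `n_fixed` fixed
# differences plus a shared outgroup row of ancestral states.
two_clade_matrix <- function(n_per_clade = 4, n_fixed = 20, n_private = 2,
                             seed = 1) {
  set.seed(seed)
  n_cols <- n_fixed + 2 * n_per_clade * n_private + 10
  anc <- rep("A", n_cols)
  fixed_cols <- seq_len(n_fixed)
  rows <- list(ANCESTOR = anc)
  col_cursor <- n_fixed
  for (cl in c("L", "R")) {
    for (i in seq_len(n_per_clade)) {
      r <- anc
      if (cl == "R") r[fixed_cols] <- "T"
      priv <- col_cursor + seq_len(n_private)
      col_cursor <- col_cursor + n_private
      r[priv] <- "G"
      rows[[paste0(cl, i)]] <- r
    }
  }
  do.call(rbind, rows)
}
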
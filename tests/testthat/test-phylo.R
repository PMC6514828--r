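test_that("collapse merges identical sequences and applies the count filter", {
  mat <- rbind(h1 = c("A", "A"), h2 = c("A", "A"), h3 = c("A", "A"),
               h4 = c("A", "A"), h5 = c("T", "A"), h6 = c("T", "A"),
               h7 = c("G", "C"))
  col <- collapse_haplotypes(mat, min_count = 3)
  # only the 4-copy haplotype clears the strict > 3 threshold
  expect_identical(nrow(col$seqs), 1L)
  expect_identical(col$count, 4L)
  expect_setequal(col$members[[1]], c("h1", "h2", "h3", "h4"))
  # a protected id survives at any count
  col2 <- collapse_haplotypes(mat, min_count = 3, keep = "h7")
  expect_identical(nrow(col2$seqs), 2L)
  expect_true("h7" %in% rownames(col2$seqs))
  # min_count = 0 keeps every unique sequence
  col3 <- collapse_haplotypes(mat, min_count = 0)
  expect_identical(nrow(col3$seqs), 3L)
  expect_identical(sum(col3$count), 7L)
  expect_error(collapse_haplotypes(mat, min_count = 10), "removed every")
})

test_that("pairwise differences count Hamming distances pairwise-complete", {
  mat <- rbind(a = c("A", "A", "A", "A"), b = c("A", "T", "A", "G"),
               c = c("A", "T", NA, "G"))
  d <- pairwise_differences(mat)
  expect_identical(d["a", "b"], 2L)
  expect_identical(d["a", "c"], 2L) # the NA site is skipped
  expect_identical(d["b", "c"], 0L)
  expect_identical(d, t(d))
  expect_true(all(diag(d) == 0L))
  # all-identical matrix gives the zero matrix
  z <- pairwise_differences(rbind(x = c("A", "C"), y = c("A", "C")))
  expect_true(all(z == 0L))
})

test_that("neighbor joining recovers additive distances exactly", {
  for (seed in 1:3) {
    case <- random_additive_case(n_taxa = 8, seed = seed)
    tree <- nj_tree(case$d, outgroup = rownames(case$d)[1])
    rec <- cophenetic(tree)[rownames(case$d), colnames(case$d)]
    expect_equal(rec, case$d, tolerance = 1e-8)
  }
})

test_that("three-taxon neighbor joining matches the closed form", {
  d <- matrix(c(0, 3, 5, 3, 0, 4, 5, 4, 0), 3, 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tree <- nj_tree(d, outgroup = "z")
  pat <- cophenetic(tree)
  expect_equal(pat["x", "y"], 3)
  expect_equal(pat["x", "z"], 5)
  expect_equal(pat["y", "z"], 4)
  expect_true(ape::is.rooted(tree))
  expect_error(nj_tree(d[1:2, 1:2]), "at least 3")
  expect_error(nj_tree(d, outgroup = "w"), "'w'")
})

test_that("negative NJ edges are clamped without changing path lengths", {
  # classic matrix that produces a negative NJ branch
  d <- matrix(c(0, 2, 3, 9,
                2, 0, 3, 9,
                3, 3, 0, 8,
                9, 9, 8, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  raw <- ape::nj(stats::as.dist(d))
  clamped <- clamp_negative_edges(raw)
  expect_true(all(clamped$edge.length >= 0))
  expect_equal(sum(clamped$edge.length), sum(raw$edge.length), tolerance = 1e-9)
})

test_that("bootstrap gives full support to clean clades and is deterministic", {
  mat <- two_clade_matrix(n_per_clade = 4, n_fixed = 20, n_private = 2)
  res <- bootstrap_consensus(mat, outgroup = "ANCESTOR", replicates = 100,
                             seed = 3)
  expect_s3_class(res$tree, "phylo")
  expect_s3_class(res$consensus, "phylo")
  # the left/right split is separated by 20 fixed differences: every
  # bootstrap replicate must recover it
  sup <- as.numeric(res$tree$node.label)
  expect_true(any(sup == 100))
  # deterministic under a fixed seed
  res2 <- bootstrap_consensus(mat, outgroup = "ANCESTOR", replicates = 100,
                              seed = 3)
  expect_identical(res$tree$node.label, res2$tree$node.label)
  expect_identical(ape::write.tree(res$consensus), ape::write.tree(res2$consensus))
  # the consensus contains the clean clade as a monophyletic group
  right <- paste0("R", 1:4)
  expect_true(ape::is.monophyletic(res$consensus, right))
  # a single replicate still works
  one <- bootstrap_consensus(mat, replicates = 1, seed = 9)
  expect_identical(one$replicates, 1L)
})

test_that("the network keeps MST edges and labels them with mutation counts", {
  mat <- rbind(n1 = c("A", "A", "A"), n2 = c("A", "A", "T"),
               n3 = c("A", "T", "T"))
  net <- build_network(mat)
  expect_identical(sort(net$nodes$id), c("n1", "n2", "n3"))
  mst <- net$edges[net$edges$in_mst, ]
  expect_identical(nrow(mst), 2L)
  # the chain n1 - n2 - n3 with one mutation per step
  expect_identical(mst$mutations, c(1L, 1L))
  chain <- sort(c(paste(mst$from, mst$to), paste(mst$to, mst$from)))
  expect_true(all(c("n1 n2", "n2 n3") %in% chain))
  # the direct n1 - n3 edge (2 mutations) exceeds the bottleneck and is absent
  expect_false(any((net$edges$from == "n1" & net$edges$to == "n3") |
                     (net$edges$from == "n3" & net$edges$to == "n1")))
})

test_that("two haplotypes give a single edge; ties produce alternatives", {
  two <- build_network(rbind(a = c("A", "A"), b = c("T", "A")))
  expect_identical(nrow(two$edges), 1L)
  expect_identical(two$edges$mutations, 1L)
  # four mutually equidistant haplotypes: every non-MST edge ties the
  # bottleneck and is retained as an alternative connection
  eq <- rbind(a = c("T", "A", "A", "A"), b = c("A", "T", "A", "A"),
              c = c("A", "A", "T", "A"), d = c("A", "A", "A", "T"))
  net <- build_network(eq)
  expect_identical(nrow(net$edges), 6L)
  expect_identical(sum(net$edges$in_mst), 3L)
  expect_true(all(net$edges$mutations == 2L))
  expect_error(build_network(rbind(a = "A")), "at least 2")
})

test_that("networks carry multiplicities from collapsed haplotypes", {
  mat <- rbind(h1 = c("A", "A"), h2 = c("A", "A"), h3 = c("T", "A"))
  net <- build_network(collapse_haplotypes(mat, min_count = 0))
  expect_identical(sort(net$nodes$count), c(1L, 2L))
  expect_identical(tidy(net), net$edges)
})
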
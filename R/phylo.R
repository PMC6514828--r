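#' Variant-site haplotype matrix, optionally with the ancestor as outgroup
#'
#' @param alignment A `hap_alignment`.
#' @param include_ancestor Add an `"ANCESTOR"` row holding the reconstructed
#'   ancestor's base at each variant site (the usual outgroup for rooting).
#' @return A character matrix, haplotypes x variant sites.
#' @export
haplotype_matrix <- function(alignment, include_ancestor = FALSE) {
  stopifnot(inherits(alignment, "hap_alignment"))
  mat <- alignment$haplotypes
  if (include_ancestor) {
    mat <- rbind(mat, ANCESTOR = ancestor_at_variants(alignment))
  }
  mat
}

#' Collapse identical haplotypes and apply the count filter
#'
#' Collapses the input to unique sequences with multiplicities, then removes
#' every collapsed haplotype whose count is less than or equal to
#' `min_count`, except those containing a protected id (archaic haplotypes
#' and the ancestral outgroup are kept regardless of count).
#'
#' @param x A `hap_alignment` or a character matrix (haplotypes x sites,
#'   rownames = haplotype ids).
#' @param min_count Exclusive count threshold (default 3: haplotypes seen
#'   <= 3 times are dropped).
#' @param keep Character vector of protected haplotype ids.
#' @return An object of class `collapsed_haplotypes`: `seqs` (unique-sequence
#'   matrix, one row per retained haplotype), `count`, `members` (list of
#'   input ids per row).
#' @export
collapse_haplotypes <- function(x, min_count = 3, keep = character(0)) {
  mat <- if (inherits(x, "hap_alignment")) x$haplotypes else x
  if (!is.matrix(mat) || nrow(mat) == 0) abort("Need a non-empty haplotype matrix.")
  if (is.null(rownames(mat))) rownames(mat) <- sprintf("hap%03d", seq_len(nrow(mat)))
  key <- apply(mat, 1, function(r) paste(ifelse(is.na(r), ".", r), collapse = ""))
  groups <- split(rownames(mat), factor(key, levels = unique(key)))
  counts <- lengths(groups)
  protected <- vapply(groups, function(m) any(m %in% keep), logical(1))
  retain <- counts > min_count | protected
  if (!any(retain)) {
    abort(sprintf("The count filter (<= %d) removed every haplotype.", min_count))
  }
  groups <- groups[retain]
  ids <- vapply(groups, function(m) {
    kp <- intersect(m, keep)
    if (length(kp)) kp[1] else m[1]
  }, character(1))
  seqs <- mat[vapply(groups, `[`, character(1), 1), , drop = FALSE]
  rownames(seqs) <- ids
  structure(list(seqs = seqs, count = unname(lengths(groups)),
                 members = setNames(unname(groups), ids),
                 n_input = nrow(mat), min_count = min_count, keep = keep),
            class = "collapsed_haplotypes")
}

#' @export
print.collapsed_haplotypes <- function(x, ...) {
  cat(sprintf("<collapsed_haplotypes> %d unique haplotypes retained from %d input (count filter <= %d)\n",
              nrow(x$seqs), x$n_input, x$min_count))
  invisible(x)
}

#' Pairwise Hamming differences between haplotypes
#'
#' Counts, for every pair, the sites at which the two sequences differ;
#' missing bases are skipped pairwise (the count runs over mutually
#' non-missing positions).
#'
#' @param x A `collapsed_haplotypes`, `hap_alignment` or character matrix.
#' @return A symmetric integer matrix with a zero diagonal.
#' @examples
#' pairwise_differences(rbind(a = c("A", "A", "A"), b = c("A", "T", "A")))
#' @export
pairwise_differences <- function(x) {
  mat <- if (inherits(x, "collapsed_haplotypes")) x$seqs
         else if (inherits(x, "hap_alignment")) x$haplotypes else x
  if (!is.matrix(mat)) abort("Need a haplotype matrix.")
  n <- nrow(mat)
  d <- matrix(0L, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !is.na(mat[i, ]) & !is.na(mat[j, ])
      d[i, j] <- d[j, i] <- sum(mat[i, ok] != mat[j, ok])
    }
  }
  d
}

# Clamp negative NJ branch lengths to zero, moving the deficit onto the
# sibling edge so path lengths through the parent are preserved.
clamp_negative_edges <- function(tree) {
  repeat {
    neg <- which(tree$edge.length < 0)
    if (!length(neg)) break
    e <- neg[1]
    parent <- tree$edge[e, 1]
    sib <- setdiff(which(tree$edge[, 1] == parent), e)
    if (length(sib)) {
      tree$edge.length[sib[1]] <- tree$edge.length[sib[1]] + tree$edge.length[e]
    }
    tree$edge.length[e] <- 0
  }
  tree
}

#' Neighbor-joining tree from a difference matrix
#'
#' Saitou-Nei neighbor joining on the pairwise-difference matrix, rooted at
#' the outgroup haplotype. Negative branch lengths (a finite-sample artifact
#' of NJ) are clamped to zero with the deficit moved to the sibling edge.
#'
#' @param d A symmetric difference matrix (as from
#'   [pairwise_differences()]).
#' @param outgroup Row/column name to root at.
#' @return A rooted `phylo` tree.
#' @export
nj_tree <- function(d, outgroup = "ANCESTOR") {
  if (nrow(d) < 3) abort("Neighbor joining needs at least 3 haplotypes.")
  if (!outgroup %in% rownames(d)) {
    abort(sprintf("Outgroup '%s' is not among the haplotypes.", outgroup))
  }
  tree <- ape::nj(stats::as.dist(d))
  tree <- clamp_negative_edges(tree)
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}

#' Bootstrapped neighbor-joining tree with majority-rule consensus
#'
#' Resamples alignment columns with replacement `replicates` times (invariant
#' sites included when the matrix provides them), recomputes the difference
#' matrix and NJ tree for each replicate, and summarises: the full-data NJ
#' tree annotated with the percentage of replicates supporting each internal
#' node, and the >50% majority-rule consensus topology.
#'
#' @param x A `collapsed_haplotypes` or character matrix (the alignment --
#'   bootstrap resamples columns, not the distance matrix).
#' @param outgroup Haplotype id used as root.
#' @param replicates Number of bootstrap replicates (default 500).
#' @param seed Integer seed.
#' @return An object of class `consensus_tree`: `tree` (full-data rooted NJ
#'   tree, node labels = support percentages), `consensus` (majority-rule
#'   topology with supports), `replicates`.
#' @export
bootstrap_consensus <- function(x, outgroup = "ANCESTOR", replicates = 500,
                                seed = 1L) {
  replicates <- assert_count(replicates, "replicates", 1)
  mat <- if (inherits(x, "collapsed_haplotypes")) x$seqs else x
  if (!is.matrix(mat)) abort("Need a haplotype matrix or collapsed_haplotypes.")
  withr::local_seed(seed)
  full <- nj_tree(pairwise_differences(mat), outgroup)
  boots <- purrr::map(seq_len(replicates), function(i) {
    cols <- sample.int(ncol(mat), ncol(mat), replace = TRUE)
    nj_tree(pairwise_differences(mat[, cols, drop = FALSE]), outgroup)
  })
  support_on <- function(tree) {
    counts <- ape::prop.clades(tree, boots, rooted = FALSE)
    counts[is.na(counts)] <- 0
    round(100 * counts / replicates, 1)
  }
  full$node.label <- as.character(support_on(full))
  cons <- ape::consensus(boots, p = 0.5, check.labels = TRUE)
  cons <- ape::root(cons, outgroup = outgroup, resolve.root = TRUE)
  cons$node.label <- as.character(support_on(cons))
  structure(list(tree = full, consensus = cons, replicates = replicates,
                 outgroup = outgroup),
            class = "consensus_tree")
}

#' @export
print.consensus_tree <- function(x, ...) {
  cat(sprintf("<consensus_tree> %d tips, %d bootstrap replicates, rooted at '%s'\n",
              length(x$tree$tip.label), x$replicates, x$outgroup))
  invisible(x)
}

#' Minimum-spanning haplotype network
#'
#' Builds a haplotype network on the Hamming distances between retained
#' haplotypes: all minimum-spanning-tree edges plus every alternative edge
#' whose length ties the bottleneck (largest) edge weight on the MST path
#' between its endpoints. Edge labels are mutation counts; node sizes are
#' haplotype multiplicities.
#'
#' @param x A `collapsed_haplotypes` (preferred, carries multiplicities) or
#'   character matrix with at least 2 haplotypes.
#' @return An object of class `haplo_network`: `nodes` tibble (`id`,
#'   `count`), `edges` tibble (`from`, `to`, `mutations`, `in_mst`).
#' @export
build_network <- function(x) {
  counts <- NULL
  if (inherits(x, "collapsed_haplotypes")) {
    mat <- x$seqs
    counts <- x$count
  } else {
    mat <- x
  }
  if (!is.matrix(mat) || nrow(mat) < 2) abort("Need at least 2 retained haplotypes.")
  d <- pairwise_differences(mat)
  ids <- rownames(d)
  g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  # zero-distance pairs are dropped by graph_from_adjacency_matrix; restore them
  zero <- which(d == 0 & upper.tri(d), arr.ind = TRUE)
  if (nrow(zero)) {
    g <- igraph::add_edges(g, t(zero), weight = .Machine$double.eps)
  }
  mst <- igraph::mst(g, algorithm = "prim")
  mst_pairs <- igraph::as_edgelist(mst)
  in_mst <- function(a, b) {
    any((mst_pairs[, 1] == a & mst_pairs[, 2] == b) |
          (mst_pairs[, 1] == b & mst_pairs[, 2] == a))
  }
  bottleneck <- function(a, b) {
    path <- igraph::shortest_paths(mst, from = a, to = b, weights = NA)$vpath[[1]]
    w <- d[cbind(names(path)[-length(path)], names(path)[-1])]
    max(w)
  }
  edges <- list()
  for (i in seq_len(nrow(d) - 1)) {
    for (j in (i + 1):nrow(d)) {
      a <- ids[i]; b <- ids[j]
      mstv <- in_mst(a, b)
      if (mstv || d[i, j] == bottleneck(a, b)) {
        edges[[length(edges) + 1]] <- tibble(from = a, to = b,
                                             mutations = d[i, j],
                                             in_mst = mstv)
      }
    }
  }
  structure(list(nodes = tibble(id = ids,
                                count = counts %||% rep(1L, length(ids))),
                 edges = bind_rows(edges)),
            class = "haplo_network")
}

#' @export
print.haplo_network <- function(x, ...) {
  cat(sprintf("<haplo_network> %d nodes, %d edges (%d MST, %d alternative)\n",
              nrow(x$nodes), nrow(x$edges), sum(x$edges$in_mst),
              sum(!x$edges$in_mst)))
  invisible(x)
}

#' @export
tidy.haplo_network <- function(x, ...) x$edges
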
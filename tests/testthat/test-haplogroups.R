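tagT <- list(chrom = "chrT", pos = 105L, ancestral_allele = "T",
             derived_allele = "G")

test_that("haplotypes are classified by their base at the tag SNP", {
  aln <- tiny_alignment(
    rows = list(h1 = c("T", "A"), h2 = c("G", "C"), h3 = c(NA, "A"),
                h4 = c("C", "A")),
    pos = c(105L, 108L), clusters = rep("x", 4))
  expect_message(lab <- classify_haplotypes(aln, tag = tagT), "2 haplotype")
  expect_identical(lab$haplogroup,
                   c("ancestral", "derived", "unclassified", "unclassified"))
  # an alignment without the tag position is refused, naming the site
  aln2 <- tiny_alignment(rows = list(h1 = "C", h2 = "A"), pos = 103L,
                         clusters = c("x", "x"))
  expect_error(classify_haplotypes(aln2, tag = tagT), "105")
})

test_that("haplogroup proportions reproduce the reference percentages", {
  # 215 of 216 ancestral in one group, 379 of 380 derived in the other
  labeled <- tibble::tibble(
    haplogroup = c(rep("ancestral", 215), "derived",
                   rep("derived", 379), "ancestral"),
    cluster = c(rep("african", 216), rep("european", 380)))
  out <- haplogroup_proportions(labeled)
  expect_identical(out$pct_ancestral[out$group == "african"], 99.54)
  expect_identical(out$pct_derived[out$group == "european"], 99.74)
  expect_identical(out$n_haplotypes, c(216L, 380L))
  expect_equal(out$prop_ancestral + out$prop_derived, c(1, 1))
})

test_that("unclassified haplotypes leave the denominator, empty groups warn", {
  labeled <- tibble::tibble(
    haplogroup = c("ancestral", "derived", "unclassified",
                   "unclassified", "unclassified"),
    cluster = c("a", "a", "a", "b", "b"))
  expect_warning(out <- haplogroup_proportions(labeled), "\\bb\\b")
  expect_identical(nrow(out), 1L)
  expect_identical(out$prop_ancestral, 0.5)
  expect_identical(out$n_unclassified, 1L)
})

test_that("the unambiguous filter keeps only label-homozygous samples", {
  labeled <- tibble::tibble(
    sample = rep(c("s1", "s2", "s3"), each = 2),
    haplogroup = c("derived", "derived", "ancestral", "derived",
                   "ancestral", "ancestral"),
    cluster = c("eur", "eur", "eur", "afr", "afr", "afr"))
  out <- haplogroup_proportions(labeled, unambiguous_only = TRUE)
  # s2 is heterozygous for the cluster label and must drop out
  expect_identical(sum(out$n_haplotypes), 4L)
  expect_identical(out$n_derived[out$group == "eur"], 2L)
  expect_identical(out$n_ancestral[out$group == "afr"], 2L)
  expect_error(haplogroup_proportions(labeled[, -1], unambiguous_only = TRUE),
               "sample")
})

test_that("core haplotypes mark fixed bases as capitals and variable as 'n'", {
  mat <- rbind(a1 = c("A", "C", "G"), a2 = c("A", "C", "A"),
               a3 = c("A", "C", "G"), b1 = c("T", "C", "G"))
  core <- core_haplotypes(mat, c(a1 = "A", a2 = "A", a3 = "A", b1 = "B"))
  expect_identical(core$sequence[core$category == "A"], "ACn")
  # a single-haplotype category is fixed everywhere by definition
  expect_identical(core$sequence[core$category == "B"], "TCG")
  expect_identical(core$n_positions, c(3L, 3L))
  # a 2/3 threshold lets the majority base through at the variable site
  relaxed <- core_haplotypes(mat[1:3, ], c(a1 = "A", a2 = "A", a3 = "A"),
                             threshold = 2 / 3)
  expect_identical(relaxed$sequence, "ACG")
  # duplicating every haplotype leaves the consensus unchanged
  mat2 <- rbind(mat, mat)
  rownames(mat2) <- make.unique(rep(rownames(mat), 2))
  dup <- core_haplotypes(mat2,
                         stats::setNames(rep(c("A", "A", "A", "B"), 2),
                                         rownames(mat2)))
  expect_identical(dup$sequence, core$sequence)
})

test_that("majority-missing positions are emitted as 'n' with a warning", {
  mat <- rbind(a1 = c("A", NA), a2 = c("A", NA), a3 = c("A", "G"))
  expect_warning(core <- core_haplotypes(mat, c(a1 = "A", a2 = "A", a3 = "A")),
                 "missing in over half")
  expect_identical(core$sequence, "An")
})

test_that("packaged core haplotypes are 38 bases over the expected alphabet", {
  core <- fads_core_haplotypes()
  expect_identical(nchar(core$sequence), rep(38L, nrow(core)))
  expect_true(all(strsplit(paste(core$sequence, collapse = ""), "")[[1]] %in%
                    c("A", "C", "G", "T", "n")))
  expect_true(all(c("Ancestral", "Derived") %in% core$category))
  # base 10 is the tag SNP: T on the ancestral core, G on the derived core
  anc <- core$sequence[core$category == "Ancestral"]
  der <- core$sequence[core$category == "Derived"]
  expect_identical(substr(anc, fads_tag_index(), fads_tag_index()), "T")
  expect_identical(substr(der, fads_tag_index(), fads_tag_index()), "G")
})

test_that("opposite-fixed site detection matches hand examples", {
  ex <- opposite_fixed_sites("AnC", "TnC")
  expect_identical(ex$opposite, 1L)
  expect_identical(ex$one_sided, integer(0))
  ex2 <- opposite_fixed_sites("AnCG", "TACn")
  expect_identical(ex2$opposite, 1L)
  expect_identical(sort(ex2$one_sided), c(2L, 4L))
  expect_identical(opposite_fixed_sites("AnC", "TnC", exclude = 1L)$opposite,
                   integer(0))
  expect_error(opposite_fixed_sites("AA", "AAA"), "different lengths")
})

test_that("the ancestral/derived cores are oppositely fixed at exactly two sites", {
  core <- fads_core_haplotypes()
  res <- opposite_fixed_sites(core$sequence[core$category == "Ancestral"],
                              core$sequence[core$category == "Derived"])
  expect_identical(res$opposite, c(10L, 12L)) # the tag SNP and rs102274
  beyond_tag <- opposite_fixed_sites(
    core$sequence[core$category == "Ancestral"],
    core$sequence[core$category == "Derived"],
    exclude = fads_tag_index())
  expect_identical(beyond_tag$opposite, 12L)
})
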
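test_that("derived lineages carry Poisson mutation loads matching the clock", {
  # mean per-derived-haplotype count = tmrca * a_hc/(2 t_hc) * L_hq ~ 21.0
  cfg_fun <- function(seed) haplogroup_sim_config(
    n_derived = 20, n_ancestral = 2, n_archaic_near_derived = 0,
    n_archaic_near_ancestral = 0, seed = seed)
  expected <- 688474 * 0.00829 / (2 * 6.5e6) * 47820
  expect_equal(expected, 21.0, tolerance = 0.002)
  counts <- unlist(lapply(1:200, function(s) {
    aln <- simulate_haplogroup_alignment(cfg_fun(s))
    anc <- aln$ancestor_full[aln$pos - aln$region_start + 1L]
    der <- aln$meta$haplotype[aln$meta$cluster == "derived"]
    vapply(der, function(h) sum(aln$haplotypes[h, ] != anc), numeric(1))
  }))
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("zero-age derived cluster is identical to the ancestor", {
  aln <- simulate_haplogroup_alignment(haplogroup_sim_config(
    n_derived = 5, n_ancestral = 3, tmrca_derived = 0, seed = 3))
  anc <- aln$ancestor_full[aln$pos - aln$region_start + 1L]
  for (h in aln$meta$haplotype[aln$meta$cluster == "derived"]) {
    expect_identical(unname(aln$haplotypes[h, ]), anc)
  }
})

test_that("alignment simulation is bit-reproducible under a fixed seed", {
  cfg <- haplogroup_sim_config(n_derived = 8, n_ancestral = 8, seed = 99)
  a <- simulate_haplogroup_alignment(cfg)
  b <- simulate_haplogroup_alignment(cfg)
  expect_identical(a$haplotypes, b$haplotypes)
  expect_identical(a$pos, b$pos)
  expect_identical(a$ancestor_full, b$ancestor_full)
  expect_identical(a$hq_mask, b$hq_mask)
})

test_that("a mutation budget beyond the available sites is rejected", {
  # at 1 Gy the per-lineage expectation is ~0.64 mutations per site, far
  # beyond what 40 distinct high-quality sites can absorb for 100 lineages
  cfg <- haplogroup_sim_config(n_derived = 50, n_ancestral = 50,
                               length_total = 60, length_high_quality = 40,
                               tmrca_derived = 1e9, tmrca_all = 2e9, seed = 1)
  expect_error(simulate_haplogroup_alignment(cfg), "infinite-sites")
})

test_that("coalescent genealogy shares mutations between lineages", {
  aln <- simulate_haplogroup_alignment(haplogroup_sim_config(
    n_derived = 10, n_ancestral = 2, genealogy = "coalescent", seed = 5))
  anc <- aln$ancestor_full[aln$pos - aln$region_start + 1L]
  der <- aln$haplotypes[aln$meta$cluster == "derived", , drop = FALSE]
  carriers <- colSums(der != matrix(anc, nrow(der), ncol(der), byrow = TRUE))
  # some derived mutations must be carried by >1 haplotype (internal branches)
  expect_gt(sum(carriers > 1), 0)
})

test_that("planted stem mutations and tag SNP appear as fixed differences", {
  aln <- simulate_haplogroup_alignment(haplogroup_sim_config(
    n_derived = 6, n_ancestral = 6, tmrca_derived = 1000, tmrca_all = 2000,
    stem_mutations_derived = 4, plant_tag_snp = TRUE, seed = 8))
  expect_true(fads_tag_snp()$pos %in% aln$pos)
  lab <- classify_haplotypes(aln)
  expect_identical(lab$haplogroup[lab$cluster == "derived"], rep("derived", 6))
  expect_identical(lab$haplogroup[lab$cluster == "ancestral"], rep("ancestral", 6))
})

test_that("Balding-Nichols panel frequencies carry the drift parameter", {
  f_true <- 0.2
  cfg <- panel_sim_config(n_sites = 10000, sample_sizes = c(400, 400, 400),
                          drift_f = f_true, seed = 21)
  panel <- simulate_frequency_panel(cfg)
  p <- cbind(panel$a_alt / (panel$a_ref + panel$a_alt),
             panel$b_alt / (panel$b_ref + panel$b_alt),
             panel$c_alt / (panel$c_ref + panel$c_alt))
  pbar <- rowMeans(p)
  # method of moments on the Balding-Nichols variance F * p0(1-p0): with
  # p0 unobserved, E[pbar(1-pbar)] = p0(1-p0)(1 - F/3) across 3 populations,
  # so F solves F = v / (m + v/3) with v the across-population variance and
  # m the mean pbar(1-pbar) (800-allele sampling noise is negligible)
  ok <- pbar > 0.1 & pbar < 0.9
  v <- mean(apply(p[ok, ], 1, var))
  m <- mean(pbar[ok] * (1 - pbar[ok]))
  f_hat <- v / (m + v / 3)
  expect_lt(abs(f_hat - f_true) / f_true, 0.1)
})

test_that("drift-free panels differ across populations only by sampling noise", {
  cfg <- panel_sim_config(n_sites = 500, sample_sizes = c(500, 500, 500),
                          drift_f = 1e-9, seed = 4)
  panel <- simulate_frequency_panel(cfg)
  pa <- panel$a_alt / (panel$a_ref + panel$a_alt)
  pb <- panel$b_alt / (panel$b_ref + panel$b_alt)
  # binomial SE at n=1000 alleles is <= 0.016; differences should be tiny
  expect_lt(max(abs(pa - pb)), 6 * sqrt(0.25 / 1000))
})

test_that("a selected site is pushed toward fixation in the focal population", {
  cfg <- panel_sim_config(n_sites = 100, sample_sizes = c(1000, 1000, 1000),
                          drift_f = 1e-6, ancestral_freq_range = c(0.5, 0.5),
                          selected_site = list(index = 50, shift = 0.5),
                          seed = 11)
  panel <- simulate_frequency_panel(cfg)
  expect_gt(panel$a_alt[50] / (panel$a_ref[50] + panel$a_alt[50]), 0.98)
  expect_lt(abs(panel$b_alt[50] / 2000 - 0.5), 0.06)
})

test_that("panel and cline generators are deterministic and validated", {
  expect_identical(simulate_frequency_panel(panel_sim_config(n_sites = 50, seed = 2)),
                   simulate_frequency_panel(panel_sim_config(n_sites = 50, seed = 2)))
  expect_error(panel_sim_config(drift_f = 0), "strictly in")
  expect_error(panel_sim_config(n_sites = 10, selected_site = list(index = 11, shift = 0.1)),
               "index")
  tabs <- lapply(1:2, function(i) simulate_cline_table(cline_sim_config(seed = 31)))
  expect_identical(tabs[[1]], tabs[[2]])
})

test_that("noiseless cline tables are exactly linear and clipped", {
  tab <- simulate_cline_table(cline_sim_config(
    n_populations = 10, beta_latitude = 0.01, beta_admixture = 0,
    noise_sd = 0, intercept = 0.1, seed = 1))
  slope <- diff(tab$proportion) / diff(tab$latitude)
  expect_equal(slope, rep(0.01, 9), tolerance = 1e-12)
  const <- simulate_cline_table(cline_sim_config(
    n_populations = 5, beta_latitude = 0, beta_admixture = 0, noise_sd = 0,
    intercept = 0.4, seed = 1))
  expect_equal(const$proportion, rep(0.4, 5), tolerance = 1e-12)
  clipped <- simulate_cline_table(cline_sim_config(
    n_populations = 5, beta_latitude = 0.05, beta_admixture = 0, noise_sd = 0,
    intercept = 0.5, seed = 1))
  expect_true(all(clipped$proportion <= 1 & clipped$proportion >= 0))
})
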
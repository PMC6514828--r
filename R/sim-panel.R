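#' Configuration for a three-population allele-count panel
#'
#' Null (and spiked-alternative) generator for F_ST/PBS scans. Each site draws
#' a shared ancestral allele frequency, then per-population frequencies from
#' the Balding-Nichols law `Beta(p(1-F)/F, (1-p)(1-F)/F)` with differentiation
#' parameter `drift_f`, then binomial allele counts at the stated diploid
#' sample sizes. An optional selected site shifts the focal population's
#' frequency before sampling, mimicking a sweep.
#'
#' @param n_sites Number of sites.
#' @param sample_sizes Diploid sample sizes for populations A (focal), B, C.
#' @param drift_f Per-population Balding-Nichols F, each in (0, 1).
#' @param selected_site `NULL`, or `list(index =, shift =)`: population A's
#'   frequency at that site is moved by `shift` (clipped to \[0, 1\]).
#' @param ancestral_freq_range Range of the uniform ancestral-frequency draw.
#' @param chrom,pos_step Coordinates given to the sites (`pos = i * pos_step`).
#' @param seed Integer seed.
#' @return A list of class `panel_sim_config`.
#' @export
panel_sim_config <- function(n_sites = 10000,
                             sample_sizes = c(100, 100, 100),
                             drift_f = c(0.01, 0.01, 0.01),
                             selected_site = NULL,
                             ancestral_freq_range = c(0.05, 0.95),
                             chrom = "chr1", pos_step = 1000L,
                             seed = 1L) {
  n_sites <- assert_count(n_sites, "n_sites", min = 1)
  if (length(sample_sizes) != 3 || any(sample_sizes < 1)) {
    abort("`sample_sizes` must be 3 diploid counts >= 1.")
  }
  drift_f <- rep_len(drift_f, 3)
  if (any(drift_f <= 0 | drift_f >= 1)) {
    abort("`drift_f` entries must lie strictly in (0, 1).")
  }
  if (!is.null(selected_site)) {
    if (!is.list(selected_site) || is.null(selected_site$index) ||
        is.null(selected_site$shift)) {
      abort("`selected_site` must be list(index =, shift =).")
    }
    if (selected_site$index < 1 || selected_site$index > n_sites) {
      abort("`selected_site$index` must index a site in 1..n_sites.")
    }
  }
  structure(list(n_sites = n_sites, sample_sizes = as.integer(sample_sizes),
                 drift_f = drift_f, selected_site = selected_site,
                 ancestral_freq_range = ancestral_freq_range,
                 chrom = chrom, pos_step = as.integer(pos_step),
                 seed = as.integer(seed)),
            class = "panel_sim_config")
}

#' Simulate a three-population allele-count panel
#'
#' @param config A [panel_sim_config()].
#' @return A tibble with one row per site: `chrom`, `pos`, and
#'   `a_ref`, `a_alt`, `b_ref`, `b_alt`, `c_ref`, `c_alt` allele counts.
#' @examples
#' simulate_frequency_panel(panel_sim_config(n_sites = 5, seed = 7))
#' @export
simulate_frequency_panel <- function(config) {
  stopifnot(inherits(config, "panel_sim_config"))
  withr::local_seed(config$seed)
  n <- config$n_sites
  p_anc <- runif(n, config$ancestral_freq_range[1], config$ancestral_freq_range[2])
  freqs <- lapply(config$drift_f, function(f) {
    rbeta(n, p_anc * (1 - f) / f, (1 - p_anc) * (1 - f) / f)
  })
  if (!is.null(config$selected_site)) {
    i <- config$selected_site$index
    freqs[[1]][i] <- min(1, max(0, freqs[[1]][i] + config$selected_site$shift))
  }
  counts <- purrr::map2(freqs, config$sample_sizes, function(p, n_dip) {
    alt <- rbinom(n, 2L * n_dip, p)
    list(ref = 2L * n_dip - alt, alt = alt)
  })
  tibble(chrom = config$chrom,
         pos = seq_len(n) * config$pos_step,
         a_ref = counts[[1]]$ref, a_alt = counts[[1]]$alt,
         b_ref = counts[[2]]$ref, b_alt = counts[[2]]$alt,
         c_ref = counts[[3]]$ref, c_alt = counts[[3]]$alt)
}

#' Configuration for a latitude-cline population table
#'
#' Generator for testing the latitude regression
#' `lm(proportion ~ admixture + latitude)`: per-population ancestral-haplogroup
#' proportions are linear in latitude with an admixture covariate plus
#' Gaussian noise, clipped to \[0, 1\].
#'
#' @param n_populations Number of populations (>= 3).
#' @param latitude_range Degrees; populations are spread evenly over it.
#' @param beta_latitude Proportion change per degree of latitude.
#' @param beta_admixture Proportion change per unit admixture.
#' @param intercept Baseline proportion at latitude 0 with no admixture.
#' @param admixture_range Range of the uniform admixture draw.
#' @param noise_sd Residual standard deviation.
#' @param haplotypes_per_population Haplotypes sampled per population
#'   (recorded as metadata).
#' @param seed Integer seed.
#' @return A list of class `cline_sim_config`.
#' @export
cline_sim_config <- function(n_populations = 40,
                             latitude_range = c(10, 70),
                             beta_latitude = 0.01,
                             beta_admixture = -0.2,
                             intercept = 0.15,
                             admixture_range = c(0, 0.4),
                             noise_sd = 0.02,
                             haplotypes_per_population = 50,
                             seed = 1L) {
  n_populations <- assert_count(n_populations, "n_populations", min = 3)
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  structure(list(n_populations = n_populations,
                 latitude_range = latitude_range,
                 beta_latitude = beta_latitude,
                 beta_admixture = beta_admixture,
                 intercept = intercept,
                 admixture_range = admixture_range,
                 noise_sd = noise_sd,
                 haplotypes_per_population =
                   assert_count(haplotypes_per_population,
                                "haplotypes_per_population", min = 1),
                 seed = as.integer(seed)),
            class = "cline_sim_config")
}

#' Simulate a latitude-cline table
#'
#' @param config A [cline_sim_config()].
#' @return A tibble with columns `population`, `latitude`, `admixture`,
#'   `proportion` (clipped to \[0, 1\]) and `n_haplotypes`.
#' @examples
#' simulate_cline_table(cline_sim_config(n_populations = 5, seed = 3))
#' @export
simulate_cline_table <- function(config) {
  stopifnot(inherits(config, "cline_sim_config"))
  withr::local_seed(config$seed)
  n <- config$n_populations
  lat <- seq(config$latitude_range[1], config$latitude_range[2], length.out = n)
  adm <- runif(n, config$admixture_range[1], config$admixture_range[2])
  prop <- config$intercept + config$beta_latitude * lat +
    config$beta_admixture * adm +
    if (config$noise_sd > 0) rnorm(n, 0, config$noise_sd) else 0
  tibble(population = sprintf("pop_%02d", seq_len(n)),
         latitude = lat, admixture = adm,
         proportion = pmin(1, pmax(0, prop)),
         n_haplotypes = config$haplotypes_per_population)
}
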
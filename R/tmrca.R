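#' Infinite-sites filter for divergence-based TMRCA estimation
#'
#' Restricts divergence counting to high-quality sites compatible with the
#' infinite-sites model across the two haplogroups: a variant site is kept
#' only if every allele differing from the reconstructed ancestor occurs
#' exclusively among the derived haplotypes (no ancestral haplotype carries a
#' non-ancestor allele there). Sites outside the high-quality mask are always
#' excluded. Invariant high-quality sites are implicitly kept and counted in
#' the usable length.
#'
#' @param alignment A `hap_alignment`.
#' @param derived,ancestral Haplotype ids of the two clusters; default: rows
#'   whose `cluster` metadata equals `"derived"` / `"ancestral"`.
#' @return A list with `keep` (logical over the alignment's variant sites),
#'   `n_sites_used` (high-quality length minus excluded variant sites) and
#'   `n_excluded`.
#' @export
infinite_sites_filter <- function(alignment, derived = NULL, ancestral = NULL) {
  stopifnot(inherits(alignment, "hap_alignment"))
  derived <- derived %||% alignment$meta$haplotype[alignment$meta$cluster == "derived"]
  ancestral <- ancestral %||% alignment$meta$haplotype[alignment$meta$cluster == "ancestral"]
  if (length(derived) == 0) abort("No derived haplotypes to analyse.")
  anc_base <- ancestor_at_variants(alignment)
  is_hq <- variant_is_hq(alignment)
  if (length(ancestral) == 0) {
    warn("No ancestral haplotypes; infinite-sites filter falls back to the high-quality mask only.")
    violates <- rep(FALSE, length(anc_base))
  } else {
    anc_mat <- alignment$haplotypes[ancestral, , drop = FALSE]
    violates <- vapply(seq_along(anc_base), function(j) {
      b <- anc_mat[, j]
      any(!is.na(b) & b != anc_base[j])
    }, logical(1))
  }
  keep <- is_hq & !violates
  n_sites_used <- sum(alignment$hq_mask) - sum(is_hq & violates)
  list(keep = keep, n_sites_used = n_sites_used,
       n_excluded = sum(!keep))
}

#' Estimate the derived-haplogroup TMRCA from ancestor divergence
#'
#' Point estimator `TMRCA = (M / A_HC) * 2 * T_HC`, where `M` is the mean
#' per-site divergence of the derived haplotypes from the reconstructed
#' human-chimp ancestor over infinite-sites-filtered high-quality sites,
#' `A_HC` the local human-chimp per-site divergence and `T_HC` the
#' human-chimp divergence time. The per-lineage yearly substitution rate is
#' therefore `A_HC / (2 T_HC)`. The dispersion comes from applying the same
#' formula to each haplotype's own divergence.
#'
#' @param alignment A `hap_alignment`.
#' @param a_hc Human-chimp per-site divergence fraction (default 0.00829).
#' @param t_hc Human-chimp divergence time in years (default 6,500,000).
#' @param derived,ancestral Optional haplotype id sets (see
#'   [infinite_sites_filter()]).
#' @param ci Confidence-interval method: `"normal"` (default; +/- 1.96 SD of
#'   the per-haplotype TMRCA values over sqrt(n)) or `"poisson"` (treats each
#'   haplotype's filtered difference count as Poisson).
#' @return An object of class `tmrca_estimate` with elements `M`,
#'   `tmrca_years`, `sd_years`, `ci_low`, `ci_high`, `n_haplotypes`,
#'   `n_sites_used`, `a_hc`, `t_hc` and a `per_haplotype` tibble.
#' @examples
#' aln <- simulate_haplogroup_alignment(
#'   haplogroup_sim_config(n_derived = 20, n_ancestral = 20, seed = 11))
#' estimate_tmrca(aln)
#' @export
estimate_tmrca <- function(alignment, a_hc = 0.00829, t_hc = 6.5e6,
                           derived = NULL, ancestral = NULL,
                           ci = c("normal", "poisson")) {
  ci <- match.arg(ci)
  stopifnot(inherits(alignment, "hap_alignment"))
  if (a_hc <= 0) abort("`a_hc` must be positive.")
  derived <- derived %||% alignment$meta$haplotype[alignment$meta$cluster == "derived"]
  if (length(derived) < 2) abort("Need at least 2 derived haplotypes.")
  flt <- infinite_sites_filter(alignment, derived, ancestral)
  if (flt$n_sites_used <= 0) abort("Infinite-sites filter left zero usable sites.")

  anc_base <- ancestor_at_variants(alignment)[flt$keep]
  der_mat <- alignment$haplotypes[derived, flt$keep, drop = FALSE]
  diffs <- vapply(seq_along(derived), function(i) {
    b <- der_mat[i, ]
    sum(!is.na(b) & b != anc_base)
  }, numeric(1))
  divergence <- diffs / flt$n_sites_used
  M <- mean(divergence)
  scale <- 2 * t_hc / a_hc
  tmrca_i <- divergence * scale
  tmrca_years <- M * scale
  sd_years <- sd(tmrca_i)
  n <- length(derived)
  half <- if (ci == "normal") {
    1.96 * sd_years / sqrt(n)
  } else {
    1.96 * sqrt(mean(diffs) / n) / flt$n_sites_used * scale
  }
  structure(list(M = M, a_hc = a_hc, t_hc = t_hc,
                 tmrca_years = tmrca_years, sd_years = sd_years,
                 ci_low = tmrca_years - half, ci_high = tmrca_years + half,
                 ci_method = ci, n_haplotypes = n,
                 n_sites_used = flt$n_sites_used,
                 per_haplotype = tibble(haplotype = derived,
                                        n_differences = diffs,
                                        divergence = divergence,
                                        tmrca_years = tmrca_i)),
            class = "tmrca_estimate")
}

#' Build a TMRCA estimate directly from a mean divergence
#'
#' Convenience constructor for sensitivity analyses when only the mean
#' per-site divergence `M` is known (no per-haplotype data, hence no
#' dispersion or interval).
#'
#' @inheritParams estimate_tmrca
#' @param M Mean per-site divergence of the derived haplotypes from the
#'   ancestor.
#' @return A `tmrca_estimate` with `sd_years` and the interval set to `NA`.
#' @examples
#' tmrca_from_divergence(M = 0.0004145)  # -> 650,000 years at the defaults
#' @export
tmrca_from_divergence <- function(M, a_hc = 0.00829, t_hc = 6.5e6) {
  if (a_hc <= 0 || M < 0) abort("Need `a_hc` > 0 and `M` >= 0.")
  structure(list(M = M, a_hc = a_hc, t_hc = t_hc,
                 tmrca_years = M / a_hc * 2 * t_hc,
                 sd_years = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                 ci_method = "none", n_haplotypes = NA_integer_,
                 n_sites_used = NA_integer_, per_haplotype = NULL),
            class = "tmrca_estimate")
}

#' @export
print.tmrca_estimate <- function(x, ...) {
  cat(sprintf("<tmrca_estimate> TMRCA = %.0f years (M = %.3g, A_HC = %.3g, T_HC = %.3g)\n",
              x$tmrca_years, x$M, x$a_hc, x$t_hc))
  if (!is.na(x$ci_low)) {
    cat(sprintf("  95%% CI [%s]: %.0f - %.0f; SD %.0f; n = %d haplotypes over %d sites\n",
                x$ci_method, x$ci_low, x$ci_high, x$sd_years, x$n_haplotypes,
                x$n_sites_used))
  }
  invisible(x)
}

#' @export
tidy.tmrca_estimate <- function(x, ...) {
  if (is.null(x$per_haplotype)) return(tibble())
  x$per_haplotype
}

#' @export
glance.tmrca_estimate <- function(x, ...) {
  tibble(M = x$M, a_hc = x$a_hc, t_hc = x$t_hc, tmrca_years = x$tmrca_years,
         sd_years = x$sd_years, ci_low = x$ci_low, ci_high = x$ci_high,
         n_haplotypes = x$n_haplotypes, n_sites_used = x$n_sites_used)
}

#' Sensitivity of the TMRCA estimate to the human-chimp divergence time
#'
#' With `M` and `A_HC` held fixed the estimate is linear in `T_HC`, so the
#' curve over a range of divergence times is a straight line and the
#' divergence time at which the estimate equals a reference age has the
#' closed form `t_hc* = reference_age * t_hc / tmrca_years`.
#'
#' @param estimate A `tmrca_estimate` (or any list with `tmrca_years` and
#'   `t_hc`).
#' @param t_hc_range Range of divergence times to scan (default 5-7 My).
#' @param reference_age Age (years) whose crossing point is solved for
#'   (default 550,000, the floor of the modern-archaic divergence window).
#' @param n Number of curve points.
#' @return An object of class `tmrca_sensitivity`: a `curve` tibble
#'   (`t_hc`, `tmrca_years`), the `threshold` divergence time, and
#'   `threshold_in_range`.
#' @examples
#' est <- tmrca_from_divergence(M = 688474 * 0.00829 / (2 * 6.5e6))
#' tmrca_sensitivity(est)$threshold
#' @export
tmrca_sensitivity <- function(estimate, t_hc_range = c(5e6, 7e6),
                              reference_age = 550000, n = 201) {
  if (t_hc_range[1] >= t_hc_range[2]) abort("`t_hc_range` must be increasing.")
  if (reference_age <= 0) abort("`reference_age` must be positive.")
  slope <- estimate$tmrca_years / estimate$t_hc # years of TMRCA per year of T_HC
  grid <- seq(t_hc_range[1], t_hc_range[2], length.out = n)
  threshold <- reference_age / slope
  in_range <- threshold >= t_hc_range[1] && threshold <= t_hc_range[2]
  if (!in_range) {
    warn(sprintf("Threshold T_HC = %.0f lies outside the scanned range; reporting its analytic value.",
                 threshold))
  }
  structure(list(curve = tibble(t_hc = grid, tmrca_years = slope * grid),
                 threshold = threshold, threshold_in_range = in_range,
                 reference_age = reference_age, estimate = estimate),
            class = "tmrca_sensitivity")
}

#' @export
print.tmrca_sensitivity <- function(x, ...) {
  cat(sprintf("<tmrca_sensitivity> TMRCA = %.0f y at T_HC = %.3g; equals %.0f y at T_HC = %.0f%s\n",
              x$estimate$tmrca_years, x$estimate$t_hc, x$reference_age,
              x$threshold, if (x$threshold_in_range) "" else " (outside scanned range)"))
  invisible(x)
}
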
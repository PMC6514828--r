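#' Per-site F_ST from allele counts
#'
#' Two-population, single-site moment estimators of F_ST computed directly
#' from reference/alternate allele counts. The default is the Weir-Cockerham
#' (1984) analysis-of-variance estimator (the default of the tooling commonly
#' used for genome-wide scans); Hudson's estimator is available for
#' sensitivity analysis. Negative finite-sample estimates are retained. Sites
#' monomorphic across both populations are undefined (`NA`).
#'
#' @param ref1,alt1,ref2,alt2 Vectors of reference/alternate allele counts
#'   for the two populations.
#' @param estimator `"wc"` (Weir-Cockerham 1984) or `"hudson"`.
#' @return Numeric vector of F_ST estimates (`NA` where undefined).
#' @examples
#' fst_weir_cockerham(40, 0, 0, 40)   # complete fixation -> 1
#' fst_weir_cockerham(20, 20, 20, 20) # identical frequencies -> <= 0
#' @export
fst_weir_cockerham <- function(ref1, alt1, ref2, alt2,
                               estimator = c("wc", "hudson")) {
  estimator <- match.arg(estimator)
  n1 <- ref1 + alt1
  n2 <- ref2 + alt2
  p1 <- alt1 / n1
  p2 <- alt2 / n2
  pbar <- (alt1 + alt2) / (n1 + n2)
  undefined <- n1 < 2 | n2 < 2 | pbar <= 0 | pbar >= 1
  if (estimator == "wc") {
    msp <- n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2
    msg <- (n1 * p1 * (1 - p1) + n2 * p2 * (1 - p2)) / (n1 + n2 - 2)
    nc <- (n1 + n2) - (n1^2 + n2^2) / (n1 + n2)
    fst <- (msp - msg) / (msp + (nc - 1) * msg)
  } else {
    num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
    den <- p1 * (1 - p2) + p2 * (1 - p1)
    fst <- num / den
  }
  fst[undefined] <- NA_real_
  fst
}

#' Population branch statistic from three pairwise F_ST values
#'
#' `PBS = (T_ab + T_ac - T_bc) / 2` where `T = -ln(1 - F_ST)` is the
#' log-transformed divergence time proxy; population A is the focal branch.
#' Inputs must be strictly below 1 (clamp boundary estimates first).
#'
#' @param fst_ab,fst_ac,fst_bc Pairwise F_ST estimates (vectors recycle).
#' @return The PBS value(s).
#' @examples
#' pbs_from_fst(0.2, 0.3, 0.1)
#' @export
pbs_from_fst <- function(fst_ab, fst_ac, fst_bc) {
  if (any(stats::na.omit(c(fst_ab, fst_ac, fst_bc)) >= 1)) {
    abort("F_ST inputs must be < 1; clamp boundary estimates before the log transform.")
  }
  (-log(1 - fst_ab) - log(1 - fst_ac) + log(1 - fst_bc)) / 2
}

#' Genome-background PBS selection scan for a focal window
#'
#' Computes per-site pairwise F_ST and PBS across the whole panel (population
#' A is the focal branch), takes the background mean and standard deviation
#' of PBS over all sites where it is defined (the focal window included),
#' and converts each focal-window site's PBS to a Z-score, an upper-tail
#' normal p-value and a Bonferroni-corrected p-value (multiplier = number of
#' focal-window sites with defined PBS).
#'
#' @param panel A tibble with columns `chrom`, `pos`, `a_ref`, `a_alt`,
#'   `b_ref`, `b_alt`, `c_ref`, `c_alt` (as from
#'   [simulate_frequency_panel()]).
#' @param focal_region Region string `"chr:start-end"` (1-based inclusive) or
#'   a list with `chrom`, `start`, `end`. Default: the FADS gene region
#'   chr11:61,540,615-61,664,170.
#' @param window Flank added to each side of the region (default 500 kb).
#' @param estimator F_ST estimator, see [fst_weir_cockerham()].
#' @param sided `"one"` (upper tail; default, selection lengthens the focal
#'   branch) or `"two"`.
#' @param clamp F_ST values at or above 1 are clamped to this before the log
#'   transform.
#' @return A tibble of class `pbs_scan`: one row per site with defined PBS,
#'   columns `chrom`, `pos`, `fst_ab`, `fst_ac`, `fst_bc`, `pbs`, `in_window`,
#'   `z`, `p`, `p_bonf` (the last three `NA` outside the focal window).
#' @examples
#' panel <- simulate_frequency_panel(panel_sim_config(n_sites = 2000, seed = 5))
#' scan <- pbs_scan(panel, focal_region = "chr1:900000-1100000", window = 50000)
#' dplyr::arrange(dplyr::filter(scan, in_window), p_bonf)
#' @export
pbs_scan <- function(panel, focal_region = "chr11:61540615-61664170",
                     window = 500000, estimator = c("wc", "hudson"),
                     sided = c("one", "two"), clamp = 1 - 1e-12) {
  estimator <- match.arg(estimator)
  sided <- match.arg(sided)
  need <- c("chrom", "pos", "a_ref", "a_alt", "b_ref", "b_alt", "c_ref", "c_alt")
  if (!all(need %in% names(panel))) {
    abort(paste("`panel` must have columns:", paste(need, collapse = ", ")))
  }
  region <- parse_region(focal_region)

  cl <- function(x) pmin(x, clamp)
  fst_ab <- fst_weir_cockerham(panel$a_ref, panel$a_alt, panel$b_ref, panel$b_alt, estimator)
  fst_ac <- fst_weir_cockerham(panel$a_ref, panel$a_alt, panel$c_ref, panel$c_alt, estimator)
  fst_bc <- fst_weir_cockerham(panel$b_ref, panel$b_alt, panel$c_ref, panel$c_alt, estimator)
  defined <- !(is.na(fst_ab) | is.na(fst_ac) | is.na(fst_bc))
  n_dropped <- sum(!defined)
  if (n_dropped > 0) {
    inform(sprintf("Dropped %d site(s) with undefined pairwise F_ST (monomorphic pair).", n_dropped))
  }
  out <- tibble(chrom = panel$chrom[defined], pos = panel$pos[defined],
                fst_ab = fst_ab[defined], fst_ac = fst_ac[defined],
                fst_bc = fst_bc[defined])
  out$pbs <- pbs_from_fst(cl(out$fst_ab), cl(out$fst_ac), cl(out$fst_bc))
  out$in_window <- out$chrom == region$chrom &
    out$pos >= region$start - window & out$pos <= region$end + window

  if (nrow(out) < 1000) {
    warn(sprintf("Only %d background sites with defined PBS; the genome-background Z-score is unstable below ~1,000.",
                 nrow(out)))
  }
  bg_mean <- mean(out$pbs)
  bg_sd <- sd(out$pbs)
  if (!is.finite(bg_sd) || bg_sd == 0) {
    abort("Genome-background PBS standard deviation is zero; Z-scores are undefined.")
  }
  n_tests <- sum(out$in_window)
  out$z <- ifelse(out$in_window, (out$pbs - bg_mean) / bg_sd, NA_real_)
  p <- if (sided == "one") pnorm(out$z, lower.tail = FALSE) else 2 * pnorm(-abs(out$z))
  out$p <- p
  out$p_bonf <- pmin(1, p * n_tests)
  attr(out, "background") <- list(mean = bg_mean, sd = bg_sd,
                                  n_background = nrow(out), n_tests = n_tests,
                                  n_dropped = n_dropped)
  class(out) <- c("pbs_scan", class(out))
  out
}
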
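#' Fit the latitude cline for haplogroup proportion
#'
#' Ordinary least squares of per-population ancestral-haplogroup proportion
#' on European-admixture proportion and latitude,
#' `lm(proportion ~ admixture + latitude)`; the quantity of interest is the
#' latitude coefficient and its two-sided t-test p-value, with admixture as a
#' nuisance covariate. Proportions are regressed untransformed; set
#' `logit = TRUE` to fit on the logit scale instead.
#'
#' @param table A data frame with columns `proportion`, `admixture`,
#'   `latitude` (as from [simulate_cline_table()]).
#' @param logit Fit `qlogis(proportion)` (proportions clipped away from 0/1
#'   by half the smallest spacing) instead of the raw proportion.
#' @return An object of class `cline_fit` with `beta_latitude`,
#'   `beta_admixture`, `intercept`, `r_squared`, `p_latitude`, and the
#'   underlying `lm` fit.
#' @examples
#' tab <- simulate_cline_table(cline_sim_config(seed = 2))
#' fit_cline(tab)
#' @export
fit_cline <- function(table, logit = FALSE) {
  need <- c("proportion", "admixture", "latitude")
  if (!all(need %in% names(table))) {
    abort(paste("`table` must have columns:", paste(need, collapse = ", ")))
  }
  if (nrow(table) < 4) abort("Need at least 4 populations to fit the cline.")
  if (length(unique(table$latitude)) < 2) abort("`latitude` is constant; the cline is unidentifiable.")
  if (length(unique(table$admixture)) > 1 &&
      abs(stats::cor(table$admixture, table$latitude)) > 0.999) {
    abort("`admixture` and `latitude` are collinear (|r| > 0.999).")
  }
  y <- table$proportion
  if (logit) {
    eps <- 1e-6
    y <- stats::qlogis(pmin(1 - eps, pmax(eps, y)))
  }
  dat <- data.frame(y = y, admixture = table$admixture, latitude = table$latitude)
  fit <- lm(y ~ admixture + latitude, data = dat)
  sm <- summary(fit)
  # constant response: define a flat fit rather than NaNs
  if (stats::var(y) == 0) {
    sm$r.squared <- 0
    sm$coefficients["latitude", "Pr(>|t|)"] <- 1
  }
  structure(list(beta_latitude = unname(coef(fit)["latitude"]),
                 beta_admixture = unname(coef(fit)["admixture"]),
                 intercept = unname(coef(fit)["(Intercept)"]),
                 r_squared = sm$r.squared,
                 p_latitude = unname(sm$coefficients["latitude", "Pr(>|t|)"]),
                 logit = logit, n = nrow(table), fit = fit),
            class = "cline_fit")
}

#' @export
print.cline_fit <- function(x, ...) {
  cat(sprintf("<cline_fit> beta_latitude = %.5g (p = %.3g), beta_admixture = %.5g, R^2 = %.4f, n = %d\n",
              x$beta_latitude, x$p_latitude, x$beta_admixture, x$r_squared, x$n))
  invisible(x)
}

#' @export
tidy.cline_fit <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble(term = rownames(sm), estimate = sm[, 1], std.error = sm[, 2],
         statistic = sm[, 3], p.value = sm[, 4])
}

#' @export
glance.cline_fit <- function(x, ...) {
  tibble(beta_latitude = x$beta_latitude, beta_admixture = x$beta_admixture,
         intercept = x$intercept, r_squared = x$r_squared,
         p_latitude = x$p_latitude, n = x$n)
}

#' Empirical genome-wide outlier p-value
#'
#' The fraction of background (genome-wide) regression p-values strictly
#' smaller than the focal site's: `count(p_background < p_focal) / n`. Ties
#' count as not smaller. If the focal site is itself part of the background
#' set, it simply contributes to the denominator, matching the convention of
#' dividing by the total number of sites.
#'
#' @param focal_p The focal site's p-value.
#' @param background_p Vector of genome-wide per-site p-values.
#' @return The empirical p-value in \[0, 1\].
#' @examples
#' empirical_outlier_p(0.01, runif(1000))
#' @export
empirical_outlier_p <- function(focal_p, background_p) {
  assert_scalar_prob(focal_p, "focal_p")
  background_p <- background_p[!is.na(background_p)]
  if (length(background_p) == 0) abort("Empty background p-value set.")
  if (length(background_p) < 100) {
    warn(sprintf("Only %d background sites; the empirical p-value is coarse below ~100.",
                 length(background_p)))
  }
  sum(background_p < focal_p) / length(background_p)
}
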
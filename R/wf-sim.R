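#' Bottleneck-then-expansion demography for the Wright-Fisher simulator
#'
#' The demographic model of the founding of the Americas used throughout the
#' simulator: a diploid population passes through a bottleneck of
#' `bottleneck_size` individuals for the first `bottleneck_duration`
#' generations, then expands instantaneously to `expanded_size` and stays
#' constant until `total_generations` generations have elapsed.
#'
#' @param total_generations Generations since founding (default 534,
#'   i.e. 16,000 years at ~30 y/generation).
#' @param bottleneck_duration Length of the bottleneck in generations
#'   (default 10).
#' @param bottleneck_size,expanded_size Diploid effective sizes during and
#'   after the bottleneck.
#' @return A list of class `wf_demography`.
#' @examples
#' wf_demography(bottleneck_size = 100, expanded_size = 2000)
#' @export
wf_demography <- function(total_generations = 534, bottleneck_duration = 10,
                          bottleneck_size = 100, expanded_size = 2000) {
  total_generations <- assert_count(total_generations, "total_generations", 1)
  bottleneck_duration <- assert_count(bottleneck_duration, "bottleneck_duration", 0)
  if (bottleneck_duration > total_generations) {
    abort("`bottleneck_duration` must not exceed `total_generations`.")
  }
  bottleneck_size <- assert_count(bottleneck_size, "bottleneck_size", 1)
  expanded_size <- assert_count(expanded_size, "expanded_size", 1)
  structure(list(total_generations = total_generations,
                 bottleneck_duration = bottleneck_duration,
                 bottleneck_size = bottleneck_size,
                 expanded_size = expanded_size),
            class = "wf_demography")
}

#' Time-limited codominant selection acting on the focal allele
#'
#' Genotype fitnesses are `(1 + s, 1 + h s, 1)` for the focal homozygote,
#' heterozygote and other homozygote. Selection acts for the first `duration`
#' generations counted from the start of the simulation (including the
#' bottleneck); set `after_bottleneck_only = TRUE` to restrict it to
#' post-bottleneck generations instead.
#'
#' @param s Selection coefficient (must be > -1).
#' @param h Codominance coefficient in \[0, 1\] (default 0.5, genic selection).
#' @param duration Generations of selection from simulation start.
#' @param after_bottleneck_only If `TRUE`, selection only applies to
#'   generations after the bottleneck (still ending at `duration`).
#' @return A list of class `wf_selection`.
#' @examples
#' wf_selection(s = 0.01, duration = 534)
#' @export
wf_selection <- function(s = 0, h = 0.5, duration = 534,
                         after_bottleneck_only = FALSE) {
  if (!is.numeric(s) || length(s) != 1 || s <= -1) {
    abort("`s` must be a single value > -1 (fitnesses must stay positive).")
  }
  assert_scalar_prob(h, "h")
  duration <- assert_count(duration, "duration", 0)
  structure(list(s = s, h = h, duration = duration,
                 after_bottleneck_only = isTRUE(after_bottleneck_only)),
            class = "wf_selection")
}

wf_args <- function(demography, selection) {
  stopifnot(inherits(demography, "wf_demography"),
            inherits(selection, "wf_selection"))
  if (selection$duration > demography$total_generations) {
    abort("Selection `duration` exceeds `total_generations`.")
  }
  list(total_gens = demography$total_generations,
       bn_dur = demography$bottleneck_duration,
       bn_size = demography$bottleneck_size,
       exp_size = demography$expanded_size,
       s = selection$s, h = selection$h,
       sel_start = if (selection$after_bottleneck_only)
         demography$bottleneck_duration else 0L,
       sel_end = selection$duration)
}

#' Simulate one Wright-Fisher allele-frequency trajectory
#'
#' Each generation applies deterministic viability selection (while selection
#' is active) and then binomially resamples `2N` alleles at the current
#' epoch's diploid size. Frequencies 0 and 1 are absorbing. Generation 0
#' holds `p0` before any selection or sampling.
#'
#' @param p0 Initial focal-allele frequency in \[0, 1\].
#' @param demography A [wf_demography()].
#' @param selection A [wf_selection()].
#' @param seed Integer seed for the trajectory's private RNG stream.
#' @return A list of class `wf_trajectory` with `frequencies` (length
#'   `total_generations + 1`), and logicals `fixed` and `lost` assessed at the
#'   final generation.
#' @examples
#' tr <- simulate_trajectory(0.4, wf_demography(), wf_selection(s = 0.01), seed = 1)
#' tail(tr$frequencies)
#' @export
simulate_trajectory <- function(p0, demography = wf_demography(),
                                selection = wf_selection(), seed = 1L) {
  assert_scalar_prob(p0, "p0")
  a <- wf_args(demography, selection)
  freqs <- .wf_trajectory_cpp(p0, a$total_gens, a$bn_dur, a$bn_size, a$exp_size,
                              a$s, a$h, a$sel_start, a$sel_end, seed, 0, 0)
  structure(list(frequencies = freqs,
                 fixed = freqs[length(freqs)] >= 1,
                 lost = freqs[length(freqs)] <= 0,
                 p0 = p0, demography = demography, selection = selection),
            class = "wf_trajectory")
}

#' @export
tidy.wf_trajectory <- function(x, ...) {
  tibble(generation = seq_along(x$frequencies) - 1L, frequency = x$frequencies)
}

#' Proportion of replicate trajectories fixed by the final generation
#'
#' @inheritParams simulate_trajectory
#' @param replicates Number of independent trajectories (default 100).
#' @return Fraction of replicates with frequency 1 at the final generation.
#' @examples
#' fixation_proportion(0.9, wf_demography(), wf_selection(s = 0.1, duration = 534),
#'                     replicates = 50, seed = 2)
#' @export
fixation_proportion <- function(p0, demography = wf_demography(),
                                selection = wf_selection(),
                                replicates = 100, seed = 1L) {
  assert_scalar_prob(p0, "p0")
  replicates <- assert_count(replicates, "replicates", 1)
  a <- wf_args(demography, selection)
  .wf_fix_count_cpp(p0, a$total_gens, a$bn_dur, a$bn_size, a$exp_size,
                    a$s, a$h, a$sel_start, a$sel_end, replicates, seed, 1) /
    replicates
}

#' Default fixation-grid axes
#'
#' The parameter grid over which fixation proportions are tabulated:
#' bottleneck sizes 100-500, post-bottleneck sizes 2,000-10,000, selection
#' durations 67-534 generations, selection coefficients
#' \{0, 0.001, 0.01, 0.1\}, and starting frequencies 30-95% in steps of 5%
#' (5 x 5 x 8 x 4 x 14 = 11,200 cells).
#'
#' @return A named list of axis vectors.
#' @export
fixation_grid_axes <- function() {
  list(bottleneck_size = c(100L, 200L, 300L, 400L, 500L),
       expanded_size = c(2000L, 4000L, 6000L, 8000L, 10000L),
       duration = c(67L, 133L, 200L, 267L, 333L, 400L, 467L, 534L),
       s = c(0, 0.001, 0.01, 0.1),
       p0 = seq(0.30, 0.95, by = 0.05))
}

#' Fixation proportions over a parameter grid
#'
#' Evaluates [fixation_proportion()] on the full Cartesian product of the
#' axes, with a deterministic counter-based RNG stream per cell so the grid
#' is reproducible and cells are independent.
#'
#' @param axes Named list with elements `bottleneck_size`, `expanded_size`,
#'   `duration`, `s` and `p0` (defaults: [fixation_grid_axes()]).
#' @param total_generations,bottleneck_duration Shared demography settings.
#' @param h Codominance coefficient.
#' @param replicates Replicates per cell (default 100).
#' @param seed Master integer seed.
#' @return A tibble with one row per cell: the five axis columns,
#'   `prop_fixed` and `replicates`.
#' @examples
#' run_fixation_grid(list(bottleneck_size = 100, expanded_size = 2000,
#'                        duration = 534, s = c(0, 0.1), p0 = c(0.5, 0.9)),
#'                   replicates = 20, seed = 1)
#' @export
run_fixation_grid <- function(axes = fixation_grid_axes(),
                              total_generations = 534,
                              bottleneck_duration = 10,
                              h = 0.5, replicates = 100, seed = 1L) {
  need <- c("bottleneck_size", "expanded_size", "duration", "s", "p0")
  if (!all(need %in% names(axes)) || any(lengths(axes[need]) == 0)) {
    abort("`axes` must provide non-empty bottleneck_size, expanded_size, duration, s and p0.")
  }
  grid <- tidyr::expand_grid(bottleneck_size = as.integer(axes$bottleneck_size),
                             expanded_size = as.integer(axes$expanded_size),
                             duration = as.integer(axes$duration),
                             s = axes$s, p0 = axes$p0)
  bad <- which(grid$p0 < 0 | grid$p0 > 1 | grid$s <= -1 |
                 grid$duration > total_generations |
                 grid$bottleneck_size < 1 | grid$expanded_size < 1)
  if (length(bad)) {
    abort(sprintf("Grid cell %d (Nb=%s, Ne=%s, dur=%s, s=%s, p0=%s) violates parameter bounds.",
                  bad[1], grid$bottleneck_size[bad[1]], grid$expanded_size[bad[1]],
                  grid$duration[bad[1]], grid$s[bad[1]], grid$p0[bad[1]]))
  }
  replicates <- assert_count(replicates, "replicates", 1)
  grid$prop_fixed <- .wf_grid_cpp(grid$p0, grid$bottleneck_size,
                                  grid$expanded_size, grid$duration, grid$s,
                                  as.integer(total_generations),
                                  as.integer(bottleneck_duration),
                                  h, replicates, seed)
  grid$replicates <- replicates
  class(grid) <- c("fixation_grid", class(grid))
  grid
}

#' Exact fixation probability by a time-inhomogeneous Markov chain
#'
#' Brute-force oracle for small populations: the allele-count distribution is
#' propagated through per-generation binomial transition kernels (selection
#' applied to the expected frequency first), and the probability mass on the
#' all-focal state at the final generation is returned. Tractable only for
#' `2 * max(N) <= 200`.
#'
#' @inheritParams simulate_trajectory
#' @return The exact probability that the allele is fixed at the final
#'   generation.
#' @examples
#' exact_fixation_probability(0.5, wf_demography(bottleneck_size = 3,
#'                                               expanded_size = 3))
#' @export
exact_fixation_probability <- function(p0, demography = wf_demography(),
                                       selection = wf_selection()) {
  assert_scalar_prob(p0, "p0")
  a <- wf_args(demography, selection)
  if (2 * max(a$bn_size, a$exp_size) > 200) {
    abort("Exact chain restricted to 2*max(N) <= 200; use the simulator for larger populations.")
  }
  sel_freq <- function(p) {
    q <- 1 - p
    wbar <- p^2 * (1 + a$s) + 2 * p * q * (1 + a$h * a$s) + q^2
    p * (p * (1 + a$s) + q * (1 + a$h * a$s)) / wbar
  }
  n_of_gen <- function(t) if (t < a$bn_dur) a$bn_size else a$exp_size
  sel_of_gen <- function(t) t >= a$sel_start && t < a$sel_end

  # transition kernels cached by (N_from, N_to, selected)
  kernels <- new.env(parent = emptyenv())
  kernel <- function(n_from, n_to, selected) {
    key <- paste(n_from, n_to, selected)
    if (!is.null(kernels[[key]])) return(kernels[[key]])
    p_states <- (0:(2 * n_from)) / (2 * n_from)
    pp <- if (selected) vapply(p_states, sel_freq, numeric(1)) else p_states
    K <- t(vapply(pp, function(p) dbinom(0:(2 * n_to), 2 * n_to, p),
                  numeric(2 * n_to + 1)))
    kernels[[key]] <- K
    K
  }

  # generation 0 holds p0 as a frequency, not a count state
  p_first <- if (sel_of_gen(0)) sel_freq(p0) else p0
  v <- dbinom(0:(2 * n_of_gen(0)), 2 * n_of_gen(0), p_first)
  n_cur <- n_of_gen(0)
  for (t in seq_len(a$total_gens - 1)) {
    n_next <- n_of_gen(t)
    v <- as.vector(v %*% kernel(n_cur, n_next, sel_of_gen(t)))
    n_cur <- n_next
  }
  v[length(v)]
}
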
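# ggplot2 views of the main result types.

#' Plot a fixation-proportion grid
#'
#' Heat-map of fixation proportion over starting frequency and selection
#' duration, faceted by bottleneck and post-bottleneck size, one panel set
#' per selection coefficient.
#'
#' @param object A `fixation_grid` from [run_fixation_grid()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fixation_grid <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$p0, y = factor(.data$duration),
                                       fill = .data$prop_fixed)) +
    ggplot2::geom_tile() +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$bottleneck_size, .data$expanded_size),
      cols = ggplot2::vars(.data$s), labeller = ggplot2::label_both) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "prop. fixed") +
    ggplot2::labs(x = "starting allele frequency",
                  y = "selection duration (generations)")
}

#' Plot a PBS scan
#'
#' Per-site PBS along the chromosome; focal-window sites are highlighted and
#' coloured by Bonferroni significance at 0.05.
#'
#' @param object A `pbs_scan` tibble.
#' @param alpha Significance threshold for the colouring (default 0.05).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pbs_scan <- function(object, alpha = 0.05, ...) {
  object <- mutate(object,
                   status = dplyr::case_when(
                     !.data$in_window ~ "background",
                     .data$p_bonf <= alpha ~ "window: significant",
                     TRUE ~ "window: not significant"))
  ggplot2::ggplot(object, ggplot2::aes(x = .data$pos, y = .data$pbs,
                                       colour = .data$status)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_colour_manual(values = c("background" = "grey60",
                                            "window: significant" = "red3",
                                            "window: not significant" = "steelblue")) +
    ggplot2::labs(x = "position (bp)", y = "PBS", colour = NULL)
}

#' Plot a TMRCA sensitivity curve
#'
#' TMRCA estimate as a function of the assumed human-chimp divergence time,
#' with the reference age and the solved threshold marked.
#'
#' @param object A `tmrca_sensitivity`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tmrca_sensitivity <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$t_hc, y = .data$tmrca_years)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$reference_age, linetype = 2) +
    ggplot2::geom_vline(xintercept = object$threshold, linetype = 3,
                        colour = "red3") +
    ggplot2::labs(x = "assumed human-chimp divergence time (years)",
                  y = "TMRCA estimate (years)")
}

#' Plot a latitude cline fit
#'
#' Observed proportions against latitude with the admixture-adjusted fitted
#' line (admixture held at its mean).
#'
#' @param object A `cline_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cline_fit <- function(object, ...) {
  dat <- object$fit$model
  mean_adm <- mean(dat$admixture)
  line <- tibble(latitude = range(dat$latitude))
  line$y <- object$intercept + object$beta_admixture * mean_adm +
    object$beta_latitude * line$latitude
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$latitude, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = line, colour = "red3") +
    ggplot2::labs(x = "latitude (degrees)",
                  y = if (object$logit) "logit proportion" else "ancestral-haplogroup proportion")
}

#' Plot a haplotype network
#'
#' Nodes scaled by haplotype multiplicity, edges labelled by mutation counts;
#' alternative (bottleneck-tie) links are drawn dashed. Uses a
#' Fruchterman-Reingold layout from igraph.
#'
#' @param x A `haplo_network`.
#' @param seed Layout seed.
#' @param ... Unused.
#' @return Invisibly, the layout coordinates.
#' @export
plot.haplo_network <- function(x, seed = 1L, ...) {
  g <- igraph::graph_from_data_frame(x$edges, directed = FALSE,
                                     vertices = x$nodes)
  withr::local_seed(seed)
  lay <- igraph::layout_with_fr(g)
  igraph::plot.igraph(
    g, layout = lay,
    vertex.size = 6 + 3 * sqrt(x$nodes$count),
    edge.label = x$edges$mutations,
    edge.lty = ifelse(x$edges$in_mst, 1, 2))
  invisible(lay)
}
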
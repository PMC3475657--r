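#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_col facet_wrap
#'   facet_grid labs theme_minimal scale_y_log10 geom_hline
NULL

#' @export
ggplot2::autoplot

#' Plot occupancy time courses
#'
#' @param object An `occupancy_trajectory` or `protocol_trajectory`.
#' @param ... Unused.
#' @return A ggplot of state probabilities versus time, one line per
#'   state, faceted by protocol segment where applicable.
#' @export
autoplot.occupancy_trajectory <- function(object, ...) {
  labels <- attr(object, "state_labels")
  long <- pivot_longer(as_tibble(object), all_of(labels),
                       names_to = "state", values_to = "probability")
  ggplot(long, aes(x = .data$t, y = .data$probability, colour = .data$state)) +
    geom_line() +
    labs(x = "time (s)", y = "occupancy P(t)") +
    theme_minimal()
}

#' @rdname autoplot.occupancy_trajectory
#' @export
autoplot.protocol_trajectory <- function(object, ...) {
  labels <- attr(object, "state_labels")
  long <- pivot_longer(as_tibble(object), all_of(labels),
                       names_to = "state", values_to = "probability")
  ggplot(long, aes(x = .data$t, y = .data$probability, colour = .data$state)) +
    geom_line() +
    facet_wrap(~segment, scales = "free_x",
               labeller = ggplot2::labeller(segment = function(s) paste("segment", s))) +
    labs(x = "time within segment (s)", y = "occupancy P(t)") +
    theme_minimal()
}

#' Plot flux-density time courses per transition
#'
#' @param object A `flux_record` from [flux_density()].
#' @param which `"net"` for net densities only, `"both"` to overlay the
#'   unidirectional components.
#' @param ... Unused.
#' @export
autoplot.flux_record <- function(object, which = c("net", "both"), ...) {
  which <- match.arg(which)
  d <- as_tibble(object)
  if (!"segment" %in% names(d)) d$segment <- 1L
  p <- ggplot(d, aes(x = .data$t)) +
    geom_hline(yintercept = 0, linewidth = 0.2, colour = "grey60") +
    geom_line(aes(y = .data$f_net, colour = "net")) +
    facet_grid(edge ~ segment, scales = "free") +
    labs(x = "time (s)", y = "probability flux density (1/s)", colour = NULL) +
    theme_minimal()
  if (which == "both") {
    p <- p +
      geom_line(aes(y = .data$f_uni_forward, colour = "forward")) +
      geom_line(aes(y = .data$f_uni_backward, colour = "backward"))
  }
  p
}

#' Plot integrated total net fluxes as signed bars per transition
#'
#' @param object A `flux_totals` table from [total_net_flux()].
#' @param ... Unused.
#' @export
autoplot.flux_totals <- function(object, ...) {
  d <- as_tibble(object)
  if (!"segment" %in% names(d)) d$segment <- 1L
  ggplot(d, aes(x = .data$edge, y = .data$F_total)) +
    geom_col() +
    geom_hline(yintercept = 0, linewidth = 0.2) +
    facet_wrap(~segment) +
    labs(x = NULL, y = "total net flux F (fraction of unity)") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Plot a pathway decomposition as ranked weights
#'
#' @param object A `pathway_decomposition`.
#' @param ... Unused.
#' @export
autoplot.pathway_decomposition <- function(object, ...) {
  d <- tidy(object)
  d$path <- factor(d$path, levels = rev(d$path))
  ggplot(d, aes(x = .data$weight, y = .data$path)) +
    geom_col() +
    labs(x = "pathway flux (fraction of unity)", y = NULL) +
    theme_minimal()
}
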
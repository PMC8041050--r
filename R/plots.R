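#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the training loss of a Siamese matcher
#'
#' @param object A trained [siamese_matcher()].
#' @param ... Unused.
#' @return A ggplot of mean squared loss per epoch.
#' @method autoplot siamese_matcher
#' @export
autoplot.siamese_matcher <- function(object, ...) {
  if (nrow(object$loss_trace) == 0) {
    stop("autoplot.siamese_matcher: the matcher has not been trained yet")
  }
  ggplot2::ggplot(object$loss_trace, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "epoch", y = "mean squared loss",
                  title = "Siamese matcher training loss") +
    ggplot2::theme_minimal()
}

#' Plot the EM log-likelihood trace of a BKT fit
#'
#' @param object A [bkt_fit()].
#' @param ... Unused.
#' @return A ggplot of the (non-decreasing) log-likelihood per EM
#'   iteration of the winning restart.
#' @method autoplot bkt_fit
#' @export
autoplot.bkt_fit <- function(object, ...) {
  ggplot2::ggplot(object$trace, ggplot2::aes(x = .data$iteration, y = .data$loglik)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "EM iteration", y = "log-likelihood",
                  title = "BKT expectation-maximization trace") +
    ggplot2::theme_minimal()
}

#' Plot a learner's per-skill mastery posteriors
#'
#' @param object A [learner_state()].
#' @param mastery_threshold Threshold drawn as a dashed line
#'   (default 0.95).
#' @param ... Unused.
#' @return A ggplot bar chart, weakest skills first.
#' @method autoplot learner_state
#' @export
autoplot.learner_state <- function(object, mastery_threshold = 0.95, ...) {
  rep <- mastery_report(object, mastery_threshold)
  rep$skill <- factor(rep$skill, levels = rep$skill)
  ggplot2::ggplot(rep, ggplot2::aes(x = .data$skill, y = .data$posterior,
                                    fill = .data$status)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = mastery_threshold, linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "mastery posterior",
                  title = "Skill mastery (Bayesian Knowledge Tracing)") +
    ggplot2::theme_minimal()
}

#' Plot the pattern-analysis network of a session
#'
#' Renders the factor-to-hypothesis links of the pattern analysis:
#' positive links blue, negative links red, line width by weight, and the
#' hypothesis display score shown in the node label.
#'
#' @param session A session on which [submit_pattern_links()] was called.
#' @return A ggplot.
#' @export
plot_pattern_analysis <- function(session) {
  stopifnot(inherits(session, "vp_session"))
  if (is.null(session$pattern_links)) {
    stop("plot_pattern_analysis: no pattern links submitted yet")
  }
  links <- session$pattern_links
  links <- links[links$sign != "none", , drop = FALSE]
  factors <- unique(session$gathered)
  hyps <- unique(session$differential)
  nodes <- dplyr::bind_rows(
    tibble::tibble(id = factors, x = 0,
                   y = seq_along(factors), type = "factor"),
    tibble::tibble(id = hyps, x = 1, y = seq_along(hyps) *
                     max(1, length(factors)) / max(1, length(hyps)),
                   type = "hypothesis")
  )
  seg <- dplyr::left_join(links, stats::setNames(nodes[, c("id", "x", "y")],
                                                 c("factor", "x0", "y0")),
                          by = "factor")
  seg <- dplyr::left_join(seg, stats::setNames(nodes[, c("id", "x", "y")],
                                               c("hypothesis", "x1", "y1")),
                          by = "hypothesis")
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1,
                   yend = .data$y1, colour = .data$sign,
                   linewidth = .data$weight)) +
    ggplot2::scale_colour_manual(values = c(positive = "steelblue",
                                            negative = "firebrick")) +
    ggplot2::scale_linewidth_manual(values = c(low = 0.5, high = 1.6)) +
    ggplot2::geom_label(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y, label = .data$id)) +
    ggplot2::labs(title = "Pattern analysis", x = NULL, y = NULL) +
    ggplot2::theme_void()
}
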
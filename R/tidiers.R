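#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a phasing trial into its per-iteration trace
#'
#' @param x A `phasing_trial` from [run_trial()].
#' @param ... Unused.
#' @return Tibble with `iteration`, `cc` (CC_M), `n_eta` and, when the
#'   trial tracked ground truth, `aligned_cc`.
#' @export
tidy.phasing_trial <- function(x, ...) {
  out <- tibble::tibble(iteration = seq_along(x$cc_trace),
                        cc = x$cc_trace, n_eta = x$n_eta_trace)
  if (!is.null(x$aligned_trace) && length(x$aligned_trace) == nrow(out))
    out$aligned_cc <- x$aligned_trace
  out
}

#' One-row summary of a phasing trial
#'
#' @param x A `phasing_trial`.
#' @param ... Unused.
#' @return Tibble with `converged`, `n_iter`, `cc_final`, `q`,
#'   `aligned_cc`, `success`.
#' @export
glance.phasing_trial <- function(x, ...) {
  tibble::tibble(
    converged = x$converged, n_iter = x$n_iter,
    cc_final = x$cc_trace[length(x$cc_trace)], q = x$q,
    aligned_cc = if (!is.null(x$alignment)) x$alignment$best_cc else NA_real_,
    success = if (!is.null(x$success)) x$success else NA)
}

#' Per-trial summary of a batch
#'
#' @param x A `phasing_batch` from [run_batch()].
#' @param ... Unused.
#' @return The per-trial summary tibble.
#' @export
tidy.phasing_batch <- function(x, ...) x$summary

#' One-row summary of a batch
#'
#' @param x A `phasing_batch`.
#' @param ... Unused.
#' @return Tibble with the number of trials, converged and correct
#'   counts, mean iteration count over converged trials (`NA` when none
#'   converged -- reported as "n.c." in printed tables) and the mean Q.
#' @export
glance.phasing_batch <- function(x, ...) {
  s <- x$summary
  tibble::tibble(
    n_trials = nrow(s),
    n_converged = sum(s$converged),
    n_success = if (all(is.na(s$success))) NA_integer_
                else sum(s$success, na.rm = TRUE),
    mean_n_iter = if (any(s$converged)) mean(s$n_iter[s$converged]) else NA_real_,
    mean_q = mean(s$q, na.rm = TRUE))
}

#' Plot the CC_M and peak-count traces of a trial
#'
#' The two diagnostic curves of a refinement: CC_M rises, plateaus and
#' jumps at convergence, while the eta peak count N_eta drops sharply at
#' the same point.
#'
#' @param object A `phasing_trial`.
#' @param ... Unused.
#' @return A ggplot object (facetted, one panel per diagnostic).
#' @method autoplot phasing_trial
#' @export
autoplot.phasing_trial <- function(object, ...) {
  df <- tidy(object)
  long <- tidyr::pivot_longer(df[, c("iteration", "cc", "n_eta")],
                              c("cc", "n_eta"),
                              names_to = "diagnostic", values_to = "value")
  long$diagnostic <- factor(long$diagnostic, c("cc", "n_eta"),
                            c("CC[M]", "N[eta]"))
  ggplot2::ggplot(long, ggplot2::aes(.data$iteration, .data$value)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::facet_wrap(~diagnostic, ncol = 1, scales = "free_y",
                        labeller = ggplot2::label_parsed) +
    ggplot2::labs(x = "iteration", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the CC_M traces of all trials in a batch
#'
#' @param object A `phasing_batch`.
#' @param ... Unused.
#' @return A ggplot object; converged trials drawn in black, others in
#'   grey.
#' @method autoplot phasing_batch
#' @export
autoplot.phasing_batch <- function(object, ...) {
  df <- purrr::map2_dfr(object$trials, seq_along(object$trials),
                        function(tr, k)
                          tibble::tibble(trial = k, converged = tr$converged,
                                         iteration = seq_along(tr$cc_trace),
                                         cc = tr$cc_trace))
  ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$cc,
                                   group = .data$trial,
                                   colour = .data$converged)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "black", `FALSE` = "grey60"),
                                 name = "converged") +
    ggplot2::labs(x = "iteration", y = expression(CC[M])) +
    ggplot2::theme_minimal()
}

#' Tab-separated batch summary in the benchmark-table layout
#'
#' One row per trial with the columns of the published benchmark tables
#' (trial, N_iter or "n.c.", final CC_M, N_eta(2), Q).
#'
#' @param batch A `phasing_batch`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_batch_summary <- function(batch, path) {
  s <- batch$summary
  out <- data.frame(trial = s$trial,
                    n_iter = ifelse(s$converged, as.character(s$n_iter), "n.c."),
                    cc_m = sprintf("%.3f", s$cc_final),
                    n_eta2 = s$n_eta2, q = sprintf("%.2f", s$q))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
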
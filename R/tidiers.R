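#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy variance components
#'
#' One row per distinct (co)variance parameter, with delta-free asymptotic
#' standard errors where available.
#'
#' @param x A [varcomp()].
#' @param ... Unused.
#' @return Tibble `term`, `parameter`, `estimate`, `se`.
#' @export
#' @exportS3Method generics::tidy
tidy.cb_varcomp <- function(x, ...) {
  th <- vc_to_theta(x)
  nms <- theta_names(x)
  se <- if (is.null(x$asymp_cov)) rep(NA_real_, length(th)) else
    sqrt(pmax(diag(x$asymp_cov), 0))
  tibble::tibble(
    term = sub("_(var1|var2|cov)$", "", nms),
    parameter = sub("^.*_(var1|var2|cov)$", "\\1", nms),
    estimate = th, se = se)
}

#' @rdname tidy.cb_varcomp
#' @export
#' @exportS3Method generics::glance
glance.cb_varcomp <- function(x, ...) {
  d <- x$details
  tibble::tibble(
    loglik = d$loglik %||% NA_real_,
    iterations = d$iterations %||% NA_integer_,
    converged = d$converged %||% NA,
    n_animals = d$n_animals %||% NA_integer_,
    n_obs = d$n_obs %||% NA_integer_)
}

#' Tidy a fitted evaluation
#'
#' @param x A `cb_fit`.
#' @param what `"ebv"` (default) or `"fixed"`.
#' @param ... Unused.
#' @return The EBV tibble (`id`, `term`, `trait`, `ebv`) or the fixed-effect
#'   solutions.
#' @export
#' @exportS3Method generics::tidy
tidy.cb_fit <- function(x, what = c("ebv", "fixed"), ...) {
  what <- match.arg(what)
  if (what == "ebv") x$ebv else x$fixed
}

#' @rdname tidy.cb_fit
#' @export
#' @exportS3Method generics::glance
glance.cb_fit <- function(x, ...) {
  tibble::tibble(method = x$spec$method,
                 n_animals = length(x$animals),
                 n_obs = x$n_obs,
                 n_terms = length(x$spec$terms),
                 has_pev = !is.null(x$pev))
}

#' @export
#' @exportS3Method generics::tidy
tidy.cb_gamma <- function(x, ...) {
  tibble::tibble(parameter = c("gamma_B", "gamma_BH", "gamma_H"),
                 estimate = c(x$gamma_B, x$gamma_BH, x$gamma_H))
}

#' Plot LR validation estimators
#'
#' Dot plot of the four LR estimators by trait (and method when several
#' reports are bound together), with reference lines at the no-bias /
#' no-dispersion expectations.
#'
#' @param object A tibble from [run_lr()] (rows from several methods may be
#'   combined).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.cb_lr <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[c("method", "trait", "bias", "dispersion",
                                "accuracy", "ratio")],
    cols = c("bias", "dispersion", "accuracy", "ratio"),
    names_to = "estimator", values_to = "value")
  refs <- tibble::tibble(estimator = c("bias", "dispersion"), ref = c(0, 1))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$method, y = .data$value,
                                     colour = .data$trait)) +
    ggplot2::geom_point(size = 2, position = ggplot2::position_dodge(0.3)) +
    ggplot2::geom_hline(data = refs, ggplot2::aes(yintercept = .data$ref),
                        linetype = 2, colour = "grey50") +
    ggplot2::facet_wrap(~estimator, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, colour = "trait")
}

#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.cb_qc_report <- function(object, ...) {
  ggplot2::ggplot(object$tally,
                  ggplot2::aes(x = .data$rule, y = .data$removed)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "QC rule", y = "removed")
}

#' Heatmap of a relationship matrix
#'
#' @param A Labeled symmetric relationship matrix.
#' @param max_n Subsample cap on the number of animals shown (default 200).
#' @return A ggplot object.
#' @export
plot_relmat <- function(A, max_n = 200L) {
  if (nrow(A) > max_n) {
    keep <- sort(sample.int(nrow(A), max_n))
    A <- A[keep, keep]
  }
  df <- tidyr::expand_grid(i = factor(rownames(A), levels = rownames(A)),
                           j = factor(colnames(A), levels = colnames(A)))
  df$value <- as.vector(t(A))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::theme(axis.text = ggplot2::element_blank(),
                   axis.ticks = ggplot2::element_blank()) +
    ggplot2::labs(x = NULL, y = NULL, fill = "relationship")
}

#' @importFrom rlang .data
NULL
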
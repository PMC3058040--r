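#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
print.pep_pca <- function(x, ...) {
  cat("PCA model:", x$n_components, "component(s) on", x$n, "x", x$k,
      "matrix\n")
  cat("  R2X(cum):", paste(round(x$r2x_cum, 3), collapse = ", "), "\n")
  if (!is.null(x$q2_cum)) {
    cat("  Q2(cum): ", paste(round(x$q2_cum, 3), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
print.pep_pls <- function(x, ...) {
  cat("PLS model:", x$n_lv, "latent variable(s),",
      length(x$coefficients), "predictors\n")
  cat("  R2Y:", round(x$r2y, 3))
  if (!is.null(x$q2_cum)) cat("  Q2(cum):", round(x$q2_cum, 3))
  cat("\n")
  invisible(x)
}

#' @export
print.pep_permtest <- function(x, ...) {
  cat("Permutation validation:", x$n_perm, "permutations,", x$n_lv,
      "latent variable(s)\n")
  cat("  R2 intercept:", round(x$r2_intercept, 3),
      " Q2 intercept:", round(x$q2_intercept, 3),
      " valid:", x$valid, "\n")
  invisible(x)
}

#' Tidy a PCA model
#'
#' One row per component with its explained and cross-validated variation.
#'
#' @param x a [fit_pca()] model.
#' @param ... unused.
#' @return Tibble: `component`, `r2x`, `r2x_cum`, `q2`, `q2_cum`.
#' @export
tidy.pep_pca <- function(x, ...) {
  tibble::tibble(
    component = seq_len(x$n_components),
    r2x = x$r2x, r2x_cum = x$r2x_cum,
    q2 = x$q2 %||% NA_real_, q2_cum = x$q2_cum %||% NA_real_
  )
}

#' @rdname tidy.pep_pca
#' @export
glance.pep_pca <- function(x, ...) {
  tibble::tibble(
    n_components = x$n_components,
    r2x_cum = x$r2x_cum[x$n_components],
    q2_cum = if (is.null(x$q2_cum)) NA_real_ else x$q2_cum[x$n_components],
    n = x$n, k = x$k
  )
}

#' Tidy a PLS model
#'
#' One row per predictor with its regression coefficient on the
#' preprocessed scale (see [pls_coefficients()]).
#'
#' @param x a [fit_pls()] model.
#' @param ... unused.
#' @return Tibble as from [pls_coefficients()].
#' @export
tidy.pep_pls <- function(x, ...) pls_coefficients(x)

#' @rdname tidy.pep_pls
#' @export
glance.pep_pls <- function(x, ...) {
  tibble::tibble(n_lv = x$n_lv, r2y = x$r2y,
                 q2_cum = x$q2_cum %||% NA_real_,
                 n = length(x$y), k = length(x$coefficients))
}

#' @export
tidy.pep_permtest <- function(x, ...) x$results

#' @export
glance.pep_permtest <- function(x, ...) {
  tibble::tibble(n_perm = x$n_perm, r2_intercept = x$r2_intercept,
                 q2_intercept = x$q2_intercept, valid = x$valid)
}

#' Score plot of a PCA model
#'
#' @param object a [fit_pca()] model.
#' @param components two component indices to plot.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.pep_pca <- function(object, components = c(1, 2), ...) {
  sc <- tibble::as_tibble(object$scores, rownames = "row")
  a <- paste0("PC", components[1]); b <- paste0("PC", components[2])
  if (object$n_components < max(components)) {
    stop("model has only ", object$n_components, " components",
         call. = FALSE)
  }
  ggplot2::ggplot(sc, ggplot2::aes(.data[[a]], .data[[b]],
                                   label = .data$row)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.6, size = 3) +
    ggplot2::labs(
      x = sprintf("%s (%.0f%%)", a, 100 * object$r2x[components[1]]),
      y = sprintf("%s (%.0f%%)", b, 100 * object$r2x[components[2]]),
      title = "PCA score plot"
    ) +
    ggplot2::theme_minimal()
}

#' Coefficient bar plot of a PLS model
#'
#' The indicator-variable SAR view: one bar per (position, residue)
#' coefficient, positive bars marking residues beneficial for high
#' affinity.
#'
#' @param object a [fit_pls()] model.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.pep_pls <- function(object, ...) {
  co <- pls_coefficients(object)
  co$variable <- factor(co$variable, levels = co$variable)
  ggplot2::ggplot(co, ggplot2::aes(.data$variable, .data$coefficient,
                                   fill = .data$position)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(x = NULL, y = "PLS coefficient (scaled units)",
                  title = "PLS regression coefficients") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Permutation validation plot
#'
#' R2Y and Q2 of each permuted model against the absolute correlation of
#' the permuted response with the original, with the fitted regression
#' lines whose intercepts summarize the chance-correlation level.
#'
#' @param object a [permutation_test()] report.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.pep_permtest <- function(object, ...) {
  long <- tidyr::pivot_longer(object$results, c("r2y", "q2"),
                              names_to = "statistic")
  ggplot2::ggplot(long, ggplot2::aes(abs(.data$correlation), .data$value,
                                     colour = .data$statistic)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4) +
    ggplot2::labs(x = "|cor(permuted y, y)|", y = NULL,
                  title = "Permutation validation") +
    ggplot2::theme_minimal()
}

#' Distance-to-model plot
#'
#' @param model a [fit_pca()] model.
#' @param threshold reference line (default 2, a conventional alert level).
#' @return A ggplot of per-observation DModX.
#' @export
plot_dmodx <- function(model, threshold = 2) {
  d <- model$dmodx
  d$row <- factor(d$row, levels = d$row)
  ggplot2::ggplot(d, ggplot2::aes(.data$row, .data$dmodx)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = threshold, linetype = 2,
                        colour = "red") +
    ggplot2::labs(x = NULL, y = "DModX", title = "Distance to model") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
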
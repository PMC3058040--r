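#' Mean-center and unit-variance scale a data matrix
#'
#' Standard multivariate preprocessing applied before every PCA and PLS
#' model in this package: each column is mean-centered and divided by its
#' sample standard deviation. Zero-variance columns cannot be scaled and are
#' dropped with a warning; a matrix whose columns are all constant is an
#' error.
#'
#' @param x numeric matrix or data frame (rows = observations).
#' @param center,uv_scale logical flags.
#' @return The preprocessed matrix with attributes `center`, `scale`
#'   (per-column values used) and `dropped` (names of removed constant
#'   columns).
#' @export
mv_preprocess <- function(x, center = TRUE, uv_scale = TRUE) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  sds <- apply(x, 2, stats::sd)
  dropped <- character(0)
  if (uv_scale && any(sds == 0)) {
    dropped <- colnames(x)[sds == 0]
    if (length(dropped) == ncol(x)) {
      stop("all columns are constant; nothing to scale", call. = FALSE)
    }
    warning("dropping constant column(s): ", paste(dropped, collapse = ", "),
            call. = FALSE)
    x <- x[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  mu <- if (center) colMeans(x) else stats::setNames(rep(0, ncol(x)),
                                                     colnames(x))
  if (center) x <- sweep(x, 2, mu)
  sc <- if (uv_scale) sds else stats::setNames(rep(1, ncol(x)),
                                               colnames(x))
  if (uv_scale) x <- sweep(x, 2, sc, `/`)
  structure(x, center = mu, scale = sc, dropped = dropped)
}

apply_preprocess <- function(new, mu, sc) {
  new <- as.matrix(new)
  if (is.null(colnames(new))) colnames(new) <- paste0("V", seq_len(ncol(new)))
  new <- new[, names(mu), drop = FALSE]
  sweep(sweep(new, 2, mu), 2, sc, `/`)
}

#' Principal component analysis with cross-validated Q2 and DModX
#'
#' Fits a PCA on the mean-centered, unit-variance-scaled matrix. Explained
#' variation is reported per component and cumulatively (R2X(cum));
#' predictive ability Q2(cum) is estimated by element-wise cross-validation:
#' for each component the cells of the (deflated) matrix are deleted in
#' `cv_groups` diagonal groups, the component is re-estimated from the
#' remaining cells by NIPALS with missing-value handling, and the deleted
#' cells are predicted. Observation-level model fit is summarized by DModX,
#' the normalized residual standard deviation (see [dmodx()]).
#'
#' @param x numeric matrix or data frame.
#' @param n_components number of components to extract.
#' @param center,uv_scale preprocessing flags (see [mv_preprocess()]).
#' @param cv_groups number of element-deletion groups (default 7); set to
#'   `0` to skip cross-validation.
#' @return An object of class `pep_pca`: list with `scores`, `loadings`,
#'   `r2x`, `r2x_cum`, `q2`, `q2_cum`, `dmodx`, preprocessing parameters.
#' @export
fit_pca <- function(x, n_components, center = TRUE, uv_scale = TRUE,
                    cv_groups = 7) {
  xp <- mv_preprocess(x, center = center, uv_scale = uv_scale)
  n <- nrow(xp); k <- ncol(xp)
  max_a <- min(n - 1, k)
  if (n_components > max_a) {
    stop("n_components (", n_components, ") exceeds min(rows-1, cols) = ",
         max_a, call. = FALSE)
  }
  sv <- svd(xp, nu = n_components, nv = n_components)
  scores <- sv$u %*% diag(sv$d[seq_len(n_components)], n_components)
  loadings <- sv$v
  ss_tot <- sum(xp^2)
  r2x <- sv$d[seq_len(n_components)]^2 / ss_tot
  rownames(scores) <- rownames(xp) %||% as.character(seq_len(n))
  rownames(loadings) <- colnames(xp)
  colnames(scores) <- colnames(loadings) <-
    paste0("PC", seq_len(n_components))

  q2 <- q2_cum <- NULL
  if (cv_groups > 1) {
    press_ratio <- numeric(n_components)
    xa <- xp
    for (a in seq_len(n_components)) {
      press_ratio[a] <- pca_component_press(xa, cv_groups) / sum(xa^2)
      xa <- xa - scores[, a, drop = FALSE] %*% t(loadings[, a, drop = FALSE])
    }
    q2 <- 1 - press_ratio
    q2_cum <- 1 - cumprod(press_ratio)
  }

  model <- structure(list(
    scores = scores, loadings = loadings,
    n_components = n_components,
    r2x = r2x, r2x_cum = cumsum(r2x),
    q2 = q2, q2_cum = q2_cum,
    center = attr(xp, "center"), scale = attr(xp, "scale"),
    dropped = attr(xp, "dropped"),
    centered = center, n = n, k = k
  ), class = "pep_pca")
  resid <- xp - scores %*% t(loadings)
  a0 <- if (center) 1 else 0
  model$s0 <- sqrt(sum(resid^2) /
                     (max(n - n_components - a0, 1) * max(k - n_components, 1)))
  model$dmodx <- dmodx(model, x)
  model
}

# PRESS for one component by diagonal element-deletion cross-validation.
pca_component_press <- function(xa, groups) {
  n <- nrow(xa); k <- ncol(xa)
  idx <- outer(seq_len(n), seq_len(k), `+`) %% groups
  press <- 0
  for (g in seq_len(groups) - 1) {
    xm <- xa
    xm[idx == g] <- NA
    cmp <- nipals_component(xm)
    pred <- cmp$t %*% t(cmp$p)
    press <- press + sum((xa[idx == g] - pred[idx == g])^2)
  }
  press
}

# One NIPALS PCA component tolerating missing cells.
nipals_component <- function(x, tol = 1e-10, max_iter = 500) {
  miss <- is.na(x)
  x0 <- x
  x0[miss] <- 0
  start <- which.max(apply(x, 2, function(col) stats::var(col, na.rm = TRUE)))
  t_vec <- x0[, start]
  if (all(t_vec == 0)) t_vec <- stats::rnorm(nrow(x))
  for (iter in seq_len(max_iter)) {
    tw <- matrix(t_vec, nrow(x), ncol(x))
    tw[miss] <- 0
    p_vec <- colSums(x0 * tw) / colSums(tw^2)
    p_vec <- p_vec / sqrt(sum(p_vec^2))
    pw <- matrix(p_vec, nrow(x), ncol(x), byrow = TRUE)
    pw[miss] <- 0
    t_new <- rowSums(x0 * pw) / rowSums(pw^2)
    if (sum((t_new - t_vec)^2) < tol * sum(t_new^2)) {
      t_vec <- t_new
      break
    }
    t_vec <- t_new
  }
  list(t = matrix(t_vec), p = matrix(p_vec))
}

#' Distance to a PCA model (DModX)
#'
#' Normalized residual standard deviation of each observation: the RMS of
#' its residuals off the model plane, divided by the pooled residual
#' standard deviation of the training set (with degrees of freedom corrected
#' for the extracted components and, if centering was used, the mean).
#' Observations lying in the model plane score 0; under the chosen
#' normalization the cohort average is close to 1, and clear outliers stand
#' out with large values.
#'
#' @param model a fitted [fit_pca()] object.
#' @param x data to evaluate (original scale); default: training data is
#'   required, so pass the matrix the model was fitted on or new data with
#'   the same columns.
#' @return Tibble with columns `row` and `dmodx`.
#' @export
dmodx <- function(model, x) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  xp <- apply_preprocess(x, model$center, model$scale)
  t_new <- xp %*% model$loadings
  resid <- xp - t_new %*% t(model$loadings)
  a <- model$n_components
  k <- model$k
  s_i <- sqrt(rowSums(resid^2) / max(k - a, 1))
  d <- if (model$s0 > 0) s_i / model$s0 else ifelse(s_i == 0, 0, Inf)
  tibble::tibble(
    row = rownames(xp) %||% as.character(seq_len(nrow(xp))),
    dmodx = unname(d)
  )
}

#' Partial least squares regression (PLS1, NIPALS)
#'
#' Projects the predictors onto latent variables that maximize covariance
#' with a single response, the standard NIPALS PLS1 algorithm. Predictors
#' and response are mean-centered and unit-variance scaled by default
#' (indicator columns are scaled like any variable; disable with
#' `scale_x = FALSE`). Predictive ability Q2(cum) is estimated by
#' leave-one-out cross-validation with preprocessing re-estimated inside
#' each fold.
#'
#' @param x predictor matrix or data frame (e.g. an indicator matrix from
#'   [encode_indicators()]).
#' @param y numeric response vector.
#' @param n_lv number of latent variables; `NULL` selects the number (from
#'   1 to `max_lv`) that maximizes Q2(cum).
#' @param scale_x,scale_y unit-variance scale predictors / response.
#' @param max_lv search bound used when `n_lv` is `NULL`.
#' @param cv `"loo"` (default) or `"none"`.
#' @return An object of class `pep_pls`: weights `w`, scores `t`, loadings
#'   `p`, y-loadings `q`, coefficients on the preprocessed scale
#'   (`coefficients`), fitted values and residuals on the original y scale,
#'   `r2y`, `q2_cum`, preprocessing parameters.
#' @export
fit_pls <- function(x, y, n_lv = NULL, scale_x = TRUE, scale_y = TRUE,
                    max_lv = NULL, cv = c("loo", "none")) {
  cv <- match.arg(cv)
  x <- as.matrix(x)
  y <- as.numeric(y)
  stopifnot(nrow(x) == length(y))
  if (stats::sd(y) == 0) stop("response is constant", call. = FALSE)
  rank_x <- qr(scale(x, scale = FALSE))$rank
  if (is.null(n_lv)) {
    max_lv <- min(max_lv %||% rank_x, rank_x)
    if (cv == "none") stop("automatic n_lv selection needs cv = 'loo'",
                           call. = FALSE)
    q2s <- vapply(seq_len(max_lv), function(a) {
      pls_loo_q2(x, y, a, scale_x, scale_y)
    }, numeric(1))
    n_lv <- which.max(q2s)
  }
  if (n_lv > rank_x) {
    stop("n_lv (", n_lv, ") exceeds predictor rank (", rank_x, ")",
         call. = FALSE)
  }
  core <- pls_core(x, y, n_lv, scale_x, scale_y)
  q2_cum <- if (cv == "loo") pls_loo_q2(x, y, n_lv, scale_x, scale_y) else NULL
  structure(c(core, list(q2_cum = q2_cum, n_lv = n_lv,
                         scale_x = scale_x, scale_y = scale_y)),
            class = "pep_pls")
}

# NIPALS PLS1 on given data; returns model pieces + training fit.
pls_core <- function(x, y, n_lv, scale_x, scale_y) {
  xp <- mv_preprocess(x, center = TRUE, uv_scale = scale_x)
  y_mu <- mean(y)
  y_sc <- if (scale_y) stats::sd(y) else 1
  yp <- (y - y_mu) / y_sc
  n <- nrow(xp); k <- ncol(xp)
  w_mat <- p_mat <- matrix(0, k, n_lv)
  t_mat <- matrix(0, n, n_lv)
  q_vec <- numeric(n_lv)
  xa <- xp; ya <- yp
  for (a in seq_len(n_lv)) {
    w <- crossprod(xa, ya)
    w_norm <- sqrt(sum(w^2))
    if (w_norm < 1e-12) {
      stop("latent variable ", a, " is degenerate (X carries no further ",
           "covariance with y); reduce n_lv", call. = FALSE)
    }
    w <- w / w_norm
    t_vec <- xa %*% w
    tt <- sum(t_vec^2)
    p <- crossprod(xa, t_vec) / tt
    q <- sum(ya * t_vec) / tt
    xa <- xa - t_vec %*% t(p)
    ya <- ya - q * t_vec
    w_mat[, a] <- w; p_mat[, a] <- p; t_mat[, a] <- t_vec; q_vec[a] <- q
  }
  # b on the preprocessed scale: y_pre_hat = X_pre %*% b
  b <- w_mat %*% solve(t(p_mat) %*% w_mat, diag(n_lv)) %*% q_vec
  rownames(b) <- colnames(xp)
  fitted_pre <- xp %*% b
  fitted <- as.numeric(fitted_pre) * y_sc + y_mu
  r2y <- 1 - sum((yp - fitted_pre)^2) / sum(yp^2)
  dimnames(w_mat) <- dimnames(p_mat) <- list(colnames(xp),
                                             paste0("LV", seq_len(n_lv)))
  dimnames(t_mat) <- list(rownames(xp) %||% as.character(seq_len(n)),
                          paste0("LV", seq_len(n_lv)))
  list(w = w_mat, p = p_mat, t = t_mat, q = q_vec,
       coefficients = stats::setNames(as.numeric(b), colnames(xp)),
       x_center = attr(xp, "center"), x_scale = attr(xp, "scale"),
       y_center = y_mu, y_scale = y_sc,
       fitted = fitted, residuals = y - fitted, y = y, r2y = r2y)
}

# Leave-one-out Q2(cum): PRESS from per-fold refits over centered-y SS.
pls_loo_q2 <- function(x, y, n_lv, scale_x, scale_y) {
  n <- length(y)
  press <- 0
  for (i in seq_len(n)) {
    fit <- pls_core(x[-i, , drop = FALSE], y[-i], n_lv, scale_x, scale_y)
    x_new <- apply_preprocess(x[i, , drop = FALSE], fit$x_center, fit$x_scale)
    pred <- as.numeric(x_new %*% fit$coefficients) * fit$y_scale +
      fit$y_center
    press <- press + (y[i] - pred)^2
  }
  1 - press / sum((y - mean(y))^2)
}

#' Predict from a PLS model
#'
#' @param object a fitted [fit_pls()] model.
#' @param newdata matrix/data frame with the model's predictor columns.
#' @param ... unused.
#' @return Numeric vector of predictions on the original response scale.
#' @export
predict.pep_pls <- function(object, newdata, ...) {
  xp <- apply_preprocess(as.matrix(newdata), object$x_center, object$x_scale)
  as.numeric(xp %*% object$coefficients) * object$y_scale + object$y_center
}

#' PLS regression coefficients as a tidy table
#'
#' Coefficients on the preprocessed (unitless) scale, ordered
#' position-major as in the indicator encoding. A large positive
#' coefficient marks a residue beneficial for high affinity at its
#' position; a large negative one marks a detrimental residue.
#'
#' @param model a fitted [fit_pls()] model.
#' @return Tibble with columns `variable`, `position` (prefix before the
#'   first `.` if present, else `NA`), `residue`, `coefficient`.
#' @export
pls_coefficients <- function(model) {
  v <- names(model$coefficients)
  has_pos <- grepl("\\.", v)
  tibble::tibble(
    variable = v,
    position = ifelse(has_pos, sub("\\..*$", "", v), NA_character_),
    residue = ifelse(has_pos, sub("^[^.]*\\.", "", v), v),
    coefficient = unname(model$coefficients)
  )
}

#' Permutation validation of a PLS model
#'
#' Refits the model `n_perm` times with the response randomly permuted and
#' records, for each permutation, the correlation between permuted and
#' original response, R2Y, and leave-one-out Q2. The intercepts of the
#' regression lines of R2Y and Q2 against the absolute correlation (the
#' classic validation plot) estimate the fit obtainable from chance
#' correlation alone; a model is flagged valid when both intercepts fall
#' below conventional limits (R2 intercept < 0.3, Q2 intercept < 0.05).
#'
#' @param x,y data as in [fit_pls()].
#' @param n_lv number of latent variables (fixed across permutations).
#' @param n_perm number of permutations (default 100; fewer than 10 warns).
#' @param seed integer seed (mandatory, for reproducibility).
#' @param scale_x,scale_y passed to [fit_pls()].
#' @return An object of class `pep_permtest`: tibble `results` (first row =
#'   unpermuted model, `correlation` 1), `r2_intercept`, `q2_intercept`,
#'   `valid`.
#' @export
permutation_test <- function(x, y, n_lv, n_perm = 100, seed,
                             scale_x = TRUE, scale_y = TRUE) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  if (n_perm < 10) warning("fewer than 10 permutations gives an unstable ",
                           "validation plot", call. = FALSE)
  if (stats::sd(y) == 0) stop("response is constant", call. = FALSE)
  set.seed(seed)
  one <- function(y_use) {
    fit <- pls_core(as.matrix(x), y_use, n_lv, scale_x, scale_y)
    c(r2y = fit$r2y,
      q2 = pls_loo_q2(as.matrix(x), y_use, n_lv, scale_x, scale_y))
  }
  base <- one(y)
  perms <- purrr::map(seq_len(n_perm), function(i) {
    y_perm <- sample(y)
    c(correlation = stats::cor(y_perm, y), one(y_perm))
  })
  results <- dplyr::bind_rows(
    tibble::tibble(perm = 0L, correlation = 1,
                   r2y = base[["r2y"]], q2 = base[["q2"]]),
    purrr::imap_dfr(perms, function(v, i) {
      tibble::tibble(perm = as.integer(i), correlation = v[["correlation"]],
                     r2y = v[["r2y"]], q2 = v[["q2"]])
    })
  )
  line_int <- function(stat) {
    unname(stats::coef(stats::lm(stat ~ abs(results$correlation)))[1])
  }
  r2_int <- line_int(results$r2y)
  q2_int <- line_int(results$q2)
  structure(list(results = results,
                 r2_intercept = r2_int, q2_intercept = q2_int,
                 valid = r2_int < 0.3 && q2_int < 0.05,
                 n_perm = n_perm, n_lv = n_lv, seed = seed),
            class = "pep_permtest")
}
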
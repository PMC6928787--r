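#' Fit autoscaling parameters
#'
#' Column means and sample standard deviations (n-1 denominator) of a
#' training matrix, for the mean-centering and unit-variance scaling
#' applied to all descriptor matrices before latent-variable modelling.
#' Constant columns get a scale of 1 (with a warning) so that
#' near-constant descriptors in small congeneric series do not abort a
#' fit; their model coefficients are necessarily 0.
#'
#' @param x Numeric matrix (>= 2 rows).
#' @return An object of class `"autoscale"`: list with `center` and
#'   `scale`, one entry per column.
#' @seealso [autoscale_apply()], [autoscale_invert()]
#' @export
autoscale_fit <- function(x) {
  x <- as.matrix(x)
  stopifnot(nrow(x) >= 2L)
  center <- colMeans(x)
  scale <- apply(x, 2L, stats::sd)
  const <- !is.finite(scale) | scale <= 0
  if (any(const)) {
    warning(sum(const), " constant column(s) scaled by 1", call. = FALSE)
    scale[const] <- 1
  }
  structure(list(center = center, scale = scale), class = "autoscale")
}

#' Apply or invert an autoscaling transform
#'
#' @param x Numeric matrix or vector (columns/positions matching the fit).
#' @param scaling An `"autoscale"` object from [autoscale_fit()].
#' @return Matrix (or vector) of the same shape.
#' @export
autoscale_apply <- function(x, scaling) {
  if (is.null(dim(x))) {
    return((x - scaling$center) / scaling$scale)
  }
  sweep(sweep(as.matrix(x), 2L, scaling$center, "-"), 2L, scaling$scale, "/")
}

#' @rdname autoscale_apply
#' @export
autoscale_invert <- function(x, scaling) {
  if (is.null(dim(x))) {
    return(x * scaling$scale + scaling$center)
  }
  sweep(sweep(as.matrix(x), 2L, scaling$scale, "*"), 2L, scaling$center, "+")
}

# Core single-response OPLS on matrices already autoscaled.
#
# The predictive weight is w = X'y / ||X'y||. Orthogonal components are
# extracted one at a time: the loading of the current predictive score is
# split into its part along w and its remainder; the remainder (normalized)
# is the orthogonal weight, whose score/loading pair is deflated from X.
# Because deflation never changes X'y (the orthogonal score is exactly
# uncorrelated with y by construction), w is invariant across components.
# With a single response the power iteration converges in one step, so no
# iterative refinement is needed.
opls_fit_core <- function(xs, ys, n_ortho) {
  p <- ncol(xs)
  w <- drop(crossprod(xs, ys))
  nw <- sqrt(sum(w^2))
  if (!is.finite(nw) || nw < 1e-12) {
    stop("degenerate fit: X'y is numerically zero (constant response?)",
         call. = FALSE)
  }
  w <- w / nw
  w_o <- p_o <- matrix(0, p, 0)
  xc <- xs
  for (i in seq_len(n_ortho)) {
    t <- drop(xc %*% w)
    pl <- drop(crossprod(xc, t)) / sum(t^2)
    wo <- pl - sum(w * pl) * w
    nwo <- sqrt(sum(wo^2))
    if (!is.finite(nwo) || nwo < 1e-10) break  # no orthogonal variation left
    wo <- wo / nwo
    to <- drop(xc %*% wo)
    po <- drop(crossprod(xc, to)) / sum(to^2)
    w_o <- cbind(w_o, wo)
    p_o <- cbind(p_o, po)
    xc <- xc - tcrossprod(to, po)
  }
  t <- drop(xc %*% w)
  pl <- drop(crossprod(xc, t)) / sum(t^2)
  cc <- sum(t * ys) / sum(t^2)
  list(w = w, p = pl, c = cc, w_o = w_o, p_o = p_o,
       n_ortho = ncol(w_o), t = t, x_filtered = xc)
}

# Autoscaled regression coefficients b with yhat_scaled = b . x_scaled,
# obtained by propagating w back through the orthogonal filtering maps
# x -> (I - p_o w_o') x.
opls_core_coef <- function(fit) {
  v <- fit$w
  for (i in rev(seq_len(fit$n_ortho))) {
    v <- v - fit$w_o[, i] * sum(fit$p_o[, i] * v)
  }
  fit$c * v
}

# Project one (possibly incomplete) autoscaled row through the model.
# Scores use the standard NIPALS missing-value convention: least-squares
# projection onto the observed coordinates, t = x_obs . w_obs / (w_obs . w_obs).
opls_project_row <- function(xrow, w, w_o, p_o, pl) {
  obs <- is.finite(xrow)
  if (!any(obs)) stop("all descriptor values missing", call. = FALSE)
  x <- xrow
  t_o <- numeric(ncol(w_o))
  for (i in seq_len(ncol(w_o))) {
    wi <- w_o[, i]
    t_o[i] <- sum(x[obs] * wi[obs]) / sum(wi[obs]^2)
    x[obs] <- x[obs] - t_o[i] * p_o[obs, i]
  }
  t <- sum(x[obs] * w[obs]) / sum(w[obs]^2)
  res <- x - t * pl
  res[!obs] <- NA_real_
  list(t = t, t_o = t_o, residual = res,
       rsd = sqrt(mean(res[obs]^2)))
}

#' Fit an orthogonal projections to latent structures (OPLS) model
#'
#' Single-response OPLS regression: the systematic variation in the
#' descriptor matrix is separated into one component linearly related to
#' the response and `n_ortho` components orthogonal to it. Inputs are
#' mean-centered and autoscaled internally; the response is treated as a
#' continuous variable (for ordinal class responses, the integer class).
#' With `n_ortho = "auto"` the number of orthogonal components is chosen
#' by 7-fold cross-validation: components are added while the cumulative
#' Q2Y improves by more than `q2_threshold`.
#'
#' The residual-standard-deviation applicability-domain reference (the
#' average left-out-fold compound rsd under the same cross-validation) is
#' computed at fit time and stored in the model; see [ad_assess()].
#'
#' @param x Numeric descriptor matrix (rows = compounds, named columns).
#' @param y Numeric response, one value per row of `x`.
#' @param n_ortho Number of orthogonal components, or `"auto"`.
#' @param folds Number of cross-validation folds (default 7).
#' @param seed Integer seed controlling the fold assignment.
#' @param q2_threshold Minimum cumulative Q2Y improvement for accepting a
#'   further orthogonal component (default 0.01).
#' @param max_ortho Hard cap on orthogonal components (default 10).
#' @param ad_threshold_factor Multiplier of the training average rsd
#'   beyond which a query is out of the applicability domain (default 2).
#' @return An object of class `"opls"`; see Details. Key fields:
#'   `weights` (unit predictive weight), `loadings`, `ortho_weights`,
#'   `ortho_loadings`, `n_ortho`, `coefficients` (autoscaled), `cv`
#'   (per-component Q2Y report when selection ran), `ad_reference`.
#' @export
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(200), 20, 10, dimnames = list(NULL, paste0("d", 1:10)))
#' y <- x[, 1] - x[, 2] + rnorm(20, sd = 0.1)
#' m <- opls(x, y, n_ortho = 0)
#' round(cor(predict(m, x), y), 2)
opls <- function(x, y, n_ortho = "auto", folds = 7L, seed = 1L,
                 q2_threshold = 0.01, max_ortho = 10L,
                 ad_threshold_factor = 2) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  stopifnot(nrow(x) == length(y), nrow(x) >= 2L)
  if (anyNA(x)) stop("training descriptor matrix must be complete", call. = FALSE)
  if (anyNA(y)) stop("training response must be complete", call. = FALSE)
  if (stats::sd(y) == 0) {
    stop("degenerate input: response is constant", call. = FALSE)
  }
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))

  cv <- NULL
  if (identical(n_ortho, "auto")) {
    cv <- select_components(x, y, folds = folds, seed = seed,
                            q2_threshold = q2_threshold,
                            max_ortho = max_ortho)
    n_ortho <- cv$n_ortho
  }
  n_ortho <- as.integer(n_ortho)
  stopifnot(n_ortho >= 0L)

  scaling <- autoscale_fit(x)
  y_center <- mean(y)
  y_scale <- stats::sd(y)
  xs <- autoscale_apply(x, scaling)
  ys <- (y - y_center) / y_scale
  fit <- opls_fit_core(xs, ys, n_ortho)
  b <- opls_core_coef(fit)

  fitted_scaled <- fit$c * fit$t
  fitted <- y_center + y_scale * fitted_scaled
  x_res <- fit$x_filtered - tcrossprod(fit$t, fit$p)
  rsd_train <- sqrt(rowMeans(x_res^2))

  model <- structure(list(
    descriptor_names = colnames(x),
    scaling = scaling,
    y_center = y_center, y_scale = y_scale,
    weights = stats::setNames(fit$w, colnames(x)),
    loadings = stats::setNames(fit$p, colnames(x)),
    score_coef = fit$c,
    ortho_weights = fit$w_o,
    ortho_loadings = fit$p_o,
    n_ortho = fit$n_ortho,
    coefficients = stats::setNames(b, colnames(x)),
    cv = cv,
    fitted.values = fitted,
    residuals = y - fitted,
    y = y,
    rsd_train = rsd_train,
    ad_reference = NA_real_,
    ad_threshold_factor = ad_threshold_factor,
    folds = as.integer(folds), seed = as.integer(seed),
    call = match.call()
  ), class = "opls")
  model$ad_reference <- training_reference_rsd(
    x, y, n_ortho = fit$n_ortho, folds = folds, seed = seed
  )
  model
}

#' Cross-validated selection of orthogonal components
#'
#' Computes the cumulative Q2Y of OPLS models with 0, 1, 2, ... orthogonal
#' components under k-fold cross-validation (seeded shuffle, contiguous
#' blocks) and applies the selection rule: keep adding orthogonal
#' components while the cumulative Q2Y improves by more than
#' `q2_threshold`, up to `max_ortho`.
#'
#' @inheritParams opls
#' @return An object of class `"opls_cv"`: list with `q2` (named vector,
#'   entry `"0"` upward), `n_ortho` (the chosen count), `folds`, `seed`,
#'   `q2_threshold`.
#' @export
select_components <- function(x, y, folds = 7L, seed = 1L,
                              q2_threshold = 0.01, max_ortho = 10L) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  n <- nrow(x)
  folds <- as.integer(folds)
  if (folds > n) stop("more folds than rows", call. = FALSE)
  if (stats::sd(y) == 0) {
    stop("degenerate input: response is constant", call. = FALSE)
  }
  fold_id <- cv_fold_assignment(n, folds, seed)
  ss_tot <- sum((y - mean(y))^2)
  max_ortho <- min(as.integer(max_ortho), n - n %/% folds - 2L, ncol(x) - 1L)
  max_ortho <- max(max_ortho, 0L)

  q2 <- numeric(0)
  for (k in 0:max_ortho) {
    press <- 0
    for (f in seq_len(folds)) {
      hold <- fold_id == f
      scaling <- autoscale_fit(x[!hold, , drop = FALSE])
      yc <- mean(y[!hold]); ysc <- stats::sd(y[!hold])
      if (ysc == 0) ysc <- 1
      fit <- opls_fit_core(autoscale_apply(x[!hold, , drop = FALSE], scaling),
                           (y[!hold] - yc) / ysc, k)
      xh <- autoscale_apply(x[hold, , drop = FALSE], scaling)
      pred <- apply(xh, 1L, function(r) {
        pr <- opls_project_row(r, fit$w, fit$w_o, fit$p_o, fit$p)
        yc + ysc * fit$c * pr$t
      })
      press <- press + sum((y[hold] - pred)^2)
    }
    q2 <- c(q2, 1 - press / ss_tot)
    # stop early once an added component no longer improves
    len <- length(q2)
    if (len >= 2L && q2[len] <= q2[len - 1L] + q2_threshold) break
  }
  names(q2) <- as.character(seq_along(q2) - 1L)
  chosen <- 0L
  for (k in seq_len(length(q2) - 1L)) {
    if (q2[k + 1L] > q2[k] + q2_threshold) chosen <- k else break
  }
  structure(list(q2 = q2, n_ortho = chosen, folds = folds,
                 seed = as.integer(seed), q2_threshold = q2_threshold),
            class = "opls_cv")
}

# Contiguous-block fold assignment after a seeded shuffle.
cv_fold_assignment <- function(n, folds, seed) {
  perm <- with_seed(seed, sample.int(n))
  sizes <- rep(n %/% folds, folds)
  extra <- n %% folds
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  fold_id <- integer(n)
  fold_id[perm] <- rep(seq_len(folds), sizes)
  fold_id
}

# Evaluate expr with a temporary RNG state seeded by `seed`.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

opls_project <- function(object, newdata) {
  xs <- prepare_newdata(object, newdata)
  rows <- lapply(seq_len(nrow(xs)), function(i) {
    opls_project_row(xs[i, ], object$weights, object$ortho_weights,
                     object$ortho_loadings, object$loadings)
  })
  t <- vapply(rows, `[[`, 0, "t")
  list(
    t = t,
    rsd = vapply(rows, `[[`, 0, "rsd"),
    residuals = do.call(rbind, lapply(rows, `[[`, "residual")),
    yhat = object$y_center + object$y_scale * object$score_coef * t
  )
}

prepare_newdata <- function(object, newdata) {
  if (is.null(dim(newdata))) {
    newdata <- matrix(newdata, nrow = 1L,
                      dimnames = list(NULL, names(newdata)))
  }
  newdata <- as.matrix(newdata)
  storage.mode(newdata) <- "double"
  nms <- object$descriptor_names
  if (!is.null(colnames(newdata))) {
    missing_cols <- setdiff(nms, colnames(newdata))
    if (length(missing_cols)) {
      stop("newdata lacks descriptor column(s): ",
           paste(utils::head(missing_cols, 5L), collapse = ", "),
           call. = FALSE)
    }
    newdata <- newdata[, nms, drop = FALSE]
  } else if (ncol(newdata) != length(nms)) {
    stop("newdata has ", ncol(newdata), " columns; model expects ",
         length(nms), call. = FALSE)
  }
  autoscale_apply(newdata, object$scaling)
}

#' Predict from an OPLS model
#'
#' Orthogonal components are removed from the (autoscaled) query row, the
#' predictive score is formed, and the response is returned on its
#' original scale. Missing descriptor entries (`NA`) are handled by the
#' standard NIPALS convention: every score is the least-squares projection
#' onto the observed coordinates only.
#'
#' @param object An `"opls"` model.
#' @param newdata Matrix, data frame or single named vector of descriptor
#'   values; columns are matched by name when names are present.
#' @param type `"response"` (default) for the continuous prediction or
#'   `"class"` for the rounded ordinal class (see [round_to_class()]).
#' @param ... Unused.
#' @return Numeric (or integer, for `type = "class"`) vector of
#'   predictions.
#' @export
predict.opls <- function(object, newdata, type = c("response", "class"), ...) {
  type <- match.arg(type)
  pr <- opls_project(object, newdata)
  if (type == "class") round_to_class(pr$yhat) else pr$yhat
}

#' X-space residuals of an OPLS model
#'
#' @param object An `"opls"` model.
#' @param newdata Optional query matrix; when omitted, the training
#'   response residuals (`y - fitted`) are returned like other model
#'   classes. With `newdata`, the autoscaled X-residual matrix after
#'   removal of all model components is returned (missing positions `NA`).
#' @param ... Unused.
#' @export
residuals.opls <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$residuals)
  opls_project(object, newdata)$residuals
}

#' Extract OPLS regression coefficients
#'
#' The autoscaled coefficient vector `b` satisfying
#' `yhat = y_center + y_scale * sum(b * x_scaled)` for complete query
#' rows. With `threshold` set, only coefficients with absolute value
#' strictly greater than the threshold are returned (the conventional
#' display cut for coefficient plots is 0.05).
#'
#' @param object An `"opls"` model.
#' @param threshold Optional absolute-value filter.
#' @param ... Unused.
#' @return Named numeric vector.
#' @export
coef.opls <- function(object, threshold = NULL, ...) {
  b <- object$coefficients
  if (!is.null(threshold)) b <- b[abs(b) > threshold]
  b
}

#' @export
fitted.opls <- function(object, ...) object$fitted.values

#' @export
print.opls <- function(x, ...) {
  cat("OPLS model: 1 predictive + ", x$n_ortho, " orthogonal component(s), ",
      length(x$descriptor_names), " descriptors, n = ", length(x$y), "\n",
      sep = "")
  if (!is.null(x$cv)) {
    cat("  cross-validated Q2Y by orthogonal components:\n")
    print(round(x$cv$q2, 4))
  }
  cat("  AD reference rsd: ", signif(x$ad_reference, 4),
      " (threshold factor ", x$ad_threshold_factor, ")\n", sep = "")
  invisible(x)
}

#' @export
summary.opls <- function(object, ...) {
  r2 <- 1 - sum(object$residuals^2) / sum((object$y - mean(object$y))^2)
  big <- sort(abs(object$coefficients), decreasing = TRUE)
  out <- list(
    n = length(object$y),
    n_descriptors = length(object$descriptor_names),
    n_ortho = object$n_ortho,
    r2y = r2,
    cv = object$cv,
    ad_reference = object$ad_reference,
    top_coefficients = object$coefficients[names(utils::head(big, 10L))]
  )
  class(out) <- "summary.opls"
  out
}

#' @export
print.summary.opls <- function(x, ...) {
  cat("OPLS model summary\n")
  cat("  n =", x$n, ", descriptors =", x$n_descriptors,
      ", orthogonal components =", x$n_ortho, "\n")
  cat("  R2Y (training) =", round(x$r2y, 4), "\n")
  if (!is.null(x$cv)) {
    cat("  Q2Y(cum):", paste(names(x$cv$q2), round(x$cv$q2, 3),
                             sep = "=", collapse = "  "), "\n")
  }
  cat("  largest |coefficients|:\n")
  print(round(x$top_coefficients, 4))
  invisible(x)
}

#' Serialize an OPLS model to JSON
#'
#' Full-precision JSON serialization; [read_opls()] reproduces
#' predictions to machine precision.
#'
#' @param model An `"opls"` model.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_opls <- function(model, path) {
  obj <- list(
    format = "lysoacc-opls", format_version = 1L,
    package_version = as.character(utils::packageVersion("lysoacc")),
    descriptor_names = model$descriptor_names,
    x_center = unname(model$scaling$center),
    x_scale = unname(model$scaling$scale),
    y_center = model$y_center, y_scale = model$y_scale,
    weights = unname(model$weights),
    loadings = unname(model$loadings),
    score_coef = model$score_coef,
    ortho_weights = model$ortho_weights,
    ortho_loadings = model$ortho_loadings,
    n_ortho = model$n_ortho,
    coefficients = unname(model$coefficients),
    cv = if (!is.null(model$cv)) unclass(model$cv),
    ad_reference = model$ad_reference,
    ad_threshold_factor = model$ad_threshold_factor,
    folds = model$folds, seed = model$seed
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load an OPLS model serialized by [write_opls()]
#'
#' @param path JSON file path.
#' @return An `"opls"` model (without training data fields).
#' @export
read_opls <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "lysoacc-opls")) {
    stop("not a serialized OPLS model: ", path, call. = FALSE)
  }
  nms <- obj$descriptor_names
  p <- length(nms)
  as_mat <- function(m) {
    if (is.null(m) || length(m) == 0L) return(matrix(0, p, 0))
    m <- as.matrix(m)
    stopifnot(nrow(m) == p)
    m
  }
  structure(list(
    descriptor_names = nms,
    scaling = structure(list(center = stats::setNames(obj$x_center, nms),
                             scale = stats::setNames(obj$x_scale, nms)),
                        class = "autoscale"),
    y_center = obj$y_center, y_scale = obj$y_scale,
    weights = stats::setNames(obj$weights, nms),
    loadings = stats::setNames(obj$loadings, nms),
    score_coef = obj$score_coef,
    ortho_weights = as_mat(obj$ortho_weights),
    ortho_loadings = as_mat(obj$ortho_loadings),
    n_ortho = as.integer(obj$n_ortho),
    coefficients = stats::setNames(obj$coefficients, nms),
    cv = if (!is.null(obj$cv)) structure(obj$cv, class = "opls_cv"),
    ad_reference = obj$ad_reference,
    ad_threshold_factor = obj$ad_threshold_factor,
    folds = obj$folds, seed = obj$seed
  ), class = "opls")
}
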
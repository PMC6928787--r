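#' Cross-validated training reference rsd for the applicability domain
#'
#' For each of `folds` cross-validation folds, the model (autoscaling plus
#' OPLS with `n_ortho` orthogonal components) is refit on the remaining
#' folds and the residual standard deviation (rsd) of each left-out
#' compound -- the root-mean-square of its autoscaled X-residuals after
#' removal of all model components, i.e. the information in the
#' descriptor row the model does not use -- is computed against that
#' fold model. The mean over all compounds is the applicability-domain
#' reference stored with a fitted model.
#'
#' @param x Training descriptor matrix.
#' @param y Training response.
#' @param n_ortho Number of orthogonal components of the model spec.
#' @param folds Number of folds (default 7); must not exceed `nrow(x)`.
#' @param seed Integer seed for the fold assignment.
#' @return The mean left-out-compound rsd (positive scalar).
#' @export
training_reference_rsd <- function(x, y, n_ortho, folds = 7L, seed = 1L) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  n <- nrow(x)
  folds <- as.integer(folds)
  if (folds > n) stop("fewer rows than folds", call. = FALSE)
  fold_id <- cv_fold_assignment(n, folds, seed)
  rsd <- numeric(n)
  for (f in seq_len(folds)) {
    hold <- fold_id == f
    scaling <- autoscale_fit(x[!hold, , drop = FALSE])
    yc <- mean(y[!hold]); ysc <- stats::sd(y[!hold])
    if (ysc == 0) ysc <- 1
    fit <- opls_fit_core(autoscale_apply(x[!hold, , drop = FALSE], scaling),
                         (y[!hold] - yc) / ysc, n_ortho)
    xh <- autoscale_apply(x[hold, , drop = FALSE], scaling)
    rsd[hold] <- apply(xh, 1L, function(r) {
      opls_project_row(r, fit$w, fit$w_o, fit$p_o, fit$p)$rsd
    })
  }
  mean(rsd)
}

#' Applicability-domain assessment of query compounds
#'
#' A query compound is inside the applicability domain when its residual
#' standard deviation -- the root-mean-square of its autoscaled
#' X-residuals over observed descriptor positions after removal of all
#' model components -- does not exceed `threshold_factor` times the
#' model's cross-validated training average rsd (the default factor of 2
#' corresponds to an approximate 95% confidence cut). Missing descriptor
#' entries are excluded from both numerator and denominator of the rsd.
#'
#' @param model A fitted `"opls"` model (carrying `ad_reference`).
#' @param newdata Query descriptor matrix / data frame / named vector.
#' @param threshold_factor Multiplier of the reference rsd (defaults to
#'   the factor stored in the model, normally 2).
#' @return Data frame of class `"ad_diagnostics"` with columns `rsd` and
#'   `in_domain`, one row per query compound; the reference and factor
#'   are attached as attributes.
#' @export
ad_assess <- function(model, newdata, threshold_factor = NULL) {
  stopifnot(inherits(model, "opls"))
  if (is.null(threshold_factor)) threshold_factor <- model$ad_threshold_factor
  if (is.na(model$ad_reference)) {
    stop("model carries no applicability-domain reference", call. = FALSE)
  }
  pr <- opls_project(model, newdata)
  out <- data.frame(
    rsd = pr$rsd,
    in_domain = pr$rsd <= threshold_factor * model$ad_reference
  )
  nd <- if (is.null(dim(newdata))) NULL else rownames(newdata)
  if (!is.null(nd)) rownames(out) <- nd
  attr(out, "training_avg_rsd") <- model$ad_reference
  attr(out, "threshold_factor") <- threshold_factor
  class(out) <- c("ad_diagnostics", "data.frame")
  out
}
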
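#' Accumulation class cutpoints on the I/E scale
#'
#' Upper bounds of classes 1-4 on the intracellular/extracellular
#' concentration-ratio (I/E) scale; class 5 is open-ended. The printed
#' half-unit gaps between class ranges reflect a data resolution of 0.5,
#' so the bounds are implemented as half-open continuous intervals with
#' the upper bound inclusive in the lower class. On the %AZI scale
#' (accumulation relative to azithromycin) every bound is exactly twice
#' its I/E counterpart.
#'
#' @return Numeric vector `c(7, 33, 92, 220)`.
#' @export
acc_class_cutpoints <- function() c(7, 33, 92, 220)

#' Map an I/E ratio to its accumulation class
#'
#' Five ordinal classes of cellular accumulation: class 1 (no/low,
#' I/E <= 7), 2 (moderate, <= 33), 3 (high, <= 92), 4 (very high,
#' <= 220), 5 (extremely high, > 220).
#'
#' @param ie_ratio Nonnegative numeric vector of I/E ratios.
#' @return Integer vector of classes in 1..5.
#' @export
#' @examples
#' acc_class_from_ie(c(5, 50, 300))  # 1, 3, 5
acc_class_from_ie <- function(ie_ratio) {
  ie_ratio <- as.numeric(ie_ratio)
  if (anyNA(ie_ratio) || any(!is.finite(ie_ratio))) {
    stop("ie_ratio must be finite", call. = FALSE)
  }
  if (any(ie_ratio < 0)) stop("ie_ratio must be nonnegative", call. = FALSE)
  cuts <- acc_class_cutpoints()
  cls <- 1L + rowSums(outer(ie_ratio, cuts, ">"))
  as.integer(cls)
}

#' Convert between the %AZI and I/E accumulation scales
#'
#' Accumulation relative to the control compound azithromycin (%AZI) is
#' exactly twice the I/E ratio; conversions are exact with no rounding.
#'
#' @param azi_percent,ie_ratio Numeric vectors.
#' @return Numeric vector on the other scale.
#' @export
azi_to_ie <- function(azi_percent) as.numeric(azi_percent) / 2

#' @rdname azi_to_ie
#' @export
ie_to_azi <- function(ie_ratio) as.numeric(ie_ratio) * 2

#' Round a continuous prediction to an ordinal class
#'
#' Nearest integer, halves rounded away from zero, clamped to 1..5.
#'
#' @param x Finite numeric vector.
#' @return Integer vector in 1..5.
#' @export
#' @examples
#' round_to_class(c(2.4, 3.5, 5.7))  # 2, 4, 5
round_to_class <- function(x) {
  x <- as.numeric(x)
  if (anyNA(x) || any(!is.finite(x))) {
    stop("predictions must be finite for class rounding", call. = FALSE)
  }
  cls <- sign(x) * floor(abs(x) + 0.5)
  as.integer(pmin(pmax(cls, 1), 5))
}

#' Printed per-class compound counts of the study design
#'
#' The marginal distribution of the 77-compound set over the five
#' accumulation classes: `acc` counts compounds by their LC-MS/MS-derived
#' ACC class and `ltr` counts the 47 compounds that also carry the
#' imaging-derived LTR class. (The printed ACC counts sum to 75 rather
#' than 77; the synthetic generator keeps the printed proportions and
#' rescales them to the requested sample size.)
#'
#' @return List with integer vectors `acc` and `ltr` (length 5 each).
#' @export
table1_counts <- function() {
  list(acc = c(22L, 23L, 14L, 9L, 7L),
       ltr = c(14L, 10L, 7L, 11L, 5L))
}

#' Assign compounds to training and validation sets
#'
#' The split rule of the study design: compounds with both ACC and LTR
#' class labels form the training set; compounds with an ACC label but no
#' LTR label form the validation set. An explicit `set_label` column
#' overrides the rule where present. Rows with no ACC label are left
#' unassigned (`NA`) with a warning.
#'
#' @param records Data frame with columns `acc_class`, `ltr_class` and
#'   optionally `set_label`.
#' @return The records with a filled `set_label` column.
#' @export
assign_sets <- function(records) {
  stopifnot(is.data.frame(records))
  lab <- if (is.null(records$set_label)) rep(NA_character_, nrow(records)) else
    as.character(records$set_label)
  auto <- ifelse(!is.na(records$acc_class) & !is.na(records$ltr_class),
                 "training",
                 ifelse(!is.na(records$acc_class), "validation",
                        NA_character_))
  fill <- is.na(lab) | !nzchar(lab)
  lab[fill] <- auto[fill]
  if (anyNA(lab)) {
    warning(sum(is.na(lab)), " row(s) without ACC label left unassigned",
            call. = FALSE)
  }
  records$set_label <- lab
  records
}

ltr_column <- "LTR_class"

#' Fit the three-model accumulation suite
#'
#' Fits, on a fully labeled training table, the three OPLS models of the
#' accumulation pipeline:
#' \describe{
#'   \item{model1}{ACC class ~ 97 descriptors + the measured LTR class
#'     (98 predictor columns).}
#'   \item{model2}{ACC class ~ 97 descriptors.}
#'   \item{model3}{LTR class ~ 97 descriptors (the surrogate-imaging
#'     model whose prediction can replace the experimental LTR value).}
#' }
#' Each model runs its own cross-validated orthogonal-component selection
#' and stores its own applicability-domain reference.
#'
#' @param train Data frame holding the 97 descriptor columns plus
#'   `acc_class` and `ltr_class` (no missing labels), as produced by
#'   [build_descriptor_table()] or [lyso_simulate()].
#' @param folds,seed,q2_threshold,max_ortho,ad_threshold_factor Passed to
#'   [opls()].
#' @return Object of class `"lyso_models"`: list with elements `model1`,
#'   `model2`, `model3` plus bookkeeping.
#' @export
lyso_fit <- function(train, folds = 7L, seed = 1L, q2_threshold = 0.01,
                     max_ortho = 10L, ad_threshold_factor = 2) {
  stopifnot(is.data.frame(train))
  nms <- descriptor_names()
  missing_cols <- setdiff(c(nms, "acc_class", "ltr_class"), names(train))
  if (length(missing_cols)) {
    stop("training table lacks column(s): ",
         paste(utils::head(missing_cols, 5L), collapse = ", "), call. = FALSE)
  }
  if (anyNA(train$acc_class) || anyNA(train$ltr_class)) {
    stop("all training rows must carry both acc_class and ltr_class",
         call. = FALSE)
  }
  x <- as.matrix(train[, nms, drop = FALSE])
  storage.mode(x) <- "double"
  x1 <- cbind(x, matrix(as.numeric(train$ltr_class), ncol = 1L,
                        dimnames = list(NULL, ltr_column)))
  acc <- as.numeric(train$acc_class)
  ltr <- as.numeric(train$ltr_class)
  args <- list(folds = folds, seed = seed, q2_threshold = q2_threshold,
               max_ortho = max_ortho, ad_threshold_factor = ad_threshold_factor)
  models <- structure(list(
    model1 = do.call(opls, c(list(x1, acc, n_ortho = "auto"), args)),
    model2 = do.call(opls, c(list(x, acc, n_ortho = "auto"), args)),
    model3 = do.call(opls, c(list(x, ltr, n_ortho = "auto"), args)),
    descriptor_names = nms,
    n_train = nrow(train),
    seed = as.integer(seed)
  ), class = "lyso_models")
  models
}

#' @export
print.lyso_models <- function(x, ...) {
  comp <- vapply(x[c("model1", "model2", "model3")], `[[`, 0L, "n_ortho")
  cat("Three-model accumulation suite (n_train = ", x$n_train, ")\n", sep = "")
  cat("  model1 (ACC ~ descriptors + LTR): 1 + ", comp[1L],
      " components\n", sep = "")
  cat("  model2 (ACC ~ descriptors):       1 + ", comp[2L],
      " components\n", sep = "")
  cat("  model3 (LTR ~ descriptors):       1 + ", comp[3L],
      " components\n", sep = "")
  invisible(x)
}

#' Predict validation compounds under the three schemes
#'
#' Applies the fitted suite to query compounds that carry no measured LTR
#' class, under up to three prediction schemes:
#' \describe{
#'   \item{`no_ltr`}{model2 applied to the 97 descriptors.}
#'   \item{`missing_ltr`}{model1 with the LTR position treated as missing
#'     data (NIPALS observed-coordinate projection).}
#'   \item{`predicted_ltr`}{model3 first predicts the LTR class from the
#'     descriptors; its output (rounded to an integer class by default)
#'     is inserted as the LTR descriptor value and model1 is applied --
#'     the information-fusion scheme.}
#' }
#' Applicability-domain diagnostics are computed per scheme against that
#' scheme's model.
#'
#' @param object A `"lyso_models"` suite from [lyso_fit()].
#' @param newdata Data frame or matrix with the 97 descriptor columns
#'   (and optionally `compound_id`).
#' @param scheme `"all"` (default) or a subset of
#'   `c("predicted_ltr", "missing_ltr", "no_ltr")`.
#' @param ltr_input `"class"` (default) rounds model3's output to an
#'   integer class before insertion; `"continuous"` passes it through
#'   unrounded (sensitivity analysis).
#' @param ... Unused.
#' @return Data frame with columns `compound_id`, `scheme`,
#'   `y_continuous`, `y_class`, `rsd`, `in_domain` -- one row per
#'   compound and scheme.
#' @export
predict.lyso_models <- function(object, newdata,
                                scheme = "all",
                                ltr_input = c("class", "continuous"), ...) {
  ltr_input <- match.arg(ltr_input)
  schemes <- c("predicted_ltr", "missing_ltr", "no_ltr")
  if (!identical(scheme, "all")) {
    scheme <- match.arg(scheme, schemes, several.ok = TRUE)
    schemes <- schemes[schemes %in% scheme]
  }
  if (is.data.frame(newdata) && "compound_id" %in% names(newdata)) {
    ids <- as.character(newdata$compound_id)
  } else if (!is.null(rownames(newdata))) {
    ids <- rownames(newdata)
  } else {
    ids <- as.character(seq_len(nrow(newdata)))
  }
  x <- as.matrix(as.data.frame(newdata)[, object$descriptor_names,
                                        drop = FALSE])
  storage.mode(x) <- "double"

  one_scheme <- function(sch) {
    if (sch == "no_ltr") {
      model <- object$model2
      xq <- x
    } else {
      model <- object$model1
      ltr_val <- if (sch == "missing_ltr") {
        rep(NA_real_, nrow(x))
      } else {
        ltr_hat <- predict(object$model3, x)
        if (ltr_input == "class") as.numeric(round_to_class(ltr_hat)) else
          ltr_hat
      }
      xq <- cbind(x, matrix(ltr_val, ncol = 1L,
                            dimnames = list(NULL, ltr_column)))
    }
    pr <- opls_project(model, xq)
    ad <- pr$rsd <= model$ad_threshold_factor * model$ad_reference
    data.frame(compound_id = ids, scheme = sch,
               y_continuous = pr$yhat,
               y_class = round_to_class(pr$yhat),
               rsd = pr$rsd, in_domain = ad,
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(schemes, one_scheme))
  rownames(out) <- NULL
  out
}

#' Stratified internal holdout of the training set
#'
#' Selects approximately `frac` of the training compounds as an internal
#' validation set, stratified by accumulation class (a seeded utility for
#' internal validation runs).
#'
#' @param acc_class Integer vector of training classes.
#' @param frac Holdout fraction (default 1/3).
#' @param seed Integer seed.
#' @return Integer vector of holdout row indices.
#' @export
internal_holdout <- function(acc_class, frac = 1 / 3, seed = 1L) {
  stopifnot(frac > 0, frac < 1)
  with_seed(seed, {
    idx <- unlist(lapply(split(seq_along(acc_class), acc_class), function(i) {
      k <- max(1L, round(length(i) * frac))
      if (length(i) == 1L) i else sample(i, k)
    }), use.names = FALSE)
    sort(idx)
  })
}

#' Write a prediction table to CSV
#'
#' Byte-identical output for identical inputs; numeric columns are
#' written at full precision.
#'
#' @param predictions Data frame from [predict.lyso_models()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  utils::write.csv(predictions, path, row.names = FALSE, na = "")
  invisible(path)
}
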
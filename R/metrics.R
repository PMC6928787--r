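#' Multi-class balanced accuracy (non-error rate)
#'
#' Macro-average of per-class recall over the classes present in the
#' truth vector; insensitive to class imbalance. Classes absent from the
#' truth are excluded from the average; classes never predicted
#' contribute recall 0 for their true members as usual.
#'
#' @param truth,predicted Equal-length nonempty class label vectors.
#' @return Balanced accuracy in \[0, 1\].
#' @export
#' @examples
#' balanced_accuracy(c(1, 1, 2, 2, 3), c(1, 2, 2, 2, 3))  # 0.8333
balanced_accuracy <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    stop("truth and predicted must have equal length", call. = FALSE)
  }
  if (length(truth) == 0L) stop("empty label vectors", call. = FALSE)
  recalls <- vapply(split(predicted == truth, truth), mean, 0)
  mean(recalls)
}

#' Per-class recall
#'
#' @inheritParams balanced_accuracy
#' @param classes Class labels to report (default 1:5).
#' @return Named numeric vector; `NA` for classes absent from truth.
#' @export
per_class_recall <- function(truth, predicted, classes = 1:5) {
  vapply(classes, function(k) {
    i <- truth == k
    if (!any(i)) NA_real_ else mean(predicted[i] == k)
  }, 0, USE.NAMES = FALSE) -> r
  stats::setNames(r, as.character(classes))
}

#' Spearman rank correlation
#'
#' Pearson correlation of average-ranked values (ties averaged). Errors
#' on degenerate input with zero rank variance.
#'
#' @param truth,predicted Equal-length numeric/ordinal vectors, length >= 3.
#' @return Correlation in \[-1, 1\].
#' @export
#' @examples
#' spearman_r(1:5, c(1, 3, 2, 4, 5))  # 0.9
spearman_r <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    stop("truth and predicted must have equal length", call. = FALSE)
  }
  if (length(truth) < 3L) stop("need at least 3 observations", call. = FALSE)
  rt <- rank(truth)
  rp <- rank(predicted)
  if (stats::sd(rt) == 0 || stats::sd(rp) == 0) {
    stop("Spearman correlation undefined: zero rank variance", call. = FALSE)
  }
  stats::cor(rt, rp)
}

#' McNemar's chi-squared test with continuity correction
#'
#' Paired comparison of two classifiers over the same compounds from
#' their correctness indicators. With `b` compounds correct under scheme
#' A only and `c` under scheme B only, the continuity-corrected statistic
#' is `(|b - c| - 1)^2 / (b + c)` with a two-sided p-value from the
#' chi-squared distribution with 1 degree of freedom. When `b + c = 0`
#' the statistic is 0 and the p-value 1.
#'
#' @param correct_a,correct_b Equal-length logical vectors: was each
#'   compound's class predicted exactly right under scheme A / B?
#' @return Object of class `"mcnemar_cc"`: list with `b`, `c`,
#'   `statistic`, `p_value`.
#' @export
#' @examples
#' mcnemar_cc(rep(c(TRUE, FALSE), c(8, 2)), rep(c(FALSE, TRUE), c(8, 2)))
mcnemar_cc <- function(correct_a, correct_b) {
  if (length(correct_a) != length(correct_b)) {
    stop("correctness vectors must have equal length", call. = FALSE)
  }
  correct_a <- as.logical(correct_a)
  correct_b <- as.logical(correct_b)
  if (anyNA(correct_a) || anyNA(correct_b)) {
    stop("correctness vectors must not contain NA", call. = FALSE)
  }
  b <- sum(correct_a & !correct_b)
  cc <- sum(!correct_a & correct_b)
  if (b + cc == 0L) {
    stat <- 0
    p <- 1
  } else {
    stat <- (abs(b - cc) - 1)^2 / (b + cc)
    p <- stats::pchisq(stat, df = 1L, lower.tail = FALSE)
  }
  structure(list(b = b, c = cc, statistic = stat, p_value = p),
            class = "mcnemar_cc")
}

#' @export
print.mcnemar_cc <- function(x, ...) {
  cat("McNemar's chi-squared test (continuity corrected)\n")
  cat("  discordant counts: b =", x$b, ", c =", x$c, "\n")
  cat("  X-squared =", signif(x$statistic, 5),
      ", df = 1, p-value =", signif(x$p_value, 4), "\n")
  invisible(x)
}

#' Confusion table over fixed class labels
#'
#' @inheritParams balanced_accuracy
#' @param classes Class labels spanning the table (default 1:5).
#' @return Integer matrix, rows = truth, columns = predicted.
#' @export
confusion_table <- function(truth, predicted, classes = 1:5) {
  tab <- table(factor(truth, levels = classes),
               factor(predicted, levels = classes))
  m <- matrix(as.integer(tab), length(classes), length(classes),
              dimnames = list(truth = as.character(classes),
                              predicted = as.character(classes)))
  m
}

#' Evaluation report for one set of class predictions
#'
#' Bundles balanced accuracy, Spearman rank correlation, the 5x5
#' confusion table, the maximum absolute class error, and sample sizes.
#' With `ad_filter = TRUE` all metrics are restricted to in-domain
#' compounds; an empty in-domain subset yields `NA` metrics (flagged via
#' `defined = FALSE`) rather than an error.
#'
#' @param truth Integer truth classes.
#' @param predicted Integer predicted classes.
#' @param in_domain Optional logical applicability-domain flags.
#' @param ad_filter Restrict metrics to in-domain compounds?
#' @return Object of class `"lyso_eval"` (a list).
#' @export
evaluate_predictions <- function(truth, predicted, in_domain = NULL,
                                 ad_filter = FALSE) {
  if (length(truth) != length(predicted)) {
    stop("truth and predicted must have equal length", call. = FALSE)
  }
  n_total <- length(truth)
  if (is.null(in_domain)) in_domain <- rep(TRUE, n_total)
  n_in <- sum(in_domain)
  keep <- if (ad_filter) in_domain else rep(TRUE, n_total)
  out <- list(n_total = n_total, n_in_domain = n_in,
              ad_filter = ad_filter, defined = any(keep))
  if (!any(keep)) {
    out[c("balanced_accuracy", "spearman_r", "max_class_error")] <- NA_real_
    out$confusion <- confusion_table(integer(0), integer(0))
    out$per_class_recall <- stats::setNames(rep(NA_real_, 5L), 1:5)
  } else {
    tr <- truth[keep]
    pr <- predicted[keep]
    out$balanced_accuracy <- balanced_accuracy(tr, pr)
    out$spearman_r <- tryCatch(spearman_r(tr, pr),
                               error = function(e) NA_real_)
    out$confusion <- confusion_table(tr, pr)
    out$max_class_error <- max(abs(pr - tr))
    out$per_class_recall <- per_class_recall(tr, pr)
  }
  class(out) <- "lyso_eval"
  out
}

#' @export
print.lyso_eval <- function(x, ...) {
  cat("Evaluation (", if (x$ad_filter) "in-domain compounds only" else
    "all compounds", "): n = ", x$n_total,
    ", in-domain = ", x$n_in_domain, "\n", sep = "")
  cat("  balanced accuracy =", round(x$balanced_accuracy, 4),
      "; Spearman R =", round(x$spearman_r, 4),
      "; max class error =", x$max_class_error, "\n")
  print(x$confusion)
  invisible(x)
}

#' Evaluate prediction schemes and compare them pairwise
#'
#' For each prediction scheme, computes an evaluation report (AD-off and,
#' when requested, AD-on restricted to that scheme's in-domain
#' compounds), and compares every pair of schemes with McNemar's test on
#' the common, unfiltered compound set using exact-class correctness.
#'
#' @param truth Named or ordered integer truth classes, one per compound.
#' @param predictions Prediction data frame from [predict.lyso_models()]
#'   (columns `compound_id`, `scheme`, `y_class`, `in_domain`).
#' @param ad_filter `"both"` (default), `"on"` or `"off"`.
#' @return Object of class `"lyso_report"`: list with `schemes` (per
#'   scheme, reports `ad_off`/`ad_on`) and `pairwise` (per scheme pair, a
#'   [mcnemar_cc()] result).
#' @export
evaluate_schemes <- function(truth, predictions,
                             ad_filter = c("both", "on", "off")) {
  ad_filter <- match.arg(ad_filter)
  stopifnot(is.data.frame(predictions))
  schemes <- unique(predictions$scheme)
  by_scheme <- split(predictions, predictions$scheme)
  ids <- unique(predictions$compound_id)
  if (!all(vapply(by_scheme, nrow, 0L) == length(ids))) {
    stop("schemes must cover the same compound set", call. = FALSE)
  }
  if (is.null(names(truth))) {
    if (length(truth) != length(ids)) {
      stop("truth length must match the compound set", call. = FALSE)
    }
    truth <- stats::setNames(as.integer(truth), ids)
  }

  reports <- lapply(by_scheme, function(d) {
    d <- d[match(ids, d$compound_id), ]
    tr <- truth[ids]
    r <- list()
    if (ad_filter != "on") {
      r$ad_off <- evaluate_predictions(tr, d$y_class, d$in_domain,
                                       ad_filter = FALSE)
    }
    if (ad_filter != "off") {
      r$ad_on <- evaluate_predictions(tr, d$y_class, d$in_domain,
                                      ad_filter = TRUE)
    }
    r
  })

  pairwise <- list()
  if (length(schemes) >= 2L) {
    correct <- lapply(by_scheme, function(d) {
      d <- d[match(ids, d$compound_id), ]
      d$y_class == truth[ids]
    })
    combs <- utils::combn(sort(names(by_scheme)), 2L, simplify = FALSE)
    for (pair in combs) {
      pairwise[[paste(pair, collapse = "_vs_")]] <-
        mcnemar_cc(correct[[pair[1L]]], correct[[pair[2L]]])
    }
  }
  structure(list(schemes = reports, pairwise = pairwise),
            class = "lyso_report")
}

#' @export
print.lyso_report <- function(x, ...) {
  for (s in names(x$schemes)) {
    r <- x$schemes[[s]]$ad_off %||% x$schemes[[s]]$ad_on
    cat(sprintf("%-14s BA = %.3f  Spearman R = %.3f  (n = %d, in-AD = %d)\n",
                s, r$balanced_accuracy, r$spearman_r, r$n_total,
                r$n_in_domain))
  }
  for (p in names(x$pairwise)) {
    m <- x$pairwise[[p]]
    cat(sprintf("%s: b = %d, c = %d, X2 = %.3f, p = %.4f\n",
                p, m$b, m$c, m$statistic, m$p_value))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an evaluation report to JSON
#'
#' Schema: `{scheme: {ad_off: {...}, ad_on: {...}}, pairwise:
#' {pair: {b, c, statistic, p_value}}}` with confusion tables as 5x5
#' arrays.
#'
#' @param report A `"lyso_report"` from [evaluate_schemes()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  strip <- function(r) {
    r$confusion <- unname(r$confusion)
    r$per_class_recall <- as.list(r$per_class_recall)
    unclass(r)
  }
  obj <- list(
    schemes = lapply(report$schemes, function(s) lapply(s, strip)),
    pairwise = lapply(report$pairwise, unclass)
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       na = "null", pretty = TRUE)
  invisible(path)
}
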
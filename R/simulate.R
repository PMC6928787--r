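#' Configuration of the synthetic-data generator
#'
#' Defaults reproduce the statistical structure of the study design: a
#' 47-compound training set and 30-compound validation set over 97
#' descriptors; five ordinal accumulation classes with the printed
#' marginal distribution (22:23:14:9:7, rescaled to the sample size by
#' largest-remainder rounding); an imaging surrogate (LTR class) agreeing
#' with the ACC class 81% of the time with errors of at most one class;
#' and a descriptor matrix built from a latent accumulation propensity
#' (the response-predictive variation), response-orthogonal systematic
#' factors, an LTR-specific signal direction, and heteroscedastic noise.
#'
#' Per-compound noise scales are lognormal with `noise_tail_sd` chosen so
#' that twice the average compound residual sits at the ~95th percentile
#' of the residual distribution -- the design reading of the
#' applicability-domain cut as an approximate 95% confidence interval.
#'
#' @param n_train,n_valid Training / validation sample sizes (47 / 30).
#' @param n_descriptors Number of descriptor columns (97; with the
#'   default the real descriptor names are used so generated tables are
#'   drop-in compatible with [lyso_fit()]).
#' @param n_predictive_factors Latent factors carrying the accumulation
#'   propensity (default 2).
#' @param n_orthogonal_factors Response-orthogonal systematic factors
#'   (default 3).
#' @param noise_sd Noise standard deviation per descriptor entry
#'   (default 0.1).
#' @param ltr_agreement Probability that the LTR class equals the ACC
#'   class (default 0.81); disagreements are one class off.
#' @param latent_cor Correlation between the descriptor-visible
#'   propensity and the full accumulation propensity (default 0.6):
#'   2D descriptors only partially determine accumulation, while the
#'   imaging surrogate reflects the measured accumulation itself -- this
#'   is what makes the surrogate genuinely complementary to the
#'   descriptors' direct signal.
#' @param acc_class_counts Five class counts (default: printed marginal
#'   counts rescaled to `n_train + n_valid`).
#' @param predictive_scale Total loading norm of the predictive variation
#'   (default 2.5: the compound series is engineered to span the
#'   accumulation range, making the propensity the dominant axis).
#' @param orth_scale Loading norm of each orthogonal factor (default 0.5).
#' @param ltr_signal Strength of the LTR-specific descriptor direction;
#'   documented levels 0.06 / 0.15 / 0.6 (weak / moderate / strong), the
#'   strong level being the default.
#' @param n_ltr_columns Number of descriptor columns carrying the
#'   LTR-specific signal (default 12): the imaging response has its own
#'   structural signature confined to a subset of descriptors.
#' @param noise_tail_sd Lognormal sd of per-compound noise scales
#'   (default solves the 95th-percentile condition above).
#' @return List of class `"lyso_sim_config"`.
#' @export
lyso_sim_config <- function(n_train = 47L, n_valid = 30L,
                            n_descriptors = 97L,
                            n_predictive_factors = 2L,
                            n_orthogonal_factors = 3L,
                            noise_sd = 0.1,
                            ltr_agreement = 0.81,
                            latent_cor = 0.6,
                            acc_class_counts = NULL,
                            predictive_scale = 2.5,
                            orth_scale = 0.5,
                            ltr_signal = 0.6,
                            n_ltr_columns = 12L,
                            noise_tail_sd = NULL) {
  n <- n_train + n_valid
  if (is.null(acc_class_counts)) {
    acc_class_counts <- scale_counts(table1_counts()$acc, n)
  }
  stopifnot(length(acc_class_counts) == 5L, sum(acc_class_counts) == n,
            n > 0L, noise_sd > 0, ltr_agreement > 0, ltr_agreement <= 1,
            latent_cor > 0, latent_cor <= 1)
  if (is.null(noise_tail_sd)) {
    # P(scale > 2 * E[scale]) = 0.05 for lognormal with unit mean:
    # solve (log 2 + sd^2/2)/sd = qnorm(0.95)
    q <- stats::qnorm(0.95)
    noise_tail_sd <- q - sqrt(q^2 - 2 * log(2))
  }
  structure(list(
    n_train = as.integer(n_train), n_valid = as.integer(n_valid),
    n_descriptors = as.integer(n_descriptors),
    n_predictive_factors = as.integer(n_predictive_factors),
    n_orthogonal_factors = as.integer(n_orthogonal_factors),
    noise_sd = noise_sd, ltr_agreement = ltr_agreement,
    latent_cor = latent_cor,
    acc_class_counts = as.integer(acc_class_counts),
    predictive_scale = predictive_scale, orth_scale = orth_scale,
    ltr_signal = ltr_signal,
    n_ltr_columns = min(as.integer(n_ltr_columns), as.integer(n_descriptors)),
    noise_tail_sd = noise_tail_sd
  ), class = "lyso_sim_config")
}

# Largest-remainder rescaling of integer counts to a new total.
scale_counts <- function(counts, n) {
  raw <- counts * n / sum(counts)
  out <- floor(raw)
  short <- n - sum(out)
  if (short > 0) {
    add <- order(raw - out, decreasing = TRUE)[seq_len(short)]
    out[add] <- out[add] + 1
  }
  as.integer(out)
}

# Descriptor columns with a positive / negative planted contribution to
# accumulation: partial-charge surface areas and lipophilicity push
# accumulation up, hydrogen bonding pushes it down.
planted_positive_columns <- function() {
  c("PEOE_VSA6", "PEOE_VSA13", "MolLogP", "SlogP_VSA1",
    "PEOE_VSA7", "SlogP_VSA5", "MolMR", "LabuteASA")
}

planted_negative_columns <- function() {
  c("NHOHCount", "NumHDonors", "NumHAcceptors", "NOCount", "TPSA")
}

#' Generate a seeded synthetic accumulation dataset
#'
#' Draws a dataset with the statistical structure described in
#' [lyso_sim_config()]:
#' \enumerate{
#'   \item a latent accumulation propensity `u` per compound; I/E ratios
#'     are placed log-linearly inside the class bins so that the class
#'     marginal exactly matches the configured counts (quantile matching
#'     of `u`) and `acc_class == acc_class_from_ie(ie_ratio)` holds
#'     exactly;
#'   \item a descriptor matrix `u`-loaded on lipophilicity/charged
#'     surface-area columns (positive) and hydrogen-bonding columns
#'     (negative), plus orthogonal systematic factors, an LTR-specific
#'     direction, and heteroscedastic Gaussian noise;
#'   \item an LTR class equal to the ACC class with probability
#'     `ltr_agreement`, otherwise one class off (clamped to 1..5),
#'     reported for training rows only;
#'   \item a class-stratified training/validation assignment.
#' }
#' Fully reproducible from `seed`.
#'
#' @param config A [lyso_sim_config()] object.
#' @param seed Integer seed.
#' @return Object of class `"lyso_sim"`: list with `data` (data frame:
#'   `compound_id`, `set_label`, `ie_ratio`, `acc_class`, `ltr_class`,
#'   then the descriptor columns) and `truth` (planted ground truth, see
#'   [planted_truth()]).
#' @export
lyso_simulate <- function(config = lyso_sim_config(), seed = 1L) {
  stopifnot(inherits(config, "lyso_sim_config"))
  with_seed(seed, lyso_simulate_impl(config, seed))
}

lyso_simulate_impl <- function(cfg, seed) {
  n <- cfg$n_train + cfg$n_valid
  p <- cfg$n_descriptors
  nf <- cfg$n_predictive_factors
  k <- cfg$n_orthogonal_factors
  nms <- if (p == 97L) descriptor_names() else sprintf("D%03d", seq_len(p))

  # descriptor-visible propensity (sum of predictive factors) plus a
  # descriptor-invisible part: 2D structure only partially determines
  # accumulation
  u_f <- matrix(stats::rnorm(n * nf, sd = sqrt(1 / nf)), n, nf)
  u_vis <- rowSums(u_f)
  rho <- cfg$latent_cor
  u <- rho * u_vis + sqrt(1 - rho^2) * stats::rnorm(n)

  # class assignment by quantile matching, then I/E placed log-linearly
  # inside the class bin by within-class rank -> marginal counts exact
  cls <- integer(n)
  cls[order(u)] <- rep(1:5, cfg$acc_class_counts)
  lo <- c(0.5, acc_class_cutpoints())
  hi <- c(acc_class_cutpoints(), 10 * acc_class_cutpoints()[4L])
  ie <- numeric(n)
  for (kcls in 1:5) {
    i <- which(cls == kcls)
    if (!length(i)) next
    frac <- (rank(u[i]) - 0.5) / length(i)
    ie[i] <- exp(log(lo[kcls]) + frac * (log(hi[kcls]) - log(lo[kcls])))
  }
  acc <- acc_class_from_ie(ie)
  stopifnot(identical(acc, cls))

  # imaging surrogate: agreement with ACC, errors of one class at most
  agree <- stats::runif(n) <= cfg$ltr_agreement
  shift <- ifelse(acc == 1L, 1L, ifelse(acc == 5L, -1L,
                  ifelse(stats::runif(n) < 0.5, -1L, 1L)))
  ltr <- ifelse(agree, acc, acc + shift)

  # the imaging signature lives on its own descriptor family, disjoint
  # from the accumulation-driving columns
  signed <- if (p == 97L) {
    which(nms %in% c(planted_positive_columns(), planted_negative_columns()))
  } else integer(0)
  s_pool <- setdiff(seq_len(p), signed)
  s_cols <- sort(sample(s_pool, cfg$n_ltr_columns))

  # planted loadings: signed base pattern on named columns + jitter,
  # zero on the imaging-signature columns
  base <- stats::rnorm(p, sd = 0.25)
  names(base) <- nms
  if (p == 97L) {
    base[planted_positive_columns()] <- abs(stats::rnorm(
      length(planted_positive_columns()), mean = 1, sd = 0.2))
    base[planted_negative_columns()] <- -abs(stats::rnorm(
      length(planted_negative_columns()), mean = 1, sd = 0.2))
  }
  a <- matrix(0, p, nf)
  for (f in seq_len(nf)) {
    v <- base + stats::rnorm(p, sd = 0.15)
    v[s_cols] <- 0
    a[, f] <- cfg$predictive_scale * v / sqrt(sum(v^2))
  }

  orthogonalize <- function(v, basis) {
    for (j in seq_len(ncol(basis))) {
      bj <- basis[, j]
      v <- v - sum(v * bj) / sum(bj^2) * bj
    }
    v / sqrt(sum(v^2))
  }
  bmat <- matrix(0, p, k)
  span <- a
  for (j in seq_len(k)) {
    bmat[, j] <- orthogonalize(stats::rnorm(p), span)
    span <- cbind(span, bmat[, j])
  }
  # LTR signature confined to its column subset
  s <- numeric(p)
  s[s_cols] <- stats::rnorm(cfg$n_ltr_columns)
  s <- s / sqrt(sum(s^2))
  z <- matrix(stats::rnorm(n * k), n, k)

  ltr_c <- as.numeric(scale(ltr))
  noise_scale <- stats::rlnorm(n, meanlog = -cfg$noise_tail_sd^2 / 2,
                               sdlog = cfg$noise_tail_sd)
  noise <- matrix(stats::rnorm(n * p, sd = cfg$noise_sd), n, p) * noise_scale

  x <- tcrossprod(u_f, a) +
    tcrossprod(z, bmat * cfg$orth_scale) +
    cfg$ltr_signal * tcrossprod(ltr_c, s) +
    noise
  colnames(x) <- nms

  # class-stratified training assignment (largest-remainder quota per class)
  raw <- cfg$acc_class_counts * cfg$n_train / n
  train_counts <- floor(raw)
  short <- cfg$n_train - sum(train_counts)
  if (short > 0) {
    add <- order(raw - train_counts, decreasing = TRUE)[seq_len(short)]
    train_counts[add] <- train_counts[add] + 1
  }
  is_train <- logical(n)
  for (kcls in 1:5) {
    i <- which(acc == kcls)
    take <- min(train_counts[kcls], length(i))
    if (take > 0) is_train[sample(i, take)] <- TRUE
  }
  # top up if any class had fewer rows than its training quota
  deficit <- cfg$n_train - sum(is_train)
  if (deficit > 0) {
    pool <- which(!is_train)
    is_train[sample(pool, deficit)] <- TRUE
  }

  data <- data.frame(
    compound_id = sprintf("SYN%03d", seq_len(n)),
    set_label = ifelse(is_train, "training", "validation"),
    ie_ratio = ie,
    acc_class = acc,
    ltr_class = ifelse(is_train, ltr, NA_integer_),
    x,
    stringsAsFactors = FALSE, check.names = FALSE
  )
  # the planted response-predictive direction in descriptor space is the
  # direction of cov(x, acc): the u-factor loadings weighted by their
  # realized covariance with the class plus the LTR-injected direction
  # weighted by its covariance with the class (noise and orthogonal
  # factors excluded)
  pred_dir <- drop(a %*% apply(u_f, 2L, function(f) stats::cov(f, acc))) +
    cfg$ltr_signal * s * stats::cov(ltr_c, acc)
  truth <- list(
    u = u,
    u_visible = u_vis,
    u_factors = u_f,
    ltr_all = as.integer(ltr),
    predictive_loadings = a,
    predictive_direction = pred_dir / sqrt(sum(pred_dir^2)),
    ortho_directions = bmat,
    ltr_direction = s,
    noise_scale = noise_scale,
    config = cfg,
    seed = as.integer(seed)
  )
  structure(list(data = data, truth = truth), class = "lyso_sim")
}

#' Planted ground truth of a synthetic dataset
#'
#' Returns the generator's hidden state for parameter-recovery tests: the
#' latent propensity `u`, the (unit) planted predictive direction, the
#' orthogonal factor directions, the LTR signal direction, the full LTR
#' classes (including validation rows), and the configuration.
#'
#' @param sim A `"lyso_sim"` object from [lyso_simulate()].
#' @return The `truth` list.
#' @export
planted_truth <- function(sim) {
  stopifnot(inherits(sim, "lyso_sim"))
  sim$truth
}

#' Planted response-predictive direction for a row subset
#'
#' The descriptor-space direction of `cov(x, acc_class)` implied by the
#' planted structure over the given rows: the predictive-factor loadings
#' weighted by their realized covariance with the class plus the
#' LTR-injected direction weighted by its covariance with the class.
#' Noise and orthogonal factors are excluded -- this is the direction a
#' predictive weight should recover. Use `rows = ` the training indices
#' when comparing against a model fit on the training subset.
#'
#' @param sim A `"lyso_sim"` object.
#' @param rows Integer or logical row subset (default: all rows).
#' @return Unit-norm numeric vector (raw descriptor space; divide by the
#'   training column standard deviations to compare against autoscaled
#'   model weights).
#' @export
planted_predictive_direction <- function(sim, rows = NULL) {
  stopifnot(inherits(sim, "lyso_sim"))
  tr <- sim$truth
  n <- nrow(sim$data)
  if (is.null(rows)) rows <- seq_len(n)
  acc <- sim$data$acc_class[rows]
  ltr_c <- as.numeric(scale(tr$ltr_all))[rows]
  w_f <- apply(tr$u_factors[rows, , drop = FALSE], 2L,
               function(f) stats::cov(f, acc))
  d <- drop(tr$predictive_loadings %*% w_f) +
    tr$config$ltr_signal * tr$ltr_direction * stats::cov(ltr_c, acc)
  d / sqrt(sum(d^2))
}

#' @export
print.lyso_sim <- function(x, ...) {
  d <- x$data
  cat("Synthetic accumulation dataset: ", nrow(d), " compounds (",
      sum(d$set_label == "training"), " training, ",
      sum(d$set_label == "validation"), " validation), ",
      length(x$truth$predictive_direction), " descriptors\n", sep = "")
  cat("  ACC class counts:", paste(tabulate(d$acc_class, 5), collapse = "/"),
      "\n")
  invisible(x)
}

#' Write a synthetic dataset to CSV (plus planted-truth sidecar)
#'
#' The CSV is drop-in compatible with [lyso_fit()] /
#' [predict.lyso_models()] and byte-identical across runs for the same
#' seed. When `truth_path` is given, the planted ground truth and the
#' generator configuration are written as a JSON sidecar.
#'
#' @param sim A `"lyso_sim"` object.
#' @param path CSV output path.
#' @param truth_path Optional JSON sidecar path.
#' @return `path`, invisibly.
#' @export
write_sim_csv <- function(sim, path, truth_path = NULL) {
  stopifnot(inherits(sim, "lyso_sim"))
  utils::write.csv(sim$data, path, row.names = FALSE, na = "")
  if (!is.null(truth_path)) {
    tr <- sim$truth
    obj <- list(
      config = unclass(tr$config),
      seed = tr$seed,
      u = tr$u,
      ltr_all = tr$ltr_all,
      predictive_direction = tr$predictive_direction,
      ortho_directions = tr$ortho_directions,
      ltr_direction = tr$ltr_direction
    )
    jsonlite::write_json(obj, truth_path, digits = NA, auto_unbox = TRUE)
  }
  invisible(path)
}
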
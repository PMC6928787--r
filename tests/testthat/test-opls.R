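rand_problem <- function(n, p, seed) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("d", seq_len(p))))
  y <- drop(x %*% rnorm(p, sd = 0.5)) + rnorm(n, sd = 0.3)
  list(x = x, y = y)
}

test_that("autoscaling fits the n-1 convention and round-trips", {
  sc <- autoscale_fit(cbind(a = c(1, 3), b = c(0, 10)))
  expect_equal(unname(sc$center), c(2, 5))
  expect_equal(unname(sc$scale), c(sqrt(2), sqrt(50)))

  set.seed(42)
  x <- matrix(rnorm(40 * 97), 40, 97)
  sc <- autoscale_fit(x)
  xs <- autoscale_apply(x, sc)
  expect_equal(max(abs(colMeans(xs))), 0, tolerance = 1e-12)
  expect_equal(unname(apply(xs, 2, sd)), rep(1, 97), tolerance = 1e-12)
  # idempotence of the transform on an already autoscaled matrix
  sc2 <- autoscale_fit(xs)
  expect_equal(max(abs(sc2$center)), 0, tolerance = 1e-12)
  expect_equal(unname(sc2$scale), rep(1, 97), tolerance = 1e-12)
  # round trip
  expect_equal(autoscale_invert(xs, sc), x, tolerance = 1e-10,
               ignore_attr = TRUE)
  # constant columns are scaled by 1 with a warning, not an error
  expect_warning(sc3 <- autoscale_fit(cbind(c(1, 1, 1), c(1, 2, 3))),
                 "constant")
  expect_equal(unname(sc3$scale[1]), 1)
})

test_that("with zero orthogonal components predictions equal the PLS1 oracle", {
  for (seed in 1:20) {
    pr <- rand_problem(40, 20, seed)
    m <- opls(pr$x, pr$y, n_ortho = 0)
    expect_equal(predict(m, pr$x), pls1_oracle_predict(pr$x, pr$y, pr$x),
                 tolerance = 1e-8)
  }
})

test_that("orthogonal scores are uncorrelated with the response", {
  sim <- lyso_simulate(lyso_sim_config(), seed = 3)
  train <- sim$data[sim$data$set_label == "training", ]
  x <- as.matrix(train[, descriptor_names()])
  m <- opls(x, train$acc_class, n_ortho = 3)
  expect_identical(m$n_ortho, 3L)
  xs <- autoscale_apply(x, m$scaling)
  ys <- (train$acc_class - m$y_center) / m$y_scale
  xc <- xs
  for (i in seq_len(m$n_ortho)) {
    t_o <- drop(xc %*% m$ortho_weights[, i])
    expect_lt(abs(sum(t_o * ys)) / sqrt(sum(t_o^2) * sum(ys^2)), 1e-8)
    xc <- xc - tcrossprod(t_o, m$ortho_loadings[, i])
  }
})

test_that("total sum of squares splits into component and residual parts", {
  for (seed in 1:5) {
    pr <- rand_problem(30, 15, seed)
    m <- opls(pr$x, pr$y, n_ortho = 3)
    xs <- autoscale_apply(pr$x, m$scaling)
    ys <- (pr$y - m$y_center) / m$y_scale
    fit <- lysoacc:::opls_fit_core(xs, ys, 3L)
    ss_ortho <- 0
    xc <- xs
    for (i in seq_len(fit$n_ortho)) {
      t_o <- drop(xc %*% fit$w_o[, i])
      comp <- tcrossprod(t_o, fit$p_o[, i])
      ss_ortho <- ss_ortho + sum(comp^2)
      xc <- xc - comp
    }
    t <- drop(xc %*% fit$w)
    ss_pred <- sum(tcrossprod(t, fit$p)^2)
    ss_res <- sum((xc - tcrossprod(t, fit$p))^2)
    expect_equal(ss_pred + ss_ortho + ss_res, sum(xs^2), tolerance = 1e-6)
  }
})

test_that("a noise-free rank-1 problem is solved exactly with 0 components", {
  set.seed(7)
  u <- rnorm(30)
  x <- outer(u, rnorm(12)) # rank-1, y generated by the single factor
  colnames(x) <- paste0("d", 1:12)
  y <- 2 * u + 1
  m <- opls(x, y, n_ortho = "auto", seed = 1)
  expect_identical(m$n_ortho, 0L)
  expect_equal(predict(m, x), y, tolerance = 1e-8)
  # training rows reconstruct perfectly: X-residuals ~ 0
  expect_lt(max(m$rsd_train), 1e-8)
  expect_lt(m$ad_reference, 1e-8)
})

test_that("constant response is rejected as degenerate", {
  pr <- rand_problem(20, 5, 1)
  expect_error(opls(pr$x, rep(2, 20)), "constant")
  expect_error(select_components(pr$x, rep(2, 20)), "constant")
})

test_that("a planted orthogonal direction is recovered at low noise", {
  # continuous latent response and a large sample keep the finite-sample
  # factor correlation (the floor on recovery) below the tolerance
  cos_o <- sapply(1:20, function(seed) {
    cfg <- lyso_sim_config(n_train = 300L, n_predictive_factors = 1L,
                           n_orthogonal_factors = 1L,
                           orth_scale = 3, ltr_signal = 0,
                           latent_cor = 1, noise_sd = 0.01)
    sim <- lyso_simulate(cfg, seed = seed)
    it <- sim$data$set_label == "training"
    x <- as.matrix(sim$data[it, descriptor_names()])
    m <- opls(x, planted_truth(sim)$u[it], n_ortho = 1)
    recovery_cosine(m$ortho_weights[, 1],
                    planted_truth(sim)$ortho_directions[, 1], x)
  })
  expect_gte(mean(cos_o), 0.99)
})

test_that("missing entries follow the observed-coordinate projection", {
  sim <- lyso_simulate(lyso_sim_config(), seed = 5)
  train <- sim$data[sim$data$set_label == "training", ]
  x <- as.matrix(train[, descriptor_names()])
  m <- opls(x, train$acc_class, n_ortho = 2)
  xq <- x[3, ]
  xq[c(5, 20, 60)] <- NA
  expect_equal(unname(predict(m, xq)), projection_oracle_predict(m, xq),
               tolerance = 1e-10)
  # masked vs unmasked genuinely differ when the entries carry weight
  expect_false(isTRUE(all.equal(unname(predict(m, xq)),
                                unname(predict(m, x[3, ])))))
  # all-missing row errors
  expect_error(predict(m, xq * NA_real_), "missing")
})

test_that("masking a variable the model ignores is a no-op", {
  pr <- rand_problem(25, 8, 2)
  x <- cbind(pr$x, dead = 5)  # constant column: weight and loading exactly 0
  suppressWarnings(m <- opls(x, pr$y, n_ortho = 1))
  xq <- x[4, ]
  xq["dead"] <- NA
  expect_equal(predict(m, xq), predict(m, x[4, , drop = FALSE]),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("cross-validated component selection behaves at the extremes", {
  # pure-noise response: no Q2 improvement, zero orthogonal components
  set.seed(11)
  x <- matrix(rnorm(60 * 20), 60, 20)
  y <- rnorm(60)
  cv <- select_components(x, y, seed = 4)
  expect_identical(cv$n_ortho, 0L)
  expect_true(all(cv$q2 <= 0.05))
  # deterministic replay
  cv2 <- select_components(x, y, seed = 4)
  expect_identical(cv, cv2)
  # error when folds exceed rows
  expect_error(select_components(x[1:5, ], y[1:5], folds = 7), "folds")
})

test_that("two strongly planted orthogonal factors are both selected", {
  picks <- sapply(1:50, function(seed) {
    cfg <- lyso_sim_config(n_predictive_factors = 1L,
                           n_orthogonal_factors = 2L,
                           predictive_scale = 0.5, orth_scale = 6,
                           ltr_signal = 0, latent_cor = 0.95,
                           noise_sd = 0.02)
    sim <- lyso_simulate(cfg, seed = seed)
    it <- sim$data$set_label == "training"
    x <- as.matrix(sim$data[it, descriptor_names()])
    select_components(x, planted_truth(sim)$u[it], seed = seed,
                      q2_threshold = 0.02)$n_ortho
  })
  expect_gte(mean(picks == 2L), 0.9)
})

test_that("coefficients reproduce predictions as a linear form", {
  for (seed in 1:5) {
    pr <- rand_problem(35, 12, seed + 100)
    m <- opls(pr$x, pr$y, n_ortho = 2)
    b <- coef(m)
    xs <- autoscale_apply(pr$x, m$scaling)
    lin <- m$y_center + m$y_scale * drop(xs %*% b)
    expect_equal(predict(m, pr$x), lin, tolerance = 1e-10)
  }
  # threshold filter keeps strictly-greater coefficients only
  m <- opls(rand_problem(35, 12, 1)$x, rand_problem(35, 12, 1)$y, n_ortho = 0)
  m$coefficients <- stats::setNames(c(0.04, 0.06, -0.2), c("a", "b", "c"))
  expect_identical(names(coef(m, threshold = 0.05)), c("b", "c"))
})

test_that("coefficient mass concentrates on the generating column", {
  set.seed(9)
  x <- matrix(rnorm(40 * 10), 40, 10, dimnames = list(NULL, paste0("d", 1:10)))
  y <- x[, 1]
  m <- opls(x, y, n_ortho = 0)
  expect_identical(names(which.max(abs(coef(m)))), "d1")
})

test_that("column permutation with names leaves predictions unchanged", {
  pr <- rand_problem(30, 10, 3)
  m <- opls(pr$x, pr$y, n_ortho = 2)
  perm <- sample(ncol(pr$x))
  expect_equal(predict(m, pr$x[, perm]), predict(m, pr$x), tolerance = 1e-12)
})

test_that("serialized models round-trip to machine precision", {
  sim <- lyso_simulate(lyso_sim_config(), seed = 8)
  train <- sim$data[sim$data$set_label == "training", ]
  x <- as.matrix(train[, descriptor_names()])
  m <- opls(x, train$acc_class, n_ortho = "auto", seed = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_opls(m, path)
  m2 <- read_opls(path)
  expect_equal(predict(m2, x), predict(m, x), tolerance = 1e-12)
  expect_identical(m2$n_ortho, m$n_ortho)
  expect_equal(m2$ad_reference, m$ad_reference, tolerance = 1e-12)
  xq <- x[2, ]
  xq[10] <- NA
  expect_equal(predict(m2, xq), predict(m, xq), tolerance = 1e-12)
})

test_that("model accessors expose the standard fit summaries", {
  pr <- rand_problem(30, 10, 4)
  m <- opls(pr$x, pr$y, n_ortho = 1)
  expect_equal(fitted(m) + residuals(m), pr$y, tolerance = 1e-12)
  s <- summary(m)
  expect_gt(s$r2y, 0)
  expect_output(print(m), "OPLS model")
  expect_output(print(s), "R2Y")
})
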
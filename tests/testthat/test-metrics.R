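test_that("balanced accuracy is the macro-average of per-class recalls", {
  expect_identical(balanced_accuracy(1:5, 1:5), 1)
  expect_equal(balanced_accuracy(c(1, 1, 2, 2, 3), c(1, 2, 2, 2, 3)),
               (0.5 + 1 + 1) / 3)
  # constant predictor on k present classes scores exactly 1/k
  for (k in 2:5) {
    truth <- rep(seq_len(k), times = sample(3:7, k, replace = TRUE))
    expect_identical(balanced_accuracy(truth, rep(1L, length(truth))), 1 / k)
  }
  # invariance under a joint relabeling permutation
  set.seed(30)
  truth <- sample(1:5, 200, replace = TRUE)
  pred <- sample(1:5, 200, replace = TRUE)
  perm <- sample(5)
  expect_equal(balanced_accuracy(perm[truth], perm[pred]),
               balanced_accuracy(truth, pred))
  expect_error(balanced_accuracy(1:3, 1:4), "length")
  expect_error(balanced_accuracy(integer(0), integer(0)), "empty")
})

test_that("uniform random predictions score at the 1/k chance baseline", {
  set.seed(31)
  truth <- sample(1:5, 10000, replace = TRUE)
  pred <- sample(1:5, 10000, replace = TRUE)
  expect_equal(balanced_accuracy(truth, pred), 0.2, tolerance = 0.03 / 0.2)
})

test_that("spearman correlation matches the rank-based definition", {
  expect_equal(spearman_r(1:5, 1:5), 1)
  expect_equal(spearman_r(1:5, 5:1), -1)
  expect_equal(spearman_r(1:5, c(1, 3, 2, 4, 5)), 0.9)
  # tie-free closed form 1 - 6*sum(d^2)/(n(n^2-1)) on random permutations
  set.seed(32)
  for (i in 1:10) {
    n <- sample(5:30, 1)
    a <- sample(n)
    b <- sample(n)
    expect_equal(spearman_r(a, b),
                 1 - 6 * sum((a - b)^2) / (n * (n^2 - 1)))
  }
  # ties are handled by average ranks (cross-check against stats::cor)
  a <- c(1, 2, 2, 3, 5)
  b <- c(2, 2, 3, 4, 4)
  expect_equal(spearman_r(a, b), stats::cor(a, b, method = "spearman"))
  expect_error(spearman_r(c(1, 1, 1), c(1, 2, 3)), "variance")
  expect_error(spearman_r(1:2, 1:2), "3")
})

test_that("mcnemar_cc implements the continuity-corrected statistic", {
  r <- mcnemar_cc(rep(c(TRUE, FALSE), c(8, 2)), rep(c(FALSE, TRUE), c(8, 2)))
  expect_identical(c(r$b, r$c), c(8L, 2L))
  expect_equal(r$statistic, 2.5)
  # symmetry in the discordant counts
  r2 <- mcnemar_cc(rep(c(FALSE, TRUE), c(8, 2)), rep(c(TRUE, FALSE), c(8, 2)))
  expect_equal(r2$statistic, r$statistic)
  expect_equal(r2$p_value, r$p_value)
  # identical correctness: no discordance, p = 1
  v <- c(TRUE, FALSE, TRUE)
  r3 <- mcnemar_cc(v, v)
  expect_identical(c(r3$b, r3$c), c(0L, 0L))
  expect_identical(r3$statistic, 0)
  expect_identical(r3$p_value, 1)
  expect_error(mcnemar_cc(c(TRUE, FALSE), TRUE), "length")
  expect_error(mcnemar_cc(c(TRUE, NA), c(TRUE, TRUE)), "NA")
})

test_that("mcnemar_cc matches the formula by enumeration and stats oracle", {
  for (b in 0:30) {
    for (cc in 0:(30 - b)) {
      ca <- rep(c(TRUE, FALSE, TRUE), c(b, cc, 2))
      cb <- rep(c(FALSE, TRUE, TRUE), c(b, cc, 2))
      r <- mcnemar_cc(ca, cb)
      if (b + cc == 0) {
        expect_identical(r$statistic, 0)
        expect_identical(r$p_value, 1)
      } else {
        expect_equal(r$statistic, (abs(b - cc) - 1)^2 / (b + cc))
        expect_equal(r$p_value,
                     stats::pchisq((abs(b - cc) - 1)^2 / (b + cc), 1,
                                   lower.tail = FALSE))
      }
    }
  }
  # spot cross-check against the standard contingency-table test
  # (excluding b = c, where stats::mcnemar.test clamps the corrected
  # difference at zero instead of applying the formula)
  for (bc in list(c(8, 2), c(1, 12), c(10, 3))) {
    tab <- matrix(c(4, bc[2], bc[1], 3), 2)
    r <- mcnemar_cc(rep(c(TRUE, FALSE, TRUE, FALSE), c(bc[1], bc[2], 4, 3)),
                    rep(c(FALSE, TRUE, TRUE, FALSE), c(bc[1], bc[2], 4, 3)))
    ref <- stats::mcnemar.test(tab, correct = TRUE)
    expect_equal(r$statistic, unname(ref$statistic))
    expect_equal(r$p_value, unname(ref$p.value))
  }
})

test_that("evaluation reports bundle the expected summaries", {
  truth <- c(1, 1, 2, 2, 3, 4, 5, 5)
  pred <- c(1, 2, 2, 2, 3, 5, 5, 3)
  r <- evaluate_predictions(truth, pred)
  expect_equal(unname(rowSums(r$confusion)),
               as.numeric(table(factor(truth, levels = 1:5))))
  expect_identical(r$max_class_error, 2)
  expect_identical(r$n_total, 8L)
  expect_equal(r$balanced_accuracy, mean(c(0.5, 1, 1, 0, 0.5)))
  # AD filtering: all in-domain means filtered report equals unfiltered
  ad <- rep(TRUE, 8)
  expect_equal(evaluate_predictions(truth, pred, ad, ad_filter = TRUE)[
    c("balanced_accuracy", "spearman_r", "max_class_error")],
    r[c("balanced_accuracy", "spearman_r", "max_class_error")])
  # empty in-domain subset flags metrics as undefined instead of erroring
  none <- evaluate_predictions(truth, pred, rep(FALSE, 8), ad_filter = TRUE)
  expect_false(none$defined)
  expect_true(is.na(none$balanced_accuracy))
  expect_identical(none$n_in_domain, 0L)
})

test_that("scheme evaluation reports per scheme and pairs, or no pairs", {
  sim <- lyso_simulate(lyso_sim_config(), seed = 18)
  fit <- sim_fit_eval(sim, seed = 18, ad_filter = "both")
  report <- fit$report
  expect_setequal(names(report$schemes),
                  c("predicted_ltr", "missing_ltr", "no_ltr"))
  expect_length(report$pairwise, 3L)
  for (s in names(report$schemes)) {
    r <- report$schemes[[s]]$ad_off
    expect_identical(r$n_total, 30L)
    expect_true(r$balanced_accuracy >= 0 && r$balanced_accuracy <= 1)
    ron <- report$schemes[[s]]$ad_on
    expect_lte(ron$n_in_domain, 30L)
  }
  # single scheme: no pairwise comparisons
  single <- evaluate_schemes(
    stats::setNames(fit$valid$acc_class, fit$valid$compound_id),
    fit$pred[fit$pred$scheme == "no_ltr", ])
  expect_length(single$pairwise, 0L)
  expect_output(print(report), "BA")
})

test_that("reports serialize to the documented JSON schema", {
  sim <- lyso_simulate(lyso_sim_config(), seed = 19)
  fit <- sim_fit_eval(sim, seed = 19, ad_filter = "both")
  path <- withr::local_tempfile(fileext = ".json")
  write_report_json(fit$report, path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_setequal(names(obj$schemes),
                  c("predicted_ltr", "missing_ltr", "no_ltr"))
  no_ltr <- obj$schemes$no_ltr$ad_off
  expect_identical(dim(no_ltr$confusion), c(5L, 5L))
  expect_equal(no_ltr$balanced_accuracy,
               fit$report$schemes$no_ltr$ad_off$balanced_accuracy)
  pair <- obj$pairwise$no_ltr_vs_predicted_ltr
  expect_true(all(c("b", "c", "statistic", "p_value") %in% names(pair)))
})
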
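# Independent closed-form one-component PLS1: autoscale, w = X'y/||X'y||,
# t = Xw, c = t'y/t't, prediction = y_mean + y_sd * c * (x_scaled . w).
pls1_oracle_predict <- function(x, y, newdata) {
  mx <- colMeans(x)
  sx <- apply(x, 2L, stats::sd)
  sx[sx == 0] <- 1
  xs <- sweep(sweep(x, 2L, mx), 2L, sx, "/")
  my <- mean(y)
  sy <- stats::sd(y)
  ys <- (y - my) / sy
  w <- drop(crossprod(xs, ys))
  w <- w / sqrt(sum(w^2))
  t <- drop(xs %*% w)
  cc <- sum(t * ys) / sum(t^2)
  ns <- sweep(sweep(as.matrix(newdata), 2L, mx), 2L, sx, "/")
  my + sy * cc * drop(ns %*% w)
}

# Brute-force observed-coordinate projection of a possibly incomplete row
# through a fitted opls model, written against the serialized model fields.
projection_oracle_predict <- function(model, xrow) {
  xs <- (xrow - model$scaling$center) / model$scaling$scale
  obs <- !is.na(xs)
  for (i in seq_len(model$n_ortho)) {
    wo <- model$ortho_weights[, i]
    po <- model$ortho_loadings[, i]
    t <- sum(xs[obs] * wo[obs]) / sum(wo[obs]^2)
    xs[obs] <- xs[obs] - t * po[obs]
  }
  t <- sum(xs[obs] * model$weights[obs]) / sum(model$weights[obs]^2)
  model$y_center + model$y_scale * model$score_coef * t
}

# Cosine between a fitted (autoscaled-space) weight vector and a planted
# raw-space direction, mapped into the scaled space of the training matrix.
recovery_cosine <- function(weights, direction_raw, train_x) {
  sdev <- apply(train_x, 2L, stats::sd)
  sdev[sdev == 0] <- 1
  d <- direction_raw / sdev
  abs(sum(weights * d)) / sqrt(sum(d^2))
}

# Fit the three-model suite on a simulated dataset and evaluate the
# schemes on its validation rows.
sim_fit_eval <- function(sim, seed, ad_filter = "off") {
  d <- sim$data
  train <- d[d$set_label == "training", ]
  valid <- d[d$set_label == "validation", ]
  models <- lyso_fit(train, seed = seed)
  pred <- predict(models, valid)
  truth <- stats::setNames(valid$acc_class, valid$compound_id)
  list(models = models, pred = pred, valid = valid,
       report = evaluate_schemes(truth, pred, ad_filter = ad_filter))
}

# 20 simple molecules with hand-derived graph counts used as the
# brute-force oracle for the additive count descriptors.
count_fixture <- function() {
  m <- rbind(
    c("ethanol", "CCO", 3, 0, 1, 1, 1),
    c("benzene", "c1ccccc1", 6, 1, 0, 0, 0),
    c("acetic_acid", "CC(=O)O", 4, 0, 1, 1, 2),
    c("pyridine", "c1ccncc1", 6, 1, 0, 0, 1),
    c("phenol", "Oc1ccccc1", 7, 1, 1, 1, 1),
    c("aniline", "Nc1ccccc1", 7, 1, 1, 2, 1),
    c("cyclohexane", "C1CCCCC1", 6, 1, 0, 0, 0),
    c("acetamide", "CC(N)=O", 4, 0, 1, 2, 2),
    c("dimethyl_ether", "COC", 3, 0, 0, 0, 1),
    c("naphthalene", "c1ccc2ccccc2c1", 10, 2, 0, 0, 0),
    c("ethylamine", "CCN", 3, 0, 1, 2, 1),
    c("glycine", "NCC(=O)O", 5, 0, 2, 3, 3),
    c("acetonitrile", "CC#N", 3, 0, 0, 0, 1),
    c("imidazole", "c1c[nH]cn1", 5, 1, 1, 1, 2),
    c("dmso", "CS(=O)C", 4, 0, 0, 0, 1),
    c("urea", "NC(N)=O", 4, 0, 2, 4, 3),
    c("toluene", "Cc1ccccc1", 7, 1, 0, 0, 0),
    c("thf", "C1CCOC1", 5, 1, 0, 0, 1),
    c("pyrrolidine", "C1CCNC1", 5, 1, 1, 1, 1),
    c("isopropanol", "CC(C)O", 4, 0, 1, 1, 1)
  )
  out <- data.frame(
    compound_id = m[, 1L], smiles = m[, 2L], stringsAsFactors = FALSE
  )
  out$HeavyAtomCount <- as.numeric(m[, 3L])
  out$RingCount <- as.numeric(m[, 4L])
  out$NumHDonors <- as.numeric(m[, 5L])
  out$NHOHCount <- as.numeric(m[, 6L])
  out$NOCount <- as.numeric(m[, 7L])
  out
}
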
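# Linear max-margin LB/HB classifier: cross-validation, drop-one feature
# selection, final fit, and signed hyperplane-distance scoring.
#
# The solver is an L2-regularized squared-hinge linear SVC fit by dual
# coordinate descent (src/linsvc.cpp). LB is always the positive class:
# decision values and hyperplane distances are > 0 on the LB side. Class
# imbalance (the training ratio is ~1:40 LB:HB) is handled by hinge-loss
# weights inversely proportional to class frequency; features are
# standardized to zero location and unit scale before fitting, with the
# scaling learned on training rows only.

# tol is the projected-gradient-range stopping criterion. 0.01 keeps
# held-out accuracies stable enough that drop-one differences at the 0.1%
# level reflect the features, not solver noise; tightening to 1e-5 changes
# recovered directions by <1e-3 in cosine.
.svc_fit <- function(X, y_lb, C = 1, balanced = TRUE, tol = 0.01,
                     max_iter = 1000L, perm_seed = 1L, skip = -1L,
                     alpha0 = NULL) {
  n <- length(y_lb)
  y <- ifelse(y_lb, 1, -1)
  Ci <- rep(C, n)
  if (balanced) {
    n_pos <- sum(y_lb)
    n_neg <- n - n_pos
    Ci <- C * ifelse(y_lb, n / (2 * n_pos), n / (2 * n_neg))
  }
  Xt <- t.default(cbind(X, 1))
  fit <- .dcd_svc(Xt, y, Ci, as.integer(max_iter), tol,
                  as.integer(perm_seed), as.integer(skip), alpha0)
  p <- ncol(X)
  list(w = fit$w[seq_len(p)], b = fit$w[p + 1L], alpha = fit$alpha,
       iter = fit$iter)
}

.scale_fit <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[scl == 0 | is.na(scl)] <- 1
  list(center = ctr, scale = scl)
}

.scale_apply <- function(X, sc) {
  sweep(sweep(X, 2, sc$center, "-"), 2, sc$scale, "/")
}

# Stratified fold assignment; k = n gives leave-one-out.
.make_folds <- function(y_lb, k, seed) {
  n <- length(y_lb)
  if (k < 2 || k > n) abort("k must be between 2 and the number of rows.")
  if (k == n) return(seq_len(n))
  folds <- integer(n)
  withr::with_seed(seed, {
    folds[y_lb] <- sample(rep_len(seq_len(k), sum(y_lb)))
    folds[!y_lb] <- sample(rep_len(seq_len(k), sum(!y_lb)))
  })
  folds
}

.fm_matrix <- function(fm, feats) {
  X <- as.matrix(fm[, feats, drop = FALSE])
  if (!is.numeric(X)) abort("Feature columns must be numeric.")
  if (anyNA(X)) abort("Feature matrix contains missing values.")
  X
}

#' Cross-validate the LB/HB linear classifier
#'
#' Stratified k-fold cross-validation of the class-weighted linear SVC.
#' Accuracy is the raw held-out accuracy per fold; the ROC curve is
#' computed from the decision values of all held-out rows pooled across
#' folds, with LB as the positive class.
#'
#' @param fm Labeled feature-matrix tibble (`label` column of
#'   `"LB"`/`"HB"`).
#' @param k Number of folds (default 10); `k = nrow(fm)` is leave-one-out.
#' @param seed Integer seed controlling fold assignment.
#' @param C Regularization strength (hinge-loss cost; larger fits harder).
#' @param tol Solver stopping tolerance on the projected-gradient range of
#'   the dual problem (default 0.01).
#' @param features Feature columns to use; defaults to all.
#' @return An object of class `lb_cv`: fold accuracies, their mean and
#'   standard deviation, pooled ROC points, AUC, and the per-row held-out
#'   predictions.
#' @seealso [select_features()], [fit_final()]
#' @export
train_cv <- function(fm, k = 10, seed = 1, C = 1, tol = 0.01,
                     features = NULL) {
  feats <- features %||% feature_names(fm)
  .check_labels(fm$label)
  y_lb <- fm$label == "LB"
  X <- .fm_matrix(fm, feats)
  folds <- .make_folds(y_lb, k, seed)
  k <- max(folds)

  acc <- numeric(k)
  dec <- numeric(nrow(X))
  for (f in seq_len(k)) {
    tr <- folds != f
    sc <- .scale_fit(X[tr, , drop = FALSE])
    Xtr <- .scale_apply(X[tr, , drop = FALSE], sc)
    Xte <- .scale_apply(X[!tr, , drop = FALSE], sc)
    fit <- .svc_fit(Xtr, y_lb[tr], C = C, tol = tol,
                    perm_seed = seed + f)
    d <- drop(Xte %*% fit$w) + fit$b
    dec[!tr] <- d
    acc[f] <- mean((d > 0) == y_lb[!tr])
  }

  ro <- pROC::roc(response = factor(fm$label, levels = c("HB", "LB")),
                  predictor = dec, levels = c("HB", "LB"),
                  direction = "<", quiet = TRUE)
  roc_points <- arrange(
    tibble(fpr = 1 - ro$specificities, tpr = ro$sensitivities),
    .data$fpr, .data$tpr
  )

  structure(
    list(
      fold_accuracies = acc,
      mean_accuracy = mean(acc),
      sd_accuracy = sd(acc),
      roc_points = roc_points,
      auc = as.numeric(ro$auc),
      predictions = tibble(fold = folds, label = fm$label, decision = dec,
                           predicted = ifelse(dec > 0, "LB", "HB")),
      k = k, seed = seed, C = C, features = feats
    ),
    class = "lb_cv"
  )
}

#' Drop-one cross-validated feature selection
#'
#' For each feature, compares the mean cross-validated accuracy of the
#' full-featured model against the model with that single feature excluded
#' (same folds, single pass; not greedy backward elimination). Features
#' whose exclusion costs at least `drop_threshold` mean accuracy (default
#' 0.1%) are retained.
#'
#' The per-fold drop-one refits reuse the full model's dual solution as a
#' warm start, which makes the 340-model sweep tractable at catalog scale.
#'
#' @inheritParams train_cv
#' @param drop_threshold Minimum mean accuracy drop for retention.
#' @return Character vector of retained feature names, with a `drops`
#'   attribute (tibble `feature, mean_drop`) recording every feature's
#'   drop.
#' @export
select_features <- function(fm, drop_threshold = 0.001, k = 10, seed = 1,
                            C = 1, tol = 0.01) {
  feats <- feature_names(fm)
  if (length(feats) < 2) abort("Need at least two features.")
  .check_labels(fm$label)
  y_lb <- fm$label == "LB"
  X <- .fm_matrix(fm, feats)
  folds <- .make_folds(y_lb, k, seed)
  k <- max(folds)
  p <- length(feats)

  drops <- matrix(0, nrow = p, ncol = k)
  for (f in seq_len(k)) {
    tr <- folds != f
    sc <- .scale_fit(X[tr, , drop = FALSE])
    Xtr <- .scale_apply(X[tr, , drop = FALSE], sc)
    Xte <- .scale_apply(X[!tr, , drop = FALSE], sc)
    y_tr <- y_lb[tr]
    y_te <- y_lb[!tr]
    full <- .svc_fit(Xtr, y_tr, C = C, tol = tol, perm_seed = seed + f)
    a_full <- mean(((Xte %*% full$w + full$b) > 0) == y_te)
    for (j in seq_len(p)) {
      fitj <- .svc_fit(Xtr, y_tr, C = C, tol = tol, perm_seed = seed + f,
                       skip = j - 1L, alpha0 = full$alpha)
      a_j <- mean(((Xte %*% fitj$w + fitj$b) > 0) == y_te)
      drops[j, f] <- a_full - a_j
    }
  }

  mean_drop <- rowMeans(drops)
  keep <- feats[mean_drop >= drop_threshold]
  if (length(keep) == 0) {
    abort(paste0(
      "All features fall below the drop threshold (max mean drop ",
      signif(max(mean_drop), 3),
      "); consider lowering drop_threshold."
    ))
  }
  attr(keep, "drops") <- tibble(feature = feats, mean_drop = mean_drop)
  keep
}

#' Single-feature classifier weights
#'
#' Fits the classifier on each feature alone (standardized) and reports the
#' signed weight: positive weights mark LB-predictive features, negative
#' weights HB-predictive ones. Used to visualize feature directionality.
#'
#' @inheritParams train_cv
#' @return Tibble `feature, weight, direction` with direction `"LB"`,
#'   `"HB"`, or `"none"` (constant feature).
#' @export
single_feature_weights <- function(fm, C = 1, tol = 0.01) {
  feats <- feature_names(fm)
  .check_labels(fm$label)
  y_lb <- fm$label == "LB"
  X <- .fm_matrix(fm, feats)
  sc <- .scale_fit(X)
  Xs <- .scale_apply(X, sc)
  w <- vapply(seq_along(feats), function(j) {
    if (sd(X[, j]) == 0) return(0)
    .svc_fit(Xs[, j, drop = FALSE], y_lb, C = C, tol = tol,
             perm_seed = j)$w
  }, numeric(1))
  tibble(
    feature = feats,
    weight = w,
    direction = dplyr::case_when(w > 0 ~ "LB", w < 0 ~ "HB", TRUE ~ "none")
  )
}

#' Fit the final classification model on all rows
#'
#' Fits the class-weighted linear SVC on every row of the (typically
#' down-sampled) training matrix restricted to the selected features, with
#' nothing withheld for testing. The feature scaling learned here is stored
#' on the model and reused verbatim when scoring new data.
#'
#' @inheritParams train_cv
#' @param features Selected feature names (e.g. from [select_features()]).
#' @return An object of class `lb_model`: named weight vector `w`,
#'   intercept `b`, selected feature names, and the per-feature
#'   location/scale used at fit time.
#' @export
fit_final <- function(fm, features = NULL, C = 1, tol = 0.01,
                      seed = 1) {
  feats <- features %||% feature_names(fm)
  if (length(feats) == 0) abort("Empty feature list.")
  unknown <- setdiff(feats, names(fm))
  if (length(unknown) > 0) {
    abort(paste0("Unknown feature(s): ", paste(head(unknown, 5),
                                               collapse = ", ")))
  }
  .check_labels(fm$label)
  y_lb <- fm$label == "LB"
  X <- .fm_matrix(fm, feats)
  sc <- .scale_fit(X)
  fit <- .svc_fit(.scale_apply(X, sc), y_lb, C = C, tol = tol,
                  perm_seed = seed)
  structure(
    list(
      w = setNames(fit$w, feats),
      b = fit$b,
      features = feats,
      center = setNames(sc$center, feats),
      scale = setNames(sc$scale, feats),
      C = C,
      n_train = nrow(X)
    ),
    class = "lb_model"
  )
}

#' Score mutations by signed hyperplane distance
#'
#' Computes each mutation's signed perpendicular distance
#' `d = (w . x + b) / ||w||` from the model's classification hyperplane
#' (after applying the model's stored feature scaling); `d > 0` lies on the
#' LB side, and larger distances are more "driver-like" under the
#' low-burden hypothesis. The input may be the full mutation catalog, not
#' just the down-sampled training rows.
#'
#' @param fm Feature-matrix tibble containing all model features.
#' @param model An `lb_model` from [fit_final()].
#' @return Tibble sorted by descending distance with columns `raw_distance`
#'   and `rank` (ties broken by variant key) appended to the variant key
#'   and annotation columns.
#' @export
score_mutations <- function(fm, model) {
  stopifnot(inherits(model, "lb_model"))
  missing <- setdiff(model$features, names(fm))
  if (length(missing) > 0) {
    abort(paste0("Feature column(s) missing from input: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  X <- .fm_matrix(fm, model$features)
  Xs <- .scale_apply(X, list(center = model$center, scale = model$scale))
  nw <- sqrt(sum(model$w^2))
  if (nw == 0) abort("Model weight vector is zero; cannot rank.")
  d <- (drop(Xs %*% model$w) + model$b) / nw
  keep <- intersect(
    c("chrom", "pos", "ref", "alt", "mtype", "n_donors", "label", "gene",
      "gene_length", "consequence", "impact", "coding"),
    names(fm)
  )
  out <- fm[, keep, drop = FALSE]
  out$raw_distance <- d
  ord <- order(-out$raw_distance, variant_key(out), method = "radix")
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  as_tibble(out)
}

#' Platt-type probability calibration of decision values
#'
#' Fits a logistic sigmoid mapping classifier decision values to LB-class
#' probabilities (a convention for probability plots; the max-margin model
#' itself has no probabilistic output).
#'
#' @param decision Numeric decision values.
#' @param label `"LB"`/`"HB"` labels aligned with `decision`.
#' @return Function mapping decision values to `P(LB)`.
#' @export
platt_calibration <- function(decision, label) {
  .check_labels(label)
  df <- data.frame(y = label == "LB", d = decision)
  fit <- glm(y ~ d, data = df, family = binomial())
  function(d) as.numeric(predict(fit, newdata = data.frame(d = d),
                                 type = "response"))
}

#' Serialize a trained model to versioned JSON
#'
#' @param model An `lb_model`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "lb_model"))
  payload <- list(
    format = "panelforge-lb-model",
    version = 1L,
    features = model$features,
    w = unname(model$w),
    b = model$b,
    center = unname(model$center),
    scale = unname(model$scale),
    C = model$C,
    n_train = model$n_train
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a serialized model
#'
#' @param path JSON path written by [write_model()].
#' @return An `lb_model`.
#' @export
read_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$format, "panelforge-lb-model")) {
    abort("Not a panelforge model file.")
  }
  structure(
    list(
      w = setNames(x$w, x$features),
      b = x$b,
      features = x$features,
      center = setNames(x$center, x$features),
      scale = setNames(x$scale, x$features),
      C = x$C,
      n_train = x$n_train
    ),
    class = "lb_model"
  )
}
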
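test_that("solver agrees with an independent SVM implementation", {
  skip_if_not_installed("e1071")
  fm <- small_fm(n = 120, p = 4, m = 2, effect = 2, seed = 3)
  model <- fit_final(fm, seed = 1)

  X <- scale(as.matrix(fm[, feature_names(fm)]))
  y <- factor(fm$label, levels = c("HB", "LB"))
  sv <- e1071::svm(X, y, kernel = "linear", cost = 1, scale = FALSE)
  w_ref <- drop(t(sv$coefs) %*% sv$SV)
  # orient the reference hyperplane with LB positive (libsvm's internal
  # sign depends on which class it saw first)
  lb_side <- mean((drop(X %*% w_ref) - sv$rho > 0) == (fm$label == "LB"))
  if (lb_side < 0.5) w_ref <- -w_ref

  cosine <- sum(model$w * w_ref) / sqrt(sum(model$w^2) * sum(w_ref^2))
  expect_gt(cosine, 0.95)

  d_mine <- drop(X %*% model$w) + model$b
  agree <- mean((d_mine > 0) == (predict(sv, X) == "LB"))
  expect_gt(agree, 0.97)
})

test_that("cross-validation separates separable classes and not permuted ones", {
  fm <- small_fm(n = 300, p = 6, m = 3, effect = 3, seed = 11)
  cv <- train_cv(fm, k = 10, seed = 2)
  expect_gte(cv$mean_accuracy, 0.99)
  expect_gt(cv$auc, 0.99)
  expect_length(cv$fold_accuracies, 10)

  # ROC runs from (0,0) to (1,1) monotonically
  rp <- cv$roc_points
  expect_equal(unlist(rp[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(rp[nrow(rp), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(rp$fpr) >= 0))
  expect_true(all(diff(rp$tpr) >= 0))

  perm <- fm
  perm$label <- withr::with_seed(4, sample(perm$label))
  cv_p <- train_cv(perm, k = 10, seed = 2)
  maj <- max(table(perm$label)) / nrow(perm)
  expect_lt(abs(cv_p$mean_accuracy - maj), 0.12)

  one_class <- dplyr::mutate(fm, label = "HB")
  expect_error(train_cv(one_class, k = 5, seed = 1), "Both LB and HB")
})

test_that("leave-one-out runs with 0/1 fold accuracies", {
  fm <- small_fm(n = 40, p = 3, m = 2, effect = 3, seed = 21)
  cv <- train_cv(fm, k = nrow(fm), seed = 1)
  expect_length(cv$fold_accuracies, 40)
  expect_true(all(cv$fold_accuracies %in% c(0, 1)))
})

test_that("imbalanced training predicts fewer LB than HB mutations", {
  fm <- small_fm(n = 2050, p = 10, m = 4, effect = 1.5, seed = 31,
                 lb_fraction = 1 / 41)
  cv <- train_cv(fm, k = 5, seed = 3)
  frac_lb <- mean(cv$predictions$predicted == "LB")
  expect_lt(frac_lb, 1 - frac_lb)
})

test_that("drop-one selection recovers planted features and rejects pure noise", {
  # n large enough that a 0.1% accuracy drop (8 held-out flips) cannot
  # arise from sampling noise alone
  fm <- small_fm(n = 8000, p = 10, m = 2, effect = 2, seed = 41)
  sel <- select_features(fm, k = 10, seed = 5)
  expect_setequal(sel, c("f001", "f002"))
  drops <- attr(sel, "drops")
  expect_equal(nrow(drops), 10)
  expect_true(all(drops$mean_drop[drops$feature %in% sel] >= 0.001))

  # a duplicated informative feature splits the credit; at most the pair
  # survives and nothing else does
  dup <- fm
  dup$f011 <- dup$f001
  dup <- panelforge:::.set_features(dup, c(feature_names(fm), "f011"))
  sel_dup <- tryCatch(select_features(dup, k = 10, seed = 5),
                      error = function(e) character())
  expect_true(all(sel_dup %in% c("f001", "f002", "f011")))

  # six copies of one feature: excluding any single copy changes nothing,
  # so every drop is exactly zero and selection must refuse
  redundant <- small_fm(n = 300, p = 1, m = 1, effect = 2, seed = 43)
  for (nm in paste0("f", sprintf("%03d", 2:6))) redundant[[nm]] <- redundant$f001
  redundant <- panelforge:::.set_features(redundant,
                                          sprintf("f%03d", 1:6))
  expect_error(select_features(redundant, k = 5, seed = 1), "threshold")

  single <- tibble::tibble(chrom = "chr1", pos = 1:100, ref = "A", alt = "T",
                           label = rep(c("LB", "HB"), 50),
                           f001 = rnorm(100))
  expect_error(select_features(single, k = 5, seed = 1), "two features")
})

test_that("single-feature weights point toward the class they predict", {
  fm <- small_fm(n = 200, p = 5, m = 1, effect = 2, seed = 51)
  fm$f002 <- -fm$f001           # anti-aligned with LB
  fm$f003 <- 1                  # constant
  fm$f004 <- ifelse(fm$label == "LB", 1, -1) # perfectly LB-aligned
  sfw <- single_feature_weights(fm)
  expect_gt(sfw$weight[sfw$feature == "f001"], 0)
  expect_lt(sfw$weight[sfw$feature == "f002"], 0)
  expect_equal(sfw$weight[sfw$feature == "f003"], 0)
  expect_equal(sfw$direction[sfw$feature == "f003"], "none")
  expect_gt(sfw$weight[sfw$feature == "f004"], 0)
})

test_that("final refit attains at least the cross-validated accuracy on a separable fixture", {
  fm <- small_fm(n = 300, p = 8, m = 3, effect = 2, seed = 61)
  cv <- train_cv(fm, k = 5, seed = 7)
  model <- fit_final(fm, seed = 7)
  X <- as.matrix(fm[, feature_names(fm)])
  Xs <- scale(X, center = model$center, scale = model$scale)
  train_acc <- mean(((Xs %*% model$w + model$b) > 0) == (fm$label == "LB"))
  expect_gte(train_acc, cv$mean_accuracy - 1e-9)

  expect_error(fit_final(fm, features = character()), "Empty")
  expect_error(fit_final(fm, features = "nope"), "nope")
})

test_that("hyperplane distances follow the closed form and rank deterministically", {
  model <- structure(
    list(w = c(f001 = 3, f002 = 4), b = 0, features = c("f001", "f002"),
         center = c(f001 = 0, f002 = 0), scale = c(f001 = 1, f002 = 1),
         C = 1, n_train = 10),
    class = "lb_model"
  )
  fm <- tibble::tibble(
    chrom = "chr1", pos = c(10L, 20L, 30L), ref = "A", alt = "T",
    f001 = c(1, 0, 2), f002 = c(1, 0, 2)
  )
  scored <- score_mutations(fm, model)
  # x=(1,1): d = 7/5; x on the hyperplane: d = 0; doubling x doubles d
  expect_equal(scored$raw_distance[scored$pos == 10], 1.4)
  expect_equal(scored$raw_distance[scored$pos == 20], 0)
  expect_equal(scored$raw_distance[scored$pos == 30], 2.8)
  expect_equal(scored$rank, 1:3)
  expect_equal(scored$pos, c(30L, 10L, 20L))

  # ties break by variant key
  fm_tie <- tibble::tibble(
    chrom = "chr1", pos = c(5L, 3L), ref = "A", alt = "T",
    f001 = c(1, 1), f002 = c(1, 1)
  )
  s_tie <- score_mutations(fm_tie, model)
  expect_equal(s_tie$pos, c(3L, 5L))

  expect_error(score_mutations(fm[, -5], model), "f001")
})

test_that("fitted weights recover the generative direction", {
  # strong-signal regime: +3 sd shifts keep the max-margin direction from
  # leaning on the 319 noise dimensions
  fm <- simulate_feature_matrix(n = 5000, n_features = 339,
                                n_informative = 20, effect_size = 3,
                                seed = 71)
  model <- fit_final(fm, seed = 1)
  truth <- as.numeric(feature_names(fm) %in% attr(fm, "informative"))
  cosine <- sum(model$w * truth) / sqrt(sum(model$w^2) * sum(truth^2))
  expect_gte(cosine, 0.95)
})

test_that("planted LB mutations are enriched at the top of the ranking", {
  fm <- simulate_feature_matrix(n = 3000, n_features = 20,
                                n_informative = 5, effect_size = 1.5,
                                lb_fraction = 0.2, seed = 81)
  model <- fit_final(fm, seed = 1)
  scored <- score_mutations(fm, model)
  top <- head(scored, ceiling(0.01 * nrow(scored)))
  k <- sum(top$label == "LB")
  K <- sum(scored$label == "LB")
  p <- phyper(k - 1, K, nrow(scored) - K, nrow(top), lower.tail = FALSE)
  expect_lt(p, 1e-6)
})

test_that("training, selection, and scoring are deterministic under a fixed seed", {
  fm <- small_fm(n = 500, p = 8, m = 2, effect = 1.2, seed = 91)
  expect_identical(train_cv(fm, k = 5, seed = 13)[c(1:5)],
                   train_cv(fm, k = 5, seed = 13)[c(1:5)])
  s1 <- select_features(fm, k = 5, seed = 13)
  s2 <- select_features(fm, k = 5, seed = 13)
  expect_identical(s1, s2)
  m1 <- fit_final(fm, seed = 13)
  m2 <- fit_final(fm, seed = 13)
  expect_identical(m1, m2)
  expect_identical(score_mutations(fm, m1), score_mutations(fm, m2))
})

test_that("models round-trip through versioned JSON", {
  fm <- small_fm(n = 150, p = 5, m = 2, effect = 2, seed = 101)
  model <- fit_final(fm, seed = 1)
  f <- withr::local_tempfile(fileext = ".json")
  write_model(model, f)
  back <- read_model(f)
  expect_equal(back$w, model$w)
  expect_equal(back$b, model$b)
  # JSON carries full double precision up to decimal representation
  expect_equal(score_mutations(fm, back), score_mutations(fm, model),
               tolerance = 1e-12)
})

test_that("probability calibration maps decision values onto [0, 1] monotonically", {
  fm <- small_fm(n = 400, p = 6, m = 2, effect = 1.5, seed = 111)
  cv <- train_cv(fm, k = 5, seed = 1)
  cal <- platt_calibration(cv$predictions$decision, cv$predictions$label)
  d <- seq(-3, 3, length.out = 21)
  p <- cal(d)
  expect_true(all(p >= 0 & p <= 1))
  expect_true(all(diff(p) >= 0))
})
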
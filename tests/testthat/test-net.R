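# The convolutional-recurrent classifier: encoding stages, training
# behaviour, and the fold machinery.

test_that("conv_encode preserves length, handles L = 1, and maps zero to zero", {
  set.seed(101)
  params <- mbsnet:::.init_params(29, quick_config())
  x0 <- matrix(0, 6, 29)
  expect_equal(conv_encode(params, x0), matrix(0, 6, 16))  # tanh(0) = 0
  x1 <- matrix(rnorm(29), 1, 29)
  expect_equal(nrow(conv_encode(params, x1)), 1)
  xL <- matrix(rnorm(10 * 29), 10, 29)
  expect_equal(dim(conv_encode(params, xL)), c(10, 16))
  expect_error(conv_encode(params, xL[0, , drop = FALSE]), "zero-length")
})

test_that("a width-1 identity filter reproduces the input through the conv nonlinearity", {
  params <- list(Wc = matrix(1, 1, 1), bc = 0,
                 Wz = matrix(0, 1, 1), Uz = matrix(0, 1, 1), bz = 0,
                 Wr = matrix(0, 1, 1), Ur = matrix(0, 1, 1), br = 0,
                 Wn = matrix(0, 1, 1), Un = matrix(0, 1, 1), bn = 0,
                 Wo = matrix(0, 2, 1), bo = c(0, 0), filter_width = 1L)
  x <- matrix(seq(-0.3, 0.3, length.out = 7), 7, 1)
  expect_equal(conv_encode(params, x), tanh(x), ignore_attr = TRUE)
})

test_that("recurrent encoding is deterministic and order-sensitive", {
  set.seed(202)
  params <- mbsnet:::.init_params(29, quick_config())
  sp <- conv_encode(params, matrix(rnorm(12 * 29), 12, 29))
  h1 <- recurrent_encode(params, sp)
  h2 <- recurrent_encode(params, sp)
  expect_identical(h1, h2)
  expect_length(h1, 24)
  expect_true(all(is.finite(h1)))
  h_rev <- recurrent_encode(params, sp[12:1, ])
  expect_false(isTRUE(all.equal(h1, h_rev)))
  expect_error(recurrent_encode(params, sp[0, , drop = FALSE]),
               "zero-length")
})

test_that("classify_hidden produces normalised probabilities and confidences", {
  params <- list(Wo = diag(2), bo = c(0, 0))
  even <- classify_hidden(params, c(0, 0))
  expect_equal(even$p_physiological, 0.5)
  expect_equal(even$confidence, 0)
  expect_equal(even$class, "adventitious")   # tie at beta goes negative
  sure <- classify_hidden(params, c(10, -10))
  expect_gt(sure$p_physiological, 0.999)
  expect_gt(sure$confidence, 0.998)
  expect_equal(sure$class, "physiological")
  set.seed(303)
  for (i in 1:10) {
    pr <- classify_hidden(params, rnorm(2, sd = 4))
    expect_equal(pr$p_physiological + pr$p_adventitious, 1, tolerance = 1e-12)
    expect_equal(pr$confidence, abs(2 * pr$p_physiological - 1),
                 tolerance = 1e-12)
  }
})

test_that("training learns a strongly separable synthetic problem", {
  ds <- quick_dataset(n = 80, seed = 421)
  fit <- mbsnet(ds, config = quick_config(), control = quick_control(),
                seed = 5)
  test <- quick_dataset(n = 50, seed = 422)
  p <- predict(fit, test)
  expect_gte(mean(p$class == test$labels), 0.8)
  expect_true(all(abs(p$p_physiological + p$p_adventitious - 1) < 1e-6))
  expect_equal(p$confidence, abs(p$p_physiological - p$p_adventitious))
})

test_that("label-shuffled training stays near chance", {
  ds <- quick_dataset(n = 80, seed = 431)
  X <- lapply(ds$sites, function(s) s$values)
  set.seed(77)
  shuffled <- sample(ds$labels)
  fit <- mbsnet(X, shuffled, config = quick_config(),
                control = quick_control(), seed = 6)
  test <- quick_dataset(n = 60, seed = 432)
  set.seed(78)
  p <- predict(fit, test)
  acc <- mean(p$class == sample(test$labels))
  expect_gte(acc, 0.4)
  expect_lte(acc, 0.6)
})

test_that("the same seed reproduces the training trajectory bitwise", {
  ds <- quick_dataset(n = 25, seed = 441)
  f1 <- mbsnet(ds, config = quick_config(),
               control = quick_control(max_epochs = 8, patience = 8),
               seed = 11)
  f2 <- mbsnet(ds, config = quick_config(),
               control = quick_control(max_epochs = 8, patience = 8),
               seed = 11)
  expect_identical(f1$val_loss, f2$val_loss)
  expect_identical(f1$train_loss, f2$train_loss)
  expect_identical(f1$params$Wc, f2$params$Wc)
})

test_that("training requires both classes and 29 matching columns", {
  ds <- quick_dataset(n = 20, seed = 451)
  X <- lapply(ds$sites, function(s) s$values)
  expect_error(mbsnet(X, rep("physiological", length(X)),
                      config = quick_config(), control = quick_control()),
               "both classes")
  fit <- mbsnet(ds, config = quick_config(),
                control = quick_control(max_epochs = 3, patience = 3),
                seed = 3)
  expect_error(predict(fit, list(matrix(0, 5, 28))), "feature count")
})

test_that("raising the physiological class weight does not hurt its recall", {
  ds <- generate_dataset(40, 120, seed = 461)
  test <- generate_dataset(60, 60, seed = 462)
  recall <- sapply(c(1.0, 1.7), function(w) {
    fit <- mbsnet(ds, config = quick_config(),
                  control = quick_control(class_weight = w), seed = 17)
    p <- predict(fit, test)
    mean(p$class[test$labels == "physiological"] == "physiological")
  })
  expect_gte(recall[2], recall[1])
})

test_that("make_folds partitions, stratifies, and respects groups", {
  labels <- rep(c("physiological", "adventitious"), c(60, 40))
  f <- make_folds(labels, k = 10, seed = 9)
  expect_equal(sort(unique(as.integer(f))), 1:10)
  expect_equal(as.vector(table(f)), rep(10L, 10))
  per_fold_pos <- tapply(labels == "physiological", as.integer(f), sum)
  expect_true(all(per_fold_pos %in% 5:7))
  f2 <- make_folds(labels, k = 10, seed = 9)
  expect_identical(f2, f)

  groups <- rep(1:20, each = 5)
  fg <- make_folds(labels, k = 5, groups = groups, seed = 10)
  expect_true(all(tapply(as.integer(fg), groups,
                         function(v) length(unique(v))) == 1))
  expect_error(make_folds(labels, k = 10, groups = rep(1:5, 20)),
               "exceeds")
  expect_error(make_folds(labels, k = 2), "k >= 3")
})

test_that("cross-validation rotates folds and predicts each site once", {
  ds <- quick_dataset(n = 24, seed = 471)
  cv <- mbsnet_cv(ds, k = 4, config = quick_config(),
                  control = quick_control(max_epochs = 6, patience = 6),
                  seed = 12)
  expect_length(cv$models, 4)
  expect_equal(sort(cv$predictions$site_id), sort(ds$site_ids))
  expect_equal(nrow(cv$predictions), 48)
  cm <- cv$confusion
  expect_equal(cm$TP + cm$FN + cm$FP + cm$TN, 48)
  expect_equal(sort(unique(cv$predictions$fold)), 1:4)
})

test_that("prediction output is invariant to site ordering", {
  ds <- quick_dataset(n = 15, seed = 481)
  fit <- mbsnet(ds, config = quick_config(),
                control = quick_control(max_epochs = 4, patience = 4),
                seed = 8)
  p_fwd <- predict(fit, ds)
  perm <- rev(seq_along(ds$sites))
  p_rev <- predict(fit, ds[perm])
  expect_equal(p_rev[order(p_rev$site_id), -1],
               p_fwd[order(p_fwd$site_id), -1], ignore_attr = TRUE)
})
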
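test_that("folds partition the patients into near-equal parts", {
  f <- make_folds(10, 10, seed = 1)
  expect_equal(sort(tabulate(f$fold_index, 10)), rep(1L, 10))

  f <- make_folds(102, 4, seed = 2)
  expect_equal(sort(tabulate(f$fold_index, 4)), c(25L, 25L, 26L, 26L))

  f <- make_folds(5, 2, seed = 3)
  expect_equal(sort(tabulate(f$fold_index, 2)), c(2L, 3L))

  expect_identical(make_folds(50, 5, seed = 9), make_folds(50, 5, seed = 9))
  expect_false(identical(make_folds(50, 5, 9)$fold_index,
                         make_folds(50, 5, 10)$fold_index))
  expect_error(make_folds(5, 6, seed = 1), class = "slgeno_parameter_error")
  expect_error(make_folds(5, 1, seed = 1), class = "slgeno_parameter_error")

  # property: partition with size gap <= 1 for many (n, k)
  for (i in 1:25) {
    n <- sample(5:200, 1)
    k <- sample(2:min(n, 12), 1)
    f <- make_folds(n, k, seed = i)
    sizes <- table(factor(f$fold_index, levels = 1:k))
    expect_equal(sum(sizes), n)
    expect_lte(max(sizes) - min(sizes), 1)
  }
})

test_that("the two losses implement their definitions and bounds", {
  y <- c(0.5, -1, 2, 0)
  expect_equal(risk("sqe", y, y), 0)
  expect_equal(risk("one_minus_r", y, y), 0)
  expect_equal(risk("sqe", c(0, 2), c(1, 1)), 1)
  expect_equal(risk("one_minus_r", y, -y), 2)   # perfect anticorrelation
  expect_warning(r <- risk("one_minus_r", y, rep(1, 4)), "constant")
  expect_equal(r, 1)

  # property: bounds and (non-)invariance under positive affine maps
  withr::with_seed(50, {
    for (i in 1:200) {
      n <- sample(3:40, 1)
      yy <- rnorm(n); pp <- rnorm(n)
      r1 <- risk("one_minus_r", yy, pp)
      expect_gte(r1, 0); expect_lte(r1, 2)
      expect_gte(risk("sqe", yy, pp), 0)
      a <- runif(1, 0.1, 3); b <- runif(1, -2, 2)
      expect_equal(risk("one_minus_r", yy, a * pp + b), r1,
                   tolerance = 1e-10)
    }
  })
  expect_false(isTRUE(all.equal(risk("sqe", y, 2 * y), risk("sqe", y, y))))
})

test_that("cross-validated risk averages per-fold risks of out-of-fold fits", {
  # exact functional truth: CART recovers y = 2 x1 perfectly per fold
  d <- withr::with_seed(51, {
    G <- matrix(rbinom(60 * 3, 1, 0.5), 60, 3,
                dimnames = list(paste0("P", 1:60), paste0("x", 1:3)))
    geno_dataset(G, 2 * G[, 1])
  })
  folds <- make_folds(60, 5, seed = 4)
  cv <- cross_validated_risk(learner_spec("cart", list(cp = 0.001, min_split = 4,
                                                       min_bucket = 2)),
                             d, folds, "sqe")
  expect_equal(cv$mean_risk, 0, tolerance = 1e-12)

  # training-mean learner vs a closed-form per-split oracle
  d2 <- tiny_dataset(n = 40, p = 3, seed = 52)
  cv2 <- cross_validated_risk(learner_spec("cart", list(cp = 1)), d2, folds = make_folds(40, 4, seed = 5),
                              loss = "sqe")
  oracle <- vapply(1:4, function(f) {
    v <- make_folds(40, 4, seed = 5)$fold_index == f
    mean((d2$outcome[v] - mean(d2$outcome[!v]))^2)
  }, 0)
  expect_equal(cv2$fold_risks, oracle, tolerance = 1e-12)
  expect_equal(cv2$mean_risk, mean(oracle))
})

test_that("level-one columns are loss-independent and fold-consistent", {
  d <- tiny_dataset(n = 45, p = 4, seed = 53)
  folds <- make_folds(45, 3, seed = 6)
  spec <- learner_spec("rf", list(n_trees = 15), seed = 77L)
  a <- cross_validated_risk(spec, d, folds, "sqe")
  b <- cross_validated_risk(spec, d, folds, "one_minus_r")
  expect_identical(a$level_one, b$level_one)

  Z <- level_one_matrix(list(learner_spec("lm1"), spec), d, folds)
  expect_equal(colnames(Z), c("lm1", "rf"))
  expect_equal(unname(Z[, "rf"]), a$level_one)
})

test_that("ranking assigns mean ranks on ties and sums to L(L+1)/2", {
  risks <- c(LM1 = 0.216, LM2 = 1.218, RF = 0.258, DSA = 0.283,
             CART = 0.264, SL5 = 0.216)
  expect_equal(rank_learners(risks),
               c(LM1 = 1.5, LM2 = 6, RF = 3, DSA = 5, CART = 4, SL5 = 1.5))
  expect_equal(unname(rank_learners(rep(0.3, 5))), rep(3, 5))
  expect_equal(unname(rank_learners(c(a = 1, b = 2, c = 3))), 1:3)
  withr::with_seed(54, {
    for (i in 1:50) {
      L <- sample(2:8, 1)
      r <- rank_learners(stats::setNames(sample(c(1, 2, 2, 3, 4), L,
                                                replace = TRUE),
                                         paste0("l", 1:L)))
      expect_equal(sum(r), L * (L + 1) / 2)
    }
  })
})

test_that("cv_risk_table ties risks, ranks and the level-one matrix together", {
  d <- tiny_dataset(n = 40, p = 4, seed = 55)
  folds <- make_folds(40, 4, seed = 7)
  specs <- list(learner_spec("lm1"), learner_spec("cart"))
  tab <- cv_risk_table(specs, d, folds, "sqe")
  expect_s3_class(tab, "cv_risk_table")
  expect_equal(tab$learner, c("lm1", "cart"))
  expect_equal(tab$mean_risk,
               unname(rowMeans(as.matrix(tab[, paste0("fold_", 1:4)]))))
  expect_equal(tab$rank, unname(rank_learners(
    stats::setNames(tab$mean_risk, tab$learner))))
  f <- tempfile(fileext = ".csv")
  write_cv_table(tab, f)
  expect_equal(utils::read.csv(f)$mean_risk, tab$mean_risk, tolerance = 1e-12)
})
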
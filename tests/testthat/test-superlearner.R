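# Brute-force oracle: minimum risk over the simplex grid with the given
# step (all non-negative weight vectors summing to 1).
simplex_grid <- function(L, step = 0.02) {
  m <- round(1 / step)
  if (L == 2) {
    w1 <- 0:m
    return(cbind(w1, m - w1) / m)
  }
  grids <- utils::combn(seq_len(m + L - 1), L - 1)   # stars and bars
  t(apply(grids, 2, function(bars) diff(c(0, bars, m + L)) - 1)) / m
}

grid_min_risk <- function(Z, y, loss, step = 0.02) {
  W <- simplex_grid(ncol(Z), step)
  P <- Z %*% t(W)
  if (loss == "sqe") {
    min(colMeans((y - P)^2))
  } else {
    sds <- apply(P, 2, stats::sd)
    cors <- rep(-1, ncol(P))
    ok <- sds > 0
    cors[ok] <- suppressWarnings(stats::cor(y, P[, ok]))
    min(1 - cors)
  }
}

test_that("discrete Super Learner picks the minimum-risk learner, roster order on ties", {
  risks <- c(lm1 = 0.216, lm2 = 1.218, rf = 0.258, dsa = 0.283,
             cart = 0.264, logicreg = 0.653)
  expect_equal(discrete_super_learner(risks), "lm1")
  expect_equal(discrete_super_learner(c(dsa = 0.5)), "dsa")
  # exact two-way tie: rf precedes dsa in the roster order
  expect_equal(discrete_super_learner(c(dsa = 0.3, rf = 0.3, cart = 0.4)),
               "rf")
})

test_that("weights live on the simplex and an interpolating column takes weight 1", {
  withr::with_seed(60, {
    y <- rnorm(25)
    Z <- cbind(lm1 = y, cart = rnorm(25), rf = y + rnorm(25))
    for (loss in c("sqe", "one_minus_r")) {
      w <- fit_sl_weights(Z, y, loss)
      expect_gte(min(w$weights), 0)
      expect_equal(sum(w$weights), 1, tolerance = 1e-8)
      expect_equal(unname(w$weights["lm1"]), 1, tolerance = 1e-6)
      expect_equal(w$risk, 0, tolerance = 1e-8)
    }
    # duplicate columns: returned risk equals the single-column risk
    Z2 <- cbind(a = Z[, 3], b = Z[, 3])
    w2 <- fit_sl_weights(Z2, y, "sqe")
    expect_equal(w2$risk, risk("sqe", y, Z[, 3]), tolerance = 1e-6)
  })
})

test_that("constant level-one matrices fall back to uniform weights", {
  y <- rnorm(10)
  Z <- cbind(a = rep(1, 10), b = rep(2, 10))
  expect_warning(w <- fit_sl_weights(Z, y, "sqe"), "uniform")
  expect_equal(unname(w$weights), c(0.5, 0.5))
})

test_that("fitted weights match the exhaustive simplex-grid oracle (spot check)", {
  withr::with_seed(61, {
    for (i in 1:10) {
      y <- rnorm(30)
      Z <- matrix(rnorm(30 * 3), 30, 3,
                  dimnames = list(NULL, c("lm1", "rf", "cart")))
      Z <- Z + y %o% runif(3, 0, 1)   # give columns some signal
      for (loss in c("sqe", "one_minus_r")) {
        w <- fit_sl_weights(Z, y, loss, seed = i)
        expect_lte(w$risk, grid_min_risk(Z, y, loss) + 1e-6)
      }
    }
  })
})

test_that("build_super_learner wires rosters, prediction and dominance together", {
  expect_equal(sl_roster("SL5"), c("lm1", "lm2", "rf", "dsa", "cart"))
  expect_equal(sl_roster("SL6"),
               c("lm1", "lm2", "rf", "dsa", "cart", "logicreg"))

  d <- tiny_dataset(n = 40, p = 4, seed = 62)
  sl <- build_super_learner(d, roster = "SL5", k = 3, loss = "sqe",
                            seed = 5, learner_args = cheap_learner_args())
  expect_length(sl$full_fits, 5)
  expect_gte(min(sl$weights$weights), 0)
  expect_equal(sum(sl$weights$weights), 1, tolerance = 1e-8)

  # indicator weights reduce the SL to a single candidate
  sl1 <- sl
  sl1$weights$weights <- stats::setNames(c(1, 0, 0, 0, 0),
                                         names(sl$weights$weights))
  expect_equal(predict(sl1, d), unname(predict(sl$full_fits$lm1, d)))

  # convex averaging of constant candidates
  Zc <- cbind(a = rep(0, 5), b = rep(2, 5))
  wc <- structure(list(weights = c(a = 0.5, b = 0.5), loss = "sqe",
                       risk = NA_real_), class = "sl_weights")
  expect_equal(drop(Zc %*% wc$weights), rep(1, 5))

  # level-one dominance under the fitting loss
  single <- apply(sl$level_one[, sl_roster("SL5")], 2,
                  function(col) risk("sqe", d$outcome, col))
  expect_lte(sl_level_one_risk(sl, y = d$outcome), min(single))

  # one-candidate roster: SL risk equals that candidate's risk
  Z1 <- sl$level_one[, "lm1", drop = FALSE]
  w1 <- fit_sl_weights(Z1, d$outcome, "sqe")
  expect_equal(w1$risk, risk("sqe", d$outcome, Z1[, 1]))
})

test_that("weights serialize to JSON with metadata", {
  y <- rnorm(12)
  Z <- cbind(lm1 = y + rnorm(12, 0, 0.1), cart = rnorm(12))
  w <- fit_sl_weights(Z, y, "sqe")
  f <- tempfile(fileext = ".json")
  write_sl_weights(w, f, roster = "SL5", seed = 3L)
  j <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(unlist(j$weights), w$weights, tolerance = 1e-12)
  expect_equal(j$loss, "sqe")
  expect_equal(j$roster, "SL5")
})

test_that("honest nested CV is no more optimistic than the level-one risk", {
  # scaled-down simulation: small n, cheap candidates; the optimism gap
  # of weight fitting on shared level-one data should be >= 0 on average
  gaps <- vapply(1:15, function(s) {
    d <- tiny_dataset(n = 36, p = 4, seed = 200 + s, noise_sd = 0.8)
    args <- list(rf = list(n_trees = 10L),
                 dsa = list(maxsize = 2L, inner_folds = 3L))
    sl <- build_super_learner(d, "SL5", k = 3, loss = "sqe", seed = s,
                              learner_args = args)
    hon <- honest_sl_risk(d, "SL5", k = 3, loss = "sqe", seed = s,
                          outer_k = 3, learner_args = args)
    hon$mean_risk - sl_level_one_risk(sl, y = d$outcome)
  }, 0)
  expect_gt(mean(gaps), 0)
})
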
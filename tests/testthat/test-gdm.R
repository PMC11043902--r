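test_that("build_site_pairs enumerates all unordered pairs with aligned predictors", {
  set.seed(14)
  regions <- c("A", "B", "C", "D")
  resp <- matrix(runif(16, 0, 0.9), 4, dimnames = list(regions, regions))
  resp <- (resp + t(resp)) / 2; diag(resp) <- 0
  sc <- matrix(rnorm(8), 4, 2, dimnames = list(regions, c("e1", "e2")))
  geo <- great_circle(data.frame(lat = 1:4, lon = c(2, 5, 1, 9),
                                 row.names = regions))
  pr <- build_site_pairs(dist_matrix(resp), sc, list(geo = geo))
  expect_equal(length(pr$response), 6)
  expect_equal(pr$response[1], resp["A", "B"])
  expect_equal(pr$response[6], resp["C", "D"])
  expect_equal(pr$predictors$geo$values["B", "C"], unclass(geo)["B", "C"])

  # 3-region hand enumeration
  r3 <- resp[1:3, 1:3]
  pr3 <- build_site_pairs(dist_matrix(r3))
  expect_equal(pr3$response, c(r3[1, 2], r3[1, 3], r3[2, 3]))

  expect_error(build_site_pairs(dist_matrix(resp), sc[1:3, ]),
               "does not match")
})

test_that("I-spline basis is 0 at the minimum, 1 at the maximum and monotone", {
  set.seed(22)
  x <- c(0, sort(runif(200, 0, 3)), 3)
  B <- ispline_basis(x, knots = c(0, 1.2, 3))
  expect_equal(unname(B[1, ]), c(0, 0, 0))
  expect_equal(unname(B[nrow(B), ]), c(1, 1, 1))
  expect_true(all(diff(B[, 1]) >= -1e-12))
  expect_true(all(diff(B[, 2]) >= -1e-12))
  expect_true(all(diff(B[, 3]) >= -1e-12))
  expect_warning(ispline_basis(c(-1, 2), c(0, 1, 3)), "clamped")
  expect_error(ispline_basis(c(1, 1), c(1, 1, 1)), "degenerate")
})

test_that("I-spline values equal the numerically integrated M-spline density", {
  # each basis function's derivative is piecewise linear (an order-3
  # M-spline up to normalization); integrating it numerically must
  # reproduce the closed-form basis
  knots <- c(0, 0.4, 1)
  grid <- seq(0, 1, length.out = 2001)
  B <- ispline_basis(grid, knots)
  h <- diff(grid)[1]
  for (j in 1:3) {
    dens <- diff(B[, j]) / h             # derivative on the grid
    expect_true(all(dens >= -1e-8))      # non-negative density
    integ <- cumsum(c(0, dens * h))
    expect_equal(integ, unname(B[, j]), tolerance = 1e-3)
  }
})

test_that("a constant response yields the null model with zero coefficients", {
  regions <- sprintf("R%d", 1:8)
  resp <- matrix(0.4, 8, 8, dimnames = list(regions, regions)); diag(resp) <- 0
  # note: off-diagonal all equal -> response constant across pairs
  sc <- matrix(rnorm(8), 8, 1, dimnames = list(regions, "x"))
  pr <- build_site_pairs(dist_matrix(resp), sc)
  fit <- gdm_fit(pr)
  expect_equal(fit$deviance_explained, 0)
  expect_true(all(fit$coefficients == 0))
})

test_that("gdm_fit recovers a known noise-free model", {
  pr <- known_gdm_pairs(40, list(grad = c(0.4, 0.3, 0.3)), a0 = 0.05,
                        seed = 101)
  fit <- gdm_fit(pr)
  expect_gte(fit$deviance_explained, 99)
  expect_equal(unname(fit$heights["grad"]), 1.0, tolerance = 0.1)
  expect_true(all(fit$coefficients >= 0))
  expect_true(all(fit$fitted >= 0 & fit$fitted < 1))
  expect_true(fit$converged)
})

test_that("deviance is zero iff fitted equals observed, and constant predictors are dropped", {
  d <- c(0.2, 0.5, 0)
  expect_equal(gdm_deviance(d, d), 0, tolerance = 1e-9)
  expect_gt(gdm_deviance(d, rep(mean(d), 3)), 0)

  regions <- sprintf("R%d", 1:6)
  set.seed(2)
  resp <- matrix(runif(36, 0.1, 0.6), 6, dimnames = list(regions, regions))
  resp <- (resp + t(resp)) / 2; diag(resp) <- 0
  sc <- cbind(flat = rep(1, 6), ok = rnorm(6))
  rownames(sc) <- regions
  pr <- build_site_pairs(dist_matrix(resp), sc)
  expect_warning(fit <- gdm_fit(pr), "constant predictor")
  expect_equal(fit$dropped, "flat")
})

test_that("adding a predictor never decreases in-sample deviance explained", {
  set.seed(33)
  pr2 <- known_gdm_pairs(15, list(g1 = c(0.3, 0.2, 0.2), g2 = c(0.1, 0.1, 0)),
                         seed = 33)
  pr1 <- pr2; pr1$predictors <- pr1$predictors["g1"]
  f1 <- gdm_fit(pr1); f2 <- gdm_fit(pr2)
  expect_gte(f2$deviance_explained, f1$deviance_explained - 1e-6)
})

test_that("permutation importance identifies the sole informative predictor", {
  pr <- known_gdm_pairs(20, list(grad = c(0.5, 0.4, 0.4)), seed = 55)
  # add a pure-noise scalar predictor
  set.seed(56)
  pr$predictors$noise <- list(name = "noise", type = "scalar",
                              values = stats::setNames(rnorm(20),
                                                       pr$region_ids))
  fit <- gdm_fit(pr)
  imp <- var_importance(pr, fit, n_perm = 50, seed = 2)
  tab <- imp$table
  expect_gt(tab$importance[tab$predictor == "grad"], 50)
  expect_lt(abs(tab$importance[tab$predictor == "noise"]), 5)
  expect_lt(imp$model_p, 0.05)
  expect_true(all(imp$table$p >= 0 & imp$table$p <= 1))
  expect_error(var_importance(pr, fit, n_perm = 10), "at least 50")
})
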
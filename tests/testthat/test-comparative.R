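make_inc <- function(m, regions, species)
  incidence_matrix(matrix(m, length(regions), length(species), byrow = TRUE,
                          dimnames = list(regions, species)))

test_that("region_pseudotree reproduces the hand-computed 3-region case", {
  # A = {s1,s2}, B = {s1,s3}, C = {s4}: d(AB) = 0.5, d(AC) = d(BC) = 1;
  # complete linkage joins A,B at 0.5, then C at 1
  flea <- make_inc(c(1, 1, 0, 0,
                     1, 0, 1, 0,
                     0, 0, 0, 1), c("A", "B", "C"), paste0("s", 1:4))
  host <- make_inc(c(1, 1, 1), c("A", "B", "C"), "h1")
  # hosts identical across regions: shared species inflate a but the
  # hand-computed flea-only distances are checked via vegdist directly
  d <- vegan::vegdist(cbind(unclass(flea)), method = "bray")
  expect_equal(as.matrix(d)["A", "B"], 0.5)
  expect_equal(as.matrix(d)["A", "C"], 1)

  tr <- region_pseudotree(flea, make_inc(c(1, 0, 0, 0, 1, 0, 0, 0, 1),
                                         c("A", "B", "C"), paste0("h", 1:3)))
  expect_true(ape::is.ultrametric(tr, tol = 1e-10))
  expect_setequal(tr$tip.label, c("A", "B", "C"))
})

test_that("patristic distances on the region tree equal the complete-linkage merge heights", {
  set.seed(23)
  flea <- random_incidence(sprintf("R%d", 1:10), paste0("f", 1:15), p = 0.4)
  host <- random_incidence(sprintf("R%d", 1:10), paste0("h", 1:12), p = 0.4)
  tr <- region_pseudotree(flea, host)
  comb <- cbind(unclass(flea), unclass(host))
  coph <- stats::cophenetic(stats::hclust(vegan::vegdist(comb, "bray"),
                                          "complete"))
  expect_equal(ape::cophenetic.phylo(tr)[rownames(as.matrix(coph)),
                                         colnames(as.matrix(coph))],
               as.matrix(coph), tolerance = 1e-10)
  expect_error(region_pseudotree(flea, host[1:9, ]), "different region sets")
})

test_that("identical and disjoint regions sit at dissimilarity 0 and 1", {
  flea <- make_inc(c(1, 1, 0, 0,
                     0, 0, 1, 1), c("A", "B"), paste0("f", 1:4))
  host <- make_inc(c(1, 0, 0, 1), c("A", "B"), paste0("h", 1:2))
  tr <- region_pseudotree(flea, host)  # fully disjoint: merge height 1
  expect_equal(ape::cophenetic.phylo(tr)["A", "B"], 1, tolerance = 1e-12)
  # each pendant is merge height / 2
  expect_equal(sort(tr$edge.length), c(0.5, 0.5))
})

test_that("bm_covariance gives MRCA depths (star, 2-leaf, nested cases)", {
  star <- ape::read.tree(text = "(a:0.7,b:0.7,c:0.7);")
  expect_equal(unclass(bm_covariance(star)),
               diag(0.7, 3), ignore_attr = TRUE)

  two <- ape::read.tree(text = "(a:0.5,b:0.5);")
  expect_equal(unclass(bm_covariance(two)), diag(0.5, 2), ignore_attr = TRUE)

  # ((A,B) at height 0.5, C) at height 1 -> leaf depth 0.5 each after /2:
  # C_AB = depth of their ancestor = 0.5 - 0.25 = 0.25
  nested <- ape::read.tree(text = "((A:0.25,B:0.25):0.25,C:0.5);")
  C <- bm_covariance(nested)
  expect_equal(C["A", "B"], 0.25)
  expect_equal(C["A", "C"], 0)
  expect_equal(C["A", "A"], 0.5)

  nu <- ape::read.tree(text = "(a:1,b:2);")
  expect_error(bm_covariance(nu), "ultrametric")
})

test_that("pgls_fit equals OLS under identity covariance and is exact on noiseless data", {
  set.seed(5)
  n <- 20
  X <- cbind(1, x1 = rnorm(n), x2 = rnorm(n))
  y <- 2 + 0.5 * X[, 2] - 1.2 * X[, 3] + rnorm(n)
  fit <- pgls_fit(y, X, diag(n))
  ols <- stats::lm.fit(X, y)
  expect_equal(unname(fit$coefficients$estimate),
               unname(ols$coefficients), tolerance = 1e-10)

  y0 <- drop(X %*% c(1, 2, 3))
  fit0 <- pgls_fit(y0, X, diag(n))
  expect_equal(fit0$sigma2, 0, tolerance = 1e-14)
  expect_equal(fit0$residuals, rep(0, n), tolerance = 1e-10)
})

test_that("pgls_fit matches the explicit matrix-algebra oracle on a 5-region fixture", {
  X <- cbind(1, x = c(0.2, -1, 0.5, 2, -0.7))
  y <- c(1.1, 0.3, 0.9, 2.4, 0.2)
  C <- matrix(c(1, .5, .2, 0, 0,
                .5, 1, .3, 0, 0,
                .2, .3, 1, 0, 0,
                0, 0, 0, 1, .4,
                0, 0, 0, .4, 1), 5)
  fit <- pgls_fit(y, X, C)
  Ci <- solve(C)
  beta <- solve(t(X) %*% Ci %*% X, t(X) %*% Ci %*% y)
  expect_equal(unname(fit$coefficients$estimate), unname(drop(beta)),
               tolerance = 1e-10)
  r <- y - X %*% beta
  expect_equal(fit$sigma2, drop(t(r) %*% Ci %*% r) / 5, tolerance = 1e-10)
  # AIC identity: 2k - 2 logLik with k = coefficients + sigma2
  expect_equal(fit$AIC, 2 * 3 - 2 * fit$logLik, tolerance = 1e-12)
})

test_that("the GLS estimate maximizes the likelihood (random perturbation check)", {
  set.seed(77)
  n <- 12
  tr <- ape::compute.brlen(ape::rtree(n), method = "Grafen")
  C <- ape::vcv.phylo(tr)
  X <- cbind(1, x = rnorm(n))
  y <- drop(X %*% c(1, 0.8)) + drop(t(chol(C)) %*% rnorm(n, 0, 0.7))
  loglik_at <- function(beta) {
    r <- y - drop(X %*% beta)
    s2 <- drop(t(r) %*% solve(C, r)) / n
    -0.5 * (n * log(2 * pi * s2) + determinant(C)$modulus[1] + n)
  }
  fit <- pgls_fit(y, X, C)
  base <- loglik_at(fit$coefficients$estimate)
  expect_equal(base, fit$logLik, tolerance = 1e-8)
  for (k in 1:20)
    expect_gte(base, loglik_at(fit$coefficients$estimate + rnorm(2, 0, 0.3)))
})

test_that("forward stepwise never returns a worse AIC than intercept-only", {
  set.seed(9)
  n <- 25
  C <- diag(n)
  cand <- matrix(rnorm(n * 4), n, dimnames = list(NULL, paste0("v", 1:4)))
  y <- rnorm(n)
  fit <- phylostep_forward(y, cand, C)
  null_fit <- pgls_fit(y, matrix(1, n, 1), C)
  expect_lte(fit$AIC, null_fit$AIC)
  expect_true(all(diff(fit$path$criterion) < 0) || nrow(fit$path) == 1)
  empty <- phylostep_forward(y, cand[, 0, drop = FALSE], C)
  expect_equal(length(empty$selected), 0)
})

test_that("morans_i matches its analytic expectation and the ape implementation", {
  set.seed(12)
  n <- 11
  coords <- data.frame(lat = runif(n, 0, 10), lon = runif(n, 0, 10))
  z <- rnorm(n)
  mi <- morans_i(z, coords)
  expect_equal(mi$expectation, -0.1)
  # cross-check the statistic against ape::Moran.I with the same weights
  w <- 1 / as.matrix(great_circle(coords)); diag(w) <- 0
  w <- w / rowSums(w)
  ref <- ape::Moran.I(z, w, scaled = FALSE)
  expect_equal(mi$I, ref$observed, tolerance = 1e-10)
  expect_equal(mi$expectation, ref$expected, tolerance = 1e-12)
})

test_that("a strong spatial gradient in residuals is detected", {
  n <- 20
  coords <- data.frame(lat = rep(0, n) + seq(0, 5, length.out = n) * 0.01,
                       lon = seq(0, 19, length.out = n))
  resid <- coords$lon + rnorm(n, 0, 0.1)
  set.seed(4)
  mi <- morans_i(resid, coords)
  expect_gt(mi$I, 0)
  expect_lt(mi$p, 0.05)
})

test_that("morans_i rejects coincident coordinates", {
  coords <- data.frame(lat = c(1, 1, 2, 3), lon = c(1, 1, 2, 3))
  expect_error(morans_i(rnorm(4), coords), "jitter")
})
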
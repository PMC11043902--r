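test_that("prepare_traits ln-transforms, standardizes and dummy-codes as declared", {
  prep <- prepare_traits(toy_traits())
  m <- prep$matrix

  # ln(e^k) = k before scaling; (1..5) scales to mean 0, sample var 1
  expect_equal(unname(m[, "range_size"]),
               as.numeric(scale(1:5)), tolerance = 1e-12)

  # scaled columns: mean 0, sample variance 1
  for (cn in c("mass", "range_size", "size_rank")) {
    expect_lt(abs(mean(m[, cn])), 1e-10)
    expect_lt(abs(stats::var(m[, cn]) - 1), 1e-8)
  }

  # nominal with 3 levels -> exactly 3 dummy columns, row sums 1
  dum <- m[, startsWith(colnames(m), "shelter."), drop = FALSE]
  expect_equal(ncol(dum), 3)
  expect_true(all(dum %in% c(0, 1)))
  expect_equal(unname(rowSums(dum)), rep(1, 5))

  # ordinal ranks follow the declared ordering
  expect_true(all(diff(m[, "size_rank"]) >= 0))
})

test_that("prepare_traits errors on bad input and warns on constant columns", {
  tt <- toy_traits()
  tt$data$range_size[2] <- -1
  expect_error(prepare_traits(tt), "non-positive.*sp2")

  tt2 <- toy_traits()
  tt2$data$mass <- rep(3, 5)
  expect_warning(prep <- prepare_traits(tt2), "constant")
  expect_equal(unname(prep$matrix[, "mass"]), rep(0, 5))
})

test_that("standardized column (1,2,3) maps to (-1,0,1) under the sample-variance convention", {
  tt <- trait_table(data.frame(x = c(1, 2, 3)),
                    schema = data.frame(trait = "x", kind = "continuous"),
                    species_ids = c("a", "b", "c"))
  expect_equal(unname(prepare_traits(tt)$matrix[, "x"]), c(-1, 0, 1))
})

test_that("gower_distance matches hand computation and stays in [0,1]", {
  # two columns with ranges 2 and 4, row difference (1, 1):
  # d = (1/2)(1/2 + 1/4) = 0.375
  prep <- structure(list(matrix = matrix(c(0, 1, 2, 0, 1, 4), 3,
                                         dimnames = list(c("a", "b", "c"),
                                                         c("u", "v"))),
                         ranges = c(u = 2, v = 4)),
                    class = "prepared_traits")
  d <- gower_distance(prep)
  expect_equal(d["a", "b"], 0.375)
  expect_equal(d["a", "c"], 1)       # opposite extremes of every column
  expect_equal(diag(d), c(a = 0, b = 0, c = 0))
  expect_true(all(d >= 0 & d <= 1))
})

test_that("gower_distance agrees with the vegan range-standardized oracle", {
  set.seed(11)
  prep <- prepare_traits(toy_traits())
  mine <- gower_distance(prep)
  ref <- as.matrix(vegan::vegdist(prep$matrix, method = "gower"))
  expect_equal(unclass(mine), ref, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("gower_distance is invariant to affine rescaling of an input column", {
  tt <- toy_traits()
  d1 <- gower_distance(prepare_traits(tt))
  tt$data$mass <- tt$data$mass * 5 + 3
  d2 <- gower_distance(prepare_traits(tt))
  expect_equal(unclass(d1), unclass(d2), tolerance = 1e-12)
})

test_that("species permutation permutes the distance matrix accordingly", {
  tt <- toy_traits()
  d1 <- gower_distance(prepare_traits(tt))
  perm <- c(3, 1, 5, 2, 4)
  tt2 <- trait_table(tt$data[perm, ], tt$schema,
                     species_ids = tt$species_ids[perm])
  d2 <- gower_distance(prepare_traits(tt2))
  expect_equal(unclass(d2[tt$species_ids, tt$species_ids]), unclass(d1),
               tolerance = 1e-12)
})

test_that("env_composites: single and perfectly correlated categories explain all variance", {
  set.seed(2)
  x <- rnorm(12)
  env <- data.frame(a = x, b = 2 * x + 5, c = rnorm(12),
                    row.names = sprintf("R%02d", 1:12))
  cats <- c(a = "temp", b = "temp", c = "veg")
  ec <- env_composites(env, cats)
  expect_equal(unname(ec$variance_explained["temp"]), 1, tolerance = 1e-12)
  expect_equal(unname(ec$variance_explained["veg"]), 1)
  # single-variable category: scores equal the standardized variable
  expect_equal(unname(ec$scores[, "veg"]), as.numeric(scale(env$c)),
               tolerance = 1e-12)
  # sign convention: composite increases with the raw variables
  expect_gt(cor(ec$scores[, "temp"], x), 0.99)
  expect_lt(abs(mean(ec$scores[, "temp"])), 1e-10)
})

test_that("two independent standard normals split PC1 variance about evenly", {
  set.seed(3)
  n <- 10000
  env <- data.frame(a = rnorm(n), b = rnorm(n))
  rownames(env) <- paste0("r", seq_len(n))
  ec <- env_composites(env, c(a = "x", b = "x"))
  expect_equal(unname(ec$variance_explained["x"]), 0.5, tolerance = 0.02)
})

test_that("env_composites rejects zero-variance categories", {
  env <- data.frame(a = rep(1, 5), row.names = paste0("r", 1:5))
  expect_error(env_composites(env, c(a = "veg")), "zero-variance")
})
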
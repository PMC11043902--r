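#' Monotone I-spline basis
#'
#' Order-3 (piecewise-quadratic) I-splines: each basis function is 0 at
#' the domain minimum, 1 at the maximum, non-decreasing and continuously
#' differentiable. With three splines and knots (k1, k2, k3) at the
#' 0/50/100th percentiles of the observed values, spline j is the
#' integrated M-spline supported on the knot triple
#' (k1,k1,k2), (k1,k2,k3), (k2,k3,k3). Values outside [k1, k3] are
#' clamped with a warning. A non-negative combination of such splines is
#' itself non-decreasing, which is what lets the model coefficients be
#' read as turnover along the gradient.
#'
#' @param x numeric predictor values.
#' @param knots numeric vector of 3 increasing knot values.
#' @return matrix `length(x)` x 3 of basis values in [0, 1].
#' @export
ispline_basis <- function(x, knots) {
  stopifnot(length(knots) == 3)
  if (knots[1] >= knots[3]) stop("degenerate knots: all values equal")
  if (any(x < knots[1] - 1e-12) || any(x > knots[3] + 1e-12))
    warning("values outside the knot range clamped")
  x <- pmin(pmax(x, knots[1]), knots[3])
  q <- rbind(c(knots[1], knots[1], knots[2]),
             c(knots[1], knots[2], knots[3]),
             c(knots[2], knots[3], knots[3]))
  b <- sapply(1:3, function(j) quad_ispline(x, q[j, 1], q[j, 2], q[j, 3]))
  matrix(b, ncol = 3, dimnames = list(NULL, paste0("I", 1:3)))
}

# one piecewise-quadratic I-spline on knot triple q1 <= q2 <= q3
quad_ispline <- function(v, q1, q2, q3) {
  out <- numeric(length(v))
  out[v >= q3] <- 1
  mid <- v > q1 & v < q3
  vlo <- mid & v <= q2
  vhi <- mid & v > q2
  if (q2 > q1)
    out[vlo] <- (v[vlo] - q1)^2 / ((q3 - q1) * (q2 - q1))
  out[vhi] <- 1 - (q3 - v[vhi])^2 / ((q3 - q1) * (q3 - q2))
  out
}

#' Build a site-pair table for generalized dissimilarity modelling
#'
#' Enumerates all unordered region pairs (in the order the regions
#' appear) and attaches, per pair, the response dissimilarity, each
#' scalar predictor's pair of site values, and each matrix predictor's
#' pairwise value. Scalar predictors (the environmental composites)
#' enter as site values whose I-spline-transformed difference is the
#' model term; matrix predictors (host functional dissimilarity,
#' geographic distance) enter as pre-formed distances.
#'
#' @param response `dist_matrix` of response dissimilarities in [0, 1].
#' @param scalar_predictors region x predictor matrix/data.frame with
#'   region rownames (or NULL).
#' @param matrix_predictors named list of `dist_matrix` objects (or
#'   NULL).
#' @return an object of class `site_pair_table`.
#' @export
build_site_pairs <- function(response, scalar_predictors = NULL,
                             matrix_predictors = NULL) {
  regions <- rownames(response)
  if (any(response < 0 | response > 1)) stop("response must lie in [0, 1]")
  check_regions <- function(r, what) {
    if (!setequal(r, regions) || length(r) != length(regions))
      stop("region set of ", what, " does not match the response")
  }
  preds <- list()
  if (!is.null(scalar_predictors)) {
    sp <- as.matrix(scalar_predictors)
    check_regions(rownames(sp), "scalar predictors")
    sp <- sp[regions, , drop = FALSE]
    for (nm in colnames(sp))
      preds[[nm]] <- list(name = nm, type = "scalar", values = sp[, nm])
  }
  if (!is.null(matrix_predictors)) {
    for (nm in names(matrix_predictors)) {
      m <- as.matrix(matrix_predictors[[nm]])
      check_regions(rownames(m), paste("matrix predictor", nm))
      preds[[nm]] <- list(name = nm, type = "matrix",
                          values = m[regions, regions])
    }
  }
  ij <- which(upper.tri(response), arr.ind = TRUE)
  ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE]
  structure(list(region_ids = regions,
                 i = ij[, 1], j = ij[, 2],
                 response = as.matrix(response)[ij],
                 predictors = preds),
            class = "site_pair_table")
}

#' @export
print.site_pair_table <- function(x, ...) {
  cat(sprintf("site_pair_table: %d regions, %d pairs, %d predictor(s): %s\n",
              length(x$region_ids), length(x$response), length(x$predictors),
              paste(names(x$predictors), collapse = ", ")))
  invisible(x)
}

# Per-pair design columns for one predictor. Knots at the 0/50/100th
# percentiles of the observed site values (scalar) or pair distances
# (matrix). Returns NULL for degenerate (constant) predictors.
pred_design <- function(pred, i, j, knots = NULL) {
  if (pred$type == "scalar") {
    if (is.null(knots)) knots <- stats::quantile(pred$values, c(0, .5, 1),
                                                 names = FALSE)
    if (knots[1] >= knots[3]) return(NULL)
    B <- ispline_basis(pred$values, knots)
    cols <- abs(B[i, , drop = FALSE] - B[j, , drop = FALSE])
  } else {
    pv <- pred$values[cbind(i, j)]
    if (is.null(knots)) knots <- stats::quantile(pv, c(0, .5, 1), names = FALSE)
    if (knots[1] >= knots[3]) return(NULL)
    cols <- ispline_basis(pv, knots)
  }
  colnames(cols) <- paste(pred$name, colnames(cols), sep = ".")
  list(cols = cols, knots = knots)
}

# binomial-form deviance for proportion data, limit form at d in {0,1}
gdm_deviance <- function(d, mu) {
  mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
  t1 <- ifelse(d > 0, d * log(d / mu), 0)
  t2 <- ifelse(d < 1, (1 - d) * log((1 - d) / (1 - mu)), 0)
  2 * sum(t1 + t2)
}

#' Fit a generalized dissimilarity model
#'
#' Models pairwise dissimilarity d through the link mu = 1 - exp(-eta)
#' with eta = a0 + sum of non-negative I-spline terms, by minimizing
#' the binomial-form deviance with iteratively reweighted non-negative
#' least squares on the link scale. All coefficients (including the
#' intercept) are constrained >= 0, so every fitted per-predictor
#' transform is non-decreasing and fitted values lie in [0, 1). The
#' height of a predictor's transform (sum of its three coefficients)
#' is the total amount of turnover associated with that gradient,
#' holding the others constant.
#'
#' @param pairs a [build_site_pairs()] table.
#' @param max_iter maximum IRLS iterations (default 100).
#' @param tol convergence tolerance on the deviance change (default
#'   1e-8).
#' @return an object of class `gdm_fit`: `intercept`, `coefficients`
#'   (named vector, 3 per retained predictor), `knots` (per
#'   predictor), `heights`, `fitted`, `deviance`, `null_deviance`,
#'   `deviance_explained` (percent), `converged`, `dropped`.
#' @export
gdm_fit <- function(pairs, max_iter = 100, tol = 1e-8) {
  stopifnot(inherits(pairs, "site_pair_table"))
  d <- pairs$response
  if (length(d) < 10) stop("need at least 10 site pairs")
  null_dev <- gdm_deviance(d, rep(mean(d), length(d)))
  designs <- lapply(pairs$predictors, pred_design, i = pairs$i, j = pairs$j)
  dropped <- names(designs)[vapply(designs, is.null, logical(1))]
  if (length(dropped))
    warning("constant predictor(s) dropped: ", paste(dropped, collapse = ", "))
  designs <- designs[!vapply(designs, is.null, logical(1))]
  if (null_dev < 1e-12 || !length(designs)) {
    # constant response (or nothing to fit): the null model is optimal
    co <- stats::setNames(rep(0, 3 * length(designs)),
                          unlist(lapply(designs, function(z) colnames(z$cols))))
    return(structure(list(intercept = -log(1 - min(mean(d), 1 - 1e-12)),
                          coefficients = co,
                          knots = lapply(designs, `[[`, "knots"),
                          heights = stats::setNames(rep(0, length(designs)),
                                                    names(designs)),
                          fitted = rep(mean(d), length(d)),
                          deviance = null_dev, null_deviance = null_dev,
                          deviance_explained = 0, converged = TRUE,
                          dropped = dropped),
                     class = "gdm_fit"))
  }
  X <- do.call(cbind, lapply(designs, `[[`, "cols"))
  fit <- gdm_irls(d, X, max_iter = max_iter, tol = tol)
  co <- fit$beta
  heights <- vapply(names(designs), function(nm) {
    sum(co[startsWith(names(co), paste0(nm, ".I"))])
  }, numeric(1))
  structure(list(intercept = fit$a0, coefficients = co,
                 knots = lapply(designs, `[[`, "knots"),
                 heights = heights, fitted = fit$mu,
                 deviance = fit$deviance, null_deviance = null_dev,
                 deviance_explained = 100 * (1 - fit$deviance / null_dev),
                 converged = fit$converged, dropped = dropped),
            class = "gdm_fit")
}

# IRLS with non-negative least squares on the link scale.
# mu = 1 - exp(-eta); d mu / d eta = 1 - mu; Var(mu) = mu (1 - mu).
gdm_irls <- function(d, X, max_iter = 100, tol = 1e-8) {
  A0 <- cbind(`(Intercept)` = 1, X)
  mu <- pmin(pmax((d + mean(d)) / 2, 1e-4), 1 - 1e-4)
  eta <- -log(1 - mu)
  dev <- gdm_deviance(d, mu)
  converged <- FALSE
  beta <- rep(0, ncol(A0))
  for (it in seq_len(max_iter)) {
    dmu <- 1 - mu
    w <- dmu^2 / (mu * dmu)            # = (1 - mu) / mu
    z <- eta + (d - mu) / dmu
    sw <- sqrt(w)
    sol <- pracma::lsqnonneg(A0 * sw, z * sw)
    beta <- sol$x
    eta <- drop(A0 %*% beta)
    mu <- pmin(pmax(1 - exp(-eta), 1e-10), 1 - 1e-10)
    new_dev <- gdm_deviance(d, mu)
    if (abs(new_dev - dev) < tol) { dev <- new_dev; converged <- TRUE; break }
    dev <- new_dev
  }
  if (!converged)
    message("gdm_irls: IRLS did not converge; returning last iterate")
  list(a0 = beta[1], beta = stats::setNames(beta[-1], colnames(X)),
       mu = mu, deviance = dev, converged = converged)
}

#' @export
print.gdm_fit <- function(x, ...) {
  cat(sprintf("gdm_fit: %.1f%% deviance explained (D = %.4f, null %.4f)%s\n",
              x$deviance_explained, x$deviance, x$null_deviance,
              if (x$converged) "" else " [not converged]"))
  cat("spline heights:\n")
  print(round(x$heights, 4))
  invisible(x)
}

#' Predictor importance by matrix permutation
#'
#' For each predictor, region identities are permuted for that
#' predictor only (site values for scalars; rows and columns jointly
#' for matrix predictors), the model is refitted, and the importance is
#' the mean percent decrease in deviance explained relative to the full
#' model. The permutation p-value is the fraction of permutations whose
#' deviance explained is at least the full model's. Model-level
#' significance permutes all predictors jointly (one shared permutation
#' per iteration), leaving the response in place.
#'
#' @param pairs a [build_site_pairs()] table.
#' @param fit the full-model [gdm_fit()] on `pairs`.
#' @param n_perm number of permutations (>= 50; default 100).
#' @param seed integer seed for the permutation stream.
#' @return an object of class `gdm_importance`: data.frame `table`
#'   with columns `predictor`, `importance`, `p`, plus `model_p`,
#'   `full_deviance_explained`, `n_perm`, `seed`.
#' @export
var_importance <- function(pairs, fit, n_perm = 100, seed = 1) {
  stopifnot(inherits(pairs, "site_pair_table"), inherits(fit, "gdm_fit"))
  if (n_perm < 50) stop("n_perm must be at least 50")
  de_full <- fit$deviance_explained
  if (de_full <= 0)
    stop("importance undefined: full model explains no deviance")
  nr <- length(pairs$region_ids)
  pn <- names(pairs$predictors)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  perms <- replicate(n_perm, sample.int(nr), simplify = FALSE)
  permute_pred <- function(pred, prm) {
    if (pred$type == "scalar") pred$values <- unname(pred$values[prm])
    else pred$values <- pred$values[prm, prm]
    pred
  }
  de_perm <- matrix(NA_real_, n_perm, length(pn), dimnames = list(NULL, pn))
  de_model <- numeric(n_perm)
  for (t in seq_len(n_perm)) {
    prm <- perms[[t]]
    for (p in pn) {
      pp <- pairs
      pp$predictors[[p]] <- permute_pred(pp$predictors[[p]], prm)
      de_perm[t, p] <- suppressWarnings(gdm_fit(pp))$deviance_explained
    }
    pp <- pairs
    pp$predictors <- lapply(pp$predictors, permute_pred, prm = prm)
    de_model[t] <- suppressWarnings(gdm_fit(pp))$deviance_explained
  }
  imp <- 100 * (de_full - colMeans(de_perm)) / de_full
  pvals <- colMeans(sweep(de_perm, 2, de_full, ">="))
  structure(list(table = data.frame(predictor = pn,
                                    importance = unname(imp),
                                    p = unname(pvals)),
                 model_p = mean(de_model >= de_full),
                 full_deviance_explained = de_full,
                 n_perm = n_perm, seed = seed),
            class = "gdm_importance")
}

#' @export
print.gdm_importance <- function(x, ...) {
  cat(sprintf("gdm_importance: %d permutations (seed %d), full DE %.1f%%, model p = %.3f\n",
              x$n_perm, x$seed, x$full_deviance_explained, x$model_p))
  print(transform(x$table, importance = round(importance, 2)))
  invisible(x)
}
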
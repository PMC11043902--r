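#' Pseudo-phylogenetic tree of regions from species composition
#'
#' Regions sharing flea and host species are not independent
#' observations. To model this, the flea and host incidence matrices
#' are column-concatenated, Bray-Curtis dissimilarity is computed
#' between regions (for 0/1 rows this is 1 - 2a / (2a + b + c), with a
#' the shared and b, c the unique species counts), a complete-linkage
#' dendrogram is built, and the dendrogram is converted to a rooted
#' ultrametric tree with leaf depth equal to half the merge height —
#' so the patristic distance between two regions equals their
#' cophenetic merge height. Identical regions merge at height zero
#' (zero-length branches are allowed).
#'
#' @param flea_inc,host_inc [incidence_matrix()] objects over the same
#'   region set.
#' @return an ultrametric [ape::phylo] with regions as tips.
#' @export
region_pseudotree <- function(flea_inc, host_inc) {
  if (!setequal(rownames(flea_inc), rownames(host_inc)))
    stop("flea and host incidence matrices cover different region sets")
  host_inc <- host_inc[rownames(flea_inc), , drop = FALSE]
  comb <- cbind(unclass(flea_inc), unclass(host_inc))
  d <- vegan::vegdist(comb, method = "bray")
  hc <- stats::hclust(d, method = "complete")
  tree <- ape::as.phylo(hc)  # leaf depth = merge height / 2
  tree
}

#' Brownian-motion covariance matrix from an ultrametric region tree
#'
#' Under Brownian motion along the tree, the covariance between two
#' leaves is the depth (root-to-node path length) of their most recent
#' common ancestor, and the variance of each leaf is the total tree
#' depth.
#'
#' @param tree an ultrametric [ape::phylo].
#' @param tol ultrametricity tolerance on root-to-leaf depth spread.
#' @return symmetric positive semidefinite matrix with leaf labels.
#' @export
bm_covariance <- function(tree, tol = 1e-8) {
  if (!ape::is.ultrametric(tree, tol = tol, option = 1))
    stop("region tree is not ultrametric")
  ape::vcv.phylo(tree)
}

#' Generalized least squares with a fixed covariance structure
#'
#' Fits y = X beta + e, e ~ N(0, sigma^2 C), by generalized least
#' squares: beta = (X' C^-1 X)^-1 X' C^-1 y. sigma^2 is reported as the
#' maximum-likelihood estimate r' C^-1 r / n; coefficient standard
#' errors use the unbiased residual variance (n - k denominator) and t
#' tests have n - k degrees of freedom (k = number of coefficients).
#' AIC counts k + 1 parameters (coefficients plus sigma^2). If C is
#' numerically singular a jitter of 1e-10 * mean(diag(C)) is added to
#' the diagonal (with a message).
#'
#' @param y response vector (region values).
#' @param X design matrix including the intercept column.
#' @param C covariance matrix aligned with `y` (e.g. from
#'   [bm_covariance()]).
#' @return an object of class `pgls_fit`: coefficient table, sigma2
#'   (ML), logLik, AIC, residuals, fitted values.
#' @export
pgls_fit <- function(y, X, C) {
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n, nrow(C) == n, ncol(C) == n)
  if (qr(X)$rank < ncol(X)) {
    stop("rank-deficient design; collinear column(s): ",
         paste(colnames(X)[qr(X)$pivot[-seq_len(qr(X)$rank)]], collapse = ", "))
  }
  L <- tryCatch(chol(C), error = function(e) {
    message("pgls_fit: covariance singular, adding diagonal jitter")
    chol(C + diag(1e-10 * mean(diag(C)), n))
  })
  # whiten: solve L' u = v  (C = L'L with R's upper-triangular chol)
  wy <- backsolve(L, y, transpose = TRUE)
  wX <- backsolve(L, X, transpose = TRUE)
  XtCiX <- crossprod(wX)
  beta <- drop(solve(XtCiX, crossprod(wX, wy)))
  names(beta) <- colnames(X)
  resid <- as.numeric(y - X %*% beta)
  wresid <- as.numeric(wy - wX %*% beta)
  rss <- sum(wresid^2)               # r' C^-1 r
  k <- ncol(X)
  sigma2_ml <- rss / n
  logdetC <- 2 * sum(log(diag(L)))
  logLik <- -0.5 * (n * log(2 * pi * sigma2_ml) + logdetC + n)
  aic <- 2 * (k + 1) - 2 * logLik
  XtCiX_inv <- solve(XtCiX)
  se <- sqrt(pmax(diag(XtCiX_inv), 0) * rss / max(n - k, 1))
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df = n - k)
  coef_tab <- data.frame(estimate = beta, se = se, t = tval, p = pval,
                         row.names = colnames(X))
  structure(list(coefficients = coef_tab, sigma2 = sigma2_ml,
                 logLik = logLik, AIC = aic, n = n, k = k,
                 residuals = resid, fitted = as.numeric(X %*% beta)),
            class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat(sprintf("pgls_fit: n = %d, logLik = %.3f, AIC = %.3f, sigma2 = %.4g\n",
              x$n, x$logLik, x$AIC, x$sigma2))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Forward stepwise PGLS selection
#'
#' Starting from the intercept-only model, repeatedly adds the
#' candidate predictor giving the largest decrease of the information
#' criterion, stopping when no addition decreases it. Candidates are
#' typically the matching host alpha-diversity component plus the
#' three environmental composites. The default criterion is AICc
#' (AIC with the second-order small-sample correction): with realms of
#' 15-36 regions and up to five parameters, n/k is well under 40, the
#' regime where uncorrected AIC is known to over-select spurious
#' predictors.
#'
#' @param y response vector.
#' @param candidates matrix or data.frame of candidate predictors
#'   (named columns), rows aligned with `y`.
#' @param C covariance matrix (see [pgls_fit()]).
#' @param criterion `"AICc"` (default) or `"AIC"`.
#' @return the final [pgls_fit()], with `$selected` (character vector
#'   of chosen predictors in entry order) and `$path` (data.frame of
#'   the selection trace).
#' @export
phylostep_forward <- function(y, candidates, C, criterion = c("AICc", "AIC")) {
  criterion <- match.arg(criterion)
  candidates <- as.matrix(candidates)
  n <- length(y)
  crit_of <- function(fit) {
    K <- fit$k + 1  # coefficients + sigma^2
    if (criterion == "AIC") fit$AIC
    else fit$AIC + 2 * K * (K + 1) / max(n - K - 1, 1)
  }
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  current <- pgls_fit(y, X, C)
  cur_crit <- crit_of(current)
  selected <- character()
  path <- data.frame(step = 0L, added = "(none)", criterion = cur_crit)
  pool <- colnames(candidates)
  repeat {
    if (!length(pool)) break
    crits <- vapply(pool, function(p) {
      crit_of(pgls_fit(y, cbind(X, candidates[, p, drop = FALSE]), C))
    }, numeric(1))
    best <- names(which.min(crits))
    if (crits[best] >= cur_crit) break
    X <- cbind(X, candidates[, best, drop = FALSE])
    current <- pgls_fit(y, X, C)
    cur_crit <- crit_of(current)
    selected <- c(selected, best)
    pool <- setdiff(pool, best)
    path <- rbind(path, data.frame(step = length(selected), added = best,
                                   criterion = cur_crit))
  }
  current$selected <- selected
  current$path <- path
  current$criterion <- criterion
  current
}

#' Moran's I test for residual spatial autocorrelation
#'
#' Spatial weights are inverse great-circle distances between region
#' centres (w_ii = 0), row-standardized. The statistic is
#' I = (n / W) * sum_ij w_ij z_i z_j / sum_i z_i^2 with z the centred
#' residuals and W the weight total. The expectation under the
#' randomization null is -1/(n-1); the variance uses the standard
#' randomization (kurtosis-corrected) formula and the p-value is
#' two-sided under the normal approximation.
#'
#' @param resid residual vector.
#' @param coords data.frame/matrix with columns `lat`, `lon` in decimal
#'   degrees, rows aligned with `resid`.
#' @param weights weighting scheme: inverse great-circle distance
#'   (default) or symmetric k-nearest-neighbour adjacency (k = 4).
#' @return an object of class `moran_result`: `I`, `expectation`,
#'   `variance`, `p`.
#' @export
morans_i <- function(resid, coords, weights = c("inverse_distance", "knn")) {
  weights <- match.arg(weights)
  n <- length(resid)
  if (n < 4) stop("Moran's I needs at least 4 regions")
  gd <- great_circle(coords)
  if (any(gd[upper.tri(gd)] == 0))
    stop("coincident region coordinates (zero distance); jitter the coordinates")
  if (weights == "inverse_distance") {
    w <- 1 / gd
  } else {
    w <- matrix(0, n, n)
    k <- min(4, n - 1)
    for (i in seq_len(n)) w[i, order(gd[i, ])[2:(k + 1)]] <- 1
    w <- pmax(w, t(w))  # symmetrize
  }
  diag(w) <- 0
  w <- w / rowSums(w)
  z <- resid - mean(resid)
  W <- sum(w)
  I <- (n / W) * sum(w * tcrossprod(z)) / sum(z^2)
  EI <- -1 / (n - 1)
  S1 <- 0.5 * sum((w + t(w))^2)
  S2 <- sum((rowSums(w) + colSums(w))^2)
  b2 <- n * sum(z^4) / sum(z^2)^2
  VI <- (n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * W^2) -
         b2 * ((n^2 - n) * S1 - 2 * n * S2 + 6 * W^2)) /
        ((n - 1) * (n - 2) * (n - 3) * W^2) - EI^2
  p <- 2 * stats::pnorm(-abs(I - EI) / sqrt(VI))
  structure(list(I = I, expectation = EI, variance = VI, p = p,
                 weights = weights),
            class = "moran_result")
}

#' @export
print.moran_result <- function(x, ...) {
  cat(sprintf("Moran's I = %.4f (E = %.4f, var = %.5f), p = %.4f [%s]\n",
              x$I, x$expectation, x$variance, x$p, x$weights))
  invisible(x)
}
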
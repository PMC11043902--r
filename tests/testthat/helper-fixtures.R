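# Shared fixture builders. Everything is generated in code; no data files.

# A random tree with strictly positive branch lengths whose patristic
# matrix is an exact additive (tree) metric.
random_additive_tree <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rtree(n, br = function(k) stats::runif(k, 0.1, 1))
  tr$tip.label <- sprintf("t%02d", seq_len(n))
  tr
}

# Independent branch-membership oracle for the rooted Ochiai beta
# dissimilarity: per-region branch sets built from explicit
# root-to-tip node paths (ape::nodepath), not from edge_leaf_map.
ochiai_beta_oracle <- function(tree, inc) {
  root <- length(tree$tip.label) + 1L
  edge_id <- function(p, ch) which(tree$edge[, 1] == p & tree$edge[, 2] == ch)
  tip_path_edges <- lapply(seq_along(tree$tip.label), function(tip) {
    nodes <- ape::nodepath(tree, root, tip)
    vapply(seq_len(length(nodes) - 1),
           function(k) edge_id(nodes[k], nodes[k + 1]), integer(1))
  })
  names(tip_path_edges) <- tree$tip.label
  region_branches <- lapply(rownames(inc), function(r) {
    sp <- colnames(inc)[inc[r, ] == 1]
    sort(unique(unlist(tip_path_edges[sp])))
  })
  names(region_branches) <- rownames(inc)
  n <- nrow(inc)
  d <- matrix(0, n, n, dimnames = list(rownames(inc), rownames(inc)))
  len <- tree$edge.length
  for (i in seq_len(n)) for (j in seq_len(n)) {
    Ki <- region_branches[[i]]; Kj <- region_branches[[j]]
    a <- sum(len[intersect(Ki, Kj)])
    b <- sum(len[setdiff(Ki, Kj)])
    cc <- sum(len[setdiff(Kj, Ki)])
    d[i, j] <- 1 - a / sqrt((a + b) * (a + cc))
  }
  d
}

# Random incidence matrix over given species where every region holds
# >= min_sp species and every species occurs somewhere.
random_incidence <- function(regions, species, p = 0.5, min_sp = 2) {
  repeat {
    m <- matrix(rbinom(length(regions) * length(species), 1, p),
                length(regions), length(species),
                dimnames = list(regions, species))
    if (all(rowSums(m) >= min_sp) && all(colSums(m) >= 1))
      return(incidence_matrix(m))
  }
}

# Small mixed-type trait table used across trait_prep tests.
toy_traits <- function() {
  trait_table(
    data.frame(mass = c(2, 4, 8, 16, 32),
               range_size = exp(c(1, 2, 3, 4, 5)),
               size_rank = c("small", "small", "medium", "large", "large"),
               shelter = c("burrow", "hair", "none", "burrow", "hair")),
    schema = data.frame(
      trait = c("mass", "range_size", "size_rank", "shelter"),
      kind = c("continuous", "continuous", "ordinal", "nominal"),
      ln_transform = c(FALSE, TRUE, FALSE, FALSE),
      levels = c(NA, NA, "small,medium,large", NA)),
    species_ids = paste0("sp", 1:5))
}

# Noise-free site-pair data generated from a known GDM: scalar
# predictors with uniform site values, given intercept and I-spline
# coefficients (list of length-3 vectors per predictor).
known_gdm_pairs <- function(n_regions, coefs, a0 = 0.05, seed = 1) {
  set.seed(seed)
  regions <- sprintf("R%02d", seq_len(n_regions))
  x <- sapply(seq_along(coefs), function(k) runif(n_regions))
  dimnames(x) <- list(regions, names(coefs))
  ij <- which(upper.tri(diag(n_regions)), arr.ind = TRUE)
  ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE]
  eta <- rep(a0, nrow(ij))
  for (k in seq_along(coefs)) {
    kn <- quantile(x[, k], c(0, .5, 1), names = FALSE)
    B <- ispline_basis(x[, k], kn)
    eta <- eta + abs(B[ij[, 1], ] - B[ij[, 2], ]) %*% coefs[[k]]
  }
  d <- 1 - exp(-as.numeric(eta))
  resp <- matrix(0, n_regions, n_regions, dimnames = list(regions, regions))
  resp[ij] <- d; resp <- resp + t(resp)
  build_site_pairs(dist_matrix(resp), scalar_predictors = x)
}
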
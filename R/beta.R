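#' Branch-based functional dissimilarity between regions (Ochiai)
#'
#' Functional beta diversity measured over tree branches (functional
#' units) instead of species. For each region, the relevant branch set
#' K_r contains every branch lying on a root-to-leaf path of a species
#' present in that region, using the tree as rooted at its stored
#' construction root (optionally midpoint-rerooted first). For regions
#' i and j, with branch-length totals
#' a = shared branches, b = branches unique to i, c = unique to j,
#' the dissimilarity is the complement of the Ochiai similarity
#' (coefficient S12 of the Gower-Legendre family in its incidence
#' form):
#' \deqn{d_{ij} = 1 - a / \sqrt{(a + b)(a + c)}}
#'
#' @param tree functional tree ([ape::phylo]) covering the incidence
#'   species.
#' @param inc an [incidence_matrix()].
#' @param reroot `"none"` (use the construction root, default) or
#'   `"midpoint"`.
#' @return a `dist_matrix` of pairwise functional dissimilarities in
#'   [0, 1] with region labels.
#' @export
functional_dissimilarity <- function(tree, inc, reroot = c("none", "midpoint")) {
  reroot <- match.arg(reroot)
  stopifnot(inherits(inc, "incidence_matrix"))
  missing_sp <- setdiff(colnames(inc), tree$tip.label)
  if (length(missing_sp))
    stop("species in incidence missing from tree: ",
         paste(missing_sp, collapse = ", "))
  if (reroot == "midpoint") {
    if (!requireNamespace("phangorn", quietly = TRUE))
      stop("midpoint rerooting requires the 'phangorn' package")
    tree <- phangorn::midpoint(tree)
  }
  map <- edge_leaf_map(tree)  # edge x tip: tip below edge
  # K_r: edge on a root-to-leaf path of some present species
  K <- (map[, colnames(inc), drop = FALSE] %*% t(unclass(inc))) > 0
  len <- tree$edge.length
  nr <- nrow(inc)
  d <- matrix(0, nr, nr, dimnames = list(rownames(inc), rownames(inc)))
  tot <- colSums(len * K)  # a + b for each region
  for (i in seq_len(nr - 1)) for (j in (i + 1):nr) {
    a <- sum(len[K[, i] & K[, j]])
    d[i, j] <- d[j, i] <- 1 - a / sqrt(tot[i] * tot[j])
  }
  dist_matrix(d)
}

#' Great-circle distances between region centres
#'
#' Haversine distances on a sphere of mean Earth radius 6371.0 km.
#'
#' @param coords data.frame/matrix with columns `lat`, `lon` in decimal
#'   degrees; rownames (if present) are used as region labels.
#' @return a `dist_matrix` of distances in kilometres.
#' @export
great_circle <- function(coords) {
  coords <- as.data.frame(coords)
  if (!all(c("lat", "lon") %in% names(coords)))
    stop("coords needs 'lat' and 'lon' columns")
  if (any(coords$lat < -90 | coords$lat > 90))
    stop("latitude out of [-90, 90]")
  if (any(coords$lon < -180 | coords$lon > 180))
    stop("longitude out of [-180, 180]")
  p <- as.matrix(coords[, c("lon", "lat")])
  n <- nrow(p)
  d <- matrix(0, n, n)
  for (i in seq_len(n))
    d[i, ] <- geosphere::distHaversine(p[i, ], p, r = 6371000) / 1000
  d <- (d + t(d)) / 2  # enforce exact symmetry
  diag(d) <- 0
  labs <- rownames(coords)
  if (is.null(labs)) labs <- as.character(seq_len(n))
  dimnames(d) <- list(labs, labs)
  dist_matrix(d)
}
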
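#' Construct a species x trait table with a typed schema
#'
#' Mixed-type trait data need an explicit schema before they can be
#' turned into a numeric matrix: each trait is continuous, ordinal,
#' binary or nominal, ordinal traits carry an explicit level ordering,
#' and continuous traits may be flagged for ln-transformation (used for
#' strongly right-skewed variables such as geographic range size).
#'
#' @param data data.frame of trait values, one row per species.
#' @param schema data.frame with columns `trait`, `kind`
#'   (`"continuous"`, `"ordinal"`, `"nominal"` or `"binary"`), optional
#'   `ln_transform` (logical) and optional `levels` (comma-separated
#'   ordering for ordinal traits).
#' @param species_ids character vector of species labels (defaults to
#'   `rownames(data)`).
#' @return an object of class `trait_table`.
#' @export
trait_table <- function(data, schema, species_ids = rownames(data)) {
  data <- as.data.frame(data)
  if (is.null(species_ids)) stop("trait table needs species labels")
  if (anyDuplicated(species_ids)) stop("duplicate species labels in trait table")
  schema <- as.data.frame(schema, stringsAsFactors = FALSE)
  if (!all(c("trait", "kind") %in% names(schema)))
    stop("schema needs 'trait' and 'kind' columns")
  if (is.null(schema$ln_transform)) schema$ln_transform <- FALSE
  schema$ln_transform[is.na(schema$ln_transform)] <- FALSE
  if (is.null(schema$levels)) schema$levels <- NA_character_
  miss <- setdiff(names(data), schema$trait)
  if (length(miss)) stop("schema does not cover trait(s): ",
                         paste(miss, collapse = ", "))
  bad <- setdiff(schema$kind, c("continuous", "ordinal", "nominal", "binary"))
  if (length(bad)) stop("unknown trait kind(s): ", paste(bad, collapse = ", "))
  ord <- schema$trait[schema$kind == "ordinal"]
  for (tr in ord)
    if (is.na(schema$levels[schema$trait == tr]))
      stop("ordinal trait '", tr, "' needs an explicit level ordering")
  rownames(data) <- species_ids
  structure(list(data = data, schema = schema, species_ids = species_ids),
            class = "trait_table")
}

#' Read a trait table and its schema from CSV files
#'
#' The trait file has the species label in the first column; the schema
#' file has columns `trait`, `kind`, and optionally `ln_transform` and
#' `levels` (comma-separated for ordinal traits).
#'
#' @param path trait CSV path.
#' @param schema_path schema CSV path.
#' @param exclusions species labels to drop.
#' @return a [trait_table()].
#' @export
read_traits <- function(path, schema_path, exclusions = character()) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  sp <- as.character(df[[1]])
  df <- df[, -1, drop = FALSE]
  keep <- !(sp %in% exclusions)
  schema <- utils::read.csv(schema_path, stringsAsFactors = FALSE)
  trait_table(df[keep, , drop = FALSE], schema, species_ids = sp[keep])
}

#' Write a trait table (and its schema) to CSV
#' @param traits a [trait_table()].
#' @param path trait CSV path.
#' @param schema_path schema CSV path.
#' @return `path`, invisibly.
#' @export
write_traits <- function(traits, path, schema_path) {
  df <- data.frame(species = traits$species_ids, traits$data,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  # schema 'levels' strings contain commas; keep quoting on
  utils::write.csv(traits$schema, schema_path, row.names = FALSE)
  invisible(path)
}

#' @export
print.trait_table <- function(x, ...) {
  cat(sprintf("trait_table: %d species x %d traits (%s)\n",
              nrow(x$data), ncol(x$data),
              paste(sprintf("%d %s", table(x$schema$kind),
                            names(table(x$schema$kind))), collapse = ", ")))
  invisible(x)
}

#' Prepare a trait table for distance computation
#'
#' Flagged continuous traits are ln-transformed first; continuous and
#' ordinal traits (the latter as integer ranks along their declared
#' level ordering) are standardized to zero mean and unit sample
#' variance (n - 1 denominator); binary traits are passed through as
#' 0/1; nominal traits with k levels are expanded to k dummy columns.
#' Constant columns are kept as all-zero with a warning so that column
#' bookkeeping stays aligned across realms.
#'
#' @param traits a [trait_table()].
#' @return an object of class `prepared_traits`: list with `matrix`
#'   (species x numeric columns), `ranges` (observed max - min per
#'   column, the Gower normalizers), `provenance` (source trait per
#'   column) and `scaling` metadata.
#' @export
prepare_traits <- function(traits) {
  stopifnot(inherits(traits, "trait_table"))
  data <- traits$data
  schema <- traits$schema
  cols <- list(); prov <- character()
  for (tr in names(data)) {
    kind <- schema$kind[schema$trait == tr]
    v <- data[[tr]]
    if (kind %in% c("continuous", "ordinal")) {
      if (kind == "ordinal") {
        lev <- strsplit(schema$levels[schema$trait == tr], ",")[[1]]
        lev <- trimws(lev)
        if (!all(as.character(v) %in% lev))
          stop("ordinal trait '", tr, "' has values outside declared levels")
        v <- match(as.character(v), lev)
      } else {
        v <- as.numeric(v)
        if (isTRUE(schema$ln_transform[schema$trait == tr])) {
          if (any(v <= 0))
            stop("ln-transform of non-positive value for species ",
                 paste(traits$species_ids[v <= 0], collapse = ", "),
                 " in trait '", tr, "'")
          v <- log(v)
        }
      }
      if (stats::sd(v) == 0) {
        warning("constant trait '", tr, "' kept as zeros")
        v <- rep(0, length(v))
      } else {
        v <- as.numeric(scale(v))  # sample variance convention
      }
      cols[[tr]] <- v
      prov <- c(prov, tr)
    } else if (kind == "binary") {
      v <- as.numeric(v)
      if (!all(v %in% c(0, 1))) stop("binary trait '", tr, "' must be 0/1")
      cols[[tr]] <- v
      prov <- c(prov, tr)
    } else {  # nominal -> one dummy column per level
      f <- factor(v)
      for (lv in levels(f)) {
        cols[[paste(tr, lv, sep = ".")]] <- as.numeric(f == lv)
        prov <- c(prov, tr)
      }
    }
  }
  m <- do.call(cbind, cols)
  rownames(m) <- traits$species_ids
  structure(list(matrix = m,
                 ranges = apply(m, 2, function(x) diff(range(x))),
                 provenance = stats::setNames(prov, colnames(m)),
                 scaling = list(variance = "sample (n-1)",
                                gower_input = "prepared columns (scaled + dummies)")),
            class = "prepared_traits")
}

#' Gower distance on a prepared trait matrix
#'
#' Range-normalized mean absolute difference over the prepared numeric
#' columns: d(i,j) = (1/p) * sum_k |x_ik - x_jk| / range_k, where
#' range_k is the observed max - min of column k. Zero-range columns
#' carry no information and are skipped (p is reduced accordingly).
#' Distances lie in [0, 1].
#'
#' @param prepared a [prepare_traits()] result.
#' @return a `dist_matrix`: symmetric numeric matrix with zero diagonal
#'   and species labels.
#' @export
gower_distance <- function(prepared) {
  stopifnot(inherits(prepared, "prepared_traits"))
  m <- prepared$matrix
  if (nrow(m) < 2) stop("need at least 2 species for a distance matrix")
  rng <- prepared$ranges
  use <- rng > 0
  if (!any(use)) stop("all columns have zero range")
  ms <- sweep(m[, use, drop = FALSE], 2, rng[use], "/")
  p <- sum(use)
  d <- as.matrix(stats::dist(ms, method = "manhattan")) / p
  dist_matrix(d)
}

#' Validate and label a symmetric distance matrix
#' @param d symmetric numeric matrix with labels.
#' @return the matrix with class `dist_matrix`.
#' @export
dist_matrix <- function(d) {
  d <- as.matrix(d)
  if (is.null(rownames(d))) stop("distance matrix needs labels")
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix not symmetric")
  if (any(diag(d) != 0)) stop("distance matrix diagonal must be zero")
  if (any(d < 0)) stop("negative distances")
  colnames(d) <- rownames(d)
  structure(d, class = c("dist_matrix", "matrix", "array"))
}

#' Collapse environmental variables to per-category PC1 composites
#'
#' Each category of raw environmental variables (e.g. vegetation,
#' temperature, precipitation) is standardized and subjected to a
#' correlation-matrix PCA; the category is then represented by its
#' first principal component scores. The sign of each composite is
#' fixed so that it correlates positively with the mean of the
#' category's standardized raw variables, i.e. composites read as "an
#' increase in the respective original variables".
#'
#' @param env data.frame or matrix of raw environmental variables with
#'   region labels as rownames.
#' @param categories named character vector mapping variable name ->
#'   category.
#' @return an object of class `env_composite`: list with `scores`
#'   (region x category matrix, zero-mean columns),
#'   `variance_explained` (per category) and `flipped` (sign flips).
#' @export
env_composites <- function(env, categories) {
  env <- as.matrix(env)
  if (is.null(rownames(env))) stop("env table needs region labels")
  miss <- setdiff(colnames(env), names(categories))
  if (length(miss)) stop("no category for variable(s): ",
                         paste(miss, collapse = ", "))
  cats <- unique(categories[colnames(env)])
  scores <- matrix(NA_real_, nrow(env), length(cats),
                   dimnames = list(rownames(env), cats))
  ve <- stats::setNames(numeric(length(cats)), cats)
  flipped <- stats::setNames(logical(length(cats)), cats)
  for (ct in cats) {
    vars <- colnames(env)[categories[colnames(env)] == ct]
    x <- env[, vars, drop = FALSE]
    if (any(apply(x, 2, stats::sd) == 0))
      stop("zero-variance variable(s) in category '", ct, "'")
    xs <- scale(x)
    pc <- stats::prcomp(xs, center = FALSE, scale. = FALSE)
    s <- pc$x[, 1]
    # orient so the composite increases with the raw variables
    if (stats::cor(s, rowMeans(xs)) < 0) { s <- -s; flipped[ct] <- TRUE }
    scores[, ct] <- s
    ve[ct] <- pc$sdev[1]^2 / sum(pc$sdev^2)
  }
  structure(list(scores = scores, variance_explained = ve, flipped = flipped),
            class = "env_composite")
}
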
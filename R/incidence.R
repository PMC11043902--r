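#' Construct a region x species incidence matrix
#'
#' An incidence matrix records which species (columns) were recorded in
#' which regions (rows), coded 0/1. Every region must hold at least one
#' species and every species must occur in at least one region; labels
#' must be unique.
#'
#' @param values numeric matrix of 0/1 with regions in rows and species
#'   in columns; dimnames are taken as region and species labels.
#' @param region_ids,species_ids optional label vectors overriding the
#'   dimnames of `values`.
#' @return an object of class `incidence_matrix` (a 0/1 integer matrix
#'   with row and column names).
#' @export
incidence_matrix <- function(values, region_ids = rownames(values),
                             species_ids = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(region_ids) || is.null(species_ids))
    stop("incidence matrix needs region and species labels")
  if (anyDuplicated(region_ids))
    stop("duplicate region labels: ",
         paste(unique(region_ids[duplicated(region_ids)]), collapse = ", "))
  if (anyDuplicated(species_ids))
    stop("duplicate species labels: ",
         paste(unique(species_ids[duplicated(species_ids)]), collapse = ", "))
  bad <- which(!(values %in% c(0, 1)))
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(values)) + 1
    j <- ((bad[1] - 1) %/% nrow(values)) + 1
    stop(sprintf("non-binary incidence value at region '%s', species '%s'",
                 region_ids[i], species_ids[j]))
  }
  storage.mode(values) <- "integer"
  dimnames(values) <- list(region_ids, species_ids)
  if (any(rowSums(values) == 0))
    stop("region(s) with no species: ",
         paste(region_ids[rowSums(values) == 0], collapse = ", "))
  if (any(colSums(values) == 0))
    stop("species occurring in no region: ",
         paste(species_ids[colSums(values) == 0], collapse = ", "))
  structure(values, class = c("incidence_matrix", "matrix", "array"))
}

#' Read an incidence matrix from CSV
#'
#' The file must be comma-separated UTF-8 with a header row of species
#' labels and the region label in the first column. Cells are 0/1.
#' Species on the exclusion list are dropped before validation; regions
#' left with zero species after exclusion are dropped with a warning
#' (dataset-wide cleanups such as removing synanthropic species can
#' legitimately empty a region).
#'
#' @param path path to a CSV file.
#' @param exclusions character vector of species labels to drop.
#' @return an [incidence_matrix()].
#' @export
read_incidence <- function(path, exclusions = character()) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("incidence file needs a region column plus species columns")
  regions <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric incidence cells in ", path)
  rownames(m) <- regions
  apply_exclusions(m, exclusions)
}

# Shared by read_incidence and the simulator: drop excluded species
# columns, then drop any region emptied by the exclusion (warning).
apply_exclusions <- function(m, exclusions = character()) {
  if (length(exclusions)) {
    keep <- !(colnames(m) %in% exclusions)
    m <- m[, keep, drop = FALSE]
    if (ncol(m) == 0) stop("all species excluded")
  }
  empty <- rowSums(m) == 0
  if (any(empty)) {
    warning("dropping region(s) with no remaining species: ",
            paste(rownames(m)[empty], collapse = ", "))
    m <- m[!empty, , drop = FALSE]
  }
  incidence_matrix(m)
}

#' Write an incidence matrix to CSV
#'
#' @param inc an [incidence_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_incidence <- function(inc, path) {
  df <- data.frame(region = rownames(inc), unclass(inc), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.incidence_matrix <- function(x, ...) {
  cat(sprintf("incidence_matrix: %d regions x %d species, %d occurrences\n",
              nrow(x), ncol(x), sum(x)))
  invisible(x)
}
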
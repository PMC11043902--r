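#' Write / read pipeline results as structured JSON
#'
#' Results (alpha tables, fits, truth records, ...) are written as
#' type-annotated JSON via [jsonlite::serializeJSON()], which preserves
#' R types, attributes and full double precision, so
#' `read_results(write_results(x))` returns an object equal to `x`.
#'
#' @param result any pipeline result (list, data.frame, fit object).
#' @param path output file path.
#' @return `write_results` returns `path` invisibly; `read_results`
#'   returns the restored object.
#' @export
write_results <- function(result, path) {
  check <- function(x, where) {
    if (is.environment(x) || is.function(x) ||
        typeof(x) %in% c("externalptr", "S4"))
      stop("unserializable result field at ", where, " (", typeof(x), ")")
    if (is.list(x)) {
      nm <- if (is.null(names(x))) seq_along(x) else names(x)
      for (k in seq_along(x)) check(x[[k]], paste(where, nm[k], sep = "$"))
    }
  }
  check(result, "result")
  json <- tryCatch(jsonlite::serializeJSON(result, digits = NA, pretty = TRUE),
                   error = function(e)
                     stop("unserializable result: ", conditionMessage(e)))
  writeLines(json, path)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  jsonlite::unserializeJSON(paste(readLines(path), collapse = "\n"))
}

#' Pipeline run configuration
#'
#' Collects the settings every stage needs: species exclusions, the
#' seed recorded in all result artifacts, GDM settings, the regularity
#' metric handed to the PGLS stage and the Moran's I weighting scheme.
#'
#' @param exclusions species labels dropped on ingest.
#' @param seed integer seed used by all stochastic stages.
#' @param n_splines I-splines per GDM predictor (fixed at 3).
#' @param n_perm GDM importance permutations (>= 50).
#' @param regularity_metric alpha regularity variable used by PGLS:
#'   `"evenness"` (bounded, higher = more regular; default) or
#'   `"variance"` (raw branch-length variance).
#' @param moran_weights Moran's I weighting scheme (see [morans_i()]).
#' @return a list of class `run_config`.
#' @export
run_config <- function(exclusions = character(), seed = 1,
                       n_splines = 3, n_perm = 100,
                       regularity_metric = c("evenness", "variance"),
                       moran_weights = c("inverse_distance", "knn")) {
  if (seed <= 0 || n_splines <= 0 || n_perm <= 0)
    stop("numeric settings must be positive")
  structure(list(exclusions = exclusions, seed = as.integer(seed),
                 n_splines = n_splines, n_perm = n_perm,
                 regularity_metric = match.arg(regularity_metric),
                 moran_weights = match.arg(moran_weights)),
            class = "run_config")
}
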
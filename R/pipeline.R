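#' Run the full alpha + beta inference pipeline on one realm
#'
#' Chains every stage of the analysis exactly as it would be run on a
#' real realm dataset:
#' \enumerate{
#' \item prepare flea and host traits, build Gower distances and
#'   neighbour-joining functional trees;
#' \item compute the three alpha components per region for both taxa;
#' \item build environmental PC1 composites;
#' \item build the region pseudo-phylogeny from combined species
#'   composition and its Brownian-motion covariance;
#' \item for each flea alpha component, run forward-stepwise PGLS on
#'   the matching host component plus the three composites, with a
#'   Moran's I residual test;
#' \item compute flea and host branch-based functional dissimilarity
#'   and great-circle distances;
#' \item fit the GDM of flea functional dissimilarity on host
#'   functional dissimilarity, the composites and geographic distance,
#'   and the permutation importance table.
#' }
#'
#' @param realm a [simulate_realm()] result (or a list with the same
#'   fields read from files).
#' @param config a [run_config()].
#' @return list of class `realm_analysis` with elements `alpha`
#'   (flea/host tables), `env` ([env_composites()]), `region_tree`,
#'   `pgls` (one entry per flea component: fit + Moran's I), `beta`
#'   (flea/host/geo matrices), `gdm` ([gdm_fit()]) and `importance`
#'   ([var_importance()]).
#' @export
run_realm_analysis <- function(realm, config = run_config()) {
  ftree <- nj_build(gower_distance(prepare_traits(realm$flea_traits)))
  htree <- nj_build(gower_distance(prepare_traits(realm$host_traits)))
  falpha <- alpha_components(ftree, realm$flea_incidence)
  halpha <- alpha_components(htree, realm$host_incidence)
  envc <- env_composites(realm$env, realm$env_categories)

  rtree <- region_pseudotree(realm$flea_incidence, realm$host_incidence)
  C <- bm_covariance(rtree)
  regions <- rownames(realm$flea_incidence)
  C <- C[regions, regions]

  reg_metric <- config$regularity_metric
  comp_map <- c(richness = "richness", divergence = "divergence",
                regularity = if (reg_metric == "evenness") "evenness" else "variance")
  keep <- !falpha$singleton & !halpha$singleton
  if (any(!keep))
    message("run_realm_analysis: excluding singleton region(s) from PGLS: ",
            paste(falpha$region[!keep], collapse = ", "))
  pgls <- lapply(names(comp_map), function(comp) {
    col <- comp_map[[comp]]
    y <- falpha[[col]][keep]
    cand <- cbind(host = halpha[[col]][keep],
                  envc$scores[regions, , drop = FALSE][keep, , drop = FALSE])
    fit <- phylostep_forward(y, cand, C[keep, keep])
    moran <- morans_i(fit$residuals, realm$coords[regions, ][keep, ],
                      weights = config$moran_weights)
    list(component = comp, fit = fit, moran = moran)
  })
  names(pgls) <- names(comp_map)

  fbeta <- functional_dissimilarity(ftree, realm$flea_incidence)
  hbeta <- functional_dissimilarity(htree, realm$host_incidence)
  geo <- great_circle(realm$coords[regions, ])
  pairs <- build_site_pairs(fbeta,
                            scalar_predictors = envc$scores[regions, , drop = FALSE],
                            matrix_predictors = list(host_fd = hbeta,
                                                     geo_dist = geo))
  fit <- gdm_fit(pairs)
  imp <- var_importance(pairs, fit, n_perm = config$n_perm,
                        seed = config$seed)

  structure(list(alpha = list(flea = falpha, host = halpha),
                 env = envc, region_tree = rtree,
                 functional_trees = list(flea = ftree, host = htree),
                 pgls = pgls,
                 beta = list(flea = fbeta, host = hbeta, geo = geo),
                 gdm = fit, importance = imp, config = config),
            class = "realm_analysis")
}

#' @export
print.realm_analysis <- function(x, ...) {
  cat("realm_analysis\n")
  for (comp in names(x$pgls)) {
    f <- x$pgls[[comp]]
    cat(sprintf("  PGLS %-11s selected: %s (AIC %.2f, Moran p = %.3f)\n",
                comp,
                if (length(f$fit$selected)) paste(f$fit$selected, collapse = ", ")
                else "(intercept only)",
                f$fit$AIC, f$moran$p))
  }
  cat(sprintf("  GDM: %.1f%% deviance explained; importance ranking: %s\n",
              x$gdm$deviance_explained,
              paste(x$importance$table$predictor[
                order(-x$importance$table$importance)], collapse = " > ")))
  invisible(x)
}
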
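#' Simulate a biogeographic realm with known flea-host coupling
#'
#' Generates a realm-like dataset — region coordinates, environmental
#' variables, host and flea incidence matrices and mixed-type trait
#' tables — with a tunable, known ground-truth coupling between host
#' and flea functional structure, so that every downstream stage of the
#' pipeline has a recovery test.
#'
#' The generative model:
#' \itemize{
#' \item Regions sit on a jittered grid spanning 20 degrees of latitude
#'   by 40 degrees of longitude. Three latent environmental gradients
#'   (vegetation, temperature, precipitation) are linear in the
#'   standardized coordinates; each is observed through 2 noisy raw
#'   variables, so the PC1-composite stage is nontrivial.
#' \item Hosts carry 3 continuous traits (ln body mass, relative brain
#'   mass, ln geographic range — the ln-flagged ones generated
#'   log-normally), 1 ordinal and 2 nominal traits. Host occupancy is
#'   logistic in the latent gradients with host-specific niche
#'   coefficients and no intercept, so expected regional host richness
#'   is flat across the gradient.
#' \item Each flea gets a preferred host-trait profile (a random host's
#'   continuous-trait vector, jittered). Compatibility is a threshold
#'   on Euclidean distance in standardized host-trait space; the
#'   threshold is the global 25% quantile of all flea-host distances,
#'   so the mean host range per flea is about a quarter of the host
#'   pool. Fleas with no host under the threshold get their nearest
#'   host.
#' \item Flea traits mix the compatible-host mean profile with
#'   independent noise at weight `theta_match`: continuous traits
#'   lat_span and host_phylo_div are theta-mixed host-trait means,
#'   body-size and ctenidia ranks discretize theta-mixed latents,
#'   microhabitat follows the majority host nest location with
#'   probability `theta_match`, and n_hosts is the compatible-host
#'   count.
#' \item Flea occupancy requires at least one compatible host in the
#'   region, then draws presence with probability
#'   `((1 - theta_match)/2 + theta_match * availability) * filter`,
#'   where availability is the fraction of the flea's compatible hosts
#'   present and the environmental filter is
#'   `exp(-theta_env * (temperature gradient - optimum)^2)` with
#'   flea-specific optima. At `theta_match = 0` flea occupancy is
#'   independent of host composition; as it grows, flea composition
#'   tracks host composition.
#' }
#' Realizations with empty regions or globally absent species are
#' redrawn up to `max_retry` times (the retry count is recorded in the
#' truth record); persistent failure is an error.
#'
#' @param n_regions,n_hosts,n_fleas counts (>= 2); defaults emulate a
#'   mid-sized realm (30 regions, 50 hosts, 40 fleas).
#' @param theta_match host-flea coupling strength in [0, 1].
#' @param theta_env environmental-filtering strength >= 0.
#' @param seed integer seed; the realm is a deterministic function of
#'   the arguments.
#' @param max_retry maximum occupancy redraws (default 100).
#' @return an object of class `synthetic_realm`: list with
#'   `host_incidence`, `flea_incidence` ([incidence_matrix()]),
#'   `host_traits`, `flea_traits` ([trait_table()]), `env` (region x 6
#'   raw variables), `env_categories` (variable -> category map),
#'   `coords` (region lat/lon) and `truth` (generator parameters).
#' @export
simulate_realm <- function(n_regions = 30, n_hosts = 50, n_fleas = 40,
                           theta_match = 0.7, theta_env = 0.25, seed = 1,
                           max_retry = 100) {
  if (n_regions < 2 || n_hosts < 2 || n_fleas < 2)
    stop("counts must be at least 2")
  if (theta_match < 0 || theta_match > 1) stop("theta_match must be in [0, 1]")
  if (theta_env < 0) stop("theta_env must be non-negative")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)

  regions <- sprintf("R%02d", seq_len(n_regions))
  hosts <- sprintf("host_%02d", seq_len(n_hosts))
  fleas <- sprintf("flea_%02d", seq_len(n_fleas))

  ## --- coordinates: jittered grid over 20 x 40 degrees
  nc <- ceiling(sqrt(2 * n_regions)); nr <- ceiling(n_regions / nc)
  grid <- expand.grid(row = seq_len(nr), col = seq_len(nc))[seq_len(n_regions), ]
  lat <- 10 + (grid$row - 0.5) / nr * 20 + stats::runif(n_regions, -1, 1)
  lon <- -20 + (grid$col - 0.5) / nc * 40 + stats::runif(n_regions, -1, 1)
  coords <- data.frame(lat = lat, lon = lon, row.names = regions)

  ## --- latent environmental gradients (linear in standardized coords)
  latz <- as.numeric(scale(lat)); lonz <- as.numeric(scale(lon))
  grad_coef <- rbind(vegetation   = c(lat = 0.6,  lon =  0.8),
                     temperature  = c(lat = -1.0, lon =  0.1),
                     precipitation = c(lat = 0.3, lon = -0.9))
  latent <- cbind(latz, lonz) %*% t(grad_coef)
  colnames(latent) <- rownames(grad_coef)
  env <- data.frame(
    ndvi_wet = latent[, "vegetation"] + stats::rnorm(n_regions, 0, 0.5),
    ndvi_dry = latent[, "vegetation"] + stats::rnorm(n_regions, 0, 0.5),
    temp_mean = 15 + 8 * latent[, "temperature"] + stats::rnorm(n_regions, 0, 2),
    temp_max = 25 + 8 * latent[, "temperature"] + stats::rnorm(n_regions, 0, 2),
    prec_summer = 400 + 150 * latent[, "precipitation"] +
      stats::rnorm(n_regions, 0, 60),
    prec_winter = 150 + 80 * latent[, "precipitation"] +
      stats::rnorm(n_regions, 0, 40),
    row.names = regions)
  env_categories <- c(ndvi_wet = "vegetation", ndvi_dry = "vegetation",
                      temp_mean = "temperature", temp_max = "temperature",
                      prec_summer = "precipitation", prec_winter = "precipitation")

  ## --- host traits
  ln_mass <- stats::rnorm(n_hosts, 3.5, 1.2)     # ln grams
  brain <- stats::rnorm(n_hosts, 0, 1)           # relative brain mass (scaled)
  ln_range <- stats::rnorm(n_hosts, 12, 1.5)     # ln km^2
  host_traits <- trait_table(
    data.frame(
      body_mass = exp(ln_mass),
      brain_mass = brain,
      range_size = exp(ln_range),
      social_group = sample(c("small", "medium", "large"), n_hosts, TRUE),
      nest_location = sample(c("above", "below", "ground"), n_hosts, TRUE),
      diel_activity = sample(c("diurnal", "nocturnal", "cathemeral"),
                             n_hosts, TRUE)),
    schema = data.frame(
      trait = c("body_mass", "brain_mass", "range_size", "social_group",
                "nest_location", "diel_activity"),
      kind = c("continuous", "continuous", "continuous", "ordinal",
               "nominal", "nominal"),
      ln_transform = c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE),
      levels = c(NA, NA, NA, "small,medium,large", NA, NA)),
    species_ids = hosts)

  ## --- host niches and flea compatibility
  H <- scale(cbind(ln_mass, brain, ln_range))    # standardized trait space
  # Host niches are trait-structured (environmental filtering acts on
  # traits): niche coefficients are linear maps of the host trait
  # vector plus idiosyncratic noise, over both the observed gradients
  # and two hidden (unmeasured) spatial factors. The hidden channel is
  # weighted more heavily, so host composition carries strong
  # functional structure beyond the observed environment; the logit
  # scale of 2 makes presence close to deterministic given the niche.
  hidden <- matrix(stats::rnorm(n_regions * 2), n_regions, 2)
  D <- matrix(stats::rnorm(2 * 3, 0, 1), 2, 3)   # traits -> hidden-factor niche
  u <- matrix(stats::rnorm(n_hosts * 3, 0, 0.5), n_hosts, 3)
  w <- 1.2 * H %*% t(D) + matrix(stats::rnorm(n_hosts * 2, 0, 0.3), n_hosts, 2)
  host_logit <- 2 * (u %*% t(latent) + w %*% t(hidden))  # hosts x regions
  host_prob <- stats::plogis(host_logit)

  pref <- H[sample.int(n_hosts, n_fleas, replace = TRUE), , drop = FALSE] +
    matrix(stats::rnorm(n_fleas * 3, 0, 0.5), n_fleas, 3)
  dist_fh <- sqrt(pmax(outer(rowSums(pref^2), rowSums(H^2), "+") -
                       2 * pref %*% t(H), 0))
  thr <- stats::quantile(dist_fh, 0.25, names = FALSE)
  compat <- dist_fh <= thr
  for (f in which(rowSums(compat) == 0))
    compat[f, which.min(dist_fh[f, ])] <- TRUE
  dimnames(compat) <- list(fleas, hosts)

  ## --- flea traits (theta-mixed with compatible-host means)
  mix <- function(host_col) {
    m <- as.numeric(compat %*% host_col / rowSums(compat))
    theta_match * m + (1 - theta_match) *
      stats::rnorm(n_fleas, mean(host_col), stats::sd(host_col))
  }
  lat_span <- mix(ln_range)
  host_pd <- mix(brain)
  size_latent <- mix(ln_mass)
  cten_latent <- -size_latent + stats::rnorm(n_fleas, 0, 0.3)
  tercile <- function(x, labels) labels[
    findInterval(x, stats::quantile(x, c(1, 2) / 3, names = FALSE),
                 left.open = TRUE) + 1]
  nest_major <- apply(compat, 1, function(cc) {
    tab <- table(host_traits$data$nest_location[cc])
    names(tab)[which.max(tab)]
  })
  habitat_map <- c(above = "hair", below = "burrow", ground = "none")
  micro <- ifelse(stats::runif(n_fleas) < theta_match,
                  habitat_map[nest_major],
                  sample(c("hair", "burrow", "none"), n_fleas, TRUE))
  flea_traits <- trait_table(
    data.frame(
      ctenidia = tercile(cten_latent, c("none", "pronotal", "both")),
      body_size = tercile(size_latent, c("small", "medium", "large")),
      n_hosts = rowSums(compat),
      host_phylo_div = host_pd,
      lat_span = lat_span,
      microhabitat = unname(micro)),
    schema = data.frame(
      trait = c("ctenidia", "body_size", "n_hosts", "host_phylo_div",
                "lat_span", "microhabitat"),
      kind = c("ordinal", "ordinal", "continuous", "continuous",
               "continuous", "nominal"),
      ln_transform = FALSE,
      levels = c("none,pronotal,both", "small,medium,large", NA, NA, NA, NA)),
    species_ids = fleas)

  ## --- flea environmental filter (temperature axis)
  temp_lat <- latent[, "temperature"]
  opt <- stats::runif(n_fleas, min(temp_lat), max(temp_lat))
  filter_prob <- exp(-theta_env * outer(opt, temp_lat, "-")^2)  # fleas x regions

  ## --- occupancy draws (redrawn until all invariants hold)
  retries <- 0
  repeat {
    host_occ <- matrix(stats::rbinom(n_hosts * n_regions, 1, host_prob),
                       n_hosts, n_regions, dimnames = list(hosts, regions))
    avail <- (compat %*% host_occ) / rowSums(compat)      # fleas x regions
    any_compat <- (compat %*% host_occ) > 0
    # sharpened availability response: fleas concentrate in regions where
    # an above-average share of their compatible hosts is present
    track <- stats::plogis(12 * (avail - rowMeans(avail)))
    pres_prob <- ((1 - theta_match) * 0.5 + theta_match * track) * filter_prob
    flea_occ <- matrix(stats::rbinom(n_fleas * n_regions, 1,
                                     pres_prob * any_compat),
                       n_fleas, n_regions, dimnames = list(fleas, regions))
    ok <- all(colSums(host_occ) > 0) && all(rowSums(host_occ) > 0) &&
          all(colSums(flea_occ) > 0) && all(rowSums(flea_occ) > 0)
    if (ok) break
    retries <- retries + 1
    if (retries > max_retry)
      stop("could not realize a realm with non-empty regions after ",
           max_retry, " redraws (theta_env too strong?)")
  }
  if (retries > 0)
    message(sprintf("simulate_realm: %d occupancy redraw(s)", retries))

  truth <- list(
    theta_match = theta_match, theta_env = theta_env, seed = seed,
    n_regions = n_regions, n_hosts = n_hosts, n_fleas = n_fleas,
    gradients = grad_coef,
    env_filter_coefficients = rep(theta_env, n_fleas),
    env_optima = opt,
    compatibility = compat,
    expected_host_richness = colSums(host_prob),
    retries = retries)

  structure(list(host_incidence = incidence_matrix(t(host_occ)),
                 flea_incidence = incidence_matrix(t(flea_occ)),
                 host_traits = host_traits, flea_traits = flea_traits,
                 env = env, env_categories = env_categories,
                 coords = coords, truth = truth),
            class = "synthetic_realm")
}

#' Ground-truth parameter record of a synthetic realm
#'
#' Returns the generator parameters that recovery tests compare
#' against: the coupling and filtering strengths, the environmental
#' gradient coefficients, the per-flea environmental filter
#' coefficients (all zero when `theta_env = 0`) and the expected host
#' richness per region.
#'
#' @param realm a [simulate_realm()] result.
#' @return named list of ground-truth parameters.
#' @export
truth_report <- function(realm) {
  stopifnot(inherits(realm, "synthetic_realm"))
  t <- realm$truth
  list(theta_match = t$theta_match, theta_env = t$theta_env, seed = t$seed,
       n_regions = t$n_regions, n_hosts = t$n_hosts, n_fleas = t$n_fleas,
       gradients = t$gradients,
       env_filter_coefficients = t$env_filter_coefficients,
       expected_host_richness = t$expected_host_richness,
       retries = t$retries)
}

#' @export
print.synthetic_realm <- function(x, ...) {
  cat(sprintf(paste0("synthetic_realm: %d regions, %d hosts, %d fleas ",
                     "(theta_match = %.2f, theta_env = %.2f, seed = %d)\n"),
              x$truth$n_regions, x$truth$n_hosts, x$truth$n_fleas,
              x$truth$theta_match, x$truth$theta_env, x$truth$seed))
  invisible(x)
}

#' Write a synthetic realm to a directory of CSV files
#'
#' Writes the full bundle: flea/host incidence, flea/host traits and
#' schemas, environmental variables, category map, coordinates, and the
#' truth record as JSON.
#'
#' @param realm a [simulate_realm()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_realm <- function(realm, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_incidence(realm$flea_incidence, p("flea_incidence.csv"))
  write_incidence(realm$host_incidence, p("host_incidence.csv"))
  write_traits(realm$flea_traits, p("flea_traits.csv"), p("flea_schema.csv"))
  write_traits(realm$host_traits, p("host_traits.csv"), p("host_schema.csv"))
  utils::write.csv(data.frame(region = rownames(realm$env), realm$env),
                   p("env.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(variable = names(realm$env_categories),
                              category = unname(realm$env_categories)),
                   p("env_categories.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(region = rownames(realm$coords), realm$coords),
                   p("coords.csv"), row.names = FALSE, quote = FALSE)
  write_results(truth_report(realm), p("truth.json"))
  invisible(dir)
}
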
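# Synthetic-data generator. Emulates the study's three data streams — a
# small riverside parkland, confidence-weighted ground/thermal survey
# records, and an expert-elicitation panel — with the statistical structure
# the downstream models assume, so the whole pipeline is testable without
# external data and parameter recovery can be checked against known truth.

# Derive a channel seed from the single global seed, so each generation
# channel (geometry, landscape, surveys, experts, ...) draws from its own
# reproducible stream and can be regenerated independently.
derive_seed <- function(seed, channel) {
  h <- sum(utf8ToInt(channel) * seq_along(utf8ToInt(channel)))
  as.integer((as.numeric(seed) * 48271 + h * 7919) %% (2^31 - 1))
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

#' Simulation truth parameters
#'
#' Houses the data-generating parameters for the synthetic study: the
#' occupancy coefficients on the logit scale (intercept plus the six
#' standardized covariates), the habitat-suitability coefficients driving
#' the expert panel, the expert-to-expert random-intercept SD, the Beta
#' precision of elicited probabilities, and the observer-bias rate coupling
#' ground-detection probability to distance from the nearest path.
#'
#' Defaults encode a landscape where presence increases with foliage cover
#' and remnant Eucalyptus and decreases with distance to fresh water — the
#' habitat structure the study area exhibits — with experts who are
#' informative about the same gradients.
#'
#' @param beta_true Named occupancy coefficients (logit scale) for
#'   `(Intercept)` plus [sdm_covariates()], applied to covariates
#'   standardized within the generated landscape.
#' @param beta_suit_true Suitability coefficients, same layout.
#' @param sigma_expert SD of expert random intercepts (>= 0).
#' @param phi Beta precision of elicited probabilities (> 0).
#' @param observer_bias Logit decline in ground-detection probability per
#'   metre of distance-to-path (>= 0); 0 removes observer bias.
#' @param ground_detect0 Ground-detection probability at a site on a path.
#' @param thermal_detect Thermal-imagery detection probability (bias-free).
#' @param seed Integer seed recorded alongside the parameters.
#' @return An object of class `sdm_truth` (a list of the above).
#' @export
sdm_truth <- function(beta_true = c(
                        "(Intercept)" = -0.2, longitude = 0.3, latitude = 0.4,
                        fpc = 0.7, rev = 0.5, dist_path = 0.2,
                        dist_water = -0.9
                      ),
                      beta_suit_true = c(
                        "(Intercept)" = 0.2, longitude = 0.2, latitude = 0.3,
                        fpc = 0.8, rev = 0.6, dist_path = 0.1,
                        dist_water = -0.8
                      ),
                      sigma_expert = 0.5,
                      phi = 30,
                      observer_bias = 0.012,
                      ground_detect0 = 0.55,
                      thermal_detect = 0.42,
                      seed = 1L) {
  stopifnot(phi > 0, sigma_expert >= 0, observer_bias >= 0)
  p <- length(c("(Intercept)", sdm_covariates()))
  stopifnot(length(beta_true) == p, length(beta_suit_true) == p)
  names(beta_true) <- names(beta_suit_true) <- c("(Intercept)", sdm_covariates())
  structure(
    list(
      beta_true = beta_true, beta_suit_true = beta_suit_true,
      sigma_expert = sigma_expert, phi = phi,
      observer_bias = observer_bias, ground_detect0 = ground_detect0,
      thermal_detect = thermal_detect, seed = as.integer(seed)
    ),
    class = "sdm_truth"
  )
}

#' @export
print.sdm_truth <- function(x, ...) {
  cat("Simulation truth (seed", x$seed, ")\n")
  cat("occupancy coefficients:\n")
  print(round(x$beta_true, 3))
  cat("suitability coefficients:\n")
  print(round(x$beta_suit_true, 3))
  cat(sprintf(
    "sigma_expert = %.3g, phi = %.3g, observer_bias = %.3g /m\n",
    x$sigma_expert, x$phi, x$observer_bias
  ))
  invisible(x)
}

#' Synthetic park geometry
#'
#' A roughly triangular parkland of about 0.2 km^2 bounded on its long edge
#' by a river, with a small generated network of walking paths. The river is
#' the polygon edge joining the second and third vertices; paths are three
#' polylines from the landward edges toward the interior, generated from the
#' seed's geometry channel.
#'
#' @param seed Global simulation seed.
#' @param region Polygon (two-column matrix of vertices, metres). The river
#'   is the polyline from the second vertex through the last, so it bends
#'   wherever the polygon does; the first edge(s) are the landward boundary.
#'   The default is a bent triangle of about 0.21 km^2.
#' @return List with elements `region` (polygon matrix), `river` and `paths`
#'   (feature lists for [distance_to_features()]).
#' @export
park_geometry <- function(seed = 1L,
                          region = rbind(
                            c(0, 0), c(540, 0), c(300, 260), c(420, 430),
                            c(0, 580)
                          )) {
  region <- as.matrix(region)
  if (nrow(region) < 3L || polygon_area(region) <= 0) {
    stop("degenerate region polygon", call. = FALSE)
  }
  river <- list(region[2:nrow(region), , drop = FALSE])
  paths <- with_seed(derive_seed(seed, "geometry"), {
    lapply(1:3, function(i) {
      # a path from the landward (western/southern) boundary bending inward
      start <- if (i %% 2L == 0L) {
        c(0, stats::runif(1, 0.1, 0.9) * max(region[, 2L]))
      } else {
        c(stats::runif(1, 0.1, 0.9) * max(region[, 1L]), 0)
      }
      mid <- colMeans(region) * stats::runif(1, 0.6, 1.1)
      end <- colMeans(region) * stats::runif(1, 0.2, 0.5) +
        start * stats::runif(1, 0.2, 0.4)
      rbind(start, mid, end)
    })
  })
  list(region = region, river = river, paths = paths)
}

# Uniform points inside a polygon by rejection from the bounding box.
runif_in_polygon <- function(n, poly) {
  out <- matrix(numeric(0), 0L, 2L)
  lo <- apply(poly, 2L, min)
  hi <- apply(poly, 2L, max)
  while (nrow(out) < n) {
    m <- max(2L * (n - nrow(out)), 32L)
    cand <- cbind(stats::runif(m, lo[1L], hi[1L]), stats::runif(m, lo[2L], hi[2L]))
    out <- rbind(out, cand[points_in_polygon(cand, poly), , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

# Derive the six habitat covariates at planar positions. FPC follows a
# logistic gradient rising toward the river (denser vegetation near fresh
# water); remnant Eucalyptus is more likely where FPC is high. Positions are
# also reported as geographic degrees about a nominal origin so that the
# longitude/latitude covariates look like the real tables (an affine map, so
# standardized values are unaffected).
covariates_at <- function(xy, geom, fpc_noise_sd = 0.8) {
  d_water <- distance_to_features(xy, geom$river)
  d_path <- distance_to_features(xy, geom$paths)
  eta_fpc <- 1.2 - 0.012 * d_water + stats::rnorm(nrow(xy), 0, fpc_noise_sd)
  fpc <- 100 * stats::plogis(eta_fpc)
  rev <- stats::rbinom(nrow(xy), 1L, stats::plogis(-1.5 + 0.05 * fpc))
  # field-style ordinal vegetation structure (1 = tallest / densest class),
  # used only for elicitation design, never as a model covariate
  fpc_noisy <- fpc + stats::rnorm(nrow(xy), 0, 5)
  veg_height <- 6L - as.integer(cut(fpc_noisy, c(-Inf, 15, 35, 55, 75, Inf)))
  veg_density <- 5L - as.integer(cut(fpc_noisy, c(-Inf, 10, 30, 70, Inf)))
  origin <- c(lon = 153.19, lat = -27.69)
  data.frame(
    longitude = origin["lon"] + xy[, 1L] / (111320 * cos(origin["lat"] * pi / 180)),
    latitude = origin["lat"] + xy[, 2L] / 110540,
    fpc = fpc, rev = rev, dist_path = d_path, dist_water = d_water,
    veg_height = veg_height, veg_density = veg_density,
    x = xy[, 1L], y = xy[, 2L], row.names = NULL
  )
}

#' Generate a synthetic landscape of survey sites
#'
#' Sites are placed uniformly in the park polygon; distance-to-water is the
#' distance to the river edge, distance-to-path the distance to the
#' generated path network; foliage projective cover follows a spatial
#' gradient increasing toward the river, and the remnant-Eucalyptus
#' indicator is sampled with probability increasing in FPC.
#'
#' @param n_sites Number of sites (>= 0).
#' @param seed Global simulation seed (the landscape channel is derived from
#'   it).
#' @param geom Park geometry from [park_geometry()].
#' @return Covariate data frame: `site_id`, the [sdm_covariates()] columns,
#'   and planar `x`, `y` (metres).
#' @export
generate_landscape <- function(n_sites, seed = 1L, geom = park_geometry(seed)) {
  stopifnot(n_sites >= 0)
  if (n_sites == 0L) {
    out <- covariates_at(matrix(numeric(0), 0L, 2L), geom)
    return(cbind(site_id = character(0), out))
  }
  with_seed(derive_seed(seed, "landscape"), {
    xy <- runif_in_polygon(n_sites, geom$region)
    cov <- covariates_at(xy, geom)
    cbind(site_id = sprintf("S%04d", seq_len(n_sites)), cov)
  })
}

# Linear predictor of the occupancy (or suitability) process: coefficients
# apply to covariates standardized within the supplied reference scaling.
truth_linpred <- function(cov, beta, ref) {
  z <- standardize(cov, ref)
  drop(sdm_design_matrix(z) %*% beta)
}

#' Simulate ground and thermal survey observations
#'
#' True occupancy is Bernoulli on the logit-linear occupancy process. The
#' ground channel detects occupied sites with probability declining in
#' distance-to-path (observer bias), recorded at weight 1.00; the thermal
#' channel detects occupied sites with a higher, bias-free probability, each
#' detection assigned one of the three confidence classes (weights 1.00 /
#' 0.90 / 0.50) by the class mixture. Sites detected by both channels are
#' recorded as ground sightings. Absences are drawn at random from sites
#' with no detection, carry weight 0.90 (false negatives are possible), and
#' by default are count-matched to the presences so the output is balanced.
#'
#' @param cov Landscape covariate table from [generate_landscape()].
#' @param truth [sdm_truth()] parameters.
#' @param seed Global simulation seed (survey channel derived from it).
#' @param ref Reference scaling under which `truth$beta_true` applies;
#'   defaults to the scaling of `cov` itself.
#' @param thermal_class_probs Mixture over the thermal confidence classes
#'   (high_confirmed, uncertain_confirmed, uncertain_unconfirmed). The study
#'   does not report this split; the default leans toward confirmed
#'   hotspots.
#' @param balanced If `TRUE` (default) absences are count-matched to
#'   presences; if `FALSE` every undetected site is emitted as an absence.
#' @param absence_weight Weight given to generated absences (default 0.90).
#' @return Observation data frame: `site_id`, `source` ("ground" or
#'   "thermal"; generated absences are tagged "thermal" since full-area
#'   thermal coverage is what certifies them), `y`, `weight`.
#' @export
simulate_surveys <- function(cov, truth, seed = truth$seed,
                             ref = reference_scaling(cov),
                             thermal_class_probs = c(0.35, 0.30, 0.35),
                             balanced = TRUE,
                             absence_weight = assign_weight("absence", "generated")) {
  if (nrow(cov) == 0L) stop("empty landscape", call. = FALSE)
  stopifnot(length(thermal_class_probs) == 3L, all(thermal_class_probs >= 0))
  with_seed(derive_seed(seed, "surveys"), {
    eta <- truth_linpred(cov, truth$beta_true, ref)
    occ <- stats::rbinom(nrow(cov), 1L, stats::plogis(eta))
    p_ground <- stats::plogis(
      stats::qlogis(truth$ground_detect0) - truth$observer_bias * cov$dist_path
    )
    det_g <- occ == 1L & stats::runif(nrow(cov)) < p_ground
    det_t <- occ == 1L & stats::runif(nrow(cov)) < truth$thermal_detect
    detected <- det_g | det_t
    if (!any(occ == 1L)) warning("no occupied sites at the given truth")
    pres_idx <- which(detected)
    source <- ifelse(det_g[pres_idx], "ground", "thermal")
    classes <- c("high_confirmed", "uncertain_confirmed", "uncertain_unconfirmed")
    w <- numeric(length(pres_idx))
    w[source == "ground"] <- assign_weight("ground", "presence")
    n_t <- sum(source == "thermal")
    if (n_t > 0L) {
      cls <- sample(classes, n_t, replace = TRUE, prob = thermal_class_probs)
      w[source == "thermal"] <- assign_weight(rep("thermal", n_t), cls)
    }
    undet <- which(!detected)
    n_abs <- if (balanced) min(length(pres_idx), length(undet)) else length(undet)
    abs_idx <- if (n_abs > 0L) sort(sample(undet, n_abs)) else integer(0)
    out <- data.frame(
      site_id = c(cov$site_id[pres_idx], cov$site_id[abs_idx]),
      source = c(source, rep("thermal", n_abs)),
      y = c(rep(1L, length(pres_idx)), rep(0L, n_abs)),
      weight = c(w, rep(absence_weight, n_abs)),
      stringsAsFactors = FALSE
    )
    out[order(match(out$site_id, cov$site_id)), , drop = FALSE] |>
      `rownames<-`(NULL)
  })
}

#' Simulate an expert-elicitation panel
#'
#' Each expert carries a Gaussian random intercept u_e ~ N(0, sigma^2). For
#' every viewed site the elicited habitat-suitability probability is drawn
#' from a Beta distribution with logit-linear mean mu = plogis(x'beta + u_e)
#' and precision phi. Suitability confidence categories are drawn from a
#' mixture skewed toward "quite sure"/"very sure" (experts judge suitability
#' confidently even when unsure about presence); the presence
#' minimum/mode/maximum triple is generated as ordered perturbations around
#' a presence-process analogue with its own, less confident category mix.
#'
#' @param sites Covariate table of the sites shown to experts.
#' @param truth [sdm_truth()] parameters.
#' @param n_experts Number of experts (>= 1).
#' @param seed Global simulation seed (expert channel derived from it).
#' @param ref Reference scaling under which the truth coefficients apply.
#' @param site_assignment Optional list of length `n_experts` of site_id
#'   vectors: the subset each expert views. Default: all experts view all
#'   `sites`.
#' @param conf_suit Mixture over (not_very_sure, quite_sure, very_sure) for
#'   suitability confidence; default puts 98% of mass on the upper two.
#' @param conf_pres Same for presence confidence; default about 77% on the
#'   upper two.
#' @return Elicitation data frame with the canonical columns (see
#'   [load_elicitations()]).
#' @export
simulate_elicitation <- function(sites, truth, n_experts = 6L,
                                 seed = truth$seed,
                                 ref = reference_scaling(sites),
                                 site_assignment = NULL,
                                 conf_suit = c(0.02, 0.50, 0.48),
                                 conf_pres = c(0.23, 0.40, 0.37)) {
  stopifnot(n_experts >= 1L)
  with_seed(derive_seed(seed, "experts"), {
    u <- stats::rnorm(n_experts, 0, truth$sigma_expert)
    eta_suit <- truth_linpred(sites, truth$beta_suit_true, ref)
    eta_pres <- truth_linpred(sites, truth$beta_true, ref)
    rows <- vector("list", n_experts)
    for (e in seq_len(n_experts)) {
      keep <- if (is.null(site_assignment)) {
        seq_len(nrow(sites))
      } else {
        match(site_assignment[[e]], sites$site_id)
      }
      ns <- length(keep)
      mu_s <- stats::plogis(eta_suit[keep] + u[e])
      p_suit <- stats::rbeta(ns, mu_s * truth$phi, (1 - mu_s) * truth$phi)
      mu_p <- stats::plogis(eta_pres[keep] + u[e])
      p_mode <- stats::rbeta(ns, mu_p * truth$phi, (1 - mu_p) * truth$phi)
      p_min <- p_mode * stats::runif(ns, 0.3, 0.9)
      p_max <- p_mode + (1 - p_mode) * stats::runif(ns, 0.1, 0.7)
      suit_conf <- sample(CONFIDENCE_LEVELS, ns, TRUE, prob = conf_suit)
      pres_conf <- sample(CONFIDENCE_LEVELS, ns, TRUE, prob = conf_pres)
      rows[[e]] <- data.frame(
        expert_id = e, site_id = sites$site_id[keep],
        p_min = p_min, p_mode = p_mode, p_max = p_max,
        presence_confidence = pres_conf,
        p_suitability = p_suit,
        suitability_confidence = suit_conf,
        weight = expert_weight(suit_conf),
        stringsAsFactors = FALSE
      )
    }
    do.call(rbind, rows) |> `rownames<-`(NULL)
  })
}

#' Generate a regular prediction grid over the park
#'
#' Lays a square grid over the region's bounding box, clips it to the
#' polygon, and derives the habitat covariates exactly as
#' [generate_landscape()] does. Grid spacing is chosen so the clipped count
#' comes as close as possible to `n`; if `n` cannot be hit exactly the
#' nearest achievable count is used and reported in a message.
#'
#' @param geom Park geometry from [park_geometry()].
#' @param n Target number of grid sites (default 636, the study's
#'   visualization grid).
#' @param seed Global simulation seed (grid covariate-noise channel).
#' @return Covariate data frame like [generate_landscape()]'s.
#' @export
generate_prediction_grid <- function(geom = park_geometry(), n = 636L,
                                     seed = 1L) {
  stopifnot(n >= 1L)
  poly <- geom$region
  lo <- apply(poly, 2L, min)
  hi <- apply(poly, 2L, max)
  area <- polygon_area(poly)
  grid_at <- function(spacing) {
    gx <- seq(lo[1L] + spacing / 2, hi[1L], by = spacing)
    gy <- seq(lo[2L] + spacing / 2, hi[2L], by = spacing)
    pts <- as.matrix(expand.grid(x = gx, y = gy))
    pts[points_in_polygon(pts, poly), , drop = FALSE]
  }
  s_lo <- sqrt(area / (4 * n)) # finer than needed
  s_hi <- sqrt(4 * area / n) # coarser than needed
  for (i in 1:40) {
    s_mid <- (s_lo + s_hi) / 2
    cnt <- nrow(grid_at(s_mid))
    if (cnt == n) break
    if (cnt > n) s_lo <- s_mid else s_hi <- s_mid
  }
  xy <- grid_at(s_mid)
  if (nrow(xy) != n) {
    message(
      "grid resolution cannot hit n = ", n, " exactly; using ", nrow(xy),
      " sites"
    )
  }
  with_seed(derive_seed(seed, "grid"), {
    cov <- covariates_at(xy, geom)
    cbind(site_id = sprintf("P%04d", seq_len(nrow(xy))), cov)
  })
}

#' Simulate a complete study-mimic dataset
#'
#' Convenience wrapper that generates the park geometry, a landscape of
#' candidate sites, balanced survey observations, an expert panel viewing a
#' clustered ten-image subset of the observed sites, and the prediction
#' grid — the full set of inputs [run_study()] needs — together with the
#' truth parameters used.
#'
#' With the default truth and `n_sites = 150`, expected record counts mimic
#' the study's bookkeeping: roughly 17 ground presences, 24 thermal
#' presences and an equal number of generated absences, and a 6-expert by
#' 10-site panel (n = 60).
#'
#' @param seed Global simulation seed.
#' @param n_sites Number of candidate landscape sites.
#' @param n_experts Number of experts.
#' @param n_images Number of images (site clusters) shown to each expert.
#' @param n_grid Prediction-grid size.
#' @param truth [sdm_truth()] parameters.
#' @return List with `geom`, `landscape`, `observations`, `covariates`
#'   (covariates of observed sites), `elicitations`, `grid`, `truth`.
#' @export
simulate_study <- function(seed = 1L, n_sites = 150L, n_experts = 6L,
                           n_images = 10L, n_grid = 636L,
                           truth = sdm_truth(seed = seed)) {
  geom <- park_geometry(seed)
  landscape <- generate_landscape(n_sites, seed, geom)
  ref_land <- reference_scaling(landscape)
  obs <- simulate_surveys(landscape, truth, seed = seed, ref = ref_land)
  cov <- landscape[match(obs$site_id, landscape$site_id), , drop = FALSE]
  rownames(cov) <- NULL

  # elicitation design: cluster the observed sites on mixed features and
  # give each expert one randomly drawn image per cluster
  feats <- clustering_features(cov, obs)
  gd <- gower_distance(feats)
  labels <- cluster_sites(gd, n_clusters = n_images)
  assignment <- lapply(seq_len(n_experts), function(e) {
    sample_image_subset(labels, seed = derive_seed(seed, paste0("subset", e)))
  })
  elic <- simulate_elicitation(
    cov, truth,
    n_experts = n_experts, seed = seed, ref = ref_land,
    site_assignment = assignment
  )
  grid <- generate_prediction_grid(geom, n = n_grid, seed = seed)
  list(
    geom = geom, landscape = landscape, observations = obs,
    covariates = cov, elicitations = elic, grid = grid, truth = truth
  )
}

#' Write a simulated study to CSV files (plus a truth sidecar)
#'
#' Emits `observations.csv`, `elicitations.csv` and `grid.csv` together with
#' `truth.json` (the generating parameters, for recovery checks).
#'
#' @param study Output of [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_inputs <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_observations(
    study$observations, study$covariates,
    file.path(dir, "observations.csv")
  )
  write_elicitations(study$elicitations, file.path(dir, "elicitations.csv"))
  utils::write.csv(
    study$grid[c("site_id", sdm_covariates())],
    file.path(dir, "grid.csv"),
    row.names = FALSE, quote = FALSE
  )
  truth <- study$truth
  jsonlite::write_json(
    list(
      beta_true = as.list(truth$beta_true),
      beta_suit_true = as.list(truth$beta_suit_true),
      sigma_expert = truth$sigma_expert, phi = truth$phi,
      observer_bias = truth$observer_bias,
      ground_detect0 = truth$ground_detect0,
      thermal_detect = truth$thermal_detect, seed = truth$seed
    ),
    file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
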
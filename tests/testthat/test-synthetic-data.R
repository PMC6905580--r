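# Behaviour of the synthetic-data generator: determinism, the spatial
# structure it promises, detection behaviour, and study-mimic bookkeeping.

test_that("generation is deterministic in the seed and independent across channels", {
  a <- generate_landscape(40, seed = 11)
  b <- generate_landscape(40, seed = 11)
  expect_identical(a, b)
  expect_false(identical(a, generate_landscape(40, seed = 12)))

  truth <- sdm_truth(seed = 11)
  expect_identical(
    simulate_surveys(a, truth, seed = 11),
    simulate_surveys(a, truth, seed = 11)
  )
  expect_identical(
    simulate_elicitation(a[1:10, ], truth, n_experts = 3, seed = 11),
    simulate_elicitation(a[1:10, ], truth, n_experts = 3, seed = 11)
  )
  # n = 0 gives an empty table
  expect_equal(nrow(generate_landscape(0, seed = 1)), 0L)
  expect_error(park_geometry(region = rbind(c(0, 0), c(1, 1), c(2, 2))), "degenerate")
})

test_that("foliage cover declines away from the river across a large landscape", {
  land <- generate_landscape(10000, seed = 21)
  expect_lt(cor(land$fpc, land$dist_water), 0)
  # and remnant vegetation concentrates where cover is high
  expect_gt(mean(land$fpc[land$rev == 1]), mean(land$fpc[land$rev == 0]))
  expect_true(all(land$fpc >= 0 & land$fpc <= 100))
  expect_true(all(land$dist_path >= 0) && all(land$dist_water >= 0))
})

test_that("perfect detection without observer bias reports every site exactly once", {
  land <- generate_landscape(200, seed = 31)
  truth <- sdm_truth(
    seed = 31, observer_bias = 0, ground_detect0 = 1, thermal_detect = 1
  )
  obs <- simulate_surveys(land, truth,
    seed = 31, balanced = FALSE,
    absence_weight = 1
  )
  expect_setequal(obs$site_id, land$site_id)
  expect_equal(anyDuplicated(obs$site_id), 0L)
  # every presence was ground-detected (detection probability 1 on both
  # channels, ground takes precedence)
  expect_true(all(obs$source[obs$y == 1] == "ground"))
})

test_that("default survey output is balanced and mimics the study's channel ratio", {
  counts <- t(sapply(101:130, function(s) {
    land <- generate_landscape(150, seed = s)
    obs <- simulate_surveys(land, sdm_truth(seed = s), seed = s)
    c(
      ground = sum(obs$source == "ground" & obs$y == 1),
      thermal = sum(obs$source == "thermal" & obs$y == 1),
      absent = sum(obs$y == 0),
      presences = sum(obs$y == 1)
    )
  }))
  # balance invariant holds replicate by replicate
  expect_equal(counts[, "presences"], counts[, "absent"])
  m <- colMeans(counts)
  # mean bookkeeping near the study's 17 : 24 : 41
  expect_equal(unname(m["ground"]), 17, tolerance = 0.2)
  expect_equal(unname(m["thermal"]), 24, tolerance = 0.2)
  expect_equal(unname(m["absent"]), 41, tolerance = 0.2)
  # weights drawn only from the study's classes
  land <- generate_landscape(150, seed = 101)
  obs <- simulate_surveys(land, sdm_truth(seed = 101), seed = 101)
  expect_true(all(obs$weight %in% c(0.5, 0.9, 1.0)))
  expect_true(all(obs$weight[obs$y == 0] == 0.9))
})

test_that("ground detection frequency follows the stated observer-bias curve", {
  land <- generate_landscape(60, seed = 41)
  truth <- sdm_truth(seed = 41, thermal_detect = 1) # presences = occupied set
  hits <- matrix(0, 400, nrow(land))
  pres <- matrix(FALSE, 400, nrow(land))
  for (r in seq_len(400)) {
    obs <- simulate_surveys(land, truth, seed = 41000 + r, balanced = FALSE)
    idx <- match(obs$site_id[obs$y == 1], land$site_id)
    pres[r, idx] <- TRUE
    gidx <- match(obs$site_id[obs$y == 1 & obs$source == "ground"], land$site_id)
    hits[r, gidx] <- 1
  }
  n_occ <- colSums(pres)
  freq <- colSums(hits) / pmax(n_occ, 1)
  expected <- plogis(qlogis(truth$ground_detect0) - truth$observer_bias * land$dist_path)
  keep <- n_occ >= 40
  mc_err <- sqrt(expected * (1 - expected) / pmax(n_occ, 1))
  expect_true(all(abs(freq[keep] - expected[keep]) < 4 * mc_err[keep] + 0.02))
  # and the curve really declines with distance to path
  expect_lt(
    mean(freq[keep][land$dist_path[keep] > median(land$dist_path)]),
    mean(freq[keep][land$dist_path[keep] <= median(land$dist_path)])
  )
})

test_that("elicited suitability means match the mixed-model integral (quadrature oracle)", {
  land <- generate_landscape(3, seed = 51)
  truth <- sdm_truth(seed = 51)
  ref <- reference_scaling(generate_landscape(100, seed = 51))
  elic <- simulate_elicitation(land, truth, n_experts = 2000, seed = 51, ref = ref)
  z <- standardize(land, ref)
  eta <- drop(sdmfuse:::sdm_design_matrix(z) %*% truth$beta_suit_true)
  for (i in 1:3) {
    # E[plogis(eta + u)], u ~ N(0, sigma^2), by deterministic quadrature
    want <- integrate(
      function(u) plogis(eta[i] + u) * dnorm(u, 0, truth$sigma_expert),
      -Inf, Inf
    )$value
    got <- mean(elic$p_suitability[elic$site_id == land$site_id[i]])
    expect_equal(got, want, tolerance = 0.025)
  }
  # degenerate noise: sigma = 0 and huge precision pins responses at mu
  truth0 <- sdm_truth(seed = 52, sigma_expert = 0, phi = 5e5)
  elic0 <- simulate_elicitation(land, truth0, n_experts = 4, seed = 52, ref = ref)
  mu0 <- plogis(drop(sdmfuse:::sdm_design_matrix(z) %*% truth0$beta_suit_true))
  expect_equal(elic0$p_suitability, rep(mu0, each = 1)[match(elic0$site_id, land$site_id)],
    tolerance = 5e-3
  )
  # record count: experts x viewed sites
  elic6 <- simulate_elicitation(land[1:2, ], truth, n_experts = 6, seed = 53, ref = ref)
  expect_equal(nrow(elic6), 12L)
  expect_true(all(elic6$p_min <= elic6$p_mode & elic6$p_mode <= elic6$p_max))
  expect_true(all(elic6$weight %in% c(0.5, 0.75, 1.0)))
})

test_that("the prediction grid is clipped, regular, and near the requested size", {
  geom <- park_geometry(61)
  grid <- suppressMessages(generate_prediction_grid(geom, n = 636, seed = 61))
  expect_true(all(sdmfuse:::points_in_polygon(cbind(grid$x, grid$y), geom$region)))
  expect_equal(nrow(grid), 636, tolerance = 0.02)
  # uniform spacing within rows
  sp <- unlist(tapply(grid$x, grid$y, function(x) diff(sort(x))))
  expect_equal(unname(sp), rep(sp[[1]], length(sp)), tolerance = 1e-9)
})

test_that("a simulated study round-trips through its CSV sidecar files", {
  st <- simulate_study(seed = 71, n_sites = 120, n_grid = 60)
  dir <- withr::local_tempdir()
  write_study_inputs(st, dir)
  obs <- load_observations(file.path(dir, "observations.csv"))
  expect_equal(obs$observations$site_id, st$observations$site_id)
  expect_equal(obs$observations$weight, st$observations$weight, tolerance = 1e-12)
  elic <- load_elicitations(file.path(dir, "elicitations.csv"))
  expect_equal(nrow(elic), nrow(st$elicitations))
  expect_equal(elic$p_suitability, st$elicitations$p_suitability, tolerance = 1e-9)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  expect_equal(unlist(truth$beta_true), st$truth$beta_true)
  grid <- load_grid(file.path(dir, "grid.csv"))
  expect_equal(nrow(grid), nrow(st$grid))
})
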
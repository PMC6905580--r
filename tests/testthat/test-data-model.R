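# Weight mapping, reference standardization, distance covariates, CSV I/O.

test_that("weight table covers every source/category pair and hits all four values", {
  tab <- weight_table()
  expect_equal(sort(unique(tab$weight)), c(0.50, 0.75, 0.90, 1.00))
  # total on the enumeration, vectorised
  expect_equal(assign_weight(tab$source, tab$category), tab$weight)
  # printed study values
  expect_identical(assign_weight("ground", "presence"), 1.00)
  expect_identical(assign_weight("thermal", "uncertain_unconfirmed"), 0.50)
  expect_identical(assign_weight("expert", "quite_sure"), 0.75)
  expect_identical(assign_weight("absence", "generated"), 0.90)
  expect_error(assign_weight("ground", "absence"), "valid pairs")
  expect_equal(
    expert_weight(c("not_very_sure", "quite_sure", "very_sure")),
    c(0.50, 0.75, 1.00)
  )
})

test_that("reference scaling matches sample moments and self-standardizes to mean 0 / sd 1", {
  cov <- small_covariates(25, seed = 3)
  ref <- reference_scaling(cov)
  # brute-force oracle per covariate
  for (v in sdm_covariates()) {
    expect_equal(ref$mean[ref$variable == v], mean(cov[[v]]))
    expect_equal(ref$sd[ref$variable == v], sd(cov[[v]]))
  }
  z <- standardize(cov, ref)
  expect_equal(unname(colMeans(as.matrix(z[sdm_covariates()]))),
    rep(0, 6),
    tolerance = 1e-12
  )
  expect_equal(unname(apply(as.matrix(z[sdm_covariates()]), 2, sd)),
    rep(1, 6),
    tolerance = 1e-12
  )
  # forced-by-definition case
  tiny <- reference_scaling(
    data.frame(
      longitude = c(1, 2, 3), latitude = c(1, 2, 3), fpc = c(1, 2, 3),
      rev = c(0, 1, 1), dist_path = c(1, 2, 3), dist_water = c(1, 2, 3)
    )
  )
  expect_equal(tiny$mean[tiny$variable == "fpc"], 2)
  expect_equal(tiny$sd[tiny$variable == "fpc"], 1)
})

test_that("standardization applied to held-out data matches direct arithmetic and inverts", {
  base <- small_covariates(30, seed = 4)
  held <- small_covariates(12, seed = 5)
  ref <- reference_scaling(base)
  z <- standardize(held, ref)
  for (v in sdm_covariates()) {
    m <- mean(base[[v]])
    s <- sd(base[[v]])
    expect_equal(z[[v]], (held[[v]] - m) / s)
  }
  # x at the reference mean maps to 0; mean + sd maps to 1
  at_mean <- base[1, ]
  for (v in sdm_covariates()) at_mean[[v]] <- mean(base[[v]])
  expect_equal(
    unname(unlist(standardize(at_mean, ref)[sdm_covariates()])), rep(0, 6)
  )
  # affine invertibility to 1e-12
  back <- unstandardize(z, ref)
  for (v in sdm_covariates()) {
    expect_equal(back[[v]], held[[v]], tolerance = 1e-12)
  }
  expect_error(
    reference_scaling(transform(base, rev = 1)), "constant"
  )
})

test_that("distance to features reproduces exact cases and a brute-force minimum", {
  seg <- rbind(c(0, 0), c(4, 0))
  # point on the segment, and the 3-4-5 triangle cases
  expect_equal(distance_to_features(rbind(c(2, 0)), seg), 0)
  expect_equal(distance_to_features(rbind(c(4, 3), c(8, 3)), seg), c(3, 5))
  # brute force over 100 random segments
  set.seed(8)
  feats <- lapply(1:100, function(i) matrix(runif(4, -50, 50), 2, 2))
  pts <- matrix(runif(20, -50, 50), 10, 2)
  got <- distance_to_features(pts, feats)
  point_seg <- function(p, a, b) {
    ab <- b - a
    t <- sum((p - a) * ab) / sum(ab^2)
    t <- min(max(t, 0), 1)
    sqrt(sum((p - (a + t * ab))^2))
  }
  want <- apply(pts, 1, function(p) {
    min(vapply(feats, function(f) point_seg(p, f[1, ], f[2, ]), numeric(1)))
  })
  expect_equal(got, want, tolerance = 1e-12)
  expect_error(distance_to_features(pts, list()), "empty")
})

test_that("distance is invariant under rigid rotation and translation", {
  set.seed(9)
  feats <- lapply(1:20, function(i) matrix(runif(4, -10, 10), 2, 2))
  pts <- matrix(runif(10, -10, 10), 5, 2)
  d0 <- distance_to_features(pts, feats)
  theta <- 0.73
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  shift <- c(12.5, -7.25)
  move <- function(m) sweep(m %*% t(R), 2, -shift)
  d1 <- distance_to_features(move(pts), lapply(feats, move))
  expect_equal(d1, d0, tolerance = 1e-9)
})

test_that("observation tables round-trip through CSV and validate on load", {
  cov <- small_covariates(14, seed = 6)
  obs <- small_observations(cov, seed = 6)
  path <- withr::local_tempfile(fileext = ".csv")
  write_observations(obs, cov, path)
  got <- load_observations(path)
  expect_equal(got$observations$site_id, obs$site_id)
  expect_equal(got$observations$y, obs$y)
  expect_equal(got$observations$weight, obs$weight, tolerance = 1e-12)
  expect_equal(got$observations$source, obs$source)
  for (v in sdm_covariates()) {
    expect_equal(got$covariates[[v]], cov[[v]], tolerance = 1e-9)
  }

  # header-only file: empty collections, no error
  writeLines(paste(sdmfuse:::OBS_COLUMNS, collapse = ","), path)
  empty <- load_observations(path)
  expect_equal(nrow(empty$observations), 0L)
  expect_equal(nrow(empty$covariates), 0L)

  # schema error names the missing column
  df <- cbind(cov, obs[-1])
  bad <- df[setdiff(names(df), "fpc")]
  write.csv(bad, path, row.names = FALSE)
  expect_error(load_observations(path), "fpc")

  # out-of-range value reports the row
  df2 <- df
  df2$fpc[3] <- 150
  write.csv(df2, path, row.names = FALSE)
  expect_error(load_observations(path), "row 3")
})

test_that("column mapping lets external headers load unchanged", {
  cov <- small_covariates(6, seed = 7)
  obs <- small_observations(cov, seed = 7)
  df <- merge(cov, obs, by = "site_id", sort = FALSE)
  names(df)[names(df) == "fpc"] <- "FPC"
  names(df)[names(df) == "dist_water"] <- "Water"
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  expect_error(load_observations(path), "fpc")
  got <- load_observations(path, column_mapping(fpc = "FPC", dist_water = "Water"))
  expect_equal(got$covariates$fpc, cov$fpc, tolerance = 1e-9)
  expect_equal(got$covariates$dist_water, cov$dist_water, tolerance = 1e-9)
})

test_that("elicitation tables validate ordering and confidence categories", {
  el <- data.frame(
    expert_id = 1:2, site_id = c("A", "B"),
    p_min = c(0.1, 0.2), p_mode = c(0.3, 0.4), p_max = c(0.5, 0.6),
    presence_confidence = c("quite_sure", "very_sure"),
    p_suitability = c(0.7, 0.8),
    suitability_confidence = c("very_sure", "not_very_sure"),
    weight = c(1.0, 0.5)
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_elicitations(el, path)
  got <- load_elicitations(path)
  expect_equal(got$p_suitability, el$p_suitability)
  # weight derived from confidence when absent
  write.csv(el[setdiff(names(el), "weight")], path, row.names = FALSE)
  got2 <- load_elicitations(path)
  expect_equal(got2$weight, c(1.0, 0.5))
  # ordering violation rejected
  el$p_min[1] <- 0.9
  write.csv(el, path, row.names = FALSE)
  expect_error(load_elicitations(path), "p_min <= p_mode")
})

test_that("GeoJSON features feed the distance computation", {
  path <- withr::local_tempfile(fileext = ".geojson")
  writeLines('{
    "type": "FeatureCollection",
    "features": [
      {"type": "Feature", "properties": {"name": "path"},
       "geometry": {"type": "LineString", "coordinates": [[0,0],[4,0]]}},
      {"type": "Feature", "properties": {"name": "river"},
       "geometry": {"type": "MultiLineString",
                    "coordinates": [[[0,10],[10,10]],[[0,20],[10,20]]]}}
    ]
  }', path)
  feats <- read_features_geojson(path)
  expect_length(feats, 3L)
  expect_equal(distance_to_features(rbind(c(4, 3)), feats[1]), 3)
  expect_equal(distance_to_features(rbind(c(5, 12)), feats), 2)
})
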
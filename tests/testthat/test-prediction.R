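set.seed(404)

test_that("hull mask matches brute-force point-in-polygon on a square", {
  sq <- tibble::tibble(site_id = 1:4,
                       latitude = c(30, 30, 40, 40),
                       longitude = c(-90, -80, -90, -80))
  grid <- tidyr::expand_grid(longitude = seq(-95, -75, by = 0.5),
                             latitude = seq(25, 45, by = 0.5))
  m0 <- buffered_hull_mask(sq, grid, buffer_deg = 0)
  inside_brute <- grid$longitude >= -90 & grid$longitude <= -80 &
    grid$latitude >= 30 & grid$latitude <= 40
  # boundary cells may differ by floating-point orientation; interiors match
  interior <- grid$longitude > -90 & grid$longitude < -80 &
    grid$latitude > 30 & grid$latitude < 40
  expect_true(all(m0[interior]))
  expect_true(all(!m0[!inside_brute]))
  # dilation is monotone and contains the sites' own cells
  m2 <- buffered_hull_mask(sq, grid, buffer_deg = 2)
  expect_true(all(m2[m0]))
  own <- sapply(seq_len(4), function(i) {
    which.min((grid$longitude - sq$longitude[i])^2 +
                (grid$latitude - sq$latitude[i])^2)
  })
  expect_true(all(m2[own]))
  # exact Minkowski dilation: a point 1.9 degrees east of the hull is in,
  # a point 2.1 degrees out is not
  probe <- tibble::tibble(longitude = c(-78.1, -77.9), latitude = c(35, 35))
  expect_equal(buffered_hull_mask(sq, probe, 2), c(TRUE, FALSE))
  expect_error(buffered_hull_mask(sq[1:2, ], grid), "3")
  coll <- tibble::tibble(site_id = 1:3, latitude = c(30, 31, 32),
                         longitude = c(-90, -89, -88))
  expect_error(buffered_hull_mask(coll, grid), "collinear")
})

test_that("index closed forms match hand evaluations", {
  expect_equal(proportion_area_occupied(rep(0.5, 10)), 0.5)
  expect_equal(proportion_area_occupied(c(0.2, 0.6)), 0.4)
  expect_equal(proportion_area_occupied(c(0.6, 0.2)), 0.4)  # order-invariant
  expect_equal(mean_breeding_latitude(c(0.2, 0.6), c(30, 40)), 37.5)
  psi <- runif(20)
  lats <- runif(20, 30, 45)
  mb <- mean_breeding_latitude(psi, lats)
  expect_equal(mean_breeding_latitude(rep(0.3, 20), lats), mean(lats))
  expect_true(mb >= min(lats) && mb <= max(lats))
  expect_error(mean_breeding_latitude(rep(0, 3), c(1, 2, 3)), "zero")
})

test_that("range limits recover a uniform latitude band to 0.1 degree", {
  lats <- rep(seq(30, 40, by = 0.05), each = 3)
  psi <- rep(1, length(lats))
  rl <- range_limits(psi, lats)
  expect_lt(abs(rl["south"] - 30), 0.1)
  expect_lt(abs(rl["north"] - 40), 0.1)
  expect_lt(rl["south"], rl["north"])
  # mass concentrated in two bands: limits bracket them
  lats2 <- c(32, 36)
  rl2 <- range_limits(c(1, 1), lats2)
  expect_gte(rl2["south"], 32 - 1e-6)
  expect_lte(rl2["north"], 36 + 1e-6)
  expect_error(range_limits(c(1, 1), c(35, 35)), "distinct")
})

test_that("PAO decomposes over any partition of the cells", {
  psi <- runif(100)
  part <- sample(rep(1:4, 25))
  pao_parts <- tapply(psi, part, mean)
  n_parts <- tabulate(part)
  expect_equal(proportion_area_occupied(psi),
               sum(pao_parts * n_parts) / sum(n_parts), tolerance = 1e-12)
})

fit_small <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- small_sim()
      cache <<- fit_occupancy(sim$data, sim$truth$basis, gvs_config(),
                              chains = 1, iter = 150, warmup = 100,
                              seed = 5)
    }
    cache
  }
})

test_that("prediction at the training sites reproduces in-sample psi", {
  fit <- fit_small()
  sim <- small_sim()
  grid <- tibble::tibble(cell_id = seq_len(sim$data$N),
                         latitude = sim$data$coords$latitude,
                         longitude = sim$data$coords$longitude)
  covs <- dplyr::bind_rows(lapply(seq_len(sim$data$T), function(t) {
    tibble::tibble(cell_id = grid$cell_id, year = sim$data$years[t],
                   var1 = sim$data$X[, t, 1], var2 = sim$data$X[, t, 2],
                   var3 = sim$data$X[, t, 3], var4 = sim$data$X[, t, 4],
                   var5 = sim$data$X[, t, 5])
  }))
  ids <- c(1, 50, 150)
  psi <- predict_occupancy(fit, grid, covs, draw_ids = ids)
  for (d in seq_along(ids)) {
    pars <- occugam:::params_from_draw(fit, ids[d])
    psi_in <- plogis(occugam:::occ_linpred(pars, sim$data,
                                           sim$truth$basis))
    expect_lt(max(abs(psi[d, , ] - psi_in)), 1e-10)
  }
})

test_that("a null draw predicts psi = 0.5 everywhere", {
  fit <- fit_small()
  dm <- occugam:::draw_matrix(fit)
  # zero out one draw
  fit2 <- fit
  fit2$draws[1, 1, grepl("^nu\\[|^beta\\[|^omega\\[", fit$par_names)] <- 0
  grid <- tibble::tibble(cell_id = 1:5,
                         latitude = seq(33, 41, by = 2),
                         longitude = rep(-85, 5))
  psi <- predict_occupancy(fit2, grid, grid_covariates = NULL,
                           draw_ids = 1)
  expect_true(all(abs(psi[1, , ] - 0.5) < 1e-12))
})

test_that("index series and net change have coherent structure", {
  fit <- fit_small()
  sim <- small_sim()
  grid <- make_prediction_grid(sim$data$coords, cell_deg = 1,
                               buffer_deg = 1)
  covs <- dplyr::bind_rows(lapply(seq_len(sim$data$T), function(t) {
    tibble::tibble(cell_id = grid$cell_id, year = sim$data$years[t],
                   var1 = 0, var2 = 0, var3 = 0, var4 = 0, var5 = 0)
  }))
  psi <- predict_occupancy(fit, grid, covs,
                           draw_ids = seq(1, 150, by = 10))
  # draw-wise ordering of the three latitudinal indices
  lat <- grid$latitude
  for (d in 1:3) for (t in 1:2) {
    m <- psi[d, , t]
    rl <- range_limits(m, lat)
    mb <- mean_breeding_latitude(m, lat)
    expect_lte(rl["south"], mb)
    expect_lte(mb, rl["north"])
  }
  idx <- range_index_series(psi)
  expect_s3_class(idx, "occu_indices")
  expect_equal(sort(unique(idx$index)),
               c("mean_lat", "north_limit", "pao", "south_limit"))
  expect_true(all(idx$lo <= idx$mean & idx$mean <= idx$hi))
  nc <- net_change_map(psi)
  expect_true(all(nc$mean >= -1 & nc$mean <= 1))
  # identical years give an all-zero change map
  nc0 <- net_change_map(psi, first = attr(psi, "years")[1],
                        last = attr(psi, "years")[1])
  expect_true(all(nc0$mean == 0))
  p1 <- autoplot(idx)
  p2 <- autoplot(nc)
  expect_s3_class(p1, "ggplot")
  expect_s3_class(p2, "ggplot")
})

test_that("posterior mean map tracks a simulated northward shift", {
  sh <- make_fixture("shift", seed = 9)
  truth_psi <- sh$truth$psi
  lat <- sh$truth$coords$latitude
  mbl <- sapply(seq_len(ncol(truth_psi)), function(t) {
    mean_breeding_latitude(truth_psi[, t], lat)
  })
  expect_true(all(diff(mbl) > 0))
})
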
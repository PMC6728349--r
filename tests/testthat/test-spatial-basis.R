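set.seed(101)
sites25 <- tibble::tibble(
  site_id = sprintf("r%02d", 1:25),
  latitude = runif(25, 30, 45),
  longitude = runif(25, -95, -75)
)

test_that("basis has the contracted shapes and a symmetric PSD penalty", {
  b <- build_tprs_basis(sites25, k = 10)
  expect_equal(dim(b$basis_matrix), c(25L, 10L))
  expect_equal(dim(b$penalty_matrix), c(10L, 10L))
  expect_equal(b$penalty_matrix, t(b$penalty_matrix))
  ev <- eigen(b$penalty_matrix, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-10)
  expect_equal(b$null_space_dim, 3L)
  expect_equal(qr(b$basis_matrix)$rank, 10L)
})

test_that("penalty null space is exactly the affine functions of lat/lon", {
  co <- tibble::tibble(site_id = 1:5,
                       latitude = c(30, 35, 40, 32, 38),
                       longitude = c(-90, -85, -80, -82, -88))
  b <- build_tprs_basis(co, k = 4)
  for (abc in list(c(1, 0, 0), c(2, 0.5, -0.3), c(-1, 0.1, 0.2))) {
    f <- abc[1] + abc[2] * co$latitude + abc[3] * co$longitude
    nu <- qr.solve(b$basis_matrix, f)
    # the coefficients reproduce the affine function on the sites ...
    expect_lt(max(abs(b$basis_matrix %*% nu - f)), 1e-8)
    # ... and pay zero smoothing penalty
    expect_lt(abs(t(nu) %*% b$penalty_matrix %*% nu), 1e-10)
  }
})

test_that("lambda -> infinity penalized fit converges to the OLS plane", {
  b <- build_tprs_basis(sites25, k = 10)
  set.seed(7)
  yobs <- 1 + 0.2 * sites25$latitude - 0.1 * sites25$longitude + rnorm(25)
  X <- b$basis_matrix; S <- b$penalty_matrix
  lam <- 1e9
  nu <- solve(crossprod(X) + lam * S, crossprod(X, yobs))
  fit_pen <- X %*% nu
  fit_ols <- fitted(lm(yobs ~ latitude + longitude, data = sites25))
  expect_lt(max(abs(fit_pen - fit_ols)), 1e-6)
})

test_that("richer bases achieve no worse penalized training fit", {
  set.seed(8)
  yobs <- sin(sites25$latitude / 3) + cos(sites25$longitude / 4) +
    rnorm(25, 0, 0.1)
  dev <- sapply(c(6, 12, 20), function(k) {
    b <- build_tprs_basis(sites25, k)
    nu <- solve(crossprod(b$basis_matrix) + 0.5 * b$penalty_matrix,
                crossprod(b$basis_matrix, yobs))
    sum((yobs - b$basis_matrix %*% nu)^2)
  })
  expect_true(all(diff(dev) <= 1e-8))
})

test_that("degenerate inputs fail loudly", {
  col <- tibble::tibble(site_id = 1:10, latitude = seq(30, 39),
                        longitude = seq(-90, -81))
  expect_error(build_tprs_basis(col, 5), "collinear")
  expect_error(build_tprs_basis(sites25, 3), "k")
  expect_error(build_tprs_basis(sites25, 26), "distinct")
  dup <- sites25
  dup$latitude <- rep(dup$latitude[1:5], 5)
  dup$longitude <- rep(dup$longitude[1:5], 5)
  expect_error(build_tprs_basis(dup, 10), "distinct")
  bad <- sites25; bad$latitude[3] <- 100
  expect_error(build_tprs_basis(bad, 5), "latitude")
})

test_that("evaluation at training coordinates reproduces the basis matrix", {
  b <- build_tprs_basis(sites25, k = 12)
  X2 <- evaluate_basis(b, sites25)
  expect_lt(max(abs(X2 - b$basis_matrix)), 1e-10)
  ctr <- tibble::tibble(latitude = mean(sites25$latitude),
                        longitude = mean(sites25$longitude))
  row <- evaluate_basis(b, ctr)
  expect_equal(dim(row), c(1L, 12L))
  expect_true(all(is.finite(row)))
  expect_false(attr(row, "extrapolated")[1])
})

test_that("affine smooths are reproduced exactly at new locations", {
  b <- build_tprs_basis(sites25, k = 10)
  f_train <- 0.5 + 0.3 * sites25$latitude
  nu <- qr.solve(b$basis_matrix, f_train)
  grid <- tidyr::expand_grid(latitude = seq(31, 44, by = 0.5),
                             longitude = seq(-94, -76, by = 0.5))
  G <- evaluate_basis(b, grid)
  expect_lt(max(abs(G %*% nu - (0.5 + 0.3 * grid$latitude))), 1e-6)
})

test_that("points outside the training hull are flagged as extrapolation", {
  b <- build_tprs_basis(sites25, k = 8)
  far <- tibble::tibble(latitude = c(60, mean(sites25$latitude)),
                        longitude = c(-120, mean(sites25$longitude)))
  G <- evaluate_basis(b, far)
  expect_equal(attr(G, "extrapolated"), c(TRUE, FALSE))
})

test_that("the plane-only basis spans exactly the null space", {
  b <- null_space_basis(sites25)
  expect_equal(b$k, 3L)
  expect_equal(b$penalty_rank, 0L)
  expect_true(all(b$penalty_matrix == 0))
  X2 <- evaluate_basis(b, sites25)
  expect_lt(max(abs(X2 - b$basis_matrix)), 1e-12)
})
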
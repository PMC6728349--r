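#' Build a low-rank thin-plate regression spline basis over site coordinates
#'
#' Constructs the 2-D thin-plate regression spline (TPRS) basis used for the
#' spatial occupancy surface, together with its smoothing-penalty matrix. The
#' smooth is the standard low-rank eigen-reduction of the full thin-plate
#' kernel: the penalty null space is exactly the span of \{constant, latitude,
#' longitude\} (dimension 3), so the penalized log-prior is flat over affine
#' trends and penalizes only wiggliness. Coordinates are centered and divided
#' by a common scale (the larger coordinate range) before kernel evaluation;
#' the transform is stored so the identical basis functions can be evaluated
#' at new locations with [evaluate_basis()].
#'
#' @param coords A data frame with columns `site_id`, `latitude`, `longitude`
#'   (decimal degrees, WGS-84 assumed; no projection is performed).
#' @param k Basis dimension (number of columns), at least 4 and at most the
#'   number of distinct coordinate pairs.
#' @return An object of class `occu_basis`: a list with `basis_matrix`
#'   (N x k, rows named by `site_id`), `penalty_matrix` (k x k, symmetric
#'   positive semi-definite), `null_space_dim` (always 3), `transform`
#'   (centering/scaling constants) and the training coordinates.
#' @examples
#' set.seed(1)
#' sites <- tibble::tibble(site_id = 1:30,
#'                         latitude = runif(30, 30, 45),
#'                         longitude = runif(30, -95, -75))
#' b <- build_tprs_basis(sites, k = 10)
#' dim(b$basis_matrix)
#' @export
build_tprs_basis <- function(coords, k) {
  coords <- validate_coords(coords)
  if (length(k) != 1 || !is.finite(k) || k < 4) {
    abort("`k` must be a single integer >= 4 (null space dimension 3 + 1)")
  }
  k <- as.integer(k)
  uniq <- !duplicated(coords[, c("latitude", "longitude")])
  n_distinct <- sum(uniq)
  if (n_distinct < k) {
    abort(sprintf(
      "only %d distinct coordinate pairs but k = %d basis functions requested",
      n_distinct, k
    ))
  }
  # collinear site sets reduce the null space; fail loudly
  A <- cbind(1, coords$latitude, coords$longitude)
  if (qr(A)$rank < 3) {
    abort("site coordinates are collinear; the spatial smooth is degenerate")
  }
  tr <- list(
    center_lon = mean(coords$longitude),
    center_lat = mean(coords$latitude),
    scale = max(diff(range(coords$longitude)), diff(range(coords$latitude)))
  )
  if (tr$scale <= 0) abort("all sites share a single location")
  d <- data.frame(
    u = (coords$longitude - tr$center_lon) / tr$scale,
    v = (coords$latitude - tr$center_lat) / tr$scale
  )
  sm <- mgcv::smoothCon(mgcv::s(u, v, bs = "tp", k = k),
                        data = d, absorb.cons = FALSE)[[1]]
  X <- sm$X
  S <- (sm$S[[1]] + t(sm$S[[1]])) / 2
  rownames(X) <- as.character(coords$site_id)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) abort("penalty matrix is not positive semi-definite")
  nsd <- sum(ev < max(ev) * 1e-10)
  if (nsd != 3) {
    abort(sprintf("penalty null space has dimension %d, expected 3", nsd))
  }
  structure(
    list(
      basis_matrix = X,
      penalty_matrix = S,
      null_space_dim = 3L,
      k = k,
      transform = tr,
      smooth = sm,
      type = "tprs",
      coords = coords,
      penalty_rank = k - 3L,
      penalty_logpdet = sum(log(ev[ev > max(ev) * 1e-10]))
    ),
    class = "occu_basis"
  )
}

#' Degenerate plane-only spatial basis
#'
#' The penalty-null-space-only smooth: columns \{constant, scaled latitude,
#' scaled longitude\} with a zero penalty matrix. Useful for collapsing the
#' model onto a plain logistic trend surface (e.g. for cross-checks against
#' direct optimization) and for very small site sets where no penalized
#' thin-plate basis can be built.
#'
#' @inheritParams build_tprs_basis
#' @return An `occu_basis` with `k = 3` and `penalty_rank = 0`.
#' @export
null_space_basis <- function(coords) {
  coords <- validate_coords(coords)
  A <- cbind(1, coords$latitude, coords$longitude)
  if (qr(A)$rank < 3) {
    abort("site coordinates are collinear; the spatial smooth is degenerate")
  }
  tr <- list(
    center_lon = mean(coords$longitude),
    center_lat = mean(coords$latitude),
    scale = max(diff(range(coords$longitude)), diff(range(coords$latitude)))
  )
  X <- cbind(1, (coords$latitude - tr$center_lat) / tr$scale,
             (coords$longitude - tr$center_lon) / tr$scale)
  rownames(X) <- as.character(coords$site_id)
  structure(
    list(basis_matrix = X, penalty_matrix = matrix(0, 3, 3),
         null_space_dim = 3L, k = 3L, transform = tr, smooth = NULL,
         type = "plane", coords = coords, penalty_rank = 0L,
         penalty_logpdet = 0),
    class = "occu_basis"
  )
}

validate_coords <- function(coords) {
  if (!is.data.frame(coords)) abort("`coords` must be a data frame")
  need <- c("site_id", "latitude", "longitude")
  miss <- setdiff(need, names(coords))
  if (length(miss)) abort(paste("missing coordinate columns:",
                                paste(miss, collapse = ", ")))
  coords <- as_tibble(coords)[, need]
  assert_finite(coords$latitude, "latitude")
  assert_finite(coords$longitude, "longitude")
  if (any(abs(coords$latitude) > 90)) abort("latitude outside [-90, 90]")
  if (any(abs(coords$longitude) > 180)) abort("longitude outside [-180, 180]")
  if (anyDuplicated(coords$site_id)) abort("site_ids are not unique")
  coords
}

#' Evaluate a fitted spline basis at new coordinates
#'
#' Evaluates the same basis functions constructed by [build_tprs_basis()]
#' (using the stored coordinate transform) at arbitrary new locations, e.g.
#' the cell centers of a prediction grid. Points outside the convex hull of
#' the training sites are permitted but flagged in the `extrapolated`
#' attribute of the result.
#'
#' @param basis An `occu_basis` object.
#' @param new_coords Data frame with columns `latitude` and `longitude`
#'   (a `site_id` column is optional).
#' @return An M x k numeric matrix of basis-function values with a logical
#'   attribute `extrapolated` marking rows outside the training convex hull.
#' @export
evaluate_basis <- function(basis, new_coords) {
  stopifnot(inherits(basis, "occu_basis"))
  if (!is.data.frame(new_coords)) abort("`new_coords` must be a data frame")
  if (!all(c("latitude", "longitude") %in% names(new_coords))) {
    abort("`new_coords` needs `latitude` and `longitude` columns")
  }
  assert_finite(new_coords$latitude, "latitude")
  assert_finite(new_coords$longitude, "longitude")
  tr <- basis$transform
  d <- data.frame(
    u = (new_coords$longitude - tr$center_lon) / tr$scale,
    v = (new_coords$latitude - tr$center_lat) / tr$scale
  )
  X <- if (identical(basis$type, "plane")) {
    cbind(1, d$v, d$u)
  } else {
    mgcv::PredictMat(basis$smooth, d)
  }
  tc <- basis$coords
  hull <- grDevices::chull(tc$longitude, tc$latitude)
  bnd <- cbind(tc$longitude[hull], tc$latitude[hull])
  inside <- mgcv::in.out(rbind(bnd, bnd[1, ]),
                         cbind(new_coords$longitude, new_coords$latitude))
  attr(X, "extrapolated") <- !inside
  X
}
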
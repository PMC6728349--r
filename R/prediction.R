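# Posterior occupancy maps on a prediction grid and range-dynamics indices.

# squared distance from points to a segment (vectorized over points)
dist_to_segment <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx^2 + dy^2
  tt <- if (len2 == 0) rep(0, length(px))
        else pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / len2))
  sqrt((px - (x1 + tt * dx))^2 + (py - (y1 + tt * dy))^2)
}

#' Mask grid cells by a buffered convex hull of occupied sites
#'
#' A cell is included when its center lies inside the convex hull of the
#' occupied site coordinates dilated by `buffer_deg` (Euclidean distance in
#' degree units, i.e. the exact Minkowski dilation of the hull).
#'
#' @param occupied_coords Data frame with `latitude`/`longitude` of sites
#'   with at least one detection; needs >= 3 non-collinear points.
#' @param grid Data frame of cell centers with `latitude`/`longitude`.
#' @param buffer_deg Buffer radius in degrees (default 2).
#' @return Logical inclusion vector, one element per grid row.
#' @export
buffered_hull_mask <- function(occupied_coords, grid, buffer_deg = 2.0) {
  oc <- as_tibble(occupied_coords)
  if (nrow(oc) < 3) abort("need at least 3 occupied sites")
  A <- cbind(1, oc$latitude, oc$longitude)
  if (qr(A)$rank < 3) abort("occupied sites are collinear; hull is degenerate")
  hull <- grDevices::chull(oc$longitude, oc$latitude)
  hx <- oc$longitude[hull]; hy <- oc$latitude[hull]
  bnd <- cbind(c(hx, hx[1]), c(hy, hy[1]))
  px <- grid$longitude; py <- grid$latitude
  inside <- mgcv::in.out(bnd, cbind(px, py))
  if (buffer_deg > 0) {
    mind <- rep(Inf, length(px))
    for (i in seq_along(hx)) {
      j <- if (i == length(hx)) 1 else i + 1
      mind <- pmin(mind, dist_to_segment(px, py, hx[i], hy[i], hx[j], hy[j]))
    }
    inside <- inside | (mind <= buffer_deg)
  }
  inside
}

#' Build a regular prediction grid inside the buffered hull
#'
#' Lays a regular lattice of cell centers (default 0.5 degrees) over the
#' bounding box of the occupied sites expanded by the buffer, and keeps the
#' cells inside the buffered convex hull.
#'
#' @param occupied_coords Data frame with `latitude`/`longitude`.
#' @param cell_deg Lattice spacing in degrees (default 0.5).
#' @param buffer_deg Hull buffer in degrees (default 2).
#' @return Tibble with `cell_id`, `latitude`, `longitude`.
#' @export
make_prediction_grid <- function(occupied_coords, cell_deg = 0.5,
                                 buffer_deg = 2.0) {
  oc <- as_tibble(occupied_coords)
  lon <- seq(floor(min(oc$longitude) - buffer_deg),
             ceiling(max(oc$longitude) + buffer_deg), by = cell_deg)
  lat <- seq(floor(min(oc$latitude) - buffer_deg),
             ceiling(max(oc$latitude) + buffer_deg), by = cell_deg)
  g <- tidyr::expand_grid(longitude = lon, latitude = lat)
  keep <- buffered_hull_mask(oc, g, buffer_deg)
  g <- g[keep, ]
  tibble(cell_id = seq_len(nrow(g)), latitude = g$latitude,
         longitude = g$longitude)
}

#' Posterior occupancy probabilities on a prediction grid
#'
#' Evaluates, for each posterior draw, the occupancy surface and covariate
#' effects at the grid cell centers: `psi = plogis(G nu_t + omega beta x)`,
#' where `G` is the training basis evaluated at the new coordinates and the
#' grid covariates must be standardized with the training transform.
#'
#' @param fit An `occu_fit`.
#' @param grid Tibble with `cell_id`, `latitude`, `longitude`.
#' @param grid_covariates Tibble with `cell_id`, `year` and the five
#'   (training-standardized) climate variables, or NULL when no covariates
#'   were selected into the model. Required for every included cell-year if
#'   any covariate draw is active.
#' @param draw_ids Optional integer vector of pooled draw indices to use
#'   (default: all draws).
#' @return An object of class `occu_psi`: a draws x cells x years array with
#'   the grid attached as attribute `grid` and years as attribute `years`.
#' @export
predict_occupancy <- function(fit, grid, grid_covariates = NULL,
                              draw_ids = NULL) {
  stopifnot(inherits(fit, "occu_fit"))
  grid <- as_tibble(grid)
  dm <- draw_matrix(fit)
  if (is.null(draw_ids)) draw_ids <- seq_len(nrow(dm))
  G <- evaluate_basis(fit$basis, grid)
  K <- fit$K; T <- fit$T
  M <- nrow(grid)
  years <- fit$data$years
  nm <- fit$par_names
  nu_cols <- which(grepl("^nu\\[", nm))
  beta_cols <- which(grepl("^beta\\[", nm))
  omega_cols <- which(grepl("^omega\\[", nm))

  Xg <- NULL
  if (!is.null(grid_covariates)) {
    gc <- as_tibble(grid_covariates)
    vars <- fit$data$var_names
    miss <- setdiff(c("cell_id", "year", vars), names(gc))
    if (length(miss)) abort(paste("grid covariates missing columns:",
                                  paste(miss, collapse = ", ")))
    Xg <- array(NA_real_, dim = c(M, T, 10))
    ci <- match(gc$cell_id, grid$cell_id)
    ti <- match(gc$year, years)
    ok <- !is.na(ci) & !is.na(ti)
    for (m in seq_along(vars)) {
      v <- gc[[vars[m]]]
      Xg[cbind(ci[ok], ti[ok], m)] <- v[ok]
      Xg[cbind(ci[ok], ti[ok], m + 5)] <- v[ok]^2
    }
  }
  psi <- array(NA_real_, dim = c(length(draw_ids), M, T))
  any_active <- any(dm[draw_ids, omega_cols] != 0)
  if (any_active && is.null(Xg)) {
    abort("covariate draws are active but `grid_covariates` is NULL")
  }
  if (!is.null(Xg) && any_active) {
    for (t in seq_len(T)) {
      if (anyNA(Xg[, t, 1])) {
        abort(sprintf("missing grid covariates for year %s", years[t]))
      }
    }
  }
  for (d in seq_along(draw_ids)) {
    row <- dm[draw_ids[d], ]
    nu <- matrix(row[nu_cols], K, T)
    wb <- row[omega_cols] * row[beta_cols]
    lp <- G %*% nu
    if (!is.null(Xg) && any(wb != 0)) {
      for (m in which(wb != 0)) lp <- lp + Xg[, , m] * wb[m]
    }
    psi[d, , ] <- plogis(lp)
  }
  structure(psi, grid = grid, years = years, class = "occu_psi")
}

#' Proportion of area occupied
#'
#' The arithmetic mean occupancy probability over the (masked) map cells:
#' an index of range size. Cells are equally weighted.
#'
#' @param psi_map Numeric vector of cell occupancy probabilities for one
#'   draw-year.
#' @return A probability.
#' @export
proportion_area_occupied <- function(psi_map) {
  psi_map <- as.numeric(psi_map)
  if (length(psi_map) == 0) abort("empty occupancy map")
  mean(psi_map)
}

#' Occupancy-weighted mean breeding latitude
#'
#' `sum(lat_c * psi_c) / sum(psi_c)`: an index of the range center.
#'
#' @param psi_map Numeric vector of cell occupancy probabilities.
#' @param latitudes Cell latitudes, same length.
#' @return Latitude in degrees.
#' @export
mean_breeding_latitude <- function(psi_map, latitudes) {
  if (length(psi_map) != length(latitudes)) abort("length mismatch")
  tot <- sum(psi_map)
  if (tot <= 0) abort("total occupancy probability is zero")
  sum(latitudes * psi_map) / tot
}

#' Latitudinal range limits from the occupancy mass
#'
#' Aggregates occupancy probability by distinct latitude, forms the
#' cumulative occupancy fraction over sorted latitudes, and inverts it with
#' a shape-preserving monotone spline: the southern limit is the latitude
#' below which `tail_mass` of the total occupancy probability lies and the
#' northern limit the latitude below which `1 - tail_mass` lies (0.1% tails
#' by default, i.e. 99.9% of the occupancy mass between the limits).
#'
#' @param psi_map Numeric vector of cell occupancy probabilities.
#' @param latitudes Cell latitudes, same length.
#' @param tail_mass One-sided tail fraction (default 0.001).
#' @return Named numeric vector `c(south, north)`.
#' @export
range_limits <- function(psi_map, latitudes, tail_mass = 0.001) {
  if (length(psi_map) != length(latitudes)) abort("length mismatch")
  agg <- rowsum(psi_map, group = latitudes)
  lat <- as.numeric(rownames(agg))
  mass <- agg[, 1]
  pos <- mass > 0
  lat <- lat[pos]; mass <- mass[pos]
  if (length(lat) < 2) {
    abort("need at least 2 distinct latitudes with positive occupancy")
  }
  o <- order(lat)
  lat <- lat[o]; mass <- mass[o]
  cum <- cumsum(mass) / sum(mass)
  xs <- c(0, cum)
  ys <- c(lat[1], lat)
  f <- splinefun(xs, ys, method = "hyman")
  south <- f(tail_mass)
  north <- f(1 - tail_mass)
  c(south = unname(south), north = unname(north))
}

#' Posterior time series of the four range-dynamics indices
#'
#' For every posterior draw and year, computes the proportion of area
#' occupied, the mean breeding latitude and the southern/northern range
#' limits on the prediction map, then summarizes each index by its posterior
#' mean and central credible interval.
#'
#' @param psi An `occu_psi` array from [predict_occupancy()].
#' @param conf Credible level (default 0.95).
#' @param tail_mass Tail fraction passed to [range_limits()].
#' @return A tibble of class `occu_indices` with columns `year`, `index`
#'   (`pao`, `mean_lat`, `south_limit`, `north_limit`), `mean`, `lo`, `hi`.
#' @export
range_index_series <- function(psi, conf = 0.95, tail_mass = 0.001) {
  stopifnot(inherits(psi, "occu_psi"))
  grid <- attr(psi, "grid")
  years <- attr(psi, "years")
  lat <- grid$latitude
  D <- dim(psi)[1]; T <- dim(psi)[3]
  a <- (1 - conf) / 2
  out <- vector("list", T)
  for (t in seq_len(T)) {
    vals <- matrix(NA_real_, D, 4)
    for (d in seq_len(D)) {
      m <- psi[d, , t]
      rl <- range_limits(m, lat, tail_mass)
      vals[d, ] <- c(proportion_area_occupied(m),
                     mean_breeding_latitude(m, lat), rl["south"],
                     rl["north"])
    }
    out[[t]] <- tibble(
      year = years[t],
      index = c("pao", "mean_lat", "south_limit", "north_limit"),
      mean = colMeans(vals),
      lo = apply(vals, 2, quantile, a),
      hi = apply(vals, 2, quantile, 1 - a)
    )
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("occu_indices", class(res))
  res
}

#' Per-cell posterior summary of the occupancy change between two years
#'
#' Computes `psi_last - psi_first` draw-wise for each cell and summarizes
#' by posterior mean and central credible interval.
#'
#' @param psi An `occu_psi` array.
#' @param first,last Year values (default: first and last modeled year).
#' @param conf Credible level (default 0.95).
#' @return A tibble of class `occu_map` with `cell_id`, `latitude`,
#'   `longitude`, `mean`, `lo`, `hi`.
#' @export
net_change_map <- function(psi, first = NULL, last = NULL, conf = 0.95) {
  stopifnot(inherits(psi, "occu_psi"))
  years <- attr(psi, "years")
  grid <- attr(psi, "grid")
  first <- first %||% years[1]
  last <- last %||% years[length(years)]
  t1 <- match(first, years); t2 <- match(last, years)
  if (is.na(t1) || is.na(t2)) abort("requested years not in the fitted span")
  diff <- psi[, , t2, drop = FALSE][, , 1] - psi[, , t1, drop = FALSE][, , 1]
  diff <- matrix(diff, nrow = dim(psi)[1])
  a <- (1 - conf) / 2
  res <- tibble(
    cell_id = grid$cell_id,
    latitude = grid$latitude,
    longitude = grid$longitude,
    mean = colMeans(diff),
    lo = apply(diff, 2, quantile, a),
    hi = apply(diff, 2, quantile, 1 - a)
  )
  class(res) <- c("occu_map", class(res))
  res
}

#' @export
autoplot.occu_indices <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = year, y = mean, ymin = lo, ymax = hi)) +
    ggplot2::geom_ribbon(alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~index, scales = "free_y") +
    ggplot2::labs(x = "year", y = "posterior mean (95% CI)")
}

#' @export
autoplot.occu_map <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = longitude, y = latitude, fill = mean)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "firebrick", mid = "white",
                                  high = "steelblue", midpoint = 0) +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = expression(Delta * psi))
}
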
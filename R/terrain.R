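#' Percent slope from a digital elevation model
#'
#' Computes percent slope `S = 100 * |grad H|` from a DEM in metres on a
#' geographic grid. Degree spacing is converted to metres with the uniform
#' 111120 m/degree factor on both axes before differencing; gradients use
#' central differences in the interior and one-sided differences at the
#' edges, so any affine (planar) DEM yields its exact analytic slope in
#' every cell. Slopes steeper than 100% (a 45 degree gradient) are
#' considered impassable on foot and are stored as `NA`, as is any cell
#' whose difference stencil touches an `NA` elevation.
#'
#' @param dem A [geo_grid()] of elevations in metres, already resampled and
#'   aligned to the reference geometry.
#' @return A [geo_grid()] of percent slope in \[0, 100\], `NA` where
#'   impassable or undefined.
#' @examples
#' # a plane rising 1 m per 20 m of easting has a 5% slope everywhere
#' cs <- 20 / 111120
#' dem <- geo_grid(outer(rep(1, 5), 1:5 * 1), cell_size = cs)
#' range(as.matrix(slope_percent(dem)))
#' @export
slope_percent <- function(dem) {
  d <- dim(dem$values)
  if (d[1] < 2 || d[2] < 2) {
    stop("slope needs at least a 2 x 2 DEM", call. = FALSE)
  }
  h <- dem$values
  step_m <- degrees_to_metres(dem$cell_size)

  ddx <- gradient_axis(h, step_m, along_rows = TRUE)   # d/dx: across columns
  ddy <- gradient_axis(h, step_m, along_rows = FALSE)  # d/dy: across rows
  s <- 100 * sqrt(ddx^2 + ddy^2)
  s[is.na(h)] <- NA          # a cell without elevation has no slope
  s[!is.na(s) & s > 100] <- NA
  geo_grid(s, dem$origin_lon, dem$origin_lat, dem$cell_size, dem$nodata)
}

# numpy.gradient-style finite differences: central interior, one-sided edges.
# NA propagates through the stencil.
gradient_axis <- function(h, step, along_rows) {
  if (!along_rows) {
    return(t(gradient_axis(t(h), step, along_rows = TRUE)))
  }
  n <- ncol(h)
  g <- matrix(NA_real_, nrow(h), n)
  if (n >= 3) {
    g[, 2:(n - 1)] <- (h[, 3:n] - h[, 1:(n - 2)]) / (2 * step)
  }
  g[, 1] <- (h[, 2] - h[, 1]) / step
  g[, n] <- (h[, n] - h[, n - 1]) / step
  g
}

#' Walking speed as a function of slope
#'
#' Empirical pedestrian speed model: `speed (m/s) = 0.11 + exp(-(S + 5)^2 /
#' (2 * 30^2))` where `S` is the signed percent slope. The maximum 1.11 m/s
#' occurs on a gentle downhill (`S = -5`); speed decays towards 0.11 m/s on
#' extreme grades.
#'
#' @param S Signed percent slope (negative = downhill).
#' @return Speed in m/s.
#' @examples
#' speed_on_slope(0)    # ~1.0962 m/s on the flat
#' speed_on_slope(-5)   # 1.11 m/s, the global maximum
#' @export
speed_on_slope <- function(S) {
  0.11 + exp(-(S + 5)^2 / (2 * 30^2))
}

#' Return-trip slope impact on walking speed
#'
#' Travel to a facility is assumed to be a return trip, so a cell's slope
#' slows the walker once uphill and once downhill. The impact is the mean of
#' the slope-adjusted speeds in both directions relative to the flat-ground
#' speed:
#' `impact(S) = 0.5 * (speed(+S) + speed(-S)) / speed(0)`.
#' The uphill and downhill effects are not symmetric individually, but their
#' mean is, so the impact depends only on the slope magnitude. It equals 1
#' exactly on flat ground and decreases monotonically to about 0.1 at the
#' 100% passability limit.
#'
#' @param S Percent slope magnitude in \[0, 100\].
#' @return Dimensionless multiplier in (0, 1].
#' @examples
#' slope_impact(0)    # exactly 1
#' slope_impact(10)   # ~0.9527
#' @export
slope_impact <- function(S) {
  if (any(!is.na(S) & (S < 0 | S > 100))) {
    stop("slope_impact expects slope magnitudes in [0, 100]; ",
         "mask steeper cells as NA first", call. = FALSE)
  }
  0.5 * (speed_on_slope(S) + speed_on_slope(-S)) / speed_on_slope(0)
}

#' Slope-impact grid
#'
#' Applies [slope_impact()] cell-wise to a percent-slope grid; `NA`
#' (impassable or undefined slope) propagates.
#'
#' @param slope A [geo_grid()] from [slope_percent()].
#' @return A [geo_grid()] of dimensionless multipliers.
#' @export
impact_grid <- function(slope) {
  v <- slope$values
  out <- matrix(NA_real_, nrow(v), ncol(v))
  ok <- !is.na(v)
  out[ok] <- slope_impact(v[ok])
  geo_grid(out, slope$origin_lon, slope$origin_lat, slope$cell_size,
           slope$nodata)
}
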
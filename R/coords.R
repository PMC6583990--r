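# Below |a2| < A2_EPS the cubic's leading coefficient 2*a2^2 underflows the
# useful range; the exact linear-midline solution takes over.
A2_EPS <- 1e-10

#' Coordinate-system parameters of a rod-shaped cell
#'
#' Six scalars define one cell's coordinate system: the midline
#' `p(x) = a0 + a1*x + a2*x^2` (a second-degree polynomial running along the
#' long axis), the left/right midline endpoints `xl`, `xr`, and the cell
#' radius `r`. All lengths are in pixels; the image convention is y-down with
#' the center of the top-left pixel at (0.5, 0.5).
#'
#' @param a0 Midline intercept (px).
#' @param a1 Midline slope (dimensionless).
#' @param a2 Midline curvature coefficient (px^-1).
#' @param xl,xr Left and right endpoints of the midline domain (px),
#'   `xl < xr`.
#' @param r Cell radius (px), positive.
#'
#' @return An object of class `coord_params`.
#' @examples
#' cp <- coord_params(a0 = 5, a1 = 0, a2 = 0, xl = 1, xr = 9, r = 2)
#' cell_length(cp)
#' @export
coord_params <- function(a0, a1 = 0, a2 = 0, xl, xr, r) {
  v <- c(a0, a1, a2, xl, xr, r)
  if (length(v) != 6L || !all(is.finite(v)))
    stop("coordinate parameters must be six finite scalars")
  if (xl >= xr) stop("'xl' must be smaller than 'xr'")
  if (r <= 0) stop("radius 'r' must be positive")
  structure(list(a0 = a0, a1 = a1, a2 = a2, xl = xl, xr = xr, r = r),
            class = "coord_params")
}

#' @export
print.coord_params <- function(x, ...) {
  cat(sprintf(
    "<coord_params> p(x) = %.4g + %.4g x + %.4g x^2 on [%.4g, %.4g], r = %.4g\n",
    x$a0, x$a1, x$a2, x$xl, x$xr, x$r))
  invisible(x)
}

#' Evaluate the midline and its slope
#'
#' @param params A [coord_params] object.
#' @param x Positions (px).
#' @return `midline_y` returns p(x); `midline_slope` returns p'(x).
#' @keywords internal
midline_y <- function(params, x) params$a0 + params$a1 * x + params$a2 * x^2

midline_slope <- function(params, x) params$a1 + 2 * params$a2 * x

cbrt <- function(x) sign(x) * abs(x)^(1 / 3)

#' Closest point on the midline
#'
#' Finds, for each Cartesian point, the abscissa `xc` of the midline point
#' closest to it (the foot of the perpendicular). Setting the derivative of
#' the squared distance to zero gives a cubic in `xc`,
#' `2 a2^2 xc^3 + 3 a1 a2 xc^2 + (1 + a1^2 + 2 a2 (a0 - yp)) xc +
#'  (a1 (a0 - yp) - xp) = 0`,
#' which is solved in closed form (Cardano / trigonometric branches), never
#' iteratively. All real roots and both domain endpoints are candidates; the
#' squared distance is evaluated at each candidate clamped to `[xl, xr]` and
#' the arg-min is returned, so pole-region points clamp to an endpoint.
#'
#' @param params A [coord_params] object.
#' @param xp,yp Cartesian point coordinates (px), vectors of equal length.
#' @return Numeric vector `xc` in `[xl, xr]`.
#' @export
closest_midline_point <- function(params, xp, yp) {
  if (length(xp) != length(yp)) stop("'xp' and 'yp' must have equal length")
  if (length(xp) == 0L) return(numeric(0))
  if (!all(is.finite(xp)) || !all(is.finite(yp)))
    stop("point coordinates must be finite")
  a0 <- params$a0; a1 <- params$a1; a2 <- params$a2
  n <- length(xp)

  if (abs(a2) < A2_EPS) {
    # linear midline: orthogonal projection in closed form
    cand <- matrix((xp + a1 * (yp - a0)) / (1 + a1^2), n, 1)
  } else {
    A <- 2 * a2^2
    B <- 3 * a1 * a2
    C <- 1 + a1^2 + 2 * a2 * (a0 - yp)
    D <- a1 * (a0 - yp) - xp
    shift <- B / (3 * A)
    pc <- C / A - B^2 / (3 * A^2)
    qc <- 2 * B^3 / (27 * A^3) - B * C / (3 * A^2) + D / A
    disc <- (qc / 2)^2 + (pc / 3)^3
    cand <- matrix(NA_real_, n, 3)
    one <- disc >= 0
    if (any(one)) {
      s <- sqrt(disc[one])
      cand[one, 1] <- cbrt(-qc[one] / 2 + s) + cbrt(-qc[one] / 2 - s) - shift
    }
    if (any(!one)) {
      p3 <- pc[!one]; q3 <- qc[!one]
      m <- 2 * sqrt(-p3 / 3)
      theta <- acos(pmin(1, pmax(-1, 3 * q3 / (p3 * m)))) / 3
      for (k in 0:2)
        cand[!one, k + 1] <- m * cos(theta - 2 * pi * k / 3) - shift
    }
  }

  cand <- cbind(cand, params$xl, params$xr)
  cand <- pmin(pmax(cand, params$xl), params$xr)
  d2 <- (cand - xp)^2 + (params$a0 + params$a1 * cand + params$a2 * cand^2 - yp)^2
  d2[is.na(d2)] <- Inf
  cand[cbind(seq_len(n), max.col(-d2, ties.method = "first"))]
}

#' Arc length along the midline
#'
#' Integrates `sqrt(1 + p'(x)^2)` between two abscissae using the closed form
#' for a quadratic, `[u sqrt(1+u^2) + asinh(u)] / (4 a2)` with
#' `u = a1 + 2 a2 x`, with a guarded `a2 -> 0` limit.
#'
#' @inheritParams closest_midline_point
#' @param x_start,x_end Integration limits (px); vectors recycle.
#' @return Arc length (px).
#' @export
arc_length <- function(params, x_start, x_end) {
  if (!all(is.finite(x_start)) || !all(is.finite(x_end)))
    stop("integration limits must be finite")
  a1 <- params$a1; a2 <- params$a2
  if (abs(a2) < A2_EPS) return((x_end - x_start) * sqrt(1 + a1^2))
  antider <- function(x) {
    u <- a1 + 2 * a2 * x
    (u * sqrt(1 + u^2) + asinh(u)) / (4 * a2)
  }
  antider(x_end) - antider(x_start)
}

#' Cell length
#'
#' Arc length of the midline over its full domain `[xl, xr]`.
#'
#' @inheritParams closest_midline_point
#' @return Length (px), strictly positive.
#' @export
cell_length <- function(params) arc_length(params, params$xl, params$xr)

# Unit tangent (pointing toward +x) and top-side normal at abscissa x.
# "Top" is the smaller-y side: in the y-down image convention the normal
# (p'(x), -1)/|.| points toward the top of the displayed cell.
midline_frame <- function(params, x) {
  u <- midline_slope(params, x)
  nrm <- sqrt(1 + u^2)
  list(tx = 1 / nrm, ty = u / nrm, nx = u / nrm, ny = -1 / nrm)
}

#' Transform Cartesian points to cellular coordinates
#'
#' Maps each Cartesian point `(xp, yp)` to cellular coordinates:
#' `lc` the arc length along the midline from `xl` to the closest-point
#' abscissa `xc`; `rc` the Euclidean distance to the midline point
#' `(xc, p(xc))`; and `phi` (degrees) distinguishing top (`phi = 0`) from
#' bottom (`phi = 180`) along the cell body and parametrizing the
#' hemispherical poles. At the poles `phi` is the angle between the top-side
#' normal at the clamped endpoint and the segment from the endpoint to the
#' point, running 0 to 180 clockwise around the right pole and 180 back to 0
#' around the left pole. `phi` on the midline itself (`rc = 0`) is defined
#' as 0.
#'
#' @inheritParams closest_midline_point
#' @return A data.frame with columns `xc`, `lc`, `rc`, `phi`.
#' @export
map_to_cellular <- function(params, xp, yp) {
  xc <- closest_midline_point(params, xp, yp)
  yc <- midline_y(params, xc)
  rc <- sqrt((xp - xc)^2 + (yp - yc)^2)
  lc <- arc_length(params, params$xl, xc)

  phi <- ifelse(yp < midline_y(params, xp), 0, 180)
  pole <- xc == params$xl | xc == params$xr
  if (any(pole)) {
    fr <- midline_frame(params, xc[pole])
    vx <- xp[pole] - xc[pole]
    vy <- yp[pole] - yc[pole]
    rr <- rc[pole]
    cosang <- (fr$nx * vx + fr$ny * vy) / ifelse(rr > 0, rr, 1)
    phi[pole] <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  }
  phi[rc < 1e-9] <- 0
  data.frame(xc = xc, lc = lc, rc = rc, phi = phi)
}

# Invert the arc-length function: find xc in [xl, xr] with
# arc_length(xl, xc) = lc. Newton iteration on the monotone closed form;
# the derivative sqrt(1 + p'^2) >= 1 keeps the step bounded.
invert_arc_length <- function(params, lc, tol = 1e-9) {
  L <- cell_length(params)
  xc <- params$xl + lc / L * (params$xr - params$xl)
  for (i in 1:100) {
    f <- arc_length(params, params$xl, xc) - lc
    step <- f / sqrt(1 + midline_slope(params, xc)^2)
    xc <- pmin(pmax(xc - step, params$xl), params$xr)
    if (max(abs(step)) < tol / 10) break
  }
  xc
}

#' Transform cellular coordinates back to Cartesian
#'
#' Inverse of [map_to_cellular()]: `xc` is recovered from `lc` by inverting
#' the monotone arc-length function (Newton iteration to 1e-9 px), and the
#' point is placed at distance `rc` from the midline along the direction
#' selected by `phi` — the top/bottom normal for body points, the rotated
#' endpoint normal for pole points (`lc = 0` or `lc = L`).
#'
#' @inheritParams closest_midline_point
#' @param lc Longitudinal coordinate (px) in `[0, cell_length(params)]`.
#' @param rc Radial coordinate (px), non-negative.
#' @param phi Angular coordinate (degrees) in `[0, 180]`.
#' @return A data.frame with columns `xp`, `yp`.
#' @export
map_to_cartesian <- function(params, lc, rc, phi) {
  n <- max(length(lc), length(rc), length(phi))
  lc <- rep_len(lc, n); rc <- rep_len(rc, n); phi <- rep_len(phi, n)
  L <- cell_length(params)
  if (any(lc < -1e-6 | lc > L + 1e-6))
    stop("'lc' outside [0, cell_length]")
  lc <- pmin(pmax(lc, 0), L)
  if (any(rc < 0)) stop("'rc' must be non-negative")

  xc <- invert_arc_length(params, lc)
  # snap the endpoints exactly
  xc[lc <= 0] <- params$xl
  xc[lc >= L] <- params$xr
  yc <- midline_y(params, xc)
  fr <- midline_frame(params, xc)

  at_l <- lc <= 0
  at_r <- lc >= L
  body <- !(at_l | at_r)

  xp <- numeric(n); yp <- numeric(n)
  if (any(body)) {
    sgn <- ifelse(phi[body] < 90, 1, -1)
    xp[body] <- xc[body] + sgn * rc[body] * fr$nx[body]
    yp[body] <- yc[body] + sgn * rc[body] * fr$ny[body]
  }
  pole <- !body
  if (any(pole)) {
    # outward tangent: +T at the right pole, -T at the left pole
    tsgn <- ifelse(at_r[pole], 1, -1)
    ang <- phi[pole] * pi / 180
    ux <- cos(ang) * fr$nx[pole] + sin(ang) * tsgn * fr$tx[pole]
    uy <- cos(ang) * fr$ny[pole] + sin(ang) * tsgn * fr$ty[pole]
    xp[pole] <- xc[pole] + rc[pole] * ux
    yp[pole] <- yc[pole] + rc[pole] * uy
  }
  data.frame(xp = xp, yp = yp)
}

#' Per-pixel coordinate maps
#'
#' Evaluates the cellular coordinates of every pixel center of an image of
#' the given dimensions. Pixel (row i, col j), 1-based, has center
#' `(j - 0.5, i - 0.5)`.
#'
#' @inheritParams closest_midline_point
#' @param dim Image dimensions `c(nrow, ncol)`.
#' @return A list of four matrices: `xc`, `lc`, `rc`, `phi`.
#' @export
coordinate_maps <- function(params, dim) {
  dim <- as.integer(dim)
  if (length(dim) != 2L || any(dim <= 0L)) stop("'dim' must be two positive integers")
  nr <- dim[1]; nc <- dim[2]
  xs <- seq_len(nc) - 0.5
  ys <- seq_len(nr) - 0.5
  xp <- rep(xs, each = nr)
  yp <- rep(ys, times = nc)
  cp <- map_to_cellular(params, xp, yp)
  lapply(cp[c("xc", "lc", "rc", "phi")], matrix, nrow = nr, ncol = nc)
}
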
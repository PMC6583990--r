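#' Radial distance image
#'
#' The per-pixel radial coordinate rc under a given coordinate system; the
#' rc plane of [coordinate_maps()].
#'
#' @inheritParams coordinate_maps
#' @return Numeric matrix of rc values (px).
#' @export
radial_distance_image <- function(params, dim) coordinate_maps(params, dim)$rc

as_pixels <- function(image) {
  if (inherits(image, "image_element")) image$pixels
  else if (is.matrix(image)) image
  else stop("expected an image_element or matrix")
}

#' Binary chi-square objective
#'
#' Thresholds the radial distance image at the radius r, giving a model
#' mask `rc <= r`, and counts disagreeing pixels against the measured
#' binary: `chi2 = sum((model - data)^2)`.
#'
#' @inheritParams coordinate_maps
#' @param binary Binary [image_element] or 0/1 matrix.
#' @return Non-negative chi-square value (a pixel count).
#' @export
objective_binary <- function(params, binary) {
  data <- as_pixels(binary)
  model <- (radial_distance_image(params, dim(data)) <= params$r) * 1
  sum((model - data)^2)
}

# Fill empty histogram bins with the value of the nearest non-empty bin.
fill_nearest <- function(vals, centers) {
  miss <- is.na(vals)
  if (!any(miss)) return(vals)
  if (all(miss)) stop("profile has no occupied bins")
  have <- which(!miss)
  nearest <- have[pmax(1, apply(abs(outer(centers[miss], centers[have], "-")),
                                1, which.min))]
  vals[miss] <- vals[nearest]
  vals
}

#' Angularly averaged radial intensity profile
#'
#' Bins pixel intensities by their radial coordinate rc (histogram binning)
#' and averages within each bin, i.e. the intensity as a function of distance
#' from the midline, averaged along the angular coordinate. Empty bins carry
#' the nearest non-empty bin's value.
#'
#' @inheritParams coordinate_maps
#' @param image Intensity [image_element] or matrix (non-binary).
#' @param bin_width Radial bin width (px), default 0.5.
#' @param rc Optional precomputed rc image (saves recomputation).
#' @param mask Optional logical matrix restricting the contributing pixels.
#' @return A data.frame with columns `x` (bin centers, px), `mean`, `n`.
#' @export
radial_profile_of_image <- function(params, image, bin_width = 0.5,
                                    rc = NULL, mask = NULL) {
  px <- as_pixels(image)
  if (is.null(rc)) rc <- radial_distance_image(params, dim(px))
  v <- as.vector(px); rcv <- as.vector(rc)
  if (!is.null(mask)) {
    keep <- as.vector(mask)
    v <- v[keep]; rcv <- rcv[keep]
  }
  nb <- floor(max(rcv) / bin_width) + 1L
  idx <- pmin(floor(rcv / bin_width) + 1L, nb)
  n <- tabulate(idx, nb)
  s <- as.vector(rowsum(v, idx, reorder = TRUE))
  vals <- rep(NA_real_, nb)
  vals[sort(unique(idx))] <- s / n[n > 0]
  centers <- (seq_len(nb) - 0.5) * bin_width
  data.frame(x = centers, mean = fill_nearest(vals, centers), n = n)
}

#' Simulate an angularly isotropic image
#'
#' Replaces every pixel by the radial-profile value at its rc (linear
#' interpolation between bin centers): the isotropic image the current
#' coordinate system predicts from the measurement.
#'
#' @inheritParams radial_profile_of_image
#' @return Numeric matrix, a pure function of rc.
#' @export
simulate_isotropic_image <- function(params, image, bin_width = 0.5,
                                     rc = NULL, mask = NULL) {
  px <- as_pixels(image)
  if (is.null(rc)) rc <- radial_distance_image(params, dim(px))
  prof <- radial_profile_of_image(params, px, bin_width, rc = rc, mask = mask)
  sim <- stats::approx(prof$x, prof$mean, xout = as.vector(rc),
                       rule = 2)$y
  matrix(sim, nrow(px), ncol(px))
}

#' Image chi-square objective
#'
#' Squared difference between the measurement and its isotropic simulation
#' under the current coordinate system, summed over pixels with
#' `rc <= r + margin` (far background is excluded so it dominates neither
#' the profile nor the chi-square).
#'
#' @inheritParams radial_profile_of_image
#' @param margin Background exclusion margin beyond r (px), default 5.
#' @return Non-negative chi-square value.
#' @export
objective_image <- function(params, image, bin_width = 0.5, margin = 5) {
  px <- as_pixels(image)
  rc <- radial_distance_image(params, dim(px))
  mask <- rc <= params$r + margin
  if (!any(mask)) return(Inf)
  sim <- simulate_isotropic_image(params, px, bin_width, rc = rc, mask = mask)
  sum((px[mask] - sim[mask])^2)
}

#' Localization chi-square objective
#'
#' Sum of squared deviations between each localization's radial coordinate
#' and the radius: `chi2 = sum((rc_i - r)^2)`. Minimal when the isodistance
#' outline at r runs through the localization cloud.
#'
#' @inheritParams coordinate_maps
#' @param locs A non-empty [loc_table] in the cell frame.
#' @return Non-negative chi-square value (px^2).
#' @export
objective_localizations <- function(params, locs) {
  if (!nrow(locs)) stop("localization table is empty")
  rc <- map_to_cellular(params, locs$x, locs$y)$rc
  sum((rc - params$r)^2)
}

#' Half-maximum radius from a radial profile
#'
#' Takes the angularly averaged radial intensity profile, finds its peak and
#' far-field baseline (mean over the outermost bins), and returns the radial
#' position where the profile first crosses halfway between the two outward
#' of the peak, linearly interpolated between bins. Monotone profiles take
#' their peak at rc = 0. The default bin width is finer than the profile
#' chi-square's 0.5 px: the crossing interpolation is sensitive to binning
#' bias at the steep membrane edge.
#'
#' @inheritParams radial_profile_of_image
#' @return Radius estimate (px).
#' @export
fit_radius_halfmax <- function(params, image, bin_width = 0.25) {
  prof <- radial_profile_of_image(params, image, bin_width)
  v <- prof$mean
  if (max(v) - min(v) < sqrt(.Machine$double.eps) * max(abs(v), 1))
    stop("radial profile is flat; no half-maximum point")
  pk <- which.max(v)
  nb <- length(v)
  tail_n <- max(3L, ceiling(0.1 * nb))
  if (pk > nb - tail_n) stop("profile peak lies in the far field")
  baseline <- mean(v[(nb - tail_n + 1L):nb])
  half <- (v[pk] + baseline) / 2
  below <- which(v[(pk + 1L):nb] <= half)
  if (!length(below)) stop("profile never crosses its half-maximum")
  i <- pk + below[1]
  # linear interpolation between bins i-1 and i
  x0 <- prof$x[i - 1]; x1 <- prof$x[i]
  y0 <- v[i - 1]; y1 <- v[i]
  if (y0 == y1) return(x1)
  x0 + (half - y0) / (y1 - y0) * (x1 - x0)
}

params_to_vec <- function(p) c(p$a0, p$a1, p$a2, p$xl, p$xr, p$r)

vec_to_params <- function(v) {
  tryCatch(coord_params(v[1], v[2], v[3], v[4], v[5], v[6]),
           error = function(e) NULL)
}

# Characteristic Nelder-Mead step per parameter.
PAR_SCALE <- c(a0 = 1, a1 = 0.01, a2 = 1e-4, xl = 1, xr = 1, r = 0.5)

#' Refine a cell's coordinate system
#'
#' Runs a derivative-free Nelder-Mead search from the cell's current
#' parameters, minimizing the chi-square objective matching `method`:
#' `"binary"` and `"localizations"` optimize all six parameters; `"image"`
#' optimizes the five shape parameters and then sets the radius by the
#' half-maximum point of the radial intensity profile. The returned
#' chi-square never exceeds the starting chi-square.
#'
#' @param cell A [new_cell()] object with non-null `coords`.
#' @param element_name Name of the data element to fit against.
#' @param method One of `"binary"`, `"image"`, `"localizations"`.
#' @param bin_width Radial profile bin width for the image method (px).
#' @param maxit Maximum objective evaluations per Nelder-Mead pass.
#' @param restarts Nelder-Mead restarts from the incumbent (default 1).
#' @return An object of class `cc_fit` with fields `params`, `chi2`,
#'   `chi2_init`, `n_eval`, `converged`, `method`, and `cell` (the input
#'   cell with its coordinates replaced by the optimum).
#' @export
optimize_cell <- function(cell, element_name,
                          method = c("binary", "image", "localizations"),
                          bin_width = 0.5, maxit = 600, restarts = 1) {
  method <- match.arg(method)
  element <- get_element(cell, element_name)
  p0 <- cell$coords
  if (is.null(p0)) stop("cell has no coordinate parameters to start from")

  obj_full <- switch(method,
    binary = function(p) objective_binary(p, element),
    image = function(p) objective_image(p, element, bin_width = bin_width),
    localizations = function(p) objective_localizations(p, element))

  free <- if (method == "image") 1:5 else 1:6
  v0 <- params_to_vec(p0)
  chi0 <- obj_full(p0)
  if (!is.finite(chi0)) stop("objective is non-finite at the starting point")

  # large finite penalty keeps Nelder-Mead away from invalid geometries
  penalty <- (abs(chi0) + 1) * 1e6
  fn <- function(v) {
    full <- v0
    full[free] <- v
    p <- vec_to_params(full)
    if (is.null(p) || p$xr - p$xl < 1) return(penalty)
    val <- obj_full(p)
    if (!is.finite(val)) penalty else val
  }

  v <- v0[free]
  n_eval <- 0L
  conv <- FALSE
  for (i in seq_len(restarts + 1)) {
    res <- stats::optim(v, fn, method = "Nelder-Mead",
                        control = list(parscale = PAR_SCALE[free],
                                       reltol = 1e-6, maxit = maxit))
    v <- res$par
    n_eval <- n_eval + res$counts[["function"]]
    conv <- res$convergence == 0
  }

  best <- v0; best[free] <- v
  p_best <- vec_to_params(best)
  if (is.null(p_best)) p_best <- p0
  if (method == "image") {
    r_hm <- tryCatch(fit_radius_halfmax(p_best, element),
                     error = function(e) p_best$r)
    p_best <- coord_params(p_best$a0, p_best$a1, p_best$a2,
                           p_best$xl, p_best$xr, max(r_hm, 0.5))
  }
  chi_best <- obj_full(p_best)
  if (!is.finite(chi_best) || chi_best > chi0) {
    # never return a worse point than the start
    p_keep <- p0
    if (method == "image") {
      # keep the half-maximum radius even when the shape step is rejected
      r_hm <- tryCatch(fit_radius_halfmax(p0, element),
                       error = function(e) p0$r)
      p_alt <- coord_params(p0$a0, p0$a1, p0$a2, p0$xl, p0$xr,
                            max(r_hm, 0.5))
      if (isTRUE(obj_full(p_alt) <= chi0)) p_keep <- p_alt
    }
    p_best <- p_keep
    chi_best <- obj_full(p_best)
  }

  cell$coords <- p_best
  structure(list(params = p_best, chi2 = chi_best, chi2_init = chi0,
                 n_eval = n_eval, converged = conv, method = method,
                 cell = cell),
            class = "cc_fit")
}

#' @export
print.cc_fit <- function(x, ...) {
  cat(sprintf("<cc_fit %s> chi2 %.4g (start %.4g), %d evals, converged: %s\n",
              x$method, x$chi2, x$chi2_init, x$n_eval, x$converged))
  invisible(x)
}
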
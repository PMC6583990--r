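#' Axial distribution of a data element
#'
#' Distribution of an element along one cellular coordinate axis: image
#' elements are averaged (mean pixel intensity per bin), localization
#' elements are counted. The radial axis is in px, the longitudinal axis in
#' px over `[0, L]`, the angular axis in degrees over `[0, 180]`.
#'
#' @param cell A cell with fitted coordinates.
#' @param element_name Element to distribute.
#' @param axis One of `"radial"`, `"longitudinal"`, `"angular"`.
#' @param n_bins Number of bins (default 30).
#' @return A data.frame: `x` (bin centers), `mean` (mean intensity, image
#'   elements) or `count` (localizations), `n` (pixels/localizations per
#'   bin).
#' @export
axial_distribution <- function(cell, element_name,
                               axis = c("radial", "longitudinal", "angular"),
                               n_bins = 30) {
  axis <- match.arg(axis)
  element <- get_element(cell, element_name)
  params <- cell$coords
  if (is.null(params)) stop("cell has no coordinate parameters")

  if (inherits(element, "image_element")) {
    maps <- coordinate_maps(params, dim(element$pixels))
    coord <- switch(axis, radial = maps$rc, longitudinal = maps$lc,
                    angular = maps$phi)
    vals <- as.vector(element$pixels)
    coord <- as.vector(coord)
  } else {
    cc <- map_to_cellular(params, element$x, element$y)
    coord <- switch(axis, radial = cc$rc, longitudinal = cc$lc,
                    angular = cc$phi)
    vals <- NULL
  }
  upper <- switch(axis, radial = max(coord), longitudinal = cell_length(params),
                  angular = 180)
  upper <- max(upper, .Machine$double.eps)
  bw <- upper / n_bins
  idx <- pmin(pmax(floor(coord / bw) + 1L, 1L), n_bins)
  n <- tabulate(idx, n_bins)
  centers <- (seq_len(n_bins) - 0.5) * bw
  if (is.null(vals))
    return(data.frame(x = centers, count = n, n = n))
  s <- rep(NA_real_, n_bins)
  ss <- rowsum(vals, idx, reorder = TRUE)
  s[sort(unique(idx))] <- as.vector(ss) / n[n > 0]
  data.frame(x = centers, mean = fill_nearest(s, centers), n = n)
}

#' Ensemble radial distribution across cells
#'
#' Each cell's radial profile is computed on a normalized radial grid
#' (rc divided by the cell's fitted radius, so the membrane sits at x = 1)
#' and normalized in y by its own maximum; the ensemble mean and standard
#' deviation per bin are returned, so the spread reports only on profile
#' shape variation.
#'
#' @param cells A [cell_collection]; every cell needs a fitted radius.
#' @param element_name Image or localization element name.
#' @param n_bins Bins over the normalized radius (default 40).
#' @param x_max Upper edge of the normalized grid (default 2).
#' @return A data.frame: `x` (normalized radius), `mean`, `std`, `n`
#'   (contributing cells per bin).
#' @export
ensemble_radial_distribution <- function(cells, element_name, n_bins = 40,
                                         x_max = 2) {
  missing_r <- names(cells)[vapply(unclass(cells),
                                   function(c) is.null(c$coords), logical(1))]
  if (length(missing_r))
    stop("cells without a fitted radius: ",
         paste(missing_r, collapse = ", "))
  bw <- x_max / n_bins
  centers <- (seq_len(n_bins) - 0.5) * bw
  curves <- vapply(unclass(cells), function(cell) {
    element <- get_element(cell, element_name)
    r <- cell$coords$r
    if (inherits(element, "image_element")) {
      rc <- radial_distance_image(cell$coords, dim(element$pixels)) / r
      vals <- as.vector(element$pixels)
    } else {
      rc <- map_to_cellular(cell$coords, element$x, element$y)$rc / r
      vals <- rep(1, length(rc))
    }
    idx <- floor(as.vector(rc) / bw) + 1L
    keep <- idx >= 1L & idx <= n_bins
    idx <- idx[keep]; vals <- vals[keep]
    n <- tabulate(idx, n_bins)
    y <- rep(NA_real_, n_bins)
    if (inherits(element, "image_element")) {
      s <- rowsum(vals, idx, reorder = TRUE)
      y[sort(unique(idx))] <- as.vector(s) / n[n > 0]
      y <- fill_nearest(y, centers)
    } else {
      y <- n   # localization count profile
    }
    y / max(y)
  }, numeric(n_bins))
  curves <- matrix(curves, nrow = n_bins)
  data.frame(x = centers,
             mean = rowMeans(curves),
             std = apply(curves, 1, stats::sd),
             n = rowSums(!is.na(curves)))
}

#' Align many cells onto a model cell
#'
#' Transforms every pixel center (weight = intensity) or localization
#' (weight = intensity) of the chosen element into cellular coordinates,
#' rescales longitudinally by `L_model / L_cell` and radially by
#' `r_model / r_cell`, maps the result back to Cartesian coordinates in the
#' model-cell frame, and renders the weighted point cloud by summing
#' discrete 2-D Gaussians of width `sigma` (each stamp normalized to unit
#' discrete mass, truncated at 4 sigma), so total mass is conserved up to
#' frame clipping.
#'
#' @param cells A [cell_collection].
#' @param element_name Element to align.
#' @param model [coord_params] of the model cell.
#' @param sigma Gaussian render width (model px), default 0.5.
#' @param dim Output dimensions; when `NULL` the frame is sized to hold
#'   every rendered stamp, so mass is conserved exactly (a user-supplied
#'   `dim` may clip).
#' @param margin Image pixels farther than `r + margin` (px) from the
#'   midline are excluded: far background carries no shape information and
#'   would map outside the model cell.
#' @return Numeric matrix (the aligned image).
#' @export
align_cells <- function(cells, element_name, model, sigma = 0.5, dim = NULL,
                        margin = 2) {
  if (sigma <= 0) stop("'sigma' must be positive")
  L_model <- cell_length(model)
  xs <- numeric(0); ys <- numeric(0); ws <- numeric(0)
  for (cell in unclass(cells)) {
    params <- cell$coords
    if (is.null(params)) stop(sprintf("cell '%s' has no coordinates", cell$id))
    L_cell <- cell_length(params)
    if (L_cell <= 0) stop(sprintf("cell '%s' has zero length", cell$id))
    element <- get_element(cell, element_name)
    if (inherits(element, "image_element")) {
      nr <- nrow(element$pixels); ncx <- ncol(element$pixels)
      px <- rep(seq_len(ncx) - 0.5, each = nr)
      py <- rep(seq_len(nr) - 0.5, times = ncx)
      w <- as.vector(element$pixels)
      keep <- w != 0
      cc <- map_to_cellular(params, px[keep], py[keep])
      w <- w[keep]
      near <- cc$rc <= params$r + margin
      cc <- cc[near, , drop = FALSE]
      w <- w[near]
    } else {
      cc <- map_to_cellular(params, element$x, element$y)
      w <- element$intensity
    }
    lc <- pmin(cc$lc / L_cell, 1) * L_model
    rc <- cc$rc * model$r / params$r
    pt <- map_to_cartesian(model, lc, rc, cc$phi)
    xs <- c(xs, pt$xp); ys <- c(ys, pt$yp); ws <- c(ws, w)
  }
  if (is.null(dim)) {
    base <- frame_dim(model)
    hw <- ceiling(4 * sigma) + 1
    dim <- c(max(base[1], if (length(ys)) ceiling(max(ys)) + hw else 0),
             max(base[2], if (length(xs)) ceiling(max(xs)) + hw else 0))
  }
  render_gaussian_cloud(xs, ys, ws, dim, sigma)
}

# Sum of per-point discrete Gaussians; each point's stamp is normalized to
# its own discrete sum so the rendered mass equals sum(w) minus clipping.
render_gaussian_cloud <- function(x, y, w, dim, sigma) {
  nr <- dim[1]; nc <- dim[2]
  if (!length(x)) return(matrix(0, nr, nc))
  hw <- ceiling(4 * sigma)
  offs <- expand.grid(di = -hw:hw, dj = -hw:hw)
  i0 <- ceiling(y); j0 <- ceiling(x)
  np <- length(x)
  idx_all <- integer(0); val_all <- numeric(0); pid_all <- integer(0)
  for (k in seq_len(nrow(offs))) {
    ii <- i0 + offs$di[k]; jj <- j0 + offs$dj[k]
    cxx <- jj - 0.5; cyy <- ii - 0.5
    g <- exp(-((cxx - x)^2 + (cyy - y)^2) / (2 * sigma^2))
    ok <- ii >= 1 & ii <= nr & jj >= 1 & jj <= nc & g > 1e-12
    if (!any(ok)) next
    idx_all <- c(idx_all, (jj[ok] - 1L) * nr + ii[ok])
    val_all <- c(val_all, g[ok])
    pid_all <- c(pid_all, which(ok))
  }
  # per-point normalization over the full (unclipped) stamp
  full <- numeric(np)
  for (k in seq_len(nrow(offs))) {
    g <- exp(-(((j0 + offs$dj[k]) - 0.5 - x)^2 +
                 ((i0 + offs$di[k]) - 0.5 - y)^2) / (2 * sigma^2))
    full <- full + ifelse(g > 1e-12, g, 0)
  }
  val_all <- val_all * w[pid_all] / full[pid_all]
  acc <- rowsum(val_all, idx_all, reorder = TRUE)
  out <- numeric(nr * nc)
  out[as.integer(rownames(acc))] <- acc
  matrix(out, nr, nc)
}

#' Positions of localizations along the cell perimeter
#'
#' Maps each localization to its arc position along the closed isodistance
#' outline at distance r, measured clockwise from the start of the top
#' membrane segment (lc = 0, phi = 0, rc = r): top segment, right pole
#' (phi 0 to 180), bottom segment (back from L to 0), left pole (phi 180
#' back to 0). Positions are converted to nm and binned.
#'
#' @inheritParams coordinate_maps
#' @param locs A [loc_table] (expected near the outline; not enforced).
#' @param pixel_size nm per px (default 80).
#' @param bin_width Spatial bin width (nm), default 10.
#' @return A data.frame of class `perimeter_trace`: `position` (bin center,
#'   nm), `count`; attributes `perimeter` (nm), `bin_width` (nm) and
#'   `positions` (raw per-localization positions, nm).
#' @export
perimeter_positions <- function(params, locs, pixel_size = 80,
                                bin_width = 10) {
  og <- outline_geometry(params, params$r)
  cc <- map_to_cellular(params, locs$x, locs$y)
  L <- cell_length(params)
  b1 <- og$s_top; b2 <- b1 + og$pole; b3 <- b2 + og$s_bot

  s <- numeric(nrow(locs))
  at_r <- cc$xc == params$xr
  at_l <- cc$xc == params$xl
  body <- !(at_r | at_l)
  top <- body & cc$phi < 90
  bot <- body & !top
  if (any(top))
    s[top] <- stats::approx(og$xs, og$cum_top, xout = cc$xc[top], rule = 2)$y
  if (any(bot))
    s[bot] <- b2 + og$s_bot -
      stats::approx(og$xs, og$cum_bot, xout = cc$xc[bot], rule = 2)$y
  s[at_r] <- b1 + cc$phi[at_r] / 180 * og$pole
  s[at_l] <- b3 + (180 - cc$phi[at_l]) / 180 * og$pole
  s <- s %% og$total

  pos_nm <- s * pixel_size
  perim_nm <- og$total * pixel_size
  nb <- ceiling(perim_nm / bin_width)
  idx <- pmin(floor(pos_nm / bin_width) + 1L, nb)
  counts <- tabulate(idx, nb)
  out <- data.frame(position = (seq_len(nb) - 0.5) * bin_width,
                    count = counts)
  attr(out, "perimeter") <- perim_nm
  attr(out, "bin_width") <- bin_width
  attr(out, "positions") <- pos_nm
  class(out) <- c("perimeter_trace", "data.frame")
  out
}

#' Detrended spatial autocorrelation of a perimeter trace
#'
#' Unbiased autocorrelation of the binned counts over lags 0 to half the
#' perimeter, minus its centered moving average of width `window` — the
#' sliding-window subtraction removes the low-frequency envelope and leaves
#' the oscillatory component, with mean approximately zero.
#'
#' @param trace A `perimeter_trace` (or numeric count vector with a
#'   `bin_width` attribute / explicit `bin_width`).
#' @param window Sliding-window width (nm), default 150.
#' @param bin_width Bin width (nm); taken from the trace when `NULL`.
#' @return Numeric vector of detrended autocorrelation values, one per lag
#'   starting at lag 0; attribute `bin_width` carries the lag spacing (nm).
#' @export
autocorrelate_detrend <- function(trace, window = 150, bin_width = NULL) {
  if (inherits(trace, "perimeter_trace")) {
    v <- trace$count
    if (is.null(bin_width)) bin_width <- attr(trace, "bin_width")
  } else {
    v <- as.numeric(trace)
  }
  if (is.null(bin_width)) stop("'bin_width' is required")
  n <- length(v)
  wbins <- round(window / bin_width)
  if (wbins < 3) stop("window must span at least 3 bins")
  if (n < 2 * wbins) stop("trace too short for the requested window")
  nlag <- floor(n / 2)
  ac <- vapply(0:nlag, function(k)
    sum(v[seq_len(n - k)] * v[seq_len(n - k) + k]) / (n - k), numeric(1))
  # centered moving average, shrinking at the edges
  if (wbins %% 2 == 0) wbins <- wbins + 1
  half <- (wbins - 1) / 2
  m <- length(ac)
  ma <- vapply(seq_len(m), function(i) {
    lo <- max(1, i - half); hi <- min(m, i + half)
    mean(ac[lo:hi])
  }, numeric(1))
  out <- ac - ma
  attr(out, "bin_width") <- bin_width
  out
}

#' Dominant periodicity of a detrended signal
#'
#' Wavelength of the largest-amplitude Fourier component, excluding the
#' zero-frequency term. The spectrum is computed with 4x zero padding for
#' peak resolution.
#'
#' @param signal Detrended numeric signal (uniform spacing).
#' @param bin_width Sample spacing (nm); taken from the signal's attribute
#'   when `NULL`.
#' @return Wavelength (nm) of the dominant component.
#' @export
dominant_periodicity <- function(signal, bin_width = NULL) {
  if (is.null(bin_width)) bin_width <- attr(signal, "bin_width")
  if (is.null(bin_width)) stop("'bin_width' is required")
  v <- as.numeric(signal)
  if (all(v == 0)) stop("signal is identically zero")
  n <- length(v)
  np <- 4L * n
  sp <- Mod(stats::fft(c(v - mean(v), numeric(np - n))))
  ks <- seq_len(floor(np / 2))          # positive frequencies, k/np cycles/bin
  kmax <- ks[which.max(sp[ks + 1L])]
  np * bin_width / kmax
}

#' Write a profile, distribution or trace as delimited text
#'
#' @param x A data.frame (profile, distribution, trace, benchmark table).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
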
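#' Geometry sampling configuration
#'
#' Distributions (normal, truncated to bounds) for the geometric parameters
#' of synthetic rod cells. Defaults emulate E. coli imaged at 80 nm/px:
#' radius ~ N(5, 0.5) px, midline chord length ~ N(25, 5) px truncated above
#' 10 px, curvature a2 ~ N(0, 0.004) px^-1.
#'
#' @param r_mean,r_sd Radius distribution (px).
#' @param length_mean,length_sd Midline chord length `xr - xl` (px).
#' @param a2_mean,a2_sd Curvature coefficient (px^-1).
#' @param r_bounds,length_bounds,a2_bounds Truncation bounds.
#' @param pixel_size Physical pixel size (nm/px), default 80.
#' @return A list of class `geometry_config`.
#' @export
geometry_config <- function(r_mean = 5, r_sd = 0.5,
                            length_mean = 25, length_sd = 5,
                            a2_mean = 0, a2_sd = 0.004,
                            r_bounds = c(2, 10),
                            length_bounds = c(10, 60),
                            a2_bounds = c(-0.015, 0.015),
                            pixel_size = 80) {
  stopifnot(r_sd >= 0, length_sd >= 0, a2_sd >= 0,
            r_bounds[1] > 0, length_bounds[1] > 0, pixel_size > 0)
  structure(list(r_mean = r_mean, r_sd = r_sd,
                 length_mean = length_mean, length_sd = length_sd,
                 a2_mean = a2_mean, a2_sd = a2_sd,
                 r_bounds = r_bounds, length_bounds = length_bounds,
                 a2_bounds = a2_bounds, pixel_size = pixel_size),
            class = "geometry_config")
}

rtruncnorm1 <- function(mean, sd, bounds, max_tries = 1000) {
  if (sd == 0) {
    if (mean < bounds[1] || mean > bounds[2])
      stop("degenerate distribution mean outside bounds")
    return(mean)
  }
  for (i in seq_len(max_tries)) {
    v <- stats::rnorm(1, mean, sd)
    if (v >= bounds[1] && v <= bounds[2]) return(v)
  }
  stop("could not satisfy geometry bounds after 1000 draws")
}

#' Sample one synthetic cell geometry
#'
#' Draws radius, chord length and curvature from the configured truncated
#' normals and places the cell in its own frame: the midline is levelled
#' (slope zero at its center) and offset so the outline clears the frame
#' border by a fixed margin. Uses the R session RNG; seed via `set.seed()`
#' for reproducibility.
#'
#' @param config A [geometry_config].
#' @param margin Frame clearance margin (px), default 3.
#' @return A [coord_params] object positioned in its own frame.
#' @export
sample_geometry <- function(config, margin = 3) {
  r <- rtruncnorm1(config$r_mean, config$r_sd, config$r_bounds)
  len <- rtruncnorm1(config$length_mean, config$length_sd, config$length_bounds)
  a2 <- rtruncnorm1(config$a2_mean, config$a2_sd, config$a2_bounds)
  xl <- r + margin
  xr <- xl + len
  a1 <- -a2 * (xl + xr)          # slope zero at the midline center
  # offset so the lowest midline point sits margin + r below y = 0
  xs <- seq(xl, xr, length.out = 101)
  rel <- a1 * xs + a2 * xs^2
  a0 <- r + margin - min(rel)
  coord_params(a0 = a0, a1 = a1, a2 = a2, xl = xl, xr = xr, r = r)
}

# Frame just enclosing the outline at distance d plus margin.
frame_dim <- function(params, margin = 3, d = params$r) {
  xs <- seq(params$xl, params$xr, length.out = 201)
  ys <- midline_y(params, xs)
  nr <- ceiling(max(ys) + d + margin)
  nc <- ceiling(params$xr + d + margin)
  c(nr, nc)
}

#' Render the exact binary of a cell
#'
#' Pixel = 1 iff the pixel center's radial coordinate satisfies `rc <= r`.
#'
#' @inheritParams coordinate_maps
#' @param dim Frame dimensions; computed from the geometry when `NULL`.
#' @return A binary [image_element].
#' @export
render_binary <- function(params, dim = NULL) {
  if (is.null(dim)) dim <- frame_dim(params)
  bin <- (radial_distance_image(params, dim) <= params$r) * 1
  if (any(bin[1, ] > 0) || any(bin[nrow(bin), ] > 0) ||
      any(bin[, 1] > 0) || any(bin[, ncol(bin)] > 0))
    stop("cell is clipped by the frame")
  image_element(bin, "binary", "binary")
}

#' Radial intensity function for synthetic brightfield images
#'
#' Returns the normalized (background = 1) radial intensity as a function of
#' rc. The default `"edge"` shape is a logistic step centered at the
#' membrane radius — interior brighter than background by `contrast`, with
#' the half-maximum point exactly at r, so the half-maximum radius
#' convention recovers the membrane radius by construction. The `"ring"`
#' shape is a Gaussian membrane ring centered at r. The peak-to-background
#' contrast is held constant across photon levels.
#'
#' @param shape `"edge"` or `"ring"`.
#' @param contrast Peak intensity above background (background = 1).
#' @param width Edge/ring width scale (px).
#' @return `function(rc, r)` returning normalized intensity.
#' @export
brightfield_profile <- function(shape = c("edge", "ring"),
                                contrast = 0.5, width = 1.5) {
  shape <- match.arg(shape)
  if (shape == "edge") {
    s <- width / 2
    function(rc, r) 1 + contrast / (1 + exp((rc - r) / s))
  } else {
    function(rc, r) 1 + contrast * exp(-(rc - r)^2 / (2 * width^2))
  }
}

#' Render a noisy synthetic brightfield image
#'
#' Noiseless model: `photons * profile(rc, r)` with background level 1.
#' Shot noise is simulated by drawing each pixel from a Poisson distribution
#' with the noiseless value as mean; finally Gaussian read noise of standard
#' deviation `read_noise` photon counts is added. With `noise = FALSE`
#' (expectation mode) the noiseless model is returned exactly.
#'
#' @inheritParams render_binary
#' @param photons Background photon count (paper conditions: 500, 1000,
#'   10000).
#' @param profile Radial intensity function from [brightfield_profile()].
#' @param read_noise Gaussian read-noise sd (photons), default 20.
#' @param noise Draw shot and read noise (default TRUE).
#' @return A brightfield [image_element].
#' @export
render_brightfield <- function(params, photons, dim = NULL,
                               profile = brightfield_profile(),
                               read_noise = 20, noise = TRUE) {
  stopifnot(photons > 0)
  if (is.null(dim)) dim <- frame_dim(params)
  rc <- radial_distance_image(params, dim)
  img <- photons * profile(rc, params$r)
  if (noise) {
    img <- matrix(stats::rpois(length(img), as.vector(img)), dim[1], dim[2])
    img <- img + matrix(stats::rnorm(length(img), 0, read_noise),
                        dim[1], dim[2])
  }
  image_element(img, "brightfield", "brightfield")
}

# Geometry of the closed isodistance outline at distance d from the midline:
# cumulative arc length along the top and bottom offset curves (fine-grid
# chordal integration) plus the two semicircular pole caps of radius d.
outline_geometry <- function(params, d, n_grid = 1501) {
  xs <- seq(params$xl, params$xr, length.out = n_grid)
  fr <- midline_frame(params, xs)
  ys <- midline_y(params, xs)
  seg_len <- function(ox, oy) c(0, cumsum(sqrt(diff(ox)^2 + diff(oy)^2)))
  top_x <- xs + d * fr$nx; top_y <- ys + d * fr$ny
  bot_x <- xs - d * fr$nx; bot_y <- ys - d * fr$ny
  cum_top <- seg_len(top_x, top_y)
  cum_bot <- seg_len(bot_x, bot_y)
  list(xs = xs, cum_top = cum_top, cum_bot = cum_bot,
       s_top = cum_top[n_grid], s_bot = cum_bot[n_grid],
       pole = pi * d,
       total = cum_top[n_grid] + cum_bot[n_grid] + 2 * pi * d)
}

# Convert positions s along the closed outline (clockwise from the start of
# the top segment) into cellular coordinates (lc, phi) at radius d.
outline_s_to_cellular <- function(params, og, s, d) {
  L <- cell_length(params)
  n <- length(s)
  lc <- numeric(n); phi <- numeric(n)
  b1 <- og$s_top                 # end of top segment
  b2 <- b1 + og$pole             # end of right pole
  b3 <- b2 + og$s_bot            # end of bottom segment
  seg <- findInterval(s, c(b1, b2, b3))  # 0 top, 1 right pole, 2 bottom, 3 left pole
  if (any(seg == 0)) {
    xc <- stats::approx(og$cum_top, og$xs, xout = s[seg == 0], rule = 2)$y
    lc[seg == 0] <- arc_length(params, params$xl, xc)
    phi[seg == 0] <- 0
  }
  if (any(seg == 1)) {
    lc[seg == 1] <- L
    phi[seg == 1] <- (s[seg == 1] - b1) / og$pole * 180
  }
  if (any(seg == 2)) {
    # bottom segment runs from xr back to xl
    xc <- stats::approx(og$cum_bot, og$xs,
                        xout = og$s_bot - (s[seg == 2] - b2), rule = 2)$y
    lc[seg == 2] <- arc_length(params, params$xl, xc)
    phi[seg == 2] <- 180
  }
  if (any(seg == 3)) {
    lc[seg == 3] <- 0
    phi[seg == 3] <- 180 - (s[seg == 3] - b3) / og$pole * 180
  }
  list(lc = pmin(pmax(lc, 0), L), phi = pmin(pmax(phi, 0), 180))
}

#' Sample membrane-localized SMLM data
#'
#' Draws localizations homogeneously along the closed isodistance outline at
#' `mean_radius` and scatters them radially with Gaussian noise of standard
#' deviation `sigma` (paper condition: 0.25 px = 20 nm at 80 nm/px).
#'
#' @inheritParams coordinate_maps
#' @param mean_radius Mean radial distance of the membrane (px).
#' @param sigma Radial scatter sd (px).
#' @param n Number of localizations.
#' @param modulation_period Optional spatial period (nm) of a cosine
#'   intensity modulation along the perimeter (emulates periodic membrane
#'   fine structure); `NULL` for homogeneous sampling.
#' @param modulation_depth Relative modulation amplitude in (0, 1].
#' @param pixel_size nm per px, used only for the modulation period.
#' @return A [loc_table] with exactly `n` rows in the cell frame.
#' @export
sample_membrane_localizations <- function(params, mean_radius,
                                          sigma = 0.25, n = 200,
                                          modulation_period = NULL,
                                          modulation_depth = 0.8,
                                          pixel_size = 80) {
  stopifnot(n > 0, mean_radius > 0, sigma >= 0)
  og <- outline_geometry(params, mean_radius)
  if (is.null(modulation_period)) {
    s <- stats::runif(n, 0, og$total)
  } else {
    # rejection sampling from density 1 + depth * cos(2 pi s / period)
    s <- numeric(0)
    period_px <- modulation_period / pixel_size
    while (length(s) < n) {
      cand <- stats::runif(2L * n, 0, og$total)
      acc <- stats::runif(2L * n) <
        (1 + modulation_depth * cos(2 * pi * cand / period_px)) /
          (1 + modulation_depth)
      s <- c(s, cand[acc])
    }
    s <- s[seq_len(n)]
  }
  cc <- outline_s_to_cellular(params, og, s, mean_radius)
  rc <- pmax(mean_radius + stats::rnorm(n, 0, sigma), 0)
  pt <- map_to_cartesian(params, cc$lc, rc, cc$phi)
  loc_table(x = pt$xp, y = pt$yp, frame = 1L, intensity = 1)
}

#' Build one ground-truth synthetic cell
#'
#' A synthetic cell with known true parameters: an exact binary
#' (`rc <= r`), optionally a noisy brightfield image, and inner/outer
#' membrane localization tables. The inner membrane sits at
#' `inner_frac * r` (default 0.9); the outer element 100 nm further out.
#'
#' @param params True [coord_params]; sampled from `geometry` when `NULL`.
#' @param geometry A [geometry_config] used when `params` is `NULL`.
#' @param photons Brightfield photon count, or `NULL` to skip brightfield.
#' @param n_locs Localizations per membrane element (default 200).
#' @param sigma Radial localization scatter sd (px), default 0.25.
#' @param inner_frac Inner membrane radius as a fraction of r.
#' @param id Cell id.
#' @param profile Brightfield radial intensity function.
#' @param read_noise Brightfield read-noise sd (photons).
#' @return A list of class `gt_cell`: `id`, `params`, `r_inner`, `r_outer`,
#'   and `elements` (binary, optional brightfield, storm_inner, storm_outer).
#' @export
synthetic_cell <- function(params = NULL, geometry = geometry_config(),
                           photons = NULL, n_locs = 200, sigma = 0.25,
                           inner_frac = 0.9, id = "synthetic",
                           profile = brightfield_profile(),
                           read_noise = 20) {
  if (is.null(params)) params <- sample_geometry(geometry)
  dim <- frame_dim(params)
  r_inner <- inner_frac * params$r
  r_outer <- r_inner + 100 / geometry$pixel_size
  elements <- list(binary = render_binary(params, dim))
  if (!is.null(photons))
    elements$brightfield <- render_brightfield(params, photons, dim,
                                               profile = profile,
                                               read_noise = read_noise)
  elements$storm_inner <- sample_membrane_localizations(params, r_inner,
                                                        sigma, n_locs)
  elements$storm_outer <- sample_membrane_localizations(params, r_outer,
                                                        sigma, n_locs)
  structure(list(id = id, params = params, r_inner = r_inner,
                 r_outer = r_outer, elements = elements),
            class = "gt_cell")
}

#' Degrade a binary with boundary noise
#'
#' Emulates imperfect segmentation: pixels within `band` px of the outline
#' (in radial distance) are re-assigned foreground/background at random with
#' probability `p_flip`, producing a rough, slightly eroded/dilated mask.
#'
#' @inheritParams coordinate_maps
#' @param binary Binary [image_element] or matrix.
#' @param band Half-width of the boundary band (px), default 1.
#' @param p_flip Re-assignment probability inside the band, default 0.5.
#' @return A degraded binary [image_element].
#' @export
degrade_binary <- function(binary, params, band = 1, p_flip = 0.5) {
  m <- as_pixels(binary)
  rc <- radial_distance_image(params, dim(m))
  in_band <- abs(rc - params$r) <= band
  out <- m
  flip <- in_band & matrix(stats::runif(length(m)) < p_flip, nrow(m))
  out[flip] <- stats::rbinom(sum(flip), 1, 0.5)
  if (sum(out) < 4) out <- m   # keep a usable mask
  image_element(out, "binary", "binary")
}

#' Field composition configuration
#'
#' @param dim Field dimensions (px), default 512 x 512 (40 um at 80 nm/px).
#' @param n_mean,n_sd Cells per field ~ round(N(10, 3)), clipped at 0.
#' @param min_dist Minimum binary-to-binary distance (px), default 5.
#' @param photons Brightfield background photon count.
#' @param read_noise Gaussian read-noise sd (photons).
#' @param pixel_size nm per px.
#' @param max_tries Placement retries per cell before giving up.
#' @return A list of class `field_config`.
#' @export
field_config <- function(dim = c(512, 512), n_mean = 10, n_sd = 3,
                         min_dist = 5, photons = 1000, read_noise = 20,
                         pixel_size = 80, max_tries = 60) {
  stopifnot(min_dist >= 0, photons > 0)
  structure(list(dim = dim, n_mean = n_mean, n_sd = n_sd,
                 min_dist = min_dist, photons = photons,
                 read_noise = read_noise, pixel_size = pixel_size,
                 max_tries = max_tries),
            class = "field_config")
}

#' Sample per-field cell counts
#'
#' @param n Number of fields.
#' @param mean,sd Count distribution parameters (default 10 +/- 3).
#' @return Integer vector: `pmax(0, round(rnorm(n, mean, sd)))`.
#' @export
sample_cell_count <- function(n, mean = 10, sd = 3) {
  pmax(0L, as.integer(round(stats::rnorm(n, mean, sd))))
}

#' Compose a synthetic field of cells
#'
#' Randomly rotates and places ground-truth cells in a field, enforcing the
#' configured minimum distance between binaries, and renders the labelled
#' mask, the noisy brightfield and the combined localization table (in
#' full-frame px, with `truth_id` and `element` columns retained).
#'
#' @param gt_cells List of [synthetic_cell()] objects to draw from
#'   (with replacement).
#' @param config A [field_config].
#' @param n_cells Cells to attempt; sampled from the count distribution when
#'   `NULL`.
#' @param profile Brightfield radial intensity function.
#' @return A list: `mask` (labelled matrix), `brightfield`
#'   ([image_element]), `localizations` ([loc_table] with `truth_id`),
#'   `placements` (data.frame: label, cell index, position, angle,
#'   centroid, localization count).
#' @export
compose_field <- function(gt_cells, config = field_config(), n_cells = NULL,
                          profile = brightfield_profile()) {
  if (!length(gt_cells)) stop("need at least one ground-truth cell")
  nr <- config$dim[1]; nc <- config$dim[2]
  if (is.null(n_cells)) n_cells <- sample_cell_count(1, config$n_mean, config$n_sd)
  mask <- matrix(0L, nr, nc)
  bf <- matrix(1, nr, nc)
  fg_x <- numeric(0); fg_y <- numeric(0)
  locs <- list(); placements <- list()
  label <- 0L

  for (k in seq_len(n_cells)) {
    ci <- sample.int(length(gt_cells), 1)
    gt <- gt_cells[[ci]]
    p <- gt$params
    ext <- max(frame_dim(p, margin = 0)) / 2 + 2   # rotated half-extent
    placed <- FALSE
    for (try in seq_len(config$max_tries)) {
      ang <- stats::runif(1, 0, 360)
      cx <- stats::runif(1, ext, nc - ext)
      cy <- stats::runif(1, ext, nr - ext)
      # field pixels in the candidate bounding box, pulled back to the cell
      # frame and classified by the exact geometry
      j0 <- max(1L, floor(cx - ext)); j1 <- min(nc, ceiling(cx + ext))
      i0 <- max(1L, floor(cy - ext)); i1 <- min(nr, ceiling(cy + ext))
      jj <- rep(j0:j1, each = i1 - i0 + 1)
      ii <- rep(i0:i1, times = j1 - j0 + 1)
      fdim <- frame_dim(p)
      cen <- c(fdim[2] / 2, fdim[1] / 2)
      src <- rotate_points(jj - 0.5, ii - 0.5, -ang, c(cx, cy), cen)
      cc <- map_to_cellular(p, src$x, src$y)
      fg <- cc$rc <= p$r
      if (!any(fg)) next
      nx <- (jj - 0.5)[fg]; ny <- (ii - 0.5)[fg]
      if (length(fg_x)) {
        near <- abs(fg_x - cx) < ext + config$min_dist + 2 &
          abs(fg_y - cy) < ext + config$min_dist + 2
        if (any(near)) {
          d2min <- min_cross_dist2(nx, ny, fg_x[near], fg_y[near])
          if (d2min < config$min_dist^2) next
        }
      }
      # accept placement
      label <- label + 1L
      mask[cbind(ii[fg], jj[fg])] <- label
      bf[cbind(ii, jj)] <- bf[cbind(ii, jj)] +
        (profile(cc$rc, p$r) - 1)
      fg_x <- c(fg_x, nx); fg_y <- c(fg_y, ny)
      cl <- list()
      for (nm in c("storm_inner", "storm_outer")) {
        lt <- gt$elements[[nm]]
        q <- rotate_points(lt$x, lt$y, ang, cen, c(cx, cy))
        cl[[nm]] <- data.frame(x = q$x, y = q$y, frame = lt$frame,
                               intensity = lt$intensity,
                               element = nm, truth_id = label)
      }
      locs[[length(locs) + 1L]] <- do.call(rbind, cl)
      placements[[length(placements) + 1L]] <- data.frame(
        truth_id = label, cell_index = ci, x = cx, y = cy, angle = ang,
        centroid_x = mean(nx), centroid_y = mean(ny),
        n_locs = sum(vapply(cl, nrow, integer(1))))
      placed <- TRUE
      break
    }
    if (!placed)
      message(sprintf("field composition: cell %d could not be placed", k))
  }

  bf <- bf * config$photons
  bf <- matrix(stats::rpois(length(bf), as.vector(bf)), nr, nc) +
    matrix(stats::rnorm(length(bf), 0, config$read_noise), nr, nc)
  loc_all <- if (length(locs)) do.call(rbind, locs) else
    data.frame(x = numeric(0), y = numeric(0), frame = integer(0),
               intensity = numeric(0), element = character(0),
               truth_id = integer(0))
  class(loc_all) <- c("loc_table", "data.frame")
  placements <- if (length(placements)) do.call(rbind, placements) else
    data.frame(truth_id = integer(0), cell_index = integer(0),
               x = numeric(0), y = numeric(0), angle = numeric(0),
               centroid_x = numeric(0), centroid_y = numeric(0),
               n_locs = integer(0))
  list(mask = mask,
       brightfield = image_element(bf, "brightfield", "brightfield"),
       localizations = loc_all,
       placements = placements)
}

# Squared minimum distance between two 2-D point sets (blocked to bound
# memory).
min_cross_dist2 <- function(ax, ay, bx, by, block = 2000L) {
  best <- Inf
  nb <- length(bx)
  for (s in seq(1L, nb, by = block)) {
    e <- min(s + block - 1L, nb)
    d2 <- outer(ax, bx[s:e], "-")^2 + outer(ay, by[s:e], "-")^2
    best <- min(best, min(d2))
  }
  best
}

#' Match measured cells back to ground truth
#'
#' Greedy nearest-centroid matching between placement records and measured
#' cells, gated at `gate` px. Measured cells whose localization count falls
#' below `min_recovery` of their truth counterpart are flagged for
#' discarding.
#'
#' @param placements Placement records from [compose_field()].
#' @param measured A [cell_collection] from [extract_cells()] on the field.
#' @param gate Maximum centroid distance for a match (px), default 5.
#' @param min_recovery Minimum measured/truth localization fraction.
#' @return A list: `pairs` (data.frame truth_id, measured_id, dist,
#'   recovery, flagged), `unmatched_truth`, `unmatched_measured`.
#' @export
match_measured_to_truth <- function(placements, measured, gate = 5,
                                    min_recovery = 0.5) {
  if (!nrow(placements) || !length(measured))
    stop("both truth placements and measured cells are required")
  mc <- t(vapply(unclass(measured),
                 function(cell) cell$meta$centroid_frame, numeric(2)))
  d <- sqrt(outer(placements$centroid_x, mc[, 1], "-")^2 +
            outer(placements$centroid_y, mc[, 2], "-")^2)
  pairs <- list()
  while (TRUE) {
    if (!any(is.finite(d)) || min(d, na.rm = TRUE) > gate) break
    ij <- arrayInd(which.min(d), dim(d))
    ti <- ij[1]; mi <- ij[2]
    cell <- measured[[mi]]
    n_meas <- if (!is.null(cell$elements$localizations))
      nrow(cell$elements$localizations) else 0L
    n_truth <- placements$n_locs[ti]
    rec <- if (n_truth > 0) n_meas / n_truth else NA_real_
    pairs[[length(pairs) + 1L]] <- data.frame(
      truth_id = placements$truth_id[ti],
      measured_id = cell$id,
      dist = d[ti, mi],
      recovery = rec,
      flagged = is.na(rec) || rec < min_recovery)
    d[ti, ] <- Inf
    d[, mi] <- Inf
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(truth_id = integer(0), measured_id = character(0),
               dist = numeric(0), recovery = numeric(0), flagged = logical(0))
  list(pairs = pairs,
       unmatched_truth = setdiff(placements$truth_id, pairs$truth_id),
       unmatched_measured = setdiff(names(measured), pairs$measured_id))
}

#' Relative chi-square of a fitted coordinate system
#'
#' The localization chi-square at the measured parameters divided by its
#' value at the ground-truth parameters; 1 indicates a perfectly fitted
#' coordinate system.
#'
#' @param measured_params,true_params [coord_params] objects.
#' @param locs A non-empty [loc_table].
#' @return The chi-square ratio.
#' @export
relative_chi2 <- function(measured_params, true_params, locs) {
  denom <- objective_localizations(true_params, locs)
  if (denom < 1e-12)
    stop("ground-truth chi-square is zero; cannot normalize")
  objective_localizations(measured_params, locs) / denom
}

#' Benchmark the coordinate-system pipeline on synthetic cells
#'
#' Generates `n_cells` ground-truth cells, degrades their binaries to
#' emulate imperfect segmentation, derives initial guesses from the degraded
#' binaries, optimizes per requested method, and scores each fit by the
#' relative chi-square against the inner-membrane localizations and by the
#' radial-coordinate errors of all membrane localizations (normalized to the
#' true inner-membrane radius). The ground-truth coordinate system for the
#' localization chi-square carries the inner-membrane radius, the value a
#' perfect localization fit recovers.
#'
#' @param n_cells Cells per method.
#' @param methods Subset of `c("binary", "image", "localizations")`.
#' @param photons Brightfield photon count (used by the image method).
#' @param geometry A [geometry_config].
#' @param n_locs,sigma,inner_frac Localization generation settings.
#' @param seed Optional RNG seed (applies to the whole run).
#' @param degrade Degrade binaries before guessing (default TRUE).
#' @param maxit Nelder-Mead iteration budget per fit.
#' @return A data.frame, one row per cell x method: relative chi-square,
#'   recovered and true radii, and the localization radial-deviation
#'   summaries `d_mean` (absolute mean deviation), `d_rms` (root mean
#'   squared deviation) and `med_abs_dev`, all relative to the true
#'   inner-membrane radius.
#' @export
run_benchmark <- function(n_cells = 100,
                          methods = c("binary", "image", "localizations"),
                          photons = 10000,
                          geometry = geometry_config(),
                          n_locs = 200, sigma = 0.25, inner_frac = 0.9,
                          seed = NULL, degrade = TRUE, maxit = 600) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (!is.null(seed)) set.seed(seed)
  need_bf <- "image" %in% methods
  rows <- list()
  for (i in seq_len(n_cells)) {
    gt <- synthetic_cell(geometry = geometry,
                         photons = if (need_bf) photons else NULL,
                         n_locs = n_locs, sigma = sigma,
                         inner_frac = inner_frac,
                         id = sprintf("gt_%04d", i))
    seg <- if (degrade) degrade_binary(gt$elements$binary, gt$params)
           else gt$elements$binary
    guess <- tryCatch(initial_coordinate_guess(seg), error = function(e) NULL)
    if (is.null(guess)) next
    truth_storm <- coord_params(gt$params$a0, gt$params$a1, gt$params$a2,
                                gt$params$xl, gt$params$xr, gt$r_inner)
    inner <- gt$elements$storm_inner
    all_locs <- rbind(gt$elements$storm_inner, gt$elements$storm_outer)
    rc_true <- map_to_cellular(gt$params, all_locs$x, all_locs$y)$rc

    for (m in methods) {
      elements <- list(binary = seg)
      el_name <- switch(m, binary = "binary", image = "brightfield",
                        localizations = "storm_inner")
      if (m == "image") elements$brightfield <- gt$elements$brightfield
      if (m == "localizations") elements$storm_inner <- inner
      cell <- new_cell(gt$id, coords = guess, elements = elements)
      fit <- tryCatch(
        optimize_cell(cell, el_name, method = m, maxit = maxit),
        error = function(e) NULL)
      if (is.null(fit)) {
        message(sprintf("benchmark: %s fit failed for %s", m, gt$id))
        next
      }
      rel <- relative_chi2(fit$params, truth_storm, inner)
      rc_fit <- map_to_cellular(fit$params, all_locs$x, all_locs$y)$rc
      dev <- (rc_fit - rc_true) / gt$r_inner
      rows[[length(rows) + 1L]] <- data.frame(
        cell = gt$id, method = m, photons = if (need_bf) photons else NA,
        rel_chi2 = rel,
        r_est = fit$params$r,
        r_true_cell = gt$params$r,
        r_true_inner = gt$r_inner,
        d_mean = mean(abs(dev)),
        d_rms = sqrt(mean(dev^2)),
        med_abs_dev = stats::median(abs(dev)),
        converged = fit$converged,
        n_eval = fit$n_eval)
    }
  }
  if (!length(rows)) stop("benchmark produced no results")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
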
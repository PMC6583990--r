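#' Image data element
#'
#' A named 2-D intensity array attached to a cell. Binary elements contain
#' only 0/1; brightfield and fluorescence elements carry photon counts or
#' arbitrary intensities.
#'
#' @param pixels Numeric matrix (row = y, col = x, y-down).
#' @param role One of `"binary"`, `"brightfield"`, `"fluorescence"`.
#' @param name Element label; defaults to the role.
#' @return An object of class `image_element`.
#' @export
image_element <- function(pixels,
                          role = c("fluorescence", "binary", "brightfield"),
                          name = NULL) {
  role <- match.arg(role)
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("'pixels' must be a numeric matrix")
  if (role == "binary" && !all(pixels %in% c(0, 1)))
    stop("binary elements may contain only 0 and 1")
  structure(list(pixels = pixels, role = role,
                 name = if (is.null(name)) role else name),
            class = "image_element")
}

#' @export
print.image_element <- function(x, ...) {
  cat(sprintf("<image_element '%s' (%s), %d x %d>\n",
              x$name, x$role, nrow(x$pixels), ncol(x$pixels)))
  invisible(x)
}

#' Localization table
#'
#' Sparse SMLM/STORM data: one row per fitted fluorophore position, in pixel
#' units of the owning frame.
#'
#' @param x,y Coordinates (px).
#' @param frame Acquisition frame index (default 1).
#' @param intensity Photon count per localization (default 1).
#' @param ... Further per-localization columns, carried along untouched.
#' @return A data.frame of class `loc_table`.
#' @export
loc_table <- function(x = numeric(0), y = numeric(0),
                      frame = 1L, intensity = 1, ...) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (length(x) && (!all(is.finite(x)) || !all(is.finite(y))))
    stop("localization coordinates must be finite")
  d <- data.frame(x = x, y = y,
                  frame = rep_len(frame, length(x)),
                  intensity = rep_len(intensity, length(x)), ...)
  class(d) <- c("loc_table", "data.frame")
  d
}

is_loc_table <- function(x) inherits(x, "loc_table")

#' Single-cell object
#'
#' One cropped, horizontally oriented cell: a named collection of data
#' elements (exactly one binary image, optional further image channels and
#' localization tables) plus its coordinate-system parameters.
#'
#' @param id Cell label.
#' @param coords A [coord_params] object (may be `NULL` until guessed).
#' @param elements Named list of [image_element] / [loc_table] objects.
#' @param meta Optional provenance list (source label, crop origin, rotation
#'   angle, full-frame centroid), filled by [extract_cells()].
#' @return An object of class `cc_cell`.
#' @export
new_cell <- function(id, coords = NULL, elements = list(), meta = list()) {
  nb <- sum(vapply(elements, function(e)
    inherits(e, "image_element") && e$role == "binary", logical(1)))
  if (nb != 1L) stop("a cell needs exactly one binary element")
  dims <- lapply(Filter(function(e) inherits(e, "image_element"), elements),
                 function(e) dim(e$pixels))
  if (length(unique(dims)) > 1L)
    stop("all image elements of a cell must share dimensions")
  structure(list(id = as.character(id), coords = coords,
                 elements = elements, meta = meta),
            class = "cc_cell")
}

cell_binary <- function(cell) {
  for (e in cell$elements)
    if (inherits(e, "image_element") && e$role == "binary") return(e)
  stop("cell has no binary element")
}

get_element <- function(cell, name) {
  e <- cell$elements[[name]]
  if (is.null(e)) stop(sprintf("cell '%s' has no element '%s'", cell$id, name))
  e
}

#' @export
print.cc_cell <- function(x, ...) {
  cat(sprintf("<cell '%s'> elements: %s\n", x$id,
              paste(names(x$elements), collapse = ", ")))
  if (!is.null(x$coords)) print(x$coords)
  invisible(x)
}

#' Ordered collection of cells
#'
#' @param cells List of [new_cell()] objects with unique ids.
#' @return An object of class `cell_collection`.
#' @export
cell_collection <- function(cells = list()) {
  ids <- unname(vapply(cells, function(c) c$id, character(1)))
  if (anyDuplicated(ids)) stop("cell ids must be unique")
  structure(cells, class = "cell_collection", names = ids)
}

#' @export
`[.cell_collection` <- function(x, i) {
  cell_collection(unclass(x)[i])
}

#' @export
print.cell_collection <- function(x, ...) {
  cat(sprintf("<cell_collection of %d cells>\n", length(x)))
  invisible(x)
}

#' Principal-axis orientation of a binary image
#'
#' Angle of the long axis from second-order central image moments,
#' `theta = atan2(2*mu11, mu20 - mu02) / 2`, in degrees in (-90, 90].
#' Positive angles run from the +x axis toward +y (downward on screen).
#'
#' @param binary An [image_element] with role binary, or a 0/1 matrix.
#' @return Orientation angle in degrees.
#' @export
orientation_angle <- function(binary) {
  m <- if (inherits(binary, "image_element")) binary$pixels else binary
  idx <- which(m > 0, arr.ind = TRUE)
  if (nrow(idx) < 2L) stop("need at least 2 foreground pixels")
  x <- idx[, 2] - 0.5
  y <- idx[, 1] - 0.5
  xm <- x - mean(x); ym <- y - mean(y)
  mu11 <- mean(xm * ym)
  mu20 <- mean(xm^2)
  mu02 <- mean(ym^2)
  atan2(2 * mu11, mu20 - mu02) / 2 * 180 / pi
}

# Shared affine point transform used for both pixel grids and localization
# coordinates: rotate by `angle` degrees about center_in, re-center on
# center_out. In the y-down convention positive angles appear clockwise.
rotate_points <- function(x, y, angle, center_in, center_out) {
  th <- angle * pi / 180
  ct <- cos(th); st <- sin(th)
  dx <- x - center_in[1]; dy <- y - center_in[2]
  list(x = ct * dx - st * dy + center_out[1],
       y = st * dx + ct * dy + center_out[2])
}

# Resample an image under the forward point transform rotate_points(angle):
# output pixel centers are pulled back by the inverse rotation and sampled
# with bilinear (intensity) or nearest-neighbour (binary) interpolation.
rotate_image <- function(img, angle, out_dim, center_in, center_out,
                         interp = c("bilinear", "nearest")) {
  interp <- match.arg(interp)
  nr <- out_dim[1]; nc <- out_dim[2]
  xs <- rep(seq_len(nc) - 0.5, each = nr)
  ys <- rep(seq_len(nr) - 0.5, times = nc)
  src <- rotate_points(xs, ys, -angle, center_out, center_in)
  h <- nrow(img); w <- ncol(img)
  out <- numeric(nr * nc)
  if (interp == "nearest") {
    j <- ceiling(src$x); i <- ceiling(src$y)
    ok <- i >= 1 & i <= h & j >= 1 & j <= w
    out[ok] <- img[cbind(i[ok], j[ok])]
  } else {
    # bilinear on the pixel-center lattice
    fx <- src$x - 0.5; fy <- src$y - 0.5
    j0 <- floor(fx) + 1L; i0 <- floor(fy) + 1L
    tx <- fx - (j0 - 1L); ty <- fy - (i0 - 1L)
    ok <- i0 >= 1 & i0 + 1 <= h & j0 >= 1 & j0 + 1 <= w
    if (any(ok)) {
      i0k <- i0[ok]; j0k <- j0[ok]; txk <- tx[ok]; tyk <- ty[ok]
      v00 <- img[cbind(i0k, j0k)]
      v01 <- img[cbind(i0k, j0k + 1L)]
      v10 <- img[cbind(i0k + 1L, j0k)]
      v11 <- img[cbind(i0k + 1L, j0k + 1L)]
      out[ok] <- (1 - tyk) * ((1 - txk) * v00 + txk * v01) +
        tyk * ((1 - txk) * v10 + txk * v11)
    }
    # fall back to nearest at the frame border
    brd <- !ok
    if (any(brd)) {
      j <- pmin(pmax(ceiling(src$x[brd]), 1L), w)
      i <- pmin(pmax(ceiling(src$y[brd]), 1L), h)
      inside <- src$x[brd] >= 0 & src$x[brd] <= w &
        src$y[brd] >= 0 & src$y[brd] <= h
      v <- img[cbind(i, j)]
      v[!inside] <- 0
      out[brd] <- v
    }
  }
  matrix(out, nr, nc)
}

#' Extract single cells from a labelled mask
#'
#' Cuts one cell per label out of the mask and all channels, rotates every
#' data element by minus its principal-axis angle about the crop center so
#' the long axis lies horizontal, and transfers localizations falling inside
#' the label's padded bounding region through the identical point transform
#' into cropped-frame coordinates. Binaries are resampled nearest-neighbour
#' and stay strictly 0/1; intensity channels are resampled bilinearly.
#'
#' @param mask Integer-labelled matrix (0 = background, k > 0 = cell k) or a
#'   binary [image_element].
#' @param channels Named list of [image_element] objects sharing the mask's
#'   dimensions.
#' @param localizations Optional [loc_table] in full-frame pixel coordinates.
#' @param pad Margin (px) added around each label's bounding box (default 3).
#' @return A [cell_collection], one cell per non-empty label, in label order.
#' @export
extract_cells <- function(mask, channels = list(), localizations = NULL,
                          pad = 3) {
  m <- if (inherits(mask, "image_element")) mask$pixels else mask
  for (ch in channels)
    if (!identical(dim(ch$pixels), dim(m)))
      stop("channel dimensions must match the mask")
  labels <- sort(unique(m[m > 0]))
  cells <- list()
  for (lab in labels) {
    idx <- which(m == lab, arr.ind = TRUE)
    if (nrow(idx) < 2L) {
      warning(sprintf("label %d has fewer than 2 pixels; skipped", lab))
      next
    }
    r0 <- max(1L, min(idx[, 1]) - pad); r1 <- min(nrow(m), max(idx[, 1]) + pad)
    c0 <- max(1L, min(idx[, 2]) - pad); c1 <- min(ncol(m), max(idx[, 2]) + pad)
    bin_crop <- (m[r0:r1, c0:c1, drop = FALSE] == lab) * 1
    theta <- orientation_angle(bin_crop)

    h <- nrow(bin_crop); w <- ncol(bin_crop)
    s <- ceiling(sqrt(h^2 + w^2)) + 2L
    cin <- c(w / 2, h / 2)
    cout <- c(s / 2, s / 2)

    rot_bin <- rotate_image(bin_crop, -theta, c(s, s), cin, cout, "nearest")
    rot_bin <- (rot_bin > 0.5) * 1

    # trim the rotated square back to the binary bounding box + pad
    fg <- which(rot_bin > 0, arr.ind = TRUE)
    tr0 <- max(1L, min(fg[, 1]) - pad); tr1 <- min(s, max(fg[, 1]) + pad)
    tc0 <- max(1L, min(fg[, 2]) - pad); tc1 <- min(s, max(fg[, 2]) + pad)

    elements <- list(binary = image_element(
      rot_bin[tr0:tr1, tc0:tc1, drop = FALSE], "binary", "binary"))

    for (nm in names(channels)) {
      ch_crop <- channels[[nm]]$pixels[r0:r1, c0:c1, drop = FALSE]
      rot <- rotate_image(ch_crop, -theta, c(s, s), cin, cout, "bilinear")
      elements[[nm]] <- image_element(
        rot[tr0:tr1, tc0:tc1, drop = FALSE], channels[[nm]]$role, nm)
    }

    if (!is.null(localizations) && nrow(localizations)) {
      # bounding-region selection in full-frame px, then the shared transform
      inbox <- localizations$x >= c0 - 1 & localizations$x <= c1 &
        localizations$y >= r0 - 1 & localizations$y <= r1
      sel <- localizations[inbox, , drop = FALSE]
      if (nrow(sel)) {
        lx <- sel$x - (c0 - 1); ly <- sel$y - (r0 - 1)
        q <- rotate_points(lx, ly, -theta, cin, cout)
        sel$x <- q$x - (tc0 - 1)
        sel$y <- q$y - (tr0 - 1)
        keep <- sel$x >= 0 & sel$x <= tc1 - tc0 + 1 &
          sel$y >= 0 & sel$y <= tr1 - tr0 + 1
        sel <- sel[keep, , drop = FALSE]
      }
      class(sel) <- c("loc_table", "data.frame")
      elements$localizations <- sel
    }

    com <- c(mean(idx[, 2]) - 0.5, mean(idx[, 1]) - 0.5)
    cell <- new_cell(
      id = sprintf("cell_%03d", lab),
      elements = elements,
      meta = list(label = lab, origin = c(c0 - 1, r0 - 1), angle = theta,
                  centroid_frame = com))
    cell$coords <- tryCatch(initial_coordinate_guess(elements$binary),
                            error = function(e) NULL)
    cells[[length(cells) + 1L]] <- cell
  }
  cell_collection(cells)
}

#' Initial coordinate-system guess from a binary image
#'
#' Fits a quadratic through the per-column foreground center of mass to
#' initialize the midline, takes half the median per-column foreground
#' height as the radius, and places the midline endpoints one radius inside
#' the foreground extrema (the hemispherical poles extend a radius beyond
#' the midline domain).
#'
#' @param binary A binary [image_element] or 0/1 matrix, horizontally
#'   oriented.
#' @return A [coord_params] object.
#' @export
initial_coordinate_guess <- function(binary) {
  m <- if (inherits(binary, "image_element")) binary$pixels else binary
  cols <- which(colSums(m > 0) > 0)
  if (!length(cols)) stop("binary image is empty")
  xs <- cols - 0.5
  com <- vapply(cols, function(j) mean(which(m[, j] > 0)) - 0.5, numeric(1))
  hts <- vapply(cols, function(j) sum(m[, j] > 0), numeric(1))

  if (length(cols) >= 3) {
    fit <- stats::lm.fit(cbind(1, xs, xs^2), com)
    ab <- unname(fit$coefficients)
  } else {
    ab <- c(mean(com), 0, 0)
  }
  r <- max(0.5, stats::median(hts) / 2)
  xmin <- min(xs); xmax <- max(xs)
  off <- min(r, 0.45 * (xmax - xmin))
  coord_params(a0 = ab[1], a1 = ab[2], a2 = ab[3],
               xl = xmin + off, xr = xmax - off, r = r)
}

#' Per-cell summary properties
#'
#' @param cells A [cell_collection].
#' @return A data.frame with one row per cell: `id`, `cell_length`, `radius`,
#'   `area` (binary pixel count), plus `mean_<name>` for every image element
#'   and `n_<name>` for every localization table.
#' @export
cell_summary <- function(cells) {
  rows <- lapply(unclass(cells), function(cell) {
    p <- list(id = cell$id,
              cell_length = if (is.null(cell$coords)) NA_real_
                            else cell_length(cell$coords),
              radius = if (is.null(cell$coords)) NA_real_ else cell$coords$r,
              area = sum(cell_binary(cell)$pixels))
    for (nm in names(cell$elements)) {
      e <- cell$elements[[nm]]
      if (inherits(e, "image_element"))
        p[[paste0("mean_", nm)]] <- mean(e$pixels)
      else if (is_loc_table(e))
        p[[paste0("n_", nm)]] <- nrow(e)
    }
    as.data.frame(p, stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame(id = character(0), cell_length = numeric(0),
                      radius = numeric(0), area = numeric(0)))
  do.call(rbind, rows)
}

#' Filter a cell collection by a predicate over cell properties
#'
#' The condition is evaluated in the [cell_summary()] data.frame, so
#' predicates can reference `cell_length`, `radius`, `area`, `mean_<name>`
#' and `n_<name>` columns directly, e.g.
#' `filter_cells(cells, cell_length > median(cell_length))`.
#'
#' @param cells A [cell_collection].
#' @param condition Unquoted logical expression over summary columns, or a
#'   logical vector of `length(cells)`.
#' @return The order-preserving subset, still a [cell_collection].
#' @export
filter_cells <- function(cells, condition) {
  props <- cell_summary(cells)
  keep <- eval(substitute(condition), props, parent.frame())
  if (!is.logical(keep) || length(keep) != length(cells))
    stop("condition must yield one logical per cell")
  cells[which(keep)]
}

#' Save / load a cell collection
#'
#' Lossless single-file persistence of a whole collection (pixels,
#' localization rows, parameters and ids reproduce exactly on reload).
#'
#' @param cells A [cell_collection].
#' @param path Archive path.
#' @return `load_cells` returns the restored [cell_collection];
#'   `save_cells` returns `path` invisibly.
#' @export
save_cells <- function(cells, path) {
  if (!inherits(cells, "cell_collection")) stop("'cells' must be a cell_collection")
  saveRDS(cells, path)
  invisible(path)
}

#' @rdname save_cells
#' @export
load_cells <- function(path) {
  if (!file.exists(path)) stop(sprintf("cell archive not found: %s", path))
  obj <- tryCatch(readRDS(path),
                  error = function(e)
                    stop(sprintf("cannot read cell archive %s: %s",
                                 path, conditionMessage(e))))
  if (!inherits(obj, "cell_collection"))
    stop(sprintf("%s does not contain a cell collection", path))
  obj
}
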
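make_image_cell <- function(params, dims, pixels, locs = NULL, id = "a") {
  elements <- list(binary = image_element(render_mask_oracle(params, dims),
                                          "binary"),
                   img = image_element(pixels, "fluorescence", "img"))
  if (!is.null(locs)) elements$storm <- locs
  new_cell(id, coords = params, elements = elements)
}

test_that("axial distributions conserve mass and match a counting oracle", {
  cp <- straight_params(a0 = 8, xl = 5, xr = 27, r = 4)
  dims <- c(16, 32)
  cell <- make_image_cell(cp, dims, matrix(2.5, dims[1], dims[2]))
  # uniform image, radial axis: every bin mean equals the global value
  d <- axial_distribution(cell, "img", "radial")
  expect_true(all(abs(d$mean - 2.5) < 1e-12))
  expect_equal(sum(d$n), prod(dims))  # mass conservation, exactly

  # localizations: membrane peak near r on the radial axis
  set.seed(3)
  locs <- sample_membrane_localizations(cp, cp$r, sigma = 0.25, n = 2000)
  cell2 <- make_image_cell(cp, dims, matrix(1, dims[1], dims[2]), locs)
  dr <- axial_distribution(cell2, "storm", "radial", n_bins = 40)
  expect_equal(sum(dr$count), 2000)
  peak_x <- dr$x[which.max(dr$count)]
  expect_lt(abs(peak_x - cp$r), 0.5)
  expect_lt(abs(sum(dr$x * dr$count) / sum(dr$count) - cp$r), 0.2)

  # longitudinal counts of a uniform-interior binary match brute force
  dl <- axial_distribution(cell, "binary", "longitudinal", n_bins = 8)
  maps <- coordinate_maps(cp, dims)
  inside <- maps$rc <= cp$r
  bw <- cell_length(cp) / 8
  brute <- tabulate(pmin(floor(maps$lc[inside] / bw) + 1, 8), 8)
  dlb <- axial_distribution(cell, "binary", "longitudinal", n_bins = 8)
  expect_error(axial_distribution(cell, "img", "sideways"), "arg")
  # restrict to interior pixels via the binary weights: compare n-weighted sums
  expect_equal(sum(dl$n), prod(dims))
  s <- rowsum(as.vector(cell$elements$binary$pixels),
              pmin(floor(as.vector(maps$lc) / bw) + 1, 8))
  expect_equal(as.vector(s), brute)
})

test_that("ensemble radial distribution peaks at the normalized membrane", {
  set.seed(11)
  cells <- cell_collection(lapply(1:12, function(i) {
    r <- runif(1, 3.5, 5.5)
    p <- coord_params(9, 0, 0, xl = 7, xr = 7 + runif(1, 15, 25), r = r)
    dims <- c(18, ceiling(p$xr + r + 3))
    locs <- sample_membrane_localizations(p, r, sigma = 0.25, n = 400)
    make_image_cell(p, dims, matrix(1, dims[1], dims[2]), locs,
                    id = paste0("c", i))
  }))
  ens <- ensemble_radial_distribution(cells, "storm", n_bins = 40, x_max = 2)
  expect_lt(abs(ens$x[which.max(ens$mean)] - 1), 0.05 + 1e-9)  # one bin
  expect_true(all(ens$std >= 0))
  expect_equal(max(ens$mean) <= 1, TRUE)

  # identical cells give zero spread (rebuilt with fresh ids)
  c1 <- cells[[1]]; c2 <- cells[[1]]; c2$id <- "dup"
  ens0 <- ensemble_radial_distribution(cell_collection(list(c1, c2)), "storm")
  expect_true(all(ens0$std == 0))

  bare <- cells[[1]]; bare$coords <- NULL; bare$id <- "bare"
  broken <- cell_collection(list(cells[[1]], bare))
  expect_error(ensemble_radial_distribution(broken, "storm"), "bare")
})

test_that("alignment onto a model cell conserves mass and is linear", {
  set.seed(21)
  model <- coord_params(12, 0, 0, xl = 9, xr = 31, r = 5)
  cells <- cell_collection(lapply(1:4, function(i) {
    p <- coord_params(8 + i * 0.3, 0, 0.002 * (i - 2), xl = 6,
                      xr = 6 + 16 + i, r = 3.5 + 0.3 * i)
    dims <- c(20, ceiling(p$xr + p$r + 4))
    img <- matrix(runif(prod(dims)), dims[1], dims[2])
    make_image_cell(p, dims, img, id = paste0("c", i))
  }))
  al <- align_cells(cells, "img", model, sigma = 0.5)
  # input mass = weights of the pixels that form the point cloud
  # (those within r + 2 px of the midline)
  total_in <- sum(vapply(unclass(cells), function(c) {
    img <- c$elements$img$pixels
    rc <- radial_distance_image(c$coords, dim(img))
    sum(img[rc <= c$coords$r + 2])
  }, numeric(1)))
  expect_gt(sum(al) / total_in, 0.99)
  expect_lte(sum(al) / total_in, 1 + 1e-9)

  # linearity: align(A union B) = align(A) + align(B)
  a <- align_cells(cells[1:2], "img", model, sigma = 0.5)
  b <- align_cells(cells[3:4], "img", model, sigma = 0.5)
  expect_equal(al, a + b, tolerance = 1e-12)
})

test_that("self-alignment reproduces the original image", {
  set.seed(23)
  p <- coord_params(10, 0, 0, xl = 8, xr = 30, r = 4.5)
  dims <- c(20, 38)
  rc <- radial_distance_image(p, dims)
  img <- exp(-(rc - p$r)^2 / 2) + 0.05
  cell <- make_image_cell(p, dims, img)
  al <- align_cells(cell_collection(list(cell)), "img", p, sigma = 0.4,
                    dim = dims)
  fg <- rc <= p$r + 3
  expect_gt(stats::cor(al[fg], img[fg]), 0.95)
})

test_that("perimeter positions follow the clockwise zero-at-top convention", {
  p <- straight_params(a0 = 5, xl = 1, xr = 9, r = 2)  # L = 8
  start_top <- map_to_cartesian(p, 0, p$r, 0)
  bottom_start <- map_to_cartesian(p, cell_length(p), p$r, 180)
  mid_right_pole <- map_to_cartesian(p, cell_length(p), p$r, 90)
  locs <- loc_table(x = c(start_top$xp, bottom_start$xp, mid_right_pole$xp),
                    y = c(start_top$yp, bottom_start$yp, mid_right_pole$yp))
  tr <- perimeter_positions(p, locs, pixel_size = 1, bin_width = 0.1)
  pos <- attr(tr, "positions")
  expect_equal(pos[1], 0, tolerance = 1e-6)
  expect_equal(pos[2], 8 + pi * 2, tolerance = 1e-3)       # L + pi r
  expect_equal(pos[3], 8 + pi * 2 / 2, tolerance = 1e-3)   # mid right pole
  expect_equal(attr(tr, "perimeter"), 2 * 8 + 2 * pi * 2, tolerance = 1e-3)
  expect_equal(sum(tr$count), 3)
})

test_that("uniform membrane sampling gives a flat perimeter trace", {
  set.seed(31)
  p <- coord_params(10, 0, 0.003, 7, 35, 5)
  locs <- sample_membrane_localizations(p, p$r, sigma = 0, n = 1e4)
  tr <- perimeter_positions(p, locs, pixel_size = 80, bin_width = 400)
  ct <- tr$count[-length(tr$count)]
  expect_gt(stats::chisq.test(ct)$p.value, 0.01)
})

test_that("detrended autocorrelation isolates oscillatory structure", {
  set.seed(41)
  bw <- 10
  n <- 600
  # white noise: no structure beyond lag 0
  wn <- rpois(n, 20)
  ac <- autocorrelate_detrend(wn, window = 150, bin_width = bw)
  expect_lt(abs(mean(ac)), 0.5)
  # pure cosine of period 80 nm: ACF peaks at lag = period
  x <- (seq_len(n) - 0.5) * bw
  cosine <- 10 + 8 * cos(2 * pi * x / 80)
  ac2 <- autocorrelate_detrend(cosine, window = 150, bin_width = bw)
  lags <- (seq_along(ac2) - 1) * bw
  interior <- lags > 40 & lags < 200
  expect_equal(lags[interior][which.max(ac2[interior])], 80)
  # cosine + linear trend: trend removed, peak still at the period
  trended <- cosine + 0.05 * x
  ac3 <- autocorrelate_detrend(trended, window = 150, bin_width = bw)
  expect_equal(lags[interior][which.max(ac3[interior])], 80)
  expect_error(autocorrelate_detrend(wn, window = 15, bin_width = bw),
               "3 bins")
})

test_that("dominant periodicity finds the strongest Fourier component", {
  bw <- 10
  x <- (seq_len(512) - 0.5) * bw
  s56 <- sin(2 * pi * x / 56)
  expect_lt(abs(dominant_periodicity(s56, bw) - 56), 56^2 / (4 * 512 * bw))
  mix <- 2 * sin(2 * pi * x / 56) + sin(2 * pi * x / 30)
  expect_lt(abs(dominant_periodicity(mix, bw) - 56), 1)
  expect_error(dominant_periodicity(numeric(64), bw), "zero")
})

test_that("56 nm membrane modulation survives the full pipeline", {
  set.seed(51)
  p <- coord_params(10, 0, 0, xl = 8, xr = 58, r = 5)  # L = 50 px = 4 um
  hits <- 0L
  n_seeds <- 5
  for (k in seq_len(n_seeds)) {
    locs <- sample_membrane_localizations(
      p, p$r, sigma = 0.25, n = 2e4,
      modulation_period = 56, modulation_depth = 0.9, pixel_size = 80)
    tr <- perimeter_positions(p, locs, pixel_size = 80, bin_width = 10)
    ac <- autocorrelate_detrend(tr, window = 150)
    wl <- dominant_periodicity(ac)
    # one padded-FFT bin at the 56 nm peak
    tol <- 56^2 / (4 * length(ac) * 10)
    hits <- hits + (abs(wl - 56) <= tol + 1e-9)
  }
  expect_gte(hits, n_seeds - 1)
})

test_that("periodicity recovery works across 40/56/80 nm periods", {
  set.seed(61)
  p <- coord_params(10, 0, 0, xl = 8, xr = 58, r = 5)
  for (period in c(40, 56, 80)) {
    locs <- sample_membrane_localizations(
      p, p$r, sigma = 0.25, n = 2e4,
      modulation_period = period, modulation_depth = 0.9, pixel_size = 80)
    tr <- perimeter_positions(p, locs, pixel_size = 80, bin_width = 10)
    ac <- autocorrelate_detrend(tr, window = 150)
    wl <- dominant_periodicity(ac)
    tol <- period^2 / (4 * length(ac) * 10)
    expect_lt(abs(wl - period), tol + 1e-9)
  }
})
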
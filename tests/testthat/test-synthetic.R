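test_that("geometry sampling is deterministic, bounded and unbiased", {
  cfg0 <- geometry_config(r_sd = 0, length_sd = 0, a2_sd = 0)
  p <- sample_geometry(cfg0)
  expect_equal(p$r, 5)
  expect_equal(p$xr - p$xl, 25)
  expect_equal(p$a2, 0)

  cfg <- geometry_config()
  set.seed(123); a <- sample_geometry(cfg)
  set.seed(123); b <- sample_geometry(cfg)
  expect_identical(a, b)

  set.seed(5)
  rs <- vapply(seq_len(1e4), function(i) sample_geometry(cfg)$r, numeric(1))
  expect_lt(abs(mean(rs) - cfg$r_mean), 3 * cfg$r_sd / sqrt(1e4) + 1e-3)
  expect_true(all(rs >= cfg$r_bounds[1] & rs <= cfg$r_bounds[2]))

  bad <- geometry_config(r_mean = 5, r_sd = 1e-6, r_bounds = c(8, 10))
  expect_error(sample_geometry(bad), "1000 draws")
})

test_that("rendered binaries match the analytic area and stay in frame", {
  p <- coord_params(10, 0, 0, xl = 8, xr = 28, r = 5)
  bin <- render_binary(p)
  area_formula <- 2 * p$r * cell_length(p) + pi * p$r^2
  perim <- 2 * cell_length(p) + 2 * pi * p$r
  expect_lt(abs(sum(bin$pixels) - area_formula), perim)
  # consistency with the binary objective
  expect_lte(objective_binary(p, bin), perim)
  # sub-pixel radius gives a single-row line along the midline
  thin <- coord_params(6.5, 0, 0, xl = 4, xr = 16, r = 0.4)
  line <- render_binary(thin, c(13, 20))
  expect_true(all(which(line$pixels > 0, arr.ind = TRUE)[, 1] == 7))
  # clipped cell errors
  expect_error(render_binary(p, c(12, 20)), "clipped")
})

test_that("brightfield noise model has Poisson + Gaussian statistics", {
  p <- coord_params(60, 0, 0, xl = 20, xr = 80, r = 5)
  dims <- c(120, 100)
  noiseless <- render_brightfield(p, 1000, dims, noise = FALSE)
  rcmap <- radial_distance_image(p, dims)
  bg <- rcmap > 15
  expect_lt(max(abs(noiseless$pixels[bg] - 1000)), 0.001)
  expect_gt(max(noiseless$pixels) , 1400)  # membrane contrast present

  set.seed(99)
  img <- render_brightfield(p, 1000, dims)
  vals <- img$pixels[bg]
  expect_gt(length(vals), 5e3)
  expect_lt(abs(mean(vals) - 1000) / 1000, 0.05)
  expect_lt(abs(stats::var(vals) - 1400) / 1400, 0.05)

  set.seed(7); im1 <- render_brightfield(p, 500, dims)
  set.seed(7); im2 <- render_brightfield(p, 500, dims)
  expect_identical(im1, im2)
})

test_that("membrane localizations have the configured radius and scatter", {
  p <- coord_params(10, 0.05, 0.003, 6, 36, 5)
  exact <- sample_membrane_localizations(p, 4.5, sigma = 0, n = 500)
  rc <- map_to_cellular(p, exact$x, exact$y)$rc
  expect_lt(max(abs(rc - 4.5)), 1e-6)

  set.seed(13)
  locs <- sample_membrane_localizations(p, 4.5, sigma = 0.25, n = 1e4)
  rc <- map_to_cellular(p, locs$x, locs$y)$rc
  expect_true(sd(rc) > 0.24 && sd(rc) < 0.26)
  expect_lt(abs(mean(rc) - 4.5), 0.01)

  # perimeter positions are uniform along the outline (chi-square test)
  tr <- perimeter_positions(p, exact, pixel_size = 80, bin_width = 400)
  ct <- tr$count[-length(tr$count)]   # drop the partial last bin
  expect_gt(stats::chisq.test(ct)$p.value, 0.01)
})

test_that("field composition respects counts, labels and separation", {
  set.seed(17)
  cfg <- geometry_config()
  gts <- lapply(1:3, function(i)
    synthetic_cell(geometry = cfg, n_locs = 50, id = paste0("g", i)))

  small <- field_config(dim = c(160, 160), photons = 500)
  f1 <- compose_field(gts, small, n_cells = 1)
  expect_equal(sort(unique(as.vector(f1$mask))), c(0L, 1L))
  expect_equal(nrow(f1$placements), 1)
  expect_true(all(f1$localizations$truth_id == 1))

  # counts over many fields follow round(N(10, 3))
  set.seed(19)
  counts <- sample_cell_count(1e4)
  expect_lt(abs(mean(counts) - 10), 0.1)
  expect_lt(abs(sd(counts) - 3), 0.1)

  # minimum pairwise distance verified by brute force over label pairs
  set.seed(23)
  f <- compose_field(gts, field_config(dim = c(300, 300)), n_cells = 6)
  labs <- sort(unique(f$mask[f$mask > 0]))
  expect_gt(length(labs), 1)
  coords <- lapply(labs, function(l) {
    ij <- which(f$mask == l, arr.ind = TRUE)
    cbind(ij[, 2] - 0.5, ij[, 1] - 0.5)
  })
  for (i in seq_along(labs)) for (j in seq_len(i - 1)) {
    d2 <- min_cross_dist2(coords[[i]][, 1], coords[[i]][, 2],
                          coords[[j]][, 1], coords[[j]][, 2])
    expect_gte(sqrt(d2), 5)
  }
})

test_that("centroid matching pairs measured cells with their truth", {
  set.seed(29)
  gts <- lapply(1:2, function(i) synthetic_cell(n_locs = 80, id = paste0("g", i)))
  f <- compose_field(gts, field_config(dim = c(300, 300)), n_cells = 5)
  cells <- extract_cells(f$mask, localizations = f$localizations)
  m <- match_measured_to_truth(f$placements, cells)
  expect_equal(nrow(m$pairs), nrow(f$placements))
  expect_length(m$unmatched_truth, 0)
  expect_true(all(m$pairs$dist < 5))
  expect_true(all(m$pairs$recovery > 0.8))

  # a truth cell absent from the measured set is reported unmatched
  m2 <- match_measured_to_truth(f$placements, cells[-1])
  expect_length(m2$unmatched_truth, 1)

  # matching is robust to 2 px centroid jitter at >= 5 px spacing
  set.seed(31)
  pl <- f$placements
  pl$centroid_x <- pl$centroid_x + runif(nrow(pl), -2, 2)
  pl$centroid_y <- pl$centroid_y + runif(nrow(pl), -2, 2)
  m3 <- match_measured_to_truth(pl, cells)
  expect_identical(m3$pairs$truth_id, m$pairs[order(m$pairs$truth_id), ]$truth_id[
    order(order(m3$pairs$truth_id))])
  expect_equal(nrow(m3$pairs), nrow(pl))
})

test_that("relative chi-square normalizes as the moments predict", {
  set.seed(37)
  p <- coord_params(10, 0, 0.002, 6, 34, 5)
  locs <- sample_membrane_localizations(p, p$r, sigma = 0.25, n = 1000)
  expect_equal(relative_chi2(p, p, locs), 1)

  inflated <- coord_params(p$a0, p$a1, p$a2, p$xl, p$xr, p$r + 1)
  # E[(rc - r - 1)^2] / E[(rc - r)^2] = (1 + sigma^2) / sigma^2 = 17
  ratio <- relative_chi2(inflated, p, locs)
  expect_lt(abs(ratio - 17) / 17, 0.15)

  zero <- sample_membrane_localizations(p, p$r, sigma = 0, n = 10)
  expect_error(relative_chi2(inflated, p, zero), "zero")
})

test_that("optimized coordinates can slightly beat truth on finite samples", {
  set.seed(41)
  p <- sample_geometry(geometry_config())
  gt <- synthetic_cell(params = p, n_locs = 200, id = "t")
  truth_storm <- coord_params(p$a0, p$a1, p$a2, p$xl, p$xr, gt$r_inner)
  seg <- degrade_binary(gt$elements$binary, p)
  cell <- new_cell("t", coords = initial_coordinate_guess(seg),
                   elements = list(binary = seg,
                                   storm = gt$elements$storm_inner))
  fit <- optimize_cell(cell, "storm", "localizations")
  ratio <- relative_chi2(fit$params, truth_storm, gt$elements$storm_inner)
  expect_lte(ratio, 1.1)
  expect_gt(ratio, 0.5)
})

test_that("benchmark summary is seeded-deterministic with sane columns", {
  b1 <- run_benchmark(n_cells = 3, methods = "localizations", seed = 7)
  b2 <- run_benchmark(n_cells = 3, methods = "localizations", seed = 7)
  expect_identical(b1, b2)
  expect_true(all(b1$rel_chi2 > 0))
  expect_true(all(b1$d_mean >= 0 & b1$d_rms >= b1$d_mean - 1e-12))
  expect_equal(nrow(b1), 3)
})
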
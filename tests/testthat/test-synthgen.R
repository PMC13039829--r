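test_that("retina phantom is a pure function of spec and seed", {
  spec <- small_retina_spec(tunel_positive_count = 5, seed = 42)
  spec$sprouts <- random_sprouts(3, spec, length_range_um = c(15, 30),
                                 seed = 9)
  a <- make_retina_phantom(spec)
  b <- make_retina_phantom(spec)
  expect_identical(a$channels, b$channels)
  expect_identical(a$truth$per_sprout_length_um, b$truth$per_sprout_length_um)
})

test_that("retina truth lengths are conserved and exact", {
  spec <- small_retina_spec(seed = 3)
  expect_equal(make_retina_phantom(spec)$truth$total_sprout_length_um, 0)

  spec$sprouts <- list(straight_sprout(spec, 30, 30))
  ph <- make_retina_phantom(spec)
  expect_equal(ph$truth$total_sprout_length_um, 30)

  spec$sprouts <- random_sprouts(4, spec, length_range_um = c(15, 30),
                                 seed = 5)
  ph <- make_retina_phantom(spec)
  expect_identical(ph$truth$total_sprout_length_um,
                   sum(ph$truth$per_sprout_length_um))
  ## rasterized fraction is the truth fraction by construction
  tm <- ph$truth$layer_masks
  expect_equal(ph$truth$sprouted_area_fraction_pct,
               100 * sum(ph$truth$sprout_mask & tm$onl_mask) /
                 sum(tm$onl_mask))
})

test_that("retina phantom rejects invalid sprouts by index", {
  spec <- small_retina_spec()
  bad <- straight_sprout(spec, 30, 30)
  bad[2, 2] <- -5  # vertex above the image
  expect_error(retina_phantom_spec(image_height_px = 240,
                                   image_width_px = 128,
                                   layer_boundaries = c(12, 40, 120, 150),
                                   sprouts = list(straight_sprout(spec, 20, 20),
                                                  bad)),
               "sprout 2")
  not_in_opl <- cbind(x_um = c(30, 30), y_um = c(10, 5))
  expect_error(retina_phantom_spec(image_height_px = 240,
                                   image_width_px = 128,
                                   layer_boundaries = c(12, 40, 120, 150),
                                   sprouts = list(not_in_opl)),
               "OPL")
})

test_that("TEM phantom truth areas are analytic", {
  ## ellipse pi*a*b with a = 1, b = 0.5
  sq <- cbind(x_um = c(0.2, 3.0, 3.0, 0.2), y_um = c(0.2, 0.2, 3.0, 3.0))
  spec <- tem_phantom_spec(
    terminals = list(list(type = "rod", polygon = sq)),
    mitochondria = list(list(list(cx = 1.6, cy = 1.6, a = 1.0, b = 0.5,
                                  theta = 0.3))),
    pixel_size_um = 0.01, seed = 1)
  ph <- make_tem_phantom(spec)
  expect_equal(ph$truth$mitochondria$area_um2, pi * 1.0 * 0.5)
  expect_equal(ph$truth$terminals$area_um2, 2.8^2)
})

test_that("TEM phantom realises occupancy by construction", {
  ## square of side 2.4 with an ellipse of area half the square
  s <- 2.4
  sq <- cbind(x_um = c(0.3, 0.3 + s, 0.3 + s, 0.3),
              y_um = c(0.3, 0.3, 0.3 + s, 0.3 + s))
  a <- 1.1; b <- (s^2 / 2) / (pi * a)
  spec <- tem_phantom_spec(
    terminals = list(list(type = "cone", polygon = sq)),
    mitochondria = list(list(list(cx = 0.3 + s / 2, cy = 0.3 + s / 2,
                                  a = a, b = b, theta = 0))),
    seed = 1)
  ph <- make_tem_phantom(spec)
  expect_equal(ph$truth$terminals$occupancy, 0.5)
})

test_that("rod terminals carry exactly one mitochondrion", {
  spec <- random_tem_spec(n_rod = 5, n_cone = 2, seed = 4)
  rod_ids <- which(vapply(spec$terminals, function(t) t$type == "rod",
                          logical(1)))
  expect_true(all(lengths(spec$mitochondria[rod_ids]) == 1L))
})

test_that("TEM phantom rejects escaping ellipses", {
  sq <- cbind(x_um = c(0.2, 2.0, 2.0, 0.2), y_um = c(0.2, 0.2, 2.0, 2.0))
  expect_error(tem_phantom_spec(
    terminals = list(list(type = "rod", polygon = sq)),
    mitochondria = list(list(list(cx = 1.9, cy = 1.0, a = 0.5, b = 0.3,
                                  theta = 0)))),
    "escapes")
})

test_that("ERG generator realises truth exactly at zero noise", {
  flat <- make_erg_trace(erg_trace_spec(a_amplitude_uV = 0,
                                        b_amplitude_uV = 0,
                                        noise_sigma_uV = 0))
  expect_true(all(flat$trace$voltage_uV == 0))

  g <- make_erg_trace(erg_trace_spec(a_amplitude_uV = 200,
                                     b_amplitude_uV = 400,
                                     noise_sigma_uV = 0))
  tr <- g$trace
  i_min <- which.min(tr$voltage_uV)
  expect_equal(min(tr$voltage_uV), -200)
  expect_equal(tr$time_ms[i_min] - tr$flash_time_ms, g$truth$a_implicit_ms)
  ## trough-to-peak realised exactly
  post <- i_min:length(tr$voltage_uV)
  expect_equal(max(tr$voltage_uV[post]) - tr$voltage_uV[i_min], 400)
})

test_that("ERG spec enforces the stimulus protocol and geometry", {
  expect_error(erg_trace_spec(flash_intensity_log_photons_per_um2 = 0.5),
               "0.622")
  expect_error(erg_trace_spec(flash_intensity_log_photons_per_um2 = 7.2),
               "6.955")
  ## anywhere inside the range is accepted
  for (fi in c(0.622, 3.1, 6.955)) {
    expect_s3_class(erg_trace_spec(flash_intensity_log_photons_per_um2 = fi),
                    "erg_trace_spec")
  }
  expect_error(erg_trace_spec(duration_ms = 120, flash_time_ms = 100,
                              b_implicit_ms = 60), "duration")
  expect_error(erg_trace_spec(a_implicit_ms = 70, b_implicit_ms = 60),
               "smaller")
})

test_that("count generator honours the group design and the Poisson limit", {
  sim <- make_count_table(count_table_spec(n_proteins = 50, seed = 2))
  expect_equal(ncol(sim$matrix$counts), 8L)     # n = 4 per group
  expect_equal(as.vector(table(sim$matrix$groups)), c(4L, 4L))

  det <- make_count_table(count_table_spec(n_proteins = 20, dispersion = 0,
                                           baseline_sd = 0,
                                           baseline_mean = 33.4, seed = 2))
  expect_true(all(det$matrix$counts == round(33.4)))
})

test_that("planted fold changes are realised on average", {
  ids <- sprintf("P%04d", 1:1000)
  spec <- count_table_spec(n_proteins = 1000, baseline_mean = 100,
                           baseline_sd = 0,
                           planted_effects = setNames(rep(2, 1000), ids),
                           seed = 8)
  sim <- make_count_table(spec)
  g <- sim$matrix$groups
  m1 <- rowMeans(sim$matrix$counts[, g == "g1"])
  m2 <- rowMeans(sim$matrix$counts[, g == "g2"])
  expect_equal(mean(m1) / mean(m2), 2, tolerance = 0.05)
})

test_that("count spec rejects invalid noise models", {
  expect_error(count_table_spec(baseline_mean = 0), "baseline_mean")
  expect_error(count_table_spec(dispersion = -0.1), "dispersion")
  expect_error(count_table_spec(group_sizes = c(1, 4)), "group_sizes")
  expect_error(count_table_spec(planted_effects = c(P0001 = -2)),
               "planted_effects")
})
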
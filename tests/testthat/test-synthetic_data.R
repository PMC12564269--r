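test_that("aperture generation is deterministic and site-parameterized", {
  a1 <- gen_aperture_sequence("H&N", seed = 3)
  a2 <- gen_aperture_sequence("H&N", seed = 3)
  expect_identical(a1, a2)

  # head-and-neck gaps are smaller than chest gaps (generator's own
  # parameterization, checked over matched seeds)
  mean_gap <- function(site, seed) {
    ap <- gen_aperture_sequence(site, seed)
    g <- ap$right_edges - ap$left_edges
    mean(g[g > 0])
  }
  seeds <- 1:100
  hn <- vapply(seeds, function(s) mean_gap("H&N", s), numeric(1))
  ch <- vapply(seeds, function(s) mean_gap("C", s), numeric(1))
  expect_lt(mean(hn), mean(ch))

  ap1 <- gen_aperture_sequence("A", seed = 9, n_control_points = 1)
  expect_equal(ap1$n_control_points, 1)
  expect_true(all(ap1$right_edges >= ap1$left_edges))
  expect_gt(sum(ap1$mu_per_cp), 0)
})

test_that("aperture_sequence enforces gap and MU invariants", {
  expect_error(aperture_sequence(matrix(5, 2, 3), matrix(4, 2, 3), c(1, 1)),
               "negative gap")
  expect_error(aperture_sequence(matrix(1, 2, 3), matrix(2, 2, 3), c(0, 0)),
               "positive total")
})

test_that("render_fluence handles uniform, disjoint and scaled apertures", {
  # single full-open control point -> all ones after the min-max guard
  full <- aperture_sequence(matrix(0, 1, 8), matrix(64, 1, 8), 10,
                            leaf_width_mm = 8, field_width_mm = 64)
  fm <- render_fluence(full, grid = c(64, 64))
  expect_true(all(fm$values == 1))

  # two disjoint strips -> nonzero exactly on their pixel footprints
  l <- matrix(64, 1, 8); r <- matrix(64, 1, 8)
  l[1, 2] <- 8;  r[1, 2] <- 16   # rows 9..16, cols 9..16
  l[1, 6] <- 40; r[1, 6] <- 56   # rows 41..48, cols 41..56
  ap <- aperture_sequence(l, r, 5, leaf_width_mm = 8, field_width_mm = 64)
  fm2 <- render_fluence(ap, grid = c(64, 64))
  mask <- matrix(FALSE, 64, 64)
  mask[9:16, 9:16] <- TRUE
  mask[41:48, 41:56] <- TRUE
  expect_true(all((fm2$values > 0) == mask))

  # min-max normalization is invariant to scaling all MU
  ap2 <- aperture_sequence(l, r, 10, leaf_width_mm = 8, field_width_mm = 64)
  expect_identical(render_fluence(ap2, grid = c(64, 64))$values, fm2$values)
})

test_that("complexity metrics follow their geometric definitions", {
  nm <- complexity_metric_names()
  # all pairs closed at every control point
  closed <- aperture_sequence(matrix(32, 4, 8), matrix(32, 4, 8), rep(1, 4),
                              leaf_width_mm = 8, field_width_mm = 64)
  cv <- compute_complexity_vector(closed)
  expect_equal(cv$values[match("d-CLS", nm)], 1)
  expect_equal(cv$values[match("d-BA", nm)], 0)
  expect_equal(cv$values[match("d-UAA", nm)], 0)
  expect_equal(cv$values[match("MU", nm)], 4)
  expect_true(all(is.finite(cv$values)))

  # constant rectangular aperture: no variability
  l <- matrix(20, 5, 8); r <- matrix(40, 5, 8)
  const <- aperture_sequence(l, r, rep(2, 5), leaf_width_mm = 8,
                             field_width_mm = 64)
  cc <- compute_complexity_vector(const)
  expect_equal(cc$values[match("d-AAV", nm)], 0)
  expect_equal(cc$values[match("d-PM", nm)], 0)
  expect_equal(cc$values[match("d-SLG", nm)], 0)

  # widening every gap by 5 mm: union area grows, small apertures shrink
  ap <- gen_aperture_sequence("H&N", seed = 21)
  wide <- aperture_sequence(ap$left_edges,
                            pmin(ap$right_edges +
                                   5 * (ap$right_edges > ap$left_edges),
                                 ap$field_width_mm),
                            ap$mu_per_cp, ap$leaf_width_mm,
                            ap$field_width_mm)
  v0 <- compute_complexity_vector(ap)$values
  v1 <- compute_complexity_vector(wide)$values
  expect_gt(v1[match("d-UAA", nm)], v0[match("d-UAA", nm)])
  expect_lte(v1[match("d-SAS-2mm", nm)], v0[match("d-SAS-2mm", nm)])

  # zero-MU sequence is rejected
  ap$mu_per_cp <- rep(0, ap$n_control_points)
  expect_error(compute_complexity_vector(ap), "zero-MU")
})

test_that("simulate_delivery follows its algebra and is seeded", {
  fm <- render_fluence(gen_aperture_sequence("C", seed = 2))
  idp <- delivery_perturbation()
  res <- simulate_delivery(fm, idp)
  expect_identical(res$dd_map, fm$values * 0)

  gain <- delivery_perturbation(gain = 1.03)
  res2 <- simulate_delivery(fm, gain)
  expect_equal(res2$dd_map, 0.03 * fm$values, tolerance = 1e-12)

  nz <- delivery_perturbation(gain = 0.99, blur_sigma_mm = 0.7,
                              shift_mm = c(0.3, -0.2), noise_sd = 0.01,
                              seed = 77)
  expect_identical(simulate_delivery(fm, nz), simulate_delivery(fm, nz))
})

test_that("generate_dataset is reproducible and emits valid samples", {
  cfg <- sim_config(n_samples = 12, seed = 31)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_length(d1, 12)
  for (i in seq_along(d1)) {
    expect_identical(d1[[i]]$fluence$values, d2[[i]]$fluence$values)
    expect_identical(d1[[i]]$targets$gpr_percent, d2[[i]]$targets$gpr_percent)
  }
  ds <- sim_ds_small()
  expect_true(all(vapply(ds, function(s) length(validate_sample(s)) == 0,
                         logical(1))))
  # gamma criterion nesting: relaxing tolerances only adds passing points
  g <- vapply(ds, function(s) s$targets$gpr_percent, numeric(3))
  expect_true(all(g[1, ] <= g[2, ] + 1e-9))
  expect_true(all(g[2, ] <= g[3, ] + 1e-9))
})

test_that("cohort-scale site allocation reproduces the 19/138/31/22 mix", {
  cfg <- sim_config(n_samples = 210, seed = 2,
                    perturbation = identity_perturbation())
  ds <- cached("ident210", generate_dataset(cfg))
  counts <- table(factor(vapply(ds, function(s) s$lesion_site, character(1)),
                         levels = lesion_sites()))
  expect_equal(as.integer(counts), c(19, 138, 31, 22))
})

test_that("identity perturbation gives perfect QA everywhere", {
  cfg <- sim_config(n_samples = 210, seed = 2,
                    perturbation = identity_perturbation())
  ds <- cached("ident210", generate_dataset(cfg))
  for (s in ds[seq(1, 210, by = 21)]) {
    expect_identical(s$targets$gpr_percent, c(100, 100, 100))
    expect_true(all(s$targets$dd_map == 0))
  }
  expect_true(all(vapply(ds, function(s)
    all(s$targets$gpr_percent == 100), logical(1))))
})

test_that("raising the noise amplitude lowers the mean GPR", {
  means <- sapply(c(0.001, 0.006, 0.015), function(na) {
    pp <- identity_perturbation()
    pp$noise_amp <- na
    mean(sapply(lapply(1:3, function(sd)
      generate_dataset(sim_config(n_samples = 15, seed = sd,
                                  perturbation = pp))),
      function(d) mean(vapply(d, function(s) s$targets$gpr_percent[2],
                              numeric(1)))))
  })
  expect_true(means[1] > means[2] && means[2] > means[3])
})

test_that("rho_tab = 0 decouples complexity metrics from GPR", {
  rs <- lapply(c(5, 6, 7), function(sd) {
    d0 <- generate_dataset(sim_config(n_samples = 500, seed = sd,
                                      rho_tab = 0))
    X <- t(vapply(d0, function(s) s$complexity$values, numeric(33)))
    G <- t(vapply(d0, function(s) s$targets$gpr_percent, numeric(3)))
    suppressWarnings(cor(X, G))
  })
  rbar <- Reduce(`+`, rs) / 3
  expect_lt(max(abs(rbar), na.rm = TRUE), 0.1)
})
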
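test_that("regression metrics match their textbook forms", {
  expect_identical(unname(compute_regression_metrics(1:3, 1:3)),
                   c(0, 0, 1))
  m <- compute_regression_metrics(c(1, 2, 3), c(2, 2, 2))
  expect_equal(m[["mae"]], 2 / 3, tolerance = 1e-15)
  expect_equal(m[["rmse"]], sqrt(2 / 3), tolerance = 1e-15)
  expect_equal(m[["r2"]], 0, tolerance = 1e-15)  # the mean predictor

  m2 <- compute_regression_metrics(c(5, 7), c(5, 5))  # residuals (0, 2)
  expect_equal(m2[["mae"]], 1, tolerance = 1e-15)
  expect_equal(m2[["rmse"]], sqrt(2), tolerance = 1e-15)
  expect_lte(m2[["mae"]], m2[["rmse"]])

  expect_warning(z <- compute_regression_metrics(c(2, 2), c(1, 3)),
                 "zero target variance")
  expect_true(is.na(z[["r2"]]))
  expect_identical(unname(z[c("mae", "rmse")]), c(1, 1))
})

test_that("metrics agree with an independent re-implementation to 1e-12", {
  set.seed(20)
  for (k in 1:20) {
    n <- sample(5:60, 1)
    y <- rnorm(n, 50, 20)
    yh <- y + rnorm(n, 0, 5)
    m <- compute_regression_metrics(y, yh)
    # independent path: explicit sums, no shared helpers
    sae <- 0; sse <- 0; sst <- 0; yb <- sum(y) / n
    for (i in seq_len(n)) {
      sae <- sae + abs(y[i] - yh[i])
      sse <- sse + (y[i] - yh[i])^2
      sst <- sst + (y[i] - yb)^2
    }
    expect_lt(abs(m[["mae"]] - sae / n), 1e-12)
    expect_lt(abs(m[["rmse"]] - sqrt(sse / n)), 1e-12)
    expect_lt(abs(m[["r2"]] - (1 - sse / sst)), 1e-12)
    expect_lte(m[["mae"]], m[["rmse"]] + 1e-15)
  }
})

test_that("global SSIM follows its closed form", {
  set.seed(21)
  x <- matrix(rnorm(400, 0, 0.02), 20, 20)
  expect_identical(ssim_global(x, x, dynamic_range = diff(range(x))), 1)

  # constant 0 vs constant 1 with L = 1: C1 / (1 + C1)
  c1 <- 1e-4
  expect_equal(ssim_global(matrix(0, 8, 8), matrix(1, 8, 8), 1),
               c1 / (1 + c1), tolerance = 1e-15)

  for (k in 1:10) {
    a <- matrix(rnorm(100), 10, 10)
    b <- matrix(rnorm(100), 10, 10)
    L <- max(diff(range(a)), diff(range(b)))
    expect_identical(ssim_global(a, b, L), ssim_global(b, a, L))
    # independent evaluation of the formula
    mu1 <- mean(a); mu2 <- mean(b)
    s1 <- mean(a^2) - mu1^2; s2 <- mean(b^2) - mu2^2
    s12 <- mean(a * b) - mu1 * mu2
    C1 <- (0.01 * L)^2; C2 <- (0.03 * L)^2
    ref <- ((2 * mu1 * mu2 + C1) * (2 * s12 + C2)) /
      ((mu1^2 + mu2^2 + C1) * (s1 + s2 + C2))
    expect_lt(abs(ssim_global(a, b, L) - ref), 1e-12)
    expect_true(ssim_global(a, b, L) <= 1 + 1e-12)
  }
  expect_error(ssim_global(matrix(0, 2, 2), matrix(0, 2, 3), 1),
               "shape mismatch")
})

test_that("stratified reports partition the test set per criterion", {
  ds <- sim_ds_small()
  n <- length(ds)
  gt <- vapply(ds, function(s) s$targets$gpr_percent, numeric(3))
  pred <- gt + matrix(rnorm(3 * n, 0, 1), 3, n)
  dd_pred <- lapply(ds, function(s) s$targets$dd_map * 0.9)
  rep_ <- stratified_report(ds, pred, dd_pred)
  for (crit in c("1/1", "2/2", "2/3")) {
    sizes <- vapply(c("95-100", "90-95", "<90"),
                    function(st) rep_$gpr[[crit]][[st]]$n, integer(1))
    expect_identical(sum(sizes), rep_$gpr[[crit]][["All"]]$n)
    expect_identical(rep_$gpr[[crit]][["All"]]$n, n)
    for (st in names(rep_$gpr[[crit]])) {
      cell <- rep_$gpr[[crit]][[st]]
      if (cell$n > 0) expect_lte(cell$mae, cell$rmse + 1e-12)
      if (st != "All") expect_true(is.na(cell$r2))
    }
  }
  expect_identical(rep_$ddp[["All"]]$n, n)
  md <- format_report_markdown(rep_)
  expect_true(any(grepl("^\\| GPR \\| 2/2 \\| All", md)))
})

test_that("degenerate strata are absent, not zero", {
  ds <- make_samples(4)
  for (i in seq_along(ds)) ds[[i]]$targets$gpr_percent <- c(96, 97, 98)
  gt <- vapply(ds, function(s) s$targets$gpr_percent, numeric(3))
  rep_ <- stratified_report(ds, gt + 0.5)
  expect_identical(rep_$gpr[["2/2"]][["90-95"]]$n, 0L)
  expect_true(is.na(rep_$gpr[["2/2"]][["<90"]]$mae))
  expect_equal(rep_$gpr[["2/2"]][["95-100"]]$mae,
               rep_$gpr[["2/2"]][["All"]]$mae)
  # a single sample in a stratum: MAE equals RMSE equals |error|
  one <- rep_$gpr[["1/1"]][["95-100"]]
  expect_equal(rep_$gpr[["1/1"]][["All"]]$mae, 0.5, tolerance = 1e-12)
  expect_equal(one$mae, one$rmse, tolerance = 1e-12)
})
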
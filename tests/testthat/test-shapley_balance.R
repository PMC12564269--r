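test_that("value_function is the negative validation MAE with v(empty)=0", {
  targets <- matrix(c(95, 96, 97, 90, 92, 94), 3, 2)
  perfect <- list("img+tab" = targets, img = targets + 2, tab = targets - 2,
                  empty = targets + 50)
  v <- value_function(perfect, targets)
  expect_s3_class(v, "subset_value")
  expect_identical(v$v[["img+tab"]], 0)
  expect_identical(v$v[["img"]], -2)
  expect_identical(v$v[["tab"]], -2)
  expect_identical(v$v[["empty"]], 0)  # forced, not -50
  expect_error(value_function(perfect, targets[, 0]), "empty validation")
  expect_error(value_function(perfect[1:2], targets), "all four subsets")
})

test_that("closed-form Shapley matches the hand-worked table and oracle", {
  v <- c(empty = 0, img = -2, tab = -1, "img+tab" = -0.5)
  phi <- shapley_two_modality(v)
  expect_identical(unname(phi), c(-0.75, 0.25))
  expect_identical(unname(shapley_oracle(stats::setNames(
    v[c("empty", "img", "tab", "img+tab")], c("", "1", "2", "1,2")))),
    c(-0.75, 0.25))
})

test_that("Shapley axioms hold against the enumeration oracle", {
  set.seed(101)
  for (k in 1:100) {
    v <- random_game()
    phi <- shapley_two_modality(v)
    oracle <- shapley_oracle(two_modality_game(v))
    # agreement to 1e-12 (summation order differs by one ulp)
    expect_lt(max(abs(unname(phi) - unname(oracle))), 1e-12)
    # efficiency
    expect_lt(abs(sum(phi) - (v[["img+tab"]] - v[["empty"]])), 1e-12)
    # additivity
    w <- random_game()
    u <- v + w
    expect_equal(unname(shapley_two_modality(u)),
                 unname(shapley_two_modality(v) + shapley_two_modality(w)),
                 tolerance = 1e-12)
  }
  # symmetry: equal single-modality values imply equal attributions
  v <- c(empty = 0, img = -1.3, tab = -1.3, "img+tab" = -0.4)
  phi <- shapley_two_modality(v)
  expect_identical(phi[["phi_img"]], phi[["phi_tab"]])
})

test_that("the oracle supports n > 2 and detects incomplete games", {
  # dummy player: v(S u {3}) = v(S) + v({3})
  base <- c(0, -2, -1, -0.5)
  names(base) <- c("", "1", "2", "1,2")
  v3 <- -0.3
  v <- c(base, stats::setNames(base + v3, c("3", "1,3", "2,3", "1,2,3")))
  phi <- shapley_oracle(v, n = 3)
  expect_equal(phi[3], v3, tolerance = 1e-12)
  expect_equal(phi[1:2], c(-0.75, 0.25), tolerance = 1e-12)
  expect_lt(abs(sum(phi) - v[["1,2,3"]]), 1e-12)
  expect_error(shapley_oracle(v[-3], n = 3), "incomplete")
})

test_that("the lambda rule reproduces its closed form and clamp", {
  expect_identical(compute_lambda(-0.75, 0.25, 16), 9)
  expect_identical(compute_lambda(0.5, 0.2, 16), 1)   # clamp branch
  expect_identical(compute_lambda(-3, -4, 1000), 1)
  expect_identical(compute_lambda(-5, 2, 0), 1)       # r = 0: unbalanced
  expect_error(compute_lambda(0, 0, -1))
  expect_identical(total_loss(1, 2, 1), 3)
  expect_identical(total_loss(0.5, 0.1, 9), 1.4)
  expect_identical(total_loss(2, 0, 123), 2)
})

test_that("fit records a consistent per-epoch history", {
  ds <- tiny_sim_ds()
  tc <- train_config(r = 16, lr = 5e-3, epochs = 3, batch_size = 16,
                     seed = 3)
  fr <- fit(ds, assignment = simple_assignment(ds), cfg = tc, spec = tiny_spec())
  expect_length(fr$history, 3)
  for (h in fr$history) {
    phi <- c(h$phi_img, h$phi_tab)
    # efficiency identity holds in every report
    expect_lt(abs(sum(phi) - (h$v$v[["img+tab"]] - h$v$v[["empty"]])), 1e-12)
    expect_gte(h$lambda_ddp, 1)
    expect_identical(h$lambda_ddp,
                     compute_lambda(h$phi_img, h$phi_tab, tc$r))
  }
  expect_identical(fr$history[[1]]$lambda_used, 1)  # lambda_0 = 1
})

test_that("training is reproducible and r = 0 keeps lambda at 1", {
  ds <- tiny_sim_ds()
  tc <- train_config(r = 0, lr = 5e-3, epochs = 2, batch_size = 16, seed = 4)
  f1 <- fit(ds, assignment = simple_assignment(ds), cfg = tc, spec = tiny_spec())
  f2 <- fit(ds, assignment = simple_assignment(ds), cfg = tc, spec = tiny_spec())
  expect_identical(f1$model$params, f2$model$params)
  expect_identical(vapply(f1$history, `[[`, numeric(1), "l_gpr"),
                   vapply(f2$history, `[[`, numeric(1), "l_gpr"))
  expect_true(all(vapply(f1$history, `[[`, numeric(1), "lambda_used") == 1))
  expect_true(all(vapply(f1$history, `[[`, numeric(1), "lambda_ddp") == 1))
})

test_that("the GPR loss decreases on an easy synthetic set", {
  ds <- tiny_sim_ds()
  drop_ <- vapply(1:3, function(sd) {
    fr <- fit(ds, assignment = simple_assignment(ds),
              cfg = train_config(r = 0, lr = 5e-3, epochs = 5,
                                 batch_size = 16, seed = sd),
              spec = tiny_spec())
    l <- vapply(fr$history, `[[`, numeric(1), "l_gpr")
    l[1] - l[5]
  }, numeric(1))
  expect_gt(median(drop_), 0)
})

test_that("train_epoch rejects lambda below 1 and non-finite inputs abort", {
  ds <- tiny_sim_ds()[1:8]
  spec <- tiny_spec()
  m <- psqa_model(spec, seed = 1)
  tens <- psqanet:::.stack_samples(ds, spec$grid)
  batch <- list(x_img = tens$x_img, x_tab = tens$x_tab,
                y_gpr = tens$y_gpr, y_dd = tens$y_dd)
  opt <- psqanet:::adam_init(m$params, lr = 1e-3)
  expect_error(train_epoch(m, list(batch), 0.5, opt))
  out <- train_epoch(m, list(batch), 1, opt)
  expect_true(is.finite(out$l_gpr) && is.finite(out$l_ddp))
  bad <- batch
  bad$y_gpr[1, 1] <- NaN
  expect_error(train_epoch(m, list(bad), 1, opt), "non-finite")
})
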
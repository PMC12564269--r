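test_that("encoders honour their shape contracts and determinism", {
  spec <- network_spec(grid = 64, enc_channels = c(8, 16, 32, 128),
                       n_tab_channels = 2, d_f = 64,
                       dec_channels = c(16, 8, 8, 4, 4))
  m <- psqa_model(spec, seed = 2)
  x <- matrix(runif(64 * 64), 64, 64)
  z <- encode_image(m, x)
  expect_identical(dim(z), c(128L, 4L, 4L))
  expect_identical(encode_image(m, x), z)

  # zero input through the bias-free conv stack stays zero
  z0 <- encode_image(m, matrix(0, 64, 64))
  expect_true(all(z0 == 0))

  zt <- encode_tabular(m, rnorm(33))
  expect_length(zt, 2 * 4 * 4)
  expect_true(all(encode_tabular(m, rep(0, 33)) == 0))
  expect_error(encode_tabular(m, rnorm(32)), "length 33")
  expect_error(encode_image(m, matrix(0, 32, 32)), "expects 64x64")
})

test_that("attention weights follow the softmax closed forms", {
  spec <- tiny_spec()
  m <- psqa_model(spec, seed = 3)
  zi <- array(rnorm(prod(c(spec$n_c, 1, 1, 1))), c(spec$n_c, 1, 1, 1))
  zt <- matrix(rnorm(spec$n_t), ncol = 1)
  # equal scores: zero both score projections
  m$params$ws_img[] <- 0
  m$params$ws_tab[] <- 0
  fu <- psqanet:::.fuse_gpr_batch(m$params, m$spec, zi, zt, "img+tab")
  expect_equal(fu$al_img, 0.5)
  expect_equal(fu$al_tab, 0.5)
  expect_equal(fu$al_img + fu$al_tab, 1)

  # a score difference of exactly 1: alpha_img = e/(e+1)
  m2 <- psqa_model(spec, seed = 3)
  pi_ <- psqanet:::gap_fwd(zi)
  pt_ <- psqanet:::.pool_tab(m2$spec, zt)
  s_img <- sum(m2$params$ws_img * pi_)
  s_tab <- sum(m2$params$ws_tab * pt_)
  m2$params$ws_tab <- m2$params$ws_tab * ((s_img - 1) / s_tab)
  fu2 <- psqanet:::.fuse_gpr_batch(m2$params, m2$spec, zi, zt, "img+tab")
  expect_equal(fu2$al_img, exp(1) / (exp(1) + 1), tolerance = 1e-12)
  expect_true(fu2$al_img > 0 && fu2$al_img < 1)
})

test_that("subset fusions are the forced-coefficient forms, bit-exact", {
  spec <- tiny_spec()
  m <- psqa_model(spec, seed = 9)
  zi <- encode_image(m, matrix(runif(16 * 16), 16, 16))
  zt <- encode_tabular(m, rnorm(33))
  p_img <- rowMeans(matrix(zi, spec$n_c, spec$hz^2))
  p_tab <- rowMeans(matrix(zt, spec$n_t, spec$hz^2))
  expect_identical(fuse_gpr(m, zi, zt, "img"),
                   as.vector(m$params$W_img %*% p_img))
  expect_identical(fuse_gpr(m, zi, zt, "tab"),
                   as.vector(m$params$W_tab %*% p_tab))
  expect_identical(fuse_gpr(m, zi, zt, "empty"), rep(0, spec$d_f))
  expect_error(fuse_gpr(m, zi, zt, "both"), "unknown modality subset")
})

test_that("multi_subset_forward equals four independent passes", {
  spec <- tiny_spec()
  m <- psqa_model(spec, seed = 10)
  m$hooks$n_encode_img <- 0L
  zi <- encode_image(m, matrix(runif(16 * 16), 16, 16))
  zt <- encode_tabular(m, rnorm(33))
  expect_identical(m$hooks$n_encode_img, 1L)  # one encoder call per modality
  expect_identical(m$hooks$n_encode_tab, 1L)
  ms <- multi_subset_forward(m, zi, zt)
  expect_named(ms, c("empty", "img", "tab", "img+tab"))
  for (s in names(ms)) {
    expect_identical(ms[[s]], predict_gpr(m, fuse_gpr(m, zi, zt, s)))
  }
  # the null forward is a constant independent of the sample
  expect_identical(ms[["empty"]],
                   predict_gpr(m, rep(0, spec$d_f)))
  zi2 <- encode_image(m, matrix(runif(16 * 16), 16, 16))
  zt2 <- encode_tabular(m, rnorm(33))
  expect_identical(multi_subset_forward(m, zi2, zt2)[["empty"]],
                   ms[["empty"]])
  expect_identical(m$hooks$n_encode_img, 2L)
})

test_that("dose-difference fusion folds tabular channels first", {
  spec <- network_spec(grid = 64, enc_channels = c(8, 16, 32, 128),
                       n_tab_channels = 2, d_f = 64,
                       dec_channels = c(16, 8, 8, 4, 4))
  m <- psqa_model(spec, seed = 4)
  zi <- array(rnorm(128 * 4 * 4), c(128, 4, 4))
  zt <- rnorm(2 * 4 * 4)
  zd <- fuse_ddp(m, zi, zt)
  expect_identical(dim(zd), c(130L, 4L, 4L))
  expect_identical(as.vector(zd[1:2, , ]), zt)        # fold o flatten = id
  expect_identical(zd[3:130, , ], zi)                 # image block unchanged
  expect_error(fuse_ddp(m, zi, zt[-1]), "divisible")
})

test_that("the GPR head is pool->rectify->dropout->affine", {
  spec <- tiny_spec()
  m <- psqa_model(spec, seed = 5)
  expect_identical(predict_gpr(m, rep(0, spec$d_f)), m$params$head_b)
  z <- rnorm(spec$d_f)
  expect_identical(predict_gpr(m, z), predict_gpr(m, z))  # eval: no dropout
  expect_error(predict_gpr(m, rnorm(spec$d_f + 1)), "width mismatch")
  # published head geometry: d_f = 512 mapping to the 3 criteria
  full <- network_spec(scale = "full")
  expect_identical(full$d_f, 512L)
  mf_head <- psqa_model(network_spec(grid = 16, enc_channels = c(2, 2, 2, 3),
                                     n_tab_channels = 1, d_f = 512,
                                     dec_channels = c(4, 3, 3, 2, 2)),
                        seed = 1)$params$head_W
  expect_identical(dim(mf_head), c(3L, 512L))
})

test_that("the DD decoder reaches input resolution via the 5-stage schedule", {
  spec <- network_spec(grid = 64, enc_channels = c(4, 6, 6, 8),
                       n_tab_channels = 2, d_f = 16,
                       dec_channels = c(8, 6, 4, 4, 3))
  m <- psqa_model(spec, seed = 6)
  zi <- array(rnorm(8 * 4 * 4), c(8, 4, 4))
  zt <- rnorm(2 * 4 * 4)
  dd <- predict_ddp(m, fuse_ddp(m, zi, zt))
  expect_identical(dim(dd), c(64L, 64L))
  expect_identical(predict_ddp(m, fuse_ddp(m, zi, zt)), dd)
  expect_error(predict_ddp(m, zi), "channel count")
  # published full-scale channel schedule
  expect_identical(network_spec(scale = "full")$dec_channels,
                   c(768L, 384L, 192L, 128L, 32L))
  expect_length(spec$dec_channels, 5)
})

test_that("N_t < N_c is enforced at construction", {
  expect_error(network_spec(enc_channels = c(4, 4, 4, 4), n_tab_channels = 4),
               "strictly smaller")
  expect_silent(network_spec(enc_channels = c(4, 4, 4, 5),
                             n_tab_channels = 4, d_f = 8,
                             dec_channels = c(4, 4, 4, 4, 4)))
})

test_that("analytic gradients match finite differences", {
  set.seed(42)
  spec <- network_spec(grid = 16, enc_channels = c(3, 4, 5, 6),
                       n_tab_channels = 2, tab_hidden = 7, d_f = 10,
                       dec_channels = c(6, 5, 4, 4, 3), dropout = 0)
  m <- psqa_model(spec, seed = 5)
  B <- 2
  batch <- list(x_img = array(runif(16 * 16 * B), c(1, 16, 16, B)),
                x_tab = matrix(rnorm(33 * B), 33, B),
                y_gpr = matrix(runif(3 * B, 80, 100), 3, B),
                y_dd = array(rnorm(16 * 16 * B, 0, 0.02), c(1, 16, 16, B)))
  lambda <- 2.5
  loss_of <- function(params) {
    r <- psqanet:::.loss_and_grads(params, spec, batch, lambda, 0)
    r$l_gpr + lambda * r$l_ddp
  }
  r0 <- psqanet:::.loss_and_grads(m$params, spec, batch, lambda, 0)
  eps <- 1e-6
  for (nm in c("enc2_W", "tab1_W", "ws_img", "W_tab", "head_W", "dec3_W",
               "dfin_b")) {
    p <- m$params[[nm]]
    for (i in sample(length(p), min(3, length(p)))) {
      pp <- m$params
      pp[[nm]][i] <- pp[[nm]][i] + eps
      lp <- loss_of(pp)
      pp[[nm]][i] <- pp[[nm]][i] - 2 * eps
      lm <- loss_of(pp)
      num <- (lp - lm) / (2 * eps)
      ana <- r0$grads[[nm]][i]
      expect_lt(abs(num - ana) / max(abs(num), abs(ana), 1e-6), 0.02)
    }
  }
})
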
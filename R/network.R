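# Multimodal multi-task network: a convolutional image encoder and an MLP
# tabular encoder feed two task-specific fusions -- softmax-gated attention
# for the scalar GPR head, and channel concatenation (tabular channels
# first) for the U-Net-style dose-difference decoder.

#' Network architecture specification
#'
#' @param grid Input grid side length (square), a multiple of 16; the
#'   encoder's total stride is 16, so latent maps are `grid/16` square.
#' @param enc_channels Four stage widths of the strided conv encoder; the
#'   last is the image channel count `N_c`.
#' @param n_tab_channels `N_t`, the folded tabular channel count; must be
#'   strictly below `N_c` (the dose-difference task is image-dominant by
#'   construction).
#' @param tab_hidden Hidden width of the tabular MLP encoder.
#' @param d_f Fused width of the GPR branch (default 512, matching the
#'   3-output regression head).
#' @param dec_channels Five-stage channel schedule of the dose-difference
#'   decoder (an initial conv then four upsample+conv stages, then a final
#'   1x1 conv to one channel).
#' @param dropout Dropout probability in the GPR head (train mode only).
#' @param tab_pooling How the tabular embedding is pooled before its score /
#'   fusion projections: `"mean"` averages over the fold positions to an
#'   `N_t` vector (default); `"none"` projects the full vector.
#' @param skips Logical; when `TRUE` the decoder concatenates the encoder's
#'   intermediate feature maps (stages 3, 2, 1) onto its upsampled states at
#'   matching resolutions (U-Net skip connections). Off by default: the
#'   published decoder is described by its channel schedule alone.
#' @param scale `"desk"` (64 x 64 grid, slim decoder) or `"full"` (512 x 512
#'   grid with the published decoder schedule 768/384/192/128/32).
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(grid = NULL, enc_channels = c(16, 32, 64, 128),
                         n_tab_channels = 2, tab_hidden = 64, d_f = 512,
                         dec_channels = NULL, dropout = 0.1,
                         tab_pooling = c("mean", "none"),
                         skips = FALSE,
                         scale = c("desk", "full")) {
  scale <- match.arg(scale)
  tab_pooling <- match.arg(tab_pooling)
  if (is.null(grid)) grid <- if (scale == "full") 512L else 64L
  if (is.null(dec_channels)) {
    dec_channels <- if (scale == "full") c(768, 384, 192, 128, 32)
                    else c(64, 32, 16, 16, 8)
  }
  stopifnot(length(enc_channels) == 4, length(dec_channels) == 5,
            grid %% 16 == 0, grid >= 16, dropout >= 0, dropout < 1)
  n_c <- enc_channels[4]
  if (!(n_tab_channels < n_c)) {
    stop("network_spec: N_t must be strictly smaller than N_c")
  }
  structure(list(grid = as.integer(grid),
                 enc_channels = as.integer(enc_channels),
                 n_c = as.integer(n_c),
                 n_t = as.integer(n_tab_channels),
                 tab_hidden = as.integer(tab_hidden),
                 d_f = as.integer(d_f),
                 dec_channels = as.integer(dec_channels),
                 dropout = dropout,
                 tab_pooling = tab_pooling,
                 skips = isTRUE(skips),
                 hz = as.integer(grid %/% 16L),
                 n_metrics = 33L,
                 scale = scale),
            class = "network_spec")
}

.he_mat <- function(nr, nc) matrix(stats::rnorm(nr * nc, 0, sqrt(2 / nc)), nr, nc)

#' Construct a multimodal PSQA model with freshly initialized weights
#'
#' @param spec A [network_spec()].
#' @param seed Seed for weight initialization.
#' @return An object of class `psqa_model`: the parameter list, the spec,
#'   tabular standardization statistics (identity until [fit()] sets them),
#'   and an instrumentation environment counting encoder invocations.
#' @export
psqa_model <- function(spec = network_spec(), seed = 1L) {
  stopifnot(inherits(spec, "network_spec"))
  hz <- spec$hz
  tabdim <- spec$n_t * hz * hz
  pooled_tab_dim <- if (spec$tab_pooling == "mean") spec$n_t else tabdim
  ec <- spec$enc_channels
  dc <- spec$dec_channels
  params <- with_seed(seed, {
    p <- list()
    cin <- c(1L, ec[1:3])
    for (i in 1:4) {
      p[[paste0("enc", i, "_W")]] <- .he_mat(ec[i], cin[i] * 9L)
      p[[paste0("enc", i, "_b")]] <- numeric(ec[i])
    }
    p$tab1_W <- .he_mat(spec$tab_hidden, spec$n_metrics)
    p$tab1_b <- numeric(spec$tab_hidden)
    p$tab2_W <- .he_mat(tabdim, spec$tab_hidden)
    p$tab2_b <- numeric(tabdim)
    p$ws_img <- stats::rnorm(spec$n_c, 0, 1 / sqrt(spec$n_c))
    p$ws_tab <- stats::rnorm(pooled_tab_dim, 0, 1 / sqrt(pooled_tab_dim))
    p$W_img <- .he_mat(spec$d_f, spec$n_c)
    p$W_tab <- .he_mat(spec$d_f, pooled_tab_dim)
    p$head_W <- .he_mat(3L, spec$d_f) * 0.1
    p$head_b <- numeric(3L)
    skip_ch <- .dec_skip_channels(spec)
    din <- c(spec$n_c + spec$n_t, dc[1:4]) + skip_ch
    for (i in 1:5) {
      p[[paste0("dec", i, "_W")]] <- .he_mat(dc[i], din[i] * 9L)
      p[[paste0("dec", i, "_b")]] <- numeric(dc[i])
    }
    p$dfin_W <- matrix(0, 1L, dc[5])  # zero init: untrained model predicts 0
    p$dfin_b <- numeric(1L)
    p
  })
  structure(list(spec = spec, params = params,
                 tab_center = numeric(33L), tab_scale = rep(1, 33L),
                 hooks = local({
                   e <- new.env(parent = emptyenv())
                   e$n_encode_img <- 0L; e$n_encode_tab <- 0L
                   e
                 })),
            class = "psqa_model")
}

# ---- batched forward primitives (training path and user ops share these) --

.enc_img_fwd <- function(params, x) {
  caches <- vector("list", 4)
  a <- x
  for (i in 1:4) {
    cf <- conv_fwd(a, params[[paste0("enc", i, "_W")]],
                   params[[paste0("enc", i, "_b")]], k = 3L, stride = 2L,
                   pad = 1L)
    caches[[i]] <- list(conv = cf, pre = cf$out)
    a <- relu_fwd(cf$out)
    caches[[i]]$act <- a
  }
  list(out = a, caches = caches)
}

.enc_tab_fwd <- function(params, x) {
  pre1 <- params$tab1_W %*% x + params$tab1_b
  h1 <- relu_fwd(pre1)
  out <- params$tab2_W %*% h1 + params$tab2_b
  list(out = out, pre1 = pre1, h1 = h1, x = x)
}

.pool_tab <- function(spec, z_tab) {
  if (spec$tab_pooling == "none") return(z_tab)
  hw <- spec$hz^2
  d <- dim(z_tab)
  m <- z_tab
  dim(m) <- c(spec$n_t, hw, d[2])
  apply(m, 3, rowMeans) -> pt
  matrix(pt, spec$n_t, d[2])
}

# Fused GPR representation for one modality subset; z_img (N_c,hz,hz,B),
# z_tab (N_t*hz*hz, B). Returns (d_f, B) plus the attention cache.
.fuse_gpr_batch <- function(params, spec, z_img, z_tab, subset) {
  B <- dim(z_img)[4]
  p_img <- gap_fwd(z_img)                       # N_c x B
  p_tab <- .pool_tab(spec, z_tab)
  a_img <- params$W_img %*% p_img               # d_f x B
  a_tab <- params$W_tab %*% p_tab
  if (subset == "img+tab") {
    s_img <- as.vector(crossprod(params$ws_img, p_img))
    s_tab <- as.vector(crossprod(params$ws_tab, p_tab))
    mx <- pmax(s_img, s_tab)
    e1 <- exp(s_img - mx); e2 <- exp(s_tab - mx)
    al_img <- e1 / (e1 + e2); al_tab <- e2 / (e1 + e2)
  } else if (subset == "img") {
    al_img <- rep(1, B); al_tab <- rep(0, B)
  } else if (subset == "tab") {
    al_img <- rep(0, B); al_tab <- rep(1, B)
  } else if (subset == "empty") {
    al_img <- rep(0, B); al_tab <- rep(0, B)
  } else stop("unknown modality subset: ", subset)
  Z <- a_img * rep(al_img, each = spec$d_f) + a_tab * rep(al_tab, each = spec$d_f)
  list(Z = Z, p_img = p_img, p_tab = p_tab, a_img = a_img, a_tab = a_tab,
       al_img = al_img, al_tab = al_tab, subset = subset)
}

.head_fwd <- function(params, Z, dropout_p = 0, train = FALSE) {
  r <- relu_fwd(Z)
  mask <- NULL
  h <- r
  if (train && dropout_p > 0) {
    mask <- matrix(stats::runif(length(r)) >= dropout_p, nrow(r)) /
      (1 - dropout_p)
    h <- r * mask
  }
  out <- params$head_W %*% h + params$head_b
  list(out = out, r = r, mask = mask, h = h, Z = Z)
}

.fold_tab <- function(spec, z_tab) {
  d2 <- ncol(z_tab)
  array(z_tab, c(spec$n_t, spec$hz, spec$hz, d2))
}

# Extra input channels per decoder stage contributed by skip connections:
# stage 2 receives encoder stage 3 (same resolution), stage 3 receives
# stage 2, stage 4 receives stage 1; the full-resolution stage has no skip.
.dec_skip_channels <- function(spec) {
  if (!spec$skips) return(rep(0L, 5))
  ec <- spec$enc_channels
  c(0L, ec[3], ec[2], ec[1], 0L)
}

.cat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1] + db[1], da[2], da[3], da[4]))
  out[seq_len(da[1]), , , ] <- a
  out[da[1] + seq_len(db[1]), , , ] <- b
  out
}

# skips: NULL, or list of encoder activations for stages 2..4
# (list(s2 = enc3_act, s3 = enc2_act, s4 = enc1_act)).
.dec_fwd <- function(params, spec, z_ddp, skips = NULL) {
  if (spec$skips && is.null(skips)) {
    stop("decoder configured with skip connections but none supplied")
  }
  caches <- list()
  a <- z_ddp
  for (i in 1:5) {
    if (i > 1) {
      caches[[paste0("updim", i)]] <- dim(a)
      a <- upsample2_fwd(a)
      sk <- skips[[paste0("s", i)]]
      if (spec$skips && !is.null(sk)) a <- .cat_channels(a, sk)
    }
    cf <- conv_fwd(a, params[[paste0("dec", i, "_W")]],
                   params[[paste0("dec", i, "_b")]], k = 3L, stride = 1L,
                   pad = 1L)
    caches[[paste0("conv", i)]] <- cf
    a <- lrelu_fwd(cf$out)
    caches[[paste0("act", i)]] <- a
  }
  d <- dim(a)
  am <- a
  dim(am) <- c(d[1], prod(d[2:4]))
  out <- params$dfin_W %*% am + params$dfin_b
  dim(out) <- c(1L, d[2], d[3], d[4])
  caches$final_in <- am
  caches$final_dim <- d
  list(out = out, caches = caches)
}

# ---- user-facing operations (single sample) -------------------------------

.as_img_input <- function(model, x_img) {
  if (inherits(x_img, "fluence_map")) x_img <- x_img$values
  stopifnot(is.matrix(x_img))
  g <- model$spec$grid
  if (!all(dim(x_img) == c(g, g))) {
    stop(sprintf("encode_image: input is %dx%d but the model expects %dx%d",
                 nrow(x_img), ncol(x_img), g, g))
  }
  array(x_img, c(1L, g, g, 1L))
}

.as_tab_input <- function(model, x_tab) {
  if (inherits(x_tab, "complexity_vector")) x_tab <- x_tab$values
  if (length(x_tab) != 33L) {
    stop("encode_tabular: complexity vector must have length 33")
  }
  matrix((x_tab - model$tab_center) / model$tab_scale, 33L, 1L)
}

#' Encode a fluence map into image feature maps
#'
#' Four strided 3x3 convolution stages (total stride 16) with ReLU; returns
#' an `N_c x H_z x W_z` feature array. Any backbone producing that shape is
#' admissible behind this contract; this is the bundled desk-scale encoder.
#'
#' @param model A [psqa_model()].
#' @param x_img A [fluence_map()] or numeric matrix matching the model grid.
#' @return Numeric array `N_c x H_z x W_z`.
#' @export
encode_image <- function(model, x_img) {
  x <- .as_img_input(model, x_img)
  model$hooks$n_encode_img <- model$hooks$n_encode_img + 1L
  z <- .enc_img_fwd(model$params, x)$out
  array(z, dim(z)[1:3])
}

#' Encode a complexity vector into the tabular embedding
#'
#' Two-layer MLP producing a length `N_t * H_z * W_z` vector (inputs are
#' standardized with the statistics captured by [fit()]).
#'
#' @param model A [psqa_model()].
#' @param x_tab A [complexity_vector()] or numeric vector of length 33.
#' @return Numeric vector of length `N_t * H_z * W_z`.
#' @export
encode_tabular <- function(model, x_tab) {
  x <- .as_tab_input(model, x_tab)
  model$hooks$n_encode_tab <- model$hooks$n_encode_tab + 1L
  as.vector(.enc_tab_fwd(model$params, x)$out)
}

.subset_labels <- function() c("empty", "img", "tab", "img+tab")

#' Attention fusion of the two modality embeddings for the GPR branch
#'
#' Pools both embeddings, projects each to a scalar score, softmax-normalizes
#' the scores into attention weights, and returns the weighted combination
#' of the projected embeddings. For the single-modality subsets the
#' coefficients are forced to (1,0) or (0,1); the empty subset is the zero
#' vector.
#'
#' @param model A [psqa_model()].
#' @param z_img Image features (`N_c x H_z x W_z`) from [encode_image()].
#' @param z_tab Tabular embedding vector from [encode_tabular()].
#' @param subset One of `"img+tab"`, `"img"`, `"tab"`, `"empty"`.
#' @return Fused numeric vector of width `d_f`.
#' @export
fuse_gpr <- function(model, z_img, z_tab, subset = "img+tab") {
  if (!subset %in% .subset_labels()) {
    stop("fuse_gpr: unknown modality subset '", subset, "'")
  }
  zi <- array(z_img, c(dim(z_img)[1:3], 1L))
  zt <- matrix(z_tab, length(z_tab), 1L)
  as.vector(.fuse_gpr_batch(model$params, model$spec, zi, zt, subset)$Z)
}

#' Predict the GPR 3-vector from a fused representation
#'
#' ReLU, dropout (training mode only), then an affine map `d_f -> 3`.
#' Outputs are unbounded reals interpreted as percentages.
#'
#' @param model A [psqa_model()].
#' @param z_gpr Fused vector of width `d_f` from [fuse_gpr()].
#' @param train Logical; enables dropout.
#' @return Numeric 3-vector (1%/1mm, 2%/2mm, 2%/3mm).
#' @export
predict_gpr <- function(model, z_gpr, train = FALSE) {
  if (length(z_gpr) != model$spec$d_f) {
    stop("predict_gpr: fused vector width mismatch")
  }
  as.vector(.head_fwd(model$params, matrix(z_gpr, ncol = 1),
                      model$spec$dropout, train)$out)
}

#' GPR predictions for all four modality subsets from shared embeddings
#'
#' Computes the four fused representations from the *same* encoder outputs
#' and applies the GPR head to each; bit-identical to four independent
#' forward passes sharing the weights, at one encoder invocation per
#' modality.
#'
#' @param model A [psqa_model()].
#' @param z_img,z_tab Encoder outputs (see [encode_image()],
#'   [encode_tabular()]).
#' @return Named list of GPR 3-vectors keyed `"empty"`, `"img"`, `"tab"`,
#'   `"img+tab"`.
#' @export
multi_subset_forward <- function(model, z_img, z_tab) {
  out <- lapply(.subset_labels(), function(s)
    predict_gpr(model, fuse_gpr(model, z_img, z_tab, s)))
  stats::setNames(out, .subset_labels())
}

#' Spatial fusion for the dose-difference branch
#'
#' Folds the tabular embedding vector into `N_t` feature maps (channel-
#' fastest ordering, so fold and flatten are mutual inverses) and
#' concatenates them with the image feature maps along channels, tabular
#' channels first. No attention is applied.
#'
#' @param model A [psqa_model()].
#' @param z_img Image features `N_c x H_z x W_z`.
#' @param z_tab Tabular embedding of length `N_t * H_z * W_z`.
#' @return Array `(N_t + N_c) x H_z x W_z`.
#' @export
fuse_ddp <- function(model, z_img, z_tab) {
  spec <- model$spec
  hz <- spec$hz
  if (length(z_tab) != spec$n_t * hz * hz) {
    stop("fuse_ddp: tabular embedding length is not divisible into N_t maps")
  }
  tab_maps <- array(z_tab, c(spec$n_t, hz, hz))
  out <- array(0, c(spec$n_t + spec$n_c, hz, hz))
  out[seq_len(spec$n_t), , ] <- tab_maps
  out[spec$n_t + seq_len(spec$n_c), , ] <- z_img
  out
}

#' Decode the fused spatial representation into a dose-difference map
#'
#' U-Net-style decoder: an initial 3x3 convolution, four bilinear-upsample +
#' convolution stages following the channel schedule, and a final 1x1
#' convolution to one channel at the input resolution.
#'
#' @param model A [psqa_model()].
#' @param z_ddp Array `(N_c + N_t) x H_z x W_z` from [fuse_ddp()].
#' @param skips For models built with `skips = TRUE`: the encoder's
#'   intermediate activations (`list(s2 =, s3 =, s4 =)` at 2, 4 and 8 times
#'   the latent resolution); see `.enc_img_fwd` caches. `NULL` otherwise.
#' @return Numeric matrix `grid x grid`.
#' @export
predict_ddp <- function(model, z_ddp, skips = NULL) {
  spec <- model$spec
  if (dim(z_ddp)[1] != spec$n_c + spec$n_t) {
    stop("predict_ddp: channel count mismatch with N_c + N_t")
  }
  z <- array(z_ddp, c(dim(z_ddp)[1:3], 1L))
  if (!is.null(skips)) {
    skips <- lapply(skips, function(x) array(x, c(dim(x)[1:3], 1L)))
  }
  out <- .dec_fwd(model$params, spec, z, skips = skips)$out
  matrix(out, spec$grid, spec$grid)
}

#' End-to-end prediction for one PSQA sample
#'
#' @param object A [psqa_model()].
#' @param sample A [psqa_sample()].
#' @param ... Unused.
#' @return List with `gpr` (3-vector, percent) and `dd_map` (matrix).
#' @export
predict.psqa_model <- function(object, sample, ...) {
  x <- .as_img_input(object, sample$fluence)
  enc <- .enc_img_fwd(object$params, x)
  z_img <- array(enc$out, dim(enc$out)[1:3])
  z_tab <- encode_tabular(object, sample$complexity)
  gpr <- predict_gpr(object, fuse_gpr(object, z_img, z_tab, "img+tab"))
  skips <- if (object$spec$skips) .skips_from_enc(enc, drop_batch = TRUE)
           else NULL
  dd <- predict_ddp(object, fuse_ddp(object, z_img, z_tab), skips = skips)
  list(gpr = gpr, dd_map = dd)
}

.skips_from_enc <- function(enc, drop_batch = FALSE) {
  out <- list(s2 = enc$caches[[3]]$act, s3 = enc$caches[[2]]$act,
              s4 = enc$caches[[1]]$act)
  if (drop_batch) out <- lapply(out, function(x) array(x, dim(x)[1:3]))
  out
}

#' @export
print.psqa_model <- function(x, ...) {
  s <- x$spec
  cat(sprintf(paste0("<psqa_model> grid=%d enc=[%s] N_c=%d N_t=%d d_f=%d ",
                     "dec=[%s] dropout=%.2f\n"),
              s$grid, paste(s$enc_channels, collapse = ","), s$n_c, s$n_t,
              s$d_f, paste(s$dec_channels, collapse = ","), s$dropout))
  invisible(x)
}
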
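# Modality-contribution diagnostics and the balanced training loop.
#
# After every epoch the model is evaluated on the validation set under all
# four modality subsets (one shared encoder pass); the value of a subset is
# the negative validation MAE of its GPR predictions, the two-modality
# Shapley decomposition attributes that value to the image and tabular
# modalities, and a dominance of the tabular modality inflates the
# dose-difference loss weight for the next epoch:
#   lambda_ddp = 1 + max(phi_tab - phi_img, 0) * r / 2.

#' Training configuration
#'
#' Defaults follow the published protocol: Modality Balance Factor r = 16,
#' Adam at learning rate 5e-4, 30 epochs, batch size 32, dropout 0.1, and a
#' 7:1:2 train:validation:test split.
#'
#' @param r Modality Balance Factor (>= 0; 0 recovers unbalanced training).
#' @param lr Adam learning rate.
#' @param epochs Number of training epochs.
#' @param batch_size Mini-batch size.
#' @param split Train/validation/test proportions (must sum to 1).
#' @param dropout Dropout rate of the GPR head.
#' @param seed Master seed (fans out to init, shuffling and dropout).
#' @return An object of class `train_config`.
#' @export
train_config <- function(r = 16, lr = 5e-4, epochs = 30L, batch_size = 32L,
                         split = c(train = 0.7, val = 0.1, test = 0.2),
                         dropout = 0.1, seed = 1L) {
  stopifnot(r >= 0, lr > 0, epochs >= 1, batch_size >= 1,
            length(split) == 3, abs(sum(split) - 1) < 1e-8)
  structure(list(r = r, lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 split = stats::setNames(as.numeric(split),
                                         c("train", "val", "test")),
                 dropout = dropout, seed = as.integer(seed)),
            class = "train_config")
}

#' Value function over modality subsets
#'
#' `v(S)` is the negative mean absolute error between the GPR targets and
#' the subset-S predictions, across all validation samples and all three
#' criteria jointly. The empty subset is fixed at zero: the null forward is
#' a sample-independent constant shared by every Shapley computation, so
#' only differences matter.
#'
#' @param predictions_by_subset Named list keyed `"empty"`, `"img"`,
#'   `"tab"`, `"img+tab"`; each element a 3 x n matrix of GPR predictions.
#' @param targets 3 x n matrix of ground-truth GPRs (percent).
#' @return An object of class `subset_value`: named numeric `v` with
#'   `v["empty"] == 0`.
#' @export
value_function <- function(predictions_by_subset, targets) {
  targets <- as.matrix(targets)
  if (ncol(targets) == 0) stop("value_function: empty validation set")
  need <- .subset_labels()
  if (!all(need %in% names(predictions_by_subset))) {
    stop("value_function: predictions must cover all four subsets")
  }
  v <- vapply(need, function(s) {
    p <- as.matrix(predictions_by_subset[[s]])
    stopifnot(all(dim(p) == dim(targets)))
    -mean(abs(targets - p))
  }, numeric(1))
  v["empty"] <- 0
  structure(list(v = v, v_empty = 0), class = "subset_value")
}

.as_value_vector <- function(v) {
  if (inherits(v, "subset_value")) v <- v$v
  if (!all(.subset_labels() %in% names(v))) {
    stop("expected values for subsets: ",
         paste(.subset_labels(), collapse = ", "))
  }
  v
}

#' Closed-form two-modality Shapley decomposition
#'
#' \deqn{\phi_{img} = \tfrac12[v(\{img\}) - v(\emptyset)] +
#'       \tfrac12[v(\{img,tab\}) - v(\{tab\})]} and symmetrically for the
#' tabular modality. Satisfies efficiency, symmetry, dummy and additivity
#' (see [shapley_oracle()] for the enumeration cross-check).
#'
#' @param v A [value_function()] result or named numeric over the four
#'   subsets.
#' @return Named numeric `c(phi_img=, phi_tab=)`.
#' @export
shapley_two_modality <- function(v) {
  v <- .as_value_vector(v)
  phi_img <- 0.5 * (v[["img"]] - v[["empty"]]) +
    0.5 * (v[["img+tab"]] - v[["tab"]])
  phi_tab <- 0.5 * (v[["tab"]] - v[["empty"]]) +
    0.5 * (v[["img+tab"]] - v[["img"]])
  c(phi_img = phi_img, phi_tab = phi_tab)
}

.subset_key <- function(ix) paste(sort(ix), collapse = ",")

.all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in .all_perms(n - 1L)) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos)
    }
  }
  out
}

#' Exact Shapley values by permutation enumeration
#'
#' The verification oracle: averages each player's marginal contribution
#' over every ordering of the players. Supports up to 8 players.
#'
#' @param v Named numeric over the full power set: the empty set is keyed
#'   `""`, other subsets by comma-joined sorted player indices (e.g.
#'   `"1,3"`). The two-modality game uses players 1 = image, 2 = tabular;
#'   see [two_modality_game()].
#' @param n Number of players; inferred from the longest key when omitted.
#' @return Numeric vector of `n` Shapley values.
#' @export
shapley_oracle <- function(v, n = NULL) {
  if (inherits(v, "subset_value")) v <- two_modality_game(v)
  if (is.null(n)) {
    n <- max(vapply(strsplit(names(v), ","), length, integer(1)))
  }
  stopifnot(n >= 1, n <= 8)
  all_keys <- unlist(lapply(0:n, function(k) {
    if (k == 0) return("")
    utils::combn(n, k, .subset_key)
  }))
  missing <- setdiff(all_keys, names(v))
  if (length(missing) > 0) {
    stop("shapley_oracle: value function incomplete; missing subset(s): ",
         paste(sprintf("'%s'", missing), collapse = ", "))
  }
  look <- function(key) v[[match(key, names(v))]]  # [[ "" ]] would fail
  perms <- .all_perms(n)
  phi <- numeric(n)
  for (p in perms) {
    prev <- integer(0)
    for (i in p) {
      phi[i] <- phi[i] + look(.subset_key(c(prev, i))) -
        look(.subset_key(prev))
      prev <- c(prev, i)
    }
  }
  phi / length(perms)
}

#' Express a subset-value object as a two-player game
#' @param v A [value_function()] result.
#' @return Named numeric with keys `""`, `"1"` (image), `"2"` (tabular),
#'   `"1,2"`.
#' @export
two_modality_game <- function(v) {
  v <- .as_value_vector(v)
  stats::setNames(c(v[["empty"]], v[["img"]], v[["tab"]], v[["img+tab"]]),
                  c("", "1", "2", "1,2"))
}

#' Dose-difference loss coefficient from modality contributions
#'
#' `lambda = 1 + max(phi_tab - phi_img, 0) * r / 2`: exactly 1 whenever the
#' tabular modality does not dominate (and always when r = 0).
#'
#' @param phi_img,phi_tab Modality Shapley values.
#' @param r Modality Balance Factor (>= 0).
#' @return Scalar `lambda >= 1`.
#' @export
compute_lambda <- function(phi_img, phi_tab, r) {
  stopifnot(r >= 0)
  1 + max(phi_tab - phi_img, 0) * r / 2
}

#' Total multi-task loss
#' @param l_gpr,l_ddp Nonnegative task losses (MAE).
#' @param lambda_ddp Dose-difference loss coefficient.
#' @return `l_gpr + lambda_ddp * l_ddp`.
#' @export
total_loss <- function(l_gpr, l_ddp, lambda_ddp) {
  stopifnot(l_gpr >= 0, l_ddp >= 0)
  l_gpr + lambda_ddp * l_ddp
}

# ---- batched loss / gradients ---------------------------------------------

# batch: list(x_img (1,g,g,B), x_tab (33,B, standardized), y_gpr (3,B),
# y_dd (1,g,g,B)). Returns losses and gradients for every parameter.
.loss_and_grads <- function(params, spec, batch, lambda, dropout_p) {
  enc <- .enc_img_fwd(params, batch$x_img)
  z_img <- enc$out
  tab <- .enc_tab_fwd(params, batch$x_tab)
  fus <- .fuse_gpr_batch(params, spec, z_img, tab$out, "img+tab")
  hd <- .head_fwd(params, fus$Z, dropout_p, train = TRUE)

  n_t <- spec$n_t; hw <- spec$hz^2
  B <- dim(batch$x_img)[4]
  z_ddp <- array(0, c(n_t + spec$n_c, spec$hz, spec$hz, B))
  z_ddp[seq_len(n_t), , , ] <- .fold_tab(spec, tab$out)
  z_ddp[n_t + seq_len(spec$n_c), , , ] <- z_img
  skips <- if (spec$skips) .skips_from_enc(enc) else NULL
  dec <- .dec_fwd(params, spec, z_ddp, skips = skips)

  l_gpr <- mean(abs(hd$out - batch$y_gpr))
  l_ddp <- mean(abs(dec$out - batch$y_dd))
  if (!is.finite(l_gpr) || !is.finite(l_ddp)) {
    stop(sprintf("non-finite loss (L_gpr=%g, L_ddp=%g): aborting", l_gpr,
                 l_ddp))
  }
  g <- list()

  # GPR head
  dg <- sign(hd$out - batch$y_gpr) / length(batch$y_gpr)
  g$head_W <- dg %*% t(hd$h)
  g$head_b <- rowSums(dg)
  dh <- crossprod(params$head_W, dg)
  if (!is.null(hd$mask)) dh <- dh * hd$mask
  dZ <- dh * (fus$Z > 0)

  # attention fusion
  d_f <- spec$d_f
  dal_img <- colSums(dZ * fus$a_img)
  dal_tab <- colSums(dZ * fus$a_tab)
  da_img <- dZ * rep(fus$al_img, each = d_f)
  da_tab <- dZ * rep(fus$al_tab, each = d_f)
  g$W_img <- da_img %*% t(fus$p_img)
  g$W_tab <- da_tab %*% t(fus$p_tab)
  dp_img <- crossprod(params$W_img, da_img)
  dp_tab <- crossprod(params$W_tab, da_tab)
  ds_img <- fus$al_img * fus$al_tab * (dal_img - dal_tab)
  g$ws_img <- as.vector(fus$p_img %*% ds_img)
  g$ws_tab <- as.vector(fus$p_tab %*% (-ds_img))
  dp_img <- dp_img + outer(params$ws_img, ds_img)
  dp_tab <- dp_tab + outer(params$ws_tab, -ds_img)
  dz_img_gpr <- gap_bwd(dp_img, dim(z_img))
  dz_tab_gpr <- if (spec$tab_pooling == "mean") {
    dp_tab[rep(seq_len(n_t), times = hw), , drop = FALSE] / hw
  } else {
    dp_tab
  }

  # DDP decoder
  dd_out <- lambda * sign(dec$out - batch$y_dd) / length(batch$y_dd)
  dm <- dd_out
  dim(dm) <- c(1L, length(dm))
  g$dfin_W <- dm %*% t(dec$caches$final_in)
  g$dfin_b <- sum(dm)
  da <- crossprod(params$dfin_W, dm)
  dim(da) <- dec$caches$final_dim
  skip_ch <- .dec_skip_channels(spec)
  dskip <- list()  # gradient into encoder activations via skip connections
  for (i in 5:1) {
    cf <- dec$caches[[paste0("conv", i)]]
    da <- lrelu_bwd(da, cf$out)
    cb <- conv_bwd(da, params[[paste0("dec", i, "_W")]], cf)
    g[[paste0("dec", i, "_W")]] <- cb$dW
    g[[paste0("dec", i, "_b")]] <- cb$db
    da <- cb$dx
    if (i > 1) {
      if (skip_ch[i] > 0) {
        nin <- dim(da)[1] - skip_ch[i]
        dskip[[paste0("s", i)]] <- da[nin + seq_len(skip_ch[i]), , , ,
                                      drop = FALSE]
        da <- da[seq_len(nin), , , , drop = FALSE]
      }
      da <- upsample2_bwd(da, dec$caches[[paste0("updim", i)]])
    }
  }
  dz_ddp <- da
  dtab_flat <- dz_ddp[seq_len(n_t), , , , drop = FALSE]
  dim(dtab_flat) <- c(n_t * hw, B)
  dz_img_tot <- dz_img_gpr + dz_ddp[n_t + seq_len(spec$n_c), , , ,
                                    drop = FALSE]

  # image encoder; skip connections feed extra gradient into the
  # intermediate activations (decoder stage 2 reads encoder stage 3, etc.)
  enc_skip_grad <- list(NULL, dskip[["s3"]], dskip[["s2"]], NULL)
  if (!is.null(dskip[["s4"]])) enc_skip_grad[[1]] <- dskip[["s4"]]
  da <- dz_img_tot
  for (i in 4:1) {
    if (i < 4 && !is.null(enc_skip_grad[[i]])) {
      da <- da + enc_skip_grad[[i]]
    }
    cf <- enc$caches[[i]]$conv
    da <- relu_bwd(da, cf$out)
    cb <- conv_bwd(da, params[[paste0("enc", i, "_W")]], cf)
    g[[paste0("enc", i, "_W")]] <- cb$dW
    g[[paste0("enc", i, "_b")]] <- cb$db
    da <- cb$dx
  }

  # tabular encoder
  dz_tab_tot <- dz_tab_gpr + dtab_flat
  g$tab2_W <- dz_tab_tot %*% t(tab$h1)
  g$tab2_b <- rowSums(dz_tab_tot)
  dh1 <- crossprod(params$tab2_W, dz_tab_tot)
  dpre1 <- dh1 * (tab$pre1 > 0)
  g$tab1_W <- dpre1 %*% t(tab$x)
  g$tab1_b <- rowSums(dpre1)

  list(l_gpr = l_gpr, l_ddp = l_ddp, grads = g)
}

# Evaluation-mode subset predictions for a stacked set (one encoder pass).
.subset_preds_batch <- function(params, spec, x_img, x_tab) {
  z_img <- .enc_img_fwd(params, x_img)$out
  z_tab <- .enc_tab_fwd(params, x_tab)$out
  out <- lapply(.subset_labels(), function(s) {
    Z <- .fuse_gpr_batch(params, spec, z_img, z_tab, s)$Z
    .head_fwd(params, Z, 0, FALSE)$out
  })
  stats::setNames(out, .subset_labels())
}

# Stack a sample list into batch tensors (raw, unstandardized tabular).
.stack_samples <- function(samples, grid) {
  n <- length(samples)
  x_img <- array(0, c(1L, grid, grid, n))
  x_tab <- matrix(0, 33L, n)
  y_gpr <- matrix(0, 3L, n)
  y_dd <- array(0, c(1L, grid, grid, n))
  for (i in seq_len(n)) {
    s <- samples[[i]]
    stopifnot(all(dim(s$fluence$values) == c(grid, grid)))
    x_img[1, , , i] <- s$fluence$values
    x_tab[, i] <- s$complexity$values
    y_gpr[, i] <- s$targets$gpr_percent
    if (!is.null(s$targets$dd_map)) y_dd[1, , , i] <- s$targets$dd_map
  }
  list(x_img = x_img, x_tab = x_tab, y_gpr = y_gpr, y_dd = y_dd, n = n)
}

#' Run one training epoch at a fixed dose-difference loss weight
#'
#' One pass over the supplied mini-batches minimizing
#' `L_gpr + lambda * L_ddp` with Adam; both task heads and both encoders are
#' updated jointly.
#'
#' @param model A [psqa_model()].
#' @param batches List of batches, each a list with `x_img` (1 x g x g x B),
#'   `x_tab` (33 x B, already standardized), `y_gpr` (3 x B), `y_dd`
#'   (1 x g x g x B).
#' @param lambda_current Fixed loss weight for this epoch (>= 1).
#' @param opt Adam state from `adam_init`; updated in place.
#' @return List: updated `model`, mean `l_gpr`, mean `l_ddp`.
#' @export
train_epoch <- function(model, batches, lambda_current, opt) {
  stopifnot(lambda_current >= 1)
  lg <- ld <- numeric(length(batches))
  params <- model$params
  for (bi in seq_along(batches)) {
    r <- .loss_and_grads(params, model$spec, batches[[bi]], lambda_current,
                         model$spec$dropout)
    params <- adam_step(opt, params, r$grads)
    lg[bi] <- r$l_gpr; ld[bi] <- r$l_ddp
  }
  model$params <- params
  list(model = model, l_gpr = mean(lg), l_ddp = mean(ld))
}

#' Train the balanced multimodal model
#'
#' Runs the per-epoch procedure: train one epoch at the current lambda
#' (initialized to 1), then compute validation-set subset predictions with a
#' single shared encoder pass, the subset value function, the two-modality
#' Shapley decomposition, and the lambda for the *next* epoch. The per-epoch
#' history of contributions and lambdas is returned for contribution-curve
#' and r-sweep analyses.
#'
#' @param samples List of [psqa_sample()] (with dose-difference targets).
#' @param assignment Optional [stratified_split()] result; computed from
#'   `cfg$split` and `cfg$seed` when omitted.
#' @param cfg A [train_config()].
#' @param spec A [network_spec()]; its grid must match the samples.
#' @param verbose Print one line per epoch.
#' @return An object of class `psqa_fit`: `model`, `history` (one
#'   `shapley_report` per epoch), `assignment`, `cfg`.
#' @export
fit <- function(samples, assignment = NULL, cfg = train_config(),
                spec = network_spec(), verbose = FALSE) {
  stopifnot(length(samples) > 0)
  if (is.null(assignment)) {
    assignment <- stratified_split(samples, ratios = cfg$split,
                                   seed = cfg$seed)
  }
  ids <- vapply(samples, function(s) s$sample_id, character(1))
  split_of <- stats::setNames(assignment$split, assignment$sample_id)[ids]
  tens <- .stack_samples(samples, spec$grid)
  idx_train <- which(split_of == "train")
  idx_val <- which(split_of == "val")
  if (length(idx_train) == 0 || length(idx_val) == 0) {
    stop("fit: empty train or validation split")
  }

  model <- psqa_model(spec, seed = cfg$seed)
  # standardize the tabular modality on the training split
  ctr <- rowMeans(tens$x_tab[, idx_train, drop = FALSE])
  scl <- apply(tens$x_tab[, idx_train, drop = FALSE], 1, stats::sd)
  scl[!is.finite(scl) | scl < 1e-8] <- 1
  model$tab_center <- ctr
  model$tab_scale <- scl
  xt_std <- (tens$x_tab - ctr) / scl
  # regression-head bias starts at the training-set mean GPR
  model$params$head_b <- rowMeans(tens$y_gpr[, idx_train, drop = FALSE])

  opt <- adam_init(model$params, lr = cfg$lr)
  history <- vector("list", cfg$epochs)
  lambda <- 1
  val_targets <- tens$y_gpr[, idx_val, drop = FALSE]
  x_img_val <- tens$x_img[, , , idx_val, drop = FALSE]
  x_tab_val <- xt_std[, idx_val, drop = FALSE]

  with_seed(cfg$seed + 1L, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample(idx_train)
      starts <- seq(1, length(ord), by = cfg$batch_size)
      batches <- lapply(starts, function(s0) {
        ii <- ord[s0:min(s0 + cfg$batch_size - 1, length(ord))]
        list(x_img = tens$x_img[, , , ii, drop = FALSE],
             x_tab = xt_std[, ii, drop = FALSE],
             y_gpr = tens$y_gpr[, ii, drop = FALSE],
             y_dd = tens$y_dd[, , , ii, drop = FALSE])
      })
      te <- train_epoch(model, batches, lambda, opt)
      model <- te$model
      preds <- .subset_preds_batch(model$params, spec, x_img_val, x_tab_val)
      v <- value_function(preds, val_targets)
      phi <- shapley_two_modality(v)
      lambda_next <- compute_lambda(phi[["phi_img"]], phi[["phi_tab"]],
                                    cfg$r)
      history[[ep]] <- structure(
        list(epoch = ep, v = v, phi_img = phi[["phi_img"]],
             phi_tab = phi[["phi_tab"]], lambda_ddp = lambda_next,
             lambda_used = lambda, l_gpr = te$l_gpr, l_ddp = te$l_ddp),
        class = "shapley_report")
      if (verbose) {
        cat(sprintf(
          "epoch %2d  L_gpr=%7.3f L_ddp=%8.5f  phi_img=%7.3f phi_tab=%7.3f  lambda_next=%6.2f\n",
          ep, te$l_gpr, te$l_ddp, phi[["phi_img"]], phi[["phi_tab"]],
          lambda_next))
      }
      lambda <- lambda_next
    }
  })
  structure(list(model = model, history = history, assignment = assignment,
                 cfg = cfg),
            class = "psqa_fit")
}

#' Batched test-set predictions from a fitted model
#'
#' @param fit_obj A [fit()] result (or a `psqa_model` plus samples).
#' @param samples Samples to predict.
#' @return List: `gpr` (3 x n matrix, percent), `dd` (list of matrices).
#' @export
predict_batch <- function(fit_obj, samples) {
  model <- if (inherits(fit_obj, "psqa_fit")) fit_obj$model else fit_obj
  spec <- model$spec
  tens <- .stack_samples(samples, spec$grid)
  xt <- (tens$x_tab - model$tab_center) / model$tab_scale
  enc <- .enc_img_fwd(model$params, tens$x_img)
  z_img <- enc$out
  z_tab <- .enc_tab_fwd(model$params, xt)$out
  Z <- .fuse_gpr_batch(model$params, spec, z_img, z_tab, "img+tab")$Z
  gpr <- .head_fwd(model$params, Z, 0, FALSE)$out
  n_t <- spec$n_t
  B <- tens$n
  z_ddp <- array(0, c(n_t + spec$n_c, spec$hz, spec$hz, B))
  z_ddp[seq_len(n_t), , , ] <- .fold_tab(spec, z_tab)
  z_ddp[n_t + seq_len(spec$n_c), , , ] <- z_img
  skips <- if (spec$skips) .skips_from_enc(enc) else NULL
  dd_out <- .dec_fwd(model$params, spec, z_ddp, skips = skips)$out
  dd <- lapply(seq_len(B), function(i) matrix(dd_out[1, , , i], spec$grid,
                                              spec$grid))
  list(gpr = gpr, dd = dd)
}

#' @export
print.shapley_report <- function(x, ...) {
  cat(sprintf(
    "<shapley_report epoch %d> phi_img=%.4f phi_tab=%.4f lambda_ddp=%.3f\n",
    x$epoch, x$phi_img, x$phi_tab, x$lambda_ddp))
  invisible(x)
}
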
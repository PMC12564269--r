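# Synthetic PSQA data generation.
#
# A sliding-window IMRT beam is emulated as a sequence of MLC apertures
# (leaf-pair left/right edges sweeping across the field). The rendered,
# MU-weighted exposure is the planned fluence; simplified geometric
# summaries of the same aperture sequence fill the 33-slot complexity
# vector; a delivery perturbation model produces the "measured" dose; the
# gamma engine mints GPR targets. The perturbation family is a stand-in for
# portal-dosimetry measurement physics, which the clinical protocol does not
# describe; it is parameterized so that the tabular and image modalities can
# be made more or less informative (rho_tab, rho_img).

# Run expr with a private RNG stream, restoring the caller's stream after.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

#' Construct an MLC aperture sequence
#'
#' @param left_edges,right_edges Numeric matrices (control points x leaf
#'   pairs) of leaf positions in mm along the sweep axis; `right >= left`
#'   everywhere (gap >= 0).
#' @param mu_per_cp Nonnegative monitor units per control point; the total
#'   must be positive.
#' @param leaf_width_mm Physical width of one leaf pair.
#' @param field_width_mm Extent of the sweep axis.
#' @return An object of class `aperture_sequence`.
#' @export
aperture_sequence <- function(left_edges, right_edges, mu_per_cp,
                              leaf_width_mm = 4, field_width_mm = 64) {
  left_edges <- as.matrix(left_edges); right_edges <- as.matrix(right_edges)
  stopifnot(identical(dim(left_edges), dim(right_edges)),
            length(mu_per_cp) == nrow(left_edges))
  if (any(right_edges - left_edges < -1e-9)) {
    stop("aperture_sequence: right edge below left edge (negative gap)")
  }
  if (any(mu_per_cp < 0) || sum(mu_per_cp) <= 0) {
    stop("aperture_sequence: monitor units must be nonnegative with a positive total")
  }
  structure(list(left_edges = left_edges, right_edges = right_edges,
                 mu_per_cp = as.numeric(mu_per_cp),
                 n_control_points = nrow(left_edges),
                 leaf_pairs = ncol(left_edges),
                 leaf_width_mm = leaf_width_mm,
                 field_width_mm = field_width_mm),
            class = "aperture_sequence")
}

# Site-dependent leaf-gap statistics (mm). Head-and-neck plans are the most
# modulated (small, variable gaps); chest fields are broad and smooth.
.site_gap_params <- function(site) {
  switch(site,
         "H&N" = list(mean_gap = 8,  sd_gap = 4.0),
         "C"   = list(mean_gap = 20, sd_gap = 5.0),
         "A"   = list(mean_gap = 13, sd_gap = 4.0),
         "P"   = list(mean_gap = 16, sd_gap = 4.0),
         stop("unknown lesion site: ", site))
}

#' Generate a sliding-window aperture sequence for a treatment site
#'
#' Left and right leaf edges sweep across the field; the gap between them
#' follows site-dependent statistics (head-and-neck: smaller, more variable
#' gaps; chest: larger gaps). Leaf pairs outside a randomly chosen active
#' band stay closed.
#'
#' @param site One of [lesion_sites()].
#' @param seed Integer seed; the call is deterministic given it.
#' @param n_control_points Number of control points (default 24).
#' @param leaf_pairs Number of leaf pairs (default 16).
#' @param leaf_width_mm,field_width_mm Field geometry (defaults 4 / 64).
#' @return An [aperture_sequence()].
#' @export
gen_aperture_sequence <- function(site, seed, n_control_points = 24,
                                  leaf_pairs = 16, leaf_width_mm = 4,
                                  field_width_mm = 64) {
  stopifnot(site %in% lesion_sites(), n_control_points >= 1)
  gp <- .site_gap_params(site)
  with_seed(seed, {
    T_ <- n_control_points; P_ <- leaf_pairs
    # active band of leaf pairs (at least half the bank)
    n_active <- max(4L, sample(ceiling(P_ / 2):P_, 1))
    first <- sample(seq_len(P_ - n_active + 1L), 1)
    active <- seq(first, first + n_active - 1L)
    # sweep: aperture centre moves left -> right across the field
    margin <- 0.12 * field_width_mm
    centres <- if (T_ == 1) field_width_mm / 2 else
      seq(margin, field_width_mm - margin, length.out = T_)
    pair_offset <- stats::rnorm(P_, 0, 0.06 * field_width_mm)
    left <- matrix(0, T_, P_); right <- matrix(0, T_, P_)
    for (p in seq_len(P_)) {
      if (!(p %in% active)) {
        park <- field_width_mm / 2
        left[, p] <- park; right[, p] <- park
        next
      }
      gaps <- pmax(0, stats::rnorm(T_, gp$mean_gap, gp$sd_gap))
      mid <- centres + pair_offset[p] + stats::rnorm(T_, 0, 1.5)
      l <- mid - gaps / 2
      r <- mid + gaps / 2
      l <- pmin(pmax(l, 0), field_width_mm)
      r <- pmin(pmax(r, l), field_width_mm)
      left[, p] <- l; right[, p] <- r
    }
    mu <- stats::runif(T_, 0.6, 1.4)
    mu <- mu / sum(mu) * stats::runif(1, 60, 140)
    aperture_sequence(left, right, mu, leaf_width_mm, field_width_mm)
  })
}

#' Render an aperture sequence into a planned fluence map
#'
#' Accumulates MU-weighted open-aperture exposure on the pixel grid, applies
#' optional Gaussian smoothing, then min-max normalizes to `[0, 1]`. With a
#' constant positive exposure (no dynamic range) the open region is defined
#' as 1 and the rest 0; an all-closed sequence yields an all-zero map.
#'
#' @param ap An [aperture_sequence()].
#' @param grid Integer 2-vector (H, W), each at least 8.
#' @param spacing_mm Pixel pitch in mm.
#' @param blur_sigma_px Smoothing width in pixels (default 0 = none, which
#'   keeps aperture footprints geometrically exact).
#' @return A [fluence_map()].
#' @export
render_fluence <- function(ap, grid = c(64, 64), spacing_mm = 1.0,
                           blur_sigma_px = 0) {
  stopifnot(length(grid) == 2, all(grid >= 8))
  H <- as.integer(grid[1]); W <- as.integer(grid[2])
  acc <- matrix(0, H, W)
  # leaf pairs tile the rows top to bottom
  rows_per_pair <- H / ap$leaf_pairs
  xc <- (seq_len(W) - 0.5) * spacing_mm  # pixel centre x-coordinates
  for (t in seq_len(ap$n_control_points)) {
    mu <- ap$mu_per_cp[t]
    if (mu <= 0) next
    for (p in seq_len(ap$leaf_pairs)) {
      l <- ap$left_edges[t, p]; r <- ap$right_edges[t, p]
      if (r - l <= 0) next
      cols <- which(xc >= l & xc < r)
      if (length(cols) == 0) next
      r1 <- floor((p - 1) * rows_per_pair) + 1L
      r2 <- floor(p * rows_per_pair)
      if (r2 < r1) next
      acc[r1:r2, cols] <- acc[r1:r2, cols] + mu
    }
  }
  if (blur_sigma_px > 0) acc <- .gauss_blur(acc, blur_sigma_px)
  rng <- range(acc)
  vals <- if (rng[2] > rng[1]) {
    (acc - rng[1]) / (rng[2] - rng[1])
  } else if (rng[2] > 0) {
    (acc > 0) * 1.0
  } else {
    acc
  }
  fluence_map(vals, spacing_mm)
}

# Separable Gaussian blur with zero padding (background is zero dose).
.gauss_blur <- function(mat, sigma_px) {
  r <- max(1L, ceiling(3 * sigma_px))
  k <- stats::dnorm(-r:r, sd = sigma_px)
  k <- k / sum(k)
  H <- nrow(mat); W <- ncol(mat)
  padded <- matrix(0, H + 2 * r, W)
  padded[(r + 1):(r + H), ] <- mat
  tmp <- matrix(0, H, W)
  for (o in -r:r) tmp <- tmp + k[o + r + 1] * padded[(r + 1 + o):(r + H + o), , drop = FALSE]
  padded <- matrix(0, H, W + 2 * r)
  padded[, (r + 1):(r + W)] <- tmp
  out <- matrix(0, H, W)
  for (o in -r:r) out <- out + k[o + r + 1] * padded[, (r + 1 + o):(r + W + o), drop = FALSE]
  out
}

# Bilinear translation by (dy, dx) pixels, zero outside the grid.
.bilinear_shift <- function(mat, dy, dx) {
  if (dy == 0 && dx == 0) return(mat)
  H <- nrow(mat); W <- ncol(mat)
  i0 <- floor(dy); j0 <- floor(dx)
  fy <- dy - i0; fx <- dx - j0
  grab <- function(oi, oj) {
    out <- matrix(0, H, W)
    src_r <- seq_len(H) - oi
    src_c <- seq_len(W) - oj
    vr <- src_r >= 1 & src_r <= H
    vc <- src_c >= 1 & src_c <= W
    if (any(vr) && any(vc)) {
      out[which(vr), which(vc)] <- mat[src_r[vr], src_c[vc], drop = FALSE]
    }
    out
  }
  (1 - fy) * (1 - fx) * grab(i0, j0) +
    (1 - fy) * fx * grab(i0, j0 + 1) +
    fy * (1 - fx) * grab(i0 + 1, j0) +
    fy * fx * grab(i0 + 1, j0 + 1)
}

#' Construct a delivery perturbation
#'
#' Stand-in for measurement/delivery physics: a multiplicative gain error, a
#' Gaussian detector blur, a rigid in-plane shift, and additive Gaussian
#' noise.
#'
#' @param gain Multiplicative dose error (near 1).
#' @param blur_sigma_mm Nonnegative blur width in mm.
#' @param shift_mm Real 2-vector (row, column) shift in mm.
#' @param noise_sd Nonnegative additive noise standard deviation.
#' @param seed Integer seed for the noise stream.
#' @return An object of class `delivery_perturbation`.
#' @export
delivery_perturbation <- function(gain = 1, blur_sigma_mm = 0,
                                  shift_mm = c(0, 0), noise_sd = 0,
                                  seed = 1L) {
  stopifnot(blur_sigma_mm >= 0, noise_sd >= 0, length(shift_mm) == 2)
  structure(list(gain = gain, blur_sigma_mm = blur_sigma_mm,
                 shift_mm = as.numeric(shift_mm), noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "delivery_perturbation")
}

#' Simulate delivery of a planned fluence
#'
#' `measured = gain * shift(blur(planned)) + noise`, clipped at zero;
#' `dd_map = measured - planned`. Deterministic given the perturbation seed.
#'
#' @param planned A [fluence_map()].
#' @param pert A [delivery_perturbation()].
#' @return List with `measured` (matrix) and `dd_map` (matrix).
#' @export
simulate_delivery <- function(planned, pert) {
  stopifnot(inherits(planned, "fluence_map"),
            inherits(pert, "delivery_perturbation"))
  x <- planned$values
  sp <- planned$spacing_mm
  if (pert$blur_sigma_mm > 0) x <- .gauss_blur(x, pert$blur_sigma_mm / sp)
  x <- .bilinear_shift(x, pert$shift_mm[1] / sp, pert$shift_mm[2] / sp)
  x <- pert$gain * x
  if (pert$noise_sd > 0) {
    x <- x + with_seed(pert$seed,
                       matrix(stats::rnorm(length(x), 0, pert$noise_sd),
                              nrow(x), ncol(x)))
  }
  x <- pmax(x, 0)
  list(measured = x, dd_map = x - planned$values)
}

#' Simulation configuration
#'
#' @param n_samples Number of beams to generate.
#' @param grid Pixel grid (H, W); desk-scale default 64 x 64.
#' @param spacing_mm Pixel pitch (default 1 mm).
#' @param lesion_mix Proportions over sites (H&N, C, A, P); defaults to the
#'   19/138/31/22 plan mix of the reference cohort.
#' @param rho_tab In `[0, 1]`: how strongly the perturbation severity (hence
#'   GPR) couples to the plan-complexity metrics. 0 decouples them.
#' @param rho_img In `[0, 1]`: amplitude of the spatially structured,
#'   image-predictable dose error component.
#' @param perturbation Amplitude parameters of the delivery model:
#'   `gain_amp` (max |gain - 1|), `blur_amp` (mm), `shift_amp` (mm),
#'   `noise_amp` (dose units), `img_amp` (mean structured |dd| in dose
#'   units). `identity_perturbation()` zeroes them all.
#' @param site_difficulty Named severity multipliers per site.
#' @param seed Master seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_samples = 210,
                       grid = c(64, 64),
                       spacing_mm = 1.0,
                       lesion_mix = c("H&N" = 19, "C" = 138,
                                      "A" = 31, "P" = 22) / 210,
                       rho_tab = 0.8,
                       rho_img = 0.8,
                       perturbation = list(gain_amp = 0.03,
                                           blur_amp = 0.30,
                                           shift_amp = 0.08,
                                           noise_amp = 0.0012,
                                           img_amp = 0.003),
                       site_difficulty = c("H&N" = 1.2, "C" = 0.85,
                                           "A" = 1.0, "P" = 1.0),
                       seed = 1L) {
  stopifnot(n_samples >= 0, length(lesion_mix) == 4,
            abs(sum(lesion_mix) - 1) < 1e-8,
            rho_tab >= 0, rho_tab <= 1, rho_img >= 0, rho_img <= 1)
  structure(list(n_samples = as.integer(n_samples), grid = as.integer(grid),
                 spacing_mm = spacing_mm,
                 lesion_mix = stats::setNames(as.numeric(lesion_mix),
                                              lesion_sites()),
                 rho_tab = rho_tab, rho_img = rho_img,
                 perturbation = perturbation,
                 site_difficulty = site_difficulty,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Identity (no-error) perturbation amplitudes
#' @return List of all-zero amplitude parameters for [sim_config()].
#' @export
identity_perturbation <- function() {
  list(gain_amp = 0, blur_amp = 0, shift_amp = 0, noise_amp = 0, img_amp = 0)
}

# Largest-remainder apportionment of n among proportions p (deterministic).
largest_remainder <- function(n, p, priority = seq_along(p)) {
  quota <- n * p / sum(p)
  counts <- floor(quota)
  rem <- quota - counts
  left <- n - sum(counts)
  if (left > 0) {
    ord <- order(-rem, priority)
    counts[ord[seq_len(left)]] <- counts[ord[seq_len(left)]] + 1
  }
  as.integer(counts)
}

#' Compute the 33-slot plan-complexity vector of an aperture sequence
#'
#' Simplified geometric analogues of the published MLC complexity metrics,
#' computed on the sequence itself ("distal", `d-`) and on a jittered copy
#' standing in for the second MLC layer ("proximal", `p-`): AAV (per-control-
#' point aperture-area coefficient of variation), LSV (mean absolute
#' adjacent-leaf edge difference), MCS (AAV x LSV composite), BA (mean
#' aperture area / field area), UAA (area of the union of apertures, cm^2),
#' PI (mean perimeter^2 / (4 pi area)), PM (1 - mean area / max area), C/A
#' (mean perimeter / area), CLS (fraction of fully closed pairs), MAD (mean
#' |aperture midpoint - field axis|, mm), SAS-w (fraction of open pairs with
#' gap < w mm), ALG (mean leaf gap, mm), SLG (leaf-gap standard deviation,
#' mm), and the beam's total MU.
#'
#' @param ap An [aperture_sequence()] with positive total MU.
#' @param jitter_seed Seed of the deterministic jitter used for the proximal
#'   copy.
#' @return A [complexity_vector()].
#' @export
compute_complexity_vector <- function(ap, jitter_seed = 97L) {
  if (sum(ap$mu_per_cp) <= 0) {
    stop("compute_complexity_vector: zero-MU sequence")
  }
  prox <- with_seed(jitter_seed, .jitter_sequence(ap))
  d <- .layer_metrics(ap)
  p <- .layer_metrics(prox)
  vals <- c(as.vector(rbind(d, p)), sum(ap$mu_per_cp))
  complexity_vector(vals)
}

# Jitter midpoints and scale gaps multiplicatively so closed pairs stay
# closed; emulates the second MLC layer without transport physics.
.jitter_sequence <- function(ap) {
  gap <- ap$right_edges - ap$left_edges
  mid <- (ap$right_edges + ap$left_edges) / 2
  jmid <- mid + matrix(stats::rnorm(length(mid), 0, 0.8), nrow(mid))
  jfac <- matrix(exp(stats::rnorm(length(gap), 0, 0.15)), nrow(gap))
  g2 <- gap * jfac
  l <- pmin(pmax(jmid - g2 / 2, 0), ap$field_width_mm)
  r <- pmin(pmax(jmid + g2 / 2, l), ap$field_width_mm)
  aperture_sequence(l, r, ap$mu_per_cp, ap$leaf_width_mm, ap$field_width_mm)
}

# 16 geometric summaries of one MLC layer, in roster order (without MU).
.layer_metrics <- function(ap) {
  gap <- ap$right_edges - ap$left_edges       # T x P
  lw <- ap$leaf_width_mm
  T_ <- nrow(gap)
  open <- gap > 1e-9
  area_cp <- rowSums(gap) * lw                 # mm^2 per control point
  field_area <- ap$field_width_mm * (ap$leaf_pairs * lw)
  mean_area <- mean(area_cp)

  aav <- if (T_ > 1 && mean_area > 0) stats::sd(area_cp) / mean_area else 0
  lsv <- mean(c(abs(apply(ap$left_edges, 1, diff)),
                abs(apply(ap$right_edges, 1, diff))))
  mcs <- aav * lsv
  ba <- mean_area / field_area
  # union of open intervals per pair, accumulated across control points
  uaa_mm2 <- 0
  for (p_ in seq_len(ncol(gap))) {
    iv <- which(open[, p_])
    if (length(iv) == 0) next
    l <- ap$left_edges[iv, p_]; r <- ap$right_edges[iv, p_]
    o <- order(l)
    l <- l[o]; r <- r[o]
    tot <- 0; cl <- l[1]; cr <- r[1]
    for (k in seq_along(l)[-1]) {
      if (l[k] <= cr) cr <- max(cr, r[k])
      else { tot <- tot + (cr - cl); cl <- l[k]; cr <- r[k] }
    }
    tot <- tot + (cr - cl)
    uaa_mm2 <- uaa_mm2 + tot * lw
  }
  uaa <- uaa_mm2 / 100  # cm^2
  perim_cp <- vapply(seq_len(T_), function(t)
    sum(2 * (gap[t, open[t, ]] + lw)), numeric(1))
  has_area <- area_cp > 0
  pi_ <- if (any(has_area))
    mean(perim_cp[has_area]^2 / (4 * pi * area_cp[has_area])) else 0
  pm <- if (max(area_cp) > 0) 1 - mean_area / max(area_cp) else 0
  ca <- if (any(has_area)) mean(perim_cp[has_area] / area_cp[has_area]) else 0
  cls <- mean(!open)
  mids <- (ap$left_edges + ap$right_edges) / 2
  mad <- if (any(open))
    mean(abs(mids[open] - ap$field_width_mm / 2)) else 0
  n_open <- sum(open)
  sas <- vapply(c(2, 5, 10, 15), function(w)
    if (n_open > 0) sum(gap[open] < w) / n_open else 0, numeric(1))
  alg <- mean(gap)
  slg <- if (length(gap) > 1) stats::sd(gap) else 0

  c(AAV = aav, LSV = lsv, MCS = mcs, BA = ba, UAA = uaa, PI = pi_, PM = pm,
    "C/A" = ca, CLS = cls, MAD = mad,
    "SAS-2mm" = sas[1], "SAS-5mm" = sas[2], "SAS-10mm" = sas[3],
    "SAS-15mm" = sas[4], ALG = alg, SLG = slg)
}

#' Generate a synthetic PSQA dataset
#'
#' For each sample: a site is drawn from the lesion mix (deterministic
#' largest-remainder allocation of counts, then a seeded shuffle); an
#' aperture sequence is generated and rendered to a planned fluence; the
#' complexity vector is computed from the same geometry; a perturbation
#' whose severity couples to the complexity metrics with strength `rho_tab`
#' (and carries an image-predictable structured component scaled by
#' `rho_img`) produces the measured dose; the gamma engine computes GPR
#' targets at 1%/1mm, 2%/2mm and 2%/3mm.
#'
#' @param cfg A [sim_config()].
#' @return List of valid [psqa_sample()] objects with a `"provenance"`
#'   attribute recording the configuration and seed.
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_samples
  sites_all <- lesion_sites()
  counts <- largest_remainder(n, cfg$lesion_mix)
  site_vec <- rep(sites_all, counts)
  pp <- cfg$perturbation
  samples <- with_seed(cfg$seed, {
    site_vec <- sample(site_vec)
    seeds <- sample.int(.Machine$integer.max - 1L, max(n, 1))
    out <- vector("list", n)
    for (i in seq_len(n)) {
      site <- site_vec[i]
      ap <- gen_aperture_sequence(site, seeds[i],
                                  field_width_mm = cfg$grid[2] * cfg$spacing_mm,
                                  leaf_pairs = max(8L, cfg$grid[1] %/% 4L),
                                  leaf_width_mm = cfg$grid[1] * cfg$spacing_mm /
                                    max(8L, cfg$grid[1] %/% 4L))
      planned <- render_fluence(ap, cfg$grid, cfg$spacing_mm)
      cx <- compute_complexity_vector(ap)
      # severity in [0, 1]: complexity-coupled part vs. idiosyncratic part
      alg <- cx$values[match("d-ALG", cx$names)]
      tab_driver <- min(max((20 - alg) / 16, 0), 1)
      u <- stats::runif(1)
      sev <- cfg$rho_tab * tab_driver + (1 - cfg$rho_tab) * u
      # the site effect is part of the plan-geometry coupling, so it is
      # scaled by rho_tab as well (rho_tab = 0 fully decouples GPR from
      # everything the complexity vector can see)
      site_mult <- 1 + cfg$rho_tab * (cfg$site_difficulty[[site]] - 1)
      sev <- min(sev * site_mult, 1.25)
      # image-predictable structured error: edge softening with a fixed
      # spatial law, normalized so its magnitude is geometry-independent
      base <- planned$values
      if (cfg$rho_img > 0 && pp$img_amp > 0) {
        E <- .gauss_blur(base, 2.5 / cfg$spacing_mm) - base
        # normalize over the gamma-evaluated region so the per-map impact
        # is geometry-independent (sparse apertures are not penalized)
        infield <- base > 0.1 * max(base)
        mE <- if (any(infield)) mean(abs(E[infield])) else mean(abs(E))
        if (mE > 0) {
          # magnitude tracks the delivery severity (so the GPR remains
          # tabular-predictable) while the spatial pattern is image-only
          s_img <- (0.25 + sev) * stats::runif(1, 0.8, 1.2)
          base <- base + cfg$rho_img * pp$img_amp * s_img * E / mE
        }
      }
      pert <- delivery_perturbation(
        gain = 1 + pp$gain_amp * sev * sample(c(-1, 1), 1),
        blur_sigma_mm = pp$blur_amp * sev,
        shift_mm = pp$shift_amp * sev * stats::rnorm(2, 0, 1),
        noise_sd = pp$noise_amp * (0.25 + sev),
        seed = seeds[i] %% 1000000L + 7L)
      res <- simulate_delivery(fluence_map(pmax(pmin(base, 1), 0),
                                           cfg$spacing_mm), pert)
      measured <- res$measured
      dd <- measured - planned$values
      gpr <- gpr_targets(planned, measured)
      out[[i]] <- psqa_sample(sprintf("S%04d", i), site, planned, cx,
                              qa_targets(pmin(pmax(gpr, 0), 100), dd))
    }
    out
  })
  attr(samples, "provenance") <- list(
    seed = cfg$seed, n_samples = n, grid = cfg$grid,
    spacing_mm = cfg$spacing_mm, lesion_mix = as.list(cfg$lesion_mix),
    rho_tab = cfg$rho_tab, rho_img = cfg$rho_img,
    perturbation = pp, site_difficulty = as.list(cfg$site_difficulty))
  samples
}
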
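# 2-D gamma-index analysis between planned and measured dose grids.
#
# Protocol: absolute dose mode with global normalization -- the dose
# tolerance and the low-dose threshold are both percentages of the reference
# grid's global maximum. Points at or below the threshold are excluded from
# both the numerator and the denominator of the passing rate. A point passes
# when gamma <= 1 (boundary passes).

#' Construct a gamma analysis criterion
#'
#' @param dose_tol_percent Dose tolerance as % of the reference global max.
#' @param dist_tol_mm Distance-to-agreement tolerance in mm.
#' @param dose_threshold_percent Low-dose exclusion threshold as % of the
#'   reference global max (default 10).
#' @return An object of class `gamma_criterion`.
#' @export
gamma_criterion <- function(dose_tol_percent, dist_tol_mm,
                            dose_threshold_percent = 10) {
  stopifnot(is.numeric(dose_tol_percent), dose_tol_percent > 0,
            is.numeric(dist_tol_mm), dist_tol_mm > 0,
            is.numeric(dose_threshold_percent),
            dose_threshold_percent >= 0, dose_threshold_percent < 100)
  structure(list(dose_tol_percent = as.numeric(dose_tol_percent),
                 dist_tol_mm = as.numeric(dist_tol_mm),
                 dose_threshold_percent = as.numeric(dose_threshold_percent),
                 mode = "global absolute"),
            class = "gamma_criterion")
}

#' The three clinical criteria used throughout the package
#' @return Named list of [gamma_criterion()] objects: `1/1`, `2/2`, `2/3`.
#' @export
clinical_criteria <- function() {
  list("1/1" = gamma_criterion(1, 1), "2/2" = gamma_criterion(2, 2),
       "2/3" = gamma_criterion(2, 3))
}

# Shared discrete-grid gamma search. `max_radius_mm = Inf` enumerates every
# offset (the oracle); a finite radius restricts the search. Offsets are
# visited in order of increasing distance so the restricted search can stop
# as soon as the pure distance term alone exceeds the worst current gamma^2.
.gamma_core <- function(reference, compared, crit, spacing_mm, max_radius_mm,
                        prune = TRUE) {
  H <- nrow(reference); W <- ncol(reference)
  max_ref <- max(reference)
  if (!(max_ref > 0)) stop("gamma: global max of reference must be > 0")
  delta <- crit$dose_tol_percent / 100 * max_ref
  thresh <- crit$dose_threshold_percent / 100 * max_ref
  eval_mask <- reference > thresh
  if (!any(eval_mask)) {
    stop("gamma: all reference points are at or below the dose threshold")
  }
  dt2 <- crit$dist_tol_mm^2

  rmax_px <- if (is.finite(max_radius_mm)) {
    floor(max_radius_mm / spacing_mm)
  } else {
    max(H, W) - 1L
  }
  di <- rep(-rmax_px:rmax_px, times = 2L * rmax_px + 1L)
  dj <- rep(-rmax_px:rmax_px, each = 2L * rmax_px + 1L)
  d2 <- (di^2 + dj^2) * spacing_mm^2
  keep <- if (is.finite(max_radius_mm)) d2 <= max_radius_mm^2 else rep(TRUE, length(d2))
  di <- di[keep]; dj <- dj[keep]; d2 <- d2[keep]
  ord <- order(d2)
  di <- di[ord]; dj <- dj[ord]; d2 <- d2[ord]

  g2 <- matrix(Inf, H, W)
  for (k in seq_along(di)) {
    dist_term <- d2[k] / dt2
    if (prune && dist_term > 0) {
      worst <- max(g2[eval_mask])
      if (dist_term >= worst) break
    }
    oi <- di[k]; oj <- dj[k]
    r1 <- max(1L, 1L - oi); r2 <- min(H, H - oi)
    c1 <- max(1L, 1L - oj); c2 <- min(W, W - oj)
    if (r1 > r2 || c1 > c2) next
    dd <- compared[(r1 + oi):(r2 + oi), (c1 + oj):(c2 + oj), drop = FALSE] -
      reference[r1:r2, c1:c2, drop = FALSE]
    cand <- dist_term + (dd / delta)^2
    sub <- g2[r1:r2, c1:c2, drop = FALSE]
    g2[r1:r2, c1:c2] <- pmin(sub, cand)
  }
  gmap <- sqrt(g2)
  gmap[!eval_mask] <- NaN
  evaluated <- sum(eval_mask)
  # boundary passes; the 1e-9 slack absorbs floating-point noise in
  # ratios like 0.03/0.03 that are exactly 1 in real arithmetic
  passed <- sum(gmap[eval_mask] <= 1 + 1e-9)
  structure(list(gamma_map = gmap,
                 evaluated_count = evaluated,
                 passed_count = passed,
                 gpr_percent = 100 * passed / evaluated),
            class = "gamma_result")
}

.check_gamma_inputs <- function(reference, compared) {
  stopifnot(is.matrix(reference), is.matrix(compared))
  if (!identical(dim(reference), dim(compared))) {
    stop("gamma: reference and compared grids must have the same shape")
  }
}

#' Gamma-index map and passing rate (radius-limited search)
#'
#' For every reference point above the low-dose threshold, searches compared
#' points within `search_radius_factor * dist_tol_mm` for the minimum
#' combined dose-difference / distance-to-agreement metric:
#' \deqn{\gamma(r_m) = \min_{r_c} \sqrt{\|r_c - r_m\|^2 / \delta d^2 +
#'       (D_c(r_c) - D_m(r_m))^2 / \Delta^2}}
#' with \eqn{\Delta} the dose tolerance as a fraction of the reference global
#' maximum (global normalization). No sub-pixel interpolation is performed.
#'
#' @param reference Reference dose matrix (evaluation points live here; its
#'   global max sets the normalization and threshold).
#' @param compared Compared dose matrix, same shape and spacing.
#' @param crit A [gamma_criterion()].
#' @param spacing_mm Grid pitch in mm (default 1).
#' @param search_radius_factor Search radius in units of `dist_tol_mm`
#'   (default 3). A factor at least the grid diagonal reproduces
#'   [gamma_oracle()] exactly.
#' @return A `gamma_result`: `gamma_map` (NaN below threshold),
#'   `evaluated_count`, `passed_count`, `gpr_percent`.
#' @export
gamma_map <- function(reference, compared, crit, spacing_mm = 1.0,
                      search_radius_factor = 3) {
  .check_gamma_inputs(reference, compared)
  stopifnot(search_radius_factor > 0)
  .gamma_core(reference, compared, crit, spacing_mm,
              max_radius_mm = search_radius_factor * crit$dist_tol_mm,
              prune = TRUE)
}

#' Exhaustive gamma oracle (no radius cutoff)
#'
#' Identical contract to [gamma_map()] but minimizes over every compared
#' point; ground truth for equivalence testing on small grids.
#'
#' @inheritParams gamma_map
#' @return A `gamma_result`.
#' @export
gamma_oracle <- function(reference, compared, crit, spacing_mm = 1.0) {
  .check_gamma_inputs(reference, compared)
  if (nrow(reference) > 64 || ncol(reference) > 64) {
    stop("gamma_oracle: grids larger than 64x64 are not supported")
  }
  .gamma_core(reference, compared, crit, spacing_mm,
              max_radius_mm = Inf, prune = FALSE)
}

#' GPR targets at the three clinical criteria
#'
#' Runs gamma analysis at 1%/1mm, 2%/2mm and 2%/3mm (10% global-max dose
#' threshold) and returns the passing rates in that fixed order. By default
#' the measured grid is the reference (evaluation points live on the
#' measurement) and the planned map is the compared distribution; set
#' `reference = "planned"` to swap roles.
#'
#' @param planned A [fluence_map()] or numeric matrix (planned dose).
#' @param measured Numeric matrix (measured dose), same shape.
#' @param spacing_mm Grid pitch in mm; defaults to the fluence map's spacing
#'   when `planned` is a [fluence_map()], else 1.
#' @param reference Which grid hosts the evaluation points.
#' @param search_radius_factor Passed to [gamma_map()].
#' @return Numeric 3-vector of GPR percentages (1/1, 2/2, 2/3).
#' @export
gpr_targets <- function(planned, measured, spacing_mm = NULL,
                        reference = c("measured", "planned"),
                        search_radius_factor = 3) {
  reference <- match.arg(reference)
  if (inherits(planned, "fluence_map")) {
    if (is.null(spacing_mm)) spacing_mm <- planned$spacing_mm
    planned <- planned$values
  }
  if (is.null(spacing_mm)) spacing_mm <- 1.0
  ref <- if (reference == "measured") measured else planned
  cmp <- if (reference == "measured") planned else measured
  vapply(clinical_criteria(), function(crit) {
    gamma_map(ref, cmp, crit, spacing_mm = spacing_mm,
              search_radius_factor = search_radius_factor)$gpr_percent
  }, numeric(1))
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf("<gamma_result> evaluated=%d passed=%d GPR=%.2f%%\n",
              x$evaluated_count, x$passed_count, x$gpr_percent))
  invisible(x)
}
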
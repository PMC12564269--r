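# Regression metrics, global-statistics SSIM, and GPR-interval stratified
# reporting.

#' MAE, RMSE and R-squared of a prediction vector
#'
#' \eqn{MAE = \frac1n\sum|y_i-\hat y_i|},
#' \eqn{RMSE = \sqrt{\frac1n\sum(y_i-\hat y_i)^2}},
#' \eqn{R^2 = 1 - \sum(y_i-\hat y_i)^2 / \sum(y_i-\bar y)^2}. R-squared may
#' be negative; with zero target variance it is undefined and returned as
#' `NA` with a warning (MAE and RMSE are still valid).
#'
#' @param y,y_hat Numeric vectors of equal length (at least 2 for R^2).
#' @return Named numeric: `mae`, `rmse`, `r2`.
#' @export
compute_regression_metrics <- function(y, y_hat) {
  stopifnot(length(y) == length(y_hat), length(y) >= 1)
  res <- y - y_hat
  mae <- mean(abs(res))
  rmse <- sqrt(mean(res^2))
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (length(y) < 2 || ss_tot <= 0) {
    warning("compute_regression_metrics: zero target variance, R^2 undefined")
    NA_real_
  } else {
    1 - sum(res^2) / ss_tot
  }
  c(mae = mae, rmse = rmse, r2 = r2)
}

#' Global-statistics structural similarity index
#'
#' Single SSIM value from the global means, variances and covariance of the
#' two maps (no sliding window):
#' \deqn{SSIM = \frac{(2\mu_1\mu_2+C_1)(2\sigma_{12}+C_2)}
#'   {(\mu_1^2+\mu_2^2+C_1)(\sigma_1^2+\sigma_2^2+C_2)}}
#' with \eqn{C_1=(0.01L)^2}, \eqn{C_2=(0.03L)^2} and `L = dynamic_range`.
#' Population (1/n) moments are used. Symmetric in its arguments; equals 1
#' exactly for identical inputs.
#'
#' @param x1,x2 Numeric matrices of the same shape.
#' @param dynamic_range Positive scalar `L`.
#' @return SSIM scalar.
#' @export
ssim_global <- function(x1, x2, dynamic_range) {
  if (!identical(dim(x1), dim(x2))) {
    stop("ssim_global: shape mismatch")
  }
  stopifnot(dynamic_range > 0)
  n <- length(x1)
  c1 <- (0.01 * dynamic_range)^2
  c2 <- (0.03 * dynamic_range)^2
  mu1 <- mean(x1); mu2 <- mean(x2)
  v1 <- mean((x1 - mu1)^2)
  v2 <- mean((x2 - mu2)^2)
  cov12 <- mean((x1 - mu1) * (x2 - mu2))
  ((2 * mu1 * mu2 + c1) * (2 * cov12 + c2)) /
    ((mu1^2 + mu2^2 + c1) * (v1 + v2 + c2))
}

.report_strata <- function() c("All", "95-100", "90-95", "<90")

.stratum_of <- function(gpr) {
  ifelse(gpr >= 95, "95-100", ifelse(gpr >= 90, "90-95", "<90"))
}

#' GPR-interval stratified metrics report
#'
#' GPR metrics are reported per criterion, stratified by that criterion's
#' own ground truth into All / 95-100 / 90-95 / <90; R-squared is reported
#' for "All" only (subgroup R-squared is unstable under sparse strata).
#' Dose-difference metrics (MAE as % of the planned map's global max, raw
#' MAE, per-sample global SSIM averaged per stratum, pooled pixel R-squared
#' for All) are stratified by the 2%/2mm ground-truth GPR. Empty strata are
#' reported as `NA` (absent), never zero.
#'
#' @param samples Test-set [psqa_sample()] list (ground truth).
#' @param gpr_pred 3 x n matrix of predicted GPRs (percent).
#' @param dd_pred Optional list of n predicted dose-difference matrices.
#' @return An object of class `metrics_report` (nested lists; see
#'   [format_report_markdown()]).
#' @export
stratified_report <- function(samples, gpr_pred, dd_pred = NULL) {
  n <- length(samples)
  gpr_pred <- as.matrix(gpr_pred)
  stopifnot(ncol(gpr_pred) == n, nrow(gpr_pred) == 3)
  gt <- vapply(samples, function(s) s$targets$gpr_percent, numeric(3))
  crits <- c("1/1", "2/2", "2/3")
  strata <- .report_strata()

  cell <- function(y, yh, with_r2) {
    if (length(y) == 0) {
      return(list(n = 0L, mae = NA_real_, rmse = NA_real_, r2 = NA_real_))
    }
    res <- y - yh
    mae <- mean(abs(res))
    rmse <- sqrt(mean(res^2))
    r2 <- NA_real_
    if (with_r2 && length(y) >= 2 && sum((y - mean(y))^2) > 0) {
      r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
    }
    list(n = length(y), mae = mae, rmse = rmse, r2 = r2)
  }

  gpr_tab <- lapply(seq_along(crits), function(k) {
    lab <- .stratum_of(gt[k, ])
    out <- lapply(strata, function(st) {
      ii <- if (st == "All") seq_len(n) else which(lab == st)
      cell(gt[k, ii], gpr_pred[k, ii], with_r2 = (st == "All"))
    })
    stats::setNames(out, strata)
  })
  names(gpr_tab) <- crits

  ddp_tab <- NULL
  if (!is.null(dd_pred)) {
    stopifnot(length(dd_pred) == n)
    has_dd <- vapply(samples, function(s) !is.null(s$targets$dd_map),
                     logical(1))
    lab <- .stratum_of(gt[2, ])  # DDP strata use the 2%/2mm criterion
    per <- lapply(which(has_dd), function(i) {
      s <- samples[[i]]
      gtdd <- s$targets$dd_map
      pd <- dd_pred[[i]]
      pmax_ <- max(s$fluence$values)
      L <- diff(range(gtdd))
      if (L <= 0) L <- 1  # degenerate zero-range target: unit range
      list(i = i,
           mae_raw = mean(abs(pd - gtdd)),
           mae_pct = 100 * mean(abs(pd - gtdd)) / pmax_,
           ssim = ssim_global(gtdd, pd, L))
    })
    idx <- vapply(per, `[[`, integer(1), "i")
    mae_pct <- vapply(per, `[[`, numeric(1), "mae_pct")
    mae_raw <- vapply(per, `[[`, numeric(1), "mae_raw")
    ssim <- vapply(per, `[[`, numeric(1), "ssim")
    ddp_cell <- function(ii) {
      sel <- which(idx %in% ii)
      if (length(sel) == 0) {
        return(list(n = 0L, mae_pct = NA_real_, mae_raw = NA_real_,
                    ssim = NA_real_, r2 = NA_real_))
      }
      list(n = length(sel), mae_pct = mean(mae_pct[sel]),
           mae_raw = mean(mae_raw[sel]), ssim = mean(ssim[sel]),
           r2 = NA_real_)
    }
    ddp_tab <- lapply(strata, function(st) {
      ii <- if (st == "All") idx else intersect(which(lab == st), idx)
      ddp_cell(ii)
    })
    names(ddp_tab) <- strata
    # pooled pixel R^2 over all samples with a DD target
    yy <- unlist(lapply(which(has_dd), function(i)
      as.vector(samples[[i]]$targets$dd_map)))
    pp <- unlist(lapply(which(has_dd), function(i) as.vector(dd_pred[[i]])))
    if (length(yy) >= 2 && sum((yy - mean(yy))^2) > 0) {
      ddp_tab[["All"]]$r2 <- 1 - sum((yy - pp)^2) / sum((yy - mean(yy))^2)
    }
  }
  structure(list(gpr = gpr_tab, ddp = ddp_tab, n = n), class = "metrics_report")
}

.fmt_cell <- function(x, digits = 2) {
  if (is.null(x) || is.na(x)) "—" else formatC(x, format = "f",
                                                    digits = digits)
}

#' Render a metrics report as a Markdown table
#'
#' @param report A [stratified_report()] result.
#' @return Character vector of Markdown lines (also usable via `cat`).
#' @export
format_report_markdown <- function(report) {
  strata <- .report_strata()
  lines <- c("| Task | Criterion | Stratum | n | MAE | RMSE | SSIM | R2 |",
             "|---|---|---|---|---|---|---|---|")
  for (crit in names(report$gpr)) {
    for (st in strata) {
      c_ <- report$gpr[[crit]][[st]]
      lines <- c(lines, sprintf(
        "| GPR | %s | %s | %d | %s | %s | %s | %s |", crit, st, c_$n,
        .fmt_cell(c_$mae), .fmt_cell(c_$rmse), "—", .fmt_cell(c_$r2)))
    }
  }
  if (!is.null(report$ddp)) {
    for (st in strata) {
      c_ <- report$ddp[[st]]
      lines <- c(lines, sprintf(
        "| DDP | 2/2 strata | %s | %d | %s%% | %s | %s | %s |", st, c_$n,
        .fmt_cell(c_$mae_pct), "—", .fmt_cell(c_$ssim, 3),
        .fmt_cell(c_$r2, 3)))
    }
  }
  lines
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(format_report_markdown(x), sep = "\n")
  invisible(x)
}
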
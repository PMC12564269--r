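# Core domain types for patient-specific QA samples and their persistence.
#
# Grid convention used throughout the package: matrices are row-major in the
# physical sense -- element [1, 1] is the top-left pixel, physical coordinates
# in mm are (index - 1) * spacing_mm along rows (y) and columns (x).

#' Ordered roster of the 33 plan-complexity metric names
#'
#' Distal ("d-") and proximal ("p-") variants of each aperture-geometry
#' metric, the four small-aperture scores (2/5/10/15 mm), average leaf gap and
#' its spread, and the beam's total monitor units. The order is fixed and
#' positional: the complexity vector stores values in exactly this order.
#'
#' @return Character vector of length 33.
#' @export
complexity_metric_names <- function() {
  base <- c("AAV", "LSV", "MCS", "BA", "UAA", "PI", "PM", "C/A", "CLS", "MAD",
            "SAS-2mm", "SAS-5mm", "SAS-10mm", "SAS-15mm", "ALG", "SLG")
  c(as.vector(rbind(paste0("d-", base), paste0("p-", base))), "MU")
}

#' Construct a fluence map
#'
#' A fluence map is a rectangular grid of unitless, min-max normalized dose
#' intensity values on a regular pixel lattice.
#'
#' @param values Numeric matrix (H x W), values expected in `[0, 1]`.
#' @param spacing_mm Positive grid pitch in millimetres (default 1).
#' @return An object of class `fluence_map`.
#' @export
fluence_map <- function(values, spacing_mm = 1.0) {
  stopifnot(is.matrix(values), is.numeric(values))
  stopifnot(is.numeric(spacing_mm), length(spacing_mm) == 1L, spacing_mm > 0)
  structure(list(values = values, spacing_mm = as.numeric(spacing_mm)),
            class = "fluence_map")
}

#' Construct a plan-complexity vector
#'
#' @param values Numeric vector of length 33, ordered as
#'   [complexity_metric_names()].
#' @param names Optional character vector of 33 labels; defaults to the
#'   canonical roster.
#' @return An object of class `complexity_vector`.
#' @export
complexity_vector <- function(values, names = complexity_metric_names()) {
  stopifnot(is.numeric(values), is.character(names))
  values <- as.numeric(values)
  structure(list(values = values, names = names), class = "complexity_vector")
}

#' Construct QA targets (GPR 3-vector and dose-difference map)
#'
#' @param gpr_percent Numeric 3-vector of Gamma Passing Rates in percent,
#'   ordered (1%/1mm, 2%/2mm, 2%/3mm).
#' @param dd_map Numeric matrix (measured minus planned dose) with the same
#'   shape as the paired fluence map, or `NULL` when the dose-difference
#'   target is unavailable (image-only GPR experiments).
#' @return An object of class `qa_targets`.
#' @export
qa_targets <- function(gpr_percent, dd_map = NULL) {
  stopifnot(is.numeric(gpr_percent))
  if (!is.null(dd_map)) stopifnot(is.matrix(dd_map), is.numeric(dd_map))
  structure(list(gpr_percent = as.numeric(gpr_percent), dd_map = dd_map),
            class = "qa_targets")
}

#' The four treatment-site labels
#' @return Character vector: head-and-neck, chest, abdomen, pelvis.
#' @export
lesion_sites <- function() c("H&N", "C", "A", "P")

#' Construct a PSQA sample (one beam)
#'
#' @param sample_id Unique string identifier.
#' @param lesion_site One of `"H&N"`, `"C"`, `"A"`, `"P"`.
#' @param fluence A [fluence_map()].
#' @param complexity A [complexity_vector()].
#' @param targets A [qa_targets()].
#' @param plan_id Optional free-form plan identifier.
#' @return An object of class `psqa_sample`.
#' @export
psqa_sample <- function(sample_id, lesion_site, fluence, complexity, targets,
                        plan_id = NA_character_) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L)
  structure(list(sample_id = sample_id, lesion_site = lesion_site,
                 fluence = fluence, complexity = complexity,
                 targets = targets, plan_id = plan_id),
            class = "psqa_sample")
}

#' @export
print.psqa_sample <- function(x, ...) {
  dims <- dim(x$fluence$values)
  cat(sprintf("<psqa_sample %s> site=%s fluence=%dx%d @%gmm GPR=(%s) dd=%s\n",
              x$sample_id, x$lesion_site, dims[1], dims[2],
              x$fluence$spacing_mm,
              paste(sprintf("%.1f", x$targets$gpr_percent), collapse = ", "),
              if (is.null(x$targets$dd_map)) "absent" else "present"))
  invisible(x)
}

#' Validate a PSQA sample against the domain invariants
#'
#' Checks every invariant of the contained types and returns the violations
#' as data (an empty character vector means the sample is valid). Never
#' raises for invalid content and never mutates its input.
#'
#' @param sample A [psqa_sample()].
#' @return Character vector of human-readable violation messages.
#' @export
validate_sample <- function(sample) {
  bad <- character(0)
  add <- function(msg) bad <<- c(bad, msg)
  if (!inherits(sample, "psqa_sample")) {
    return("object is not a psqa_sample")
  }
  if (!is.character(sample$sample_id) || length(sample$sample_id) != 1L ||
      is.na(sample$sample_id) || !nzchar(sample$sample_id)) {
    add("sample_id: must be a non-empty string")
  }
  if (!(sample$lesion_site %in% lesion_sites())) {
    add(sprintf("lesion_site: '%s' is not one of %s", sample$lesion_site,
                paste(lesion_sites(), collapse = "/")))
  }
  fv <- sample$fluence$values
  if (!is.matrix(fv) || !is.numeric(fv)) {
    add("fluence: values must be a numeric matrix")
  } else {
    if (nrow(fv) < 8L || ncol(fv) < 8L) {
      add(sprintf("fluence: grid must be at least 8x8 (got %dx%d)",
                  nrow(fv), ncol(fv)))
    }
    if (anyNA(fv) || any(!is.finite(fv))) {
      add("fluence: grid contains missing or non-finite values")
    } else if (any(fv < 0) || any(fv > 1)) {
      add("fluence: values outside the normalized range [0, 1]")
    }
  }
  if (!is.numeric(sample$fluence$spacing_mm) ||
      length(sample$fluence$spacing_mm) != 1L ||
      !is.finite(sample$fluence$spacing_mm) || sample$fluence$spacing_mm <= 0) {
    add("fluence: spacing_mm must be a positive number")
  }
  cv <- sample$complexity$values
  if (length(cv) != 33L) {
    add(sprintf("complexity: vector must have length 33 (got %d)", length(cv)))
  }
  if (anyNA(cv) || any(!is.finite(cv))) {
    add("complexity: values must all be finite")
  }
  if (length(sample$complexity$names) != 33L) {
    add("complexity: names must have length 33")
  }
  gpr <- sample$targets$gpr_percent
  if (length(gpr) != 3L) {
    add(sprintf("targets: gpr_percent must have length 3 (got %d)",
                length(gpr)))
  } else if (anyNA(gpr) || any(!is.finite(gpr)) ||
             any(gpr < 0) || any(gpr > 100)) {
    add("targets: gpr_percent components must lie in [0, 100]")
  }
  dd <- sample$targets$dd_map
  if (!is.null(dd)) {
    if (!is.matrix(dd) || !is.numeric(dd)) {
      add("targets: dd_map must be a numeric matrix or NULL")
    } else if (is.matrix(fv) && !identical(dim(dd), dim(fv))) {
      add(sprintf("targets: dd_map shape %dx%d differs from fluence %dx%d",
                  nrow(dd), ncol(dd), nrow(fv), ncol(fv)))
    } else if (anyNA(dd) || any(!is.finite(dd))) {
      add("targets: dd_map contains missing or non-finite values")
    }
  }
  bad
}

# ---------------------------------------------------------------------------
# Persistence: one directory container per dataset.
#
# Layout (all plain files):
#   index.csv      -- one row per sample: sample_id, lesion_site, the 33
#                     metrics (canonical header names), gpr_1_1, gpr_2_2,
#                     gpr_2_3
#   manifest.json  -- format version, per-sample grid shape, spacing, and a
#                     has_dd flag; preserves metric name order
#   arrays/<id>.bin-- float64 little-endian: fluence values (column-major),
#                     then the dd map when present (bit-exact round trip)
#   provenance.json (optional) -- simulator seeds and parameters

.index_header <- function() {
  c("sample_id", "lesion_site", complexity_metric_names(),
    "gpr_1_1", "gpr_2_2", "gpr_2_3")
}

#' Save a PSQA dataset to a directory container
#'
#' Validates every sample first; nothing is written unless all samples are
#' valid and ids are unique (the container is assembled in a temporary
#' directory and atomically moved into place).
#'
#' @param samples List of [psqa_sample()] objects.
#' @param path Target directory (created; must not be an existing file).
#' @param provenance Optional list serialized to `provenance.json`.
#' @return Invisibly, `path`.
#' @export
save_dataset <- function(samples, path, provenance = NULL) {
  stopifnot(is.list(samples))
  reports <- lapply(samples, validate_sample)
  nbad <- vapply(reports, length, integer(1))
  if (any(nbad > 0)) {
    ids <- vapply(samples[nbad > 0], function(s)
      as.character(s$sample_id %||% "<missing id>"), character(1))
    stop("save_dataset: invalid samples: ", paste(ids, collapse = ", "),
         " (first violation: ", reports[nbad > 0][[1]][1], ")")
  }
  ids <- vapply(samples, function(s) s$sample_id, character(1))
  if (anyDuplicated(ids)) {
    stop("save_dataset: duplicate sample_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (file.exists(path) && !dir.exists(path)) {
    stop("save_dataset: path exists and is not a directory: ", path)
  }
  parent <- dirname(path)
  if (!dir.exists(parent)) stop("save_dataset: unwritable path: ", path)

  tmp <- tempfile("psqa_ds_", tmpdir = parent)
  dir.create(tmp)
  dir.create(file.path(tmp, "arrays"))
  on.exit(unlink(tmp, recursive = TRUE), add = TRUE)

  n <- length(samples)
  idx <- as.data.frame(matrix(NA_real_, nrow = n, ncol = 36))
  names(idx) <- .index_header()[-(1:2)] # numeric part
  man_samples <- vector("list", n)
  id_col <- character(n); site_col <- character(n)
  for (i in seq_len(n)) {
    s <- samples[[i]]
    id_col[i] <- s$sample_id
    site_col[i] <- s$lesion_site
    idx[i, 1:33] <- s$complexity$values
    idx[i, 34:36] <- s$targets$gpr_percent
    fv <- s$fluence$values
    has_dd <- !is.null(s$targets$dd_map)
    man_samples[[i]] <- list(sample_id = s$sample_id,
                             shape = dim(fv),
                             spacing_mm = s$fluence$spacing_mm,
                             has_dd = has_dd,
                             plan_id = s$plan_id)
    con <- file(file.path(tmp, "arrays", paste0(s$sample_id, ".bin")), "wb")
    writeBin(as.numeric(fv), con, size = 8, endian = "little")
    if (has_dd) {
      writeBin(as.numeric(s$targets$dd_map), con, size = 8, endian = "little")
    }
    close(con)
  }
  # 17 significant digits so the text index round-trips doubles exactly
  idx_txt <- as.data.frame(lapply(idx, function(col)
    sub("^NA$", "", sprintf("%.17g", col))), check.names = FALSE)
  out <- cbind(data.frame(sample_id = id_col, lesion_site = site_col,
                          stringsAsFactors = FALSE), idx_txt)
  names(out) <- .index_header()
  utils::write.csv(out, file.path(tmp, "index.csv"), row.names = FALSE,
                   fileEncoding = "UTF-8", quote = c(1, 2))
  manifest <- list(format = "psqanet-dataset", version = 1L,
                   n_samples = n,
                   metric_names = complexity_metric_names(),
                   samples = man_samples)
  jsonlite::write_json(manifest, file.path(tmp, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(provenance)) {
    jsonlite::write_json(provenance, file.path(tmp, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  if (dir.exists(path)) unlink(path, recursive = TRUE)
  if (!file.rename(tmp, path)) {
    # fall back to copy when rename crosses filesystems
    dir.create(path, recursive = TRUE)
    ok <- file.copy(list.files(tmp, full.names = TRUE), path,
                    recursive = TRUE)
    if (!all(ok)) stop("save_dataset: could not write to ", path)
  }
  on.exit(NULL)
  unlink(tmp, recursive = TRUE)
  invisible(path)
}

#' Load a PSQA dataset written by [save_dataset()]
#'
#' Arrays round-trip bit-exactly. Unknown extra columns in the index are
#' tolerated with a warning; missing required columns are a format error.
#'
#' @param path Dataset directory.
#' @return List of [psqa_sample()] objects; the provenance list (if present)
#'   is attached as attribute `"provenance"`.
#' @export
load_dataset <- function(path) {
  if (!dir.exists(path)) stop("load_dataset: no such dataset directory: ", path)
  man_path <- file.path(path, "manifest.json")
  idx_path <- file.path(path, "index.csv")
  if (!file.exists(man_path)) stop("load_dataset: format error: missing manifest.json")
  if (!file.exists(idx_path)) stop("load_dataset: format error: missing index.csv")
  manifest <- jsonlite::read_json(man_path, simplifyVector = FALSE)
  idx <- utils::read.csv(idx_path, check.names = FALSE,
                         stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- .index_header()
  missing_cols <- setdiff(need, names(idx))
  if (length(missing_cols) > 0) {
    stop("load_dataset: format error: index.csv is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  extra <- setdiff(names(idx), need)
  if (length(extra) > 0) {
    warning("load_dataset: ignoring unknown index column(s): ",
            paste(extra, collapse = ", "))
  }
  by_id <- stats::setNames(manifest$samples,
                           vapply(manifest$samples, function(m)
                             m$sample_id, character(1)))
  samples <- vector("list", nrow(idx))
  for (i in seq_len(nrow(idx))) {
    id <- idx$sample_id[i]
    m <- by_id[[id]]
    if (is.null(m)) stop("load_dataset: format error: sample '", id,
                         "' absent from manifest")
    shape <- as.integer(unlist(m$shape))
    npx <- prod(shape)
    bin <- file.path(path, "arrays", paste0(id, ".bin"))
    if (!file.exists(bin)) stop("load_dataset: missing array file for '",
                                id, "'")
    has_dd <- isTRUE(m$has_dd)
    con <- file(bin, "rb")
    vals <- readBin(con, "numeric", n = npx * (1L + has_dd), size = 8,
                    endian = "little")
    close(con)
    if (length(vals) != npx * (1L + has_dd)) {
      stop("load_dataset: corrupt array file for '", id, "'")
    }
    fl <- fluence_map(matrix(vals[seq_len(npx)], shape[1], shape[2]),
                      spacing_mm = as.numeric(m$spacing_mm))
    dd <- if (has_dd) matrix(vals[npx + seq_len(npx)], shape[1], shape[2])
          else NULL
    samples[[i]] <- psqa_sample(
      sample_id = id,
      lesion_site = idx$lesion_site[i],
      fluence = fl,
      complexity = complexity_vector(as.numeric(idx[i, 3:35])),
      targets = qa_targets(as.numeric(idx[i, 36:38]), dd),
      plan_id = if (is.null(m$plan_id) || is.na(m$plan_id)) NA_character_
                else as.character(m$plan_id))
  }
  prov_path <- file.path(path, "provenance.json")
  if (file.exists(prov_path)) {
    attr(samples, "provenance") <- jsonlite::read_json(prov_path,
                                                       simplifyVector = TRUE)
  }
  samples
}

`%||%` <- function(a, b) if (is.null(a)) b else a
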
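# Multi-factor stratified train/validation/test split: strata are the
# cross-product of a binned GPR criterion and the lesion site.

.split_bins <- function(gpr) {
  cut(gpr, breaks = c(-Inf, 85, 90, 95, Inf),
      labels = c("<85", "85-90", "90-95", ">95"), right = FALSE)
}

#' Stratified 7:1:2 split by GPR bin and lesion site
#'
#' Strata are `GPR bin x site`, with GPR binned on the configured criterion
#' into <85, 85-90, 90-95, >=95 (half-open `[lo, hi)` intervals). Within
#' each stratum, samples are sorted by id (so input order is irrelevant),
#' shuffled with the seed, and allocated to train/val/test by largest-
#' remainder rounding with ties broken train > test > val.
#'
#' @param samples List of [psqa_sample()].
#' @param ratios Length-3 proportions (train, val, test), summing to 1.
#' @param criterion Which GPR criterion bins the strata: `"2/2"` (default),
#'   `"1/1"` or `"2/3"`.
#' @param seed Integer seed; the assignment is deterministic given it.
#' @return A data frame (class `split_assignment`) with columns
#'   `sample_id`, `stratum`, `split`.
#' @export
stratified_split <- function(samples, ratios = c(0.7, 0.1, 0.2),
                             criterion = c("2/2", "1/1", "2/3"), seed = 1L) {
  criterion <- match.arg(criterion)
  if (length(samples) == 0) stop("stratified_split: empty input")
  stopifnot(length(ratios) == 3, abs(sum(ratios) - 1) < 1e-8,
            all(ratios >= 0))
  k <- match(criterion, c("1/1", "2/2", "2/3"))
  ids <- vapply(samples, function(s) s$sample_id, character(1))
  gpr <- vapply(samples, function(s) s$targets$gpr_percent[k], numeric(1))
  site <- vapply(samples, function(s) s$lesion_site, character(1))
  stratum <- paste(.split_bins(gpr), site, sep = "|")

  ord <- order(ids)
  ids <- ids[ord]; stratum <- stratum[ord]
  out_split <- character(length(ids))
  # fixed tie priority: train first, then test, then val
  prio <- c(train = 1L, test = 2L, val = 3L)
  with_seed(seed, {
    for (st in sort(unique(stratum))) {
      ii <- which(stratum == st)
      ii <- ii[sample.int(length(ii))]
      counts <- largest_remainder(length(ii),
                                  c(ratios[1], ratios[3], ratios[2]),
                                  priority = c(1L, 2L, 3L))
      # counts are (train, test, val) in priority order
      lab <- rep(c("train", "test", "val"), counts)
      out_split[ii] <- lab
    }
  })
  structure(data.frame(sample_id = ids, stratum = stratum,
                       split = out_split, stringsAsFactors = FALSE),
            class = c("split_assignment", "data.frame"))
}
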
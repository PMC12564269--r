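# Shared fixtures. Expensive synthetic datasets are memoised per test run so
# several test files can reuse them.

.fix_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fix_cache[[key]])) .fix_cache[[key]] <- force(expr)
  .fix_cache[[key]]
}

# A well-formed sample with a constant-free 64x64 fluence map.
make_sample <- function(id = "S1", site = "C", h = 64, w = 64,
                        with_dd = TRUE, seed = 1) {
  set.seed(seed)
  vals <- matrix(runif(h * w), h, w)
  vals <- (vals - min(vals)) / (max(vals) - min(vals))
  dd <- if (with_dd) matrix(rnorm(h * w, 0, 0.01), h, w) else NULL
  psqa_sample(id, site, fluence_map(vals), complexity_vector(rnorm(33)),
              qa_targets(c(90, 95, 97), dd))
}

make_samples <- function(n, ...) {
  lapply(seq_len(n), function(i) make_sample(sprintf("S%03d", i), seed = i,
                                             ...))
}

# Small simulated cohorts (memoised).
sim_ds_small <- function() {
  cached("sim30", generate_dataset(sim_config(n_samples = 30, seed = 7)))
}

sim_ds_32 <- function() {
  cached("sim32grid",
         generate_dataset(sim_config(n_samples = 17, grid = c(32, 32),
                                     seed = 13)))
}

# Tiny network spec (16x16 grid) for fast training tests.
tiny_spec <- function() {
  network_spec(grid = 16, enc_channels = c(4, 6, 6, 8), n_tab_channels = 2,
               tab_hidden = 12, d_f = 16, dec_channels = c(8, 6, 4, 4, 3),
               dropout = 0.1)
}

tiny_sim_ds <- function() {
  cached("tinysim",
         generate_dataset(sim_config(n_samples = 48, grid = c(16, 16),
                                     seed = 5)))
}

# Random subset-value table (not via value_function; arbitrary reals).
random_game <- function() {
  v <- stats::setNames(c(0, rnorm(3)), c("empty", "img", "tab", "img+tab"))
  v
}

# Simple (non-stratified) split for tiny training tests, where per-stratum
# largest-remainder rounding would starve the validation set.
simple_assignment <- function(ds, seed = 1) {
  ids <- vapply(ds, function(s) s$sample_id, character(1))
  set.seed(seed)
  n <- length(ids)
  ord <- sample(n)
  n_tr <- floor(0.7 * n); n_va <- max(1, floor(0.1 * n))
  split <- character(n)
  split[ord[seq_len(n_tr)]] <- "train"
  split[ord[n_tr + seq_len(n_va)]] <- "val"
  split[split == ""] <- "test"
  structure(data.frame(sample_id = ids, stratum = "all", split = split,
                       stringsAsFactors = FALSE),
            class = c("split_assignment", "data.frame"))
}
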
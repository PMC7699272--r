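# Shared fixtures: built once per test run, lazily, on a small grid so the
# unit tests stay fast. Acceptance tests build their own desk-scale (96^3)
# phantoms.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

small_grid <- function() grid_spec(c(48L, 48L, 48L), 1.2, 0)

small_trajectory <- function(seed = 3L) trajectory_spec(seed = seed)

small_map <- function(day = 28L, seed = 3L) {
  fixture(sprintf("map_%d_%d", day, seed), function()
    make_label_map(small_grid(), small_trajectory(seed), day, seed = seed))
}

small_echoes <- function(day = 28L, seed = 3L, noise_sigma = 0) {
  fixture(sprintf("echo_%d_%d_%g", day, seed, noise_sigma), function()
    simulate_echo_pair(small_map(day, seed), noise_sigma = noise_sigma,
                       seed = seed + 50L))
}

lung_of <- function(map)
  class_mask(map, c("lung_parenchyma", "vessel", "edema", "fibrotic_tissue",
                    "active_border"))

# brute-force Euclidean distance transform for tiny masks
edt_brute <- function(mask, spacing) {
  d <- dim(mask)
  src <- which(mask, arr.ind = TRUE)
  out <- array(NA_real_, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    dd <- sqrt(((i - src[, 1]) * spacing[1])^2 +
                 ((j - src[, 2]) * spacing[2])^2 +
                 ((k - src[, 3]) * spacing[3])^2)
    out[i, j, k] <- min(dd)
  }
  out
}
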
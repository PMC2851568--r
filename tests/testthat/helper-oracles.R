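# Brute-force oracles and small fixtures shared across tests.

# O(n^2) nearest-neighbour oracle: plain per-row scan, independent of the
# package's matrix-based implementation.
brute_nn <- function(a, b, exclude_self = FALSE) {
  vapply(seq_len(nrow(a)), function(i) {
    d <- sqrt((b$x_nm - a$x_nm[i])^2 + (b$y_nm - a$y_nm[i])^2 +
                (b$z_nm - a$z_nm[i])^2)
    if (exclude_self) d[b$id == a$id[i]] <- Inf
    min(d)
  }, numeric(1))
}

random_foci_table <- function(n, ids = seq_len(n), range_nm = 1000) {
  tibble::tibble(
    id = ids,
    x_nm = runif(n, 0, range_nm),
    y_nm = runif(n, 0, range_nm),
    z_nm = runif(n, 0, range_nm),
    diameter_nm = 500
  )
}

small_nucleus <- function(foci_per_zone = 20, n_zones = 3) {
  nucleus_config(foci_per_zone = foci_per_zone, n_zones = n_zones)
}

# chain-adjacent centre separations of a foci_set, in chain_pos order
adjacent_separations <- function(fs) {
  unlist(lapply(split(seq_len(nrow(fs)), fs$chain_id), function(i) {
    i <- i[order(fs$chain_pos[i])]
    if (length(i) < 2) return(numeric(0))
    sqrt(diff(fs$x_nm[i])^2 + diff(fs$y_nm[i])^2 + diff(fs$z_nm[i])^2)
  }))
}

# noise-free fiber config with a fixed fork rate, handy for exact arithmetic
exact_fiber_config <- function(...) {
  fiber_config(noise_sd_kbp = 0, fork_rate_kbp_per_min = 1.5, ...)
}
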
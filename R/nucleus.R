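#' Nucleus and labeling geometry for the foci simulator
#'
#' Bundles the geometry of the simulated nucleus and its S-phase time zones.
#' Defaults reproduce the reference Monte-Carlo configuration: a 10 um
#' spherical nucleus containing 350 foci of 500 nm diameter per 1 h time zone,
#' over 10 zones (3500 foci in total, a naive volume sum of 44% of the
#' nucleus).
#'
#' @param nucleus_diameter_um Nucleus diameter in micrometres.
#' @param focus_diameter_nm Focus (sphere) diameter in nanometres.
#' @param foci_per_zone Number of foci activated per time zone.
#' @param n_zones Number of S-phase time zones.
#' @param zone_duration_h Duration of one time zone in hours.
#' @return A list of class `nucleus_config`.
#' @examples
#' nucleus_config()
#' @export
nucleus_config <- function(nucleus_diameter_um = 10,
                           focus_diameter_nm = 500,
                           foci_per_zone = 350,
                           n_zones = 10,
                           zone_duration_h = 1) {
  if (nucleus_diameter_um <= 0 || focus_diameter_nm <= 0 ||
      foci_per_zone < 0 || n_zones < 0 || zone_duration_h <= 0) {
    abort("all nucleus_config dimensions must be positive (counts may be zero)")
  }
  if (focus_diameter_nm >= nucleus_diameter_um * 1000) {
    abort("focus_diameter_nm must be smaller than the nucleus diameter")
  }
  structure(
    list(
      nucleus_diameter_um = nucleus_diameter_um,
      focus_diameter_nm = focus_diameter_nm,
      foci_per_zone = as.integer(foci_per_zone),
      n_zones = as.integer(n_zones),
      zone_duration_h = zone_duration_h
    ),
    class = "nucleus_config"
  )
}

#' @export
print.nucleus_config <- function(x, ...) {
  cat(sprintf(
    "<nucleus_config> %g um nucleus, %g nm foci, %d foci/zone x %d zones\n",
    x$nucleus_diameter_um, x$focus_diameter_nm, x$foci_per_zone, x$n_zones
  ))
  invisible(x)
}

new_foci_set <- function(df, nucleus, model, seed) {
  structure(
    df,
    nucleus = nucleus,
    model = model,
    seed = seed,
    class = c("foci_set", class(tibble()))
  )
}

#' @export
print.foci_set <- function(x, ...) {
  nuc <- attr(x, "nucleus")
  cat(sprintf(
    "# A foci_set: %d foci, model = %s, nucleus %g um\n",
    nrow(x), attr(x, "model") %||% "?", nuc$nucleus_diameter_um
  ))
  NextMethod()
}

# Uniform points in a ball of radius `radius`, by rejection from the cube.
runif_ball <- function(n, radius, max_tries = 100L) {
  if (n == 0L) return(matrix(numeric(0), ncol = 3))
  out <- matrix(NA_real_, n, 3)
  filled <- 0L
  for (i in seq_len(max_tries)) {
    need <- n - filled
    # acceptance ~ pi/6; draw with headroom
    m <- ceiling(need / (pi / 6) * 1.2) + 16L
    cand <- matrix(runif(3 * m, -radius, radius), ncol = 3)
    keep <- rowSums(cand^2) <= radius^2
    cand <- cand[keep, , drop = FALSE]
    take <- min(nrow(cand), need)
    if (take > 0) {
      out[filled + seq_len(take), ] <- cand[seq_len(take), , drop = FALSE]
      filled <- filled + take
    }
    if (filled == n) return(out)
  }
  abort("rejection sampling failed: nucleus too small for requested foci count")
}

# Uniform directions on the unit sphere.
runif_sphere <- function(n) {
  v <- matrix(rnorm(3 * n), ncol = 3)
  v / sqrt(rowSums(v^2))
}

# Chain lengths: n_chains chains, each a multiple of n_zones so that zone runs
# 1..n_zones tile every chain exactly; lengths as equal as possible.
chain_lengths <- function(n_foci, n_chains, n_zones) {
  stopifnot(n_foci %% n_zones == 0)
  runs <- n_foci %/% n_zones # number of zone runs to distribute
  if (runs < n_chains) n_chains <- runs
  base <- runs %/% n_chains
  extra <- runs %% n_chains
  per_chain_runs <- rep(base, n_chains) + rep(c(1L, 0L), c(extra, n_chains - extra))
  per_chain_runs * n_zones
}

# One reflected random walk of `len` steps of length `step` inside a ball of
# radius `rmax`. Reflection is radial (Euclidean projection onto the ball),
# applied when a step leaves the ball.
chain_walk <- function(len, step, rmax) {
  pos <- matrix(NA_real_, len, 3)
  pos[1, ] <- runif_ball(1, rmax)
  if (len == 1L) return(pos)
  dirs <- runif_sphere(len - 1L)
  for (i in 2:len) {
    p <- pos[i - 1L, ] + step * dirs[i - 1L, ]
    r <- sqrt(sum(p^2))
    if (r > rmax) p <- p * ((2 * rmax - r) / r) # reflect radially at boundary
    r <- sqrt(sum(p^2))
    if (r > rmax) p <- p * (rmax / r)
    pos[i, ] <- p
  }
  pos
}

#' Simulate labeled replication foci in a spherical nucleus
#'
#' Generates `foci_per_zone * n_zones` spherical foci fully inside the nucleus
#' and assigns each focus an S-phase time zone according to one of three
#' activation models:
#'
#' * `"random"` — positions uniform in the nucleus; zone labels a random
#'   permutation, independent of position.
#' * `"spatial"` — positions uniform; one seed point per zone, each focus takes
#'   the zone of its nearest seed, then counts are rebalanced to exactly
#'   `foci_per_zone` by reassigning the farthest excess foci, so same-zone foci
#'   cluster spatially.
#' * `"genetic"` — foci lie on chains (chromosomes) built as fixed-step random
#'   walks with step length equal to the focus diameter, reflected at the
#'   nuclear boundary. Zone labels run 1..`n_zones` repeatedly along each
#'   chain, so every focus active in zone z (z < `n_zones`) is chain-adjacent
#'   to a focus active in zone z + 1 — the next-in-line structure.
#'
#' All three models carry the same chain (chromosome) structure so that
#' mitotic segregation ([apply_segregation()]) is meaningful for each; only
#' the zone labeling differs between models.
#'
#' @param config A [nucleus_config()].
#' @param model One of `"genetic"`, `"spatial"`, `"random"`.
#' @param seed Integer seed; every stochastic function in the package takes an
#'   explicit seed and is bit-for-bit reproducible.
#' @param n_chains Number of chains (chromosomes/territories); default 46.
#' @return A `foci_set`: a tibble with columns `id`, `x_nm`, `y_nm`, `z_nm`,
#'   `diameter_nm`, `zone`, `chain_id`, `chain_pos`, carrying the nucleus
#'   config, model and seed as attributes.
#' @examples
#' fs <- gen_nuclear_foci(nucleus_config(foci_per_zone = 20, n_zones = 2),
#'                        model = "genetic", seed = 1)
#' nrow(fs)
#' @export
gen_nuclear_foci <- function(config = nucleus_config(),
                             model = c("genetic", "spatial", "random"),
                             seed = 1L,
                             n_chains = 46L) {
  model <- match.arg(model)
  stopifnot(inherits(config, "nucleus_config"))
  n_zones <- config$n_zones
  fz <- config$foci_per_zone
  n <- fz * n_zones
  r_focus <- config$focus_diameter_nm / 2
  rmax <- config$nucleus_diameter_um * 1000 / 2 - r_focus
  if (rmax <= 0) abort("focus does not fit inside the nucleus")

  if (n == 0L) {
    return(new_foci_set(
      tibble(
        id = integer(), x_nm = double(), y_nm = double(), z_nm = double(),
        diameter_nm = double(), zone = integer(),
        chain_id = integer(), chain_pos = integer()
      ),
      config, model, seed
    ))
  }

  withr::local_seed(seed)

  if (model == "genetic") {
    lens <- chain_lengths(n, n_chains, n_zones)
    pieces <- lapply(seq_along(lens), function(c_id) {
      pos <- chain_walk(lens[c_id], config$focus_diameter_nm, rmax)
      tibble(
        x_nm = pos[, 1], y_nm = pos[, 2], z_nm = pos[, 3],
        zone = rep(seq_len(n_zones), lens[c_id] %/% n_zones),
        chain_id = c_id,
        chain_pos = seq_len(lens[c_id])
      )
    })
    df <- bind_rows(pieces)
  } else {
    pos <- runif_ball(n, rmax)
    # chromosome structure shared with the genetic model: partition foci into
    # chains by nearest territory centre so segregation keeps spatial blocks
    centers <- runif_ball(n_chains, rmax)
    d2 <- outer(rowSums(pos^2), rep(1, n_chains)) +
      outer(rep(1, n), rowSums(centers^2)) - 2 * pos %*% t(centers)
    chain_id <- max.col(-d2, ties.method = "first")
    if (model == "random") {
      zone <- sample(rep(seq_len(n_zones), fz))
    } else { # spatial
      seeds <- runif_ball(n_zones, rmax)
      ds2 <- outer(rowSums(pos^2), rep(1, n_zones)) +
        outer(rep(1, n), rowSums(seeds^2)) - 2 * pos %*% t(seeds)
      zone <- max.col(-ds2, ties.method = "first")
      zone <- rebalance_zones(zone, ds2, fz)
    }
    df <- tibble(
      x_nm = pos[, 1], y_nm = pos[, 2], z_nm = pos[, 3],
      zone = as.integer(zone),
      chain_id = as.integer(chain_id)
    )
    df <- df |>
      group_by(.data$chain_id) |>
      mutate(chain_pos = seq_len(dplyr::n())) |>
      ungroup()
  }

  df <- df |>
    mutate(
      id = seq_len(nrow(df)),
      diameter_nm = config$focus_diameter_nm,
      zone = as.integer(.data$zone)
    ) |>
    select("id", "x_nm", "y_nm", "z_nm", "diameter_nm",
           "zone", "chain_id", "chain_pos")
  new_foci_set(df, config, model, seed)
}

# Rebalance zone counts to exactly `fz` per zone: repeatedly move, from an
# over-quota zone, the focus farthest from that zone's seed to the nearest
# under-quota zone.
rebalance_zones <- function(zone, ds2, fz) {
  n_zones <- ncol(ds2)
  repeat {
    counts <- tabulate(zone, nbins = n_zones)
    over <- which(counts > fz)
    if (length(over) == 0L) break
    z <- over[1]
    members <- which(zone == z)
    far <- members[which.max(ds2[members, z])]
    under <- which(counts < fz)
    zone[far] <- under[which.min(ds2[far, under])]
  }
  as.integer(zone)
}

#' Retain the foci of a random subset of chains
#'
#' Emulates random mitotic segregation of labeled chromosomes over days of
#' growth: only `n_keep_chains` chains (chromosome territories), sampled
#' uniformly, remain labeled (the study grew cells to leave about 3 labeled
#' territories per cell).
#'
#' @param fs A `foci_set`.
#' @param n_keep_chains Number of chains to keep.
#' @param seed Integer seed.
#' @return A `foci_set` restricted to the sampled chains.
#' @export
apply_segregation <- function(fs, n_keep_chains, seed = 1L) {
  stopifnot(inherits(fs, "foci_set"))
  chains <- unique(fs$chain_id)
  if (n_keep_chains > length(chains)) {
    abort(sprintf(
      "n_keep_chains (%d) exceeds available chains (%d)",
      n_keep_chains, length(chains)
    ))
  }
  if (n_keep_chains == length(chains)) return(fs)
  withr::local_seed(seed)
  keep <- sample(chains, n_keep_chains)
  out <- fs[fs$chain_id %in% keep, , drop = FALSE]
  new_foci_set(out, attr(fs, "nucleus"), attr(fs, "model"), attr(fs, "seed"))
}

#' Perturb foci positions (chromosome territory plasticity)
#'
#' Emulates the innate plasticity of chromosome territories (relative
#' positional shifts of 0.2-0.6 um over 30 min in live imaging). For the
#' genetic model each chain moves rigidly (random translation with isotropic
#' Gaussian components of sd `step_sd_nm`, plus a small random rotation about
#' the chain centroid), so chain-adjacent separations are preserved; for the
#' random and spatial models each focus is displaced independently by
#' isotropic Gaussian noise. All foci are then projected back inside the
#' nucleus (radial clamp — the Euclidean projection onto the ball, which never
#' increases pairwise distances, so chain connectivity survives).
#'
#' @param fs A `foci_set`.
#' @param step_sd_nm Standard deviation of the displacement, nm, per axis.
#' @param seed Integer seed.
#' @return A `foci_set` with perturbed coordinates.
#' @export
apply_plasticity <- function(fs, step_sd_nm, seed = 1L) {
  stopifnot(inherits(fs, "foci_set"), step_sd_nm >= 0)
  if (step_sd_nm == 0 || nrow(fs) == 0L) return(fs)
  withr::local_seed(seed)
  nuc <- attr(fs, "nucleus")
  rmax <- nuc$nucleus_diameter_um * 1000 / 2 - fs$diameter_nm / 2
  pos <- cbind(fs$x_nm, fs$y_nm, fs$z_nm)

  if (identical(attr(fs, "model"), "genetic")) {
    for (c_id in unique(fs$chain_id)) {
      idx <- which(fs$chain_id == c_id)
      ctr <- colMeans(pos[idx, , drop = FALSE])
      ang <- rnorm(1, 0, step_sd_nm / 5000) # small rigid rotation, radians
      axis <- runif_sphere(1)[1, ]
      R <- rotation_matrix(axis, ang)
      shift <- rnorm(3, 0, step_sd_nm)
      pos[idx, ] <- sweep(
        sweep(pos[idx, , drop = FALSE], 2, ctr) %*% t(R),
        2, ctr + shift, `+`
      )
    }
  } else {
    pos <- pos + matrix(rnorm(3 * nrow(pos), 0, step_sd_nm), ncol = 3)
  }

  r <- sqrt(rowSums(pos^2))
  out_of_ball <- r > rmax
  if (any(out_of_ball)) {
    pos[out_of_ball, ] <- pos[out_of_ball, , drop = FALSE] *
      (rmax[out_of_ball] / r[out_of_ball])
  }
  out <- fs
  out$x_nm <- pos[, 1]
  out$y_nm <- pos[, 2]
  out$z_nm <- pos[, 3]
  out
}

# Rodrigues rotation matrix for unit axis `u` and angle `theta`.
rotation_matrix <- function(u, theta) {
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

#' Subset a foci set by time zone
#'
#' @param fs A `foci_set` (or any data frame with a `zone` column).
#' @param zones Integer vector of zones to keep.
#' @return The subset, preserving the `foci_set` class and attributes.
#' @export
zone_subset <- function(fs, zones) {
  out <- fs[fs$zone %in% zones, , drop = FALSE]
  if (inherits(fs, "foci_set")) {
    out <- new_foci_set(out, attr(fs, "nucleus"), attr(fs, "model"),
                        attr(fs, "seed"))
  }
  out
}
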
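#' Configuration for the pulse-chase-pulse DNA fiber simulator
#'
#' Defaults follow the fiber-labeling protocol of the study: a 30 min first
#' pulse (biotin-dUTP, channel 1), a 1 h unlabeled chase, and a 20 min second
#' pulse (BrdU, channel 2); fork rates uniform in 1-2 kbp/min per fiber;
#' inter-origin spacings drawn from class-specific normal models (extending
#' clusters 181.2 +/- 87.5 kbp, secondary-activation clusters 119.6 +/- 47.0
#' kbp) truncated to the 50-250 kbp range that holds 90% of adjacent origins;
#' 3-5 replicons per primary cluster; class mix 55% extending / 40% secondary
#' activation / 5% uncoupled; lengths converted at 2.59 kbp/um; measurement
#' noise 5 kbp on track endpoints.
#'
#' @param pulse1_min,chase_min,pulse2_min Durations in minutes.
#' @param fork_rate_kbp_per_min Single rate or `c(min, max)` range; one rate
#'   is drawn per fiber (uniform) when a range is given.
#' @param spacing_extending,spacing_secondary `c(mean, sd)` of the normal
#'   inter-origin spacing model for each double-labeled class, kbp.
#' @param spacing_range_kbp `c(lo, hi)` truncation range for spacings, kbp.
#' @param replicons_per_cluster Integer vector; cluster size drawn uniformly
#'   from it.
#' @param class_mix Named probabilities for `extending`,
#'   `secondary_activation`, `uncoupled`; normalized to sum to 1.
#' @param kbp_per_um Conversion factor, kbp per micrometre.
#' @param noise_sd_kbp Gaussian measurement noise added to track endpoints,
#'   kbp (0 = noise-free ground truth).
#' @return A list of class `fiber_config`.
#' @export
fiber_config <- function(pulse1_min = 30,
                         chase_min = 60,
                         pulse2_min = 20,
                         fork_rate_kbp_per_min = c(1, 2),
                         spacing_extending = c(181.2, 87.5),
                         spacing_secondary = c(119.6, 47.0),
                         spacing_range_kbp = c(50, 250),
                         replicons_per_cluster = 3:5,
                         class_mix = c(extending = 0.55,
                                       secondary_activation = 0.40,
                                       uncoupled = 0.05),
                         kbp_per_um = 2.59,
                         noise_sd_kbp = 5) {
  if (any(c(pulse1_min, chase_min, pulse2_min) < 0)) {
    abort("pulse and chase durations must be >= 0")
  }
  if (any(fork_rate_kbp_per_min <= 0)) abort("fork rate must be positive")
  if (kbp_per_um <= 0) abort("kbp_per_um must be positive")
  if (noise_sd_kbp < 0) abort("noise_sd_kbp must be >= 0")
  cls <- c("extending", "secondary_activation", "uncoupled")
  if (!all(cls %in% names(class_mix))) {
    abort("class_mix must name extending, secondary_activation and uncoupled")
  }
  class_mix <- class_mix[cls] / sum(class_mix[cls])
  structure(
    list(
      pulse1_min = pulse1_min, chase_min = chase_min, pulse2_min = pulse2_min,
      fork_rate_kbp_per_min = fork_rate_kbp_per_min,
      spacing_extending = spacing_extending,
      spacing_secondary = spacing_secondary,
      spacing_range_kbp = spacing_range_kbp,
      replicons_per_cluster = as.integer(replicons_per_cluster),
      class_mix = class_mix,
      kbp_per_um = kbp_per_um,
      noise_sd_kbp = noise_sd_kbp
    ),
    class = "fiber_config"
  )
}

# Truncated-normal spacing draw (rejection; range guaranteed non-degenerate).
draw_spacing <- function(n, mean_sd, range) {
  out <- numeric(n)
  need <- seq_len(n)
  guard <- 0L
  while (length(need) > 0L) {
    x <- rnorm(length(need), mean_sd[1], mean_sd[2])
    ok <- x >= range[1] & x <= range[2]
    out[need[ok]] <- x[ok]
    need <- need[!ok]
    guard <- guard + 1L
    if (guard > 10000L) abort("spacing rejection sampling failed")
  }
  out
}

# Label coverage of a set of origins with firing times, over a pulse window.
# origins: position kbp; fire: firing time min; v: fork rate kbp/min.
# Forks stop where and when they meet the converging fork of the adjacent
# origin (allowing for unequal firing times); outermost forks run freely.
# Returns a matrix of covered intervals (start, end) for the window, merged.
pulse_coverage <- function(origins, fire, v, t1, t2) {
  o <- order(origins)
  origins <- origins[o]
  fire <- fire[o]
  n <- length(origins)
  segs <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(n)) {
    # right fork: fuses with left fork of origin i+1
    t_stop_r <- if (i < n) {
      (origins[i + 1] - origins[i]) / (2 * v) + (fire[i] + fire[i + 1]) / 2
    } else Inf
    # left fork: fuses with right fork of origin i-1
    t_stop_l <- if (i > 1) {
      (origins[i] - origins[i - 1]) / (2 * v) + (fire[i] + fire[i - 1]) / 2
    } else Inf
    for (side in c(-1, 1)) {
      t_stop <- if (side > 0) t_stop_r else t_stop_l
      a <- max(t1, fire[i])
      b <- min(t2, t_stop)
      if (b > a) {
        p1 <- origins[i] + side * v * (a - fire[i])
        p2 <- origins[i] + side * v * (b - fire[i])
        segs <- rbind(segs, sort(c(p1, p2)))
      }
    }
  }
  merge_intervals(segs)
}

# Merge overlapping or abutting intervals (rows of (start, end)).
merge_intervals <- function(segs, eps = 1e-9) {
  if (nrow(segs) == 0L) return(segs)
  segs <- segs[order(segs[, 1]), , drop = FALSE]
  out <- segs[1, , drop = FALSE]
  for (i in seq_len(nrow(segs))[-1]) {
    j <- nrow(out)
    if (segs[i, 1] <= out[j, 2] + eps) {
      out[j, 2] <- max(out[j, 2], segs[i, 2])
    } else {
      out <- rbind(out, segs[i, , drop = FALSE])
    }
  }
  out
}

# Build one fiber of a given ground-truth class; returns a list with track
# intervals per channel (kbp, origin-anchored coordinates) and origin
# positions.
build_fiber <- function(class, cfg) {
  v <- if (length(cfg$fork_rate_kbp_per_min) > 1) {
    runif(1, cfg$fork_rate_kbp_per_min[1], cfg$fork_rate_kbp_per_min[2])
  } else cfg$fork_rate_kbp_per_min
  p1 <- cfg$pulse1_min
  t2_start <- p1 + cfg$chase_min
  t2_end <- t2_start + cfg$pulse2_min

  spacing_model <- if (class == "secondary_activation") {
    cfg$spacing_secondary
  } else {
    cfg$spacing_extending
  }

  make_cluster <- function(k, model) {
    if (k == 1L) return(0)
    cumsum(c(0, draw_spacing(k - 1L, model, cfg$spacing_range_kbp)))
  }

  k <- sample(cfg$replicons_per_cluster, 1L)
  primary <- make_cluster(k, spacing_model)
  origins <- primary
  fire <- rep(0, length(primary))

  if (class == "secondary_activation") {
    # new origins fire at the start of pulse 2 in one or both flanks, placed
    # beyond the point the outgrowing fork will have reached plus a margin so
    # their tracks stay distinct from the extending-fork track
    flanks <- sample(list(1, -1, c(-1, 1)), 1L,
                     prob = c(0.35, 0.35, 0.30))[[1]]
    for (side in flanks) {
      n_new <- sample(2:3, 1L)
      edge <- if (side > 0) max(primary) else min(primary)
      # beyond v*(2*t2_end - t2_start): the converging forks cannot fuse
      # before the end of pulse 2, so the new track stays distinct from the
      # extending-fork track; still well inside the 250 kbp coupling distance
      first_gap <- v * (2 * t2_end - t2_start) + runif(1, 20, 80)
      gaps <- c(first_gap,
                draw_spacing(n_new - 1L, cfg$spacing_secondary,
                             pmax(cfg$spacing_range_kbp, c(100, 100))))
      new_o <- edge + side * cumsum(gaps)
      origins <- c(origins, new_o)
      fire <- c(fire, rep(t2_start, n_new))
    }
  }

  uncoupled_origins <- numeric(0)
  if (class == "uncoupled") {
    # a remote de-novo cluster firing during pulse 2, beyond the exclusion
    # distance from every pulse-1-labeled track (and from the extending
    # channel-2 track, so it forms its own track group)
    side <- sample(c(-1, 1), 1L)
    edge <- if (side > 0) max(primary) else min(primary)
    n_new <- sample(2:3, 1L)
    start_gap <- t2_end * v + 250 + runif(1, 60, 160)
    gaps <- c(start_gap,
              draw_spacing(n_new - 1L, cfg$spacing_secondary,
                           pmax(cfg$spacing_range_kbp, c(100, 100))))
    uncoupled_origins <- edge + side * cumsum(gaps)
    origins <- c(origins, uncoupled_origins)
    fire <- c(fire, rep(t2_start, n_new))
  }

  # drop any origin that a fork has already passed by its firing time
  # (cannot initiate in replicated DNA); by construction this never removes
  # planted origins, it is a guard for user-supplied configurations
  keep <- rep(TRUE, length(origins))
  cov1 <- pulse_coverage(primary, rep(0, length(primary)), v, 0, t2_start)
  late <- which(fire > 0)
  if (length(late) && nrow(cov1)) {
    for (i in late) {
      inside <- any(origins[i] > cov1[, 1] & origins[i] < cov1[, 2])
      if (inside) keep[i] <- FALSE
    }
  }
  origins <- origins[keep]
  fire <- fire[keep]

  ch1 <- pulse_coverage(origins, fire, v, 0, p1)
  ch2 <- pulse_coverage(origins, fire, v, t2_start, t2_end)
  list(ch1 = ch1, ch2 = ch2, origins = sort(origins),
       uncoupled_origins = sort(uncoupled_origins), rate = v)
}

#' Simulate pulse-chase-pulse labeled DNA fibers
#'
#' Each fiber carries one replicon cluster active during the first pulse
#' plus, depending on its ground-truth class, secondary origins activated in
#' the flanking DNA during the second pulse (`secondary_activation`), no new
#' origins (`extending`), or a remote de-novo cluster labeled only in channel
#' 2 beyond the 250 kbp exclusion distance (`uncoupled`). Bidirectional forks
#' elongate at the configured rate and fuse where converging forks meet; DNA
#' replicated during pulse 1 is emitted as channel-1 tracks and during pulse
#' 2 as channel-2 tracks. Coordinates are emitted in micrometres
#' (`kbp_per_um`) with additive endpoint noise; the ground-truth class and
#' origin positions are attached per fiber.
#'
#' @param cfg A [fiber_config()].
#' @param n_fibers Number of fibers.
#' @param seed Integer seed.
#' @return A `fiber_set`: tibble of tracks with columns `fiber_id`, `channel`
#'   (1 or 2), `start_um`, `end_um`, `truth_class`, `fiber_length_um`, and
#'   list-column `truth_origins_kbp` (repeated per fiber). The config and
#'   seed are attached as attributes.
#' @examples
#' fb <- gen_fibers(fiber_config(noise_sd_kbp = 0), n_fibers = 3, seed = 1)
#' dplyr::count(fb, fiber_id, channel)
#' @export
gen_fibers <- function(cfg = fiber_config(), n_fibers = 100L, seed = 1L) {
  stopifnot(inherits(cfg, "fiber_config"), n_fibers >= 0)
  withr::local_seed(seed)
  classes <- sample(names(cfg$class_mix), n_fibers, replace = TRUE,
                    prob = cfg$class_mix)
  rows <- vector("list", n_fibers)
  for (f in seq_len(n_fibers)) {
    fib <- build_fiber(classes[f], cfg)
    tr <- rbind(
      if (nrow(fib$ch1)) cbind(1, fib$ch1),
      if (nrow(fib$ch2)) cbind(2, fib$ch2)
    )
    if (is.null(tr) || nrow(tr) == 0L) next
    # place on a fiber starting at 0 with unlabeled margins; total DNA extent
    # at least 0.8 Mbp (the study imaged fields holding >= 0.8 Mbp of fiber)
    margin_l <- runif(1, 50, 200)
    margin_r <- runif(1, 50, 200)
    shift <- margin_l - min(tr[, 2])
    tr[, 2:3] <- tr[, 2:3] + shift
    fib_len <- max(tr[, 3]) + margin_r
    if (fib_len < 800) {
      extra <- (800 - fib_len) / 2
      tr[, 2:3] <- tr[, 2:3] + extra
      shift <- shift + extra
      fib_len <- 800
    }
    origins <- fib$origins + shift
    start_kbp <- tr[, 2]
    end_kbp <- tr[, 3]
    if (cfg$noise_sd_kbp > 0) {
      start_kbp <- start_kbp + rnorm(nrow(tr), 0, cfg$noise_sd_kbp)
      end_kbp <- end_kbp + rnorm(nrow(tr), 0, cfg$noise_sd_kbp)
      swap <- start_kbp > end_kbp
      tmp <- start_kbp[swap]
      start_kbp[swap] <- end_kbp[swap]
      end_kbp[swap] <- tmp
      # noise can make neighbouring tracks overlap; a measured spread would
      # show them as one track, so merge within each channel
      merged <- lapply(c(1, 2), function(ch) {
        sel <- tr[, 1] == ch
        if (!any(sel)) return(NULL)
        cbind(ch, merge_intervals(cbind(start_kbp[sel], end_kbp[sel])))
      })
      tr <- do.call(rbind, merged)
      start_kbp <- tr[, 2]
      end_kbp <- tr[, 3]
    }
    rows[[f]] <- tibble(
      fiber_id = f,
      channel = as.integer(tr[, 1]),
      start_um = start_kbp / cfg$kbp_per_um,
      end_um = end_kbp / cfg$kbp_per_um,
      truth_class = classes[f],
      fiber_length_um = fib_len / cfg$kbp_per_um,
      truth_origins_kbp = list(origins)
    )
  }
  out <- bind_rows(rows) |> arrange(.data$fiber_id, .data$start_um)
  new_fiber_set(out, cfg, seed)
}

new_fiber_set <- function(df, cfg = NULL, seed = NULL) {
  structure(df, config = cfg, seed = seed,
            class = c("fiber_set", class(tibble())))
}

#' @export
print.fiber_set <- function(x, ...) {
  cat(sprintf("# A fiber_set: %d tracks on %d fibers\n",
              nrow(x), length(unique(x$fiber_id))))
  NextMethod()
}
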
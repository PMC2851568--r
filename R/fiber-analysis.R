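#' Convert fiber lengths between micrometres and kilobase pairs
#'
#' Spread DNA fibers are measured in micrometres and converted to kbp with a
#' fixed stretching factor (1 um = 2.59 kbp for these spreads).
#'
#' @param length_um,length_kbp Lengths to convert.
#' @param factor Conversion factor, kbp per um.
#' @return The converted length(s).
#' @examples
#' um_to_kbp(1)      # 2.59
#' kbp_to_um(2.59)   # 1
#' @export
um_to_kbp <- function(length_um, factor = 2.59) {
  stopifnot(factor > 0)
  length_um * factor
}

#' @rdname um_to_kbp
#' @export
kbp_to_um <- function(length_kbp, factor = 2.59) {
  stopifnot(factor > 0)
  length_kbp / factor
}

#' Fiber classification parameters
#'
#' @param cluster_gap_kbp Maximum gap between successive channel-1 tracks of
#'   one replicon cluster (default 250 kbp, the only reported length scale for
#'   adjacency).
#' @param exclusion_kbp A channel-2 track group farther than this from every
#'   channel-1 track is an uncoupled initiation (default 250 kbp).
#' @param max_extension_gap_kbp A lone flanking channel-2 track whose gap from
#'   the cluster edge exceeds this cannot be the extending outgrowing fork
#'   (default 130 kbp, just above the largest chase-distance rate x chase =
#'   2 kbp/min x 60 min plus the second pulse's head start).
#' @param min_fiber_kbp Fibers with less DNA than this are excluded
#'   (default 800 kbp, mirroring the study's >= 0.8 Mbp imaging fields).
#' @param kbp_per_um Conversion factor for track coordinates.
#' @return A list of class `fiber_params`.
#' @export
fiber_params <- function(cluster_gap_kbp = 250,
                         exclusion_kbp = 250,
                         max_extension_gap_kbp = 130,
                         min_fiber_kbp = 800,
                         kbp_per_um = 2.59) {
  structure(
    list(cluster_gap_kbp = cluster_gap_kbp, exclusion_kbp = exclusion_kbp,
         max_extension_gap_kbp = max_extension_gap_kbp,
         min_fiber_kbp = min_fiber_kbp, kbp_per_um = kbp_per_um),
    class = "fiber_params"
  )
}

# Tracks of one fiber in kbp: tibble channel/start_kbp/end_kbp, sorted.
fiber_tracks_kbp <- function(tracks, kbp_per_um = 2.59) {
  tibble(
    channel = tracks$channel,
    start_kbp = um_to_kbp(tracks$start_um, kbp_per_um),
    end_kbp = um_to_kbp(tracks$end_um, kbp_per_um)
  ) |> arrange(.data$start_kbp)
}

# Group sorted intervals by chaining at gaps <= gap_kbp; returns group index.
chain_groups <- function(start, end, gap_kbp) {
  n <- length(start)
  if (n == 0L) return(integer())
  g <- integer(n)
  g[1] <- 1L
  max_end <- end[1]
  for (i in seq_len(n)[-1]) {
    if (start[i] - max_end > gap_kbp) g[i] <- g[i - 1L] + 1L
    else g[i] <- g[i - 1L]
    max_end <- max(max_end, end[i])
  }
  g
}

#' Identify the primary channel-1 replicon cluster of a fiber
#'
#' Channel-1 tracks whose successive gaps are at most `cluster_gap_kbp` form
#' runs; the run with the largest DNA span is the primary cluster. The flanks
#' are the DNA on each side of the cluster, out to the exclusion distance.
#'
#' @param tracks Tracks of one fiber (tibble with `channel`, `start_um`,
#'   `end_um`).
#' @param params A [fiber_params()].
#' @return A list: `cluster` (c(start, end) kbp of the primary cluster),
#'   `cluster_tracks` (tibble of its channel-1 tracks), `flanks` (list of two
#'   c(start, end) intervals, left and right, possibly zero-length at the
#'   fiber edge).
#' @export
segment_primary_cluster <- function(tracks, params = fiber_params()) {
  tr <- fiber_tracks_kbp(tracks, params$kbp_per_um)
  ch1 <- tr[tr$channel == 1L, , drop = FALSE]
  if (nrow(ch1) == 0L) {
    return(list(cluster = NULL, cluster_tracks = ch1, flanks = NULL))
  }
  g <- chain_groups(ch1$start_kbp, ch1$end_kbp, params$cluster_gap_kbp)
  spans <- vapply(split(seq_len(nrow(ch1)), g), function(i) {
    max(ch1$end_kbp[i]) - min(ch1$start_kbp[i])
  }, numeric(1))
  best <- as.integer(names(spans)[which.max(spans)])
  ct <- ch1[g == best, , drop = FALSE]
  cl <- c(min(ct$start_kbp), max(ct$end_kbp))
  flanks <- list(
    left = c(cl[1] - params$exclusion_kbp, cl[1]),
    right = c(cl[2], cl[2] + params$exclusion_kbp)
  )
  list(cluster = cl, cluster_tracks = ct, flanks = flanks)
}

# Uncoupled channel-2 track groups: groups (chained at cluster_gap) with no
# channel-1 track within the exclusion distance.
uncoupled_groups <- function(tr, params) {
  ch2 <- tr[tr$channel == 2L, , drop = FALSE]
  ch1 <- tr[tr$channel == 1L, , drop = FALSE]
  if (nrow(ch2) == 0L) return(list(groups = integer(0), uncoupled = logical(0)))
  g <- chain_groups(ch2$start_kbp, ch2$end_kbp, params$cluster_gap_kbp)
  unc <- vapply(unique(g), function(gi) {
    s <- min(ch2$start_kbp[g == gi])
    e <- max(ch2$end_kbp[g == gi])
    if (nrow(ch1) == 0L) return(TRUE)
    d <- pmax(ch1$start_kbp - e, s - ch1$end_kbp, 0)
    min(d) > params$exclusion_kbp
  }, logical(1))
  list(groups = g, uncoupled = unc[g])
}

#' Classify a double-labeled fiber
#'
#' Applies the replication-class rules: a fiber whose flanking DNA contains
#' two or more distinct coupled channel-2 tracks shows `secondary_activation`
#' (new origins fired next to the primary cluster during the second pulse);
#' a fiber whose flanks carry at most one channel-2 track per side,
#' contiguous with the outgrowing forks (gap no larger than the chase
#' distance), is `extending`; a channel-2 track group with no channel-1
#' track within the exclusion distance (default 250 kbp) is an `uncoupled`
#' initiation, and a fiber carrying one — including a fiber with no channel-1
#' track at all — is classified `uncoupled`.
#'
#' @param tracks Tracks of one fiber (tibble with `channel`, `start_um`,
#'   `end_um`).
#' @param params A [fiber_params()].
#' @return One of `"extending"`, `"secondary_activation"`, `"uncoupled"`, or
#'   `NA_character_` for a fiber with no classifiable labeling.
#' @export
classify_fiber <- function(tracks, params = fiber_params()) {
  tr <- fiber_tracks_kbp(tracks, params$kbp_per_um)
  if (nrow(tr) == 0L) return(NA_character_)
  ch1 <- tr[tr$channel == 1L, , drop = FALSE]
  ch2 <- tr[tr$channel == 2L, , drop = FALSE]
  if (nrow(ch1) == 0L) {
    return(if (nrow(ch2) > 0L) "uncoupled" else NA_character_)
  }
  unc <- uncoupled_groups(tr, params)
  if (any(unc$uncoupled)) return("uncoupled")
  if (nrow(ch2) == 0L) return("extending")

  seg <- segment_primary_cluster(tracks, params)
  cl <- seg$cluster
  # flanking channel-2 tracks: beyond the cluster edges, near edge within the
  # exclusion distance
  left_gap <- cl[1] - ch2$end_kbp
  right_gap <- ch2$start_kbp - cl[2]
  in_left <- left_gap > 0 & left_gap <= params$exclusion_kbp
  in_right <- right_gap > 0 & right_gap <= params$exclusion_kbp
  for (side in list(list(sel = in_left, gap = left_gap),
                    list(sel = in_right, gap = right_gap))) {
    k <- sum(side$sel)
    if (k >= 2L) return("secondary_activation")
    if (k == 1L && side$gap[side$sel] > params$max_extension_gap_kbp) {
      return("secondary_activation")
    }
  }
  "extending"
}

#' Classify every fiber of a cohort
#'
#' @param fibers A `fiber_set` or tracks tibble (`fiber_id`, `channel`,
#'   `start_um`, `end_um`, optionally `fiber_length_um`, `truth_class`).
#' @param params A [fiber_params()].
#' @return A tibble with one row per fiber: `fiber_id`, `class`,
#'   `fiber_kbp` (DNA extent used for the length filter), `truth_class`
#'   when available.
#' @export
classify_fibers <- function(fibers, params = fiber_params()) {
  split_idx <- split(seq_len(nrow(fibers)), fibers$fiber_id)
  rows <- map(split_idx, function(i) {
    tr <- fibers[i, , drop = FALSE]
    len_um <- if ("fiber_length_um" %in% names(tr)) tr$fiber_length_um[1] else {
      max(tr$end_um) - min(tr$start_um)
    }
    tibble(
      fiber_id = tr$fiber_id[1],
      class = classify_fiber(tr, params),
      fiber_kbp = um_to_kbp(len_um, params$kbp_per_um),
      truth_class = if ("truth_class" %in% names(tr)) tr$truth_class[1]
      else NA_character_
    )
  })
  bind_rows(rows) |> arrange(.data$fiber_id)
}

#' Successive inter-origin distances within the primary cluster
#'
#' Uses the channel-1 track midpoint as the origin proxy (exact for
#' symmetric bidirectional forks).
#'
#' @param tracks Tracks of one fiber.
#' @param params A [fiber_params()].
#' @return Numeric vector of successive midpoint differences, kbp (empty
#'   when the primary cluster has fewer than two tracks).
#' @export
inter_origin_distances <- function(tracks, params = fiber_params()) {
  seg <- segment_primary_cluster(tracks, params)
  ct <- seg$cluster_tracks
  if (is.null(ct) || nrow(ct) < 2L) return(numeric(0))
  mids <- sort((ct$start_kbp + ct$end_kbp) / 2)
  diff(mids)
}

#' Estimate the replication fork rate from a track length
#'
#' @param track_length_kbp Labeled track length, kbp.
#' @param pulse_min Pulse duration, minutes.
#' @param bidirectional `TRUE` when the track spans both forks of one origin
#'   (rate is halved).
#' @param plausible_range Rates outside this window are flagged.
#' @return A tibble with `rate_kbp_per_min` and `plausible`.
#' @examples
#' estimate_fork_rate(90, 30)                        # 1.5, plausible
#' estimate_fork_rate(30, 20, bidirectional = FALSE) # 1.5
#' @export
estimate_fork_rate <- function(track_length_kbp, pulse_min,
                               bidirectional = TRUE,
                               plausible_range = c(0.5, 3)) {
  stopifnot(pulse_min > 0)
  rate <- track_length_kbp / pulse_min / (1 + bidirectional)
  tibble(
    rate_kbp_per_min = rate,
    plausible = rate >= plausible_range[1] & rate <= plausible_range[2]
  )
}

#' Cohort-level fiber report
#'
#' Classifies all fibers, applies the minimum-fiber-length filter, and
#' summarizes: per-class counts and proportions, per-class inter-origin
#' distance summaries, fork-rate estimates from channel-1 track lengths, and
#' the uncoupled fraction both per fiber and per labeled track group.
#'
#' @param fibers A `fiber_set` or tracks tibble.
#' @param params A [fiber_params()].
#' @param pulse1_min First-pulse duration used for fork-rate estimation.
#' @return A list of class `fiber_report`: `classes` (per-fiber tibble),
#'   `class_summary` (count/proportion per class), `inter_origin`
#'   (per-class mean/sd/n of inter-origin distances),
#'   `uncoupled_fiber_fraction`, `uncoupled_group_fraction`, `fork_rates`
#'   (per-track tibble), `n_fibers`, `n_excluded`.
#' @export
cohort_report <- function(fibers, params = fiber_params(), pulse1_min = 30) {
  if (nrow(fibers) == 0L) abort("at least one fiber is required")
  cls <- classify_fibers(fibers, params)
  kept <- cls |> filter(.data$fiber_kbp >= params$min_fiber_kbp,
                        !is.na(.data$class))
  n_excluded <- nrow(cls) - nrow(kept)
  lv <- c("extending", "secondary_activation", "uncoupled")
  counts <- table(factor(kept$class, levels = lv))
  class_summary <- tibble(
    class = lv,
    n = as.integer(counts),
    proportion = if (nrow(kept) > 0) as.numeric(counts) / nrow(kept)
    else rep(NA_real_, 3)
  )

  keep_ids <- kept$fiber_id
  fib_split <- split(seq_len(nrow(fibers)), fibers$fiber_id)
  fib_split <- fib_split[as.character(keep_ids)]

  iod <- map2(fib_split, kept$class, function(i, cl) {
    d <- inter_origin_distances(fibers[i, , drop = FALSE], params)
    if (length(d)) tibble(class = cl, distance_kbp = d) else NULL
  }) |> bind_rows()
  inter_origin <- if (nrow(iod) > 0) {
    iod |>
      group_by(.data$class) |>
      summarise(
        mean_kbp = mean(.data$distance_kbp),
        sd_kbp = if (dplyr::n() > 1) sd(.data$distance_kbp) else 0,
        n_spacings = dplyr::n(),
        .groups = "drop"
      )
  } else {
    tibble(class = character(), mean_kbp = double(), sd_kbp = double(),
           n_spacings = integer())
  }

  # labeled track groups: channel-1 cluster runs plus channel-2 groups that
  # are uncoupled (coupled channel-2 tracks belong to a channel-1 group)
  group_tally <- map(fib_split, function(i) {
    tr <- fiber_tracks_kbp(fibers[i, , drop = FALSE], params$kbp_per_um)
    ch1 <- tr[tr$channel == 1L, , drop = FALSE]
    n1 <- if (nrow(ch1)) {
      length(unique(chain_groups(ch1$start_kbp, ch1$end_kbp,
                                 params$cluster_gap_kbp)))
    } else 0L
    unc <- uncoupled_groups(tr, params)
    n_unc <- if (length(unc$uncoupled)) {
      sum(tapply(unc$uncoupled, unc$groups, any))
    } else 0L
    c(n1 = n1, n_unc = n_unc)
  })
  tot <- Reduce(`+`, group_tally, c(n1 = 0L, n_unc = 0L))
  n_groups <- tot[["n1"]] + tot[["n_unc"]]

  fr <- map(fib_split, function(i) {
    seg <- segment_primary_cluster(fibers[i, , drop = FALSE], params)
    ct <- seg$cluster_tracks
    if (is.null(ct) || nrow(ct) == 0L) return(NULL)
    estimate_fork_rate(ct$end_kbp - ct$start_kbp, pulse1_min,
                       bidirectional = TRUE)
  }) |> bind_rows()

  structure(
    list(
      classes = kept,
      class_summary = class_summary,
      inter_origin = inter_origin,
      uncoupled_fiber_fraction = if (nrow(kept)) {
        sum(kept$class == "uncoupled") / nrow(kept)
      } else NA_real_,
      uncoupled_group_fraction = if (n_groups > 0) {
        tot[["n_unc"]] / n_groups
      } else NA_real_,
      fork_rates = fr,
      n_fibers = nrow(kept),
      n_excluded = n_excluded
    ),
    class = "fiber_report"
  )
}

#' @export
print.fiber_report <- function(x, ...) {
  cat(sprintf("# fiber_report: %d fibers (%d excluded)\n",
              x$n_fibers, x$n_excluded))
  print(x$class_summary)
  cat(sprintf("uncoupled fraction: %.3f per fiber, %.3f per track group\n",
              x$uncoupled_fiber_fraction, x$uncoupled_group_fraction))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' Per-class summary rows of a fiber report
#'
#' @param x A `fiber_report`.
#' @param ... Unused.
#' @return A tibble with one row per class: counts, proportions, and
#'   inter-origin distance summaries.
#' @method tidy fiber_report
#' @export
tidy.fiber_report <- function(x, ...) {
  left_join(x$class_summary, x$inter_origin, by = "class")
}

#' One-row summary of a fiber report
#'
#' @param x A `fiber_report`.
#' @param ... Unused.
#' @method glance fiber_report
#' @export
glance.fiber_report <- function(x, ...) {
  tibble(
    n_fibers = x$n_fibers,
    n_excluded = x$n_excluded,
    prop_extending = x$class_summary$proportion[1],
    prop_secondary = x$class_summary$proportion[2],
    prop_uncoupled = x$class_summary$proportion[3],
    uncoupled_group_fraction = x$uncoupled_group_fraction,
    median_fork_rate = if (nrow(x$fork_rates)) {
      median(x$fork_rates$rate_kbp_per_min)
    } else NA_real_
  )
}
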
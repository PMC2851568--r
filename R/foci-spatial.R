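coords_matrix <- function(fs) {
  cbind(fs$x_nm, fs$y_nm, fs$z_nm)
}

# Full Euclidean cross-distance matrix between two coordinate sets.
cross_dist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

# Nearest index in each row of a distance matrix, ties broken by the lowest
# id of the candidate foci.
nearest_by_row <- function(d, ids, exclude_diag = FALSE) {
  if (exclude_diag) diag(d) <- Inf
  ord <- order(ids)
  d <- d[, ord, drop = FALSE]
  j <- max.col(-d, ties.method = "first")
  list(idx = ord[j], dist = d[cbind(seq_len(nrow(d)), j)])
}

#' Nearest-neighbour distances between two labeled channels
#'
#' For each focus of `a`, the 3D centre-to-centre Euclidean distance to its
#' nearest focus in `b` (the measurement behind the separation of first- and
#' second-pulse labeled foci). Ties are broken toward the lowest focus id.
#'
#' @param a,b Foci tables (tibbles with `id`, `x_nm`, `y_nm`, `z_nm`), e.g.
#'   from [zone_subset()].
#' @return A `distance_sample`: tibble with `focus_id`, `neighbor_id`,
#'   `dist_nm`, carrying `source` as an attribute.
#' @examples
#' a <- tibble::tibble(id = 1, x_nm = 0, y_nm = 0, z_nm = 0)
#' b <- tibble::tibble(id = 2, x_nm = 300, y_nm = 400, z_nm = 0)
#' nn_cross_channel(a, b)$dist_nm  # 500
#' @export
nn_cross_channel <- function(a, b) {
  if (nrow(a) == 0L) abort("channel a is empty")
  if (nrow(b) == 0L) abort("channel b is empty")
  d <- cross_dist(coords_matrix(a), coords_matrix(b))
  nn <- nearest_by_row(d, b$id)
  new_distance_sample(
    tibble(focus_id = a$id, neighbor_id = b$id[nn$idx], dist_nm = nn$dist),
    source = "cross-channel"
  )
}

#' Nearest-neighbour distances within one channel
#'
#' Distance from each focus to its nearest *other* focus of the same channel
#' (self-pairs excluded).
#'
#' @param a Foci table with at least two foci.
#' @return A `distance_sample` as in [nn_cross_channel()].
#' @export
nn_within_channel <- function(a) {
  if (nrow(a) < 2L) abort("within-channel analysis needs at least 2 foci")
  d <- cross_dist(coords_matrix(a), coords_matrix(a))
  nn <- nearest_by_row(d, a$id, exclude_diag = TRUE)
  new_distance_sample(
    tibble(focus_id = a$id, neighbor_id = a$id[nn$idx], dist_nm = nn$dist),
    source = "within-channel"
  )
}

new_distance_sample <- function(df, source = "") {
  structure(df, source = source,
            class = c("distance_sample", class(tibble())))
}

#' Mean, sample sd and n of a distance sample
#'
#' Reports the "mean +/- sd (n)" summary used for foci separations. The sd of
#' a single observation is 0 by convention (with a warning).
#'
#' @param d A `distance_sample` (or numeric vector of distances).
#' @return One-row tibble: `mean_nm`, `sd_nm`, `n`.
#' @export
summarize_distances <- function(d) {
  v <- if (is.data.frame(d)) d$dist_nm else d
  if (length(v) < 1L) abort("distance sample is empty")
  s <- if (length(v) == 1L) {
    warn("sd of a single distance is 0 by convention")
    0
  } else sd(v)
  tibble(mean_nm = mean(v), sd_nm = s, n = length(v))
}

#' Welch two-sample t test between two distance samples
#'
#' Two-sided, unequal-variance t test on the raw distances (the comparison
#' behind the reported labeling-condition contrasts). Two samples with zero
#' variance and equal means return p = 1 by convention.
#'
#' @param d1,d2 `distance_sample` objects or numeric vectors.
#' @return One-row tibble: `statistic`, `p_value`, `df`.
#' @export
compare_conditions <- function(d1, d2) {
  v1 <- if (is.data.frame(d1)) d1$dist_nm else d1
  v2 <- if (is.data.frame(d2)) d2$dist_nm else d2
  if (length(v1) < 2L || length(v2) < 2L) {
    abort("both samples need at least 2 values")
  }
  if (sd(v1) == 0 && sd(v2) == 0) {
    if (isTRUE(all.equal(mean(v1), mean(v2)))) {
      return(tibble(statistic = 0, p_value = 1,
                    df = length(v1) + length(v2) - 2))
    }
    return(tibble(statistic = Inf, p_value = 0,
                  df = length(v1) + length(v2) - 2))
  }
  tt <- t.test(v1, v2, var.equal = FALSE)
  tibble(statistic = unname(tt$statistic), p_value = tt$p.value,
         df = unname(tt$parameter))
}

#' Co-association fraction between two channels
#'
#' Fraction of foci in `a` whose nearest focus in `b` lies within the
#' threshold — the statistic behind the observation that first-pulse foci
#' were within 500 nm of a second-pulse focus. The comparison includes the
#' threshold itself (with a 1e-6 nm guard against floating-point ties at
#' exactly the threshold distance).
#'
#' @param a,b Foci tables.
#' @param threshold_nm Distance threshold, nm (default 500).
#' @return A proportion in `[0, 1]`.
#' @export
coassociation_fraction <- function(a, b, threshold_nm = 500) {
  if (threshold_nm <= 0) abort("threshold_nm must be positive")
  d <- nn_cross_channel(a, b)
  mean(d$dist_nm <= threshold_nm + 1e-6)
}

#' Naive volume occupancy of a foci set
#'
#' Sum of focus sphere volumes over the nucleus sphere volume, ignoring
#' overlap between foci (the naive ratio that gives 44% for the default
#' 3500-focus configuration).
#'
#' @param fs A `foci_set`.
#' @return A proportion (may exceed 1 for overlapping configurations).
#' @export
volume_occupancy <- function(fs) {
  stopifnot(inherits(fs, "foci_set"))
  nuc <- attr(fs, "nucleus")
  if (nrow(fs) == 0L) return(0)
  r_nuc <- nuc$nucleus_diameter_um * 1000 / 2
  sum((fs$diameter_nm / 2)^3) / r_nuc^3
}

#' Voxel co-localization fraction between two channels
#'
#' Rasterizes each focus as the set of voxels whose centres fall inside its
#' sphere and returns the fraction of channel-a voxels that are also
#' channel-b voxels (the per-voxel co-localization measure reported for
#' nascent-DNA chases).
#'
#' @param a,b Foci tables with `x_nm`, `y_nm`, `z_nm`, `diameter_nm`.
#' @param voxel_nm Voxel edge length, nm (default 50).
#' @return A proportion in `[0, 1]`.
#' @export
colocalization_fraction <- function(a, b, voxel_nm = 50) {
  if (voxel_nm <= 0) abort("voxel_nm must be positive")
  va <- voxelize(a, voxel_nm)
  if (length(va) == 0L) abort("channel a rasterizes to zero voxels")
  vb <- voxelize(b, voxel_nm)
  if (length(vb) == 0L) return(0)
  length(intersect(va, vb)) / length(va)
}

# Voxel keys (integer-grid coordinates packed into strings) of all voxels
# whose centres fall inside any focus sphere of the set.
voxelize <- function(fs, voxel_nm) {
  if (nrow(fs) == 0L) return(character(0))
  keys <- vector("list", nrow(fs))
  for (i in seq_len(nrow(fs))) {
    r <- fs$diameter_nm[i] / 2
    ctr <- c(fs$x_nm[i], fs$y_nm[i], fs$z_nm[i])
    # voxel centres at (k + 0.5) * voxel
    rng <- lapply(ctr, function(c0) {
      lo <- floor((c0 - r) / voxel_nm - 0.5)
      hi <- ceiling((c0 + r) / voxel_nm + 0.5)
      seq(lo, hi)
    })
    g <- expand.grid(x = rng[[1]], y = rng[[2]], z = rng[[3]])
    cx <- (g$x + 0.5) * voxel_nm
    cy <- (g$y + 0.5) * voxel_nm
    cz <- (g$z + 0.5) * voxel_nm
    inside <- (cx - ctr[1])^2 + (cy - ctr[2])^2 + (cz - ctr[3])^2 <= r^2
    keys[[i]] <- paste(g$x[inside], g$y[inside], g$z[inside], sep = ",")
  }
  unique(unlist(keys))
}
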
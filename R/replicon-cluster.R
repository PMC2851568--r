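#' Replicon length model
#'
#' The stochastic model for the length of an individual replicon: a normal
#' distribution truncated to positive values. The defaults are the published
#' fit for human HeLa replicons, mu = 140.6238 kbp and sigma = 58.8192 kbp.
#' Non-positive draws are handled per the truncation rule; the default
#' (`"resample"`) redraws them, which shifts the distribution's true mean to
#' about +0.97% of mu and its sd to about -2.8% of sigma
#' (see [truncated_normal_moments()]).
#'
#' @param mu Mean of the untruncated normal, kbp.
#' @param sigma Standard deviation of the untruncated normal, kbp.
#' @param truncation `"resample"` (redraw non-positive values) or `"clamp"`
#'   (replace them with `clamp_at`).
#' @param clamp_at Replacement value for `truncation = "clamp"`, kbp.
#' @return A list of class `replicon_length_model`.
#' @export
replicon_length_model <- function(mu = 140.6238, sigma = 58.8192,
                                  truncation = c("resample", "clamp"),
                                  clamp_at = 1e-3) {
  if (mu <= 0 || sigma <= 0) abort("mu and sigma must be positive")
  structure(
    list(mu = mu, sigma = sigma, truncation = match.arg(truncation),
         clamp_at = clamp_at),
    class = "replicon_length_model"
  )
}

#' Moments of the positive-truncated normal
#'
#' Closed-form mean and sd of a normal(mu, sigma) conditioned on being
#' positive — the true moments of the replicon length model under resample
#' truncation.
#'
#' @param mu,sigma Parameters of the untruncated normal.
#' @return Named list with `mean` and `sd`.
#' @export
truncated_normal_moments <- function(mu, sigma) {
  alpha <- -mu / sigma
  z <- 1 - pnorm(alpha)
  lam <- dnorm(alpha) / z
  m <- mu + sigma * lam
  v <- sigma^2 * (1 + alpha * lam - lam^2)
  list(mean = m, sd = sqrt(v))
}

#' Sample replicon lengths
#'
#' @param n Number of lengths to draw.
#' @param model A [replicon_length_model()].
#' @param seed Integer seed.
#' @return Numeric vector of `n` positive lengths, kbp.
#' @examples
#' sample_replicon_lengths(5, seed = 1)
#' @export
sample_replicon_lengths <- function(n, model = replicon_length_model(),
                                    seed = 1L) {
  stopifnot(inherits(model, "replicon_length_model"), n >= 1)
  withr::local_seed(seed)
  draw_replicon_lengths(n, model)
}

# RNG-stream version used inside larger simulations (no seed scoping).
draw_replicon_lengths <- function(n, model) {
  x <- rnorm(n, model$mu, model$sigma)
  if (model$truncation == "clamp") {
    x[x <= 0] <- model$clamp_at
    return(x)
  }
  bad <- which(x <= 0)
  guard <- 0L
  while (length(bad) > 0L) {
    x[bad] <- rnorm(length(bad), model$mu, model$sigma)
    bad <- bad[x[bad] <= 0]
    guard <- guard + 1L
    if (guard > 1000L) abort("resampling failed to produce positive lengths")
  }
  x
}

#' Cluster size probability mass function
#'
#' Distribution of the number of replicons per replicon cluster. The default
#' is uniform over 3-5 replicons (clusters typically contain 3-5 replicons
#' within about 1 Mbp); the exact published frequency table underlying the
#' original simulation comes from a cited reference and is user-overridable
#' here.
#'
#' @param sizes Integer vector of cluster sizes (replicons per cluster, >= 1).
#' @param prob Probabilities, same length as `sizes`; normalized to sum to 1.
#' @return A list of class `cluster_size_pmf` with `sizes` and `prob`.
#' @export
cluster_size_pmf <- function(sizes = 3:5, prob = rep(1, length(sizes))) {
  sizes <- as.integer(sizes)
  if (any(sizes < 1)) abort("cluster sizes must be >= 1")
  if (length(prob) != length(sizes) || any(prob < 0) || sum(prob) <= 0) {
    abort("prob must be non-negative, same length as sizes, with positive sum")
  }
  structure(list(sizes = sizes, prob = prob / sum(prob)),
            class = "cluster_size_pmf")
}

#' Simulate the DNA content of replicon clusters
#'
#' For each cluster, draws its size k from the cluster-size pmf and then k
#' replicon lengths from the length model; the cluster's DNA content is the
#' sum of its replicon lengths (no inter-replicon gaps).
#'
#' @param n_clusters Number of clusters to simulate.
#' @param pmf A [cluster_size_pmf()].
#' @param model A [replicon_length_model()].
#' @param seed Integer seed.
#' @return A tibble with one row per cluster: `cluster`, `k` (replicons),
#'   `dna_content_kbp`, and list-column `replicon_lengths_kbp`.
#' @examples
#' sample_clusters(3, seed = 1)
#' @export
sample_clusters <- function(n_clusters,
                            pmf = cluster_size_pmf(),
                            model = replicon_length_model(),
                            seed = 1L) {
  stopifnot(n_clusters >= 1, inherits(pmf, "cluster_size_pmf"))
  withr::local_seed(seed)
  k <- pmf$sizes[sample.int(length(pmf$sizes), n_clusters, replace = TRUE,
                            prob = pmf$prob)]
  lens <- draw_replicon_lengths(sum(k), model)
  idx <- rep(seq_len(n_clusters), k)
  tibble(
    cluster = seq_len(n_clusters),
    k = as.integer(k),
    replicon_lengths_kbp = unname(split(lens, idx)),
    dna_content_kbp = as.numeric(tapply(lens, idx, sum))
  )
}

#' Build a normalized distribution profile from lengths
#'
#' Histograms the values on `[0, max]` (max rounded up to a whole bin) with
#' the given bin width, normalizes frequencies to sum to 1, and records the
#' mean, sample sd, and central 90% interval (empirical 5th/95th percentiles,
#' linear interpolation between order statistics).
#'
#' @param values Numeric vector, kbp.
#' @param bin_width_kbp Bin width, kbp (default 50).
#' @return A `distribution_profile`: tibble with `bin_start`, `bin_end`,
#'   `frequency`; attributes `mean`, `sd`, `central90` (length-2), `n`.
#' @export
build_profile <- function(values, bin_width_kbp = 50) {
  if (length(values) == 0L) abort("values must be non-empty")
  if (bin_width_kbp <= 0) abort("bin_width_kbp must be positive")
  n_bins <- max(1L, ceiling(max(values) / bin_width_kbp))
  edges <- seq(0, n_bins * bin_width_kbp, by = bin_width_kbp)
  idx <- pmin(pmax(findInterval(values, edges, left.open = TRUE), 1L), n_bins)
  freq <- tabulate(idx, nbins = n_bins) / length(values)
  out <- tibble(
    bin_start = edges[-length(edges)],
    bin_end = edges[-1],
    frequency = freq
  )
  structure(
    out,
    mean = mean(values),
    sd = if (length(values) > 1) sd(values) else 0,
    central90 = unname(quantile(values, c(0.05, 0.95), type = 7)),
    n = length(values),
    class = c("distribution_profile", class(tibble()))
  )
}

#' @export
print.distribution_profile <- function(x, ...) {
  c90 <- attr(x, "central90")
  cat(sprintf(
    "# distribution_profile: mean %.1f +/- %.1f kbp, 90%% within %.1f-%.1f kbp (n = %d)\n",
    attr(x, "mean"), attr(x, "sd"), c90[1], c90[2], attr(x, "n")
  ))
  NextMethod()
}

#' @importFrom generics glance
#' @export
generics::glance

#' One-row summary of a distribution profile
#'
#' @param x A `distribution_profile`.
#' @param ... Unused.
#' @return A one-row tibble: `mean_kbp`, `sd_kbp`, `p05_kbp`, `p95_kbp`, `n`.
#' @method glance distribution_profile
#' @export
glance.distribution_profile <- function(x, ...) {
  c90 <- attr(x, "central90")
  tibble(
    mean_kbp = attr(x, "mean"), sd_kbp = attr(x, "sd"),
    p05_kbp = c90[1], p95_kbp = c90[2], n = attr(x, "n")
  )
}

#' Pearson correlation between two distribution profiles
#'
#' Profiles must share bin width and origin; the shorter profile is padded
#' with empty trailing bins to the common length (frequencies are invariant
#' to trailing empty bins).
#'
#' @param p,q `distribution_profile` objects.
#' @return Pearson correlation of per-bin frequencies.
#' @export
profile_correlation <- function(p, q) {
  stopifnot(inherits(p, "distribution_profile"),
            inherits(q, "distribution_profile"))
  wp <- p$bin_end[1] - p$bin_start[1]
  wq <- q$bin_end[1] - q$bin_start[1]
  if (!isTRUE(all.equal(wp, wq)) ||
      !isTRUE(all.equal(p$bin_start[1], q$bin_start[1]))) {
    abort("profiles must share bin width and origin; re-bin to a common grid")
  }
  len <- max(nrow(p), nrow(q))
  fp <- c(p$frequency, rep(0, len - nrow(p)))
  fq <- c(q$frequency, rep(0, len - nrow(q)))
  if (sd(fp) == 0 || sd(fq) == 0) {
    abort("profile has zero variance; correlation undefined")
  }
  cor(fp, fq)
}
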
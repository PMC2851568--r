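#' Smooth a timing profile with a centered moving average
#'
#' @param p A `timing_profile` (tibble with `chrom`, `start`, `end`, `value`).
#' @param window Odd window width in bins; `window = 1` is the identity.
#'   Edges are truncated (partial windows average over the available bins).
#' @return The profile with smoothed `value`.
#' @export
smooth_profile <- function(p, window = 3L) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) abort("window must be odd and >= 1")
  if (window == 1L || nrow(p) == 0L) return(p)
  half <- window %/% 2L
  v <- p$value
  n <- length(v)
  cs <- cumsum(c(0, v))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  p$value <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  p
}

# Local maxima (plateau-aware) of a numeric vector. Returns a tibble with the
# representative index of each peak (plateau midpoint) and its height.
local_maxima <- function(v) {
  n <- length(v)
  if (n == 0L) return(tibble(idx = integer(), height = double()))
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  is_max <- vapply(seq_len(k), function(i) {
    left_ok <- i == 1L || r$values[i - 1L] < r$values[i]
    right_ok <- i == k || r$values[i + 1L] < r$values[i]
    left_ok && right_ok
  }, logical(1))
  idx <- as.integer(floor((starts[is_max] + ends[is_max]) / 2))
  tibble(idx = idx, height = r$values[is_max])
}

# Topographic prominence of each peak: height minus the higher of the two key
# saddles (the minimum between the peak and the nearest higher ground on each
# side; the profile edge acts as ground at the side's minimum).
peak_prominence <- function(v, peaks) {
  vapply(seq_len(nrow(peaks)), function(i) {
    p <- peaks$idx[i]
    h <- peaks$height[i]
    left <- v[seq_len(p - 1L)]
    right <- if (p < length(v)) v[(p + 1L):length(v)] else numeric()
    saddle <- function(side, reverse) {
      if (length(side) == 0L) return(-Inf)
      if (reverse) side <- rev(side) # walk outward from the peak
      higher <- which(side > h)
      run <- if (length(higher)) side[seq_len(higher[1] - 1L)] else side
      if (length(run) == 0L) -Inf else {
        if (length(higher)) min(run) else -Inf
      }
    }
    ls <- saddle(left, reverse = TRUE)
    rs <- saddle(right, reverse = FALSE)
    key <- max(ls, rs)
    if (!is.finite(key)) key <- min(v) # global-scale peak
    h - key
  }, numeric(1))
}

#' Call replication timing domains from a binned profile
#'
#' Operationalizes the inflection-point reading of a replication timing
#' profile: after optional smoothing, local maxima whose topographic
#' prominence reaches `min_prominence` become domain apexes; each domain
#' spans from the preceding to the following valley (the local minimum
#' between consecutive retained apexes, with the profile ends counting as
#' boundaries), so adjacent domains share boundaries exactly. Domains shorter
#' than `min_domain_length_kbp` are merged into the neighbour with the higher
#' apex. Valley ties are broken toward the midpoint between the two apexes.
#'
#' @param p A `timing_profile`.
#' @param window Smoothing window in bins (odd; default 3).
#' @param min_prominence Minimum peak prominence in signal units; default
#'   0.1 x the interquartile range of the smoothed profile.
#' @param min_domain_length_kbp Minimum domain length, kbp (default 0).
#' @return A tibble of domains: `chrom`, `start`, `end`, `apex_position`,
#'   `apex_value`, `length_kbp` (0-based half-open, bp coordinates).
#' @examples
#' p <- gen_timing_profile(c(500, 600), c(2, 3))
#' call_domains(p)
#' @export
call_domains <- function(p, window = 3L, min_prominence = NULL,
                         min_domain_length_kbp = 0) {
  empty <- tibble(
    chrom = character(), start = double(), end = double(),
    apex_position = double(), apex_value = double(), length_kbp = double()
  )
  if (nrow(p) == 0L) return(empty)
  sm <- smooth_profile(p, window)
  v <- sm$value
  if (is.null(min_prominence)) min_prominence <- 0.1 * IQR(v)
  peaks <- local_maxima(v)
  if (nrow(peaks) > 0L) {
    prom <- peak_prominence(v, peaks)
    peaks <- peaks[prom >= min_prominence & prom > 0, , drop = FALSE]
  }
  if (nrow(peaks) == 0L) return(empty)

  apex_idx <- sort(peaks$idx)
  mids <- (sm$start + sm$end) / 2
  # boundaries: profile ends plus the valley between consecutive apexes; the
  # valley bin (argmin, ties toward the midpoint between apexes) is refined
  # to sub-bin precision by intersecting the flank lines around it
  inner <- numeric(0)
  if (length(apex_idx) > 1L) {
    inner <- vapply(seq_len(length(apex_idx) - 1L), function(i) {
      a <- apex_idx[i]
      b <- apex_idx[i + 1L]
      if (b - a < 2L) return(mids[a]) # adjacent apexes: boundary at the left
      seg <- v[(a + 1L):(b - 1L)]
      cand <- which(seg == min(seg)) + a
      mid <- (a + b) / 2
      j <- cand[which.min(abs(cand - mid))]
      refine_valley(v, mids, j, a, b)
    }, numeric(1))
  }
  bounds <- c(p$start[1], inner, p$end[nrow(p)])
  dom <- tibble(
    chrom = p$chrom[1],
    start = bounds[-length(bounds)],
    end = bounds[-1],
    apex_position = mids[apex_idx],
    apex_value = v[apex_idx]
  )
  dom <- merge_short_domains(dom, min_domain_length_kbp)
  dom$length_kbp <- (dom$end - dom$start) / 1000
  dom
}

# Sub-bin valley position: intersect the descending line fit just left of the
# argmin bin j with the ascending line just right of it. Two pairings are
# tried (the argmin sample itself may sit on either flank); a candidate is
# valid when the slopes have the right signs and the intersection falls next
# to j; with two valid candidates the one with the lower interpolated valley
# wins. Falls back to the argmin bin midpoint (error below one bin). Exact
# for noise-free piecewise-linear valleys.
refine_valley <- function(v, x, j, lo, hi) {
  line <- function(i1, i2) {
    s <- (v[i2] - v[i1]) / (x[i2] - x[i1])
    c(slope = s, icept = v[i1] - s * x[i1])
  }
  candidate <- function(l, r, xmin, xmax) {
    if (!is.finite(l["slope"]) || !is.finite(r["slope"])) return(NULL)
    if (l["slope"] >= 0 || r["slope"] <= 0) return(NULL)
    xi <- (r["icept"] - l["icept"]) / (l["slope"] - r["slope"])
    if (xi < xmin || xi > xmax) return(NULL)
    c(x = unname(xi),
      y = unname(l["slope"] * xi + l["icept"]))
  }
  cands <- list()
  if (j - 1L > lo && j + 2L < hi) { # argmin on the left flank
    cands <- c(cands, list(candidate(line(j - 1L, j), line(j + 1L, j + 2L),
                                     x[j], x[j + 1L])))
  }
  if (j - 2L > lo && j + 1L < hi) { # argmin on the right flank
    cands <- c(cands, list(candidate(line(j - 2L, j - 1L), line(j, j + 1L),
                                     x[j - 1L], x[j])))
  }
  cands <- cands[!vapply(cands, is.null, logical(1))]
  if (length(cands) == 0L) return(x[j])
  best <- cands[[which.min(vapply(cands, `[`, numeric(1), "y"))]]
  best[["x"]]
}

# Merge domains shorter than the minimum into the neighbour with the higher
# apex, repeating until stable.
merge_short_domains <- function(dom, min_len_kbp) {
  if (min_len_kbp <= 0) return(dom)
  repeat {
    len <- (dom$end - dom$start) / 1000
    short <- which(len < min_len_kbp)
    if (length(short) == 0L || nrow(dom) == 1L) break
    i <- short[1]
    nb <- c(if (i > 1) i - 1L, if (i < nrow(dom)) i + 1L)
    j <- nb[which.max(dom$apex_value[nb])]
    keep <- dom[min(i, j), ]
    keep$start <- dom$start[min(i, j)]
    keep$end <- dom$end[max(i, j)]
    win <- if (dom$apex_value[j] >= dom$apex_value[i]) j else i
    keep$apex_position <- dom$apex_position[win]
    keep$apex_value <- dom$apex_value[win]
    dom <- bind_rows(
      dom[seq_len(min(i, j) - 1L), ],
      keep,
      dom[seq(max(i, j) + 1L, length.out = nrow(dom) - max(i, j)), ]
    )
  }
  dom
}

#' Distribution profile of domain lengths
#'
#' @param domains A domains tibble from [call_domains()].
#' @param bin_width_kbp Bin width for [build_profile()].
#' @return A `distribution_profile` of the domain lengths.
#' @export
domain_length_profile <- function(domains, bin_width_kbp = 50) {
  if (nrow(domains) == 0L) abort("at least one domain is required")
  build_profile(domains$length_kbp, bin_width_kbp)
}
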
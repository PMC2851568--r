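#' Generate a binned replication-timing profile with planted domains
#'
#' Builds a synthetic genome-wide timing signal as a concatenation of
#' unimodal triangular peaks, one per domain: within each domain the signal
#' rises linearly from 0 at the left boundary to the domain's apex height at
#' its midpoint and falls back to 0 at the right boundary (higher = earlier
#' replication). Optional additive Gaussian noise emulates assay noise. The
#' planted domain boundaries and apexes are attached as ground truth, so the
#' domain caller ([call_domains()]) can be validated exactly.
#'
#' @param domain_lengths_kbp Numeric vector of domain lengths, kbp.
#' @param peak_heights Numeric vector, one apex height per domain
#'   (dimensionless timing signal).
#' @param bin_size_bp Bin width in bp (default 10 kb).
#' @param noise_sd Standard deviation of additive Gaussian noise, signal units.
#' @param seed Integer seed (used only when `noise_sd > 0`).
#' @param chrom Chromosome name for the emitted profile.
#' @return A `timing_profile`: tibble with columns `chrom`, `start`, `end`,
#'   `value` (0-based half-open bins), with attributes `boundaries_bp`
#'   (planted domain boundaries, including 0 and the profile end) and
#'   `apexes_bp` (planted apex positions).
#' @examples
#' p <- gen_timing_profile(c(500, 600), c(2, 3))
#' nrow(p)
#' @export
gen_timing_profile <- function(domain_lengths_kbp,
                               peak_heights,
                               bin_size_bp = 10000,
                               noise_sd = 0,
                               seed = 1L,
                               chrom = "chrS") {
  if (length(domain_lengths_kbp) != length(peak_heights)) {
    abort("one peak height per domain is required")
  }
  if (bin_size_bp <= 0) abort("bin_size_bp must be positive")
  if (length(domain_lengths_kbp) == 0L) {
    out <- tibble(chrom = character(), start = double(), end = double(),
                  value = double())
    return(new_timing_profile(out, boundaries_bp = numeric(),
                              apexes_bp = numeric()))
  }
  if (any(domain_lengths_kbp <= 0)) abort("domain lengths must be positive")

  lengths_bp <- domain_lengths_kbp * 1000
  bounds <- c(0, cumsum(lengths_bp))
  total <- bounds[length(bounds)]
  n_bins <- ceiling(total / bin_size_bp)
  starts <- (seq_len(n_bins) - 1) * bin_size_bp
  ends <- pmin(starts + bin_size_bp, total)
  mids <- (starts + ends) / 2

  dom <- findInterval(mids, bounds, rightmost.closed = TRUE)
  dom <- pmin(pmax(dom, 1L), length(lengths_bp))
  left <- bounds[dom]
  len <- lengths_bp[dom]
  apex <- left + len / 2
  # triangular peak: 0 at boundaries, peak_heights[dom] at the midpoint
  frac <- 1 - abs(mids - apex) / (len / 2)
  value <- peak_heights[dom] * pmax(frac, 0)

  if (noise_sd > 0) {
    withr::local_seed(seed)
    value <- value + rnorm(n_bins, 0, noise_sd)
  }

  out <- tibble(chrom = chrom, start = starts, end = ends, value = value)
  new_timing_profile(out, boundaries_bp = bounds,
                     apexes_bp = bounds[-length(bounds)] + lengths_bp / 2)
}

new_timing_profile <- function(df, boundaries_bp = NULL, apexes_bp = NULL) {
  structure(
    df,
    boundaries_bp = boundaries_bp,
    apexes_bp = apexes_bp,
    class = c("timing_profile", class(tibble()))
  )
}
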
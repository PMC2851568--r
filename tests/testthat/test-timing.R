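test_that("profile generator plants unimodal peaks with recorded truth", {
  p <- gen_timing_profile(c(500, 600), c(2, 3), bin_size_bp = 10000)
  expect_equal(nrow(p), 110)
  expect_equal(attr(p, "boundaries_bp"), c(0, 5e5, 1.1e6))
  # exactly two local maxima and one interior local minimum
  v <- p$value
  d <- sign(diff(v))
  turns <- rle(d)$values
  expect_equal(sum(turns == 1), 2)
  expect_equal(sum(turns == -1), 2)
  empty <- gen_timing_profile(numeric(0), numeric(0))
  expect_equal(nrow(empty), 0)
  # total length is additive over planted domains
  lens <- sample_clusters(112, seed = 1)$dna_content_kbp
  big <- gen_timing_profile(lens, rep(1, 112))
  expect_equal(max(big$end), sum(lens) * 1000)
})

test_that("profile noise is reproducible and respects the seed", {
  a <- gen_timing_profile(c(500), c(2), noise_sd = 0.2, seed = 5)
  b <- gen_timing_profile(c(500), c(2), noise_sd = 0.2, seed = 5)
  c2 <- gen_timing_profile(c(500), c(2), noise_sd = 0.2, seed = 6)
  expect_identical(a$value, b$value)
  expect_false(identical(a$value, c2$value))
})

test_that("smoothing is a centered moving average with edge truncation", {
  p <- gen_timing_profile(c(300), c(1))
  expect_identical(smooth_profile(p, 1)$value, p$value)
  const <- p
  const$value <- rep(2, nrow(p))
  expect_equal(smooth_profile(const, 5)$value, rep(2, nrow(p)))
  imp <- p
  imp$value <- rep(0, nrow(p))
  imp$value[15] <- 9
  sm <- smooth_profile(imp, 3)
  expect_equal(sm$value[14:16], rep(3, 3))
  expect_equal(sm$value[13], 0)
  expect_error(smooth_profile(p, 2), "odd")
})

test_that("a flat profile yields no domains", {
  p <- gen_timing_profile(c(500), c(1))
  p$value <- rep(3, nrow(p))
  expect_equal(nrow(call_domains(p)), 0)
})

test_that("two peaks give a boundary at the valley argmin", {
  p <- gen_timing_profile(c(400, 400), c(2, 2), bin_size_bp = 10000)
  dom <- call_domains(p, window = 1)
  expect_equal(nrow(dom), 2)
  # brute-force scan: the planted valley is the interior minimum
  v <- p$value
  interior <- 10:70
  j <- interior[which.min(v[interior])]
  expect_lt(abs(dom$end[1] - 4e5), 10000 + 1e-6)
  expect_true(dom$end[1] >= p$start[j] - 10000 &&
                dom$end[1] <= p$end[j] + 10000)
})

test_that("noise-free planted domains are recovered exactly", {
  withr::local_seed(31)
  for (rep in 1:5) {
    lens <- runif(6, 275, 935)
    hts <- runif(6, 1, 10)
    p <- gen_timing_profile(lens, hts, bin_size_bp = 10000)
    dom <- call_domains(p, window = 1)
    expect_equal(nrow(dom), 6)
    got <- sort(unique(c(dom$start, dom$end)))
    expect_equal(got, attr(p, "boundaries_bp"), tolerance = 1e-6)
    expect_equal(sort(dom$length_kbp), sort(lens), tolerance = 1e-6)
    # domains tile the profile with shared boundaries
    expect_equal(dom$start[-1], dom$end[-nrow(dom)])
    expect_equal(sum(dom$length_kbp) * 1000, max(p$end) - min(p$start))
  }
})

test_that("raising the prominence threshold never adds domains", {
  p <- gen_timing_profile(runif(8, 275, 935), runif(8, 1, 10),
                          noise_sd = 0.15, seed = 12)
  counts <- vapply(c(0, 0.2, 0.5, 1, 2, 5),
                   function(pr) nrow(call_domains(p, min_prominence = pr)),
                   integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("short domains merge into the higher-apex neighbour", {
  p <- gen_timing_profile(c(500, 60, 500), c(3, 1, 4), bin_size_bp = 10000)
  all3 <- call_domains(p, window = 1, min_prominence = 0.05)
  expect_equal(nrow(all3), 3)
  merged <- call_domains(p, window = 1, min_prominence = 0.05,
                         min_domain_length_kbp = 100)
  expect_equal(nrow(merged), 2)
  # merged tiling still covers the full span
  expect_equal(sum(merged$length_kbp) * 1000, max(p$end))
})

test_that("domain length profile delegates to build_profile", {
  p <- gen_timing_profile(c(500), c(2))
  dom <- call_domains(p, window = 1)
  prof <- domain_length_profile(dom)
  expect_equal(attr(prof, "mean"), 500, tolerance = 1e-6)
  expect_equal(attr(prof, "sd"), 0)
  # planted lengths drawn near the reported domain-length distribution are
  # recovered within sampling error of their own mean
  withr::local_seed(13)
  lens <- pmax(rnorm(112, 529.5, 208), 50)
  hts <- runif(112, 1, 10)
  big <- gen_timing_profile(lens, hts)
  dom2 <- call_domains(big, window = 1)
  expect_equal(nrow(dom2), 112)
  m <- attr(domain_length_profile(dom2), "mean")
  expect_equal(m, mean(lens), tolerance = 1e-6)
  expect_lt(abs(m - 529.5), 2 * 208 / sqrt(112))
})
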
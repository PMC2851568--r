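test_that("unit conversion uses the fiber stretching factor exactly", {
  expect_equal(um_to_kbp(1), 2.59)
  expect_equal(um_to_kbp(0), 0)
  expect_equal(um_to_kbp(34.7), 89.873)
  expect_equal(kbp_to_um(um_to_kbp(12.34)), 12.34)
})

test_that("single-replicon track arithmetic follows the pulse protocol", {
  cfg <- exact_fiber_config(
    replicons_per_cluster = 1L,
    class_mix = c(extending = 1, secondary_activation = 0, uncoupled = 0)
  )
  fb <- gen_fibers(cfg, 5, seed = 2)
  for (f in unique(fb$fiber_id)) {
    tr <- fb[fb$fiber_id == f, ]
    ch1 <- tr[tr$channel == 1, ]
    ch2 <- tr[tr$channel == 2, ]
    # bidirectional channel-1 track: 2 x 30 min x 1.5 kbp/min = 90 kbp
    expect_equal(um_to_kbp(ch1$end_um - ch1$start_um), 90, tolerance = 1e-9)
    # one outgoing-fork track per side, 20 min x 1.5 = 30 kbp each,
    # separated from the cluster by the chase distance 60 x 1.5 = 90 kbp
    expect_equal(nrow(ch2), 2)
    expect_equal(um_to_kbp(ch2$end_um - ch2$start_um), c(30, 30),
                 tolerance = 1e-9)
    gaps <- um_to_kbp(c(ch1$start_um - ch2$end_um[1],
                        ch2$start_um[2] - ch1$end_um))
    expect_equal(gaps, c(90, 90), tolerance = 1e-9)
  }
})

test_that("a zero-length second pulse leaves no channel-2 tracks", {
  cfg <- exact_fiber_config(pulse2_min = 0)
  fb <- gen_fibers(cfg, 10, seed = 3)
  expect_equal(sum(fb$channel == 2), 0)
})

test_that("fiber generation is reproducible and respects the class mix", {
  cfg <- fiber_config()
  a <- gen_fibers(cfg, 50, seed = 7)
  b <- gen_fibers(cfg, 50, seed = 7)
  expect_identical(as.data.frame(a[1:6]), as.data.frame(b[1:6]))
  cls <- classify_fibers(a)
  expect_setequal(unique(cls$truth_class),
                  c("extending", "secondary_activation", "uncoupled"))
  # every generated fiber reports at least 0.8 Mbp of DNA
  expect_true(all(um_to_kbp(a$fiber_length_um) >= 800 - 1e-9))
})

test_that("noise-free uncoupled tracks sit beyond the exclusion distance", {
  cfg <- exact_fiber_config(
    class_mix = c(extending = 0, secondary_activation = 0, uncoupled = 1)
  )
  fb <- gen_fibers(cfg, 20, seed = 4)
  for (f in unique(fb$fiber_id)) {
    tr <- nextinline:::fiber_tracks_kbp(fb[fb$fiber_id == f, ])
    unc <- nextinline:::uncoupled_groups(tr, fiber_params())
    expect_true(any(unc$uncoupled))
    ch1 <- tr[tr$channel == 1, ]
    ch2u <- tr[tr$channel == 2, ][unc$uncoupled, ]
    for (i in seq_len(nrow(ch2u))) {
      d <- pmax(ch1$start_kbp - ch2u$end_kbp[i],
                ch2u$start_kbp[i] - ch1$end_kbp, 0)
      expect_gt(min(d), 250)
    }
  }
})

test_that("primary cluster segmentation matches a brute-force gap scan", {
  mk <- function(ints, channel = 1L) {
    tibble::tibble(fiber_id = 1L, channel = channel,
                   start_um = kbp_to_um(ints[, 1]),
                   end_um = kbp_to_um(ints[, 2]))
  }
  tr <- mk(rbind(c(0, 90), c(150, 240), c(600, 690)))
  seg <- segment_primary_cluster(tr)
  # gaps 60 and 360: the 360 gap splits; the first two tracks win by span
  expect_equal(seg$cluster, c(0, 240), tolerance = 1e-9)
  expect_equal(nrow(seg$cluster_tracks), 2)
  one <- segment_primary_cluster(mk(rbind(c(100, 190))))
  expect_equal(one$cluster, c(100, 190), tolerance = 1e-9)
  expect_length(one$flanks, 2)
  none <- segment_primary_cluster(mk(rbind(c(0, 50)), channel = 2L))
  expect_null(none$cluster)
})

test_that("classification rules reproduce the three replication classes", {
  mk <- function(ch1, ch2) {
    tibble::tibble(
      fiber_id = 1L,
      channel = c(rep(1L, nrow(ch1)), rep(2L, nrow(ch2))),
      start_um = kbp_to_um(c(ch1[, 1], ch2[, 1])),
      end_um = kbp_to_um(c(ch1[, 2], ch2[, 2]))
    )
  }
  cl <- rbind(c(0, 90), c(150, 240)) # primary cluster
  # single contiguous outgrowing-fork track per flank: extending
  ext <- mk(cl, rbind(c(-120, -90), c(330, 360)))
  expect_equal(classify_fiber(ext), "extending")
  # three separated channel-2 tracks in one flank: secondary activation
  sec <- mk(cl, rbind(c(330, 360), c(400, 430), c(470, 500)))
  expect_equal(classify_fiber(sec), "secondary_activation")
  # a lone channel-2 track 300 kbp from the nearest channel-1 track
  unc <- mk(cl, rbind(c(540, 600)))
  expect_equal(classify_fiber(unc), "uncoupled")
  # channel-2-only fiber is uncoupled by definition
  only2 <- mk(cl[0, , drop = FALSE], rbind(c(0, 60)))
  expect_equal(classify_fiber(only2), "uncoupled")
  # a lone flank track too far out to be the extending fork
  lone_far <- mk(cl, rbind(c(430, 460)))
  expect_equal(classify_fiber(lone_far), "secondary_activation")
})

test_that("noise-free classification matches generator truth across seeds", {
  cfg <- fiber_config(noise_sd_kbp = 0)
  for (s in 1:20) {
    fb <- gen_fibers(cfg, 40, seed = s)
    cls <- classify_fibers(fb)
    expect_identical(cls$class, cls$truth_class)
  }
})

test_that("inter-origin distances recover planted spacings", {
  expect_equal(
    inter_origin_distances(tibble::tibble(
      fiber_id = 1L, channel = 1L,
      start_um = kbp_to_um(c(0, 150)), end_um = kbp_to_um(c(90, 240))
    )),
    150, tolerance = 1e-9
  )
  cfg <- exact_fiber_config(
    spacing_range_kbp = c(100, 250),
    class_mix = c(extending = 1, secondary_activation = 0, uncoupled = 0)
  )
  fb <- gen_fibers(cfg, 20, seed = 9)
  for (f in unique(fb$fiber_id)) {
    tr <- fb[fb$fiber_id == f, ]
    planted <- diff(tr$truth_origins_kbp[[1]])
    got <- inter_origin_distances(tr)
    if (length(planted) == 0) expect_length(got, 0)
    else expect_equal(got, planted, tolerance = 1e-9)
  }
})

test_that("fork-rate estimates follow track length over pulse time", {
  expect_equal(estimate_fork_rate(90, 30)$rate_kbp_per_min, 1.5)
  expect_true(estimate_fork_rate(90, 30)$plausible)
  expect_equal(estimate_fork_rate(30, 20, bidirectional = FALSE)$rate_kbp_per_min,
               1.5)
  slow <- estimate_fork_rate(300, 30)
  expect_equal(slow$rate_kbp_per_min, 5)
  expect_false(slow$plausible)
})

test_that("cohort report summarizes classes, spacings and uncoupling", {
  cfg <- exact_fiber_config(
    spacing_range_kbp = c(100, 250), # wide enough that tracks never merge
    class_mix = c(extending = 1, secondary_activation = 0, uncoupled = 0)
  )
  fb <- gen_fibers(cfg, 30, seed = 10)
  rep0 <- cohort_report(fb)
  expect_equal(rep0$class_summary$proportion, c(1, 0, 0))
  expect_equal(rep0$uncoupled_fiber_fraction, 0)
  expect_equal(sum(rep0$class_summary$proportion), 1)
  # every unmerged noise-free track recovers the 1.5 kbp/min fork rate
  expect_true(all(rep0$fork_rates$plausible))
  expect_equal(rep0$fork_rates$rate_kbp_per_min,
               rep(1.5, nrow(rep0$fork_rates)), tolerance = 1e-9)

  mixed <- gen_fibers(fiber_config(noise_sd_kbp = 0), 400, seed = 11)
  repm <- cohort_report(mixed)
  expect_equal(sum(repm$class_summary$proportion), 1)
  # reported spacing ordering mirrors the generator: extending clusters have
  # wider origin spacing than secondary-activation clusters
  io <- repm$inter_origin
  expect_gt(io$mean_kbp[io$class == "extending"],
            io$mean_kbp[io$class == "secondary_activation"])
  td <- tidy(repm)
  expect_equal(nrow(td), 3)
  gl <- glance(repm)
  expect_equal(gl$n_fibers, repm$n_fibers)

  # a fiber without classifiable labeling gets NA and is excluded
  expect_true(is.na(classify_fiber(tibble::tibble(
    fiber_id = integer(0), channel = integer(0),
    start_um = numeric(0), end_um = numeric(0)
  ))))
})

test_that("short fibers are excluded by the 0.8 Mbp filter", {
  short <- tibble::tibble(
    fiber_id = c(1L, 1L), channel = c(1L, 2L),
    start_um = kbp_to_um(c(0, 150)), end_um = kbp_to_um(c(90, 180))
  )
  rep1 <- cohort_report(short)
  expect_equal(rep1$n_fibers, 0)
  expect_equal(rep1$n_excluded, 1)
  rep2 <- cohort_report(short, fiber_params(min_fiber_kbp = 0))
  expect_equal(rep2$n_fibers, 1)
})
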
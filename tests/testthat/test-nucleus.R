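test_that("generated foci counts and containment hold for every model", {
  cfg <- small_nucleus(foci_per_zone = 30, n_zones = 4)
  for (model in c("genetic", "spatial", "random")) {
    fs <- gen_nuclear_foci(cfg, model = model, seed = 11, n_chains = 6)
    expect_equal(nrow(fs), 120)
    expect_equal(unname(c(table(fs$zone))), rep(30L, 4))
    r <- sqrt(fs$x_nm^2 + fs$y_nm^2 + fs$z_nm^2) + fs$diameter_nm / 2
    expect_true(all(r <= cfg$nucleus_diameter_um * 1000 / 2 + 1e-9))
    expect_false(any(duplicated(fs[c("chain_id", "chain_pos")])))
  }
})

test_that("zero zones give an empty foci set", {
  fs <- gen_nuclear_foci(nucleus_config(n_zones = 0), seed = 1)
  expect_s3_class(fs, "foci_set")
  expect_equal(nrow(fs), 0)
})

test_that("generation is bit-for-bit reproducible for a fixed seed", {
  for (model in c("genetic", "spatial", "random")) {
    a <- gen_nuclear_foci(small_nucleus(), model = model, seed = 99)
    b <- gen_nuclear_foci(small_nucleus(), model = model, seed = 99)
    expect_identical(as.data.frame(a), as.data.frame(b))
  }
})

test_that("genetic chains have consecutive-zone foci chain-adjacent", {
  # exhaustive traversal: every zone-z focus must have a zone-(z+1) focus
  # within one chain step, and the last zone-z focus of each chain must be
  # followed directly by a zone-(z+1) focus
  fs <- gen_nuclear_foci(small_nucleus(foci_per_zone = 5, n_zones = 2),
                         model = "genetic", seed = 3, n_chains = 2)
  for (i in seq_len(nrow(fs))) {
    if (fs$zone[i] == 2) next
    nbr <- fs[fs$chain_id == fs$chain_id[i] &
                abs(fs$chain_pos - fs$chain_pos[i]) <= 2 & fs$zone == 2, ]
    expect_gt(nrow(nbr), 0)
  }
  last_z1 <- do.call(rbind, lapply(split(fs, fs$chain_id), function(ch) {
    z1 <- ch[ch$zone == 1, ]
    z1[which.max(z1$chain_pos), ]
  }))
  for (j in seq_len(nrow(last_z1))) {
    succ <- fs[fs$chain_id == last_z1$chain_id[j] &
                 fs$chain_pos == last_z1$chain_pos[j] + 1, ]
    expect_equal(succ$zone, 2L)
  }
})

test_that("genetic chain steps equal the focus diameter away from the wall", {
  fs <- gen_nuclear_foci(small_nucleus(foci_per_zone = 40, n_zones = 2),
                         model = "genetic", seed = 5, n_chains = 4)
  seps <- adjacent_separations(fs)
  # reflection at the boundary may shorten a step; never lengthen it
  expect_true(all(seps <= 500 + 1e-6))
  expect_gt(mean(abs(seps - 500) < 1e-6), 0.9)
})

test_that("random model zone labels are independent of chain structure", {
  fs <- gen_nuclear_foci(small_nucleus(foci_per_zone = 200, n_zones = 2),
                         model = "random", seed = 8)
  # within-chain zone runs should look like coin flips, not blocks
  tab <- table(fs$zone, fs$chain_id)
  expect_gt(suppressWarnings(chisq.test(tab))$p.value, 1e-4)
})

test_that("segregation keeps exactly the requested number of chains", {
  fs <- gen_nuclear_foci(nucleus_config(foci_per_zone = 46, n_zones = 2),
                         model = "genetic", seed = 2, n_chains = 46)
  kept <- apply_segregation(fs, 3, seed = 4)
  expect_equal(length(unique(kept$chain_id)), 3)
  expect_true(all(kept$id %in% fs$id))
  expect_identical(as.data.frame(apply_segregation(fs, 46, seed = 1)),
                   as.data.frame(fs))
  empty <- apply_segregation(fs, 0, seed = 1)
  expect_equal(nrow(empty), 0)
  expect_error(apply_segregation(fs, 47, seed = 1), "exceeds")
})

test_that("plasticity with zero sd is the identity", {
  fs <- gen_nuclear_foci(small_nucleus(), model = "genetic", seed = 6)
  expect_identical(as.data.frame(apply_plasticity(fs, 0, seed = 1)),
                   as.data.frame(fs))
})

test_that("plasticity preserves genetic chain connectivity within 1.5x", {
  for (s in 1:5) {
    fs <- gen_nuclear_foci(small_nucleus(foci_per_zone = 30, n_zones = 3),
                           model = "genetic", seed = s, n_chains = 3)
    moved <- apply_plasticity(fs, 300, seed = s + 100)
    ratio <- adjacent_separations(moved) / adjacent_separations(fs)
    expect_true(all(ratio <= 1.5 + 1e-9))
    r <- sqrt(moved$x_nm^2 + moved$y_nm^2 + moved$z_nm^2) +
      moved$diameter_nm / 2
    expect_true(all(r <= 5000 + 1e-6))
  }
})

test_that("random-model plasticity displacement follows the 3D Gaussian norm", {
  # mean of |N(0, sd^2 I3)| is sd * sqrt(8/pi); checked on interior foci
  # (the nuclear-boundary projection only shrinks boundary displacements)
  fs <- gen_nuclear_foci(nucleus_config(foci_per_zone = 1000, n_zones = 2),
                         model = "random", seed = 3)
  moved <- apply_plasticity(fs, 300, seed = 21)
  disp <- sqrt((moved$x_nm - fs$x_nm)^2 + (moved$y_nm - fs$y_nm)^2 +
                 (moved$z_nm - fs$z_nm)^2)
  interior <- sqrt(fs$x_nm^2 + fs$y_nm^2 + fs$z_nm^2) < 4750 - 4 * 300
  expect_gt(sum(interior), 300)
  expect_equal(mean(disp[interior]), 300 * sqrt(8 / pi), tolerance = 0.05)
})

test_that("impossible geometries are rejected", {
  expect_error(nucleus_config(nucleus_diameter_um = 0.4,
                              focus_diameter_nm = 500),
               "smaller than the nucleus")
  expect_error(nucleus_config(nucleus_diameter_um = -1), "positive")
  # a focus exactly as large as the nucleus leaves no room for its centre
  broken <- structure(list(nucleus_diameter_um = 0.5, focus_diameter_nm = 500,
                           foci_per_zone = 10L, n_zones = 1L,
                           zone_duration_h = 1),
                      class = "nucleus_config")
  expect_error(gen_nuclear_foci(broken, "random", seed = 1), "fit")
})
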
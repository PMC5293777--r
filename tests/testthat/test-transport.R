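# Transport mapping: background normalization, profiles, map assembly and the
# percent-intact statistic.

test_that("normalize_background subtracts the background estimate", {
  # constant image equal to the background mean -> all-zero output
  img <- section_image(list(CTB = matrix(7, 10, 10)))
  bg <- matrix(FALSE, 10, 10); bg[, 1:3] <- TRUE
  out <- normalize_background(img, bg)
  expect_equal(get_channel(out, "CTB"), matrix(0, 10, 10))
  expect_equal(out$metadata$background_estimate, 7)

  # zero background: identity
  m <- matrix(c(rep(0, 50), rep(100, 50)), 10, 10)
  img2 <- section_image(list(CTB = m))
  out2 <- normalize_background(img2, m == 0)
  expect_equal(get_channel(out2, "CTB"), m)

  # arithmetic oracle: offset 100, signal 1000 -> signal pixels ~900
  spec <- sc_spec(seed = 3, noise_sd = 0)
  ser <- generate_sc_series(spec, 0)
  out3 <- normalize_background(ser$sections[[4]], !ser$masks[[4]])
  sig <- get_channel(out3, "CTB")[ser$masks[[4]]]
  expect_equal(unique(sig), 900)

  expect_error(normalize_background(img, matrix(TRUE, 10, 10)), "entire image")
  expect_error(normalize_background(img, matrix(FALSE, 10, 10)), "empty")
})

test_that("extract_section_profile computes per-bin masked means", {
  # uniform intensity over mask -> flat profile
  m <- matrix(3.5, 20, 40)
  img <- section_image(list(CTB = m))
  mask <- matrix(TRUE, 20, 40)
  expect_equal(unique(extract_section_profile(img, mask, 8)), 3.5)
  expect_equal(extract_section_profile(img, mask, 2), c(3.5, 3.5))

  # step image: exhaustively computed per-bin means
  step <- cbind(matrix(1, 20, 20), matrix(0, 20, 20))
  img2 <- section_image(list(CTB = step))
  prof <- extract_section_profile(img2, mask, 10)
  oracle <- vapply(1:10, function(b) {
    cols <- which(ceiling(seq_len(40) / 40 * 10) == b)
    mean(step[, cols])
  }, 0)
  expect_equal(prof, oracle)
  expect_equal(prof, c(rep(1, 5), rep(0, 5)))

  # bins with no mask pixels are NA
  half <- mask; half[, 21:40] <- FALSE
  prof2 <- extract_section_profile(img2, half, 10)
  expect_true(all(is.na(prof2[6:10])) && all(prof2[1:5] == 1))

  expect_error(extract_section_profile(img2, mask & FALSE, 10), "empty SC mask")
  expect_error(extract_section_profile(img2, mask, 1), "n_samples")
})

test_that("assemble_retinotopic_map stacks, interpolates and normalizes", {
  # single profile -> one-row map, density = profile / max
  m <- assemble_retinotopic_map(c(2, 4, 1), grid_resolution = 3,
                                reference = "max")
  expect_equal(dim(m$density), c(1L, 3L))
  expect_equal(m$density[1, ], c(0.5, 1, 0.25))

  # identical profiles -> columns constant along the rostrocaudal axis
  p <- c(1, 3, 2, 4)
  m2 <- assemble_retinotopic_map(replicate(5, p, simplify = FALSE),
                                 grid_resolution = 20, reference = "max")
  expect_true(all(apply(m2$density, 2, function(col) diff(range(col)) < 1e-12)))

  # at least one valid cell attains 1.0 and all are within [0, 1]
  expect_equal(max(m2$density[m2$valid_mask]), 1)
  expect_true(all(m2$density[m2$valid_mask] >= 0 &
                  m2$density[m2$valid_mask] <= 1))

  expect_error(assemble_retinotopic_map(list(1:3, 1:4)), "inconsistent")
})

test_that("percent_intact_transport matches its defining count", {
  # uniform map -> 100%
  u <- assemble_retinotopic_map(replicate(3, rep(2, 5), simplify = FALSE),
                                grid_resolution = 10, reference = "max")
  expect_equal(percent_intact_transport(u)$percent_intact, 100)

  # direct-count oracle: 40% of cells at 1.0, 60% at 0.5
  prof <- c(rep(1, 4), rep(0.5, 6))
  m <- assemble_retinotopic_map(replicate(2, prof, simplify = FALSE),
                                grid_resolution = 10, reference = "max")
  expect_equal(percent_intact_transport(m, 0.70)$percent_intact, 40)
  # threshold tie counts as intact
  expect_equal(percent_intact_transport(m, 0.5)$percent_intact, 100)

  expect_error(percent_intact_transport(m, 0), "threshold")
})

test_that("percent_intact is monotone in threshold and scale invariant", {
  set.seed(42)
  for (i in 1:20) {
    profs <- replicate(4, runif(12), simplify = FALSE)
    m <- assemble_retinotopic_map(profs, grid_resolution = 30)
    ths <- sort(runif(5, 0.05, 1))
    pis <- vapply(ths, function(t) {
      percent_intact_transport(m, t)$percent_intact
    }, 0)
    expect_true(all(diff(pis) <= 1e-9))
    # scale invariance of the full statistic
    k <- runif(1, 0.5, 10)
    m2 <- assemble_retinotopic_map(lapply(profs, `*`, k), grid_resolution = 30)
    expect_equal(percent_intact_transport(m2)$percent_intact,
                 percent_intact_transport(m)$percent_intact)
  }
})

test_that("pipeline recovers generator deficits and the healthy-map range", {
  for (f in c(0, 0.2, 0.4, 0.6)) {
    out <- generate_sc_series(sc_spec(seed = 20 + round(100 * f)), f)
    tr <- transport_from_sections(out$sections, out$masks)
    expect_lt(abs(tr$percent_intact - 100 * (1 - f)), 3)
  }
  # healthy default spec: >= 85% intact, the saline-eye magnitude
  healthy <- generate_sc_series(sc_spec(seed = 31), 0.05)
  expect_gte(transport_from_sections(healthy$sections, healthy$masks)$percent_intact, 85)
})
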
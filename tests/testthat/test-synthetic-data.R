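# Synthetic generators: determinism, truth recomputability, contracts.

test_that("generate_sc_series renders the requested deficit and is deterministic", {
  # identity case: no deficit -> all bright
  out0 <- generate_sc_series(sc_spec(seed = 2), 0)
  expect_equal(out0$truth$deficit_fraction, 0)
  expect_equal(oracle_dim_fraction(out0), 0)

  # brute-force pixel-count oracle at f = 0.4
  out <- generate_sc_series(sc_spec(seed = 7), 0.4)
  expect_equal(out$truth$deficit_fraction, oracle_dim_fraction(out),
               tolerance = 1e-12)
  expect_lt(abs(out$truth$deficit_fraction - 0.4), 0.01)

  # determinism: same spec + seed twice -> bit-identical images
  again <- generate_sc_series(sc_spec(seed = 7), 0.4)
  expect_identical(image_hashes(out), image_hashes(again))

  # different seed moves the wedge but not the truth distribution
  # other seeds move the wedge; discretization keeps the realized fraction
  # within ~2 boundary columns of the request at this resolution
  other <- generate_sc_series(sc_spec(seed = 8), 0.4)
  expect_false(identical(image_hashes(out), image_hashes(other)))
  expect_lt(abs(other$truth$deficit_fraction - 0.4), 0.02)

  expect_error(generate_sc_series(sc_spec(), 1.2), "\\[0, 1\\]")
  expect_error(generate_sc_series(sc_spec(), -0.1), "\\[0, 1\\]")
})

test_that("noise changes realizations but never the ground truth", {
  quiet <- generate_sc_series(sc_spec(seed = 5, noise_sd = 0), 0.3)
  loud <- generate_sc_series(sc_spec(seed = 5, noise_sd = 25), 0.3)
  expect_identical(quiet$truth$deficit_fraction, loud$truth$deficit_fraction)
  expect_false(identical(image_hashes(quiet), image_hashes(loud)))
})

test_that("generate_ihc_image hits the requested positive-area fraction", {
  spec <- synthetic_spec(image_size = c(100, 100), seed = 3)
  # exact pixel-count oracle on the rendered image: pixels above the
  # generator threshold
  for (f in c(0, 0.1234, 1)) {
    g <- generate_ihc_image(spec, f)
    img <- get_channel(g$image, "IBA1")
    n_pos <- sum(img > g$truth$threshold)
    expect_equal(n_pos, round(f * 1e4))
    expect_equal(g$truth$positive_area_fraction, n_pos / 1e4)
  }
  expect_error(generate_ihc_image(spec, 1.5), "\\[0, 1\\]")
})

test_that("generate_nuclei_image renders the stated nuclear partition", {
  # blank case
  g0 <- generate_nuclei_image(cell_spec(noise_sd = 0), 0, 0.5)
  expect_equal(max(get_channel(g0$image, "DAPI")), 10)

  # all-signal-in-nucleus case, noise-free: recomputed fraction exactly 1
  g1 <- generate_nuclei_image(cell_spec(seed = 4, noise_sd = 0), 5, 1)
  expect_equal(unname(oracle_nuclear_fractions(g1)), rep(1, 5))

  # masked-mean oracle at f = 0.8 under default noise
  g <- generate_nuclei_image(cell_spec(seed = 3), 20, 0.8)
  fr <- oracle_nuclear_fractions(g)
  expect_equal(mean(fr), 0.8, tolerance = 0.02)

  # infeasible packing is rejected with a message
  tiny <- synthetic_spec(image_size = c(32, 32), cell_radius = 6, seed = 1)
  expect_error(generate_nuclei_image(tiny, 50, 0.5), "non-overlapping")
})

test_that("generate_retina_section geometry and bookkeeping are exact", {
  ret <- generate_retina_section(retina_spec(seed = 5), 130, 16.8, 33.6,
                                 rgc_count = 12, n_distractors = 3)
  # boundary rows 130 px apart at 1 um/px (flat layers)
  expect_equal(ret$boundaries$rpe$y[1] - ret$boundaries$ilm$y[1], 130)
  expect_equal(unname(ret$truth$layer_boundaries["rpe"]), 130)
  expect_equal(ret$truth$rgc_count, 12L)
  # brute-force object count: distinct bright CTB blobs in the GCL
  ctb <- get_channel(ret$image, "CTB")
  lab <- label_components(ctb > 100 & ret$gcl_roi)
  expect_equal(attr(lab, "n"), 12L)

  # tilt preserves perpendicular separation analytically
  t10 <- generate_retina_section(retina_spec(seed = 5), 130, 16.8, 33.6,
                                 rgc_count = 0, tilt_deg = 10)
  dy <- t10$boundaries$rpe$y[1] - t10$boundaries$ilm$y[1]
  expect_equal(dy * cos(10 * pi / 180), 130, tolerance = 1e-9)

  expect_error(generate_retina_section(retina_spec(), 100, 60, 50),
               "smaller than")
})

test_that("generate_iop_series is calibrated and handles degenerate noise", {
  # noise-free arithmetic: 20 * 1.327 = 26.54 exactly
  s <- generate_iop_series(synthetic_spec(seed = 1), baseline_mmHg = 20,
                           elevation_fraction = 0.327, n_days = 5,
                           animal_sd = 0, measure_sd = 0)
  mb_post <- s$iop_mmHg[s$eye == "MICROBEAD" & s$day >= 1]
  expect_equal(unique(mb_post), 26.54)
  sal <- s$iop_mmHg[s$eye == "SALINE"]
  expect_equal(unique(sal), 20)

  # defaults calibrated to ~20 / ~26 mmHg over a large cohort
  big <- generate_iop_series(synthetic_spec(seed = 9),
                             animal_ids = sprintf("A%03d", 1:300))
  post <- big[big$day >= 1, ]
  m_sal <- mean(post$iop_mmHg[post$eye == "SALINE"])
  m_mb <- mean(post$iop_mmHg[post$eye == "MICROBEAD"])
  expect_lt(abs(m_sal - 20.12), 1)
  expect_lt(abs(m_mb - 26.69), 1)

  # null elevation: the two eyes are statistically indistinguishable
  null <- generate_iop_series(synthetic_spec(seed = 11), elevation_fraction = 0,
                              animal_ids = sprintf("A%02d", 1:30))
  post <- null[null$day >= 1, ]
  pa <- stats::aggregate(iop_mmHg ~ animal_id + eye, post, mean)
  p <- stats::t.test(iop_mmHg ~ eye, pa)$p.value
  expect_gt(p, 0.05)

  expect_error(generate_iop_series(synthetic_spec(), n_days = 0), "n_days")
})

test_that("text image round trip preserves pixels and metadata", {
  g <- generate_ihc_image(synthetic_spec(image_size = c(24, 24), seed = 2), 0.2)
  pfx <- file.path(withr::local_tempdir(), "img")
  write_section_image(g$image, pfx)
  back <- read_section_image(pfx)
  expect_equal(back$channels, g$image$channels, tolerance = 1e-12)
  expect_identical(back$tissue, g$image$tissue)
  expect_identical(back$pixel_size, g$image$pixel_size)
})
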
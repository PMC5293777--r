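# DAPI-gated nucleus segmentation and NF-kB nuclear-localization scoring.

test_that("segment_nuclei finds generated nuclei and splits touching pairs", {
  # blank image -> 0 nuclei, no error
  blank <- matrix(5, 40, 40)
  expect_equal(segment_nuclei(blank)$n_nuclei, 0)

  # k disks -> k labels with centroids within 1 px of truth
  g <- generate_nuclei_image(cell_spec(seed = 3), 12, 0.5)
  seg <- segment_nuclei(get_channel(g$image, "DAPI"))
  expect_equal(seg$n_nuclei, 12)
  truth <- g$truth$centres[order(g$truth$centres[, 1], g$truth$centres[, 2]), ]
  found <- as.matrix(seg$nuclei[order(seg$nuclei$centroid_r,
                                      seg$nuclei$centroid_c),
                                c("centroid_r", "centroid_c")])
  expect_true(all(sqrt(rowSums((truth - found)^2)) <= 1))

  # two touching disks are split by the watershed
  m <- matrix(0, 40, 60)
  mk <- function(cr, cc, r) {
    rows <- matrix(seq_len(40), 40, 60)
    cols <- matrix(seq_len(60), 40, 60, byrow = TRUE)
    (rows - cr)^2 + (cols - cc)^2 <= r^2
  }
  m[mk(20, 22, 8) | mk(20, 37, 8)] <- 200 # centres 15 px apart, radius 8
  seg2 <- segment_nuclei(m, min_area = 20)
  expect_equal(seg2$n_nuclei, 2)
})

test_that("nuclear_signal_fraction recovers the generator partition", {
  # trivial extremes, noise-free
  g1 <- generate_nuclei_image(cell_spec(seed = 4, noise_sd = 0), 6, 1)
  seg1 <- segment_nuclei(get_channel(g1$image, "DAPI"))
  r1 <- nuclear_signal_fraction(get_channel(g1$image, "NFKB"), seg1)
  expect_equal(r1$score, 1, tolerance = 1e-6)

  # uniform signal everywhere -> fraction 0.5 per cell
  uni <- matrix(80, 128, 128)
  r05 <- nuclear_signal_fraction(uni, seg1)
  expect_equal(unique(round(r05$records$nuclear_fraction, 10)), 0.5)

  # masked-mean oracle at nuclear mean 80 / cytoplasm 20 (f = 0.8)
  g <- generate_nuclei_image(cell_spec(seed = 3), 15, 0.8, total_level = 100)
  seg <- segment_nuclei(get_channel(g$image, "DAPI"))
  r <- nuclear_signal_fraction(get_channel(g$image, "NFKB"), seg)
  expect_equal(r$score, 0.8, tolerance = 0.02)
  expect_equal(r$score, mean(oracle_nuclear_fractions(g)), tolerance = 0.02)

  # recovery across the stated fractions at default noise
  for (f in c(0.3, 0.5, 0.8)) {
    gg <- generate_nuclei_image(cell_spec(seed = 17), 15, f)
    sg <- segment_nuclei(get_channel(gg$image, "DAPI"))
    rr <- nuclear_signal_fraction(get_channel(gg$image, "NFKB"), sg)
    expect_lt(abs(rr$score - f), 0.05)
  }
})

test_that("offsets pull fractions toward 0.5, so normalization must precede", {
  g <- generate_nuclei_image(cell_spec(seed = 8, noise_sd = 0), 10, 0.8)
  seg <- segment_nuclei(get_channel(g$image, "DAPI"))
  sig <- get_channel(g$image, "NFKB")
  base <- nuclear_signal_fraction(sig, seg)$records$nuclear_fraction
  shifted <- nuclear_signal_fraction(sig + 50, seg)$records$nuclear_fraction
  expect_true(all(abs(shifted - 0.5) < abs(base - 0.5)))
})

test_that("label permutation leaves the image score unchanged", {
  g <- generate_nuclei_image(cell_spec(seed = 12), 8, 0.6)
  seg <- segment_nuclei(get_channel(g$image, "DAPI"))
  sig <- get_channel(g$image, "NFKB")
  s1 <- nuclear_signal_fraction(sig, seg)$score
  # permute label ids
  perm <- sample(seq_len(seg$n_nuclei))
  lab2 <- seg$labels
  lab2[seg$labels > 0L] <- perm[seg$labels[seg$labels > 0L]]
  attr(lab2, "n") <- seg$n_nuclei
  s2 <- nuclear_signal_fraction(sig, lab2)$score
  expect_equal(s1, s2)
})

test_that("co-label classification and ratio analysis work on scores", {
  g <- generate_nuclei_image(cell_spec(seed = 5, noise_sd = 0), 5, 0.7)
  seg <- segment_nuclei(get_channel(g$image, "DAPI"))
  co <- matrix(100, 128, 128) # everything co-labeled
  r <- nuclear_signal_fraction(get_channel(g$image, "NFKB"), seg,
                               colabels = list(GFAP = co))
  expect_true(all(r$records$GFAP_positive))

  # arithmetic ratio; zero-saline exclusion
  rr <- nuclear_ratio_analysis(data.frame(microbead = 0.6, saline = 0.4))
  expect_equal(rr$records$ratio, 1.5)
  expect_warning(nuclear_ratio_analysis(data.frame(microbead = c(0.6, 0.5),
                                                   saline = c(0, 0.5))),
                 "zero saline")
})
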
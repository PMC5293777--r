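# Immunolabel thresholding, percent area and microbead:saline ratios.

test_that("threshold_positive_label handles fixed and Otsu modes", {
  z <- matrix(0, 20, 20)
  expect_equal(sum(threshold_positive_label(z, method = "fixed", threshold = 1)), 0)

  # bimodal image: Otsu separates the modes; exhaustive count oracle
  g <- generate_ihc_image(synthetic_spec(image_size = c(80, 80), seed = 5), 0.25)
  img <- get_channel(g$image, "IBA1")
  mask <- threshold_positive_label(img, method = "otsu")
  expect_lt(abs(sum(mask) - sum(g$truth$positive_mask)) / length(img), 0.01)

  # pooled pair shares one threshold
  g2 <- generate_ihc_image(synthetic_spec(image_size = c(80, 80), seed = 6), 0.5)
  m1 <- threshold_positive_label(img, method = "otsu",
                                 pooled_with = get_channel(g2$image, "IBA1"))
  m2 <- threshold_positive_label(get_channel(g2$image, "IBA1"), method = "otsu",
                                 pooled_with = img)
  expect_equal(attr(m1, "threshold"), attr(m2, "threshold"))

  # fixed threshold above max -> empty; constant image falls back with warning
  expect_equal(sum(threshold_positive_label(img, method = "fixed",
                                            threshold = max(img) + 1)), 0)
  expect_warning(
    mk <- threshold_positive_label(matrix(5, 10, 10), method = "otsu",
                                   threshold = 10),
    "constant")
  expect_equal(sum(mk), 0)
})

test_that("percent_area_positive is an exact pixel count ratio", {
  roi <- matrix(TRUE, 100, 100)
  empty <- roi & FALSE
  expect_equal(percent_area_positive(empty, roi)$percent_area, 0)
  expect_equal(percent_area_positive(roi, roi)$percent_area, 100)
  m <- empty; m[seq_len(1234)] <- TRUE
  expect_equal(percent_area_positive(m, roi)$percent_area, 12.34)
  out <- m; out[1, 1] <- TRUE
  roi2 <- roi; roi2[1, 1] <- FALSE
  expect_error(percent_area_positive(out, roi2), "subset")
  expect_error(percent_area_positive(empty, roi & FALSE), "empty")
})

test_that("percent-area recovery from the generator is within 2 pp", {
  for (f in c(0.05, 0.1, 0.25, 0.5)) {
    g <- generate_ihc_image(synthetic_spec(image_size = c(96, 96),
                                           seed = round(1000 * f)), f)
    mask <- threshold_positive_label(g$image, method = "fixed",
                                     threshold = g$truth$threshold)
    est <- percent_area_positive(mask, g$roi)$percent_area
    expect_lt(abs(est - 100 * g$truth$positive_area_fraction), 2)
  }
})

test_that("microbead_saline_ratio aggregates images -> animal -> group", {
  # hand-arithmetic oracle
  r <- microbead_saline_ratio(data.frame(microbead = c(4, 2), saline = c(2, 2)))
  expect_equal(r$records$ratio, c(2, 1))
  expect_equal(r$summary$mean_ratio, 1.5)
  expect_equal(r$summary$sem, 0.5)

  # identical eyes -> ratio exactly 1, SEM 0
  same <- data.frame(animal_id = rep(c("a", "b", "c"), each = 2),
                     eye = rep(c("SALINE", "MICROBEAD"), 3),
                     value = rep(c(3.3, 3.3), 3))
  r2 <- microbead_saline_ratio(same)
  expect_equal(r2$summary$mean_ratio, 1)
  expect_equal(r2$summary$sem, 0)

  # image -> animal averaging precedes the ratio
  long <- data.frame(animal_id = c("a", "a", "a"),
                     eye = c("SALINE", "SALINE", "MICROBEAD"),
                     value = c(1, 3, 4))
  r3 <- microbead_saline_ratio(rbind(long,
    data.frame(animal_id = "b", eye = c("SALINE", "MICROBEAD"), value = c(2, 2))))
  expect_equal(r3$records$ratio[r3$records$animal_id == "a"], 2) # 4 / mean(1,3)

  # zero saline -> animal excluded, n decremented, warning raised
  expect_warning(
    r4 <- microbead_saline_ratio(data.frame(microbead = c(4, 2),
                                            saline = c(0, 2))),
    "zero saline")
  expect_equal(r4$summary$n, 1)
  expect_true(r4$records$excluded[1])
})

test_that("ratio properties: identical pair gives 1, swap inverts", {
  g <- generate_ihc_image(synthetic_spec(image_size = c(64, 64), seed = 9), 0.3)
  mask <- threshold_positive_label(g$image, method = "fixed",
                                   threshold = g$truth$threshold)
  pct <- percent_area_positive(mask, g$roi)$percent_area
  # microbead identical to saline pixel-for-pixel
  r <- microbead_saline_ratio(data.frame(microbead = pct, saline = pct,
                                         animal_id = "a"))
  expect_identical(r$records$ratio, 1)
  # swapping eye labels maps r -> 1/r
  a <- 6.1; b <- 2.5
  r1 <- microbead_saline_ratio(data.frame(microbead = a, saline = b))
  r2 <- microbead_saline_ratio(data.frame(microbead = b, saline = a))
  expect_equal(r1$records$ratio * r2$records$ratio, 1)
})
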
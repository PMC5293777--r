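# Immunohistochemistry fields with a controlled positive-label area fraction.
#
# A Gaussian-correlated random field is thresholded at its empirical quantile
# so that exactly round(fraction * n_roi) pixels carry the high label
# intensity; the rest carry the low intensity. The generator-known positivity
# threshold is the midpoint of the two levels, and the additive noise default
# is small enough that no pixel crosses it, keeping the truth exact up to the
# stated +/-1% tolerance even under noise.

#' Generate an immunolabel image with a known positive-area fraction
#'
#' @param spec A [synthetic_spec()].
#' @param positive_area_fraction Requested fraction of ROI pixels above the
#'   generator threshold, in `[0, 1]`.
#' @param marker Channel name recorded on the image (e.g. `"IBA1"`, `"BDNF"`).
#' @param tissue,eye,animal_id Metadata.
#' @param blob_sigma Spatial correlation length (px) of the label field.
#' @param stream Extra sub-seed offset so several images drawn from one spec
#'   differ while remaining reproducible.
#' @return A list with `image` (a `section_image`), `roi` (logical matrix, here
#'   the full frame), and `truth` (a [ground_truth()] carrying the realized
#'   fraction, the positive mask and the generator threshold).
#' @export
generate_ihc_image <- function(spec, positive_area_fraction, marker = "IBA1",
                               tissue = "SC", eye = "SALINE", animal_id = "A1",
                               blob_sigma = 2.5, stream = 0L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  f <- positive_area_fraction
  if (!is.numeric(f) || length(f) != 1 || is.na(f) || f < 0 || f > 1) {
    stopf("`positive_area_fraction` must be a single number in [0, 1]")
  }
  nr <- spec$image_size[1]; nc <- spec$image_size[2]
  roi <- matrix(TRUE, nr, nc)
  k <- round(f * sum(roi))

  field <- with_seed(derive_seed(spec$seed, 300L + stream),
                     matrix(stats::rnorm(nr * nc), nr, nc))
  field <- gaussian_blur(field, blob_sigma)
  pos <- matrix(FALSE, nr, nc)
  if (k > 0) pos[order(field, decreasing = TRUE)[seq_len(k)]] <- TRUE

  img <- matrix(spec$label_low, nr, nc)
  img[pos] <- spec$label_high
  img <- with_seed(derive_seed(spec$seed, 350L + stream),
                   add_noise(img, spec$noise_sd))
  channels <- list(img)
  names(channels) <- marker
  truth <- ground_truth(
    positive_area_fraction = k / sum(roi),
    positive_area_fraction_requested = f,
    positive_mask = pos,
    threshold = (spec$label_low + spec$label_high) / 2
  )
  list(
    image = section_image(channels, pixel_size = spec$pixel_size,
                          tissue = tissue, eye = eye, animal_id = animal_id,
                          metadata = list(marker = marker)),
    roi = roi,
    truth = truth
  )
}
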
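# Synthetic-data specification and ground-truth containers.

#' Specification for the synthetic image generators
#'
#' Collects every tunable of the synthetic cohort in one validated object. The
#' same spec plus the same seed always yields bit-identical images; all
#' randomness flows from `seed` through per-object derived sub-seeds.
#'
#' Intensity defaults describe a clean epifluorescence field: constant
#' background offset plus additive Gaussian noise. The tracer signal sits well
#' above background (bright level 1000 vs offset 100) and transport deficits
#' render at 30% of the bright level, below the 70% intact-transport
#' threshold by construction.
#'
#' @param image_size `c(rows, cols)` in pixels.
#' @param n_sections Number of serial SC sections (>= 1).
#' @param pixel_size Micrometres per pixel.
#' @param background Constant background offset (intensity units).
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @param bright_level CTB intensity where transport is intact.
#' @param dim_level_frac Deficit intensity as a fraction of `bright_level`.
#' @param sector_start_deg Angular position (degrees) where a deficit sector
#'   begins in the flattened map; `NULL` draws it from the seed.
#' @param label_low,label_high Intensities of negative/positive immunolabel.
#' @param cell_radius Nucleus radius in pixels for cell-field generators.
#' @param annulus_width Perinuclear annulus width (px) the generators reserve
#'   around each nucleus when enforcing non-overlap.
#' @param seed Master integer seed.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(image_size = c(96, 96), n_sections = 8,
                           pixel_size = 10, background = 100, noise_sd = 5,
                           bright_level = 1000, dim_level_frac = 0.3,
                           sector_start_deg = NULL,
                           label_low = 50, label_high = 200,
                           cell_radius = 6, annulus_width = 3, seed = 1) {
  if (length(image_size) != 2 || any(image_size < 8)) {
    stopf("`image_size` must be c(rows, cols) with both >= 8")
  }
  if (n_sections < 1) stopf("`n_sections` must be >= 1")
  if (noise_sd < 0) stopf("`noise_sd` must be >= 0")
  if (bright_level <= background) stopf("`bright_level` must exceed `background`")
  if (dim_level_frac < 0 || dim_level_frac > 1) stopf("`dim_level_frac` in [0,1]")
  if (label_high <= label_low) stopf("`label_high` must exceed `label_low`")
  if (abs(seed) >= 2^31 - 1) stopf("`seed` must fit a 32-bit integer")
  structure(
    list(image_size = as.integer(image_size), n_sections = as.integer(n_sections),
         pixel_size = pixel_size, background = background, noise_sd = noise_sd,
         bright_level = bright_level, dim_level_frac = dim_level_frac,
         sector_start_deg = sector_start_deg,
         label_low = label_low, label_high = label_high,
         cell_radius = cell_radius, annulus_width = annulus_width,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf("<synthetic_spec> %dx%d px, %d sections, noise sd %.3g, seed %d\n",
              x$image_size[1], x$image_size[2], x$n_sections, x$noise_sd, x$seed))
  invisible(x)
}

#' Ground truth emitted alongside each synthetic object
#'
#' Generator-side truth used by recovery tests. Every field is recomputable
#' from the rendered image by an independent brute-force computation.
#'
#' @param ... Named truth fields (e.g. `deficit_fraction`,
#'   `positive_area_fraction`, `nuclear_fraction_per_cell`,
#'   `layer_boundaries`, `rgc_count`).
#' @return An object of class `ground_truth` (a named list).
#' @export
ground_truth <- function(...) {
  gt <- list(...)
  if (!is.null(gt$layer_boundaries) &&
      is.unsorted(gt$layer_boundaries, strictly = TRUE)) {
    stopf("layer boundaries must be strictly increasing with depth")
  }
  structure(gt, class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth>", paste(names(x), collapse = ", "), "\n")
  invisible(x)
}

#' Clamp intensities to be non-negative after adding noise
#' @keywords internal
#' @noRd
add_noise <- function(m, noise_sd) {
  if (noise_sd > 0) m <- m + matrix(stats::rnorm(length(m), 0, noise_sd),
                                    nrow(m), ncol(m))
  pmax(m, 0)
}
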
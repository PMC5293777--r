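# Serial superior-colliculus sections with sector-shaped transport deficits.
#
# The flattened retinotopic surface is modelled as a disc. A transport deficit
# is an angular wedge of that disc: deficits observed after ocular hypertension
# fill in complete retinotopic sectors, so a wedge whose angular extent equals
# the requested area fraction is the stated geometry. Each coronal section is
# a chord of the disc at one rostrocaudal position; within a section the SC
# appears as a horizontal band whose mediolateral extent is the chord, bright
# where transport is intact and dim (dim_level_frac * bright) inside the wedge.

#' Generate a serial SC section series with a known transport deficit
#'
#' @param spec A [synthetic_spec()].
#' @param deficit_fraction Fraction of the flattened SC surface rendered dim,
#'   in `[0, 1]`.
#' @param eye,animal_id Metadata recorded on each section.
#' @return A list with elements:
#'   \describe{
#'     \item{sections}{List of `section_image`s (channel `"CTB"`), rostral to
#'       caudal.}
#'     \item{masks}{List of logical SC masks, one per section.}
#'     \item{truth}{[ground_truth()] with the requested and the realized
#'       (pixel-counted) deficit fraction, wedge angles, and render levels.}
#'   }
#' @examples
#' out <- generate_sc_series(synthetic_spec(seed = 7), deficit_fraction = 0.4)
#' out$truth$deficit_fraction
#' @export
generate_sc_series <- function(spec, deficit_fraction, eye = "MICROBEAD",
                               animal_id = "A1") {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!is.numeric(deficit_fraction) || length(deficit_fraction) != 1 ||
      is.na(deficit_fraction) || deficit_fraction < 0 || deficit_fraction > 1) {
    stopf("`deficit_fraction` must be a single number in [0, 1]")
  }
  if (spec$n_sections < 1) stopf("spec has no sections")
  nr <- spec$image_size[1]; nc <- spec$image_size[2]
  n <- spec$n_sections

  start_deg <- spec$sector_start_deg %||%
    with_seed(derive_seed(spec$seed, 101L), stats::runif(1, 0, 360))
  wedge <- c(start_deg, start_deg + 360 * deficit_fraction) * pi / 180

  # disc of unit radius in flattened coordinates; margin keeps the chord off
  # the image border
  margin <- max(4L, round(nc * 0.08))
  half_band <- max(4L, round(nr * 0.25))
  xs <- seq(-1, 1, length.out = nc - 2 * margin)     # mediolateral
  ys <- (2 * (seq_len(n) - 0.5) / n) - 1             # rostrocaudal, rostral first

  dim_level <- spec$background + spec$dim_level_frac *
    (spec$bright_level - spec$background)
  in_wedge <- function(theta) {
    if (deficit_fraction <= 0) return(rep(FALSE, length(theta)))
    if (deficit_fraction >= 1) return(rep(TRUE, length(theta)))
    t <- (theta - wedge[1]) %% (2 * pi)
    t <= (wedge[2] - wedge[1])
  }

  sections <- vector("list", n)
  masks <- vector("list", n)
  dim_px <- 0L; sc_px <- 0L
  for (s in seq_len(n)) {
    y <- ys[s]
    chord <- sqrt(max(0, 1 - y^2))
    inside <- abs(xs) <= chord
    theta <- atan2(y, xs)
    vals <- ifelse(in_wedge(theta), dim_level, spec$bright_level)
    vals[!inside] <- NA
    img <- matrix(spec$background, nr, nc)
    mask <- matrix(FALSE, nr, nc)
    rows <- (floor(nr / 2) - half_band + 1):(floor(nr / 2) + half_band)
    cols <- (margin + 1):(nc - margin)
    colvals <- vals
    for (k in seq_along(cols)) {
      if (!inside[k]) next
      img[rows, cols[k]] <- colvals[k]
      mask[rows, cols[k]] <- TRUE
    }
    dim_px <- dim_px + sum(inside & in_wedge(theta)) * length(rows)
    sc_px <- sc_px + sum(inside) * length(rows)
    img <- with_seed(derive_seed(spec$seed, 200L + s),
                     add_noise(img, spec$noise_sd))
    sections[[s]] <- section_image(
      list(CTB = img), pixel_size = spec$pixel_size, tissue = "SC", eye = eye,
      animal_id = animal_id, section_index = s - 1L,
      metadata = list(rostrocaudal_position = y)
    )
    masks[[s]] <- mask
  }
  if (sc_px == 0) stopf("degenerate spec: SC mask empty")
  truth <- ground_truth(
    deficit_fraction = dim_px / sc_px,
    deficit_fraction_requested = deficit_fraction,
    wedge_rad = wedge,
    bright_level = spec$bright_level, dim_level = dim_level,
    background = spec$background
  )
  list(sections = sections, masks = masks, truth = truth)
}
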
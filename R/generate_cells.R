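# Two-channel cell fields (DAPI nuclei + signal) with a known
# nuclear/cytoplasmic partition, and layered retinal cross-sections with a
# known double-positive soma count.

#' Place non-overlapping disk centres by rejection sampling
#'
#' @keywords internal
#' @noRd
place_disks <- function(n, nr, nc, radius, min_sep, seed, max_tries = 2000L) {
  centres <- matrix(numeric(0), 0, 2)
  if (n == 0) return(centres)
  with_seed(seed, {
    tries <- 0L
    lo_r <- radius + 1; hi_r <- nr - radius
    lo_c <- radius + 1; hi_c <- nc - radius
    if (lo_r >= hi_r || lo_c >= hi_c) {
      stopf("image too small to place disks of radius %g", radius)
    }
    while (nrow(centres) < n) {
      tries <- tries + 1L
      if (tries > max_tries * n) {
        stopf("cannot place %d non-overlapping nuclei in a %dx%d image", n, nr, nc)
      }
      cand <- c(stats::runif(1, lo_r, hi_r), stats::runif(1, lo_c, hi_c))
      if (nrow(centres) == 0 ||
          all(sqrt(rowSums(sweep(centres, 2, cand)^2)) >= min_sep)) {
        centres <- rbind(centres, cand)
      }
    }
  })
  unname(centres)
}

#' @keywords internal
#' @noRd
disk_mask <- function(nr, nc, centre, radius) {
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  (rows - centre[1])^2 + (cols - centre[2])^2 <= radius^2
}

#' Generate a DAPI + signal cell field with a known nuclear fraction
#'
#' Renders `n_cells` circular nuclei (DAPI channel) each surrounded by a
#' cytoplasmic annulus in the signal channel. Writing the nuclear mean as
#' `f * T` and the annulus mean as `(1 - f) * T` makes the per-cell nuclear
#' fraction `nuclear_mean / (nuclear_mean + cytoplasm_mean)` equal `f` exactly
#' before noise.
#'
#' @param spec A [synthetic_spec()].
#' @param n_cells Number of nuclei (>= 0).
#' @param nuclear_fraction Target per-cell nuclear fraction in `[0, 1]`.
#' @param signal_channel Name of the signal channel (default `"NFKB"`).
#' @param total_level Sum of nuclear and cytoplasmic mean intensities.
#' @param tissue,eye,animal_id Metadata.
#' @param stream Sub-seed offset for drawing several fields from one spec.
#' @return A list with `image` (channels DAPI + signal) and `truth`
#'   ([ground_truth()] with per-cell fractions, centres and radius).
#' @export
generate_nuclei_image <- function(spec, n_cells, nuclear_fraction,
                                  signal_channel = "NFKB", total_level = 200,
                                  tissue = "SC", eye = "SALINE",
                                  animal_id = "A1", stream = 0L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (n_cells < 0) stopf("`n_cells` must be >= 0")
  f <- nuclear_fraction
  if (f < 0 || f > 1) stopf("`nuclear_fraction` must be in [0, 1]")
  nr <- spec$image_size[1]; nc <- spec$image_size[2]
  r <- spec$cell_radius
  sep <- 2 * r + spec$annulus_width + 2 # annuli must not touch other nuclei
  centres <- place_disks(n_cells, nr, nc, r + spec$annulus_width + 1, sep,
                         derive_seed(spec$seed, 400L + stream))

  dapi <- matrix(10, nr, nc)
  sig <- matrix(0, nr, nc)
  mu_n <- f * total_level
  mu_c <- (1 - f) * total_level
  for (i in seq_len(n_cells)) {
    nucl <- disk_mask(nr, nc, centres[i, ], r)
    ann <- disk_mask(nr, nc, centres[i, ], r + spec$annulus_width) & !nucl
    dapi[nucl] <- 200
    sig[nucl] <- mu_n
    sig[ann] <- mu_c
  }
  dapi <- with_seed(derive_seed(spec$seed, 450L + stream),
                    add_noise(dapi, spec$noise_sd))
  sig <- with_seed(derive_seed(spec$seed, 460L + stream),
                   add_noise(sig, spec$noise_sd))
  channels <- list(DAPI = dapi, sig)
  names(channels)[2] <- signal_channel
  truth <- ground_truth(
    nuclear_fraction_per_cell = rep(f, n_cells),
    centres = centres, radius = r, n_cells = as.integer(n_cells),
    nuclear_mean = mu_n, cytoplasm_mean = mu_c
  )
  list(
    image = section_image(channels, pixel_size = spec$pixel_size,
                          tissue = tissue, eye = eye, animal_id = animal_id),
    truth = truth
  )
}

#' Generate a vertical retinal cross-section with known layer geometry
#'
#' Depth runs down the image rows from the inner limiting membrane (row of the
#' nerve-fibre layer) to the retinal pigment epithelium. Nuclear layers (GCL,
#' INL, ONL) are bright bands in the DAPI channel; `rgc_count` CTB+/DAPI+
#' somas are placed in the ganglion cell layer together with optional
#' DAPI-only distractors. With a tilt the boundary lines keep their
#' perpendicular separation equal to the stated thicknesses (vertical spacing
#' is inflated by `1/cos(tilt)`).
#'
#' @param spec A [synthetic_spec()].
#' @param thickness_um Total retinal thickness, ILM to RPE (micrometres).
#' @param inl_um,onl_um Inner/outer nuclear layer thicknesses (micrometres);
#'   their sum must be below `thickness_um`.
#' @param rgc_count Number of CTB+/DAPI+ somas in the GCL.
#' @param n_distractors DAPI-only somas in the GCL (CTB-negative).
#' @param tilt_deg Tilt of the layer bands, degrees from horizontal.
#' @param gcl_um Ganglion-cell-layer band height (micrometres).
#' @param eye,animal_id Metadata.
#' @return A list with `image` (channels CTB + DAPI), `boundaries` (named list
#'   of polylines in pixel coordinates, ordered by depth), `gcl_roi` (logical
#'   matrix) and `truth`.
#' @export
generate_retina_section <- function(spec, thickness_um = 130, inl_um = 16.8,
                                    onl_um = 33.6, rgc_count = 12,
                                    n_distractors = 0, tilt_deg = 0,
                                    gcl_um = 20, eye = "SALINE",
                                    animal_id = "A1") {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (thickness_um <= 0 || inl_um <= 0 || onl_um <= 0) {
    stopf("thicknesses must be positive")
  }
  if (inl_um + onl_um >= thickness_um) {
    stopf("inl_um + onl_um must be smaller than thickness_um")
  }
  ps <- spec$pixel_size
  nc <- spec$image_size[2]
  slope <- tan(tilt_deg * pi / 180)
  vscale <- 1 / cos(tilt_deg * pi / 180) # keeps perpendicular distance = stated

  # depth layout (um): ILM at 0; GCL band just below; INL and ONL bands at
  # fixed relative positions; RPE at total thickness
  gcl_top <- 0.02 * thickness_um
  gcl_bot <- gcl_top + gcl_um
  inl_top <- max(gcl_bot + 0.05 * thickness_um, 0.30 * thickness_um)
  inl_bot <- inl_top + inl_um
  onl_top <- inl_bot + 0.08 * thickness_um
  onl_bot <- onl_top + onl_um
  if (onl_bot >= thickness_um) stopf("layer layout exceeds retinal thickness")

  top_px <- 4
  depth_to_row <- function(depth_um, x) {
    top_px + (depth_um * vscale) / ps + slope * (x - 1)
  }
  nr <- ceiling(depth_to_row(thickness_um, nc)) + 4
  xs <- seq_len(nc)
  boundaries <- list(
    ilm = data.frame(x = xs, y = depth_to_row(0, xs)),
    inl_top = data.frame(x = xs, y = depth_to_row(inl_top, xs)),
    inl_bottom = data.frame(x = xs, y = depth_to_row(inl_bot, xs)),
    onl_top = data.frame(x = xs, y = depth_to_row(onl_top, xs)),
    onl_bottom = data.frame(x = xs, y = depth_to_row(onl_bot, xs)),
    rpe = data.frame(x = xs, y = depth_to_row(thickness_um, xs))
  )

  dapi <- matrix(10, nr, nc)
  ctb <- matrix(10, nr, nc)
  rows <- matrix(seq_len(nr), nr, nc)
  band <- function(d0, d1) {
    y0 <- matrix(depth_to_row(d0, xs), nr, nc, byrow = TRUE)
    y1 <- matrix(depth_to_row(d1, xs), nr, nc, byrow = TRUE)
    rows >= y0 & rows <= y1
  }
  dapi[band(inl_top, inl_bot)] <- 150
  dapi[band(onl_top, onl_bot)] <- 150
  gcl_roi <- band(gcl_top, gcl_bot)

  # somas in the GCL: RGCs are CTB+/DAPI+; distractors DAPI-only
  soma_r <- max(2, min(3, floor(gcl_um / ps / 2) - 1))
  n_somas <- rgc_count + n_distractors
  gcl_rows <- range(which(apply(gcl_roi, 1, any)))
  centres <- matrix(numeric(0), 0, 2)
  if (n_somas > 0) {
    sub_nr <- gcl_rows[2] - gcl_rows[1] + 1
    centres <- place_disks(n_somas, sub_nr, nc, soma_r, 2 * soma_r + 2,
                           derive_seed(spec$seed, 500L))
    centres[, 1] <- centres[, 1] + gcl_rows[1] - 1
  }
  is_rgc <- seq_len(n_somas) <= rgc_count
  for (i in seq_len(n_somas)) {
    m <- disk_mask(nr, nc, centres[i, ], soma_r)
    dapi[m] <- 200
    if (is_rgc[i]) ctb[m] <- 180
  }
  dapi <- with_seed(derive_seed(spec$seed, 550L), add_noise(dapi, spec$noise_sd))
  ctb <- with_seed(derive_seed(spec$seed, 560L), add_noise(ctb, spec$noise_sd))

  truth <- ground_truth(
    layer_boundaries = c(ilm = 0, inl_top = inl_top, inl_bottom = inl_bot,
                         onl_top = onl_top, onl_bottom = onl_bot,
                         rpe = thickness_um),
    rgc_count = as.integer(rgc_count),
    n_distractors = as.integer(n_distractors),
    soma_centres = centres, soma_radius = soma_r,
    gcl_area_um2 = sum(gcl_roi) * ps^2,
    thickness_um = thickness_um, inl_um = inl_um, onl_um = onl_um,
    tilt_deg = tilt_deg
  )
  list(
    image = section_image(list(CTB = ctb, DAPI = dapi), pixel_size = ps,
                          tissue = "RETINA", eye = eye, animal_id = animal_id),
    boundaries = boundaries, gcl_roi = gcl_roi, truth = truth
  )
}
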
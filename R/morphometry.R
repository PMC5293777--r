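# Retinal morphometry: layer thickness from annotated boundary curves and
# CTB+/DAPI+ RGC density in the ganglion cell layer. Boundary curves are
# inputs (annotation polylines or generator truth); automatic layer
# segmentation is out of scope, mirroring manual measurement practice.

#' @keywords internal
#' @noRd
interp_boundary <- function(b, x) stats::approx(b$x, b$y, xout = x, rule = 2)$y

#' Shortest distance from a point to a polyline, in pixels
#' @keywords internal
#' @noRd
point_polyline_distance <- function(px, py, line) {
  x <- line$x; y <- line$y
  n <- length(x)
  dx <- diff(x); dy <- diff(y)
  len2 <- dx^2 + dy^2
  t <- ((px - x[-n]) * dx + (py - y[-n]) * dy) / pmax(len2, 1e-12)
  t <- pmin(pmax(t, 0), 1)
  qx <- x[-n] + t * dx
  qy <- y[-n] + t * dy
  sqrt(min((px - qx)^2 + (py - qy)^2))
}

#' Measure retinal layer thickness from boundary curves
#'
#' Thickness is the mean, over `n_locations` equally spaced positions along
#' the section's horizontal extent, of the perpendicular distance from the
#' upper to the lower boundary curve, converted to micrometres. Measured
#' pairs: total retinal thickness (ILM to RPE), INL and ONL thickness.
#'
#' @param boundaries Named list of polyline data.frames (`x`, `y` in pixel
#'   coordinates, `y` increasing with depth), ordered by depth. Recognized
#'   names: `ilm`, `inl_top`, `inl_bottom`, `onl_top`, `onl_bottom`, `rpe`
#'   (as produced by [generate_retina_section()]); `ilm` and `rpe` are
#'   required, the INL/ONL pairs optional.
#' @param pixel_size Micrometres per pixel.
#' @param n_locations Number of sampling locations (>= 1; 5 is the
#'   conventional default).
#' @return An object of class `morphometry_result` with
#'   `retinal_thickness_um`, `inl_thickness_um`, `onl_thickness_um` (NA when
#'   the pair is absent), `n_locations`, and per-location samples.
#' @export
measure_layer_thickness <- function(boundaries, pixel_size = 1,
                                    n_locations = 5) {
  if (n_locations < 1) stopf("`n_locations` must be >= 1")
  if (!all(c("ilm", "rpe") %in% names(boundaries))) {
    stopf("`boundaries` must contain at least `ilm` and `rpe`")
  }
  xr <- range(boundaries$ilm$x)
  xs <- if (n_locations == 1) mean(xr) else
    seq(xr[1] + diff(xr) * 0.1, xr[2] - diff(xr) * 0.1,
        length.out = n_locations)
  # non-crossing check at the sampling positions, in stated depth order
  present <- intersect(c("ilm", "inl_top", "inl_bottom", "onl_top",
                         "onl_bottom", "rpe"), names(boundaries))
  depths <- vapply(boundaries[present], interp_boundary, numeric(length(xs)),
                   x = xs)
  if (n_locations == 1) depths <- matrix(depths, nrow = 1)
  if (any(apply(depths, 1, function(d) is.unsorted(d, strictly = TRUE)))) {
    stopf("boundary curves cross or are not ordered by depth")
  }
  pair_thickness <- function(upper, lower) {
    if (!all(c(upper, lower) %in% names(boundaries))) return(rep(NA_real_, length(xs)))
    up <- boundaries[[upper]]
    lo <- boundaries[[lower]]
    vapply(xs, function(x) {
      point_polyline_distance(x, interp_boundary(up, x), lo) * pixel_size
    }, 0)
  }
  rt <- pair_thickness("ilm", "rpe")
  inl <- pair_thickness("inl_top", "inl_bottom")
  onl <- pair_thickness("onl_top", "onl_bottom")
  structure(
    list(retinal_thickness_um = mean(rt), inl_thickness_um = mean(inl),
         onl_thickness_um = mean(onl), n_locations = as.integer(n_locations),
         samples = data.frame(x = xs, rt_um = rt, inl_um = inl, onl_um = onl)),
    class = "morphometry_result"
  )
}

#' @export
print.morphometry_result <- function(x, ...) {
  cat(sprintf("<morphometry_result> RT %.1f um, INL %.1f um, ONL %.1f um (%d locations)\n",
              x$retinal_thickness_um, x$inl_thickness_um, x$onl_thickness_um,
              x$n_locations))
  invisible(x)
}

#' Count CTB+/DAPI+ somas in the ganglion cell layer
#'
#' Objects are detected on the DAPI channel inside the GCL ROI and deemed
#' CTB-positive when their mean CTB intensity exceeds `ctb_threshold`;
#' density is the double-positive count divided by the ROI area in um^2.
#'
#' @param ctb,dapi Numeric matrices (or one `section_image` passed as `ctb`
#'   with both channels).
#' @param gcl_roi Logical ROI matrix for the ganglion cell layer.
#' @param pixel_size Micrometres per pixel.
#' @param ctb_threshold Mean-intensity cut for CTB positivity.
#' @param dapi_threshold Fixed DAPI cut; `NULL` uses Otsu.
#' @param min_area Minimum object area (px) kept as a soma.
#' @return A list with `rgc_count`, `rgc_density` (cells/um^2),
#'   `gcl_area_um2`, `n_dapi_objects`.
#' @export
count_rgc_density <- function(ctb, dapi = NULL, gcl_roi, pixel_size = 1,
                              ctb_threshold = 100, dapi_threshold = NULL,
                              min_area = 4) {
  if (inherits(ctb, "section_image")) {
    img <- ctb
    ctb <- get_channel(img, "CTB")
    dapi <- get_channel(img, "DAPI")
    pixel_size <- img$pixel_size
  }
  if (!any(gcl_roi)) stopf("GCL ROI is empty")
  dm <- dapi
  dm[!gcl_roi] <- 0
  th <- dapi_threshold %||% otsu_threshold(dapi[gcl_roi])
  mask <- if (is.na(th)) matrix(FALSE, nrow(dm), ncol(dm)) else (dm > th & gcl_roi)
  labels <- watershed_split(mask)
  tab <- region_table(labels)
  tab <- tab[tab$area_px >= min_area, , drop = FALSE]
  n_dp <- 0L
  for (k in tab$nucleus_id) {
    if (mean(ctb[labels == k]) > ctb_threshold) n_dp <- n_dp + 1L
  }
  area <- sum(gcl_roi) * pixel_size^2
  list(rgc_count = n_dp, rgc_density = n_dp / area, gcl_area_um2 = area,
       n_dapi_objects = nrow(tab))
}
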
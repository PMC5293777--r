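# Retinotopic transport mapping: background normalization of CTB sections,
# per-section mediolateral intensity profiles, assembly of the flattened
# retinotopic density map, and the percent-intact-transport statistic (the
# fraction of the map at or above 70% of the tissue's reference maximum).

#' Subtract the background estimate from a CTB section
#'
#' The normalized intensity is `max(raw - background_estimate, 0)`. With an
#' explicit background mask the estimate is that region's mean; in `"auto"`
#' mode tissue-free pixels are taken as those below the Otsu split of the
#' channel (a constant image is treated as pure background).
#'
#' @param image A `section_image` with a `"CTB"` channel (or `channel`).
#' @param background A logical matrix marking background pixels, or `"auto"`.
#' @param channel Channel to normalize.
#' @return The image with the channel replaced by its background-subtracted
#'   version and `metadata$background_estimate` recorded.
#' @export
normalize_background <- function(image, background = "auto", channel = "CTB") {
  raw <- get_channel(image, channel)
  if (is.matrix(background)) {
    if (!is.logical(background) || !all(dim(background) == dim(raw))) {
      stopf("`background` mask must be a logical matrix matching the image")
    }
    if (!any(background)) stopf("background region is empty")
    if (all(background)) stopf("background region covers the entire image")
    bg <- mean(raw[background])
  } else if (identical(background, "auto")) {
    th <- otsu_threshold(raw)
    bg <- if (is.na(th)) mean(raw) else mean(raw[raw <= th])
  } else {
    stopf("`background` must be a logical mask or \"auto\"")
  }
  out <- set_channel(image, channel, pmax(raw - bg, 0))
  out$metadata$background_estimate <- bg
  out
}

#' Mediolateral intensity profile of one SC section
#'
#' Bins the masked SC pixels into `n_samples` equal mediolateral (column)
#' bins spanning the full image width and returns the mean normalized CTB
#' intensity per bin. Bins with no SC pixels are `NA`; they become invalid
#' cells of the assembled map, so sections of different chord widths stay in a
#' common mediolateral frame (column 1 = medial).
#'
#' @param image A `section_image`.
#' @param sc_mask Logical matrix marking SC pixels.
#' @param n_samples Number of mediolateral bins (>= 2).
#' @param channel Channel to profile.
#' @return Numeric vector of length `n_samples` (possibly with `NA`s).
#' @export
extract_section_profile <- function(image, sc_mask, n_samples = 50,
                                    channel = "CTB") {
  raw <- get_channel(image, channel)
  if (!is.logical(sc_mask) || !all(dim(sc_mask) == dim(raw))) {
    stopf("`sc_mask` must be a logical matrix matching the image")
  }
  if (!any(sc_mask)) stopf("empty SC mask: cannot identify the section")
  if (n_samples < 2) stopf("`n_samples` must be >= 2")
  idx <- which(sc_mask)
  cols <- ((idx - 1) %/% nrow(raw)) + 1
  bin <- pmin(pmax(ceiling(cols / ncol(raw) * n_samples), 1L), n_samples)
  prof <- rep(NA_real_, n_samples)
  means <- tapply(raw[idx], bin, mean)
  prof[as.integer(names(means))] <- as.numeric(means)
  prof
}

#' Assemble the flattened retinotopic map from ordered section profiles
#'
#' Profiles (rostral first) are stacked along the rostrocaudal axis and
#' bilinearly interpolated onto a `grid_resolution` x `grid_resolution` grid;
#' densities are then divided by the map's reference maximum so the brightest
#' valid cell reads 1.0. The reference maximum of a tissue is by default the
#' 99th percentile of valid interpolated intensities (robust to hot pixels);
#' `reference = "max"` uses the exact maximum. Cells interpolated from any
#' missing (`NA`) profile entry are marked invalid.
#'
#' @param profiles List of numeric vectors of identical length, ordered
#'   rostral to caudal, or a single vector.
#' @param grid_resolution Output grid size per axis.
#' @param reference `"p99"` (default) or `"max"`.
#' @return An object of class `retinotopic_map` with fields `density` (in
#'   `[0, 1]` where valid), `valid_mask`, `max_signal`, `grid_resolution`,
#'   `n_sections`.
#' @export
assemble_retinotopic_map <- function(profiles, grid_resolution = 100,
                                     reference = c("p99", "max")) {
  reference <- match.arg(reference)
  if (is.numeric(profiles)) profiles <- list(profiles)
  if (length(profiles) < 1) stopf("need at least one profile")
  lens <- lengths(profiles)
  if (length(unique(lens)) != 1) stopf("inconsistent profile lengths")
  P <- do.call(rbind, profiles)
  G <- as.integer(grid_resolution)
  if (G < 2) stopf("`grid_resolution` must be >= 2")

  interp_axis <- function(M, nout) {
    nin <- nrow(M)
    if (nin == 1) return(M[rep(1, 1), , drop = FALSE])
    pos <- seq(1, nin, length.out = nout)
    lo <- pmin(floor(pos), nin - 1)
    w <- pos - lo
    M[lo, , drop = FALSE] * (1 - w) + M[lo + 1, , drop = FALSE] * w
  }
  dens <- interp_axis(P, if (nrow(P) >= 2) G else 1)
  dens <- t(interp_axis(t(dens), G))

  valid <- !is.na(dens)
  if (!any(valid)) stopf("assembled map has no valid cells")
  vals <- dens[valid]
  ref <- if (reference == "max") max(vals) else
    as.numeric(stats::quantile(vals, 0.99, names = FALSE))
  if (ref <= 0) ref <- max(vals, 1e-12)
  dens <- pmin(dens / ref, 1)
  structure(
    list(density = dens, valid_mask = valid, max_signal = ref,
         grid_resolution = G, n_sections = length(profiles)),
    class = "retinotopic_map"
  )
}

#' @export
print.retinotopic_map <- function(x, ...) {
  cat(sprintf("<retinotopic_map> %dx%d grid, %d sections, %.1f%% valid, ref max %.4g\n",
              nrow(x$density), ncol(x$density), x$n_sections,
              100 * mean(x$valid_mask), x$max_signal))
  invisible(x)
}

#' Percent of intact transport of a retinotopic map
#'
#' The statistic is `100 * (# valid cells with density >= threshold) /
#' (# valid cells)`; the tie at the threshold counts as intact (the
#' definition is ">= 70% of the maximum").
#'
#' @param map A `retinotopic_map`.
#' @param threshold Fraction of the reference maximum in `(0, 1]`
#'   (default 0.70).
#' @return An object of class `transport_result` with `percent_intact`,
#'   `threshold`, `n_sections` and the `map`.
#' @examples
#' m <- assemble_retinotopic_map(list(c(1, 1, 0.5), c(1, 1, 0.5)),
#'                               grid_resolution = 10, reference = "max")
#' percent_intact_transport(m)$percent_intact
#' @export
percent_intact_transport <- function(map, threshold = 0.70) {
  stopifnot(inherits(map, "retinotopic_map"))
  if (threshold <= 0 || threshold > 1) stopf("`threshold` must be in (0, 1]")
  v <- map$density[map$valid_mask]
  if (length(v) == 0) stopf("map has no valid cells")
  pct <- 100 * mean(v >= threshold - 1e-9)
  structure(
    list(percent_intact = pct, threshold = threshold,
         n_sections = map$n_sections, map = map),
    class = "transport_result"
  )
}

#' @export
print.transport_result <- function(x, ...) {
  cat(sprintf("<transport_result> %.1f%% intact at threshold %.2f (%d sections)\n",
              x$percent_intact, x$threshold, x$n_sections))
  invisible(x)
}

#' Full transport pipeline for one eye's section series
#'
#' Convenience wrapper: background-normalizes every section, extracts
#' mediolateral profiles, assembles the retinotopic map and computes percent
#' intact transport.
#'
#' @param sections List of `section_image`s, rostral to caudal.
#' @param masks List of logical SC masks matching `sections`.
#' @param n_samples Profile bins per section.
#' @param grid_resolution Map grid size.
#' @param threshold Intact-transport threshold.
#' @param reference Reference-maximum rule (see
#'   [assemble_retinotopic_map()]).
#' @return A `transport_result`.
#' @export
transport_from_sections <- function(sections, masks, n_samples = 50,
                                    grid_resolution = 100, threshold = 0.70,
                                    reference = "p99") {
  stopifnot(length(sections) == length(masks), length(sections) >= 1)
  profiles <- vector("list", length(sections))
  for (i in seq_along(sections)) {
    img <- normalize_background(sections[[i]], background = !masks[[i]])
    profiles[[i]] <- extract_section_profile(img, masks[[i]], n_samples)
  }
  map <- assemble_retinotopic_map(profiles, grid_resolution, reference)
  percent_intact_transport(map, threshold)
}
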
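# NF-kB nuclear-localization scoring: DAPI-gated nucleus segmentation, the
# per-nucleus nuclear/perinuclear signal partition, and the microbead:saline
# ratio analysis of image-level scores.

#' Segment nuclei from a DAPI channel
#'
#' Thresholds the DAPI channel (Otsu by default), labels connected regions,
#' splits touching nuclei with a distance-transform watershed, and filters by
#' area. A blank image yields zero nuclei (not an error).
#'
#' @param dapi Numeric matrix (DAPI channel) or a `section_image` with a
#'   `"DAPI"` channel.
#' @param min_area,max_area Area bounds in pixels for a kept nucleus.
#' @param threshold Fixed intensity cut; `NULL` uses Otsu.
#' @param split_touching Run the watershed split (default TRUE).
#' @return A list with `labels` (integer matrix), `nuclei` (data.frame:
#'   `nucleus_id`, `centroid_r`, `centroid_c`, `area_px`) and `n_nuclei`.
#' @export
segment_nuclei <- function(dapi, min_area = 20, max_area = 5000,
                           threshold = NULL, split_touching = TRUE) {
  if (inherits(dapi, "section_image")) dapi <- get_channel(dapi, "DAPI")
  th <- threshold %||% otsu_threshold(dapi)
  mask <- if (is.na(th)) matrix(FALSE, nrow(dapi), ncol(dapi)) else dapi > th
  labels <- if (split_touching) watershed_split(mask) else label_components(mask)
  tab <- region_table(labels)
  keep <- tab$area_px >= min_area & tab$area_px <= max_area
  remap <- integer(nrow(tab))
  remap[tab$nucleus_id[keep]] <- seq_len(sum(keep))
  idx <- labels > 0L
  labels[idx] <- remap[labels[idx]]
  tab <- tab[keep, , drop = FALSE]
  tab$nucleus_id <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  attr(labels, "n") <- nrow(tab)
  list(labels = labels, nuclei = tab, n_nuclei = nrow(tab))
}

#' Per-nucleus nuclear signal fraction and image-level score
#'
#' For each nucleus the signal channel is averaged over the nucleus pixels and
#' over a perinuclear annulus of width `annulus_width` that excludes pixels of
#' every nucleus; the nuclear fraction is
#' `nuclear_mean / (nuclear_mean + cytoplasm_mean)`. The image-level score is
#' the mean per-nucleus fraction (`metric = "mean_fraction"`) or the fraction
#' of nuclei whose fraction exceeds `positivity_cut`
#' (`metric = "positive_fraction"`). Nuclei with zero signal in both
#' compartments are flagged undefined and excluded from the score. Because a
#' constant intensity offset pulls every fraction toward 0.5, the signal
#' channel should be background-normalized first (see
#' [normalize_background()]).
#'
#' Optional co-label masks (e.g. GFAP/Iba1/NeuN/CTB) classify each nucleus:
#' a nucleus belongs to a class when the co-label mean over its annulus
#' exceeds that class's threshold; classes are non-exclusive.
#'
#' @param signal Numeric matrix (signal channel) or a `section_image`.
#' @param nuclei Output of [segment_nuclei()] (or a bare label matrix).
#' @param annulus_width Annulus width in pixels (>= 1).
#' @param channel Channel name when `signal` is a `section_image`.
#' @param colabels Optional named list of numeric matrices (co-label
#'   channels).
#' @param colabel_threshold Intensity a co-label annulus mean must exceed.
#' @param metric `"mean_fraction"` or `"positive_fraction"`.
#' @param positivity_cut Per-nucleus cut for `"positive_fraction"`.
#' @return An object of class `nuclear_loc_result`: `records` (per-nucleus
#'   data.frame), `score`, `n_nuclei`, `metric`.
#' @export
nuclear_signal_fraction <- function(signal, nuclei, annulus_width = 3,
                                    channel = "NFKB", colabels = NULL,
                                    colabel_threshold = 50,
                                    metric = c("mean_fraction", "positive_fraction"),
                                    positivity_cut = 0.5) {
  metric <- match.arg(metric)
  if (inherits(signal, "section_image")) signal <- get_channel(signal, channel)
  labels <- if (is.list(nuclei)) nuclei$labels else nuclei
  if (annulus_width < 1) stopf("`annulus_width` must be >= 1")
  n <- max(labels)
  if (n < 1) stopf("need at least one segmented nucleus")
  nr <- nrow(labels); nc <- ncol(labels)
  any_nucleus <- labels > 0L
  w <- ceiling(annulus_width)

  records <- vector("list", n)
  for (k in seq_len(n)) {
    idx <- which(labels == k)
    ri <- ((idx - 1) %% nr) + 1
    ci <- ((idx - 1) %/% nr) + 1
    r0 <- max(1, min(ri) - w); r1 <- min(nr, max(ri) + w)
    c0 <- max(1, min(ci) - w); c1 <- min(nc, max(ci) + w)
    sub_r <- r0:r1; sub_c <- c0:c1
    cand <- which(!any_nucleus[sub_r, sub_c, drop = FALSE])
    if (length(cand)) {
      cr <- sub_r[((cand - 1) %% length(sub_r)) + 1]
      cc <- sub_c[((cand - 1) %/% length(sub_r)) + 1]
      # distance from each candidate pixel to the nearest nucleus pixel
      d2 <- vapply(seq_along(cand), function(m) {
        min((cr[m] - ri)^2 + (cc[m] - ci)^2)
      }, 0)
      ann_r <- cr[d2 <= annulus_width^2]
      ann_c <- cc[d2 <= annulus_width^2]
    } else {
      ann_r <- ann_c <- integer(0)
    }
    nuc_mean <- mean(signal[idx])
    cyt_mean <- if (length(ann_r)) mean(signal[cbind(ann_r, ann_c)]) else NA_real_
    undefined <- is.na(cyt_mean) || (nuc_mean + cyt_mean) == 0
    frac <- if (undefined) NA_real_ else nuc_mean / (nuc_mean + cyt_mean)
    rec <- data.frame(nucleus_id = k, centroid_r = mean(ri), centroid_c = mean(ci),
                      area_px = length(idx), nuclear_mean_signal = nuc_mean,
                      cytoplasm_mean_signal = cyt_mean,
                      nuclear_fraction = frac, undefined = undefined)
    if (!is.null(colabels)) {
      for (cl in names(colabels)) {
        clm <- if (length(ann_r)) mean(colabels[[cl]][cbind(ann_r, ann_c)]) else NA_real_
        rec[[paste0(cl, "_positive")]] <- !is.na(clm) && clm > colabel_threshold
      }
    }
    records[[k]] <- rec
  }
  records <- do.call(rbind, records)
  ok <- !records$undefined
  if (any(!ok)) warnf("%d nucleus/nuclei with zero signal excluded from score", sum(!ok))
  fr <- records$nuclear_fraction[ok]
  if (length(fr) == 0) stopf("no nucleus with a defined nuclear fraction")
  score <- if (metric == "mean_fraction") mean(fr) else mean(fr > positivity_cut)
  structure(
    list(records = records, score = score, n_nuclei = sum(ok), metric = metric),
    class = "nuclear_loc_result"
  )
}

#' @export
print.nuclear_loc_result <- function(x, ...) {
  cat(sprintf("<nuclear_loc_result> score %.3f (%s) over %d nuclei\n",
              x$score, x$metric, x$n_nuclei))
  invisible(x)
}

#' Microbead:saline ratio analysis of nuclear-localization scores
#'
#' Identical contract to [microbead_saline_ratio()] applied to image-level
#' nuclear scores (per-animal score = mean over that animal's images).
#'
#' @inheritParams microbead_saline_ratio
#' @return See [microbead_saline_ratio()].
#' @export
nuclear_ratio_analysis <- function(per_animal, group = "VEHICLE",
                                   tissue = "SC") {
  microbead_saline_ratio(per_animal, group = group, marker = "NFKB_nuclear",
                         tissue = tissue)
}
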
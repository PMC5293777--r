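# Percent-area immunolabel quantification and per-animal microbead:saline
# ratio analysis. Because both eyes of an animal are imaged under identical
# acquisition settings, a single threshold is shared by the pair (fixed from
# configuration, or Otsu derived from the pooled pair).

#' Threshold positive immunolabel within a region of interest
#'
#' @param image A `section_image` (or a bare numeric matrix).
#' @param channel Channel to threshold (ignored for a bare matrix).
#' @param method `"fixed"` (use `threshold`) or `"otsu"`.
#' @param threshold Intensity cut for `method = "fixed"`, and the fallback if
#'   Otsu is undefined (constant image).
#' @param roi Logical ROI matrix; `NULL` means the full frame.
#' @param pooled_with Optional second image/matrix (the fellow eye) whose ROI
#'   pixels are pooled before deriving the Otsu threshold, so both eyes share
#'   one cut.
#' @return Logical mask (subset of `roi`) with attribute
#'   `"threshold"` recording the intensity used.
#' @export
threshold_positive_label <- function(image, channel = NULL,
                                     method = c("fixed", "otsu"),
                                     threshold = NULL, roi = NULL,
                                     pooled_with = NULL) {
  method <- match.arg(method)
  mat <- if (inherits(image, "section_image")) {
    get_channel(image, channel %||% names(image$channels)[1])
  } else image
  if (is.null(roi)) roi <- matrix(TRUE, nrow(mat), ncol(mat))
  if (!any(roi)) stopf("ROI is empty")
  if (method == "fixed") {
    if (is.null(threshold)) stopf("`threshold` required for method = \"fixed\"")
    th <- threshold
  } else {
    pool <- mat[roi]
    if (!is.null(pooled_with)) {
      mate <- if (inherits(pooled_with, "section_image")) {
        get_channel(pooled_with, channel %||% names(pooled_with$channels)[1])
      } else pooled_with
      pool <- c(pool, as.numeric(mate))
    }
    th <- otsu_threshold(pool)
    if (is.na(th)) {
      if (is.null(threshold)) stopf("constant image under Otsu and no fixed fallback")
      warnf("constant image under Otsu; falling back to fixed threshold %.4g", threshold)
      th <- threshold
    }
  }
  mask <- mat > th & roi
  attr(mask, "threshold") <- th
  mask
}

#' Percent area of positive label within an ROI
#'
#' @param mask Logical positive-label mask (must be a subset of `roi`).
#' @param roi Logical ROI matrix.
#' @param marker,tissue Metadata carried on the result.
#' @param pixel_size Micrometres per pixel (for the ROI area in um^2).
#' @return An object of class `label_quant_result` with `percent_area`
#'   (`100 * positive / ROI pixels`), `threshold_used`, `roi_area_um2`.
#' @examples
#' roi <- matrix(TRUE, 100, 100)
#' mask <- roi & FALSE; mask[seq_len(1234)] <- TRUE
#' percent_area_positive(mask, roi)$percent_area # 12.34
#' @export
percent_area_positive <- function(mask, roi, marker = "label", tissue = "SC",
                                  pixel_size = 1) {
  if (!is.logical(mask) || !is.logical(roi) || !all(dim(mask) == dim(roi))) {
    stopf("`mask` and `roi` must be logical matrices of identical dimensions")
  }
  if (!any(roi)) stopf("ROI is empty")
  if (any(mask & !roi)) stopf("`mask` must be a subset of `roi`")
  structure(
    list(marker = marker, tissue = tissue,
         percent_area = 100 * sum(mask) / sum(roi),
         threshold_used = attr(mask, "threshold"),
         roi_area_um2 = sum(roi) * pixel_size^2,
         n_positive = sum(mask), n_roi = sum(roi)),
    class = "label_quant_result"
  )
}

#' @export
print.label_quant_result <- function(x, ...) {
  cat(sprintf("<label_quant_result> %s/%s: %.2f%% positive area\n",
              x$marker, x$tissue, x$percent_area))
  invisible(x)
}

#' Per-animal microbead:saline ratios and the group summary
#'
#' Input is one quantified value per animal and eye (itself the mean over that
#' animal's images, >= 1 per eye). The per-animal ratio is
#' `microbead / saline`; ratios are then averaged to the group mean +/- SEM
#' (averaging order: images -> animal -> group). Animals with a zero saline
#' value have an undefined ratio and are excluded with a warning.
#'
#' @param per_animal A data.frame with columns `animal_id`, `eye`
#'   (`"SALINE"`/`"MICROBEAD"`) and `value`, or a two-column matrix/data.frame
#'   with columns `microbead` and `saline` (one row per animal).
#' @param group Group label for the summary (e.g. `"VEHICLE"`).
#' @param marker,tissue Metadata.
#' @return A list with `records` (per-animal data.frame: `animal_id`,
#'   `microbead_value`, `saline_value`, `ratio`, `excluded`) and `summary`
#'   (class `group_ratio_summary`: `group`, `n`, `mean_ratio`, `sem`).
#' @examples
#' microbead_saline_ratio(data.frame(microbead = c(4, 2), saline = c(2, 2)))
#' @export
microbead_saline_ratio <- function(per_animal, group = "VEHICLE",
                                   marker = "label", tissue = "SC") {
  if (is.data.frame(per_animal) && all(c("animal_id", "eye", "value") %in%
                                       names(per_animal))) {
    agg <- stats::aggregate(value ~ animal_id + eye, per_animal, mean)
    wide <- stats::reshape(agg, idvar = "animal_id", timevar = "eye",
                           direction = "wide")
    mb <- wide$value.MICROBEAD
    sal <- wide$value.SALINE
    ids <- as.character(wide$animal_id)
    if (any(is.na(mb)) || any(is.na(sal))) {
      stopf("every animal needs both a SALINE and a MICROBEAD value")
    }
  } else {
    pa <- as.data.frame(per_animal)
    if (!all(c("microbead", "saline") %in% names(pa))) {
      stopf("`per_animal` must have microbead/saline columns or long format")
    }
    mb <- pa$microbead; sal <- pa$saline
    ids <- if (!is.null(pa$animal_id)) as.character(pa$animal_id) else
      paste0("A", seq_along(mb))
  }
  if (length(mb) < 1) stopf("need at least one animal")
  if (any(mb < 0) || any(sal < 0)) stopf("values must be >= 0")
  excluded <- sal == 0
  if (any(excluded)) {
    warnf("excluding %d animal(s) with zero saline value: %s",
          sum(excluded), paste(ids[excluded], collapse = ", "))
  }
  ratio <- ifelse(excluded, NA_real_, mb / sal)
  records <- data.frame(animal_id = ids, microbead_value = mb,
                        saline_value = sal, ratio = ratio,
                        excluded = excluded)
  keep <- ratio[!excluded]
  if (length(keep) == 0) stopf("no animal with a defined ratio")
  summary <- structure(
    list(group = group, marker = marker, tissue = tissue,
         n = length(keep), mean_ratio = mean(keep), sem = sem(keep)),
    class = "group_ratio_summary"
  )
  list(records = records, summary = summary)
}

#' @export
print.group_ratio_summary <- function(x, ...) {
  cat(sprintf("<group_ratio_summary> %s %s/%s: %.3f +/- %.3f (n = %d)\n",
              x$group, x$marker, x$tissue, x$mean_ratio,
              ifelse(is.na(x$sem), NaN, x$sem), x$n))
  invisible(x)
}
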
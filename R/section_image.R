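# The section_image container: one acquired (or synthetic) 2D multi-channel
# fluorescence field with pixel scale and tissue/eye/animal metadata.

#' Create a section image
#'
#' A `section_image` holds one 2D multi-channel fluorescence field. Channels
#' are named numeric matrices of identical dimensions (e.g. `"CTB"`, `"DAPI"`,
#' `"NFKB"`, `"IBA1"`); intensities must be finite and non-negative. The pixel
#' scale is isotropic and expressed in micrometres per pixel.
#'
#' @param channels Named list of numeric matrices, all with identical
#'   dimensions. At least one channel is required.
#' @param pixel_size Micrometres per pixel (> 0).
#' @param tissue One of `"SC"`, `"ONH"`, `"RETINA"`.
#' @param eye One of `"SALINE"`, `"MICROBEAD"`.
#' @param animal_id Animal identifier.
#' @param section_index Non-negative integer; order within a serial series
#'   (rostral to caudal for SC).
#' @param metadata Optional named list of extra metadata (kept verbatim;
#'   processing steps append to it).
#' @return An object of class `section_image`.
#' @examples
#' img <- section_image(list(CTB = matrix(1, 4, 4)), pixel_size = 2)
#' dim(get_channel(img, "CTB"))
#' @export
section_image <- function(channels, pixel_size = 1, tissue = "SC",
                          eye = "SALINE", animal_id = "A1",
                          section_index = 0L, metadata = list()) {
  if (!is.list(channels) || length(channels) < 1 || is.null(names(channels)) ||
      any(!nzchar(names(channels)))) {
    stopf("`channels` must be a non-empty named list of matrices")
  }
  dims <- lapply(channels, dim)
  if (any(vapply(channels, function(m) !is.matrix(m) || !is.numeric(m), TRUE))) {
    stopf("every channel must be a numeric matrix")
  }
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1) {
    stopf("all channels must share identical dimensions")
  }
  bad <- vapply(channels, function(m) any(!is.finite(m)) || any(m < 0), TRUE)
  if (any(bad)) {
    stopf("channel(s) %s contain non-finite or negative intensities",
          paste(names(channels)[bad], collapse = ", "))
  }
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || pixel_size <= 0) {
    stopf("`pixel_size` must be a single positive number")
  }
  tissue <- match.arg(tissue, TISSUES)
  eye <- match.arg(eye, EYES)
  if (section_index < 0) stopf("`section_index` must be >= 0")
  structure(
    list(channels = channels, pixel_size = pixel_size, tissue = tissue,
         eye = eye, animal_id = as.character(animal_id),
         section_index = as.integer(section_index), metadata = metadata),
    class = "section_image"
  )
}

#' @export
print.section_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<section_image> %s/%s/%s section %d: %dx%d px @ %.3g um/px, channels: %s\n",
              x$animal_id, x$tissue, x$eye, x$section_index, d[1], d[2],
              x$pixel_size, paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Extract a channel matrix from a section image
#'
#' @param image A `section_image`.
#' @param channel Channel name.
#' @return The channel's numeric matrix.
#' @export
get_channel <- function(image, channel) {
  stopifnot(inherits(image, "section_image"))
  if (!channel %in% names(image$channels)) {
    stopf("channel '%s' not present (have: %s)", channel,
          paste(names(image$channels), collapse = ", "))
  }
  image$channels[[channel]]
}

#' Replace a channel matrix, preserving metadata
#' @keywords internal
#' @noRd
set_channel <- function(image, channel, value) {
  image$channels[[channel]] <- value
  image
}

# ---- plain-text serialization ------------------------------------------------
# Images travel as one whitespace-delimited text matrix per channel plus a JSON
# sidecar holding pixel size, tissue/eye/animal metadata and (for synthetic
# images) the ground truth. The format is self-describing and diff-able; no
# binary container is required.

#' Write a section image as text matrices plus a JSON sidecar
#'
#' Each channel is written to `<prefix>_<channel>.tsv` (tab-separated numeric
#' matrix, full precision) and the metadata to `<prefix>.json`.
#'
#' @param image A `section_image`.
#' @param prefix Path prefix (directories are created as needed).
#' @return Invisibly, the sidecar path.
#' @export
write_section_image <- function(image, prefix) {
  stopifnot(inherits(image, "section_image"))
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (ch in names(image$channels)) {
    f <- paste0(prefix, "_", ch, ".tsv")
    utils::write.table(format(image$channels[[ch]], digits = 15, trim = TRUE,
                              scientific = FALSE),
                       f, sep = "\t", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
    files[ch] <- basename(f)
  }
  sidecar <- list(
    format = "axoquant-section-image/1",
    channels = as.list(files),
    pixel_size = image$pixel_size, tissue = image$tissue, eye = image$eye,
    animal_id = image$animal_id, section_index = image$section_index,
    metadata = image$metadata
  )
  out <- paste0(prefix, ".json")
  jsonlite::write_json(sidecar, out, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(out)
}

#' Read a section image written by [write_section_image()]
#'
#' @param prefix Path prefix used at write time (or the sidecar path itself).
#' @return A `section_image`.
#' @export
read_section_image <- function(prefix) {
  sidecar <- if (endsWith(prefix, ".json")) prefix else paste0(prefix, ".json")
  if (!file.exists(sidecar)) stopf("sidecar not found: %s", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  base <- dirname(sidecar)
  channels <- lapply(meta$channels, function(f) {
    as.matrix(utils::read.table(file.path(base, f), sep = "\t",
                                colClasses = "numeric"))
  })
  channels <- lapply(channels, function(m) {
    dimnames(m) <- NULL
    m
  })
  names(channels) <- names(meta$channels)
  section_image(channels, pixel_size = as.numeric(meta$pixel_size),
                tissue = meta$tissue, eye = meta$eye,
                animal_id = meta$animal_id,
                section_index = as.integer(meta$section_index),
                metadata = as.list(meta$metadata))
}
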
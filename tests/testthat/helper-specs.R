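# Shared fixture builders. Everything is generated in code at test time; no
# binary fixtures exist. Specs here are deliberately small so the default
# suite stays fast.

sc_spec <- function(seed = 1, ...) {
  synthetic_spec(image_size = c(96, 96), n_sections = 8, seed = seed, ...)
}

cell_spec <- function(seed = 1, noise_sd = 2, ...) {
  synthetic_spec(image_size = c(128, 128), pixel_size = 0.5,
                 noise_sd = noise_sd, cell_radius = 5, seed = seed, ...)
}

retina_spec <- function(seed = 1, ...) {
  synthetic_spec(image_size = c(64, 160), pixel_size = 1, noise_sd = 2,
                 seed = seed, ...)
}

# independent brute-force oracle: fraction of masked pixels that are "dim"
# (below the midpoint between dim and bright render levels), pooled over a
# section series
oracle_dim_fraction <- function(series) {
  cut <- (series$truth$dim_level + series$truth$bright_level) / 2
  dim_px <- 0; all_px <- 0
  for (i in seq_along(series$sections)) {
    v <- get_channel(series$sections[[i]], "CTB")[series$masks[[i]]]
    dim_px <- dim_px + sum(v < cut)
    all_px <- all_px + length(v)
  }
  dim_px / all_px
}

# independent oracle: per-cell nuclear fraction recomputed by masked means
# from generator truth geometry (not via segment_nuclei)
oracle_nuclear_fractions <- function(gen, annulus_width = 3) {
  img <- gen$image
  sig <- get_channel(img, names(img$channels)[2])
  tr <- gen$truth
  nr <- nrow(sig); nc <- ncol(sig)
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  vapply(seq_len(tr$n_cells), function(i) {
    d2 <- (rows - tr$centres[i, 1])^2 + (cols - tr$centres[i, 2])^2
    nuc <- d2 <= tr$radius^2
    ann <- d2 <= (tr$radius + annulus_width)^2 & !nuc
    mean(sig[nuc]) / (mean(sig[nuc]) + mean(sig[ann]))
  }, 0)
}

image_hashes <- function(series) {
  vapply(series$sections, function(s) {
    paste(format(sum(get_channel(s, "CTB")), digits = 17),
          format(sum(get_channel(s, "CTB")^2), digits = 17))
  }, "")
}
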
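# Minimal image-processing primitives in base R: Otsu thresholding, connected
# component labeling, a chamfer distance transform, marker-based watershed and
# separable Gaussian smoothing. Images in this package are small 2D fields, so
# clarity is preferred over asymptotic cleverness.

#' Otsu's threshold for a grayscale intensity sample
#'
#' Maximizes between-class variance on a fixed-bin histogram. Returns a single
#' intensity; pixels strictly greater than it are "positive".
#'
#' @param x Numeric vector or matrix of intensities.
#' @param nbins Number of histogram bins.
#' @return Threshold intensity, or `NA` if `x` is constant.
#' @export
otsu_threshold <- function(x, nbins = 256) {
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) == 0) return(NA_real_)
  breaks <- seq(rng[1], rng[2], length.out = nbins + 1)
  h <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE), nbins)
  mids <- (breaks[-1] + breaks[-(nbins + 1)]) / 2
  w <- cumsum(h)
  mu <- cumsum(h * mids)
  n <- w[nbins]
  m <- mu[nbins]
  # between-class variance for split after each bin
  w0 <- w[-nbins]
  bc <- (mu[-nbins] * n - m * w0)^2 / (w0 * (n - w0))
  bc[!is.finite(bc)] <- -Inf
  breaks[which.max(bc) + 1]
}

#' Label connected components of a binary mask
#'
#' Two-pass labeling with union-find; 4- or 8-connectivity.
#'
#' @param mask Logical matrix.
#' @param connectivity 4 or 8.
#' @return Integer matrix of labels (0 = background), with attribute
#'   `"n"` giving the number of components.
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask))
  mask <- mask & !is.na(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  parent <- integer(0)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  unite <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  nextlab <- 0L
  for (j in seq_len(nc)) {
    for (i in seq_len(nr)) {
      if (!mask[i, j]) next
      up <- if (i > 1 && mask[i - 1, j]) lab[i - 1, j] else 0L
      lf <- if (j > 1 && mask[i, j - 1]) lab[i, j - 1] else 0L
      ul <- if (connectivity == 8 && i > 1 && j > 1 && mask[i - 1, j - 1]) lab[i - 1, j - 1] else 0L
      ur <- if (connectivity == 8 && i < nr && j > 1 && mask[i + 1, j - 1]) lab[i + 1, j - 1] else 0L
      nb <- c(up, lf, ul, ur)
      nb <- nb[nb > 0L]
      if (length(nb) == 0) {
        nextlab <- nextlab + 1L
        parent[nextlab] <- nextlab
        lab[i, j] <- nextlab
      } else {
        m <- min(nb)
        lab[i, j] <- m
        for (o in nb) unite(m, o)
      }
    }
  }
  if (nextlab > 0L) {
    roots <- vapply(seq_len(nextlab), find, 0L)
    remap <- integer(nextlab)
    remap[sort(unique(roots))] <- seq_along(unique(roots))
    idx <- lab > 0L
    lab[idx] <- remap[roots[lab[idx]]]
    n <- max(remap)
  } else n <- 0L
  attr(lab, "n") <- as.integer(n)
  lab
}

#' Chamfer distance transform of a binary mask
#'
#' Approximate Euclidean distance (3-4 chamfer scaled to unit steps) from each
#' foreground pixel to the nearest background pixel.
#'
#' @param mask Logical matrix (TRUE = foreground).
#' @return Numeric matrix of distances (0 on background).
#' @export
distance_transform <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  big <- nr + nc + 1
  d <- matrix(0, nr, nc)
  d[mask] <- big
  s <- sqrt(2)
  # forward pass
  for (j in seq_len(nc)) {
    for (i in seq_len(nr)) {
      if (d[i, j] == 0) next
      v <- d[i, j]
      if (i > 1) v <- min(v, d[i - 1, j] + 1)
      if (j > 1) v <- min(v, d[i, j - 1] + 1)
      if (i > 1 && j > 1) v <- min(v, d[i - 1, j - 1] + s)
      if (i < nr && j > 1) v <- min(v, d[i + 1, j - 1] + s)
      d[i, j] <- v
    }
  }
  # backward pass
  for (j in rev(seq_len(nc))) {
    for (i in rev(seq_len(nr))) {
      if (d[i, j] == 0) next
      v <- d[i, j]
      if (i < nr) v <- min(v, d[i + 1, j] + 1)
      if (j < nc) v <- min(v, d[i, j + 1] + 1)
      if (i < nr && j < nc) v <- min(v, d[i + 1, j + 1] + s)
      if (i > 1 && j < nc) v <- min(v, d[i - 1, j + 1] + s)
      d[i, j] <- v
    }
  }
  d
}

#' Split touching objects by distance-transform watershed
#'
#' Markers are the connected plateaus of regional maxima of the distance
#' transform; foreground pixels are then flooded in order of decreasing
#' distance, each inheriting the label of an already-assigned neighbour.
#'
#' @param mask Logical matrix of foreground.
#' @param min_marker_distance Distance-transform value a marker plateau must
#'   reach before it seeds its own object (suppresses noise maxima).
#' @return Integer label matrix with attribute `"n"`.
#' @export
watershed_split <- function(mask, min_marker_distance = 2) {
  nr <- nrow(mask); nc <- ncol(mask)
  d <- distance_transform(mask)
  # regional maxima: pixel >= all 8 neighbours (plateau-tolerant)
  ismax <- mask & d >= min_marker_distance
  for (di in -1:1) {
    for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      sh <- matrix(-Inf, nr, nc)
      ri <- seq_len(nr) + di; cj <- seq_len(nc) + dj
      ok_r <- ri >= 1 & ri <= nr; ok_c <- cj >= 1 & cj <= nc
      sh[ok_r, ok_c] <- d[ri[ok_r], cj[ok_c]]
      ismax <- ismax & d >= sh
    }
  }
  markers <- label_components(ismax, connectivity = 8)
  nmark <- attr(markers, "n")
  if (nmark == 0) return(label_components(mask))
  lab <- matrix(0L, nr, nc)
  lab[markers > 0L] <- markers[markers > 0L]
  fg <- which(mask & lab == 0L)
  fg <- fg[order(d[fg], decreasing = TRUE)]
  # flooding; a pixel with no labeled neighbour yet is retried next sweep
  pending <- fg
  repeat {
    n_before <- length(pending)
    if (n_before == 0) break
    still <- integer(0)
    for (p in pending) {
      i <- ((p - 1) %% nr) + 1
      j <- ((p - 1) %/% nr) + 1
      best <- 0L; bestd <- -Inf
      for (di in -1:1) for (dj in -1:1) {
        if (di == 0 && dj == 0) next
        ii <- i + di; jj <- j + dj
        if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
        l <- lab[ii, jj]
        if (l > 0L && d[ii, jj] > bestd) { best <- l; bestd <- d[ii, jj] }
      }
      if (best > 0L) lab[p] <- best else still <- c(still, p)
    }
    if (length(still) == n_before) { # isolated plateau below marker cut
      lab[still[1]] <- nmark <- nmark + 1L
      still <- still[-1]
    }
    pending <- still
  }
  attr(lab, "n") <- as.integer(max(lab))
  lab
}

#' Separable Gaussian smoothing of a matrix
#'
#' Used by the synthetic generators to correlate noise into blob-like label.
#' Boundary columns/rows are renormalized (truncated kernel).
#'
#' @param x Numeric matrix.
#' @param sigma Gaussian standard deviation in pixels.
#' @return Smoothed matrix of the same dimensions.
#' @export
gaussian_blur <- function(x, sigma = 2) {
  if (sigma <= 0) return(x)
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-half:half, sd = sigma)
  smooth_axis <- function(m, n) {
    # banded Toeplitz blur matrix with edge renormalization
    B <- matrix(0, n, n)
    for (o in -half:half) {
      idx <- seq_len(n)
      tgt <- idx + o
      ok <- tgt >= 1 & tgt <= n
      B[cbind(idx[ok], tgt[ok])] <- k[o + half + 1]
    }
    B / rowSums(B)
  }
  Br <- smooth_axis(x, nrow(x))
  Bc <- smooth_axis(x, ncol(x))
  Br %*% x %*% t(Bc)
}

#' Region statistics for a label matrix
#' @keywords internal
#' @noRd
region_table <- function(labels) {
  n <- max(labels)
  if (n == 0) {
    return(data.frame(nucleus_id = integer(0), centroid_r = numeric(0),
                      centroid_c = numeric(0), area_px = integer(0)))
  }
  idx <- which(labels > 0L)
  l <- labels[idx]
  r <- ((idx - 1) %% nrow(labels)) + 1
  c <- ((idx - 1) %/% nrow(labels)) + 1
  data.frame(
    nucleus_id = seq_len(n),
    centroid_r = as.numeric(tapply(r, l, mean)),
    centroid_c = as.numeric(tapply(c, l, mean)),
    area_px = as.integer(tapply(r, l, length))
  )
}
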
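#' Slide tiling and tissue filtering
#'
#' Converts an RGB slide image into a non-overlapping grid of fixed-size
#' tiles and discards non-informative tiles whose tissue fraction falls
#' below a cutoff. Tissue is detected with Otsu's threshold on the slide's
#' grayscale intensity: pixels darker than the threshold are tissue, so a
#' blank (near-white) background contributes nothing.
#'
#' @name tiling
NULL

#' Otsu threshold of a set of intensities
#'
#' Maximizes the between-class variance over a 256-bin histogram of values
#' in `[0, 1]`. For a constant input there is no foreground/background
#' split; the minimum value is returned so that no pixel falls strictly
#' below the threshold.
#'
#' @param x Numeric vector or array of intensities in `[0, 1]`.
#' @param nbins Number of histogram bins.
#' @return Threshold in `[0, 1]`.
#' @export
otsu_threshold <- function(x, nbins = 256L) {
  x <- as.vector(x)
  if (diff(range(x)) == 0) return(min(x))
  breaks <- seq(0, 1, length.out = nbins + 1L)
  h <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE,
                             all.inside = TRUE), nbins)
  p <- h / sum(h)
  mids <- (breaks[-1L] + breaks[-(nbins + 1L)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  valid <- w0 > 0 & w0 < 1
  sigma_b <- rep(-Inf, nbins)
  sigma_b[valid] <- (mu_t * w0[valid] - mu[valid])^2 /
    (w0[valid] * (1 - w0[valid]))
  # the between-class variance is flat across empty bins between two
  # modes; take the centre of the plateau for a stable mid-gap threshold
  mean(mids[sigma_b >= max(sigma_b) - 1e-12])
}

rgb_to_gray <- function(img) {
  0.2125 * img[, , 1L] + 0.7154 * img[, , 2L] + 0.0721 * img[, , 3L]
}

#' Tile an RGB image into a fixed-size grid
#'
#' Tiles are laid out from the top-left origin with 0-based `row`/`col`
#' grid indices; tile (`row`, `col`) covers pixel offsets
#' `row * tile_size` and `col * tile_size`. Partial tiles at the right and
#' bottom edges are dropped.
#'
#' @param image Numeric array `height x width x 3` with values in `[0, 1]`.
#' @param tile_size Tile side in pixels; default 175, matching 20x
#'   whole-slide tiling.
#' @return List of tiles (`row`, `col`, `pixels`, `tissue_fraction = NA`)
#'   with attributes `n_rows`, `n_cols`, `tile_size`.
#' @export
tile_image <- function(image, tile_size = 175L) {
  d <- dim(image)
  if (length(d) != 3L || d[3L] != 3L)
    stop("image must be a height x width x 3 array")
  if (d[1L] < tile_size || d[2L] < tile_size)
    stop("image is smaller than one tile (", tile_size, " px)")
  n_rows <- d[1L] %/% tile_size
  n_cols <- d[2L] %/% tile_size
  tiles <- vector("list", n_rows * n_cols)
  k <- 0L
  for (r in seq_len(n_rows) - 1L) for (cc in seq_len(n_cols) - 1L) {
    k <- k + 1L
    tiles[[k]] <- list(
      row = r, col = cc,
      pixels = image[r * tile_size + seq_len(tile_size),
                     cc * tile_size + seq_len(tile_size), , drop = FALSE],
      tissue_fraction = NA_real_)
  }
  attr(tiles, "n_rows") <- n_rows
  attr(tiles, "n_cols") <- n_cols
  attr(tiles, "tile_size") <- tile_size
  tiles
}

#' Tissue fraction of a tile under a global threshold
#'
#' The threshold is computed once per slide (so tiles are comparable and a
#' uniform tile yields a well-defined fraction); tissue pixels are those
#' strictly darker than the threshold in grayscale.
#'
#' @param tile A tile from [tile_image()].
#' @param threshold Grayscale Otsu threshold of the whole slide.
#' @return Proportion of tissue pixels in `[0, 1]`.
#' @export
compute_tissue_fraction <- function(tile, threshold) {
  g <- rgb_to_gray(tile$pixels)
  mean(g < threshold)
}

#' Annotate all tiles with their tissue fractions
#'
#' @param tiles Tile list from [tile_image()].
#' @param image The source slide (used for the per-slide Otsu threshold);
#'   when omitted, the threshold is computed from the tiles' pixels.
#' @return The tile list with `tissue_fraction` filled in.
#' @export
annotate_tissue_fractions <- function(tiles, image = NULL) {
  gray_all <- if (is.null(image)) {
    unlist(lapply(tiles, function(t) rgb_to_gray(t$pixels)))
  } else rgb_to_gray(image)
  thr <- otsu_threshold(gray_all)
  out <- lapply(tiles, function(t) {
    t$tissue_fraction <- compute_tissue_fraction(t, thr)
    t
  })
  attributes(out) <- attributes(tiles)
  attr(out, "otsu_threshold") <- thr
  out
}

#' Filter tiles by minimum tissue fraction
#'
#' Tiles with `tissue_fraction` below `min_fraction` are excluded (the
#' boundary tile at exactly `min_fraction` is retained). Raising
#' `min_fraction` never adds tiles.
#'
#' @param tiles Tile list with fractions computed (see
#'   [annotate_tissue_fractions()]).
#' @param min_fraction Retention cutoff in `[0, 1]`; default 0.20.
#' @return List with `retained` (tile list) and `excluded` (data frame of
#'   `row`, `col`, `tissue_fraction`).
#' @export
filter_tiles <- function(tiles, min_fraction = 0.20) {
  if (!is.numeric(min_fraction) || min_fraction < 0 || min_fraction > 1)
    stop("min_fraction must lie in [0, 1]")
  fr <- vapply(tiles, function(t) t$tissue_fraction, 0)
  if (anyNA(fr)) stop("tissue fractions must be computed before filtering")
  keep <- fr >= min_fraction
  retained <- tiles[keep]
  attributes(retained) <- attributes(tiles)[c("n_rows", "n_cols",
                                              "tile_size")]
  excl <- data.frame(
    row = vapply(tiles[!keep], function(t) t$row, 0L),
    col = vapply(tiles[!keep], function(t) t$col, 0L),
    tissue_fraction = fr[!keep])
  list(retained = retained, excluded = excl)
}
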
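#' Generate a translating tile stack
#'
#' For each tile a smooth random scene (Gaussian-filtered white noise,
#' plus a few bright soma-like blobs) is sampled on a grid larger than the
#' tile by `margin` pixels on every side; frame `f` is the central window
#' displaced by `shifts[f, ]`, sampled bilinearly so subpixel shifts are
#' exact, with Gaussian pixel noise added.  Deterministic given `seed`.
#'
#' The shift convention matches [register_tile()]: frame `f` displaced by
#' `shifts[f, ]` aligns with the zero-shift template view.
#'
#' @param n_tiles Number of tiles.
#' @param n_frames Frames per tile.
#' @param shifts Matrix n_frames x 2 of `(dx, dy)` pixel shifts (or a
#'   2-vector recycled to all frames).
#' @param noise_sd Pixel noise SD (scene has SD about 1).
#' @param seed Integer seed.
#' @param tile_size Tile side (pixels).
#' @param margin Scene margin (pixels); shifts must not exceed it.
#' @param pixel_size Pixel size (um).
#' @return Object of class `vip_tiles`: `tiles` (list of
#'   tile_size x tile_size x n_frames arrays), `templates` (the zero-shift
#'   views), `shifts`, `pixel_size`.
#' @export
generate_tile_stack <- function(n_tiles, n_frames, shifts, noise_sd = 0.1,
                                seed = 1, tile_size = 48, margin = 8,
                                pixel_size = 1) {
  if (is.null(dim(shifts))) shifts <- matrix(shifts, n_frames, 2,
                                             byrow = TRUE)
  if (nrow(shifts) != n_frames) stop("shifts must have one row per frame")
  if (max(abs(shifts)) > margin) {
    stop("shift exceeds the tile margin (", margin, " px)")
  }
  with_seed(seed, {
    big <- tile_size + 2 * margin
    tiles <- vector("list", n_tiles)
    templates <- vector("list", n_tiles)
    for (ti in seq_len(n_tiles)) {
      scene <- blur2d(matrix(stats::rnorm(big^2), big, big), sigma = 2)
      # a few bright blobs so tiles have soma-like structure
      for (b in 1:3) {
        cy <- stats::runif(1, margin + 5, big - margin - 5)
        cx <- stats::runif(1, margin + 5, big - margin - 5)
        r2 <- outer((seq_len(big) - cy)^2, (seq_len(big) - cx)^2, "+")
        scene <- scene + 3 * exp(-r2 / (2 * 3^2))
      }
      scene <- scene / stats::sd(scene)
      arr <- array(0, c(tile_size, tile_size, n_frames))
      for (f in seq_len(n_frames)) {
        view <- bilinear_window(scene, margin + shifts[f, 2],
                                margin + shifts[f, 1], tile_size)
        arr[, , f] <- view + stats::rnorm(tile_size^2, 0, noise_sd)
      }
      tiles[[ti]] <- arr
      templates[[ti]] <- bilinear_window(scene, margin, margin, tile_size)
    }
    structure(list(tiles = tiles, templates = templates, shifts = shifts,
                   pixel_size = pixel_size),
              class = "vip_tiles")
  })
}

# Separable Gaussian blur with reflective boundaries.
blur2d <- function(img, sigma) {
  img <- apply(img, 2, smooth_gaussian, sigma = sigma)
  t(apply(img, 1, smooth_gaussian, sigma = sigma))
}

# Bilinear sample of a tile_size window whose top-left corner sits at
# (row0, col0) offsets (0-based, possibly fractional) into `scene`.
bilinear_window <- function(scene, row0, col0, tile_size) {
  rows <- row0 + seq_len(tile_size)
  cols <- col0 + seq_len(tile_size)
  r0 <- floor(rows); c0 <- floor(cols)
  fr <- rows - r0; fc <- cols - c0
  r1 <- pmin(r0 + 1L, nrow(scene)); c1 <- pmin(c0 + 1L, ncol(scene))
  a <- scene[r0, c0, drop = FALSE]; b <- scene[r0, c1, drop = FALSE]
  cc <- scene[r1, c0, drop = FALSE]; d <- scene[r1, c1, drop = FALSE]
  wa <- outer(1 - fr, 1 - fc); wb <- outer(1 - fr, fc)
  wc <- outer(fr, 1 - fc); wd <- outer(fr, fc)
  a * wa + b * wb + cc * wc + d * wd
}
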
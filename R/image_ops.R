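# Images are numeric arrays H x W x C with intensities in [0, 1].

#' Bilinear image resize
#'
#' @param img array H x W x C (or H x W matrix) in `[0, 1]`.
#' @param out_h,out_w output dimensions.
#' @return resized array.
#' @export
resize_bilinear <- function(img, out_h, out_w) {
  if (length(dim(img)) == 2) img <- array(img, c(dim(img), 1L))
  h <- dim(img)[1]; w <- dim(img)[2]; ch <- dim(img)[3]
  # align-corners-free sampling grid
  ys <- (seq_len(out_h) - 0.5) * h / out_h - 0.5
  xs <- (seq_len(out_w) - 0.5) * w / out_w - 0.5
  y0 <- pmin(pmax(floor(ys), 0), h - 1); y1 <- pmin(y0 + 1, h - 1)
  x0 <- pmin(pmax(floor(xs), 0), w - 1); x1 <- pmin(x0 + 1, w - 1)
  wy <- pmin(pmax(ys - y0, 0), 1); wx <- pmin(pmax(xs - x0, 0), 1)
  out <- array(0, c(out_h, out_w, ch))
  for (c in seq_len(ch)) {
    m <- img[, , c]
    a <- m[y0 + 1, x0 + 1, drop = FALSE]
    b <- m[y0 + 1, x1 + 1, drop = FALSE]
    d <- m[y1 + 1, x0 + 1, drop = FALSE]
    e <- m[y1 + 1, x1 + 1, drop = FALSE]
    top <- a * rep(1 - wx, each = out_h) + b * rep(wx, each = out_h)
    bot <- d * rep(1 - wx, each = out_h) + e * rep(wx, each = out_h)
    out[, , c] <- top * (1 - wy) + bot * wy
  }
  out
}

#' Stochastic training augmentation
#'
#' Applies, with the standard probabilities: a random resized crop with area
#' scale in `scale_range` (default 0.8-1.0, resized back to the input size),
#' horizontal flip (p = 0.5), vertical flip (p = 0.5), and joint
#' brightness/contrast jitter with factors in +/- 0.2 (p = 0.2).
#' Deterministic under `seed`.
#'
#' @param img array H x W x C in `[0, 1]`.
#' @param seed RNG seed (`NULL` uses the current stream).
#' @param scale_range crop area range.
#' @param hflip_p,vflip_p,jitter_p probabilities.
#' @param jitter_range brightness/contrast factor half-width.
#' @return augmented array, same shape, clipped to `[0, 1]`.
#' @export
augment_image <- function(img, seed = NULL, scale_range = c(0.8, 1.0),
                          hflip_p = 0.5, vflip_p = 0.5, jitter_p = 0.2,
                          jitter_range = 0.2) {
  run <- function() {
    h <- dim(img)[1]; w <- dim(img)[2]
    area <- stats::runif(1, scale_range[1], scale_range[2])
    side_f <- sqrt(area)
    ch2 <- max(1L, floor(side_f * h)); cw2 <- max(1L, floor(side_f * w))
    top <- sample.int(h - ch2 + 1L, 1L)
    left <- sample.int(w - cw2 + 1L, 1L)
    out <- img[top:(top + ch2 - 1L), left:(left + cw2 - 1L), , drop = FALSE]
    if (ch2 != h || cw2 != w) out <- resize_bilinear(out, h, w)
    if (stats::runif(1) < hflip_p) out <- out[, rev(seq_len(dim(out)[2])), , drop = FALSE]
    if (stats::runif(1) < vflip_p) out <- out[rev(seq_len(dim(out)[1])), , , drop = FALSE]
    if (stats::runif(1) < jitter_p) {
      br <- stats::runif(1, -jitter_range, jitter_range)
      ct <- stats::runif(1, -jitter_range, jitter_range)
      out <- (out - 0.5) * (1 + ct) + 0.5 + br
    }
    pmin(pmax(out, 0), 1)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Deterministic preprocessing to a model input tensor
#'
#' Resizes to `side x side`, rescales 0-255 intensities to 0-1 when needed,
#' then normalizes each channel with mean 0.5 and std 0.5, giving values in
#' `[-1, 1]`.
#'
#' @param img array H x W x C, values in `[0, 1]` or `[0, 255]`.
#' @param side output side length.
#' @return array `side x side x C` in `[-1, 1]`.
#' @export
preprocess <- function(img, side) {
  if (length(dim(img)) == 2) img <- array(img, c(dim(img), 1L))
  if (max(img) > 1 + 1e-9) img <- img / 255
  if (dim(img)[1] != side || dim(img)[2] != side)
    img <- resize_bilinear(img, side, side)
  (img - 0.5) / 0.5
}

#' Load a manifest's images as a preprocessed feature matrix
#'
#' @param manifest data frame from [read_manifest()] (or a subset).
#' @param side model input side.
#' @param base_dir directory that image paths are relative to.
#' @return numeric matrix, one flattened preprocessed image per row, rownames
#'   = image paths.
#' @export
load_images <- function(manifest, side, base_dir = ".") {
  mats <- lapply(manifest$image_path, function(p) {
    fp <- file.path(base_dir, p)
    if (!file.exists(fp)) stop("cannot read image: ", fp, call. = FALSE)
    img <- png::readPNG(fp)
    as.vector(preprocess(img, side))
  })
  m <- do.call(rbind, mats)
  rownames(m) <- manifest$image_path
  m
}
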
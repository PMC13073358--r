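# Preprocessing, augmentation and patch-sequence geometry --------------------

#' Augmentation configuration
#'
#' Training-time augmentation: horizontal/vertical flips, rotation up to
#' +/-20 degrees, translation up to 10% of the frame per axis, and
#' brightness/contrast jitter. Validation and test images are never
#' augmented (`enabled = FALSE` makes [augment()] the identity).
#'
#' @param p_hflip,p_vflip Flip probabilities in \[0,1\].
#' @param rot_deg_max Maximum absolute rotation in degrees.
#' @param translate_frac_max Maximum absolute translation as a fraction of
#'   width/height, in \[0,1).
#' @param brightness_jitter,contrast_jitter Length-2 `(lo, hi)` multiplicative
#'   scale ranges; `c(1, 1)` disables the jitter.
#' @param enabled Master switch.
#' @return An `aug_config` list.
#' @export
aug_config <- function(p_hflip = 0.5, p_vflip = 0.5, rot_deg_max = 20,
                       translate_frac_max = 0.10,
                       brightness_jitter = c(0.8, 1.2),
                       contrast_jitter = c(0.8, 1.2),
                       enabled = TRUE) {
  if (p_hflip < 0 || p_hflip > 1 || p_vflip < 0 || p_vflip > 1) {
    stopf("flip probabilities must lie in [0, 1]")
  }
  if (rot_deg_max < 0) stopf("rot_deg_max must be non-negative")
  if (translate_frac_max < 0 || translate_frac_max >= 1) {
    stopf("translate_frac_max must lie in [0, 1)")
  }
  structure(
    list(p_hflip = p_hflip, p_vflip = p_vflip, rot_deg_max = rot_deg_max,
         translate_frac_max = translate_frac_max,
         brightness_jitter = as.double(brightness_jitter),
         contrast_jitter = as.double(contrast_jitter), enabled = enabled),
    class = "aug_config"
  )
}

# Decode a PNG/JPEG into an H x W x 3 array in [0, 1].
read_image_file <- function(path) {
  a <- tryCatch({
    if (grepl("\\.png$", tolower(path))) {
      png::readPNG(path)
    } else {
      img <- EBImage::readImage(path)
      d <- EBImage::imageData(img)
      if (length(dim(d)) == 2) t(d) else aperm(d, c(2, 1, 3))
    }
  }, error = function(e) stopf("cannot read image file '%s': %s", path, conditionMessage(e)))
  if (length(dim(a)) == 2) a <- array(a, c(dim(a), 1))
  if (dim(a)[3] >= 4) a <- a[, , 1:3, drop = FALSE]
  if (dim(a)[3] == 1) a <- array(rep(a[, , 1], 3), c(dim(a)[1:2], 3))
  a
}

# Bilinear resize of an H x W x 3 array (EBImage operates in x,y order).
resize_bilinear <- function(img, h, w) {
  if (dim(img)[1] == h && dim(img)[2] == w) return(img)
  out <- EBImage::resize(EBImage::Image(aperm(img, c(2, 1, 3)), colormode = "Color"),
                         w = w, h = h)
  aperm(EBImage::imageData(out), c(2, 1, 3))
}

#' Deterministic preprocessing: RGB, resize, per-image min-max normalization
#'
#' Accepts a file path (PNG/JPEG) or an H x W x C array. Grayscale input is
#' replicated to three channels, the image is bilinearly resized to
#' `target_size` x `target_size`, and intensities are rescaled to \[0,1\] by
#' per-image min-max normalization, by default with one minimum and one
#' maximum taken jointly over all three channels. A constant image (max ==
#' min) maps to all zeros rather than dividing by zero; such frames are
#' expected to be excluded by upstream quality screens.
#'
#' @param x File path or numeric array.
#' @param target_size Output side length in pixels.
#' @param per_channel Normalize each channel with its own min/max instead of
#'   joint normalization.
#' @return `target_size` x `target_size` x 3 array in \[0,1\].
#' @export
preprocess <- function(x, target_size = 224, per_channel = FALSE) {
  img <- if (is.character(x)) read_image_file(x) else x
  if (length(dim(img)) == 2) img <- array(img, c(dim(img), 1))
  if (dim(img)[3] == 1) img <- array(rep(img[, , 1], 3), c(dim(img)[1:2], 3))
  if (!all(is.finite(img))) stopf("image contains non-finite values")
  img <- resize_bilinear(img, target_size, target_size)
  norm1 <- function(v) {
    lo <- min(v); hi <- max(v)
    if (hi - lo <= 0) v * 0 else (v - lo) / (hi - lo)
  }
  if (per_channel) {
    for (ch in 1:3) img[, , ch] <- norm1(img[, , ch])
    img
  } else {
    array(norm1(img), dim(img))
  }
}

# Reflect a real-valued coordinate into [1, n] (mirror boundary).
reflect_coord <- function(v, n) {
  if (n == 1) return(rep(1, length(v)))
  period <- 2 * (n - 1)
  v <- abs(v - 1) %% period
  ifelse(v > n - 1, period - v, v) + 1
}

# Bilinear sampling of img under rotation (degrees, about the center) plus
# translation (pixels), with reflection padding so no empty corners appear.
affine_sample <- function(img, angle_deg, ty, tx) {
  h <- dim(img)[1]; w <- dim(img)[2]
  th <- angle_deg * pi / 180
  cs <- cos(th); sn <- sin(th)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  yg <- matrix(seq_len(h), h, w) - cy - ty
  xg <- matrix(seq_len(w), h, w, byrow = TRUE) - cx - tx
  sy <- -sn * xg + cs * yg + cy
  sx <- cs * xg + sn * yg + cx
  sy <- reflect_coord(sy, h); sx <- reflect_coord(sx, w)
  y0 <- floor(sy); x0 <- floor(sx)
  wy <- sy - y0; wx <- sx - x0
  y0 <- pmin(pmax(y0, 1), h); x0 <- pmin(pmax(x0, 1), w)
  y1 <- pmin(y0 + 1, h); x1 <- pmin(x0 + 1, w)
  out <- img
  for (ch in seq_len(dim(img)[3])) {
    layer <- img[, , ch]
    v00 <- layer[cbind(c(y0), c(x0))]; v01 <- layer[cbind(c(y0), c(x1))]
    v10 <- layer[cbind(c(y1), c(x0))]; v11 <- layer[cbind(c(y1), c(x1))]
    out[, , ch] <- matrix(
      v00 * (1 - c(wy)) * (1 - c(wx)) + v01 * (1 - c(wy)) * c(wx) +
        v10 * c(wy) * (1 - c(wx)) + v11 * c(wy) * c(wx), h, w)
  }
  out
}

#' Stochastic training-time augmentation
#'
#' Applies, in order: horizontal flip, vertical flip, rotation uniform in
#' +/-`rot_deg_max`, translation uniform in +/-`translate_frac_max` per
#' axis (rotation and translation share one bilinear resampling pass with
#' reflection padding), then multiplicative brightness jitter and contrast
#' jitter about the image mean. Output is clipped to \[0,1\]. With
#' `enabled = FALSE`, or with all flip probabilities and ranges zeroed, the
#' input is returned unchanged.
#'
#' @param image H x W x 3 array in \[0,1\].
#' @param cfg An [aug_config()].
#' @param seed Optional integer making the draw reproducible.
#' @return Augmented image, same shape and range.
#' @export
augment <- function(image, cfg = aug_config(), seed = NULL) {
  if (!cfg$enabled) return(image)
  draw <- function() {
    list(u_h = stats::runif(1), u_v = stats::runif(1),
         rot = stats::runif(1, -cfg$rot_deg_max, cfg$rot_deg_max),
         ty = stats::runif(1, -cfg$translate_frac_max, cfg$translate_frac_max),
         tx = stats::runif(1, -cfg$translate_frac_max, cfg$translate_frac_max),
         sb = stats::runif(1, cfg$brightness_jitter[1], cfg$brightness_jitter[2]),
         sc = stats::runif(1, cfg$contrast_jitter[1], cfg$contrast_jitter[2]))
  }
  d <- if (is.null(seed)) draw() else with_seed(seed, draw())
  h <- dim(image)[1]; w <- dim(image)[2]
  out <- image
  if (d$u_h < cfg$p_hflip) out <- out[, rev(seq_len(w)), , drop = FALSE]
  if (d$u_v < cfg$p_vflip) out <- out[rev(seq_len(h)), , , drop = FALSE]
  if (d$rot != 0 || d$ty != 0 || d$tx != 0) {
    out <- affine_sample(out, d$rot, d$ty * h, d$tx * w)
  }
  if (d$sb != 1) out <- out * d$sb
  if (d$sc != 1) {
    m <- mean(out)
    out <- (out - m) * d$sc + m
  }
  out[out < 0] <- 0; out[out > 1] <- 1
  out
}

#' Patch-grid geometry
#'
#' @param image_size,patch_size Side lengths in pixels; `patch_size` must
#'   divide `image_size`.
#' @return List with `image_size`, `patch_size`, `n_side`, `n_patches`.
#' @export
patch_grid <- function(image_size, patch_size) {
  if (image_size %% patch_size != 0) {
    stopf("patch_size %d does not divide image_size %d", patch_size, image_size)
  }
  n_side <- image_size %/% patch_size
  list(image_size = image_size, patch_size = patch_size,
       n_side = n_side, n_patches = n_side^2)
}

#' Split an image into a row-major sequence of flattened patches
#'
#' Patch `i` (0-based) covers pixel rows `floor(i / n_side) * P` onward and
#' columns `(i %% n_side) * P` onward (half-open, P pixels each). Each patch
#' is flattened to a length `P*P*3` vector; [unpatchify()] inverts the
#' operation exactly.
#'
#' @param image H x W x 3 array; `patch_size` must divide H and W.
#' @param patch_size Patch side length P.
#' @return `n_patches` x `(P*P*3)` matrix.
#' @export
patchify <- function(image, patch_size) {
  h <- dim(image)[1]; w <- dim(image)[2]
  if (h %% patch_size != 0 || w %% patch_size != 0) {
    stopf("patch_size %d does not divide image dimensions %dx%d", patch_size, h, w)
  }
  P <- patch_size
  nr <- h %/% P; nc <- w %/% P
  a <- array(image, c(P, nr, P, nc, 3))        # (pr, block_row, pc, block_col, ch)
  b <- aperm(a, c(1, 3, 5, 4, 2))              # (pr, pc, ch, block_col, block_row)
  t(matrix(b, nrow = P * P * 3, ncol = nr * nc))
}

#' Reassemble an image from its patch sequence
#'
#' @param patches Matrix produced by [patchify()].
#' @param image_size Side length of the original (square) image.
#' @param patch_size Patch side length used to produce `patches`.
#' @return `image_size` x `image_size` x 3 array.
#' @export
unpatchify <- function(patches, image_size, patch_size) {
  P <- patch_size
  n_side <- image_size %/% P
  if (nrow(patches) != n_side^2 || ncol(patches) != P * P * 3) {
    stopf("patch matrix has wrong shape for a %dpx image with %dpx patches",
          image_size, patch_size)
  }
  b <- array(t(patches), c(P, P, 3, n_side, n_side))
  a <- aperm(b, c(1, 5, 2, 4, 3))              # (pr, block_row, pc, block_col, ch)
  array(a, c(image_size, image_size, 3))
}
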
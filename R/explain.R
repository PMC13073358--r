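# Score-CAM attribution over final-block token maps --------------------------
#
# Gradient-free attribution: each embedding channel of the final transformer
# block's patch tokens is reshaped to the patch grid, normalized, upsampled
# to input resolution, and used to mask the input; the change in the target
# class's softmax score between the masked image and an all-zero baseline
# weighs that channel's map. The rectified weighted sum, min-max normalized
# to [0,1], is the heatmap.

#' Reshape final-block patch tokens into spatial activation maps
#'
#' Channel `c` of the token matrix, reshaped row-major to the patch grid,
#' yields map `c` (row-major matches the patch order of [patchify()]).
#'
#' @param patch_tokens `n_patches` x D matrix (no \[CLS\] row), e.g. from
#'   [vit_encode()].
#' @param grid A [patch_grid()].
#' @return `n_side` x `n_side` x D array of activation maps.
#' @export
token_activation_maps <- function(patch_tokens, grid) {
  n <- nrow(patch_tokens)
  ns <- round(sqrt(n))
  if (ns^2 != n) stopf("token count %d is not a perfect square", n)
  if (!missing(grid) && ns != grid$n_side) {
    stopf("token count %d does not match grid with n_side %d", n, grid$n_side)
  }
  D <- ncol(patch_tokens)
  maps <- array(0, c(ns, ns, D))
  for (ch in seq_len(D)) {
    maps[, , ch] <- matrix(patch_tokens[, ch], ns, ns, byrow = TRUE)
  }
  maps
}

minmax01 <- function(m) {
  lo <- min(m); hi <- max(m)
  if (hi - lo <= 0) m * 0 else (m - lo) / (hi - lo)
}

upsample_map <- function(m, size) {
  if (nrow(m) == size) return(m)
  out <- EBImage::resize(EBImage::Image(t(m)), w = size, h = size)
  t(EBImage::imageData(out))
}

#' Score-CAM heatmap for one image
#'
#' For each selected activation channel: min-max normalize its spatial map,
#' bilinearly upsample it to input resolution, multiply the input image by
#' it (all three channels), and re-forward the masked image through the
#' model in evaluation mode. The channel weight is the target class's
#' softmax score on the masked image minus its score on an all-zero
#' baseline image. The heatmap is `max(0, sum_c w_c * map_c)`, min-max
#' normalized to \[0,1\]; if every weight is non-positive the map is all
#' zeros. To bound the number of re-forwards, the `top_k` channels with the
#' largest spatial variance are used by default.
#'
#' @param model A `stagevit_model`.
#' @param image Preprocessed `image_size` x `image_size` x 3 array.
#' @param target_class Ordinal class in 0..3, or `NULL` for the model's
#'   predicted class.
#' @param top_k Number of activation channels to score (clipped with a
#'   warning if it exceeds the embedding width).
#' @return A `stagevit_heatmap`: `values` (H x W in \[0,1\]),
#'   `target_class`, `weights`, `channels`.
#' @export
score_cam <- function(model, image, target_class = NULL, top_k = 64L) {
  cfg <- model$config
  S <- cfg$image_size
  patches <- patchify(image, cfg$patch_size)
  fw <- forward_batch(model, list(patches), train = FALSE)
  if (is.null(target_class)) target_class <- which.max(fw$probs[1, ]) - 1L
  if (!(target_class %in% (seq_len(cfg$n_classes) - 1L))) {
    stopf("target_class must be in 0..%d", cfg$n_classes - 1L)
  }
  maps <- token_activation_maps(fw$patch_tokens, cfg$grid)
  # score_fn: masked images -> target-class softmax scores, batched re-forward
  score_fn <- function(images) {
    plist <- lapply(images, patchify, patch_size = cfg$patch_size)
    forward_batch(model, plist, train = FALSE)$probs[, target_class + 1L]
  }
  hm <- score_cam_core(maps, image, score_fn, top_k)
  hm$target_class <- as.integer(target_class)
  hm
}

# Shared Score-CAM pipeline over an arbitrary scoring function: normalize and
# upsample each selected map, mask the input with it, score all masked images
# plus an all-zero baseline in one call, and return the rectified normalized
# weighted sum. Also exercised directly by closed-form toy models in tests.
score_cam_core <- function(maps, image, score_fn, top_k) {
  S <- dim(image)[1]
  D <- dim(maps)[3]
  if (top_k > D) {
    warning(sprintf("top_k = %d exceeds %d channels; using all channels", top_k, D))
    top_k <- D
  }
  vars <- apply(maps, 3, function(m) stats::var(as.vector(m)))
  channels <- order(vars, decreasing = TRUE)[seq_len(top_k)]
  ups <- lapply(channels, function(ch) upsample_map(minmax01(maps[, , ch]), S))
  masked <- lapply(ups, function(m) image * array(rep(m, 3), c(S, S, 3)))
  scores <- score_fn(c(masked, list(array(0, c(S, S, 3)))))
  w <- scores[seq_len(top_k)] - scores[top_k + 1L]
  acc <- matrix(0, S, S)
  for (j in seq_len(top_k)) acc <- acc + w[j] * ups[[j]]
  acc[acc < 0] <- 0
  structure(
    list(values = minmax01(acc), target_class = NA_integer_,
         weights = w, channels = channels, image_id = NA_character_),
    class = "stagevit_heatmap"
  )
}

#' Heatmap-mask overlap concordance
#'
#' The high-activation region is `A = {heatmap >= binarize_thresh}`; the
#' overlap fraction is `|A intersect mask| / |A|` (0 when A is empty), and
#' the heatmap is concordant when the fraction is at least `tau`
#' (boundary inclusive).
#'
#' @param heatmap A `stagevit_heatmap` or an H x W matrix in \[0,1\].
#' @param mask H x W binary lesion mask.
#' @param binarize_thresh Activation threshold defining the high region.
#' @param tau Minimum overlap fraction for concordance.
#' @return A `concordance_result`: `overlap_fraction`, `concordant`,
#'   `binarize_thresh`, `tau`.
#' @export
overlap_concordance <- function(heatmap, mask, binarize_thresh = 0.5, tau = 0.5) {
  v <- if (inherits(heatmap, "stagevit_heatmap")) heatmap$values else heatmap
  if (!all(dim(v) == dim(mask))) stopf("heatmap and mask dimensions differ")
  A <- v >= binarize_thresh
  nA <- sum(A)
  frac <- if (nA == 0) 0 else sum(A & (mask > 0)) / nA
  structure(list(overlap_fraction = frac, concordant = frac >= tau,
                 binarize_thresh = binarize_thresh, tau = tau),
            class = "concordance_result")
}

#' Render a color overlay of a heatmap on its image
#'
#' The heatmap is colorized on a cool-to-warm ramp (blue = low attribution,
#' red = high) and alpha-blended over the image; output values stay in
#' \[0,1\].
#'
#' @param heatmap A `stagevit_heatmap` or H x W matrix in \[0,1\].
#' @param image H x W x 3 array in \[0,1\].
#' @param alpha Blend weight of the colorized heatmap.
#' @return H x W x 3 RGB array.
#' @export
overlay_heatmap <- function(heatmap, image, alpha = 0.45) {
  v <- if (inherits(heatmap, "stagevit_heatmap")) heatmap$values else heatmap
  if (!all(dim(v) == dim(image)[1:2])) stopf("heatmap and image dimensions differ")
  ramp <- grDevices::colorRamp(c("#00004C", "#0000FF", "#00FFFF",
                                 "#FFFF00", "#FF8C00", "#FF0000"))
  cols <- ramp(as.vector(v)) / 255
  h <- dim(image)[1]; w <- dim(image)[2]
  out <- image
  for (ch in 1:3) {
    out[, , ch] <- (1 - alpha) * image[, , ch] + alpha * matrix(cols[, ch], h, w)
  }
  out[out < 0] <- 0; out[out > 1] <- 1
  out
}

#' Score-CAM concordance over a record set
#'
#' Computes one heatmap per record (for the predicted class by default) and
#' scores it against the record's ground-truth lesion mask. Records without
#' a mask, or with an empty mask, are skipped.
#'
#' @param model A `stagevit_model`.
#' @param records List of `image_record`s with masks.
#' @param target_class Fixed target class, or `NULL` for per-image predicted.
#' @param top_k,binarize_thresh,tau See [score_cam()] and
#'   [overlap_concordance()].
#' @return List with `results` (data frame: image_id, label,
#'   overlap_fraction, concordant), `rate` (mean concordance), and
#'   `heatmaps` (list, for reuse e.g. against permuted masks).
#' @export
concordance_eval <- function(model, records, target_class = NULL, top_k = 64L,
                             binarize_thresh = 0.5, tau = 0.5) {
  keep <- vapply(records, function(r) !is.null(r$mask) && sum(r$mask) > 0, logical(1))
  records <- records[keep]
  if (length(records) == 0) stopf("no records with non-empty lesion masks")
  cfg <- model$config
  heatmaps <- vector("list", length(records))
  rows <- vector("list", length(records))
  for (i in seq_along(records)) {
    r <- records[[i]]
    img <- preprocess(r$pixels, cfg$image_size)
    hm <- score_cam(model, img, target_class = target_class, top_k = top_k)
    hm$image_id <- r$image_id
    heatmaps[[i]] <- hm
    cc <- overlap_concordance(hm, r$mask, binarize_thresh, tau)
    rows[[i]] <- data.frame(image_id = r$image_id, label = r$label,
                            overlap_fraction = cc$overlap_fraction,
                            concordant = cc$concordant, stringsAsFactors = FALSE)
  }
  results <- do.call(rbind, rows)
  list(results = results, rate = mean(results$concordant), heatmaps = heatmaps,
       records = records)
}
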
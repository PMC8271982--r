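#' Bilinear upsampling of a small heat grid
#'
#' Upsamples a matrix by bilinear interpolation with half-pixel center
#' alignment (an output pixel center at row i maps to input coordinate
#' \code{(i - 0.5) * nrow(in) / nrow(out) - 0.5}, clamped to the grid).
#'
#' @param m numeric matrix.
#' @param outH,outW output dimensions.
#' @return numeric \code{outH x outW} matrix.
#' @keywords internal
upsampleBilinear <- function(m, outH, outW) {
  inH <- nrow(m); inW <- ncol(m)
  yi <- pmin(pmax((seq_len(outH) - 0.5) * inH / outH - 0.5, 0), inH - 1)
  xi <- pmin(pmax((seq_len(outW) - 0.5) * inW / outW - 0.5, 0), inW - 1)
  y0 <- pmin(floor(yi), inH - 1); y1 <- pmin(y0 + 1, inH - 1)
  x0 <- pmin(floor(xi), inW - 1); x1 <- pmin(x0 + 1, inW - 1)
  wy <- yi - y0; wx <- xi - x0
  out <- matrix(0, outH, outW)
  for (j in seq_len(outW)) {
    a <- m[, x0[j] + 1] * (1 - wx[j]) + m[, x1[j] + 1] * wx[j]
    out[, j] <- a[y0 + 1] * (1 - wy) + a[y1 + 1] * wy
  }
  out
}

#' Class activation map of an action image
#'
#' Because the network ends in global average pooling followed by a single
#' fully connected layer, the evidence for class c localizes in image space
#' as the weighted sum of the final convolution's feature maps,
#' \deqn{CAM_c(h, w) = \sum_k w_{kc} F_k(h, w),}
#' where \eqn{F_k} are the 256 post-ReLU feature maps (spatial size 3 x 8)
#' and \eqn{w_{kc}} the head weights for class c. The raw map is bilinearly
#' upsampled to the 15 x 32 image grid and min--max scaled to [0, 1] for
#' display; rows then correspond to joints of the model's ordering and
#' columns to frames, so the map shows which joints, at which times, drove
#' the prediction.
#'
#' @param model a [TrainedModel-class].
#' @param image an [ActionImage-class] matching the model's ordering.
#' @param class class label to explain; defaults to the predicted class.
#' @return list with \code{class}, \code{raw} (the 3 x 8 weighted sum),
#'   \code{map} (15 x 32, scaled to [0, 1]; all zeros if the raw map is
#'   constant) and \code{probabilities}.
#' @export
classActivationMap <- function(model, image, class = NULL) {
  stopifnot(is(image, "ActionImage"))
  .checkImageOrdering(model, list(image))
  fw <- .cnn_forward(model@params, .imagesToMatrix(list(image)),
                     want_fmaps = TRUE)
  probs <- drop(fw$probs)
  names(probs) <- model@classes
  if (is.null(class)) class <- model@classes[which.max(probs)]
  k <- match(class, model@classes)
  if (is.na(k))
    stop(sprintf("unknown class '%s'; model classes: %s", class,
                 paste(model@classes, collapse = ", ")))
  # fmaps: [24 * 256 x 1], per channel a 3 x 8 grid (column-major)
  fm <- array(fw$fmaps[, 1], dim = c(3L, 8L, 256L))
  w <- model@params$Wfc[, k]
  raw <- matrix(0, 3, 8)
  for (ch in seq_len(256)) raw <- raw + w[ch] * fm[, , ch]
  up <- upsampleBilinear(raw, 15L, 32L)
  rng <- range(up)
  map <- if (diff(rng) > 0) (up - rng[1]) / diff(rng) else matrix(0, 15, 32)
  list(class = class, raw = raw, map = map, probabilities = probs)
}
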
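# Appearance normalization and optical-flow stream generation.
#
# Day-recorded videos are "nightified": each channel of a day frame is
# scaled by the corresponding mean channel value of the night (infrared)
# recordings, i.e. out_c = in_c * ref_c / 255, which maps [0,255] input
# through the [0,1] normalized weighting and back. The flow stream encodes
# Farneback dense flow between consecutive frames either as a 3-channel
# HSV-rendered image (hue = direction, value = magnitude) so that both
# streams share one channel geometry, or as raw 2-channel (dx, dy) fields.

#' Mean night-video channel reference
#'
#' Per-channel arithmetic mean over all pixels of all frames of all supplied
#' night-recorded sequences, on the `[0, 255]` scale.
#'
#' @param night_videos List of [frame_sequence()] objects (3-channel).
#' @return Numeric length-3 vector `c(R, G, B)`.
#' @export
compute_night_reference <- function(night_videos) {
  if (inherits(night_videos, "frame_sequence")) night_videos <- list(night_videos)
  if (!length(night_videos) || !sum(vapply(night_videos, length, integer(1))))
    stop("compute_night_reference: need at least one non-empty night video")
  sums <- c(0, 0, 0); n <- 0
  for (sq in night_videos) {
    for (f in sq$frames) {
      if (dim(f)[3] != 3L) stop("night reference requires 3-channel frames")
      sums <- sums + c(sum(f[, , 1]), sum(f[, , 2]), sum(f[, , 3]))
      n <- n + prod(dim(f)[1:2])
    }
  }
  sums / n
}

#' Nightify a day-recorded frame
#'
#' @param frame `H x W x 3` array on `[0, 255]`.
#' @param ref Night reference triple from [compute_night_reference()].
#' @return `H x W x 3` array, `round(frame * ref / 255)`, in `[0, 255]`.
#' @export
nightify_frame <- function(frame, ref) {
  if (length(dim(frame)) != 3L || dim(frame)[3] != 3L)
    stop("nightify_frame: expected an H x W x 3 frame (nightify before grayscale)")
  stopifnot(length(ref) == 3, all(ref >= 0), all(ref <= 255))
  out <- frame
  for (cc in 1:3) out[, , cc] <- round(frame[, , cc] * ref[cc] / 255)
  out
}

#' Nightify every frame of a sequence (no-op for night videos)
#' @param seq A [frame_sequence()].
#' @param ref Night reference triple.
#' @return The nightified [frame_sequence()].
#' @export
nightify_sequence <- function(seq, ref) {
  if (seq$is_night) return(seq)
  seq$frames <- lapply(seq$frames, nightify_frame, ref = ref)
  seq
}

#' Luminance grayscale conversion (ITU-R 601 weights)
#'
#' @param frame `H x W x 3` array.
#' @return `H x W x 1` array, `round(0.299 R + 0.587 G + 0.114 B)`.
#' @export
to_grayscale <- function(frame) {
  if (length(dim(frame)) != 3L || dim(frame)[3] != 3L)
    stop("to_grayscale: expected an H x W x 3 frame")
  g <- round(0.299 * frame[, , 1] + 0.587 * frame[, , 2] + 0.114 * frame[, , 3])
  array(g, c(dim(frame)[1:2], 1L))
}

#' Dense optical-flow stream for a frame sequence
#'
#' Farneback dense flow is computed for each consecutive frame pair (the
#' flow at step t describes motion from frame t to frame t + 1), then
#' encoded for the flow input stream.
#'
#' @param seq A [frame_sequence()] with at least two frames.
#' @param encoding `"hsv3"` (default; direction as hue, magnitude as value,
#'   3 channels matching the RGB stream) or `"raw2"` (dx, dy channels).
#' @param params Farneback solver settings; see [farneback_flow()].
#' @param mag_scale Magnitude (pixels) mapped to full value in the HSV
#'   encoding.
#' @return List of flow fields, each a list with `dx`, `dy` (`H x W`
#'   matrices) and `frame` (`H x W x C` encoded array on `[0, 255]`).
#' @export
compute_flow_stream <- function(seq, encoding = c("hsv3", "raw2"),
                                params = farneback_params(), mag_scale = 8) {
  stopifnot(inherits(seq, "frame_sequence"))
  encoding <- match.arg(encoding)
  if (length(seq) < 2) stop("compute_flow_stream: need at least 2 frames")
  gray <- lapply(seq$frames, function(f)
    if (dim(f)[3] == 1L) f[, , 1] else 0.299 * f[, , 1] + 0.587 * f[, , 2] + 0.114 * f[, , 3])
  lapply(seq_len(length(seq) - 1L), function(i) {
    fl <- farneback_flow(gray[[i]], gray[[i + 1L]], params)
    fl$frame <- encode_flow(fl$dx, fl$dy, encoding, mag_scale)
    fl
  })
}

#' @noRd
encode_flow <- function(dx, dy, encoding = "hsv3", mag_scale = 8) {
  if (encoding == "raw2") {
    out <- array(0, c(dim(dx), 2L))
    # centered at 128 so the shared [0,255] -> [0,1] normalization applies
    out[, , 1] <- pmin(pmax(128 + dx * 127 / mag_scale, 0), 255)
    out[, , 2] <- pmin(pmax(128 + dy * 127 / mag_scale, 0), 255)
    return(out)
  }
  mag <- sqrt(dx^2 + dy^2)
  ang <- atan2(dy, dx)            # [-pi, pi]
  h <- (ang + pi) / (2 * pi)      # hue in [0, 1)
  v <- pmin(mag / mag_scale, 1)
  hsv_to_rgb255(h, rep(1, length(h)), v, dim(dx))
}

# Vectorized HSV -> RGB on [0,255]; h, s, v are equal-length vectors.
hsv_to_rgb255 <- function(h, s, v, dims) {
  h6 <- (h * 6) %% 6
  i <- floor(h6)
  f <- h6 - i
  p <- v * (1 - s)
  q <- v * (1 - s * f)
  t <- v * (1 - s * (1 - f))
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  out <- array(0, c(dims, 3L))
  out[, , 1] <- round(r * 255); out[, , 2] <- round(g * 255)
  out[, , 3] <- round(b * 255)
  out
}
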
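# Frame-sequence handling: spatial standardization, temporal downsampling
# and cuboid assembly.
#
# Frames are H x W x C numeric arrays on the [0, 255] scale (C = 3 for RGB,
# C = 1 for grayscale). A frame sequence bundles an ordered list of
# same-shaped frames with acquisition metadata; cuboids are T x H x W x C
# arrays normalized to [0, 1] with a behavior label and a provenance record.

#' Construct a frame sequence
#'
#' @param frames List of `H x W x C` numeric arrays, values in `[0, 255]`.
#'   A single `F x H x W x C` array is also accepted and unpacked.
#' @param fps Frames per second of the source recording.
#' @param source_id Identifier of the source video.
#' @param is_night Whether the video was recorded at night (infrared).
#' @return A `frame_sequence` object.
#' @export
frame_sequence <- function(frames, fps = 30, source_id = "video",
                           is_night = FALSE) {
  if (is.array(frames) && length(dim(frames)) == 4L) {
    frames <- lapply(seq_len(dim(frames)[1]), function(i) {
      f <- frames[i, , , , drop = FALSE]
      array(f, dim(frames)[2:4])
    })
  }
  stopifnot(is.list(frames))
  if (length(frames)) {
    d1 <- dim(frames[[1]])
    if (length(d1) == 2L) {
      frames <- lapply(frames, function(f) array(f, c(dim(f), 1L)))
      d1 <- dim(frames[[1]])
    }
    ok <- vapply(frames, function(f) identical(dim(f), d1), logical(1))
    if (!all(ok)) stop("all frames in a sequence must share one shape")
    if (!d1[3] %in% c(1L, 3L)) stop("frames must have 1 or 3 channels")
  }
  structure(list(frames = frames, fps = fps, source_id = source_id,
                 is_night = isTRUE(is_night)),
            class = "frame_sequence")
}

#' @export
length.frame_sequence <- function(x) length(x$frames)

#' @export
print.frame_sequence <- function(x, ...) {
  d <- if (length(x)) paste(dim(x$frames[[1]]), collapse = "x") else "empty"
  cat(sprintf("<frame_sequence '%s': %d frames (%s), %g fps%s>\n",
              x$source_id, length(x), d, x$fps,
              if (x$is_night) ", night" else ""))
  invisible(x)
}

#' Resize a frame and crop it vertically to the standard geometry
#'
#' The frame is first resized (bilinear) to a square `W x W` raster matching
#' the target width, then the rows above and below a centered band of the
#' target height are removed, yielding the standard 96 x 128 input geometry
#' by default (128 x 128 resize, 16 rows off the top and bottom).
#'
#' @param frame `H x W x C` (or `H x W`) numeric array.
#' @param target_hw Target `c(height, width)`; default `c(96, 128)`.
#' @return Array `target_hw[1] x target_hw[2] x C`; dtype/scale preserved.
#' @export
resize_and_crop <- function(frame, target_hw = c(96L, 128L)) {
  if (is.null(dim(frame)) || any(dim(frame)[1:2] == 0))
    stop("resize_and_crop: zero-sized frame")
  if (length(dim(frame)) == 2L) dim(frame) <- c(dim(frame), 1L)
  th <- target_hw[1]; tw <- target_hw[2]
  resized <- resize_bilinear(frame, tw, tw)
  margin <- (tw - th) %/% 2L
  resized[(margin + 1L):(margin + th), , , drop = FALSE]
}

# Bilinear resize of an H x W x C array via EBImage (x = width layout there).
resize_bilinear <- function(frame, out_h, out_w) {
  d <- dim(frame)
  out <- array(0, c(out_h, out_w, d[3]))
  for (cc in seq_len(d[3])) {
    img <- EBImage::as.Image(t(frame[, , cc]))
    r <- EBImage::resize(img, w = out_w, h = out_h, filter = "bilinear")
    out[, , cc] <- t(EBImage::imageData(r))
  }
  out
}

#' Temporal downsampling of a frame sequence
#'
#' Keeps frames at indices 0, `interval`, `2 * interval`, ... (zero-based),
#' the five-frame-interval subsampling of the reference pipeline.
#'
#' @param seq A [frame_sequence()].
#' @param interval Keep one frame in every `interval` (default 5).
#' @return The downsampled [frame_sequence()].
#' @export
temporal_downsample <- function(seq, interval = 5L) {
  stopifnot(inherits(seq, "frame_sequence"))
  if (interval < 1) stop("temporal_downsample: interval must be >= 1")
  keep <- seq_along(seq$frames)[(seq_along(seq$frames) - 1L) %% interval == 0L]
  out <- seq
  out$frames <- seq$frames[keep]
  attr(out, "kept_indices") <- keep
  out
}

#' Per-clip label from per-frame annotations
#'
#' Majority vote over the window's frame labels; ties are broken by the
#' label of the temporally central frame (index `floor(T/2)`, zero-based).
#'
#' @param window_labels Vector of per-frame class labels.
#' @return The single label assigned to the window.
#' @export
assign_label <- function(window_labels) {
  if (!length(window_labels)) stop("assign_label: empty label window")
  tab <- table(window_labels)
  winners <- names(tab)[tab == max(tab)]
  if (length(winners) == 1L) {
    w <- winners
  } else {
    central <- window_labels[[length(window_labels) %/% 2L + 1L]]
    w <- if (as.character(central) %in% winners) as.character(central) else winners[1]
  }
  if (is.numeric(window_labels)) as.numeric(w) else w
}

#' Assemble labeled spatiotemporal cuboids from a downsampled sequence
#'
#' Consecutive non-overlapping windows of `T` frames become cuboids; a
#' trailing remainder shorter than `T` is discarded. Pixel values are
#' normalized to `[0, 1]` at assembly.
#'
#' @param seq A (typically downsampled) [frame_sequence()].
#' @param labels Per-frame class labels, same length as `seq`.
#' @param T Temporal length of each cuboid (default 8).
#' @return List of cuboids; each is a list with `data` (`T x H x W x C`
#'   array in `[0, 1]`), `label`, and `origin` (source id, start index).
#' @export
extract_cuboids <- function(seq, labels, T = 8L) {
  stopifnot(inherits(seq, "frame_sequence"))
  if (length(labels) != length(seq))
    stop("extract_cuboids: need one label per frame (",
         length(labels), " labels for ", length(seq), " frames)")
  if (T < 1) stop("extract_cuboids: T must be >= 1")
  n_win <- length(seq) %/% T
  if (n_win == 0L) return(list())
  d <- dim(seq$frames[[1]])
  lapply(seq_len(n_win), function(w) {
    idx <- ((w - 1L) * T + 1L):(w * T)
    data <- array(0, c(T, d))
    for (i in seq_along(idx)) data[i, , , ] <- seq$frames[[idx[i]]] / 255
    list(data = data,
         label = assign_label(labels[idx]),
         origin = list(source_id = seq$source_id, start = idx[1] - 1L))
  })
}

#' Dataset split container
#'
#' @param train,validation,test Lists of cuboids (see [extract_cuboids()]).
#' @return A `dataset_split` with per-split class counts.
#' @export
dataset_split <- function(train = list(), validation = list(), test = list()) {
  counts <- function(cubs) {
    if (!length(cubs)) return(table(character(0)))
    table(vapply(cubs, function(cb) as.character(cb$label), character(1)))
  }
  structure(list(train = train, validation = validation, test = test,
                 class_counts = list(train = counts(train),
                                     validation = counts(validation),
                                     test = counts(test))),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split: %d train / %d validation / %d test cuboids>\n",
              length(x$train), length(x$validation), length(x$test)))
  invisible(x)
}

#' Persist a dataset split to disk and read it back
#'
#' The store is a single-file container holding the cuboid arrays, labels,
#' origins and class counts; the round trip is lossless (arrays compare
#' bitwise equal).
#'
#' @param split A [dataset_split()].
#' @param path File path for the store.
#' @return `write_cuboid_store` returns `path` invisibly;
#'   `read_cuboid_store` returns the [dataset_split()].
#' @export
write_cuboid_store <- function(split, path) {
  stopifnot(inherits(split, "dataset_split"))
  payload <- list(format = "hcn-cuboid-store", version = 1L, split = split)
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname write_cuboid_store
#' @export
read_cuboid_store <- function(path) {
  if (!file.exists(path))
    stop("cuboid store not found: ", path)
  payload <- tryCatch(readRDS(path),
                      error = function(e) stop("corrupt cuboid store at ",
                                               path, ": ", conditionMessage(e)))
  if (!identical(payload$format, "hcn-cuboid-store"))
    stop("not a cuboid store: ", path)
  payload$split
}

#' Leave-one-video-out cross-validation plan
#'
#' One fold per source video: that video is the test set, the remainder the
#' training set (the n = 12 protocol of the reference dataset).
#'
#' @param videos Character vector of video identifiers (no duplicates).
#' @return List of folds, each `list(train = ..., test = ...)`.
#' @export
loocv_plan <- function(videos) {
  if (anyDuplicated(videos)) stop("loocv_plan: duplicate video ids")
  if (length(videos) < 2) stop("loocv_plan: need at least two videos")
  lapply(seq_along(videos), function(i)
    list(train = videos[-i], test = videos[i]))
}
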
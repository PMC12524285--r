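# Keypoint-guided region-of-interest routing. The mouth-region crop is a
# fixed-size window centered on the mouth keypoint; the full-body input is
# the detection box expanded to a square (with a context margin) and resized
# to the network resolution. Both windows are held fixed at their keyframe
# position across all sampled frames of one sample, so that body translation
# and mouth-patch dynamics remain visible as image motion.

#' Crop a fixed-size square patch centered on a point
#'
#' The window is centered on the (rounded) keypoint pixel; when the point
#' lies within `size/2` of a border the window is clamped inside the frame
#' (keeping the output size constant), and when the frame itself is smaller
#' than `size` the patch is zero-padded symmetrically.
#'
#' @param frame Array of dim `c(H, W, C)`.
#' @param center `c(x, y)` in pixels or a [keypoint()]; a keypoint with
#'   `visible = 0` is an error (callers fall back to the full body).
#' @param size Patch side length in pixels (128 in the full-resolution
#'   setup).
#' @return Array of dim `c(size, size, C)`.
#' @export
crop_region <- function(frame, center, size = 128L) {
  size <- as.integer(size)
  if (size < 1L) stop("crop size must be >= 1")
  if (inherits(center, "satsn_keypoint") ||
      (!is.null(names(center)) && "visible" %in% names(center))) {
    if (center[["visible"]] == 0)
      stop("cannot crop around an absent keypoint (visible = 0)")
    center <- c(center[["x"]], center[["y"]])
  }
  d <- dim(frame)
  H <- d[1L]; W <- d[2L]; C <- if (length(d) >= 3L) d[3L] else 1L
  cxi <- round(center[1L]); cyi <- round(center[2L])
  half <- size %/% 2L
  take <- function(ci, n) {
    if (n >= size) {
      s <- min(max(ci - half, 1L), n - size + 1L)
      list(src = s:(s + size - 1L), dst = seq_len(size))
    } else {
      pad <- (size - n) %/% 2L
      list(src = seq_len(n), dst = pad + seq_len(n))
    }
  }
  ix <- take(cxi, W); iy <- take(cyi, H)
  out <- array(0, dim = c(size, size, C))
  fr <- if (length(d) == 2L) array(frame, dim = c(H, W, 1L)) else frame
  out[iy$dst, ix$dst, ] <- fr[iy$src, ix$src, , drop = FALSE]
  out
}

#' Sample slow- and fast-pathway frame indices
#'
#' The slow pathway takes `T` frames at temporal stride `tau`; the fast
#' pathway takes `alpha * T` frames uniformly spaced over the same
#' `T * tau`-frame window. The window is centered in the clip unless a
#' `center` frame (e.g. a keyframe) is given.
#'
#' @param n_frames Clip length.
#' @param T,tau,alpha Sampling parameters (see [satsn_config()]).
#' @param center Optional window center frame index.
#' @return List with integer vectors `slow` (length `T`) and `fast`
#'   (length `alpha * T`).
#' @export
sample_two_stream_frames <- function(n_frames, T, tau, alpha, center = NULL) {
  need <- T * tau
  if (n_frames < need)
    stop(sprintf("clip too short: %d frames, need at least %d (T * tau)",
                 n_frames, need))
  start <- if (is.null(center)) (n_frames - need) %/% 2L + 1L
           else as.integer(center) - need %/% 2L
  if (start < 1L || start + need - 1L > n_frames)
    stop(sprintf("sampling window [%d, %d] does not fit clip of %d frames",
                 start, start + need - 1L, n_frames))
  slow <- start + (seq_len(T) - 1L) * tau
  fast <- as.integer(round(seq(start, start + need - 1L,
                               length.out = alpha * T)))
  list(slow = slow, fast = fast)
}

resize_frame <- function(img, size) {
  d <- dim(img)
  if (d[1L] == size && d[2L] == size) return(img)
  out <- EBImage::resize(img, w = size, h = size)
  array(as.numeric(out), dim = c(size, size, d[3L]))
}

#' Route a clip sample into slow/fast two-stream inputs
#'
#' Implements the spatial-adaptive input strategy. In training mode
#' (`label_hint` given) the mouth crop is substituted only for samples
#' labeled licking with a visible mouth keypoint, per scheme; all other
#' samples use the full-body window in both pathways. In inference mode
#' (`label_hint = NULL`) the scheme is applied whenever the keypoint is
#' visible, with a full-body fallback otherwise; the decision is recorded
#' in the content tags. Scheme A always feeds the full body to both
#' pathways; scheme B feeds the mouth crop to the fast pathway; scheme C
#' feeds it to the slow pathway.
#'
#' @param clip A [video_clip()].
#' @param body_box A [bbox()] (pixels) at the keyframe.
#' @param mouth_kp A [keypoint()] at the keyframe.
#' @param scheme `"A"`, `"B"` or `"C"`.
#' @param config A [satsn_config()] (supplies `T`, `tau`, `alpha`,
#'   `crop_size`).
#' @param input_size Network input resolution (pixels); both pathway stacks
#'   are resized to `input_size x input_size`.
#' @param label_hint Ground-truth behavior name in training mode, else
#'   `NULL`.
#' @param center_frame Keyframe index (window center); defaults to the clip
#'   center.
#' @param context_scale Factor by which the body box is expanded (about its
#'   center, to a square) before cropping; keeps translational motion of a
#'   walking animal inside the fixed window.
#' @return Object of class `two_stream_input`: list with `slow`, `fast`
#'   (arrays `input_size x input_size x 3 x n`), `scheme`, `clip_id`,
#'   `slow_content`, `fast_content` (`"full_body"` or `"mouth_crop"`), and
#'   the sampled `frames`.
#' @export
route_inputs <- function(clip, body_box, mouth_kp, scheme = "B",
                         config = satsn_config(), input_size = 32L,
                         label_hint = NULL, center_frame = NULL,
                         context_scale = 2) {
  validate_bbox(body_box)
  if (!scheme %in% c("A", "B", "C")) stop("unknown routing scheme: ", scheme)
  idx <- sample_two_stream_frames(length(clip$frames), config$T, config$tau,
                                  config$alpha, center = center_frame)
  visible <- mouth_kp[["visible"]] > 0
  use_crop <- if (scheme == "A") FALSE
              else if (!visible) FALSE
              else if (is.null(label_hint)) TRUE
              else identical(label_hint, "licking")
  body_center <- c((body_box[["x1"]] + body_box[["x2"]]) / 2,
                   (body_box[["y1"]] + body_box[["y2"]]) / 2)
  side <- max(body_box[["x2"]] - body_box[["x1"]],
              body_box[["y2"]] - body_box[["y1"]]) * context_scale
  side <- max(2L, as.integer(round(side)))
  full_stack <- function(frame_idx) {
    arr <- array(0, dim = c(input_size, input_size, 3L, length(frame_idx)))
    for (i in seq_along(frame_idx)) {
      patch <- crop_region(clip$frames[[frame_idx[i]]], body_center, side)
      arr[, , , i] <- resize_frame(patch, input_size)
    }
    arr
  }
  crop_stack <- function(frame_idx) {
    ctr <- c(mouth_kp[["x"]], mouth_kp[["y"]])
    arr <- array(0, dim = c(input_size, input_size, 3L, length(frame_idx)))
    for (i in seq_along(frame_idx)) {
      patch <- crop_region(clip$frames[[frame_idx[i]]], ctr, config$crop_size)
      arr[, , , i] <- resize_frame(patch, input_size)
    }
    arr
  }
  slow_content <- if (scheme == "C" && use_crop) "mouth_crop" else "full_body"
  fast_content <- if (scheme == "B" && use_crop) "mouth_crop" else "full_body"
  structure(list(
    slow = if (slow_content == "mouth_crop") crop_stack(idx$slow) else full_stack(idx$slow),
    fast = if (fast_content == "mouth_crop") crop_stack(idx$fast) else full_stack(idx$fast),
    scheme = scheme, clip_id = clip$clip_id,
    slow_content = slow_content, fast_content = fast_content,
    frames = idx), class = "two_stream_input")
}
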
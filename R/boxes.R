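# Box overlap measures shared by the tracker and the evaluation layer.
# Boxes are numeric c(x1, y1, x2, y2) or n x 4 matrices.

#' Intersection over union and generalized IoU
#'
#' `iou` lies in `[0, 1]`; `giou` subtracts the enclosing-box slack and
#' lies in `(-1, 1]`, with `giou <= iou` always and `giou < 0` for
#' sufficiently separated boxes.
#'
#' @param a,b Boxes `c(x1, y1, x2, y2)` in pixels.
#' @return Scalar overlap value.
#' @export
iou <- function(a, b) {
  iw <- min(a[3L], b[3L]) - max(a[1L], b[1L])
  ih <- min(a[4L], b[4L]) - max(a[2L], b[2L])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  inter / (box_area(a) + box_area(b) - inter)
}

#' @rdname iou
#' @export
giou <- function(a, b) {
  iw <- max(0, min(a[3L], b[3L]) - max(a[1L], b[1L]))
  ih <- max(0, min(a[4L], b[4L]) - max(a[2L], b[2L]))
  inter <- iw * ih
  union <- box_area(a) + box_area(b) - inter
  cw <- max(a[3L], b[3L]) - min(a[1L], b[1L])
  ch <- max(a[4L], b[4L]) - min(a[2L], b[2L])
  encl <- cw * ch
  inter / union - (encl - union) / encl
}

box_area <- function(b) {
  if (is.matrix(b)) (b[, 3L] - b[, 1L]) * (b[, 4L] - b[, 2L])
  else (b[3L] - b[1L]) * (b[4L] - b[2L])
}

# Pairwise IoU between the rows of two n x 4 / m x 4 matrices.
iou_matrix <- function(A, B) {
  n <- nrow(A); m <- nrow(B)
  out <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m))
    out[i, j] <- iou(A[i, ], B[j, ])
  out
}

giou_matrix <- function(A, B) {
  n <- nrow(A); m <- nrow(B)
  out <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m))
    out[i, j] <- giou(A[i, ], B[j, ])
  out
}
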
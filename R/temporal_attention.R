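# Temporal attention: per-frame reweighting of fast-pathway features.
# Frame descriptors are obtained by average and max pooling over channels
# and space (preserving the temporal axis), passed through a shared
# two-layer bottleneck (reduce T -> T/r, ReLU, expand T/r -> T, no biases),
# summed over the two pooled branches, and squashed with a sigmoid into a
# weight vector M of length T with entries in (0, 1). With all weights zero
# the logits vanish and M = 0.5 exactly, which is the closed-form identity
# limit used as a unit-test anchor.

#' Temporal-attention parameters
#'
#' @param T Number of frames the block operates on.
#' @param r Reduction ratio (integer >= 1 dividing `T`).
#' @param init `"zero"` for the identity limit, `"random"` for a seeded
#'   Gaussian initialization.
#' @param sd Standard deviation of the random initialization.
#' @return List of class `ta_params` with `Wn` (`T/r x T`, reducing) and
#'   `Wm` (`T x T/r`, expanding).
#' @export
ta_params <- function(T, r = 2L, init = c("zero", "random"), sd = 0.1) {
  init <- match.arg(init)
  if (r < 1L || T %% r != 0L)
    stop("reduction ratio r must be a positive integer dividing T")
  Tr <- T %/% r
  if (init == "zero") {
    Wn <- matrix(0, Tr, T); Wm <- matrix(0, T, Tr)
  } else {
    Wn <- matrix(stats::rnorm(Tr * T, 0, sd), Tr, T)
    Wm <- matrix(stats::rnorm(T * Tr, 0, sd), T, Tr)
  }
  structure(list(Wn = Wn, Wm = Wm, T = as.integer(T), r = as.integer(r)),
            class = "ta_params")
}

#' Temporal descriptors of a feature map
#'
#' Compresses a feature map to one average and one max value per frame by
#' pooling over channels and space.
#'
#' @param X Array of dim `c(C, H, W, T)` (frames along the last axis).
#' @return List with numeric vectors `avg` and `max`, each of length `T`
#'   (`avg <= max` elementwise).
#' @export
temporal_descriptor <- function(X) {
  d <- dim(X)
  if (is.null(d) || length(d) != 4L || any(d < 1L))
    stop("X must be a non-empty array of dim c(C, H, W, T)")
  Xm <- matrix(X, prod(d[1:3]), d[4L])
  list(avg = colMeans(Xm), max = apply(Xm, 2L, max))
}

#' Temporal-attention forward pass
#'
#' Computes `M = sigmoid(Wm ReLU(Wn avg) + Wm ReLU(Wn max))`: the shared
#' bottleneck is applied to both pooled descriptors (reduction first, then
#' expansion) and the branch outputs are summed before the sigmoid.
#'
#' @param X Feature array of dim `c(C, H, W, T)`.
#' @param params A [ta_params()].
#' @return Numeric vector `M` of length `T` with entries in (0, 1).
#' @export
ta_forward <- function(X, params) {
  ta_fwd_full(X, params)$M
}

ta_fwd_full <- function(X, params) {
  d <- dim(X)
  if (d[4L] != params$T)
    stop("feature map has ", d[4L], " frames but params expect ", params$T)
  Xm <- matrix(X, prod(d[1:3]), d[4L])
  avg <- colMeans(Xm)
  arg <- apply(Xm, 2L, which.max)
  mx <- Xm[cbind(arg, seq_len(d[4L]))]
  a1 <- as.vector(params$Wn %*% avg); h1 <- pmax(a1, 0)
  a2 <- as.vector(params$Wn %*% mx);  h2 <- pmax(a2, 0)
  logits <- as.vector(params$Wm %*% h1) + as.vector(params$Wm %*% h2)
  M <- sigmoid(logits)
  list(M = M, cache = list(Xm = Xm, avg = avg, mx = mx, arg = arg,
                           a1 = a1, h1 = h1, a2 = a2, h2 = h2,
                           logits = logits, dims = d))
}

#' Apply temporal weights to a feature map
#'
#' @param X Feature array of dim `c(C, H, W, T)`.
#' @param M Weight vector of length `T`.
#' @return Array of the same shape with frame `t` scaled by `M[t]`.
#' @export
apply_ta <- function(X, M) {
  d <- dim(X)
  if (length(M) != d[4L]) stop("length(M) must equal the number of frames")
  array(matrix(X, prod(d[1:3]), d[4L]) %*% diag(M, length(M)), dim = d)
}

# Backward through Y = X * M(X) given dY; returns dX, dWn, dWm.
ta_bwd <- function(dy, params, fwd) {
  cc <- fwd$cache; d <- cc$dims
  chw <- prod(d[1:3])
  dYm <- matrix(dy, chw, d[4L])
  M <- fwd$M
  dM <- colSums(dYm * cc$Xm)
  dXm <- dYm * matrix(M, chw, d[4L], byrow = TRUE)
  dlog <- dM * M * (1 - M)
  dWm <- outer(dlog, cc$h1) + outer(dlog, cc$h2)
  dh1 <- as.vector(crossprod(params$Wm, dlog)) * (cc$a1 > 0)
  dh2 <- as.vector(crossprod(params$Wm, dlog)) * (cc$a2 > 0)
  dWn <- outer(dh1, cc$avg) + outer(dh2, cc$mx)
  davg <- as.vector(crossprod(params$Wn, dh1))
  dmax <- as.vector(crossprod(params$Wn, dh2))
  dXm <- dXm + matrix(davg / chw, chw, d[4L], byrow = TRUE)
  dXm[cbind(cc$arg, seq_len(d[4L]))] <-
    dXm[cbind(cc$arg, seq_len(d[4L]))] + dmax
  list(dx = array(dXm, dim = d), dWn = dWn, dWm = dWm)
}
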
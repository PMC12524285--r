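# Desk-scale training loop: plain SGD with momentum (defaults 4 / 200 /
# 0.02 / 0.9 following the published setup, all overridable), seeded
# shuffling and initialization, and photometric/geometric augmentation
# applied identically to both pathways of a sample.

augment_sample <- function(sample, max_rot = 15, p_flip = 0.5,
                           brightness = 0.1, contrast = 0.15) {
  flip <- stats::runif(1L) < p_flip
  ang <- stats::runif(1L, -max_rot, max_rot)
  br <- stats::runif(1L, -brightness, brightness)
  ct <- stats::runif(1L, 1 - contrast, 1 + contrast)
  tf <- function(arr) {
    d <- dim(arr)
    if (flip) arr <- arr[, d[2L]:1L, , , drop = FALSE]
    if (abs(ang) > 0.01) {
      flat <- array(arr, dim = c(d[1L], d[2L], d[3L] * d[4L]))
      rot <- EBImage::rotate(flat, ang, output.dim = c(d[1L], d[2L]),
                             bg.col = 0)
      arr <- array(as.numeric(rot), dim = d)
    }
    pmin(pmax((arr - 0.5) * ct + 0.5 + br, 0), 1)
  }
  sample$slow <- tf(sample$slow)
  sample$fast <- tf(sample$fast)
  sample
}

#' Train a SATSN model
#'
#' Cross-entropy loss minimized by SGD with momentum over routed
#' two-stream samples. Fully reproducible: the same seed gives the same
#' initialization, shuffling, augmentation draws and hence the same loss
#' curve and final parameters.
#'
#' @param samples List of routed inputs (each with `slow` and `fast`
#'   arrays, e.g. from [route_inputs()]).
#' @param labels Integer class labels in `1..num_classes`.
#' @param arch A [satsn_arch_config()].
#' @param epochs,batch_size,learning_rate,momentum Training
#'   hyperparameters; defaults follow [satsn_config()].
#' @param seed Integer seed.
#' @param augment Apply rotation/flip/brightness-contrast augmentation to
#'   training samples.
#' @param clip_norm Global gradient-norm clipping threshold (set `Inf` to
#'   disable).
#' @param verbose Print the per-epoch loss.
#' @return A `satsn_model` with attribute `log`, a data.frame of
#'   `epoch`, `loss`, `lr`.
#' @export
train_satsn <- function(samples, labels, arch = satsn_arch_config("tiny"),
                        epochs = 200L, batch_size = 4L, learning_rate = 0.02,
                        momentum = 0.9, seed = 1L, augment = TRUE,
                        clip_norm = 5, verbose = FALSE) {
  if (!length(samples)) stop("empty training set")
  if (length(labels) != length(samples))
    stop("labels and samples lengths differ")
  model <- init_satsn(arch, seed = seed)
  plain <- param_tree(model$params)
  vel <- tree_zero(plain)
  n <- length(samples)
  log <- data.frame(epoch = integer(), loss = numeric(), lr = numeric())
  with_seed(seed + 7L, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      starts <- seq(1L, n, by = batch_size)
      for (b in starts) {
        ids <- ord[b:min(b + batch_size - 1L, n)]
        gsum <- NULL
        for (i in ids) {
          s <- samples[[i]]
          if (augment) s <- augment_sample(s)
          lg <- satsn_loss_grad(model, s, labels[i])
          if (!is.finite(lg$loss))
            stop("non-finite loss at epoch ", ep, ", sample ", i,
                 "; lower the learning rate")
          ep_loss <- ep_loss + lg$loss
          gp <- grad_tree(lg$grads)
          gsum <- if (is.null(gsum)) gp else tree_map2(`+`, gsum, gp)
        }
        gavg <- tree_map2(function(g, k) g / k, gsum, length(ids))
        if (is.finite(clip_norm)) {
          sq <- 0
          walk <- function(x) {
            if (is.numeric(x)) sq <<- sq + sum(x^2)
            else for (e in x) walk(e)
          }
          walk(gavg)
          gn <- sqrt(sq)
          if (gn > clip_norm)
            gavg <- tree_map2(function(g, k) g * k, gavg, clip_norm / gn)
        }
        vel <- tree_map2(function(v, g) momentum * v - learning_rate * g,
                         vel, gavg)
        plain <- tree_map2(`+`, plain, vel)
        model$params <- restore_params(model$params, plain)
      }
      log <- rbind(log, data.frame(epoch = ep, loss = ep_loss / n,
                                   lr = learning_rate))
      if (verbose) message(sprintf("epoch %3d  loss %.4f", ep, ep_loss / n))
    }
  })
  attr(model, "log") <- log
  model
}

#' Predict class probabilities for routed samples
#'
#' @param model A `satsn_model`.
#' @param samples List of routed inputs.
#' @return Matrix (`length(samples) x num_classes`) of probabilities.
#' @export
satsn_predict <- function(model, samples) {
  K <- model$arch$num_classes
  out <- t(vapply(samples, function(s) satsn_fwd(model, s)$probs, numeric(K)))
  colnames(out) <- satsn_action_names[seq_len(K)]
  out
}

# ---- checkpoints ------------------------------------------------------------

ser_tree <- function(x) {
  if (inherits(x, "ta_params"))
    return(list(kind = "ta", T = x$T, r = x$r,
                Wn = ser_tree(x$Wn), Wm = ser_tree(x$Wm)))
  if (is.numeric(x))
    return(list(kind = "num", dim = as.integer(dim(x)), data = as.numeric(x)))
  list(kind = "list", names = names(x), items = lapply(x, ser_tree))
}

deser_tree <- function(x) {
  if (x$kind == "num") {
    v <- as.numeric(unlist(x$data))
    d <- as.integer(unlist(x$dim))
    if (length(d) == 2L) return(matrix(v, d[1L], d[2L]))
    if (length(d) > 2L) return(array(v, dim = d))
    return(v)
  }
  if (x$kind == "ta") {
    p <- list(Wn = deser_tree(x$Wn), Wm = deser_tree(x$Wm),
              T = as.integer(x$T), r = as.integer(x$r))
    class(p) <- "ta_params"
    return(p)
  }
  items <- lapply(x$items, deser_tree)
  names(items) <- unlist(x$names)
  items
}

#' Save / load a model checkpoint
#'
#' Single-file JSON archive with a versioned header carrying the
#' architecture configuration, the seed, and all parameters.
#'
#' @param model A `satsn_model`.
#' @param path Checkpoint path.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the reconstructed `satsn_model`.
#' @export
save_checkpoint <- function(model, path) {
  obj <- list(format = "satsn-checkpoint", version = 1L,
              arch = unclass(model$arch), seed = model$seed,
              params = ser_tree(model$params))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$format, "satsn-checkpoint"))
    stop("not a satsn checkpoint: ", path)
  args <- lapply(obj$arch, function(v) if (is.list(v)) unlist(v) else v)
  arch <- do.call(satsn_arch_config, c(list(profile = "default"),
    args[setdiff(names(args), "fast_channels")]))
  structure(list(arch = arch, params = deser_tree(obj$params),
                 seed = as.integer(obj$seed)),
            class = "satsn_model")
}
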
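# The spatial-adaptive two-stream network. Slow pathway: tubelet-token
# embedding plus a joint space-time ViT encoder. Fast pathway: 3x3x3
# convolution stages with reduced (beta-scaled) channel counts, spatial
# stride 2 per stage, no temporal downsampling, and a temporal-attention
# block after every stage. Stage-wise lateral connections pool each fast
# stage to the slow token grid, project it linearly and add it to the
# tokens after a configured ViT block. The head concatenates mean-pooled
# slow tokens with globally pooled final fast features and applies a linear
# softmax classifier over the four behaviors.

#' SATSN architecture configuration
#'
#' The published description fixes the two-stream layout but not the
#' capacity numbers; these defaults are the package's own. The `"tiny"`
#' profile (embed_dim 64, depth 2, 32 px inputs) is the desk-scale
#' configuration used for CPU training on synthetic scenes.
#'
#' @param profile `"default"` or `"tiny"`.
#' @param input_size Side length of both pathway inputs (pixels).
#' @param tubelet `c(t, h, w)` spatio-temporal patch size of the slow
#'   pathway.
#' @param embed_dim Token embedding dimension (divisible by `n_heads`).
#' @param depth Number of ViT encoder blocks.
#' @param n_heads Attention heads.
#' @param mlp_ratio Hidden width of the block MLP relative to `embed_dim`.
#' @param base_channels Nominal per-stage channel plan `C` of a full-width
#'   pathway; the fast pathway uses `round(beta * base_channels)`.
#' @param beta Fast-pathway channel fraction.
#' @param fusion_after ViT block indices after which each fast stage fuses
#'   laterally (length = number of stages).
#' @param T Slow-pathway frame count.
#' @param alpha Fast/slow frame-rate ratio.
#' @param ta_r Temporal-attention reduction ratio.
#' @param num_classes Number of behavior classes.
#' @return List of class `satsn_arch`.
#' @export
satsn_arch_config <- function(profile = c("default", "tiny"),
                              input_size = NULL, tubelet = c(2L, 16L, 16L),
                              embed_dim = NULL, depth = NULL, n_heads = 4L,
                              mlp_ratio = 4L, base_channels = c(64L, 128L),
                              beta = 1 / 8, fusion_after = NULL,
                              T = 4L, alpha = 4L, ta_r = 2L,
                              num_classes = 4L) {
  profile <- match.arg(profile)
  if (is.null(input_size)) input_size <- if (profile == "tiny") 32L else 128L
  if (is.null(embed_dim)) embed_dim <- if (profile == "tiny") 64L else 128L
  if (is.null(depth)) depth <- if (profile == "tiny") 2L else 4L
  if (is.null(fusion_after))
    fusion_after <- if (profile == "tiny") c(1L, 2L) else c(2L, 4L)
  fast_channels <- pmax(1L, as.integer(round(beta * base_channels)))
  arch <- list(input_size = as.integer(input_size),
               tubelet = as.integer(tubelet),
               embed_dim = as.integer(embed_dim), depth = as.integer(depth),
               n_heads = as.integer(n_heads), mlp_ratio = as.integer(mlp_ratio),
               base_channels = as.integer(base_channels), beta = beta,
               fast_channels = fast_channels,
               fusion_after = as.integer(fusion_after),
               T = as.integer(T), alpha = as.integer(alpha),
               ta_r = as.integer(ta_r), num_classes = as.integer(num_classes))
  validate_arch(arch)
  class(arch) <- "satsn_arch"
  arch
}

validate_arch <- function(a) {
  if (a$embed_dim %% a$n_heads != 0L)
    stop("embed_dim must be divisible by n_heads")
  if (a$input_size %% a$tubelet[2L] != 0L || a$input_size %% a$tubelet[3L] != 0L)
    stop("input_size must be divisible by the spatial tubelet size")
  if (a$T %% a$tubelet[1L] != 0L)
    stop("T must be divisible by the temporal tubelet size")
  if (length(a$fusion_after) != length(a$fast_channels))
    stop("need one fusion point per fast stage")
  if (any(a$fusion_after < 1L) || any(a$fusion_after > a$depth))
    stop("fusion points must index ViT blocks in 1..depth")
  Hs <- a$input_size
  Hp <- a$input_size %/% a$tubelet[2L]
  for (s in seq_along(a$fast_channels)) {
    Hs <- Hs %/% 2L
    if (Hs < 1L) stop("input smaller than the total spatial downsampling")
    if (Hs %% Hp != 0L)
      stop("fast stage ", s, " feature size ", Hs,
           " does not pool evenly to the token grid ", Hp)
  }
  Tf <- a$alpha * a$T
  if (Tf %% a$ta_r != 0L) stop("ta_r must divide the fast frame count")
  Tp <- a$T %/% a$tubelet[1L]
  if (a$T %% Tp != 0L) stop("temporal token grid mismatch")
  invisible(a)
}

token_grid <- function(arch) {
  c(arch$input_size %/% arch$tubelet[2L],
    arch$input_size %/% arch$tubelet[3L],
    arch$T %/% arch$tubelet[1L])
}

#' Initialize a SATSN model
#'
#' Seeded Gaussian initialization (convolutions He-scaled, transformer
#' weights at sd 0.02, lateral projections at zero so the network starts as
#' a pure two-pathway model, temporal attention at small random values to
#' avoid its zero saddle point).
#'
#' @param arch A [satsn_arch_config()].
#' @param seed Integer seed; recorded on the model.
#' @return List of class `satsn_model` with `arch`, `params`, `seed`.
#' @export
init_satsn <- function(arch = satsn_arch_config(), seed = 1L) {
  with_seed(seed, {
    D <- arch$embed_dim
    grid <- token_grid(arch)
    N <- prod(grid)
    patch_dim <- prod(arch$tubelet) * 3L
    rn <- function(n, sd) stats::rnorm(n, 0, sd)
    params <- list(
      embed = list(W = matrix(rn(patch_dim * D, 0.02), patch_dim, D),
                   b = numeric(D),
                   pos = matrix(rn(N * D, 0.02), N, D)),
      blocks = lapply(seq_len(arch$depth), function(i) {
        Dh <- D * arch$mlp_ratio
        list(ln1_g = rep(1, D), ln1_b = numeric(D),
             Wqkv = matrix(rn(D * 3L * D, 0.02), D, 3L * D),
             bqkv = numeric(3L * D),
             Wo = matrix(rn(D * D, 0.02), D, D), bo = numeric(D),
             ln2_g = rep(1, D), ln2_b = numeric(D),
             W1 = matrix(rn(D * Dh, 0.02), D, Dh), b1 = numeric(Dh),
             W2 = matrix(rn(Dh * D, 0.02), Dh, D), b2 = numeric(D))
      }),
      fast = {
        cin <- 3L
        lapply(seq_along(arch$fast_channels), function(s) {
          cout <- arch$fast_channels[s]
          fan <- cin * 27L
          p <- list(W = matrix(rn(cout * fan, sqrt(2 / fan)), cout, fan),
                    b = numeric(cout),
                    ta = ta_params(arch$alpha * arch$T, arch$ta_r,
                                   init = "random", sd = 0.05))
          cin <<- cout
          p
        })
      },
      lateral = lapply(arch$fast_channels, function(cs)
        list(L = matrix(0, cs, D))),
      head = {
        din <- D + arch$fast_channels[length(arch$fast_channels)]
        list(W = matrix(rn(din * arch$num_classes, 0.02), din,
                        arch$num_classes),
             b = numeric(arch$num_classes))
      })
    structure(list(arch = arch, params = params, seed = as.integer(seed)),
              class = "satsn_model")
  })
}

#' @export
print.satsn_model <- function(x, ...) {
  cat(sprintf("<satsn_model: embed_dim %d, depth %d, fast channels %s, %d parameters>\n",
              x$arch$embed_dim, x$arch$depth,
              paste(x$arch$fast_channels, collapse = "/"),
              satsn_n_params(x)))
  invisible(x)
}

#' Total number of learnable parameters
#' @param model A `satsn_model`.
#' @export
satsn_n_params <- function(model) {
  n <- 0L
  walk <- function(x) {
    if (is.numeric(x)) n <<- n + length(x)
    else if (is.list(x)) for (e in x) walk(e)
  }
  walk(strip_ta_meta(model$params))
  n
}

# ta_params carry T and r alongside their weight matrices; drop the
# bookkeeping when treating the tree as a parameter vector.
strip_ta_meta <- function(tree) {
  if (inherits(tree, "ta_params")) return(list(Wn = tree$Wn, Wm = tree$Wm))
  if (is.list(tree)) return(lapply(tree, strip_ta_meta))
  tree
}

# ---- tubelet embedding ------------------------------------------------------

tubelet_plan <- function(S, tub, T) {
  key <- paste("tub", S, paste(tub, collapse = "x"), T, sep = "_")
  plan <- .satsn_cache[[key]]
  if (!is.null(plan)) return(plan)
  th <- tub[2L]; tw <- tub[3L]; tt <- tub[1L]
  Hp <- S %/% th; Wp <- S %/% tw; Tp <- T %/% tt
  N <- Hp * Wp * Tp
  el <- expand.grid(i = seq_len(th), j = seq_len(tw), c = 1:3, f = seq_len(tt))
  Pidx <- matrix(0L, N, nrow(el))
  n <- 0L
  for (t3 in seq_len(Tp)) for (w2 in seq_len(Wp)) for (h1 in seq_len(Hp)) {
    n <- h1 + Hp * ((w2 - 1L) + Wp * (t3 - 1L))
    i <- (h1 - 1L) * th + el$i
    j <- (w2 - 1L) * tw + el$j
    f <- (t3 - 1L) * tt + el$f
    Pidx[n, ] <- i + S * ((j - 1L) + S * ((el$c - 1L) + 3L * (f - 1L)))
  }
  plan <- list(Pidx = Pidx, grid = c(Hp, Wp, Tp), N = N, patch_dim = nrow(el))
  .satsn_cache[[key]] <- plan
  plan
}

#' Embed slow-pathway frames as tubelet tokens
#'
#' Non-overlapping `t x h x w` spatio-temporal patches are flattened,
#' linearly projected to the embedding dimension and given learned
#' positional embeddings. Token order is column-major over the
#' `(H', W', T')` grid.
#'
#' @param slow Array `c(S, S, 3, T)` of slow-pathway frames.
#' @param model A `satsn_model`.
#' @return Matrix of tokens (`N x embed_dim`) with attribute `grid`.
#' @export
tubelet_embed <- function(slow, model) {
  a <- model$arch
  d <- dim(slow)
  if (d[1L] != a$input_size || d[2L] != a$input_size || d[4L] != a$T)
    stop(sprintf("slow input must be %d x %d x 3 x %d",
                 a$input_size, a$input_size, a$T))
  plan <- tubelet_plan(a$input_size, a$tubelet, a$T)
  P <- matrix(slow[plan$Pidx], plan$N, plan$patch_dim)
  Z <- P %*% model$params$embed$W +
    matrix(model$params$embed$b, plan$N, a$embed_dim, byrow = TRUE) +
    model$params$embed$pos
  attr(Z, "grid") <- plan$grid
  attr(Z, "patches") <- P
  Z
}

#' Run the ViT encoder over a token sequence
#'
#' Pre-norm transformer blocks with joint space-time self-attention (every
#' token attends to all tokens); shape preserving; `depth = 0` is the
#' identity. Lateral fusion is not applied here (see [satsn_forward()]).
#'
#' @param tokens `N x embed_dim` matrix.
#' @param model A `satsn_model`.
#' @return Encoded tokens, same shape.
#' @export
vit_encode <- function(tokens, model) {
  z <- tokens
  for (p in model$params$blocks) z <- block_fwd(z, p, model$arch$n_heads)$y
  z
}

#' Run the fast pathway
#'
#' Each stage is a 3x3x3 convolution (spatial stride 2, temporal stride 1)
#' with beta-scaled output channels, a ReLU, and a temporal-attention
#' reweighting. The temporal length is preserved throughout.
#'
#' @param fast Array `c(S, S, 3, alpha * T)` of fast-pathway frames.
#' @param model A `satsn_model`.
#' @param ta Apply the temporal-attention blocks (default TRUE).
#' @return List of per-stage feature arrays `c(C_s, S / 2^s, S / 2^s, alpha * T)`.
#' @export
fast_pathway <- function(fast, model, ta = TRUE) {
  lapply(fast_fwd(fast, model, ta = ta)$stages, `[[`, "out")
}

fast_fwd <- function(fast, model, ta = TRUE) {
  a <- model$arch
  x <- aperm(fast, c(3L, 1L, 2L, 4L))
  stages <- vector("list", length(model$params$fast))
  for (s in seq_along(stages)) {
    p <- model$params$fast[[s]]
    cv <- conv3d_fwd(x, p$W, p$b, stride = 2L)
    act <- cv$y * (cv$y > 0)
    if (ta) {
      tf <- ta_fwd_full(act, p$ta)
      out <- apply_ta(act, tf$M)
    } else {
      tf <- NULL
      out <- act
    }
    stages[[s]] <- list(conv = cv, act = act, ta = tf, out = out)
    x <- out
  }
  list(stages = stages)
}

# ---- lateral fusion ---------------------------------------------------------

pool_token_indices <- function(dims, grid, alpha) {
  Hs <- dims[2L]; Ws <- dims[3L]; Tf <- dims[4L]
  Hp <- grid[1L]; Wp <- grid[2L]; Tp <- grid[3L]
  tsel <- seq(1L, Tf, by = alpha)
  per <- length(tsel) %/% Tp
  bh <- Hs %/% Hp; bw <- Ws %/% Wp
  lapply(seq_len(Hp * Wp * Tp), function(n) {
    h1 <- (n - 1L) %% Hp + 1L
    w2 <- ((n - 1L) %/% Hp) %% Wp + 1L
    t3 <- (n - 1L) %/% (Hp * Wp) + 1L
    list(rows = (h1 - 1L) * bh + seq_len(bh),
         cols = (w2 - 1L) * bw + seq_len(bw),
         ts = tsel[(t3 - 1L) * per + seq_len(per)])
  })
}

pool_fast_to_grid <- function(feat, grid, alpha) {
  d <- dim(feat)
  spots <- pool_token_indices(d, grid, alpha)
  P <- matrix(0, length(spots), d[1L])
  for (n in seq_along(spots)) {
    sp <- spots[[n]]
    P[n, ] <- rowMeans(matrix(feat[, sp$rows, sp$cols, sp$ts, drop = FALSE],
                              d[1L]))
  }
  P
}

unpool_grid_to_fast <- function(dP, dims, grid, alpha) {
  spots <- pool_token_indices(dims, grid, alpha)
  dF <- array(0, dim = dims)
  for (n in seq_along(spots)) {
    sp <- spots[[n]]
    len <- length(sp$rows) * length(sp$cols) * length(sp$ts)
    dF[, sp$rows, sp$cols, sp$ts] <- dF[, sp$rows, sp$cols, sp$ts] +
      dP[n, ] / len
  }
  dF
}

#' Fuse a fast-pathway stage into the slow tokens
#'
#' The stage features are temporally strided by `alpha`, average-pooled to
#' the token grid, linearly projected to the embedding dimension and added
#' to the tokens.
#'
#' @param stage_feats Feature array from [fast_pathway()].
#' @param tokens `N x embed_dim` token matrix.
#' @param stage_index Which fast stage the features come from.
#' @param model A `satsn_model`.
#' @return Updated token matrix (same shape as `tokens`).
#' @export
lateral_fuse <- function(stage_feats, tokens, stage_index, model) {
  grid <- token_grid(model$arch)
  P <- pool_fast_to_grid(stage_feats, grid, model$arch$alpha)
  tokens + P %*% model$params$lateral[[stage_index]]$L
}

# ---- full forward / backward ------------------------------------------------

satsn_fwd <- function(model, sample) {
  a <- model$arch
  # center intensities: inputs arrive in [0, 1]
  sample <- list(slow = sample$slow - 0.5, fast = sample$fast - 0.5)
  ff <- fast_fwd(sample$fast, model)
  grid <- token_grid(a)
  pools <- lapply(seq_along(ff$stages), function(s)
    pool_fast_to_grid(ff$stages[[s]]$out, grid, a$alpha))
  Z <- tubelet_embed(sample$slow, model)
  P <- attr(Z, "patches")
  attr(Z, "patches") <- NULL
  zs <- vector("list", a$depth)   # block caches
  zin <- vector("list", a$depth)
  z <- Z
  for (j in seq_len(a$depth)) {
    zin[[j]] <- z
    bf <- block_fwd(z, model$params$blocks[[j]], a$n_heads)
    z <- bf$y
    zs[[j]] <- bf$cache
    for (s in which(a$fusion_after == j))
      z <- z + pools[[s]] %*% model$params$lateral[[s]]$L
  }
  Fl <- ff$stages[[length(ff$stages)]]$out
  dl <- dim(Fl)
  slow_pool <- colMeans(z)
  fast_pool <- rowMeans(matrix(Fl, dl[1L]))
  feat <- c(slow_pool, fast_pool)
  logits <- as.vector(feat %*% model$params$head$W) + model$params$head$b
  logits <- logits - max(logits)
  e <- exp(logits)
  probs <- e / sum(e)
  list(probs = probs,
       cache = list(ff = ff, pools = pools, P = P, zs = zs, z_final = z,
                    feat = feat, grid = grid, fast_dims = dl))
}

satsn_bwd <- function(model, fwd, label) {
  a <- model$arch
  cc <- fwd$cache
  K <- a$num_classes
  dlog <- fwd$probs
  dlog[label] <- dlog[label] - 1
  g <- list()
  g$head <- list(W = outer(cc$feat, dlog), b = dlog)
  dfeat <- as.vector(model$params$head$W %*% dlog)
  D <- a$embed_dim
  N <- nrow(cc$z_final)
  dz <- matrix(dfeat[seq_len(D)], N, D, byrow = TRUE) / N
  dl <- cc$fast_dims
  nl <- length(model$params$fast)
  dstage <- vector("list", nl)
  dstage[[nl]] <- array(dfeat[D + seq_len(dl[1L])] / prod(dl[2:4]), dim = dl)
  g$lateral <- vector("list", nl)
  g$blocks <- vector("list", a$depth)
  for (j in rev(seq_len(a$depth))) {
    for (s in which(a$fusion_after == j)) {
      g$lateral[[s]] <- list(L = crossprod(cc$pools[[s]], dz))
      dP <- dz %*% t(model$params$lateral[[s]]$L)
      dims_s <- dim(cc$ff$stages[[s]]$out)
      add <- unpool_grid_to_fast(dP, dims_s, cc$grid, a$alpha)
      dstage[[s]] <- if (is.null(dstage[[s]])) add else dstage[[s]] + add
    }
    bb <- block_bwd(dz, model$params$blocks[[j]], cc$zs[[j]])
    g$blocks[[j]] <- bb$grads
    dz <- bb$dz
  }
  g$embed <- list(W = crossprod(cc$P, dz), b = colSums(dz), pos = dz)
  g$fast <- vector("list", nl)
  dnext <- NULL
  for (s in rev(seq_len(nl))) {
    p <- model$params$fast[[s]]
    st <- cc$ff$stages[[s]]
    dout <- dstage[[s]]
    if (!is.null(dnext)) dout <- dout + dnext
    tb <- ta_bwd(dout, p$ta, st$ta)
    dact <- tb$dx
    dpre <- dact * (st$conv$y > 0)
    cb <- conv3d_bwd(dpre, p$W, st$conv$cache, need_dx = (s > 1L))
    g$fast[[s]] <- list(W = cb$dW, b = cb$db,
                        ta = list(Wn = tb$dWn, Wm = tb$dWm))
    dnext <- cb$dx
  }
  g
}

#' Forward pass: class probabilities for one routed sample
#'
#' Deterministic (no stochastic layers); the output is a probability
#' vector over the behavior classes summing to 1.
#'
#' @param input A `two_stream_input` from [route_inputs()] or any list
#'   with `slow` and `fast` arrays of the configured sizes.
#' @param model A `satsn_model`.
#' @return Named numeric vector of length `num_classes`.
#' @export
satsn_forward <- function(input, model) {
  p <- satsn_fwd(model, input)$probs
  names(p) <- satsn_action_names[seq_along(p)]
  p
}

# Loss and gradients for one sample (cross-entropy).
satsn_loss_grad <- function(model, sample, label) {
  fwd <- satsn_fwd(model, sample)
  loss <- -log(max(fwd$probs[label], 1e-12))
  list(loss = loss, grads = satsn_bwd(model, fwd, label), probs = fwd$probs)
}

# ---- parameter-tree helpers -------------------------------------------------

tree_map2 <- function(f, x, y) {
  if (is.numeric(x)) return(f(x, y))
  out <- x
  keys <- if (!is.null(names(x)) && all(nzchar(names(x)))) names(x)
          else seq_along(x)
  for (nm in keys) {
    if (is.null(x[[nm]])) next
    out[[nm]] <- tree_map2(f, x[[nm]],
                           if (is.list(y)) y[[nm]] else y)
  }
  out
}

tree_zero <- function(x) {
  if (is.numeric(x)) return(x * 0)
  lapply(x, function(e) if (is.null(e)) NULL else tree_zero(e))
}

grad_tree <- function(g) strip_ta_meta(g)
param_tree <- function(p) strip_ta_meta(p)

# Write updated plain values back into the (ta_params-carrying) structure.
restore_params <- function(params, plain) {
  if (inherits(params, "ta_params")) {
    params$Wn <- plain$Wn; params$Wm <- plain$Wm
    return(params)
  }
  if (is.list(params)) {
    for (i in seq_along(params))
      if (!is.null(params[[i]]))
        params[[i]] <- restore_params(params[[i]], plain[[i]])
    return(params)
  }
  plain
}
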
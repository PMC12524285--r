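test_that("tubelet embedding produces the expected token count and limits", {
  arch <- satsn_arch_config("tiny", input_size = 32L,
                            tubelet = c(2L, 16L, 16L), embed_dim = 64L,
                            T = 4L)
  m <- init_satsn(arch, seed = 1)
  slow <- with_seed(2, array(runif(32 * 32 * 3 * 4), c(32, 32, 3, 4)))
  Z <- tubelet_embed(slow, m)
  expect_equal(dim(Z), c(8L, 64L))       # 2 x 2 x 2 tokens
  expect_equal(attr(Z, "grid"), c(2L, 2L, 2L))

  # all-zero frames with zero projection bias: tokens equal the
  # positional embeddings
  m$params$embed$b[] <- 0
  Z0 <- tubelet_embed(array(0, c(32, 32, 3, 4)), m)
  expect_equal(unname(Z0[, ]), unname(m$params$embed$pos), tolerance = 1e-12)

  expect_error(tubelet_embed(array(0, c(16, 32, 3, 4)), m), "input")
})

test_that("the ViT encoder preserves shape and degenerates to identity", {
  arch <- tiny_arch()
  m <- init_satsn(arch, seed = 3)
  Z <- with_seed(1, matrix(rnorm(8 * 32), 8, 32))
  out <- vit_encode(Z, m)
  expect_equal(dim(out), dim(Z))

  m0 <- m
  m0$params$blocks <- list()
  expect_identical(vit_encode(Z, m0), Z)

  # attention rows are a probability distribution over keys
  p <- m$params$blocks[[1]]
  at <- satsn:::mha_fwd(Z, p, arch$n_heads)
  for (A in at$cache$A)
    expect_equal(rowSums(A), rep(1, nrow(Z)), tolerance = 1e-6)

  # single token: attention is a 1x1 softmax, output = Wo-projected value
  z1 <- Z[1, , drop = FALSE]
  at1 <- satsn:::mha_fwd(z1, p, arch$n_heads)
  qkv <- z1 %*% p$Wqkv + matrix(p$bqkv, 1)
  V <- qkv[, 2 * 32 + (1:32), drop = FALSE]
  expect_equal(at1$y, V %*% p$Wo + matrix(p$bo, 1), tolerance = 1e-10)
})

test_that("the fast pathway follows the beta-scaled shape plan", {
  arch <- satsn_arch_config("tiny") # input 32, channels 8/16, Tf = 16
  m <- init_satsn(arch, seed = 4)
  fast <- with_seed(5, array(runif(32 * 32 * 3 * 16), c(32, 32, 3, 16)))
  st <- fast_pathway(fast, m)
  expect_length(st, 2L)
  expect_equal(dim(st[[1]]), c(8L, 16L, 16L, 16L))  # no temporal downsample
  expect_equal(dim(st[[2]]), c(16L, 8L, 8L, 16L))

  # zero TA weights halve each stage output exactly
  m0 <- m
  for (s in 1:2) {
    m0$params$fast[[s]]$ta$Wn[] <- 0
    m0$params$fast[[s]]$ta$Wm[] <- 0
  }
  on_ta <- fast_pathway(fast, m0, ta = TRUE)
  off_ta <- fast_pathway(fast, m0, ta = FALSE)
  expect_identical(on_ta[[1]], off_ta[[1]] / 2)
  expect_identical(on_ta[[2]], off_ta[[2]] / 4) # stage 1 halving cascades
})

test_that("lateral fusion is a linear, token-preserving projection", {
  arch <- satsn_arch_config("tiny")
  m <- init_satsn(arch, seed = 6)
  fast <- with_seed(7, array(runif(32 * 32 * 3 * 16), c(32, 32, 3, 16)))
  st <- fast_pathway(fast, m)
  Z <- with_seed(8, matrix(rnorm(8 * 64), 8, 64))

  # zero projection (the initialization) leaves tokens unchanged
  expect_equal(lateral_fuse(st[[1]], Z, 1L, m), Z)

  m$params$lateral[[1]]$L <- with_seed(9, matrix(rnorm(8 * 64, 0, 0.1), 8, 64))
  f1 <- lateral_fuse(st[[1]], Z, 1L, m)
  expect_equal(dim(f1), dim(Z))
  # linearity: fuse(a + b) = fuse(a) + fuse(b) - base
  a <- st[[1]]
  b <- with_seed(10, array(rnorm(length(a)), dim(a)))
  lhs <- lateral_fuse(a + b, Z, 1L, m)
  rhs <- lateral_fuse(a, Z, 1L, m) + lateral_fuse(b, Z, 1L, m) - Z
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("forward outputs live on the probability simplex, deterministically", {
  arch <- tiny_arch()
  m <- init_satsn(arch, seed = 11)
  s <- rand_sample(arch, seed = 12)
  p1 <- satsn_forward(s, m)
  expect_equal(sum(p1), 1, tolerance = 1e-6)
  expect_true(all(p1 >= 0))
  expect_identical(p1, satsn_forward(s, m))

  # permuting the head classes permutes the probabilities identically
  perm <- c(3L, 1L, 4L, 2L)
  mp <- m
  mp$params$head$W <- m$params$head$W[, perm]
  mp$params$head$b <- m$params$head$b[perm]
  expect_equal(unname(satsn_forward(s, mp)), unname(p1)[perm],
               tolerance = 1e-12)

  # permuting samples in a batch permutes predictions identically
  ss <- list(rand_sample(arch, 1), rand_sample(arch, 2), rand_sample(arch, 3))
  P <- satsn_predict(m, ss)
  P2 <- satsn_predict(m, ss[c(3, 1, 2)])
  expect_equal(P2, P[c(3, 1, 2), ])
})

test_that("parameter counts match the closed-form formula", {
  count_formula <- function(a) {
    D <- a$embed_dim
    grid <- prod(a$input_size %/% a$tubelet[2:3], a$T %/% a$tubelet[1])
    patch <- prod(a$tubelet) * 3
    n <- patch * D + D + grid * D                      # embed + pos
    per_block <- 2 * D + D * 3 * D + 3 * D + D * D + D + # ln1, qkv, proj
      2 * D + D * (a$mlp_ratio * D) + a$mlp_ratio * D +  # ln2, mlp in
      (a$mlp_ratio * D) * D + D                          # mlp out
    n <- n + a$depth * per_block
    cin <- 3
    Tf <- a$alpha * a$T
    for (cs in a$fast_channels) {
      n <- n + cs * cin * 27 + cs +                    # conv
        2 * (Tf %/% a$ta_r) * Tf                       # ta (Wn + Wm)
      n <- n + cs * D                                  # lateral
      cin <- cs
    }
    n + (D + cin) * a$num_classes + a$num_classes      # head
  }
  for (arch in list(tiny_arch(), satsn_arch_config("tiny"))) {
    m <- init_satsn(arch, seed = 1)
    expect_equal(satsn_n_params(m), count_formula(arch))
  }
})

test_that("analytic gradients agree with finite differences", {
  arch <- tiny_arch()
  m <- init_satsn(arch, seed = 21)
  s <- rand_sample(arch, seed = 22)
  lg <- satsn:::satsn_loss_grad(m, s, 2L)
  plain <- satsn:::param_tree(m$params)
  gplain <- satsn:::grad_tree(lg$grads)
  paths <- list(list("embed", "W"), list("blocks", 1L, "Wqkv"),
                list("blocks", 1L, "ln2_g"), list("fast", 1L, "W"),
                list("fast", 2L, "ta", "Wm"), list("lateral", 2L, "L"),
                list("head", "W"))
  set_leaf <- function(tree, path, i, val) {
    if (!length(path)) { tree[i] <- val; return(tree) }
    k <- path[[1]]
    tree[[k]] <- set_leaf(tree[[k]], path[-1], i, val)
    tree
  }
  eps <- 1e-5
  for (path in paths) {
    pv <- plain; gv <- gplain
    for (k in path) { pv <- pv[[k]]; gv <- gv[[k]] }
    i <- with_seed(sum(unlist(lapply(path, nchar))), sample(length(pv), 1))
    mp <- m
    mp$params <- satsn:::restore_params(m$params,
                                        set_leaf(plain, path, i, pv[i] + eps))
    lp <- satsn:::satsn_loss_grad(mp, s, 2L)$loss
    mp$params <- satsn:::restore_params(m$params,
                                        set_leaf(plain, path, i, pv[i] - eps))
    lm <- satsn:::satsn_loss_grad(mp, s, 2L)$loss
    fd <- (lp - lm) / (2 * eps)
    expect_lt(abs(fd - gv[i]) / max(1e-8, abs(fd) + abs(gv[i])), 1e-4)
  }
})

test_that("training is reproducible and can overfit a single sample", {
  arch <- tiny_arch()
  samples <- list(rand_sample(arch, 31), rand_sample(arch, 32))
  labels <- c(1L, 3L)
  m1 <- train_satsn(samples, labels, arch, epochs = 2L, batch_size = 2L,
                    learning_rate = 0.05, seed = 9L, augment = FALSE)
  m2 <- train_satsn(samples, labels, arch, epochs = 2L, batch_size = 2L,
                    learning_rate = 0.05, seed = 9L, augment = FALSE)
  expect_identical(attr(m1, "log")$loss, attr(m2, "log")$loss)
  expect_identical(m1$params, m2$params)

  m3 <- train_satsn(samples[1], labels[1], arch, epochs = 40L,
                    batch_size = 1L, learning_rate = 0.05, seed = 2L,
                    augment = FALSE)
  log <- attr(m3, "log")
  expect_lt(log$loss[nrow(log)], log$loss[1])
  expect_lt(log$loss[nrow(log)], 0.1)
  expect_error(train_satsn(list(), integer(), arch), "empty")
})

test_that("checkpoints round-trip the model exactly", {
  arch <- tiny_arch()
  m <- init_satsn(arch, seed = 41)
  f <- withr::local_tempfile(fileext = ".json")
  save_checkpoint(m, f)
  back <- load_checkpoint(f)
  expect_equal(back$arch, m$arch)
  s <- rand_sample(arch, 42)
  expect_equal(satsn_forward(s, back), satsn_forward(s, m), tolerance = 1e-12)
})
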
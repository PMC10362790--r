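test_that("standardization centers, scales, and guards degenerate channels", {
  set.seed(1)
  x <- rbind(rnorm(200, 5, 3), rep(0, 200), rnorm(200, -2, 0.5))
  s <- standardize(x)
  expect_equal(mean(s$x[1, ]), 0, tolerance = 1e-6)
  expect_equal(stats::sd(s$x[1, ]), 1, tolerance = 1e-6)
  expect_equal(s$x[2, ], rep(0, 200))
  expect_equal(destandardize(s$x, s), x, tolerance = 1e-6)
  # padded positions are excluded from the statistics
  pad <- c(rep(FALSE, 150), rep(TRUE, 50))
  xp <- x; xp[, 151:200] <- 1e6
  sp <- standardize(xp, pad)
  expect_equal(mean(sp$x[1, 1:150]), 0, tolerance = 1e-6)
})

test_that("embedding applies the projection and positional encodings", {
  # a 0-layer model with identity reconstruction head exposes the embedding
  cfg <- tst_config(n_layers = 0, d_model = 1, n_heads = 1, d_ff = 1,
                    head_hidden = 1, dropout = 0, max_len = 4, n_channels = 1)
  m <- tst_init(cfg, seed = 1)
  m$params$Wp <- matrix(2); m$params$bp <- 1
  m$params$Wpos <- matrix(0, 4, 1)
  m$params$Wm <- matrix(1); m$params$bm <- 0
  out <- tst_forward(m, matrix(3, 1, 1), head = "mlm")$out
  expect_equal(as.numeric(out), 7)  # 2 * 3 + 1
  # zero parameters give a zero embedding
  m$params$Wp <- matrix(0); m$params$bp <- 0
  expect_equal(as.numeric(tst_forward(m, matrix(3, 1, 1), head = "mlm")$out), 0)
  # nonzero positional encodings make the output position-sensitive
  m$params$Wp <- matrix(1)
  m$params$Wpos <- matrix(c(1, 2, 3, 4), 4, 1)
  x <- matrix(c(5, 6, 7, 8), 1, 4)
  o1 <- tst_forward(m, x, head = "mlm")$out
  o2 <- tst_forward(m, x[, 4:1, drop = FALSE], head = "mlm")$out
  expect_false(isTRUE(all.equal(as.numeric(o1), as.numeric(rev(o2)))))
  # sequences beyond max_len are rejected
  expect_error(tst_forward(m, matrix(1, 1, 5), head = "mlm"), "max_len")
})

test_that("attention rows are convex weights over non-padded keys", {
  set.seed(3)
  Q <- matrix(rnorm(12), 4, 3); K <- matrix(rnorm(12), 4, 3)
  V <- matrix(rnorm(12), 4, 3)
  att <- scaled_dot_attention(Q, K, V)
  expect_equal(rowSums(att$weights), rep(1, 4))
  pad <- c(FALSE, TRUE, FALSE, TRUE)
  attp <- scaled_dot_attention(Q, K, V, pad_mask = pad)
  expect_equal(rowSums(attp$weights), rep(1, 4))
  expect_true(all(attp$weights[, pad] == 0))
  # single non-padded key: output equals that value vector everywhere
  only1 <- scaled_dot_attention(Q, K, V, pad_mask = c(FALSE, TRUE, TRUE, TRUE))
  for (i in 1:4) expect_equal(only1$out[i, ], V[1, ])
  expect_error(scaled_dot_attention(Q, K, V, pad_mask = rep(TRUE, 4)),
               "all positions padded")
  # two-position toy against an explicit softmax computation
  Q2 <- matrix(c(1, 0, 0, 1), 2, 2); K2 <- matrix(c(2, 1, 0, 1), 2, 2)
  V2 <- matrix(c(1, 2, 3, 4), 2, 2)
  S <- Q2 %*% t(K2) / sqrt(2)
  W <- exp(S) / rowSums(exp(S))
  ref <- W %*% V2
  expect_equal(scaled_dot_attention(Q2, K2, V2)$out, ref, tolerance = 1e-12)
})

test_that("predictions ignore padded positions entirely", {
  set.seed(4)
  cfg <- tiny_config()
  m <- tst_init(cfg, seed = 9)
  x <- matrix(rnorm(3 * 40), 3, 40)
  o_native <- tst_forward(m, x, head = "regress")$out
  for (junk in c(0, 17, -3)) {
    xp <- cbind(x, matrix(junk, 3, 24))
    pad <- c(rep(FALSE, 40), rep(TRUE, 24))
    o_pad <- tst_forward(m, xp, pad_mask = pad, head = "regress")$out
    expect_equal(o_pad, o_native, tolerance = 1e-5)
  }
})

test_that("regression head honors target multiplicity and zero weights", {
  cfg3 <- tst_config(n_layers = 1, d_model = 8, n_heads = 2, d_ff = 8,
                     head_hidden = 4, dropout = 0, max_len = 16,
                     n_channels = 2, targets = c("ASBP", "ADBP", "SpO2"))
  m3 <- tst_init(cfg3, seed = 2)
  out <- tst_forward(m3, matrix(rnorm(32), 2, 16), head = "regress")$out
  expect_equal(length(out), 3)
  # zero head weights leave only the output bias
  m3$params$Wy <- m3$params$Wy * 0
  m3$params$by <- c(1.5, -2, 0.25)
  out2 <- tst_forward(m3, matrix(rnorm(32), 2, 16), head = "regress")$out
  expect_equal(out2, c(1.5, -2, 0.25))
})

test_that("span masking hits the requested coverage and spares padding", {
  set.seed(5)
  x <- matrix(rnorm(4 * 2500), 4, 2500)
  m0 <- mask_for_mlm(x, ratio = 0, seed = 1)
  expect_false(any(m0$mask))
  expect_identical(m0$x, x)
  counts <- vapply(1:100, function(s) {
    sum(mask_for_mlm(x, 0.15, 3, seed = s)$mask)
  }, numeric(1))
  expect_true(all(counts >= 300 & counts <= 450))
  pad <- c(rep(FALSE, 1500), rep(TRUE, 1000))
  mp <- mask_for_mlm(x, 0.15, 3, seed = 2, pad_mask = pad)
  expect_false(any(mp$mask[pad]))
  expect_true(all(colSums(abs(mp$x[, mp$mask, drop = FALSE])) == 0))
  expect_error(mask_for_mlm(x, ratio = 1), "ratio")
})

test_that("losses follow their definitions and masking restrictions", {
  expect_equal(regression_loss(c(1, 2), c(1, 2)), 0)
  expect_equal(regression_loss(c(1, -1), c(0, 0)), 1)
  x <- matrix(rnorm(20), 2, 10)
  pred <- x + 1
  mask <- c(rep(TRUE, 3), rep(FALSE, 7))
  expect_equal(mlm_loss(pred, x, mask), 1)
  pred2 <- pred
  pred2[, !mask] <- 99  # perturbing unmasked positions changes nothing
  expect_equal(mlm_loss(pred2, x, mask), mlm_loss(pred, x, mask))
  expect_error(mlm_loss(pred, x, rep(FALSE, 10)), "nonempty mask")
})

test_that("hand-derived gradients agree with central differences", {
  set.seed(42)
  cfg <- tst_config(n_layers = 2, d_model = 8, n_heads = 2, d_ff = 12,
                    head_hidden = 5, dropout = 0, max_len = 10,
                    n_channels = 3, targets = c("ASBP", "ADBP"))
  m <- tst_init(cfg, seed = 7)
  x <- matrix(rnorm(3 * 7), 3, 7)
  pad <- c(rep(FALSE, 5), TRUE, TRUE)
  y <- c(0.3, -0.7)
  loss_at <- function(flat) {
    mp <- m; mp$params <- utils::relist(flat, m$params)
    mean((tst_forward(mp, x, pad_mask = pad, head = "regress")$out - y)^2)
  }
  fw <- tst_forward(m, x, pad_mask = pad, head = "regress", want_cache = TRUE)
  G <- ppgvitals:::tst_backward(m, fw$cache, 2 * (fw$out - y) / 2)
  flat <- unlist(m$params); gflat <- unlist(G)
  set.seed(1)
  idx <- sample(length(flat), 60)
  eps <- 1e-6
  for (i in idx) {
    up <- flat; up[i] <- up[i] + eps
    dn <- flat; dn[i] <- dn[i] - eps
    num <- (loss_at(up) - loss_at(dn)) / (2 * eps)
    expect_equal(unname(gflat[i]), num, tolerance = 1e-3)
  }
})

test_that("forward is deterministic in eval mode and dropout is seeded", {
  cfg <- tiny_config(dropout = 0.2)
  m <- tst_init(cfg, seed = 3)
  x <- matrix(rnorm(3 * 30), 3, 30)
  expect_identical(tst_forward(m, x, head = "regress")$out,
                   tst_forward(m, x, head = "regress")$out)
  ws <- ppgvitals:::with_seed
  a <- ws(5, tst_forward(m, x, head = "regress", training = TRUE)$out)
  b <- ws(5, tst_forward(m, x, head = "regress", training = TRUE)$out)
  expect_identical(a, b)
})

test_that("one optimization step moves the learnable positional encodings", {
  cfg <- tiny_config()
  m <- tst_init(cfg, seed = 6)
  x <- matrix(rnorm(3 * 20), 3, 20)
  fw <- tst_forward(m, x, head = "regress", want_cache = TRUE)
  G <- ppgvitals:::tst_backward(m, fw$cache, 2 * (fw$out - 5))
  st <- ppgvitals:::adam_init(m$params)
  upd <- ppgvitals:::adam_step(m$params, G, st, 1e-3)
  expect_false(isTRUE(all.equal(upd$params$Wpos[1:20, ], m$params$Wpos[1:20, ])))
  expect_false(isTRUE(all.equal(upd$params$Wp, m$params$Wp)))
})

test_that("a small model overfits a handful of random pairs", {
  set.seed(10)
  cfg <- tst_config(n_layers = 2, d_model = 16, n_heads = 2, d_ff = 32,
                    head_hidden = 16, dropout = 0, max_len = 32,
                    n_channels = 4, targets = "ASBP")
  xs <- lapply(1:4, function(i) matrix(rnorm(4 * 32), 4, 32))
  ys <- rnorm(4)
  m <- tst_init(cfg, seed = 2)
  st <- ppgvitals:::adam_init(m$params)
  loss <- Inf
  for (step in 1:400) {
    grads <- NULL; tot <- 0
    for (i in 1:4) {
      fw <- tst_forward(m, xs[[i]], head = "regress", want_cache = TRUE)
      e <- fw$out - ys[i]
      tot <- tot + e^2
      g <- ppgvitals:::tst_backward(m, fw$cache, 2 * e)
      grads <- if (is.null(grads)) g else ppgvitals:::tree_axpy(grads, g)
    }
    grads <- ppgvitals:::tree_map2(function(a, b) a / 4, grads, grads)
    upd <- ppgvitals:::adam_step(m$params, grads, st, 2e-3)
    m$params <- upd$params; st <- upd$state
    loss <- tot / 4
    if (loss < 1e-2) break
  }
  expect_lt(loss, 1e-2)
})

test_that("model objects print, summarize, and round trip through checkpoints", {
  m <- tst_init(tiny_config(), seed = 1)
  expect_output(print(m), "encoder")
  expect_output(blocks <- summary(m), "parameters by block")
  expect_true(all(blocks > 0))
  path <- file.path(tempdir(), "ckpt.rds")
  save_tst(m, path)
  m2 <- load_tst(path)
  expect_identical(m2$params, m$params)
  x <- matrix(rnorm(3 * 20), 3, 20)
  expect_identical(predict(m, x), predict(m2, x))
})
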
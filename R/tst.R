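# Encoder-only Time-Series Transformer for PPG-to-vitals regression.
#
# Implemented from first principles in base R matrix code: per-time-step
# linear projection, learnable positional encodings, multi-head scaled
# dot-product self-attention with key padding masks, post-norm residual
# blocks with ReLU feed-forward sublayers, a mean-pooled regression head,
# and a per-position linear head for masked-reconstruction pre-training.
# Backpropagation is derived by hand and verified against numerical
# gradients in the test suite.

#' Model configuration
#'
#' @param n_layers Number of encoder blocks (default 3).
#' @param d_model Model width D; must be divisible by `n_heads`.
#' @param n_heads Number of attention heads.
#' @param d_ff Feed-forward hidden width.
#' @param head_hidden Hidden width of the regression head (default 128).
#' @param dropout Dropout probability applied after the embedding, the
#'   attention output and the feed-forward output during training.
#' @param max_len Maximum sequence length (positional-encoding table size).
#' @param n_channels Input channels w (default 4, the EMD channels).
#' @param activation Nonlinearity; only `"relu"` is supported.
#' @param targets Character subset of `c("ASBP", "ADBP", "SpO2")`.
#' @param attn_scale Attention score scaling: `"sqrt_dk"` (conventional,
#'   default) or `"sqrt_len"` (scales by the sequence length instead).
#' @return A list of class `tst_config`.
#' @export
tst_config <- function(n_layers = 3, d_model = 128, n_heads = 8,
                       d_ff = 256, head_hidden = 128, dropout = 0.1,
                       max_len = 2500, n_channels = 4,
                       activation = "relu",
                       targets = c("ASBP", "ADBP"),
                       attn_scale = c("sqrt_dk", "sqrt_len")) {
  attn_scale <- match.arg(attn_scale)
  if (d_model %% n_heads != 0) stop_field("d_model", "must be divisible by n_heads")
  if (max_len < 1) stop_field("max_len", "must be >= 1")
  if (!identical(activation, "relu")) stop_field("activation", "only 'relu' is supported")
  targets <- match.arg(targets, c("ASBP", "ADBP", "SpO2"), several.ok = TRUE)
  structure(list(n_layers = n_layers, d_model = d_model, n_heads = n_heads,
                 d_ff = d_ff, head_hidden = head_hidden, dropout = dropout,
                 max_len = max_len, n_channels = n_channels,
                 activation = activation, targets = targets,
                 attn_scale = attn_scale),
            class = "tst_config")
}

xavier <- function(nin, nout) {
  r <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -r, r), nrow = nin, ncol = nout)
}

# Sinusoidal table of the classic transformer form; used to INITIALIZE the
# learnable positional encodings so that position similarity decays with
# distance from the very first step.
sinusoidal_table <- function(L, D) {
  pos <- matrix(0, L, D)
  for (i in seq_len(D %/% 2)) {
    f <- 1 / 10000^((2 * (i - 1)) / D)
    pos[, 2 * i - 1] <- sin((seq_len(L) - 1) * f)
    pos[, 2 * i] <- cos((seq_len(L) - 1) * f)
  }
  if (D %% 2 == 1) pos[, D] <- sin((seq_len(L) - 1) / 10000)
  pos
}

#' Initialize transformer parameters
#'
#' Xavier-uniform weight matrices, zero biases, and unit layer-norm gains.
#' Two initialization choices give the attention a locality bias that the
#' masked-reconstruction objective depends on (all parameters remain fully
#' learnable):
#'
#' * the learnable positional encodings start from the classic sinusoidal
#'   table, so the inner product of two position vectors decays with their
#'   distance;
#' * the query/key projections start near a scaled identity
#'   (`qk_locality * I` plus small Xavier noise), so initial attention
#'   scores are dominated by `Wpos_t . Wpos_s`, a kernel peaked at the
#'   query's own neighborhood.
#'
#' Together these let a masked (zeroed) position attend to its neighbors
#' from the first optimization step instead of having to escape a uniform
#' attention pattern, which is prohibitively slow at 250+ key positions.
#'
#' @param config A [tst_config()].
#' @param seed Integer seed for reproducible initialization.
#' @param qk_locality Identity gain of the query/key initialization; `0`
#'   falls back to plain Xavier.
#' @param pos_init One of `"sinusoidal"` (default) or `"normal"`.
#' @param pos_init_sd SD used when `pos_init = "normal"`.
#' @return A `tst` model object (class `tst`): list with `config`, `params`.
#' @export
tst_init <- function(config, seed = 1, qk_locality = 2,
                     pos_init = c("sinusoidal", "normal"),
                     pos_init_sd = 0.5) {
  pos_init <- match.arg(pos_init)
  D <- config$d_model; w <- config$n_channels
  H <- config$head_hidden; Ff <- config$d_ff
  nt <- length(config$targets)
  qk_init <- function() {
    if (qk_locality > 0) qk_locality * diag(D) + 0.3 * xavier(D, D)
    else xavier(D, D)
  }
  with_seed(seed, {
    params <- list(
      Wp = xavier(w, D), bp = numeric(D),
      Wpos = if (pos_init == "sinusoidal") sinusoidal_table(config$max_len, D)
             else matrix(stats::rnorm(config$max_len * D, 0, pos_init_sd),
                         nrow = config$max_len, ncol = D),
      layers = lapply(seq_len(config$n_layers), function(i) list(
        Wq = qk_init(), bq = numeric(D),
        Wk = qk_init(), bk = numeric(D),
        Wv = xavier(D, D), bv = numeric(D),
        Wo = xavier(D, D), bo = numeric(D),
        g1 = rep(1, D), be1 = numeric(D),
        W1 = xavier(D, Ff), b1 = numeric(Ff),
        W2 = xavier(Ff, D), b2 = numeric(D),
        g2 = rep(1, D), be2 = numeric(D))),
      Wh = xavier(D, H), bh = numeric(H),
      Wy = xavier(H, nt), by = numeric(nt),
      Wm = xavier(D, w), bm = numeric(w))
    structure(list(config = config, params = params, label_stats = NULL),
              class = "tst")
  })
}

# ---- standardization -------------------------------------------------------

#' Per-channel standardization of a model input
#'
#' Each channel is centered and scaled to unit variance over the non-padded
#' region; all-zero (or constant) channels pass through unchanged as zeros.
#'
#' @param x w x l numeric matrix.
#' @param pad_mask Optional logical vector of length l (`TRUE` = padded
#'   position, excluded from the statistics).
#' @return List with `x` (standardized matrix), `mean`, `sd` (per channel).
#' @export
standardize <- function(x, pad_mask = NULL) {
  valid <- if (is.null(pad_mask)) seq_len(ncol(x)) else which(!pad_mask)
  mu <- rowMeans(x[, valid, drop = FALSE])
  sdv <- apply(x[, valid, drop = FALSE], 1, stats::sd)
  out <- x
  for (i in seq_len(nrow(x))) {
    if (is.na(sdv[i]) || sdv[i] < 1e-12) {
      out[i, ] <- x[i, ] - mu[i]
      sdv[i] <- 1
    } else {
      out[i, ] <- (x[i, ] - mu[i]) / sdv[i]
    }
  }
  list(x = out, mean = mu, sd = sdv)
}

#' Invert a standardization
#'
#' @param x_std Standardized w x l matrix.
#' @param stats The list returned by [standardize()].
#' @return The de-standardized matrix.
#' @export
destandardize <- function(x_std, stats) {
  x_std * stats$sd + stats$mean
}

# ---- masking for masked-reconstruction pre-training ------------------------

#' Sample a span mask for masked-reconstruction pre-training
#'
#' Contiguous spans (geometric lengths with mean `mean_span`) covering
#' approximately `ratio` of the non-padded positions are zeroed across all
#' channels; padded positions are never masked.
#'
#' @param x_std Standardized w x l input matrix.
#' @param ratio Target masked fraction in `[0, 1)`.
#' @param mean_span Mean span length in samples (default 3).
#' @param seed Optional integer seed.
#' @param pad_mask Optional logical padding mask (length l).
#' @return List with `x` (masked matrix) and `mask` (logical vector marking
#'   exactly the zeroed positions).
#' @export
mask_for_mlm <- function(x_std, ratio = 0.15, mean_span = 3, seed = NULL,
                         pad_mask = NULL) {
  if (ratio >= 1 || ratio < 0) stop_field("ratio", "must be in [0, 1)")
  l <- ncol(x_std)
  valid <- if (is.null(pad_mask)) rep(TRUE, l) else !pad_mask
  mask <- rep(FALSE, l)
  target <- round(ratio * sum(valid))
  if (target > 0) {
    with_seed(seed, {
      free <- which(valid)
      guard <- 0L
      while (sum(mask) < target && guard < 10000L) {
        guard <- guard + 1L
        start <- free[sample.int(length(free), 1L)]
        span <- stats::rgeom(1, 1 / mean_span) + 1L
        idx <- start:min(l, start + span - 1L)
        idx <- idx[valid[idx]]
        need <- target - sum(mask)
        idx <- idx[!mask[idx]]
        if (length(idx) > need) idx <- idx[seq_len(need)]
        mask[idx] <- TRUE
      }
    })
  }
  x <- x_std
  x[, mask] <- 0
  list(x = x, mask = mask)
}

# ---- losses ----------------------------------------------------------------

#' Mean-squared regression loss
#'
#' @param yhat,y Numeric vectors (or matrices) of predictions and labels.
#' @return Mean squared error.
#' @export
regression_loss <- function(yhat, y) mean((yhat - y)^2)

#' Masked-reconstruction loss
#'
#' Mean squared error between prediction and original restricted to masked
#' positions (all channels).
#'
#' @param predicted,original w x l matrices (standardized space).
#' @param mask Logical vector of length l marking masked positions.
#' @return Mean squared error over masked positions.
#' @export
mlm_loss <- function(predicted, original, mask) {
  if (!any(mask)) stop("mlm_loss requires a nonempty mask", call. = FALSE)
  mean((predicted[, mask, drop = FALSE] - original[, mask, drop = FALSE])^2)
}

# ---- forward pass ----------------------------------------------------------

layernorm_fwd <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  list(y = sweep(xhat, 2, g, `*`) + rep(b, each = nrow(X)),
       xhat = xhat, inv = inv)
}

layernorm_bwd <- function(dY, cache, g) {
  xhat <- cache$xhat; inv <- cache$inv
  dg <- colSums(dY * xhat)
  db <- colSums(dY)
  dxhat <- sweep(dY, 2, g, `*`)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dX <- inv * (dxhat - m1 - xhat * m2)
  list(dX = dX, dg = dg, db = db)
}

row_softmax <- function(S) {
  mx <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  E <- exp(S - mx)
  E / rowSums(E)
}

#' Scaled dot-product attention (single head)
#'
#' Scores are `Q K^T / scale`; scores at padded key positions are set to
#' negative infinity before the row-wise softmax, so each output row is a
#' convex combination of the value vectors at non-padded positions.
#'
#' @param Q,K,V l x d matrices of queries, keys and values.
#' @param pad_mask Optional logical vector (`TRUE` = padded key position).
#' @param scale Score divisor; default `sqrt(ncol(Q))`.
#' @return List with `out` (l x d) and `weights` (l x l attention matrix).
#' @export
scaled_dot_attention <- function(Q, K, V, pad_mask = NULL,
                                 scale = sqrt(ncol(Q))) {
  if (!is.null(pad_mask) && all(pad_mask)) {
    stop("all positions padded", call. = FALSE)
  }
  S <- tcrossprod(Q, K) / scale
  if (!is.null(pad_mask) && any(pad_mask)) S[, pad_mask] <- -Inf
  A <- row_softmax(S)
  list(out = A %*% V, weights = A)
}

add_bias <- function(X, b) X + rep(b, each = nrow(X))

drop_mask <- function(nr, nc, p) {
  if (p <= 0) return(NULL)
  matrix(stats::rbinom(nr * nc, 1, 1 - p) / (1 - p), nrow = nr, ncol = nc)
}

# Forward pass for one sample. x_std: standardized w x l matrix. head:
# "regress", "mlm", or "encode". Returns list(out, cache) where cache is
# NULL unless want_cache.
tst_forward <- function(model, x_std, pad_mask = NULL,
                        head = c("regress", "mlm"),
                        training = FALSE, want_cache = FALSE) {
  head <- match.arg(head)
  cfg <- model$config; P <- model$params
  l <- ncol(x_std)
  if (l > cfg$max_len) stop("sequence longer than max_len", call. = FALSE)
  if (is.null(pad_mask)) pad_mask <- rep(FALSE, l)
  if (all(pad_mask)) stop("all positions padded", call. = FALSE)
  valid <- !pad_mask
  D <- cfg$d_model; nh <- cfg$n_heads; dh <- D / nh
  scale <- if (cfg$attn_scale == "sqrt_dk") sqrt(dh) else sqrt(l)
  p_drop <- if (training) cfg$dropout else 0

  T0 <- t(x_std)                                 # l x w
  E <- add_bias(T0 %*% P$Wp, P$bp) + P$Wpos[seq_len(l), , drop = FALSE]
  dm0 <- drop_mask(l, D, p_drop)
  if (!is.null(dm0)) E <- E * dm0
  Z <- E
  caches <- if (want_cache) vector("list", cfg$n_layers) else NULL

  for (li in seq_len(cfg$n_layers)) {
    L <- P$layers[[li]]
    Q <- add_bias(Z %*% L$Wq, L$bq)
    K <- add_bias(Z %*% L$Wk, L$bk)
    V <- add_bias(Z %*% L$Wv, L$bv)
    O <- matrix(0, l, D)
    A_list <- if (want_cache) vector("list", nh) else NULL
    for (h in seq_len(nh)) {
      idx <- ((h - 1) * dh + 1):(h * dh)
      att <- scaled_dot_attention(Q[, idx, drop = FALSE],
                                  K[, idx, drop = FALSE],
                                  V[, idx, drop = FALSE],
                                  pad_mask = if (any(pad_mask)) pad_mask,
                                  scale = scale)
      O[, idx] <- att$out
      if (want_cache) A_list[[h]] <- att$weights
    }
    attn <- add_bias(O %*% L$Wo, L$bo)
    dm1 <- drop_mask(l, D, p_drop)
    if (!is.null(dm1)) attn <- attn * dm1
    R1 <- Z + attn
    ln1 <- layernorm_fwd(R1, L$g1, L$be1)
    Z1 <- ln1$y
    Hpre <- add_bias(Z1 %*% L$W1, L$b1)
    Hact <- pmax(Hpre, 0)
    Ff <- add_bias(Hact %*% L$W2, L$b2)
    dm2 <- drop_mask(l, D, p_drop)
    if (!is.null(dm2)) Ff <- Ff * dm2
    R2 <- Z1 + Ff
    ln2 <- layernorm_fwd(R2, L$g2, L$be2)
    Z_next <- ln2$y
    if (want_cache) {
      caches[[li]] <- list(Z_in = Z, Q = Q, K = K, V = V, A = A_list, O = O,
                           dm1 = dm1, ln1 = ln1, Z1 = Z1, Hpre = Hpre,
                           Hact = Hact, dm2 = dm2, ln2 = ln2)
    }
    Z <- Z_next
  }

  if (head == "regress") {
    pool <- colMeans(Z[valid, , drop = FALSE])
    hpre <- as.numeric(pool %*% P$Wh) + P$bh
    hact <- pmax(hpre, 0)
    out <- as.numeric(hact %*% P$Wy) + P$by
  } else {
    out <- t(add_bias(Z %*% P$Wm, P$bm))         # w x l
  }
  cache <- if (want_cache) {
    list(T0 = T0, dm0 = dm0, layers = caches, Z_final = Z, valid = valid,
         l = l, scale = scale, pad_mask = pad_mask,
         pool = if (head == "regress") pool else NULL,
         hpre = if (head == "regress") hpre else NULL,
         hact = if (head == "regress") hact else NULL,
         head = head)
  } else NULL
  list(out = out, cache = cache)
}

# Backward pass: d_out is the gradient of the loss wrt the forward output
# (vector for "regress", w x l matrix for "mlm"). Returns gradients shaped
# like model$params.
tst_backward <- function(model, cache, d_out) {
  cfg <- model$config; P <- model$params
  l <- cache$l; D <- cfg$d_model; nh <- cfg$n_heads; dh <- D / nh
  G <- zero_like(P)

  if (cache$head == "regress") {
    dh_act <- as.numeric(tcrossprod(matrix(d_out, 1), P$Wy))
    G$Wy <- outer(cache$hact, as.numeric(d_out))
    G$by <- as.numeric(d_out)
    dh_pre <- dh_act * (cache$hpre > 0)
    G$Wh <- outer(cache$pool, dh_pre)
    G$bh <- dh_pre
    dpool <- as.numeric(tcrossprod(matrix(dh_pre, 1), P$Wh))
    dZ <- matrix(0, l, D)
    nv <- sum(cache$valid)
    dZ[cache$valid, ] <- matrix(dpool / nv, nrow = nv, ncol = D, byrow = TRUE)
  } else {
    dXhat <- t(d_out)                            # l x w
    G$Wm <- crossprod(cache$Z_final, dXhat)
    G$bm <- colSums(dXhat)
    dZ <- tcrossprod(dXhat, P$Wm)
  }

  for (li in rev(seq_len(cfg$n_layers))) {
    L <- P$layers[[li]]; C <- cache$layers[[li]]
    gl <- G$layers[[li]]
    ln2b <- layernorm_bwd(dZ, C$ln2, L$g2)
    gl$g2 <- ln2b$dg; gl$be2 <- ln2b$db
    dR2 <- ln2b$dX
    dZ1 <- dR2
    dFf <- dR2
    if (!is.null(C$dm2)) dFf <- dFf * C$dm2
    gl$W2 <- crossprod(C$Hact, dFf)
    gl$b2 <- colSums(dFf)
    dHact <- tcrossprod(dFf, L$W2)
    dHpre <- dHact * (C$Hpre > 0)
    gl$W1 <- crossprod(C$Z1, dHpre)
    gl$b1 <- colSums(dHpre)
    dZ1 <- dZ1 + tcrossprod(dHpre, L$W1)
    ln1b <- layernorm_bwd(dZ1, C$ln1, L$g1)
    gl$g1 <- ln1b$dg; gl$be1 <- ln1b$db
    dR1 <- ln1b$dX
    dZin <- dR1
    dattn <- dR1
    if (!is.null(C$dm1)) dattn <- dattn * C$dm1
    gl$Wo <- crossprod(C$O, dattn)
    gl$bo <- colSums(dattn)
    dO <- tcrossprod(dattn, L$Wo)
    dQ <- matrix(0, l, D); dK <- matrix(0, l, D); dV <- matrix(0, l, D)
    for (h in seq_len(nh)) {
      idx <- ((h - 1) * dh + 1):(h * dh)
      A <- C$A[[h]]
      dOh <- dO[, idx, drop = FALSE]
      dA <- tcrossprod(dOh, C$V[, idx, drop = FALSE])
      dV[, idx] <- crossprod(A, dOh)
      dS <- A * (dA - rowSums(dA * A))
      dQ[, idx] <- (dS %*% C$K[, idx, drop = FALSE]) / cache$scale
      dK[, idx] <- crossprod(dS, C$Q[, idx, drop = FALSE]) / cache$scale
    }
    gl$Wq <- crossprod(C$Z_in, dQ); gl$bq <- colSums(dQ)
    gl$Wk <- crossprod(C$Z_in, dK); gl$bk <- colSums(dK)
    gl$Wv <- crossprod(C$Z_in, dV); gl$bv <- colSums(dV)
    dZin <- dZin + tcrossprod(dQ, L$Wq) + tcrossprod(dK, L$Wk) + tcrossprod(dV, L$Wv)
    G$layers[[li]] <- gl
    dZ <- dZin
  }

  dE <- dZ
  if (!is.null(cache$dm0)) dE <- dE * cache$dm0
  G$Wpos[seq_len(l), ] <- G$Wpos[seq_len(l), , drop = FALSE] + dE
  G$Wp <- t(cache$T0) %*% dE
  G$bp <- colSums(dE)
  G
}

# ---- parameter-tree utilities ---------------------------------------------

zero_like <- function(p) {
  if (is.list(p)) lapply(p, zero_like) else p * 0
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- Map(function(x, y) tree_map2(f, x, y), a, b)
    out
  } else f(a, b)
}

tree_axpy <- function(a, b, alpha = 1) tree_map2(function(x, y) x + alpha * y, a, b)

n_params <- function(p) {
  if (is.list(p)) sum(vapply(p, n_params, numeric(1))) else length(p)
}

# ---- S3 methods ------------------------------------------------------------

#' @export
print.tst <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<tst> %d-layer encoder, D=%d, %d heads, d_ff=%d, w=%d, max_len=%d\n",
              cfg$n_layers, cfg$d_model, cfg$n_heads, cfg$d_ff,
              cfg$n_channels, cfg$max_len))
  cat(sprintf("  targets: %s; attention scale: %s\n",
              paste(cfg$targets, collapse = ", "), cfg$attn_scale))
  cat(sprintf("  %s trainable parameters\n",
              format(n_params(x$params), big.mark = ",")))
  invisible(x)
}

#' @export
summary.tst <- function(object, ...) {
  p <- object$params
  blocks <- c(embedding = n_params(p$Wp) + n_params(p$bp),
              positional = n_params(p$Wpos),
              encoder = n_params(p$layers),
              regression_head = n_params(p$Wh) + n_params(p$bh) +
                n_params(p$Wy) + n_params(p$by),
              mlm_head = n_params(p$Wm) + n_params(p$bm))
  print(object)
  cat("parameters by block:\n")
  for (nm in names(blocks)) cat(sprintf("  %-16s %10d\n", nm, blocks[[nm]]))
  invisible(blocks)
}

#' Predict vitals from channelized slices
#'
#' Runs the regression head over each slice. Labels predicted in
#' standardized space are mapped back through the model's stored label
#' statistics when present.
#'
#' @param object A fitted `tst` model.
#' @param newdata A list of `channelized_slice` objects, or a single w x l
#'   matrix, or a list of such matrices.
#' @param ... Unused.
#' @return A numeric matrix with one row per slice and one column per
#'   configured target.
#' @export
predict.tst <- function(object, newdata, ...) {
  if (is.matrix(newdata)) newdata <- list(newdata)
  xs <- lapply(newdata, function(s) if (inherits(s, "channelized_slice")) s$channels else s)
  nt <- length(object$config$targets)
  raw <- vapply(xs, function(x) {
    xs1 <- standardize(x)
    tst_forward(object, xs1$x, head = "regress")$out
  }, numeric(nt))
  out <- if (nt == 1) matrix(raw, ncol = 1) else t(raw)
  colnames(out) <- object$config$targets
  if (!is.null(object$label_stats)) {
    for (j in seq_along(object$config$targets)) {
      out[, j] <- out[, j] * object$label_stats$sd[j] + object$label_stats$mean[j]
    }
  }
  out
}

#' Save / load a model checkpoint
#'
#' Single-file archive holding the configuration and all named parameter
#' arrays.
#'
#' @param model A `tst` model.
#' @param path Checkpoint file path.
#' @return `load_tst` returns the model; `save_tst` invisibly returns
#'   `path`.
#' @export
save_tst <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_tst
#' @export
load_tst <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "tst"))
  m
}
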
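## Vectorized mini-batch neural-network core shared by the per-site
## autoencoder and the central classifier. Everything here is internal; all
## randomness (initialization, shuffling) is driven by the caller's seed via
## withr::with_seed.
##
## Input layout: categorical embedding blocks first (in site column order),
## then standardized continuous columns. Each embedding table has
## cardinality + 1 rows; the extra row is the dedicated "missing" level.
## Continuous missing cells are imputed with the training-rows median before
## standardization.

.fit_preproc <- function(schema, feats, rule = "default") {
  nms <- schema@featureNames
  kinds <- schema@featureKinds
  cat_cols <- nms[kinds == "categorical"]
  cont_cols <- nms[kinds == "continuous"]
  cards <- vapply(schema@levels[cat_cols], length, integer(1))
  emb_w <- if (length(cat_cols))
    vapply(cards, function(card) .embedding_width(rule, card), integer(1))
  else integer(0)
  cont_stats <- matrix(0, 3, length(cont_cols),
                       dimnames = list(c("median", "mean", "sd"), cont_cols))
  for (nm in cont_cols) {
    x <- feats[[nm]]
    med <- stats::median(x, na.rm = TRUE)
    if (!is.finite(med)) med <- 0
    xi <- x
    xi[is.na(xi)] <- med
    mu <- mean(xi)
    sdv <- stats::sd(xi)
    if (!is.finite(sdv) || sdv < 1e-12) sdv <- 1
    cont_stats[, nm] <- c(med, mu, sdv)
  }
  offs <- cumsum(c(0L, emb_w))
  list(rule = rule, cat_cols = cat_cols, cont_cols = cont_cols,
       cards = cards, emb_w = emb_w,
       emb_off = offs[seq_along(cat_cols)],
       cont_stats = cont_stats,
       n_input = sum(emb_w) + length(cont_cols))
}

# Codes / standardized values / observation mask for a feature data.frame.
.make_inputs <- function(pre, feats) {
  n <- nrow(feats)
  K <- length(pre$cat_cols)
  P <- length(pre$cont_cols)
  cat_codes <- matrix(0L, n, K)
  cat_obs <- matrix(TRUE, n, K)
  for (j in seq_len(K)) {
    cc <- feats[[pre$cat_cols[j]]]
    cat_obs[, j] <- !is.na(cc)
    cc[is.na(cc)] <- pre$cards[j] + 1L
    cat_codes[, j] <- cc
  }
  cont <- matrix(0, n, P)
  for (j in seq_len(P)) {
    st <- pre$cont_stats[, pre$cont_cols[j]]
    x <- feats[[pre$cont_cols[j]]]
    x[is.na(x)] <- st[["median"]]
    cont[, j] <- (x - st[["mean"]]) / st[["sd"]]
  }
  list(cat = cat_codes, cont = cont, cat_obs = cat_obs)
}

.init_dense <- function(nin, nout) {
  r <- 1 / sqrt(nin)
  list(W = matrix(stats::runif(nin * nout, -r, r), nin, nout),
       b = numeric(nout))
}

.init_embeddings <- function(pre) {
  lapply(seq_along(pre$cat_cols), function(j)
    matrix(stats::runif((pre$cards[j] + 1L) * pre$emb_w[j], -0.1, 0.1),
           pre$cards[j] + 1L, pre$emb_w[j]))
}

# Batch input matrix from embedding tables + continuous block.
.assemble <- function(pre, emb, inp, idx) {
  B <- length(idx)
  X <- matrix(0, B, pre$n_input)
  for (j in seq_along(pre$cat_cols)) {
    cols <- pre$emb_off[j] + seq_len(pre$emb_w[j])
    X[, cols] <- emb[[j]][inp$cat[idx, j], , drop = FALSE]
  }
  P <- length(pre$cont_cols)
  if (P)
    X[, (pre$n_input - P + 1L):pre$n_input] <- inp$cont[idx, , drop = FALSE]
  X
}

.relu_fwd <- function(A, layers) {
  L <- length(layers)
  As <- vector("list", L + 1L)
  Zs <- vector("list", L)
  As[[1L]] <- A
  B <- nrow(A)
  for (l in seq_len(L)) {
    Z <- As[[l]] %*% layers[[l]]$W + rep(layers[[l]]$b, each = B)
    Zs[[l]] <- Z
    Z[Z < 0] <- 0
    As[[l + 1L]] <- Z
  }
  list(A = As, Z = Zs)
}

# Row-wise log-softmax pieces for a logit matrix (small class counts).
.softmax_rows <- function(logits) {
  B <- nrow(logits)
  mx <- logits[cbind(seq_len(B), max.col(logits, ties.method = "first"))]
  ez <- exp(logits - mx)
  P <- ez / rowSums(ez)
  P
}

## ---- autoencoder ---------------------------------------------------------

.init_ae_params <- function(pre, hidden) {
  dims <- c(pre$n_input, hidden)
  layers <- lapply(seq_len(length(dims) - 1L),
                   function(l) .init_dense(dims[l], dims[l + 1L]))
  last <- hidden[length(hidden)]
  list(emb = .init_embeddings(pre),
       layers = layers,
       cont_head = if (length(pre$cont_cols))
         .init_dense(last, length(pre$cont_cols)) else NULL,
       cat_heads = lapply(seq_along(pre$cat_cols),
                          function(j) .init_dense(last, pre$cards[j])))
}

# One SGD step on a mini-batch; returns updated params and the summed
# per-row reconstruction loss of the batch (before the update).
.ae_batch_step <- function(pre, params, inp, idx, lr, wd) {
  B <- length(idx)
  X <- .assemble(pre, params$emb, inp, idx)
  fw <- .relu_fwd(X, params$layers)
  L <- length(params$layers)
  AL <- fw$A[[L + 1L]]
  loss <- 0
  dAL <- matrix(0, B, ncol(AL))
  grads_heads <- list()

  if (!is.null(params$cont_head)) {
    Yc <- inp$cont[idx, , drop = FALSE]
    Yhat <- AL %*% params$cont_head$W + rep(params$cont_head$b, each = B)
    R <- Yhat - Yc
    loss <- loss + sum(R * R)
    dY <- (2 / B) * R
    dAL <- dAL + tcrossprod(dY, params$cont_head$W)
    grads_heads$cont <- list(W = crossprod(AL, dY), b = colSums(dY))
  }
  grads_heads$cat <- vector("list", length(pre$cat_cols))
  for (j in seq_along(pre$cat_cols)) {
    hd <- params$cat_heads[[j]]
    logits <- AL %*% hd$W + rep(hd$b, each = B)
    P <- .softmax_rows(logits)
    tj <- inp$cat[idx, j]
    obs <- inp$cat_obs[idx, j]
    sel <- cbind(which(obs), tj[obs])
    loss <- loss - sum(log(pmax(P[sel], 1e-12)))
    G <- P
    G[sel] <- G[sel] - 1
    if (any(!obs)) G[!obs, ] <- 0
    G <- G / B
    dAL <- dAL + tcrossprod(G, hd$W)
    grads_heads$cat[[j]] <- list(W = crossprod(AL, G), b = colSums(G))
  }

  # backprop through the shared trunk
  dA <- dAL
  dX <- NULL
  for (l in rev(seq_len(L))) {
    dZ <- dA * (fw$Z[[l]] > 0)
    gW <- crossprod(fw$A[[l]], dZ)
    gb <- colSums(dZ)
    dA <- tcrossprod(dZ, params$layers[[l]]$W)
    params$layers[[l]]$W <- params$layers[[l]]$W -
      lr * (gW + wd * params$layers[[l]]$W)
    params$layers[[l]]$b <- params$layers[[l]]$b - lr * gb
  }
  dX <- dA

  if (!is.null(params$cont_head)) {
    params$cont_head$W <- params$cont_head$W -
      lr * (grads_heads$cont$W + wd * params$cont_head$W)
    params$cont_head$b <- params$cont_head$b - lr * grads_heads$cont$b
  }
  for (j in seq_along(pre$cat_cols)) {
    params$cat_heads[[j]]$W <- params$cat_heads[[j]]$W -
      lr * (grads_heads$cat[[j]]$W + wd * params$cat_heads[[j]]$W)
    params$cat_heads[[j]]$b <- params$cat_heads[[j]]$b -
      lr * grads_heads$cat[[j]]$b
  }
  for (j in seq_along(pre$cat_cols)) {
    cols <- pre$emb_off[j] + seq_len(pre$emb_w[j])
    g <- rowsum(dX[, cols, drop = FALSE], group = inp$cat[idx, j])
    rows <- as.integer(rownames(g))
    E <- params$emb[[j]] * (1 - lr * wd)
    E[rows, ] <- E[rows, ] - lr * g
    params$emb[[j]] <- E
  }
  list(params = params, loss = loss)
}

# Mean per-row reconstruction loss, forward only (chunked).
.ae_loss <- function(pre, params, inp, chunk = 8192L) {
  n <- nrow(inp$cont)
  if (!n) n <- nrow(inp$cat)
  total <- 0
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(n, start + chunk - 1L)
    B <- length(idx)
    X <- .assemble(pre, params$emb, inp, idx)
    fw <- .relu_fwd(X, params$layers)
    AL <- fw$A[[length(params$layers) + 1L]]
    if (!is.null(params$cont_head)) {
      Yc <- inp$cont[idx, , drop = FALSE]
      R <- AL %*% params$cont_head$W +
        rep(params$cont_head$b, each = B) - Yc
      total <- total + sum(R * R)
    }
    for (j in seq_along(pre$cat_cols)) {
      hd <- params$cat_heads[[j]]
      P <- .softmax_rows(AL %*% hd$W + rep(hd$b, each = B))
      tj <- inp$cat[idx, j]
      obs <- inp$cat_obs[idx, j]
      sel <- cbind(which(obs), tj[obs])
      total <- total - sum(log(pmax(P[sel], 1e-12)))
    }
  }
  total / n
}

# Post-activation output of the code (middle hidden) layer.
.ae_encode_core <- function(pre, params, inp, chunk = 8192L) {
  n <- nrow(inp$cont)
  if (!n) n <- nrow(inp$cat)
  mid <- (length(params$layers) + 1L) %/% 2L
  out <- NULL
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(n, start + chunk - 1L)
    A <- .assemble(pre, params$emb, inp, idx)
    B <- length(idx)
    for (l in seq_len(mid)) {
      A <- A %*% params$layers[[l]]$W + rep(params$layers[[l]]$b, each = B)
      A[A < 0] <- 0
    }
    out <- rbind(out, A)
  }
  out
}

.train_ae_core <- function(pre, inp, config, seed) {
  n <- nrow(inp$cont)
  if (!n) n <- nrow(inp$cat)
  withr::with_seed(seed, {
    params <- .init_ae_params(pre, config@hiddenDims)
    loss_hist <- numeric(config@epochs)
    lr_hist <- numeric(config@epochs)
    for (epoch in seq_len(config@epochs)) {
      lr <- config@initialLR * config@lrDecay^(epoch - 1L)
      lr_hist[epoch] <- lr
      ord <- sample.int(n)
      total <- 0
      for (start in seq(1L, n, by = config@batchSize)) {
        idx <- ord[start:min(n, start + config@batchSize - 1L)]
        st <- .ae_batch_step(pre, params, inp, idx, lr, config@weightDecay)
        params <- st$params
        total <- total + st$loss
      }
      loss_hist[epoch] <- total / n
      if (!is.finite(loss_hist[epoch]))
        stop(sprintf("autoencoder training diverged (non-finite loss) at epoch %d",
                     epoch))
    }
    list(params = params, loss = loss_hist, lr = lr_hist)
  })
}

## ---- classifier ----------------------------------------------------------

.init_clf_params <- function(pre, hidden) {
  dims <- c(pre$n_input, hidden)
  layers <- lapply(seq_len(length(dims) - 1L),
                   function(l) .init_dense(dims[l], dims[l + 1L]))
  list(emb = .init_embeddings(pre),
       layers = layers,
       out = .init_dense(hidden[length(hidden)], 1L))
}

# One Adam step over the whole parameter set for a mini-batch.
.clf_batch_step <- function(pre, params, state, inp, y, idx, cfg, t) {
  B <- length(idx)
  X <- .assemble(pre, params$emb, inp, idx)
  fw <- .relu_fwd(X, params$layers)
  L <- length(params$layers)
  AL <- fw$A[[L + 1L]]
  z <- drop(AL %*% params$out$W) + params$out$b
  p <- 1 / (1 + exp(-z))
  pc <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  yb <- y[idx]
  loss <- -sum(yb * log(pc) + (1 - yb) * log(1 - pc))
  dz <- (p - yb) / B
  gOutW <- crossprod(AL, dz)
  gOutb <- sum(dz)
  dA <- tcrossprod(matrix(dz, ncol = 1L), params$out$W)

  grads <- list(layers = vector("list", L))
  for (l in rev(seq_len(L))) {
    dZ <- dA * (fw$Z[[l]] > 0)
    grads$layers[[l]] <- list(W = crossprod(fw$A[[l]], dZ), b = colSums(dZ))
    dA <- tcrossprod(dZ, params$layers[[l]]$W)
  }
  dX <- dA
  grads$emb <- vector("list", length(pre$cat_cols))
  for (j in seq_along(pre$cat_cols)) {
    cols <- pre$emb_off[j] + seq_len(pre$emb_w[j])
    g <- rowsum(dX[, cols, drop = FALSE], group = inp$cat[idx, j])
    G <- matrix(0, pre$cards[j] + 1L, pre$emb_w[j])
    G[as.integer(rownames(g)), ] <- g
    grads$emb[[j]] <- G
  }
  grads$out <- list(W = gOutW, b = gOutb)

  upd <- function(p, g, s) {
    if (cfg@weightDecay > 0) g <- g + cfg@weightDecay * p
    s$m <- 0.9 * s$m + 0.1 * g
    s$v <- 0.999 * s$v + 0.001 * g * g
    mh <- s$m / (1 - 0.9^t)
    vh <- s$v / (1 - 0.999^t)
    list(p = p - cfg@lr * mh / (sqrt(vh) + 1e-8), s = s)
  }
  for (l in seq_len(L)) {
    u <- upd(params$layers[[l]]$W, grads$layers[[l]]$W, state$layers[[l]]$W)
    params$layers[[l]]$W <- u$p; state$layers[[l]]$W <- u$s
    u <- upd(params$layers[[l]]$b, grads$layers[[l]]$b, state$layers[[l]]$b)
    params$layers[[l]]$b <- u$p; state$layers[[l]]$b <- u$s
  }
  u <- upd(params$out$W, grads$out$W, state$out$W)
  params$out$W <- u$p; state$out$W <- u$s
  u <- upd(params$out$b, grads$out$b, state$out$b)
  params$out$b <- u$p; state$out$b <- u$s
  for (j in seq_along(pre$cat_cols)) {
    u <- upd(params$emb[[j]], grads$emb[[j]], state$emb[[j]])
    params$emb[[j]] <- u$p; state$emb[[j]] <- u$s
  }
  list(params = params, state = state, loss = loss)
}

.adam_state_for <- function(params) {
  zero <- function(p) list(m = p * 0, v = p * 0)
  list(layers = lapply(params$layers,
                       function(l) list(W = zero(l$W), b = zero(l$b))),
       out = list(W = zero(params$out$W), b = zero(params$out$b)),
       emb = lapply(params$emb, zero))
}

.train_clf_core <- function(pre, inp, y, config, seed) {
  n <- length(y)
  withr::with_seed(seed, {
    params <- .init_clf_params(pre, config@hiddenDims)
    state <- .adam_state_for(params)
    loss_hist <- numeric(config@epochs)
    t <- 0L
    for (epoch in seq_len(config@epochs)) {
      ord <- sample.int(n)
      total <- 0
      for (start in seq(1L, n, by = config@batchSize)) {
        idx <- ord[start:min(n, start + config@batchSize - 1L)]
        t <- t + 1L
        st <- .clf_batch_step(pre, params, state, inp, y, idx, config, t)
        params <- st$params
        state <- st$state
        total <- total + st$loss
      }
      loss_hist[epoch] <- total / n
      if (!is.finite(loss_hist[epoch]))
        stop(sprintf("classifier training diverged (non-finite loss) at epoch %d",
                     epoch))
    }
    list(params = params, loss = loss_hist)
  })
}

.clf_scores_core <- function(pre, params, inp, chunk = 8192L) {
  n <- if (nrow(inp$cont)) nrow(inp$cont) else nrow(inp$cat)
  out <- numeric(n)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(n, start + chunk - 1L)
    A <- .assemble(pre, params$emb, inp, idx)
    B <- length(idx)
    for (l in seq_along(params$layers)) {
      A <- A %*% params$layers[[l]]$W + rep(params$layers[[l]]$b, each = B)
      A[A < 0] <- 0
    }
    z <- drop(A %*% params$out$W) + params$out$b
    out[idx] <- 1 / (1 + exp(-z))
  }
  out
}

# Preprocessing for plain all-continuous matrices (latent inputs).
.fit_matrix_preproc <- function(mat) {
  mu <- colMeans(mat)
  sdv <- apply(mat, 2L, stats::sd)
  sdv[!is.finite(sdv) | sdv < 1e-12] <- 1
  ncol_ <- ncol(mat)
  list(rule = "none", cat_cols = character(0),
       cont_cols = paste0("m", seq_len(ncol_)),
       cards = integer(0), emb_w = integer(0), emb_off = integer(0),
       cont_stats = rbind(median = mu, mean = mu, sd = sdv),
       n_input = ncol_, matrix_input = TRUE)
}

.make_matrix_inputs <- function(pre, mat) {
  sc <- sweep(mat, 2L, pre$cont_stats["mean", ], "-")
  sc <- sweep(sc, 2L, pre$cont_stats["sd", ], "/")
  list(cat = matrix(0L, nrow(mat), 0L), cont = sc,
       cat_obs = matrix(TRUE, nrow(mat), 0L))
}
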
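# Sequence autoencoder for SMILES with self-attention.
#
# Encoder-decoder transformer trained with teacher forcing to reproduce the
# input token sequence; the mean-pooled final encoder layer is the compound's
# structural embedding. Implemented directly on BLAS-backed matrix ops with
# hand-written backpropagation and Adam, sized for desk-scale corpora.
# Sequences are processed unpadded, one (unique) sequence per update, with
# the gradient weighted by the sequence's multiplicity in the corpus.

#' Configuration for the SMILES autoencoder
#'
#' @param model_dim embedding width (divisible by `heads`); default 64.
#' @param heads attention heads per layer; default 4.
#' @param layers encoder and decoder layers; default 2.
#' @param ffn_dim feed-forward inner width; default `2 * model_dim`.
#' @param max_len maximum token sequence length accepted; default 128.
#' @param epochs training epochs; default 100.
#' @param learning_rate Adam step size; default 1e-3.
#' @param seed RNG seed controlling initialization and epoch shuffling.
#' @return list of class `smiles_ae_config`.
#' @export
smiles_ae_config <- function(model_dim = 64, heads = 4, layers = 2,
                             ffn_dim = 2 * model_dim, max_len = 128,
                             epochs = 100, learning_rate = 1e-3, seed = 1) {
  stopifnot(model_dim %% heads == 0, layers >= 1, max_len >= 2,
            epochs >= 1, learning_rate > 0)
  structure(list(model_dim = model_dim, heads = heads, layers = layers,
                 ffn_dim = ffn_dim, max_len = max_len, epochs = epochs,
                 learning_rate = learning_rate, seed = seed),
            class = "smiles_ae_config")
}

# sinusoidal positional encoding, rows = positions
positional_encoding <- function(max_len, d) {
  pos <- seq_len(max_len) - 1
  i <- seq_len(d) - 1
  angle <- outer(pos, 1 / 10000^(2 * floor(i / 2) / d))
  pe <- matrix(0, max_len, d)
  even <- seq(1, d, by = 2)
  odd <- seq(2, d, by = 2)
  pe[, even] <- sin(angle[, even, drop = FALSE])
  pe[, odd] <- cos(angle[, odd, drop = FALSE])
  pe
}

init_attn <- function(d, sd) {
  list(Wq = matrix(rnorm(d * d, sd = sd), d, d),
       Wk = matrix(rnorm(d * d, sd = sd), d, d),
       Wv = matrix(rnorm(d * d, sd = sd), d, d),
       Wo = matrix(rnorm(d * d, sd = sd), d, d))
}

init_ffn <- function(d, f, sd) {
  list(W1 = matrix(rnorm(d * f, sd = sd), d, f), b1 = numeric(f),
       W2 = matrix(rnorm(f * d, sd = sd), f, d), b2 = numeric(d))
}

init_transformer <- function(vocab_size, cfg) {
  d <- cfg$model_dim
  sd <- 1 / sqrt(d)
  layers <- cfg$layers
  list(
    Emb = matrix(rnorm(vocab_size * d, sd = 0.1), vocab_size, d),
    enc = lapply(seq_len(layers), function(l)
      list(attn = init_attn(d, sd), ffn = init_ffn(d, cfg$ffn_dim, sd))),
    dec = lapply(seq_len(layers), function(l)
      list(self = init_attn(d, sd), cross = init_attn(d, sd),
           ffn = init_ffn(d, cfg$ffn_dim, sd))),
    Wout = matrix(rnorm(d * vocab_size, sd = sd), d, vocab_size),
    bout = numeric(vocab_size)
  )
}

# ---- multi-head attention ---------------------------------------------------

mha_forward <- function(Xq, Xkv, p, heads, causal = FALSE) {
  d <- ncol(Xq); dh <- d / heads; scal <- 1 / sqrt(dh)
  Q <- Xq %*% p$Wq; K <- Xkv %*% p$Wk; V <- Xkv %*% p$Wv
  O <- matrix(0, nrow(Xq), d)
  A <- vector("list", heads)
  for (h in seq_len(heads)) {
    idx <- ((h - 1) * dh + 1):(h * dh)
    S <- (Q[, idx, drop = FALSE] %*% t(K[, idx, drop = FALSE])) * scal
    if (causal) S[upper.tri(S)] <- -Inf
    S <- S - apply(S, 1, max)
    E <- exp(S)
    Ah <- E / rowSums(E)
    A[[h]] <- Ah
    O[, idx] <- Ah %*% V[, idx, drop = FALSE]
  }
  out <- O %*% p$Wo
  list(out = out, cache = list(Xq = Xq, Xkv = Xkv, Q = Q, K = K, V = V,
                               A = A, O = O, heads = heads, scal = scal))
}

mha_backward <- function(dOut, p, cache) {
  heads <- cache$heads; scal <- cache$scal
  d <- ncol(dOut); dh <- d / heads
  dWo <- crossprod(cache$O, dOut)
  dO <- dOut %*% t(p$Wo)
  dQ <- matrix(0, nrow(cache$Q), d)
  dK <- matrix(0, nrow(cache$K), d)
  dV <- matrix(0, nrow(cache$V), d)
  for (h in seq_len(heads)) {
    idx <- ((h - 1) * dh + 1):(h * dh)
    Ah <- cache$A[[h]]
    dOh <- dO[, idx, drop = FALSE]
    dAh <- dOh %*% t(cache$V[, idx, drop = FALSE])
    dV[, idx] <- crossprod(Ah, dOh)
    dS <- Ah * (dAh - rowSums(dAh * Ah))
    dQ[, idx] <- (dS %*% cache$K[, idx, drop = FALSE]) * scal
    dK[, idx] <- (crossprod(dS, cache$Q[, idx, drop = FALSE])) * scal
  }
  list(dXq = dQ %*% t(p$Wq),
       dXkv = dK %*% t(p$Wk) + dV %*% t(p$Wv),
       grads = list(Wq = crossprod(cache$Xq, dQ),
                    Wk = crossprod(cache$Xkv, dK),
                    Wv = crossprod(cache$Xkv, dV),
                    Wo = dWo))
}

ffn_forward <- function(X, p) {
  Z <- sweep(X %*% p$W1, 2, p$b1, "+")
  H <- pmax(Z, 0)
  out <- sweep(H %*% p$W2, 2, p$b2, "+")
  list(out = out, cache = list(X = X, Z = Z, H = H))
}

ffn_backward <- function(dOut, p, cache) {
  dH <- dOut %*% t(p$W2)
  dZ <- dH * (cache$Z > 0)
  list(dX = dZ %*% t(p$W1),
       grads = list(W1 = crossprod(cache$X, dZ), b1 = colSums(dZ),
                    W2 = crossprod(cache$H, dOut), b2 = colSums(dOut)))
}

# ---- encoder / decoder ------------------------------------------------------

encoder_forward <- function(idx, model, cfg, pe) {
  X <- model$Emb[idx, , drop = FALSE] + pe[seq_along(idx), , drop = FALSE]
  caches <- vector("list", cfg$layers)
  for (l in seq_len(cfg$layers)) {
    a <- mha_forward(X, X, model$enc[[l]]$attn, cfg$heads)
    X1 <- X + a$out
    f <- ffn_forward(X1, model$enc[[l]]$ffn)
    caches[[l]] <- list(attn = a$cache, ffn = f$cache)
    X <- X1 + f$out
  }
  list(M = X, caches = caches)
}

decoder_forward <- function(idx_in, M, model, cfg, pe) {
  Y <- model$Emb[idx_in, , drop = FALSE] + pe[seq_along(idx_in), , drop = FALSE]
  caches <- vector("list", cfg$layers)
  for (l in seq_len(cfg$layers)) {
    s <- mha_forward(Y, Y, model$dec[[l]]$self, cfg$heads, causal = TRUE)
    Y1 <- Y + s$out
    x <- mha_forward(Y1, M, model$dec[[l]]$cross, cfg$heads)
    Y2 <- Y1 + x$out
    f <- ffn_forward(Y2, model$dec[[l]]$ffn)
    caches[[l]] <- list(self = s$cache, cross = x$cache, ffn = f$cache)
    Y <- Y2 + f$out
  }
  list(Y = Y, caches = caches)
}

# full forward pass with teacher forcing; returns loss and caches
ae_forward <- function(idx, model, cfg, pe, bos, eos) {
  enc <- encoder_forward(idx, model, cfg, pe)
  idx_in <- c(bos, idx)
  idx_out <- c(idx, eos)
  dec <- decoder_forward(idx_in, enc$M, model, cfg, pe)
  logits <- sweep(dec$Y %*% model$Wout, 2, model$bout, "+")
  mx <- apply(logits, 1, max)
  lse <- mx + log(rowSums(exp(logits - mx)))
  picked <- logits[cbind(seq_along(idx_out), idx_out)]
  loss <- mean(lse - picked)
  list(loss = loss, logits = logits, enc = enc, dec = dec,
       idx_in = idx_in, idx_out = idx_out)
}

ae_backward <- function(fw, model, cfg) {
  idx_out <- fw$idx_out
  S <- length(idx_out)
  P <- exp(fw$logits - apply(fw$logits, 1, max))
  P <- P / rowSums(P)
  dLogits <- P
  dLogits[cbind(seq_len(S), idx_out)] <-
    dLogits[cbind(seq_len(S), idx_out)] - 1
  dLogits <- dLogits / S
  g <- list(Emb = matrix(0, nrow(model$Emb), ncol(model$Emb)),
            enc = vector("list", cfg$layers),
            dec = vector("list", cfg$layers),
            Wout = crossprod(fw$dec$Y, dLogits),
            bout = colSums(dLogits))
  dY <- dLogits %*% t(model$Wout)
  dM <- matrix(0, nrow(fw$enc$M), ncol(fw$enc$M))
  for (l in rev(seq_len(cfg$layers))) {
    cc <- fw$dec$caches[[l]]
    fb <- ffn_backward(dY, model$dec[[l]]$ffn, cc$ffn)
    dY2 <- dY + fb$dX
    xb <- mha_backward(dY2, model$dec[[l]]$cross, cc$cross)
    dM <- dM + xb$dXkv
    dY1 <- dY2 + xb$dXq
    sb <- mha_backward(dY1, model$dec[[l]]$self, cc$self)
    dY <- dY1 + sb$dXq + sb$dXkv
    g$dec[[l]] <- list(self = sb$grads, cross = xb$grads, ffn = fb$grads)
  }
  for (i in seq_along(fw$idx_in))
    g$Emb[fw$idx_in[i], ] <- g$Emb[fw$idx_in[i], ] + dY[i, ]
  dX <- dM
  for (l in rev(seq_len(cfg$layers))) {
    cc <- fw$enc$caches[[l]]
    fb <- ffn_backward(dX, model$enc[[l]]$ffn, cc$ffn)
    dX1 <- dX + fb$dX
    ab <- mha_backward(dX1, model$enc[[l]]$attn, cc$attn)
    dX <- dX1 + ab$dXq + ab$dXkv
    g$enc[[l]] <- list(attn = ab$grads, ffn = fb$grads)
  }
  idx <- fw$idx_in[-1]
  for (i in seq_along(idx))
    g$Emb[idx[i], ] <- g$Emb[idx[i], ] + dX[i, ]
  g
}

# ---- Adam over the nested parameter list ------------------------------------

flatten_params <- function(p, prefix = "") {
  if (is.list(p) && !is.null(names(p)) && all(vapply(p, is.numeric, TRUE)))
    return(setNames(p, paste0(prefix, names(p))))
  out <- list()
  nm <- names(p) %||% as.character(seq_along(p))
  for (i in seq_along(p)) {
    key <- paste0(prefix, nm[i], ".")
    if (is.numeric(p[[i]])) {
      out[[paste0(prefix, nm[i])]] <- p[[i]]
    } else {
      out <- c(out, flatten_params(p[[i]], key))
    }
  }
  out
}

adam_step <- function(flat_p, flat_g, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(flat_g)) {
    g <- flat_g[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    flat_p[[nm]] <- flat_p[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(p = flat_p, state = state)
}

unflatten_into <- function(p, flat, prefix = "") {
  nm <- names(p) %||% as.character(seq_along(p))
  for (i in seq_along(p)) {
    key <- paste0(prefix, nm[i])
    if (is.numeric(p[[i]])) {
      p[[i]] <- flat[[key]]
    } else {
      p[[i]] <- unflatten_into(p[[i]], flat, paste0(key, "."))
    }
  }
  p
}

# ---- training and embedding -------------------------------------------------

#' Train the SMILES sequence autoencoder
#'
#' Tokenizes the corpus, builds the vocabulary, and trains the
#' encoder-decoder to reproduce each input sequence (teacher forcing,
#' token-level cross-entropy). Duplicate SMILES contribute through gradient
#' weights rather than repeated passes. Deterministic given `cfg$seed`.
#'
#' @param compounds CompoundSet: named character vector id -> SMILES.
#' @param cfg a [smiles_ae_config()].
#' @return object of class `smiles_ae` holding parameters, vocabulary and
#'   config, with the per-epoch training loss in `$loss_history`.
#' @export
train_autoencoder <- function(compounds, cfg = smiles_ae_config()) {
  if (!length(compounds)) stop("empty SMILES corpus")
  seqs <- list(); weights <- c(); skipped <- 0L
  for (i in seq_along(compounds)) {
    toks <- tryCatch(tokenize_smiles(compounds[[i]]), error = function(e) NULL)
    if (is.null(toks)) { skipped <- skipped + 1L; next }
    if (length(toks) + 1L > cfg$max_len) {
      hx_log("smiles_ae", "sequence ", names(compounds)[i] %||% i,
             " exceeds max_len; skipped")
      skipped <- skipped + 1L
      next
    }
    key <- paste(toks, collapse = "\r")
    if (is.null(seqs[[key]])) {
      seqs[[key]] <- toks
      weights[key] <- 1
    } else weights[key] <- weights[key] + 1
  }
  if (!length(seqs)) stop("all sequences skipped; nothing to train on")
  weights <- weights / mean(weights)
  vocab <- build_vocab(seqs)
  set.seed(cfg$seed)
  model <- init_transformer(length(vocab), cfg)
  pe <- positional_encoding(cfg$max_len, cfg$model_dim)
  bos <- vocab[["<bos>"]]; eos <- vocab[["<eos>"]]
  enc_idx <- lapply(seqs, encode_tokens, vocab = vocab)
  flat <- flatten_params(model)
  state <- list(m = lapply(flat, function(x) x * 0),
                v = lapply(flat, function(x) x * 0))
  t <- 0L
  losses <- numeric(cfg$epochs)
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample(length(enc_idx))
    tot <- 0
    for (j in ord) {
      fw <- ae_forward(enc_idx[[j]], model, cfg, pe, bos, eos)
      g <- ae_backward(fw, model, cfg)
      fg <- flatten_params(g)
      w <- weights[j]
      if (w != 1) fg <- lapply(fg, function(x) x * w)
      t <- t + 1L
      upd <- adam_step(flat, fg, state, cfg$learning_rate, t)
      flat <- upd$p; state <- upd$state
      model <- unflatten_into(model, flat)
      tot <- tot + fw$loss * w
    }
    losses[epoch] <- tot / sum(weights)
    if (epoch %% 25 == 0 || epoch == cfg$epochs)
      hx_log("smiles_ae", "epoch ", epoch, " loss ",
             formatC(losses[epoch], digits = 4, format = "f"))
  }
  structure(list(params = model, vocab = vocab, config = cfg,
                 loss_history = losses, skipped = skipped),
            class = "smiles_ae")
}

#' Structural embeddings from the trained encoder
#'
#' Runs the encoder on each compound and mean-pools the final encoder
#' layer's position outputs into one `model_dim` vector. A pure function of
#' the model state and the SMILES string; compounds whose SMILES cannot be
#' tokenized are omitted with a log line.
#'
#' @param model a trained `smiles_ae`.
#' @param compounds CompoundSet (named id -> SMILES).
#' @return numeric matrix, one row per embeddable compound.
#' @export
embed_structures <- function(model, compounds) {
  stopifnot(inherits(model, "smiles_ae"))
  cfg <- model$config
  pe <- positional_encoding(cfg$max_len, cfg$model_dim)
  rows <- list()
  for (id in names(compounds)) {
    toks <- tryCatch(tokenize_smiles(compounds[[id]]), error = function(e) NULL)
    if (is.null(toks) || length(toks) + 1L > cfg$max_len) {
      hx_log("smiles_ae", "cannot embed ", id, "; omitted")
      next
    }
    idx <- encode_tokens(toks, model$vocab)
    M <- encoder_forward(idx, model$params, cfg, pe)$M
    rows[[id]] <- colMeans(M)
  }
  if (!length(rows)) stop("no embeddable compounds")
  do.call(rbind, rows)
}

#' Teacher-forced reconstruction accuracy
#'
#' Fraction of target tokens (input sequence plus end marker) recovered by
#' the argmax of the decoder logits under teacher forcing.
#'
#' @param model a trained `smiles_ae`.
#' @param compounds CompoundSet.
#' @return accuracy in \[0, 1\].
#' @export
reconstruction_accuracy <- function(model, compounds) {
  cfg <- model$config
  pe <- positional_encoding(cfg$max_len, cfg$model_dim)
  bos <- model$vocab[["<bos>"]]; eos <- model$vocab[["<eos>"]]
  hit <- 0; total <- 0
  for (id in names(compounds)) {
    idx <- encode_tokens(tokenize_smiles(compounds[[id]]), model$vocab)
    fw <- ae_forward(idx, model$params, cfg, pe, bos, eos)
    pred <- max.col(fw$logits, ties.method = "first")
    hit <- hit + sum(pred == fw$idx_out)
    total <- total + length(fw$idx_out)
  }
  hit / total
}

#' Save / load a trained autoencoder
#' @param model a `smiles_ae`.
#' @param path file path (RDS with embedded vocabulary and config).
#' @return the path (save) or the model (load).
#' @export
save_smiles_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_smiles_model
#' @export
load_smiles_model <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "smiles_ae"))
  m
}
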
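# Similarity-space comparison of embedding variants (structure-only,
# function-only, global) and t-SNE export for visual inspection.

#' Cosine similarity mapped to [0, 1]
#'
#' Raw cosine clipped below at zero (default), preserving the conventional
#' 0.85 similar-compound threshold semantics; `method = "shift"` uses
#' `(1 + cos) / 2` instead.
#'
#' @param x,y nonzero numeric vectors of equal length.
#' @param method `"clip"` (default) or `"shift"`.
#' @return similarity in \[0, 1\].
#' @export
cosine_map <- function(x, y, method = c("clip", "shift")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) stop("cosine undefined for a zero vector")
  cs <- sum(x * y) / (nx * ny)
  cs <- max(min(cs, 1), -1)
  if (method == "clip") max(cs, 0) else (1 + cs) / 2
}

#' Pairwise mapped-cosine similarity matrix with threshold flags
#'
#' @param emb embedding matrix with id rownames.
#' @param ids optional subset of rownames; default all.
#' @param threshold flag pairs with similarity strictly above this; 0.85.
#' @param method passed to [cosine_map()].
#' @return list with `matrix` (symmetric, unit diagonal) and `flagged`
#'   (data.frame of significantly similar pairs).
#' @export
similarity_matrix <- function(emb, ids = NULL, threshold = 0.85,
                              method = c("clip", "shift")) {
  method <- match.arg(method)
  ids <- ids %||% rownames(emb)
  if (!all(ids %in% rownames(emb))) stop("ids must be embedding rows")
  if (length(ids) < 2) stop("at least two ids required")
  X <- emb[ids, , drop = FALSE]
  nrm <- sqrt(rowSums(X^2))
  if (any(nrm == 0)) stop("zero embedding vector for ",
                          ids[which(nrm == 0)[1]])
  C <- tcrossprod(X / nrm)
  C[C > 1] <- 1; C[C < -1] <- -1
  S <- if (method == "clip") pmax(C, 0) else (1 + C) / 2
  diag(S) <- 1
  S <- (S + t(S)) / 2
  dimnames(S) <- list(ids, ids)
  up <- which(upper.tri(S) & S > threshold, arr.ind = TRUE)
  flagged <- data.frame(a = ids[up[, 1]], b = ids[up[, 2]],
                        score = S[up], stringsAsFactors = FALSE)
  list(matrix = S, flagged = flagged[order(-flagged$score), , drop = FALSE])
}

#' Dispersion of off-diagonal similarity scores
#'
#' Variance of the upper-triangle scores: the scalar behind the qualitative
#' claim that global embeddings spread compound similarities more widely
#' than structure-only or function-only embeddings.
#'
#' @param sim a matrix from [similarity_matrix()] (its `$matrix`).
#' @return variance of off-diagonal scores.
#' @export
similarity_dispersion <- function(sim) {
  var(sim[upper.tri(sim)])
}

#' t-SNE projection of an embedding matrix
#'
#' Exact t-SNE (adaptive-bandwidth Gaussian input affinities matched to the
#' target perplexity by bisection; Student-t output kernel; gradient descent
#' with momentum, gain adaptation and early exaggeration). Exact pairwise
#' computation is appropriate at the tens-of-points scale used here.
#'
#' @param emb embedding matrix with id rownames.
#' @param dims output dimensionality, 2 or 3.
#' @param perplexity effective neighbour count; must be < (n - 1) / 3.
#' @param seed RNG seed for the initial layout.
#' @param max_iter gradient iterations; default 500.
#' @return data.frame with `id` and coordinate columns `x`, `y` (and `z`).
#' @export
project_tsne <- function(emb, dims = 2, perplexity = 5, seed = 1,
                         max_iter = 500) {
  if (!dims %in% 2:3) stop("dims must be 2 or 3")
  n <- nrow(emb)
  if (n < dims + 2) stop("too few points for a ", dims, "-d projection")
  if (perplexity >= (n - 1) / 3) stop("perplexity too large for n = ", n)
  D <- as.matrix(dist(emb))^2
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; lo <- -Inf; hi <- Inf
    Di <- D[i, -i]
    for (iter in 1:60) {
      w <- exp(-Di * beta)
      sw <- sum(w)
      if (sw == 0) { H <- 0; Pi <- w }
      else {
        Pi <- w / sw
        H <- -sum(Pi[Pi > 0] * log(Pi[Pi > 0]))
      }
      if (abs(H - logU) < 1e-6) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- Pi
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  set.seed(seed)
  Y <- matrix(rnorm(n * dims, sd = 1e-4), n, dims)
  dY <- matrix(0, n, dims)
  gains <- matrix(1, n, dims)
  momentum <- 0.5
  exaggeration <- 4
  eta <- 100
  for (iter in seq_len(max_iter)) {
    Pe <- if (iter <= 100) P * exaggeration else P
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    gains <- ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    dY <- momentum * dY - eta * gains * grad
    Y <- Y + dY
    Y <- sweep(Y, 2, colMeans(Y))
    if (iter == 250) momentum <- 0.8
  }
  out <- data.frame(id = rownames(emb), stringsAsFactors = FALSE)
  out$x <- Y[, 1]; out$y <- Y[, 2]
  if (dims == 3) out$z <- Y[, 3]
  out
}
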
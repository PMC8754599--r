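# Attention-weighted neighbour aggregation over the heterogeneous network
# (GO nodes excluded; they act through the functional embeddings).
#
# Content states: drugs enter as a learned linear fusion of structural and
# functional embeddings; proteins and diseases as learned projections of
# their node2vec vectors. Each layer computes softmax attention over
# neighbours (score: leaky-ReLU of a decomposed pairwise form a1.Wh_i +
# a2.Wh_j), aggregates transformed neighbour states, adds a transformed self
# term, and applies a nonlinearity. Parameters are trained by binary
# cross-entropy link prediction on training-fold drug-disease pairs only.

#' GNN configuration
#'
#' @param layers aggregation rounds; default 2, must be >= 1.
#' @param hidden_dim width of hidden and output embeddings; default 64.
#' @param epochs full-batch Adam epochs; default 150.
#' @param learning_rate Adam step size; default 5e-3.
#' @param negatives_per_pos negative pairs sampled per positive each epoch.
#' @param activation `"tanh"` (default) or `"identity"`.
#' @param attn_slope leaky-ReLU slope for attention scores; default 0.2.
#' @param seed RNG seed.
#' @return list of class `gnn_config`.
#' @export
gnn_config <- function(layers = 2, hidden_dim = 64, epochs = 150,
                       learning_rate = 5e-3, negatives_per_pos = 1,
                       activation = c("tanh", "identity"), attn_slope = 0.2,
                       seed = 1) {
  stopifnot(layers >= 1, hidden_dim >= 2, epochs >= 0, learning_rate > 0)
  activation <- match.arg(activation)
  structure(list(layers = layers, hidden_dim = hidden_dim, epochs = epochs,
                 learning_rate = learning_rate,
                 negatives_per_pos = negatives_per_pos,
                 activation = activation, attn_slope = attn_slope,
                 seed = seed),
            class = "gnn_config")
}

#' Concatenate structural and functional drug content
#'
#' Rows are aligned on the union of drug ids; a missing half is zero-filled
#' and the drug flagged. The learned projection to `hidden_dim` happens
#' inside the model; this returns the raw fused input.
#'
#' @param structural matrix from [embed_structures()] (may be `NULL`).
#' @param functional matrix from [functional_embeddings()] (may be `NULL`).
#' @return matrix `[structural || functional]` with attribute
#'   `"zero_filled"` naming drugs missing one half.
#' @export
fuse_drug_content <- function(structural, functional) {
  if (is.null(structural) && is.null(functional))
    stop("drug must be present in at least one input")
  ids <- sort(unique(c(rownames(structural), rownames(functional))))
  ds <- if (is.null(structural)) 0L else ncol(structural)
  df <- if (is.null(functional)) 0L else ncol(functional)
  out <- matrix(0, length(ids), ds + df, dimnames = list(ids, NULL))
  flagged <- character(0)
  for (id in ids) {
    if (ds && id %in% rownames(structural))
      out[id, seq_len(ds)] <- structural[id, ]
    else if (ds) flagged <- c(flagged, id)
    if (df && id %in% rownames(functional))
      out[id, ds + seq_len(df)] <- functional[id, ]
    else if (df) flagged <- c(flagged, id)
  }
  if (length(flagged))
    hx_log("gnn", length(unique(flagged)),
           " drug(s) zero-filled for a missing content half")
  attr(out, "zero_filled") <- unique(flagged)
  out
}

#' Attention weights of one node over its neighbours
#'
#' Softmax of the leaky-ReLU pairwise score `a1.(W h_center) +
#' a2.(W h_neighbor)`. With zero score parameters the weights are uniform;
#' with a single neighbour the weight is 1. With no neighbours the center
#' state passes through unchanged, by convention handled by the caller.
#'
#' @param center numeric state vector of the aggregating node.
#' @param neighbors matrix of neighbour states (rows).
#' @param a1,a2 score vectors (default zero: uniform attention).
#' @param W transform applied before scoring (default identity).
#' @param slope leaky-ReLU slope.
#' @return numeric vector of weights summing to 1.
#' @export
attention_weights <- function(center, neighbors, a1 = NULL, a2 = NULL,
                              W = NULL, slope = 0.2) {
  if (is.null(dim(neighbors))) neighbors <- matrix(neighbors, nrow = 1)
  if (!nrow(neighbors)) stop("at least one neighbour required")
  d <- length(center)
  W <- W %||% diag(d)
  a1 <- a1 %||% numeric(ncol(W))
  a2 <- a2 %||% numeric(ncol(W))
  uc <- as.numeric(center %*% W)
  un <- neighbors %*% W
  g <- sum(uc * a1) + as.numeric(un %*% a2)
  s <- ifelse(g > 0, g, slope * g)
  e <- exp(s - max(s))
  e / sum(e)
}

leaky <- function(x, slope) ifelse(x > 0, x, slope * x)
dleaky <- function(x, slope) ifelse(x > 0, 1, slope)

# group rowsum returning a full n-row matrix
rowsum_full <- function(x, g, n) {
  out <- matrix(0, n, ncol(x))
  agg <- rowsum(x, g)
  out[as.integer(rownames(agg)), ] <- agg
  out
}

init_gnn_params <- function(dims_in, cfg) {
  h <- cfg$hidden_dim
  sd <- 1 / sqrt(h)
  proj <- lapply(dims_in, function(d)
    matrix(rnorm(d * h, sd = 1 / sqrt(max(d, 1))), d, h))
  layers <- lapply(seq_len(cfg$layers), function(l)
    list(W = matrix(rnorm(h * h, sd = sd), h, h),
         Ws = matrix(rnorm(h * h, sd = sd), h, h),
         a1 = rnorm(h, sd = sd), a2 = rnorm(h, sd = sd)))
  list(proj = proj, layers = layers, bias = 0)
}

#' Identity parameters for the degenerate aggregation check
#'
#' Zero attention vectors (uniform weights), identity neighbour transform,
#' zero self transform: one layer of [propagate_states()] with
#' `activation = "identity"` then equals plain neighbourhood averaging.
#'
#' @param dim state dimension.
#' @param layers number of layers.
#' @return parameter list usable by [propagate_states()].
#' @export
identity_gnn_params <- function(dim, layers = 1) {
  list(proj = list(), layers = lapply(seq_len(layers), function(l)
    list(W = diag(dim), Ws = matrix(0, dim, dim),
         a1 = numeric(dim), a2 = numeric(dim))), bias = 0)
}

# Build directed edge index (both directions) over integer node ids.
gnn_edge_index <- function(edges, node_ids) {
  idx <- setNames(seq_along(node_ids), node_ids)
  keep <- edges$source %in% node_ids & edges$target %in% node_ids
  e <- edges[keep, , drop = FALSE]
  ei <- c(unname(idx[e$source]), unname(idx[e$target]))
  ej <- c(unname(idx[e$target]), unname(idx[e$source]))
  dup <- duplicated(cbind(ei, ej))
  list(ei = ei[!dup], ej = ej[!dup])
}

# Forward through the aggregation layers. states: n x h matrix (already
# projected content). Returns final states and per-layer caches.
gnn_layers_forward <- function(H, params, edge_index, cfg) {
  n <- nrow(H)
  ei <- edge_index$ei; ej <- edge_index$ej
  has_nb <- seq_len(n) %in% ei
  caches <- vector("list", length(params$layers))
  for (l in seq_along(params$layers)) {
    pl <- params$layers[[l]]
    U <- H %*% pl$W
    c1 <- as.numeric(U %*% pl$a1)
    c2 <- as.numeric(U %*% pl$a2)
    g <- c1[ei] + c2[ej]
    s <- leaky(g, cfg$attn_slope)
    smax <- rep(-Inf, n)
    agg <- tapply(s, ei, max)
    smax[as.integer(names(agg))] <- agg
    e <- exp(s - smax[ei])
    denom <- rowsum_full(cbind(e), ei, n)[, 1]
    alpha <- e / denom[ei]
    msg <- rowsum_full(alpha * U[ej, , drop = FALSE], ei, n)
    # isolated nodes get msg = 0: they retain their transformed self state
    Z <- msg + H %*% pl$Ws
    Hn <- if (cfg$activation == "tanh") tanh(Z) else Z
    caches[[l]] <- list(H = H, U = U, g = g, alpha = alpha, Z = Z, Hn = Hn)
    H <- Hn
  }
  list(H = H, caches = caches, has_nb = has_nb)
}

gnn_layers_backward <- function(dH, params, edge_index, cfg, fw) {
  n <- nrow(dH)
  ei <- edge_index$ei; ej <- edge_index$ej
  grads <- vector("list", length(params$layers))
  for (l in rev(seq_along(params$layers))) {
    pl <- params$layers[[l]]
    cc <- fw$caches[[l]]
    dZ <- if (cfg$activation == "tanh") dH * (1 - cc$Hn^2) else dH
    gWs <- crossprod(cc$H, dZ)
    dHprev <- dZ %*% t(pl$Ws)
    # message part
    dmsg <- dZ
    dalpha <- rowSums(dmsg[ei, , drop = FALSE] * cc$U[ej, , drop = FALSE])
    dU <- rowsum_full(cc$alpha * dmsg[ei, , drop = FALSE], ej, n)
    sum_ad <- rowsum_full(cbind(cc$alpha * dalpha), ei, n)[, 1]
    ds <- cc$alpha * (dalpha - sum_ad[ei])
    dg <- ds * dleaky(cc$g, cfg$attn_slope)
    dc1 <- rowsum_full(cbind(dg), ei, n)[, 1]
    dc2 <- rowsum_full(cbind(dg), ej, n)[, 1]
    ga1 <- as.numeric(crossprod(cc$U, dc1))
    ga2 <- as.numeric(crossprod(cc$U, dc2))
    dU <- dU + outer(dc1, pl$a1) + outer(dc2, pl$a2)
    gW <- crossprod(cc$H, dU)
    dHprev <- dHprev + dU %*% t(pl$W)
    grads[[l]] <- list(W = gW, Ws = gWs, a1 = ga1, a2 = ga2)
    dH <- dHprev
  }
  list(layer_grads = grads, dH0 = dH)
}

#' Forward propagation with given parameters
#'
#' Pure forward pass of the aggregation layers over already-projected
#' states; used both inside training and for degenerate closed-form checks
#' (see [identity_gnn_params()]). Nodes without neighbours keep their
#' transformed self state.
#'
#' @param edges data.frame of edges (any relations; traversed undirected).
#' @param states numeric matrix with node-id rownames.
#' @param params parameter list (`layers` of `W`, `Ws`, `a1`, `a2`).
#' @param cfg a [gnn_config()] (its `layers` must match `params`).
#' @return matrix of propagated states.
#' @export
propagate_states <- function(edges, states, params, cfg = gnn_config()) {
  stopifnot(length(params$layers) == cfg$layers)
  edge_index <- gnn_edge_index(edges, rownames(states))
  out <- gnn_layers_forward(states, params, edge_index, cfg)$H
  rownames(out) <- rownames(states)
  out
}

# content projection forward: list of blocks {ids, X (raw), which proj}
project_content <- function(content, params) {
  H <- matrix(0, 0, 0)
  rows <- lapply(seq_along(content), function(b)
    content[[b]]$X %*% params$proj[[b]])
  H <- do.call(rbind, rows)
  rownames(H) <- unlist(lapply(content, `[[`, "ids"))
  H
}

#' Train the attention GNN on training-fold drug-disease links
#'
#' Builds content states (drug fusion + protein/disease projections), runs
#' `cfg$layers` rounds of attention aggregation, scores drug-disease pairs
#' by a sigmoid of the embedding dot product, and minimizes binary
#' cross-entropy over the supplied training positives plus per-epoch
#' sampled negatives. Only the pairs given in `train_pairs` ever touch the
#' parameters: held-out fold edges stay outside both the objective and the
#' message graph.
#'
#' @param edges aggregation edges (drug_target, ppi, disease_gene and
#'   training-fold drug_disease only).
#' @param drug_content fused drug matrix from [fuse_drug_content()].
#' @param protein_emb,disease_emb node2vec matrices.
#' @param train_pairs data.frame with columns `drug`, `disease`, `label`.
#' @param cfg a [gnn_config()].
#' @return object of class `gnn_model` with `$embeddings` (GlobalEmbedding
#'   matrix over all non-GO nodes) and `$params`.
#' @export
train_gnn <- function(edges, drug_content, protein_emb, disease_emb,
                      train_pairs, cfg = gnn_config()) {
  stopifnot(cfg$layers >= 1)
  content <- list(
    list(ids = rownames(drug_content), X = drug_content),
    list(ids = rownames(protein_emb), X = protein_emb),
    list(ids = rownames(disease_emb), X = disease_emb))
  content <- Filter(function(b) length(b$ids) > 0, content)
  node_ids <- unlist(lapply(content, `[[`, "ids"))
  if (anyDuplicated(node_ids)) stop("duplicate node ids across content blocks")
  edges <- edges[edges$relation != "drug_go" &
                   node_kind(edges$source) != "go" &
                   node_kind(edges$target) != "go", , drop = FALSE]
  edge_index <- gnn_edge_index(edges, node_ids)
  set.seed(cfg$seed)
  params <- init_gnn_params(vapply(content, function(b) ncol(b$X), 1L), cfg)
  node_pos <- setNames(seq_along(node_ids), node_ids)

  pos <- train_pairs[train_pairs$label == 1, , drop = FALSE]
  neg_given <- train_pairs[train_pairs$label == 0, , drop = FALSE]
  pos <- pos[pos$drug %in% node_ids & pos$disease %in% node_ids, ,
             drop = FALSE]
  neg_given <- neg_given[neg_given$drug %in% node_ids &
                           neg_given$disease %in% node_ids, , drop = FALSE]
  if (!nrow(pos) && cfg$epochs > 0)
    stop("no usable positive training pairs")
  drugs <- node_ids[node_kind(node_ids) == "drug"]
  diseases <- node_ids[node_kind(node_ids) == "disease"]
  pos_key <- paste(pos$drug, pos$disease)

  flat <- flatten_params(params)
  state <- list(m = lapply(flat, function(x) x * 0),
                v = lapply(flat, function(x) x * 0))
  if (cfg$epochs > 0) {
    for (epoch in seq_len(cfg$epochs)) {
      # negatives: supplied ones plus fresh uniform draws from unknown pairs
      n_extra <- max(0L, nrow(pos) * cfg$negatives_per_pos - nrow(neg_given))
      if (n_extra > 0) {
        cand_d <- sample(drugs, 3L * n_extra, replace = TRUE)
        cand_z <- sample(diseases, 3L * n_extra, replace = TRUE)
        ok <- !(paste(cand_d, cand_z) %in% pos_key)
        cand <- head(which(ok), n_extra)
        neg <- rbind(neg_given[, c("drug", "disease")],
                     data.frame(drug = cand_d[cand], disease = cand_z[cand]))
      } else neg <- neg_given[, c("drug", "disease")]
      pd <- c(pos$drug, neg$drug)
      pz <- c(pos$disease, neg$disease)
      y <- c(rep(1, nrow(pos)), rep(0, nrow(neg)))

      H0 <- project_content(content, params)
      fw <- gnn_layers_forward(H0, params, edge_index, cfg)
      Z <- fw$H
      iu <- unname(node_pos[pd]); iv <- unname(node_pos[pz])
      logits <- rowSums(Z[iu, , drop = FALSE] * Z[iv, , drop = FALSE]) +
        params$bias
      prob <- 1 / (1 + exp(-logits))
      dlogit <- (prob - y) / length(y)
      dZ <- matrix(0, nrow(Z), ncol(Z))
      dZu <- dlogit * Z[iv, , drop = FALSE]
      dZv <- dlogit * Z[iu, , drop = FALSE]
      dZ <- dZ + rowsum_full(dZu, iu, nrow(Z)) + rowsum_full(dZv, iv, nrow(Z))
      bw <- gnn_layers_backward(dZ, params, edge_index, cfg, fw)
      # content projection grads
      gproj <- vector("list", length(content))
      off <- 0L
      for (b in seq_along(content)) {
        nb <- length(content[[b]]$ids)
        gproj[[b]] <- crossprod(content[[b]]$X,
                                bw$dH0[off + seq_len(nb), , drop = FALSE])
        off <- off + nb
      }
      grads <- list(proj = gproj, layers = bw$layer_grads,
                    bias = sum(dlogit))
      fg <- flatten_params(grads)
      upd <- adam_step(flat, fg, state, cfg$learning_rate, epoch)
      flat <- upd$p; state <- upd$state
      params <- unflatten_into(params, flat)
    }
  }
  H0 <- project_content(content, params)
  Z <- gnn_layers_forward(H0, params, edge_index, cfg)$H
  rownames(Z) <- node_ids
  structure(list(params = params, embeddings = Z, config = cfg,
                 node_ids = node_ids),
            class = "gnn_model")
}

#' Global embeddings of a trained GNN
#' @param model a `gnn_model`.
#' @return matrix, one row per non-GO node.
#' @export
global_embeddings <- function(model) {
  stopifnot(inherits(model, "gnn_model"))
  model$embeddings
}
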
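test_that("drug content fusion concatenates and zero-fills", {
  s <- matrix(1:6 / 10, 2, 3, dimnames = list(c("drug:a", "drug:b"), NULL))
  f <- matrix(1:4 / 10, 2, 2, dimnames = list(c("drug:b", "drug:c"), NULL))
  x <- suppressMessages(fuse_drug_content(s, f))
  expect_equal(dim(x), c(3, 5))
  expect_equal(rownames(x), c("drug:a", "drug:b", "drug:c"))
  expect_equal(unname(x["drug:a", 4:5]), c(0, 0))     # functional zero-fill
  expect_equal(unname(x["drug:c", 1:3]), c(0, 0, 0))  # structural zero-fill
  expect_setequal(attr(x, "zero_filled"), c("drug:a", "drug:c"))
  expect_equal(unname(x["drug:b", ]), c(s["drug:b", ], f["drug:b", ]))
  x2 <- suppressMessages(fuse_drug_content(s, f))
  expect_identical(x, x2)
  expect_error(fuse_drug_content(NULL, NULL), "at least one input")
})

test_that("attention weights are a softmax over neighbours", {
  center <- c(1, 2)
  expect_equal(attention_weights(center, rbind(c(3, 1), c(3, 1))),
               c(0.5, 0.5))
  expect_equal(attention_weights(center, rbind(c(9, 9))), 1)
  set.seed(8)
  for (i in 1:10) {
    k <- sample(1:6, 1)
    w <- attention_weights(rnorm(4), matrix(rnorm(4 * k), k),
                           a1 = rnorm(4), a2 = rnorm(4),
                           W = matrix(rnorm(16), 4))
    expect_true(all(w >= 0))
    expect_equal(sum(w), 1, tolerance = 1e-9)
  }
})

test_that("degenerate propagation equals explicit neighbourhood averaging", {
  # toy closed form: neighbours [1,0] and [0,1] average to [0.5, 0.5]
  edges <- data.frame(source = c("drug:a", "drug:a"),
                      target = c("disease:b", "disease:c"),
                      relation = "drug_disease")
  states <- rbind("drug:a" = c(0, 0), "disease:b" = c(1, 0),
                  "disease:c" = c(0, 1))
  out <- propagate_states(edges, states, identity_gnn_params(2, 1),
                          gnn_config(layers = 1, hidden_dim = 2,
                                     activation = "identity"))
  expect_equal(unname(out["drug:a", ]), c(0.5, 0.5), tolerance = 1e-9)

  # random graphs up to 6 nodes, 2 layers: oracle is the row-normalized
  # adjacency matrix applied twice
  set.seed(31)
  for (rep in 1:10) {
    n <- sample(3:6, 1)
    ids <- paste0("drug:", letters[1:n])
    pairs <- t(utils::combn(ids, 2))
    keep <- runif(nrow(pairs)) < 0.6
    if (!any(keep)) next
    edges <- data.frame(source = pairs[keep, 1], target = pairs[keep, 2],
                        relation = "drug_target")
    X <- matrix(rnorm(n * 3), n, 3, dimnames = list(ids, NULL))
    A <- matrix(0, n, n, dimnames = list(ids, ids))
    A[cbind(edges$source, edges$target)] <- 1
    A <- A + t(A)
    P <- A / pmax(rowSums(A), 1)  # isolated rows stay zero
    oracle <- P %*% (P %*% X)
    got <- propagate_states(edges, X, identity_gnn_params(3, 2),
                            gnn_config(layers = 2, hidden_dim = 3,
                                       activation = "identity"))
    expect_equal(unname(got), unname(oracle), tolerance = 1e-9)
  }
})

test_that("attention rows sum to one at every layer of a trained model", {
  net <- tiny_net()
  emb <- suppressWarnings(suppressMessages(
    benchmark_embeddings(net, seed = 3, dim = 8, ae_epochs = 3)))
  lab <- benchmark_labels(net, emb, seed = 3)
  gcfg <- gnn_config(layers = 2, hidden_dim = 8, epochs = 10, seed = 3)
  pos <- lab[lab$label == 1, ]
  edges <- rbind(emb$base_edges,
                 data.frame(source = pos$drug, target = pos$disease,
                            relation = "drug_disease"))
  model <- suppressMessages(train_gnn(edges, emb$drug_content, emb$prot_emb,
                                      emb$dis_emb, lab, gcfg))
  # recompute forward pass and check the attention normalization per layer
  content <- list(list(ids = rownames(emb$drug_content), X = emb$drug_content),
                  list(ids = rownames(emb$prot_emb), X = emb$prot_emb),
                  list(ids = rownames(emb$dis_emb), X = emb$dis_emb))
  node_ids <- unlist(lapply(content, `[[`, "ids"))
  ei <- heterorx:::gnn_edge_index(edges, node_ids)
  H0 <- heterorx:::project_content(content, model$params)
  fw <- heterorx:::gnn_layers_forward(H0, model$params, ei, gcfg)
  for (l in seq_along(fw$caches)) {
    sums <- rowsum(fw$caches[[l]]$alpha, ei$ei)
    expect_equal(unname(sums[, 1]), rep(1, nrow(sums)), tolerance = 1e-9)
  }
})

test_that("gnn training gradients match finite differences", {
  set.seed(1)
  cfg <- gnn_config(layers = 2, hidden_dim = 5, epochs = 0, seed = 2)
  dc <- matrix(rnorm(4 * 6), 4, 6, dimnames = list(paste0("drug:d", 1:4), NULL))
  pe <- matrix(rnorm(3 * 4), 3, 4, dimnames = list(paste0("protein:p", 1:3), NULL))
  de <- matrix(rnorm(2 * 4), 2, 4, dimnames = list(paste0("disease:z", 1:2), NULL))
  edges <- data.frame(
    source = c("drug:d1", "drug:d2", "protein:p1", "disease:z1"),
    target = c("protein:p1", "protein:p2", "protein:p3", "protein:p2"),
    relation = c("drug_target", "drug_target", "ppi", "disease_gene"))
  content <- list(list(ids = rownames(dc), X = dc),
                  list(ids = rownames(pe), X = pe),
                  list(ids = rownames(de), X = de))
  node_ids <- unlist(lapply(content, `[[`, "ids"))
  node_pos <- setNames(seq_along(node_ids), node_ids)
  ei <- heterorx:::gnn_edge_index(edges, node_ids)
  set.seed(5)
  params <- heterorx:::init_gnn_params(c(6, 4, 4), cfg)
  pairs <- data.frame(drug = c("drug:d1", "drug:d3"),
                      disease = c("disease:z1", "disease:z2"),
                      label = c(1, 0))
  loss_fn <- function(pp) {
    H0 <- heterorx:::project_content(content, pp)
    Z <- heterorx:::gnn_layers_forward(H0, pp, ei, cfg)$H
    iu <- unname(node_pos[pairs$drug]); iv <- unname(node_pos[pairs$disease])
    lg <- rowSums(Z[iu, , drop = FALSE] * Z[iv, , drop = FALSE]) + pp$bias
    mean(log(1 + exp(-lg)) * pairs$label + log(1 + exp(lg)) * (1 - pairs$label))
  }
  H0 <- heterorx:::project_content(content, params)
  fw <- heterorx:::gnn_layers_forward(H0, params, ei, cfg)
  Z <- fw$H
  iu <- unname(node_pos[pairs$drug]); iv <- unname(node_pos[pairs$disease])
  lg <- rowSums(Z[iu, , drop = FALSE] * Z[iv, , drop = FALSE]) + params$bias
  dlogit <- (1 / (1 + exp(-lg)) - pairs$label) / nrow(pairs)
  dZ <- heterorx:::rowsum_full(dlogit * Z[iv, , drop = FALSE], iu, nrow(Z)) +
    heterorx:::rowsum_full(dlogit * Z[iu, , drop = FALSE], iv, nrow(Z))
  bw <- heterorx:::gnn_layers_backward(dZ, params, ei, cfg, fw)
  gproj <- list(); off <- 0
  for (b in seq_along(content)) {
    nb <- length(content[[b]]$ids)
    gproj[[b]] <- crossprod(content[[b]]$X,
                            bw$dH0[off + seq_len(nb), , drop = FALSE])
    off <- off + nb
  }
  fg <- heterorx:::flatten_params(
    list(proj = gproj, layers = bw$layer_grads, bias = sum(dlogit)))
  fp <- heterorx:::flatten_params(params)
  set.seed(11)
  for (nm in sample(names(fp), 6)) {
    k <- sample(length(fp[[nm]]), 1)
    eps <- 1e-5
    fp2 <- fp; fp2[[nm]][k] <- fp2[[nm]][k] + eps
    l1 <- loss_fn(heterorx:::unflatten_into(params, fp2))
    fp2[[nm]][k] <- fp2[[nm]][k] - 2 * eps
    l2 <- loss_fn(heterorx:::unflatten_into(params, fp2))
    expect_equal(fg[[nm]][k], (l1 - l2) / (2 * eps), tolerance = 1e-4,
                 info = nm)
  }
})

test_that("zero layers are rejected", {
  expect_error(gnn_config(layers = 0), "layers")
})
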
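# independent oracle for second-order weights: classify each candidate by
# its shortest-path distance from the previous node (igraph), then apply
# the 1/p, 1, 1/q rule
oracle_transition <- function(edge_df, prev, cur, p, q) {
  g <- igraph::graph_from_data_frame(edge_df, directed = FALSE)
  d <- igraph::distances(g)
  nb <- sort(names(igraph::neighbors(g, cur)))
  w <- vapply(nb, function(x) {
    dist <- d[prev, x]
    if (dist == 0) 1 / p else if (dist == 1) 1 else 1 / q
  }, numeric(1))
  w / sum(w)
}

test_that("second-order transition probabilities follow the node2vec rule", {
  # path a-b-c, at b from a, p=1 q=2
  adj <- list(a = "b", b = c("a", "c"), c = "b")
  expect_equal(node2vec_transition_probs(adj, "a", "b", p = 1, q = 2),
               c(a = 2 / 3, c = 1 / 3))
  # triangle, at b from a, p=2 q=0.5
  adj2 <- list(a = c("b", "c"), b = c("a", "c"), c = c("a", "b"))
  expect_equal(node2vec_transition_probs(adj2, "a", "b", p = 2, q = 0.5),
               c(a = 1 / 3, c = 2 / 3))
  # p = q = 1: uniform over neighbours
  expect_equal(unname(node2vec_transition_probs(adj2, "a", "b", 1, 1)),
               rep(0.5, 2))
  expect_equal(unname(node2vec_transition_probs(adj2, NULL, "b")),
               rep(0.5, 2))
})

test_that("transition probabilities match the enumeration oracle on small graphs", {
  skip_if_not_installed("igraph")
  set.seed(7)
  for (rep in 1:30) {
    n <- sample(3:5, 1)
    nodes <- letters[1:n]
    pairs <- t(utils::combn(nodes, 2))
    keep <- runif(nrow(pairs)) < 0.7
    if (sum(keep) < n - 1) next
    edge_df <- data.frame(from = pairs[keep, 1], to = pairs[keep, 2])
    adj <- split(c(edge_df$to, edge_df$from), c(edge_df$from, edge_df$to))
    adj <- lapply(adj, function(v) sort(unique(v)))
    g <- igraph::graph_from_data_frame(edge_df, directed = FALSE)
    if (igraph::components(g)$no > 1) next
    for (cur in names(adj)) for (prev in adj[[cur]]) {
      for (pq in list(c(1, 1), c(0.5, 2), c(4, 0.25))) {
        got <- node2vec_transition_probs(adj, prev, cur, pq[1], pq[2])
        want <- oracle_transition(edge_df, prev, cur, pq[1], pq[2])
        expect_equal(got, want[names(got)], tolerance = 1e-12)
      }
    }
  }
})

test_that("walks traverse only graph edges and respect configuration", {
  net <- tiny_net()
  adj <- adjacency_list(net$graph, c("drug_target", "ppi"))
  cfg <- walk_config(p = 0.5, q = 2, walk_length = 15, walks_per_node = 4,
                     seed = 13)
  walks <- biased_walks(adj, cfg)
  expect_equal(length(walks), 4 * length(adj))
  for (w in walks) {
    expect_lte(length(w), 15)
    if (length(w) > 1)
      expect_true(all(mapply(function(u, v) v %in% adj[[u]],
                             w[-length(w)], w[-1])))
  }
  expect_identical(biased_walks(adj, cfg), walks)  # seeded reproducibility
  # neighbourless node yields no walks, with a warning
  adj$`drug:LONER` <- character(0)
  expect_warning(w2 <- biased_walks(adj, cfg), "no neighbours")
  expect_false(any(vapply(w2, function(w) "drug:LONER" %in% w, TRUE)))
})

test_that("empirical step frequencies at p=q=1 are uniform", {
  adj <- list(a = c("b", "c", "d"), b = c("a", "c", "d"),
              c = c("a", "b", "d"), d = c("a", "b", "c"))
  walks <- biased_walks(adj, walk_config(walk_length = 700,
                                         walks_per_node = 5, seed = 99))
  trans <- table(unlist(lapply(walks, function(w)
    paste(w[-length(w)], w[-1]))))
  # chi-square goodness of fit against uniform over the 12 ordered edges
  expect_gt(chisq.test(as.vector(trans))$p.value, 0.01)
})

test_that("skip-gram embeddings are deterministic and structure-aware", {
  adj <- c(
    setNames(lapply(1:4, function(i)
      paste0("drug:a", setdiff(1:4, i))), paste0("drug:a", 1:4)),
    setNames(lapply(1:4, function(i)
      paste0("drug:b", setdiff(1:4, i))), paste0("drug:b", 1:4)))
  walks <- biased_walks(adj, walk_config(walk_length = 20,
                                         walks_per_node = 8, seed = 2))
  cfg <- skipgram_config(dim = 16, epochs = 4, seed = 2)
  e1 <- train_skipgram(walks, cfg)
  e2 <- train_skipgram(walks, cfg)
  expect_identical(e1, e2)
  expect_setequal(rownames(e1), names(adj))  # unseen nodes absent

  cm <- function(i, j) cosine_map(e1[i, ], e1[j, ], method = "shift")
  a <- grep("a", rownames(e1)); b <- grep("b", rownames(e1))
  within <- mean(c(utils::combn(a, 2, function(x) cm(x[1], x[2])),
                   utils::combn(b, 2, function(x) cm(x[1], x[2]))))
  between <- mean(outer(a, b, Vectorize(cm)))
  expect_gt(within, between)

  expect_error(train_skipgram(list(c("drug:a1", "drug:a1")), cfg),
               "single node")
  expect_error(train_skipgram(list(), cfg), "empty")
})

test_that("functional embeddings come from alternating bipartite walks", {
  net <- tiny_net()
  dt <- relation_edges(net$graph, "drug_target")
  dgo <- drug_go_edges(dt, net$annotations$gene_go)
  graph <- suppressMessages(assemble_graph(list(net$graph$edges, dgo$edges),
                                           net$compounds))
  adj <- adjacency_list(graph, "drug_go")
  walks <- biased_walks(adj, walk_config(seed = 3))
  for (w in walks[1:20]) {
    kinds <- node_kind(w)
    expect_true(all(kinds[-1] != kinds[-length(kinds)]))
  }
  emb <- functional_embeddings(graph, walk_config(seed = 3),
                               skipgram_config(dim = 8, seed = 3))
  expect_true(all(node_kind(rownames(emb)) == "drug"))
  # a graph without drug_go edges cannot give functional embeddings
  expect_error(functional_embeddings(net$graph), "no drug_go")
})
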
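# node2vec: second-order biased random walks treated as sentences, embedded
# with Skip-gram + negative sampling. Used three ways: drug-GO bipartite
# walks give drugs their functional embeddings; disease-gene and
# drug-target(+ppi) projections give diseases and proteins their network
# embeddings.

#' Random-walk configuration
#'
#' @param p return parameter (weight 1/p for stepping back); default 1.
#' @param q in-out parameter (weight 1/q for moving away); default 1.
#' @param walk_length nodes per walk; default 40.
#' @param walks_per_node walks started from every node; default 10.
#' @param seed RNG seed.
#' @return list of class `walk_config`.
#' @export
walk_config <- function(p = 1, q = 1, walk_length = 40, walks_per_node = 10,
                        seed = 1) {
  stopifnot(p > 0, q > 0, walk_length >= 2, walks_per_node >= 1)
  structure(list(p = p, q = q, walk_length = walk_length,
                 walks_per_node = walks_per_node, seed = seed),
            class = "walk_config")
}

#' Skip-gram configuration
#'
#' @param dim embedding dimension; default 64.
#' @param window context window radius; default 5.
#' @param negatives negative samples per context pair; default 5.
#' @param epochs passes over the walk corpus; default 5.
#' @param learning_rate initial SGD step, linearly decayed; default 0.025.
#' @param seed RNG seed.
#' @return list of class `skipgram_config`.
#' @export
skipgram_config <- function(dim = 64, window = 5, negatives = 5, epochs = 5,
                            learning_rate = 0.025, seed = 1) {
  stopifnot(dim >= 2, window >= 1, negatives >= 1, epochs >= 1,
            learning_rate > 0)
  structure(list(dim = dim, window = window, negatives = negatives,
                 epochs = epochs, learning_rate = learning_rate, seed = seed),
            class = "skipgram_config")
}

#' Second-order transition probabilities at one step
#'
#' The normalized node2vec rule: having walked prev -> cur, the probability
#' of moving to neighbour x of cur is proportional to 1/p if x = prev, 1 if
#' x is adjacent to prev, and 1/q otherwise.
#'
#' @param adj adjacency list (named list of neighbour id vectors).
#' @param prev previous node id, or `NULL` for the uniform first step.
#' @param cur current node id.
#' @param p,q node2vec bias parameters.
#' @return named numeric vector of probabilities over neighbours of `cur`.
#' @export
node2vec_transition_probs <- function(adj, prev, cur, p = 1, q = 1) {
  nb <- adj[[cur]]
  if (!length(nb)) stop("node ", cur, " has no neighbours")
  if (is.null(prev)) {
    w <- rep(1, length(nb))
  } else {
    w <- vapply(nb, function(x) {
      if (x == prev) 1 / p
      else if (x %in% adj[[prev]]) 1
      else 1 / q
    }, numeric(1))
  }
  setNames(w / sum(w), nb)
}

#' Sample biased random walks over a graph projection
#'
#' Runs `walks_per_node` node2vec walks from every node of the adjacency
#' list. Nodes without neighbours yield no walks (with a warning). Every
#' consecutive pair in a returned walk is an edge of the projection.
#'
#' @param adj adjacency list from [adjacency_list()].
#' @param cfg a [walk_config()].
#' @return list of character vectors (the walk corpus).
#' @export
biased_walks <- function(adj, cfg = walk_config()) {
  nodes <- names(adj)
  if (!length(nodes)) stop("empty graph projection")
  deg0 <- vapply(adj, length, 1L) == 0
  if (any(deg0))
    warning(sum(deg0), " node(s) have no neighbours; no walks from them")
  idx <- setNames(seq_along(nodes), nodes)
  neigh <- lapply(adj, function(v) sort(unname(idx[v])))
  adj_ptr <- c(0L, cumsum(vapply(neigh, length, 1L)))
  adj_idx <- as.integer(unlist(neigh, use.names = FALSE)) - 1L
  set.seed(cfg$seed)
  raw <- cpp_biased_walks(as.integer(adj_ptr), adj_idx, cfg$p, cfg$q,
                          cfg$walk_length, cfg$walks_per_node)
  walks <- lapply(raw, function(w) nodes[w + 1L])
  walks[vapply(walks, length, 1L) > 0]
}

#' Train Skip-gram embeddings on a walk corpus
#'
#' Negative-sampling Skip-gram over walk sentences; the noise distribution
#' is the unigram frequency raised to 3/4. Single-threaded and seeded, so
#' identical corpora and seeds give identical matrices.
#'
#' @param corpus list of node-id walks from [biased_walks()].
#' @param cfg a [skipgram_config()].
#' @return numeric matrix, one row per node seen in the corpus.
#' @export
train_skipgram <- function(corpus, cfg = skipgram_config()) {
  if (!length(corpus)) stop("empty walk corpus")
  tokens <- unlist(corpus, use.names = FALSE)
  nodes <- sort(unique(tokens))
  if (length(nodes) < 2) stop("corpus contains a single node")
  idx <- setNames(seq_along(nodes), nodes)
  walks_int <- lapply(corpus, function(w) unname(idx[w]) - 1L)
  freq <- table(factor(tokens, levels = nodes))
  noise <- as.numeric(freq)^0.75
  noise_cdf <- cumsum(noise / sum(noise))
  set.seed(cfg$seed)
  W <- cpp_train_skipgram(walks_int, length(nodes), cfg$dim, cfg$window,
                          cfg$negatives, cfg$epochs, cfg$learning_rate,
                          noise_cdf)
  rownames(W) <- nodes
  W
}

#' node2vec embeddings over one relation projection
#'
#' @param graph a `hetero_graph`.
#' @param relations relations defining the projection, e.g. `"drug_go"`.
#' @param wcfg,scfg walk and Skip-gram configurations.
#' @param restrict_kind optional node kind; only those rows are returned.
#' @return embedding matrix with node-id rownames.
#' @export
node_embeddings <- function(graph, relations, wcfg = walk_config(),
                            scfg = skipgram_config(), restrict_kind = NULL) {
  adj <- adjacency_list(graph, relations)
  walks <- biased_walks(adj, wcfg)
  emb <- train_skipgram(walks, scfg)
  if (!is.null(restrict_kind))
    emb <- emb[node_kind(rownames(emb)) == restrict_kind, , drop = FALSE]
  emb
}

#' Functional embeddings of drugs from the drug-GO bipartite graph
#'
#' Walks alternate between drug and GO nodes; only the drug rows of the
#' Skip-gram matrix are returned.
#'
#' @inheritParams node_embeddings
#' @return embedding matrix restricted to drug nodes.
#' @export
functional_embeddings <- function(graph, wcfg = walk_config(),
                                  scfg = skipgram_config()) {
  if (!nrow(relation_edges(graph, "drug_go")))
    stop("graph has no drug_go edges")
  node_embeddings(graph, "drug_go", wcfg, scfg, restrict_kind = "drug")
}
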
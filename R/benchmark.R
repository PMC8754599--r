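# Standard synthetic benchmark: one call builds the planted-block bundle,
# the content embeddings (which never see drug-disease associations, so one
# embedding set serves many association settings), and the labelled pair set,
# ready for crossvalidate()/train_predictor().

#' Content embeddings for a synthetic benchmark bundle
#'
#' Computes enrichment-filtered drug-GO edges, structural embeddings from
#' the SMILES autoencoder, functional drug embeddings from drug-GO walks,
#' and node2vec embeddings for proteins and diseases. None of these stages
#' sees a drug-disease association, so the result can be shared across
#' folds and across association-probability settings.
#'
#' @param net a bundle from [gen_network()].
#' @param seed seed for the embedding stages.
#' @param dim embedding dimension used throughout; default 32.
#' @param ae_epochs autoencoder epochs; default 40.
#' @param alpha GO enrichment cutoff; default 0.01.
#' @return list with `graph` (drug_go edges added), `base_edges`,
#'   `drug_content`, `prot_emb`, `dis_emb`, `struct`, `func`.
#' @export
benchmark_embeddings <- function(net, seed = 1, dim = 32, ae_epochs = 40,
                                 alpha = 0.01) {
  dt <- relation_edges(net$graph, "drug_target")
  dgo <- drug_go_edges(dt, net$annotations$gene_go, alpha = alpha)
  graph <- assemble_graph(list(net$graph$edges, dgo$edges), net$compounds)
  acfg <- smiles_ae_config(model_dim = dim, heads = 4, layers = 1,
                           epochs = ae_epochs, seed = seed)
  ae <- train_autoencoder(net$compounds, acfg)
  struct <- embed_structures(ae, net$compounds)
  wcfg <- walk_config(seed = seed)
  scfg <- skipgram_config(dim = dim, seed = seed)
  func <- functional_embeddings(graph, wcfg, scfg)
  dis_emb <- node_embeddings(graph, "disease_gene", wcfg, scfg,
                             restrict_kind = "disease")
  prot_emb <- node_embeddings(graph, c("drug_target", "ppi"), wcfg, scfg,
                              restrict_kind = "protein")
  base_edges <- graph$edges[graph$edges$relation %in%
                              c("drug_target", "ppi", "disease_gene"), ]
  list(graph = graph, base_edges = base_edges,
       drug_content = fuse_drug_content(struct, func),
       prot_emb = prot_emb, dis_emb = dis_emb,
       struct = struct, func = func, enrichment = dgo$report)
}

#' Labelled association set (planted positives + sampled negatives)
#'
#' @param net a [gen_network()] bundle (training positives only; held-out
#'   positives stay out).
#' @param emb a [benchmark_embeddings()] result (defines the pair universe).
#' @param ratio negatives per positive.
#' @param seed sampling seed.
#' @return data.frame `drug`, `disease`, `label`.
#' @export
benchmark_labels <- function(net, emb, ratio = 1, seed = 1) {
  drugs <- rownames(emb$drug_content)
  diseases <- rownames(emb$dis_emb)
  pos <- net$associations
  pos <- pos[pos$drug %in% drugs & pos$disease %in% diseases, , drop = FALSE]
  neg <- sample_negatives(pos, drugs, diseases, ratio, seed = seed)
  rbind(pos, neg)
}

#' Run the full benchmark: generate, embed, label, cross-validate
#'
#' @param cfg a [synth_config()].
#' @param seed master seed; module seeds derive from it.
#' @param dim embedding width; default 32.
#' @param ae_epochs autoencoder epochs; default 40.
#' @param gnn_epochs GNN epochs per fold; default 120.
#' @param trees random-forest size; default 300.
#' @return list with the generated `net`, `emb`, `labelled` pairs, the
#'   `report` (an `eval_report`), and the configs used.
#' @export
run_benchmark <- function(cfg = synth_config(), seed = 1, dim = 32,
                          ae_epochs = 40, gnn_epochs = 120, trees = 300) {
  seeds <- derive_seeds(seed)
  cfg$seed <- as.integer(seeds[["synth"]])
  net <- gen_network(cfg)
  emb <- benchmark_embeddings(net, seed = seeds[["walker"]], dim = dim,
                              ae_epochs = ae_epochs)
  labelled <- benchmark_labels(net, emb, seed = seeds[["predictor"]])
  ccfg <- classifier_config(trees = trees, seed = seeds[["predictor"]])
  gcfg <- gnn_config(hidden_dim = dim, epochs = gnn_epochs,
                     seed = seeds[["gnn"]])
  report <- crossvalidate(emb$base_edges, emb$drug_content, emb$prot_emb,
                          emb$dis_emb, labelled, ccfg, gcfg)
  list(net = net, emb = emb, labelled = labelled, report = report,
       ccfg = ccfg, gcfg = gcfg)
}

#' Label-shuffled null distribution of the mean CV AUC
#'
#' Re-runs the cross-validation with labels randomly permuted across the
#' same pairs; under the null the mean AUC centers on one half.
#'
#' @param bench a [run_benchmark()] result.
#' @param n_reps shuffled replicates; default 5.
#' @param seed permutation seed.
#' @return numeric vector of null mean AUCs.
#' @export
shuffled_null_auc <- function(bench, n_reps = 5, seed = 1) {
  vapply(seq_len(n_reps), function(r) {
    set.seed(seed + r)
    shuffled <- bench$labelled
    shuffled$label <- sample(shuffled$label)
    rep <- crossvalidate(bench$emb$base_edges, bench$emb$drug_content,
                         bench$emb$prot_emb, bench$emb$dis_emb, shuffled,
                         bench$ccfg, bench$gcfg)
    rep$mean$auc
  }, numeric(1))
}

#' Rank percentile of held-out planted positives among unknown pairs
#'
#' Scores every pair whose drug-disease status is unknown (not a known
#' positive) and reports where the held-out planted positives — never shown
#' to any training stage — fall in the ranking (1 = top). Because the
#' gold-standard negative class is not observable, each ensemble member
#' retrains the aggregation network and forest on an independent uniform
#' negative sample and the member scores are averaged; this negative-sample
#' bagging removes the arbitrariness of any single draw.
#'
#' @param bench a [run_benchmark()] result.
#' @param n_members negative-resample ensemble size; default 5.
#' @return list with `median_percentile` (fraction of unknown pairs scoring
#'   at or below the median held-out positive, higher = better), per-pair
#'   `percentiles`, and the ranked averaged predictions.
#' @export
heldout_ranking <- function(bench, n_members = 5) {
  drugs <- rownames(bench$emb$drug_content)
  diseases <- rownames(bench$emb$dis_emb)
  pos <- bench$net$associations
  pos <- pos[pos$drug %in% drugs & pos$disease %in% diseases, , drop = FALSE]
  universe <- expand.grid(drug = drugs, disease = diseases,
                          stringsAsFactors = FALSE)
  query <- universe[!(pair_key(universe$drug, universe$disease) %in%
                        pair_key(pos$drug, pos$disease)), , drop = FALSE]
  scores <- NULL
  base <- NULL
  for (r in seq_len(n_members)) {
    neg <- sample_negatives(pos, drugs, diseases, bench$ccfg$negative_ratio,
                            seed = bench$ccfg$seed + r)
    gcfg <- bench$gcfg
    gcfg$seed <- bench$gcfg$seed + r
    model <- train_predictor(bench$emb$base_edges, bench$emb$drug_content,
                             bench$emb$prot_emb, bench$emb$dis_emb,
                             rbind(pos, neg), bench$ccfg, gcfg)
    sr <- score_and_rank(model, query)
    sr <- sr[order(sr$drug, sr$disease), , drop = FALSE]
    if (is.null(base)) {
      base <- sr[, c("drug", "disease")]
      scores <- matrix(0, nrow(sr), 0)
    }
    scores <- cbind(scores, sr$score)
  }
  base$score <- rowMeans(scores)
  ranked <- base[order(-base$score, base$drug, base$disease), , drop = FALSE]
  key <- pair_key(ranked$drug, ranked$disease)
  held <- pair_key(bench$net$truth$held_out$source,
                   bench$net$truth$held_out$target)
  hit <- which(key %in% held)
  if (!length(hit)) stop("no held-out positives scorable")
  pct <- 1 - (hit - 0.5) / length(key)
  list(median_percentile = median(pct), percentiles = pct, ranked = ranked)
}
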
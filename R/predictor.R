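# Drug-disease association prediction: random forest on concatenated global
# embeddings, stratified fivefold cross-validation with per-fold GNN
# retraining, AUC/precision/recall/F1 reporting, scoring and triage.

#' Classifier configuration
#'
#' @param trees random-forest size; default 500.
#' @param negative_ratio negatives sampled per positive; default 1.
#' @param folds cross-validation folds; default 5.
#' @param decision_threshold probability cutoff for the positive call and
#'   for candidate triage; default 0.5 (strictly greater than).
#' @param seed RNG seed.
#' @return list of class `classifier_config`.
#' @export
classifier_config <- function(trees = 500, negative_ratio = 1, folds = 5,
                              decision_threshold = 0.5, seed = 1) {
  stopifnot(trees >= 1, negative_ratio > 0, folds >= 2,
            decision_threshold > 0, decision_threshold < 1)
  structure(list(trees = trees, negative_ratio = negative_ratio,
                 folds = folds, decision_threshold = decision_threshold,
                 seed = seed),
            class = "classifier_config")
}

pair_key <- function(drug, disease) paste(drug, disease, sep = "\r")

#' Sample negative drug-disease pairs
#'
#' Draws `floor(ratio * n_positives)` pairs uniformly without replacement
#' from the unknown part of the drug x disease universe.
#'
#' @param positives data.frame with columns `drug`, `disease`.
#' @param drugs,diseases the pair universe.
#' @param ratio negatives per positive.
#' @param seed RNG seed.
#' @return data.frame `drug`, `disease`, `label = 0`.
#' @export
sample_negatives <- function(positives, drugs, diseases, ratio = 1,
                             seed = 1) {
  stopifnot(ratio > 0)
  n_neg <- floor(ratio * nrow(positives))
  universe <- expand.grid(drug = drugs, disease = diseases,
                          stringsAsFactors = FALSE)
  known <- pair_key(positives$drug, positives$disease)
  unknown <- universe[!(pair_key(universe$drug, universe$disease) %in% known),
                      , drop = FALSE]
  if (nrow(unknown) < n_neg)
    stop("not enough unknown pairs to sample ", n_neg, " negatives")
  set.seed(seed)
  neg <- unknown[sample(nrow(unknown), n_neg), , drop = FALSE]
  neg$label <- 0L
  rownames(neg) <- NULL
  neg
}

#' Concatenated pair features
#'
#' Per pair, the drug's global embedding followed by the disease's. Pairs
#' missing either embedding are dropped with a warning.
#'
#' @param embeddings GlobalEmbedding matrix (drug and disease rows).
#' @param pairs data.frame with `drug`, `disease`.
#' @return numeric feature matrix with attribute `"kept"` (row indices of
#'   `pairs` retained).
#' @export
pair_features <- function(embeddings, pairs) {
  ok <- pairs$drug %in% rownames(embeddings) &
    pairs$disease %in% rownames(embeddings)
  if (any(!ok))
    warning(sum(!ok), " pair(s) dropped for missing embeddings")
  p <- pairs[ok, , drop = FALSE]
  X <- cbind(embeddings[p$drug, , drop = FALSE],
             embeddings[p$disease, , drop = FALSE])
  rownames(X) <- pair_key(p$drug, p$disease)
  attr(X, "kept") <- which(ok)
  X
}

#' Stratified fold assignment
#'
#' Splits labelled pairs into `k` folds whose sizes differ by at most one,
#' stratified by label.
#'
#' @param labels vector of 0/1 labels.
#' @param k number of folds.
#' @param seed RNG seed.
#' @return integer fold assignment of length `length(labels)`.
#' @export
split_folds <- function(labels, k = 5, seed = 1) {
  n <- length(labels)
  if (k > n) stop("more folds than labelled pairs")
  set.seed(seed)
  fold <- integer(n)
  load <- integer(k)
  for (lv in unique(labels)) {
    idx <- which(labels == lv)
    idx <- idx[sample.int(length(idx))]
    s <- length(idx)
    counts <- rep(s %/% k, k)
    r <- s %% k
    if (r > 0) {
      # remainder goes to the currently least-loaded folds so overall
      # fold sizes never drift apart by more than one
      low <- order(load, seq_len(k))[seq_len(r)]
      counts[low] <- counts[low] + 1L
    }
    fold[idx] <- rep(seq_len(k), counts)
    load <- load + counts
  }
  fold
}

#' Area under the ROC curve
#'
#' The probability that a uniformly chosen positive outscores a uniformly
#' chosen negative, counting ties as one half (rank/Mann-Whitney form).
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels; both classes must be present.
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes required for AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Precision, recall and F1 from confusion counts
#'
#' `F1` is the harmonic mean of precision and recall; any zero denominator
#' yields 0 by convention.
#'
#' @param tp,fp,fn non-negative counts, at least one positive.
#' @return list with `precision`, `recall`, `f1`.
#' @export
f1_score <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tp + fp + fn >= 1)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  list(precision = precision, recall = recall, f1 = f1)
}

fit_rf <- function(X, y, trees, seed) {
  set.seed(seed)
  randomForest::randomForest(x = X, y = factor(y, levels = c(0, 1)),
                             ntree = trees)
}

rf_prob <- function(model, X) {
  unname(predict(model, X, type = "prob")[, "1"])
}

#' Fivefold cross-validation of the full pipeline tail
#'
#' For each fold, the GNN is retrained from scratch with only the training
#' folds' positive drug-disease edges in its objective and message graph,
#' the random forest is fit on the training pairs' concatenated embeddings,
#' and the held-out fold is scored. Test-fold pairs never touch a trained
#' parameter.
#'
#' @param edges base aggregation edges (drug_target, ppi, disease_gene).
#' @param drug_content,protein_emb,disease_emb content inputs (computed
#'   without any drug_disease edge, so shared across folds).
#' @param associations data.frame `drug`, `disease`, `label` (0/1).
#' @param ccfg a [classifier_config()].
#' @param gcfg a [gnn_config()].
#' @return an `eval_report`: per-fold and mean AUC/precision/recall/F1,
#'   fold sizes, and per-fold train/test pair keys for audit.
#' @export
crossvalidate <- function(edges, drug_content, protein_emb, disease_emb,
                          associations, ccfg = classifier_config(),
                          gcfg = gnn_config()) {
  stopifnot(all(associations$label %in% 0:1))
  if (anyDuplicated(pair_key(associations$drug, associations$disease)))
    stop("duplicate (drug, disease) pairs in the association set")
  fold <- split_folds(associations$label, ccfg$folds, ccfg$seed)
  per_fold <- list()
  audit <- list()
  for (f in sort(unique(fold))) {
    train <- associations[fold != f, , drop = FALSE]
    test <- associations[fold == f, , drop = FALSE]
    if (length(unique(test$label)) < 2) {
      hx_log("predictor", "fold ", f, " has a single class; skipped")
      next
    }
    gcfg_f <- gcfg
    gcfg_f$seed <- gcfg$seed + f
    train_edges <- rbind(
      edges,
      data.frame(source = train$drug[train$label == 1],
                 target = train$disease[train$label == 1],
                 relation = "drug_disease", stringsAsFactors = FALSE))
    gnn <- train_gnn(train_edges, drug_content, protein_emb, disease_emb,
                     train, gcfg_f)
    emb <- global_embeddings(gnn)
    Xtr <- pair_features(emb, train)
    ytr <- train$label[attr(Xtr, "kept")]
    Xte <- pair_features(emb, test)
    yte <- test$label[attr(Xte, "kept")]
    rf <- fit_rf(Xtr, ytr, ccfg$trees, ccfg$seed + f)
    prob <- rf_prob(rf, Xte)
    pred <- as.integer(prob > ccfg$decision_threshold)
    m <- f1_score(sum(pred == 1 & yte == 1), sum(pred == 1 & yte == 0),
                  sum(pred == 0 & yte == 1))
    per_fold[[length(per_fold) + 1]] <- data.frame(
      fold = f, n_train = nrow(train), n_test = nrow(test),
      auc = auc_score(prob, yte), precision = m$precision,
      recall = m$recall, f1 = m$f1)
    audit[[length(audit) + 1]] <- list(
      fold = f,
      train_keys = pair_key(train$drug, train$disease),
      test_keys = pair_key(test$drug, test$disease))
  }
  if (!length(per_fold)) stop("no evaluable folds")
  per_fold <- do.call(rbind, per_fold)
  means <- colMeans(per_fold[, c("auc", "precision", "recall", "f1")])
  structure(list(per_fold = per_fold, mean = as.list(means),
                 folds = fold, audit = audit, config = ccfg),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("fivefold cross-validation (", nrow(x$per_fold), " evaluable folds)\n",
      sep = "")
  print(round(x$per_fold, 4), row.names = FALSE)
  cat(sprintf("mean AUC %.4f  precision %.4f  recall %.4f  F1 %.4f\n",
              x$mean$auc, x$mean$precision, x$mean$recall, x$mean$f1))
  invisible(x)
}

#' Train the final predictor on all labelled pairs
#'
#' @inheritParams crossvalidate
#' @return list of class `hx_predictor` with the GNN, the random forest and
#'   the embedding matrix.
#' @export
train_predictor <- function(edges, drug_content, protein_emb, disease_emb,
                            associations, ccfg = classifier_config(),
                            gcfg = gnn_config()) {
  pos <- associations[associations$label == 1, , drop = FALSE]
  all_edges <- rbind(edges, data.frame(source = pos$drug,
                                       target = pos$disease,
                                       relation = "drug_disease",
                                       stringsAsFactors = FALSE))
  gnn <- train_gnn(all_edges, drug_content, protein_emb, disease_emb,
                   associations, gcfg)
  emb <- global_embeddings(gnn)
  X <- pair_features(emb, associations)
  y <- associations$label[attr(X, "kept")]
  rf <- fit_rf(X, y, ccfg$trees, ccfg$seed)
  structure(list(gnn = gnn, rf = rf, embeddings = emb, config = ccfg),
            class = "hx_predictor")
}

#' Score query pairs and rank them
#'
#' @param model an `hx_predictor` from [train_predictor()].
#' @param pairs data.frame `drug`, `disease` to score.
#' @return data.frame sorted by descending probability (ties broken by drug
#'   then disease id) with columns `drug`, `disease`, `score`.
#' @export
score_and_rank <- function(model, pairs) {
  stopifnot(inherits(model, "hx_predictor"))
  X <- pair_features(model$embeddings, pairs)
  p <- pairs[attr(X, "kept"), , drop = FALSE]
  p$score <- rf_prob(model$rf, X)
  p <- p[order(-p$score, p$drug, p$disease), , drop = FALSE]
  rownames(p) <- NULL
  p
}

#' Triage a prediction into affirmed / novel / unsupported
#'
#' Scores strictly above the threshold with prior evidence are `affirmed`
#' (red), above without evidence `novel` (blue), and everything else
#' `unsupported` (green). A score exactly at the threshold is unsupported.
#'
#' @param score probability in \[0, 1\] (vectorized).
#' @param has_prior_evidence logical (recycled).
#' @param threshold decision cutoff; default 0.5.
#' @return character vector of categories.
#' @export
categorize <- function(score, has_prior_evidence, threshold = 0.5) {
  stopifnot(all(score >= 0 & score <= 1))
  ifelse(score > threshold,
         ifelse(has_prior_evidence, "affirmed", "novel"),
         "unsupported")
}
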
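test_that("negative sampling is uniform over unknown pairs and seeded", {
  pos <- data.frame(drug = paste0("drug:d", 1:10),
                    disease = paste0("disease:z", rep(1:2, 5)))
  drugs <- paste0("drug:d", 1:10)
  diseases <- paste0("disease:z", 1:5)
  neg <- sample_negatives(pos, drugs, diseases, ratio = 1, seed = 4)
  expect_equal(nrow(neg), 10)
  expect_true(all(neg$label == 0))
  expect_equal(nrow(unique(neg[, 1:2])), 10)
  expect_length(intersect(paste(neg$drug, neg$disease),
                          paste(pos$drug, pos$disease)), 0)
  expect_identical(neg, sample_negatives(pos, drugs, diseases, 1, seed = 4))
  expect_error(sample_negatives(pos, drugs, diseases, ratio = 0), "ratio > 0")
  expect_error(sample_negatives(pos, "drug:d1", "disease:z1", ratio = 40),
               "not enough unknown pairs")
})

test_that("pair features concatenate drug and disease embeddings", {
  emb <- rbind("drug:a" = c(1, 2), "drug:b" = c(3, 4),
               "disease:x" = c(5, 6), "disease:y" = c(7, 8))
  pairs <- data.frame(drug = c("drug:a", "drug:b", "drug:a"),
                      disease = c("disease:x", "disease:y", "disease:x"))
  X <- pair_features(emb, pairs)
  expect_equal(ncol(X), 4)
  expect_equal(unname(X[1, ]), c(1, 2, 5, 6))
  expect_equal(X[1, ], X[3, ])  # identical pairs, identical rows
  pairs2 <- rbind(pairs, data.frame(drug = "drug:miss", disease = "disease:x"))
  expect_warning(X2 <- pair_features(emb, pairs2), "dropped")
  expect_equal(attr(X2, "kept"), 1:3)
})

test_that("folds are stratified, disjoint and near-equal", {
  labels <- c(rep(1, 11), rep(0, 11))
  f <- split_folds(labels, k = 5, seed = 2)
  expect_equal(sort(unique(f)), 1:5)
  sizes <- table(f)
  expect_lte(max(sizes) - min(sizes), 1)
  for (k in 1:5) {
    strat <- table(labels[f == k])
    expect_lte(abs(strat["0"] - strat["1"]), 1)
  }
  expect_equal(table(split_folds(rep(0:1, 5), 5, 1))[[1]], 2)
  expect_error(split_folds(c(0, 1), 5), "more folds")
})

# brute-force concordance oracle
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

test_that("AUC equals pairwise concordance with half-credit ties", {
  expect_equal(auc_score(c(0.9, 0.8, 0.4, 0.3), c(1, 1, 0, 0)), 1)
  expect_equal(auc_score(c(0.9, 0.3, 0.8, 0.4), c(1, 1, 0, 0)), 0.5)
  expect_equal(auc_score(rep(0.7, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_error(auc_score(1:3, c(1, 1, 1)), "both classes")
  set.seed(14)
  for (i in 1:40) {
    n <- sample(4:50, 1)
    labels <- sample(0:1, n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    scores <- sample(seq(0, 1, 0.05), n, replace = TRUE)  # force ties
    expect_equal(auc_score(scores, labels), oracle_auc(scores, labels))
  }
})

test_that("F1 is the harmonic mean of precision and recall", {
  m <- f1_score(2, 1, 1)
  expect_equal(m, list(precision = 2 / 3, recall = 2 / 3, f1 = 2 / 3))
  expect_equal(f1_score(0, 3, 2)$f1, 0)
  # harmonic-mean identity: P = R implies F1 = P
  expect_equal(f1_score(5, 2, 2)$f1, 5 / 7)
  expect_error(f1_score(-1, 0, 2), "tp >= 0")
})

test_that("cross-validation honours fold isolation and reports valid metrics", {
  net <- tiny_net(seed = 7)
  emb <- suppressWarnings(suppressMessages(
    benchmark_embeddings(net, seed = 7, dim = 8, ae_epochs = 3)))
  lab <- benchmark_labels(net, emb, seed = 7)
  ccfg <- classifier_config(trees = 60, seed = 7)
  gcfg <- gnn_config(hidden_dim = 8, epochs = 15, seed = 7)
  rep <- suppressMessages(crossvalidate(emb$base_edges, emb$drug_content,
                                        emb$prot_emb, emb$dis_emb, lab,
                                        ccfg, gcfg))
  metrics <- unlist(rep$per_fold[, c("auc", "precision", "recall", "f1")])
  expect_true(all(metrics >= 0 & metrics <= 1))
  # folds partition the labelled set
  expect_equal(sort(unique(rep$folds)), 1:5)
  expect_length(rep$folds, nrow(lab))
  all_keys <- paste(lab$drug, lab$disease, sep = "\r")
  for (a in rep$audit) {
    expect_length(intersect(a$train_keys, a$test_keys), 0)
    expect_setequal(c(a$train_keys, a$test_keys), all_keys)
  }
  expect_error(crossvalidate(emb$base_edges, emb$drug_content, emb$prot_emb,
                             emb$dis_emb, rbind(lab, lab[1, ]), ccfg, gcfg),
               "duplicate")
})

test_that("ranking is deterministic with lexicographic tie-breaks", {
  net <- tiny_net(seed = 7)
  emb <- suppressWarnings(suppressMessages(
    benchmark_embeddings(net, seed = 7, dim = 8, ae_epochs = 3)))
  lab <- benchmark_labels(net, emb, seed = 7)
  ccfg <- classifier_config(trees = 60, seed = 7)
  gcfg <- gnn_config(hidden_dim = 8, epochs = 15, seed = 7)
  model <- suppressMessages(train_predictor(emb$base_edges, emb$drug_content,
                                            emb$prot_emb, emb$dis_emb, lab,
                                            ccfg, gcfg))
  pairs <- expand.grid(drug = rownames(emb$drug_content),
                       disease = rownames(emb$dis_emb),
                       stringsAsFactors = FALSE)
  r <- score_and_rank(model, pairs)
  expect_true(all(diff(r$score) <= 0))
  expect_true(all(r$score >= 0 & r$score <= 1))
  ties <- r[duplicated(r$score) | duplicated(r$score, fromLast = TRUE), ]
  for (s in unique(ties$score)) {
    grp <- ties[ties$score == s, ]
    expect_false(is.unsorted(paste(grp$drug, grp$disease)))
  }
  expect_identical(r, score_and_rank(model, pairs))
})

test_that("triage categories follow the strict threshold rule", {
  expect_equal(categorize(0.86, FALSE), "novel")
  expect_equal(categorize(0.54, FALSE), "novel")
  expect_equal(categorize(0.4, FALSE), "unsupported")
  expect_equal(categorize(0.86, TRUE), "affirmed")
  expect_equal(categorize(0.5, TRUE), "unsupported")   # tie goes below
  expect_equal(categorize(0.5 + 1e-9, FALSE), "novel")
  expect_equal(categorize(c(0.9, 0.1), c(TRUE, TRUE)),
               c("affirmed", "unsupported"))
  expect_error(categorize(1.2, FALSE), "score")
})
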
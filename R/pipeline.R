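# Pipeline orchestration: one structured config, deterministic per-module
# seeding derived from a master seed, TSV artifacts and a JSON manifest.

#' Default run configuration
#'
#' All module configurations plus input paths and the master seed in one
#' list. The master seed derives every module seed through [derive_seeds()].
#'
#' @param out_dir artifact directory.
#' @param seed master seed.
#' @return nested configuration list of class `run_config`.
#' @export
default_run_config <- function(out_dir = "heterorx-out", seed = 1) {
  structure(list(
    seed = seed,
    out_dir = out_dir,
    inputs = list(drug_target = NULL, ppi = NULL, disease_gene = NULL,
                  drug_disease = NULL, smiles = NULL, gene_go = NULL),
    simulate = list(enabled = TRUE, preset = "tiny"),
    enrichment = list(alpha = 0.01),
    smiles_ae = list(model_dim = 32, heads = 4, layers = 1, epochs = 60,
                     learning_rate = 1e-3, max_len = 128),
    walker = list(p = 1, q = 1, walk_length = 40, walks_per_node = 10),
    skipgram = list(dim = 32, window = 5, negatives = 5, epochs = 5,
                    learning_rate = 0.025),
    gnn = list(layers = 2, hidden_dim = 32, epochs = 120,
               learning_rate = 5e-3),
    classifier = list(trees = 500, negative_ratio = 1, folds = 5,
                      decision_threshold = 0.5),
    simspace = list(threshold = 0.85, method = "clip", perplexity = 5,
                    dims = 2)
  ), class = "run_config")
}

#' Read a run configuration from a YAML file
#' @param path YAML file with any subset of the [default_run_config()] keys.
#' @return a validated `run_config` (unset keys take defaults).
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_run_config()
  merge_in <- function(base, upd, prefix = "") {
    for (nm in names(upd)) {
      if (!nm %in% names(base)) {
        warning("unknown config key: ", prefix, nm)
        next
      }
      if (is.list(base[[nm]]) && is.list(upd[[nm]]))
        base[[nm]] <- merge_in(base[[nm]], upd[[nm]], paste0(prefix, nm, "."))
      else base[[nm]] <- upd[[nm]]
    }
    base
  }
  cfg <- merge_in(unclass(cfg), user)
  class(cfg) <- "run_config"
  validate_config(cfg)
  cfg
}

#' Validate a run configuration
#'
#' Checks invariants of every module block and reports the derived module
#' seeds; stops on the first violation.
#'
#' @param cfg a `run_config` list.
#' @return invisibly, the derived module seed vector.
#' @export
validate_config <- function(cfg) {
  stopifnot(is.list(cfg))
  with(cfg$walker, stopifnot(p > 0, q > 0, walk_length >= 2,
                             walks_per_node >= 1))
  with(cfg$smiles_ae, stopifnot(model_dim %% heads == 0, layers >= 1,
                                epochs >= 1))
  with(cfg$skipgram, stopifnot(dim >= 2, window >= 1))
  with(cfg$gnn, stopifnot(layers >= 1, hidden_dim >= 2))
  with(cfg$classifier, stopifnot(folds >= 2, decision_threshold > 0,
                                 decision_threshold < 1, trees >= 1))
  with(cfg$enrichment, stopifnot(alpha > 0, alpha < 1))
  stopifnot(cfg$simspace$dims %in% 2:3)
  invisible(derive_seeds(cfg$seed))
}

write_embedding_tsv <- function(emb, path) {
  df <- data.frame(id = rownames(emb), round(unname(emb), 8))
  names(df) <- c("id", paste0("v", seq_len(ncol(emb))))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Read an embedding TSV written by the pipeline
#' @param path TSV with `id` then `v1..vd` columns.
#' @return numeric matrix with id rownames.
#' @export
read_embedding_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$id
  m
}

#' Run the full pipeline
#'
#' Executes assembly, structural and node2vec embedding, attention
#' aggregation, cross-validation, unknown-pair scoring with triage, and
#' similarity-space comparison, writing all artifacts under
#' `cfg$out_dir` and a `manifest.json` with config echo, derived seeds and
#' per-file MD5 checksums. Identical configs and inputs give byte-identical
#' outputs.
#'
#' @param cfg a `run_config`.
#' @return invisibly, a list with the report, predictions and manifest path.
#' @export
run_all <- function(cfg = default_run_config()) {
  validate_config(cfg)
  seeds <- derive_seeds(cfg$seed)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    hx_log("cli", "stage ", name)
    tryCatch(expr, error = function(e)
      stop("stage ", name, " failed: ", conditionMessage(e), call. = FALSE))
  }

  inp <- cfg$inputs
  truth <- NULL
  if (isTRUE(cfg$simulate$enabled) && is.null(inp$drug_target)) {
    net <- stage("simulate", make_fixture(file.path(cfg$out_dir, "inputs"),
                                          preset = cfg$simulate$preset,
                                          seed = seeds[["synth"]]))
    inp <- net$paths
    truth <- net$truth
  }

  bundle <- stage("build-net", {
    compounds <- load_smiles(inp$smiles)
    dt <- load_edges(inp$drug_target, "drug_target")
    pp <- load_edges(inp$ppi, "ppi")
    dg <- load_edges(inp$disease_gene, "disease_gene")
    gene_go <- load_annotations(inp$gene_go)
    dgo <- drug_go_edges(dt, gene_go, alpha = cfg$enrichment$alpha)
    graph <- assemble_graph(list(dt, pp, dg, dgo$edges), compounds)
    write_graph(graph, file.path(cfg$out_dir, "graph.tsv"))
    pos <- load_edges(inp$drug_disease, "drug_disease")
    list(graph = graph, compounds = compounds,
         positives = data.frame(drug = pos$source, disease = pos$target,
                                label = 1L))
  })
  graph <- bundle$graph

  struct <- stage("embed-smiles", {
    acfg <- do.call(smiles_ae_config, c(cfg$smiles_ae,
                                        list(seed = seeds[["smiles"]])))
    model <- train_autoencoder(bundle$compounds, acfg)
    save_smiles_model(model, file.path(cfg$out_dir, "smiles_model.rds"))
    emb <- embed_structures(model, bundle$compounds)
    write_embedding_tsv(emb, file.path(cfg$out_dir, "structural.tsv"))
    emb
  })

  wcfg <- do.call(walk_config, c(cfg$walker,
                                 list(seed = seeds[["walker"]])))
  scfg <- do.call(skipgram_config, c(cfg$skipgram,
                                     list(seed = seeds[["walker"]])))
  func <- stage("embed-graph drug_go", {
    emb <- functional_embeddings(graph, wcfg, scfg)
    write_embedding_tsv(emb, file.path(cfg$out_dir, "functional.tsv"))
    emb
  })
  dis_emb <- stage("embed-graph disease_gene",
    node_embeddings(graph, "disease_gene", wcfg, scfg,
                    restrict_kind = "disease"))
  prot_emb <- stage("embed-graph drug_target+ppi",
    node_embeddings(graph, c("drug_target", "ppi"), wcfg, scfg,
                    restrict_kind = "protein"))

  drug_content <- fuse_drug_content(struct, func)
  gcfg <- do.call(gnn_config, c(cfg$gnn, list(seed = seeds[["gnn"]])))
  ccfg <- do.call(classifier_config,
                  c(cfg$classifier, list(seed = seeds[["predictor"]])))

  labelled <- stage("label", {
    drugs <- rownames(drug_content)
    diseases <- rownames(dis_emb)
    pos <- bundle$positives
    pos <- pos[pos$drug %in% drugs & pos$disease %in% diseases, ,
               drop = FALSE]
    neg <- sample_negatives(pos, drugs, diseases, ccfg$negative_ratio,
                            seed = seeds[["predictor"]])
    rbind(pos, neg)
  })

  base_edges <- graph$edges[graph$edges$relation %in%
                              c("drug_target", "ppi", "disease_gene"), ]
  report <- stage("cv", {
    rep <- crossvalidate(base_edges, drug_content, prot_emb, dis_emb,
                         labelled, ccfg, gcfg)
    jsonlite::write_json(
      list(per_fold = rep$per_fold, mean = rep$mean, seed = cfg$seed,
           module_seeds = as.list(seeds)),
      file.path(cfg$out_dir, "cv_report.json"),
      auto_unbox = TRUE, digits = NA)
    rep
  })

  model <- stage("train-final",
    train_predictor(base_edges, drug_content, prot_emb, dis_emb,
                    labelled, ccfg, gcfg))

  predictions <- stage("predict", {
    drugs <- rownames(drug_content)
    diseases <- rownames(dis_emb)
    known <- pair_key(labelled$drug, labelled$disease)
    universe <- expand.grid(drug = drugs, disease = diseases,
                            stringsAsFactors = FALSE)
    query <- universe[!(pair_key(universe$drug, universe$disease) %in%
                          known), , drop = FALSE]
    ranked <- score_and_rank(model, query)
    ranked$category <- categorize(ranked$score, FALSE,
                                  ccfg$decision_threshold)
    write.table(ranked, file.path(cfg$out_dir, "predictions.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    ranked
  })

  sims <- stage("similarity", {
    drugs <- intersect(rownames(struct), rownames(func))
    glob <- model$embeddings[drugs, , drop = FALSE]
    out <- list(structural = similarity_matrix(struct, drugs,
                                               cfg$simspace$threshold,
                                               cfg$simspace$method),
                functional = similarity_matrix(func, drugs,
                                               cfg$simspace$threshold,
                                               cfg$simspace$method),
                global = similarity_matrix(glob, drugs,
                                           cfg$simspace$threshold,
                                           cfg$simspace$method))
    for (nm in names(out)) {
      write.table(round(out[[nm]]$matrix, 8),
                  file.path(cfg$out_dir, paste0("similarity_", nm, ".tsv")),
                  sep = "\t", quote = FALSE)
      write.table(out[[nm]]$flagged,
                  file.path(cfg$out_dir, paste0("flags_", nm, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    proj <- project_tsne(glob, dims = cfg$simspace$dims,
                         perplexity = min(cfg$simspace$perplexity,
                                          floor((nrow(glob) - 2) / 3)),
                         seed = seeds[["simspace"]])
    write.table(data.frame(proj, row.names = NULL),
                file.path(cfg$out_dir, "tsne.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    out
  })

  files <- list.files(cfg$out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$|\\.rds$", files)]
  manifest <- list(
    config = unclass(cfg), master_seed = cfg$seed,
    module_seeds = as.list(seeds),
    checksums = as.list(setNames(unname(tools::md5sum(files)),
                                 sub(paste0("^", cfg$out_dir, "/?"), "",
                                     files))))
  manifest_path <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA)
  hx_log("cli", "run complete; manifest at ", manifest_path)
  invisible(list(report = report, predictions = predictions,
                 similarity = sims, truth = truth,
                 manifest = manifest_path))
}
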
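# Seeded synthetic benchmark: a planted block model over drugs, diseases,
# proteins and GO terms in which shared latent blocks drive target edges,
# annotations, SMILES motifs and drug-disease associations, so every
# pipeline stage can be tested against known ground truth.

#' Synthetic benchmark configuration
#'
#' Defaults define the package's standard benchmark: three latent blocks
#' over 60 drugs, 30 diseases and 120 proteins, with dense within-block and
#' sparse cross-block wiring, and drug-disease associations planted at
#' probability 0.30 within block versus 0.02 across blocks.
#'
#' @param n_drugs,n_diseases,n_proteins,n_go entity counts.
#' @param n_blocks latent blocks; must not exceed the smaller entity counts.
#' @param p_dt_within,p_dt_cross drug-target edge probabilities.
#' @param p_dg_within,p_dg_cross disease-gene edge probabilities.
#' @param p_ppi_within,p_ppi_cross protein-protein edge probabilities.
#' @param p_assoc_within,p_assoc_cross drug-disease association
#'   probabilities.
#' @param p_ann_within,p_ann_cross annotation probabilities for
#'   block-matched vs other GO terms.
#' @param heldout_frac fraction of planted positives withheld from every
#'   training stage, for ranking checks; default 0.2.
#' @param seed RNG seed.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_drugs = 60, n_diseases = 30, n_proteins = 120,
                         n_go = 40, n_blocks = 3,
                         p_dt_within = 0.25, p_dt_cross = 0.03,
                         p_dg_within = 0.25, p_dg_cross = 0.03,
                         p_ppi_within = 0.10, p_ppi_cross = 0.01,
                         p_assoc_within = 0.30, p_assoc_cross = 0.02,
                         p_ann_within = 0.60, p_ann_cross = 0.05,
                         heldout_frac = 0.2, seed = 1) {
  probs <- c(p_dt_within, p_dt_cross, p_dg_within, p_dg_cross, p_ppi_within,
             p_ppi_cross, p_assoc_within, p_assoc_cross, p_ann_within,
             p_ann_cross, heldout_frac)
  stopifnot(all(probs >= 0 & probs <= 1),
            n_blocks >= 1, n_blocks <= min(n_drugs, n_diseases))
  structure(as.list(environment()), class = "synth_config")
}

#' Compact preset for smoke tests
#' @param seed RNG seed.
#' @return a `synth_config` of about 30 nodes.
#' @export
synth_config_tiny <- function(seed = 1) {
  synth_config(n_drugs = 10, n_diseases = 6, n_proteins = 40, n_go = 10,
               n_blocks = 2,
               p_dt_within = 0.4, p_dt_cross = 0.05,
               p_dg_within = 0.4, p_dg_cross = 0.05,
               p_ppi_within = 0.15, p_ppi_cross = 0.02,
               p_assoc_within = 0.6, p_assoc_cross = 0.05,
               p_ann_within = 0.8, p_ann_cross = 0.05,
               seed = seed)
}

block_of <- function(n, n_blocks) rep_len(seq_len(n_blocks), n)

sample_bipartite <- function(src, tgt, src_block, tgt_block, p_within,
                             p_cross) {
  pr <- ifelse(outer(src_block, tgt_block, "=="), p_within, p_cross)
  hit <- which(matrix(runif(length(pr)), nrow(pr)) < pr, arr.ind = TRUE)
  data.frame(source = src[hit[, 1]], target = tgt[hit[, 2]],
             stringsAsFactors = FALSE)
}

#' Generate a planted-block heterogeneous network
#'
#' Drugs, diseases and proteins are partitioned into blocks; drug-target,
#' disease-gene, protein-protein and drug-disease edges are drawn
#' independently with block-dependent probabilities. A `heldout_frac`
#' fraction of planted positive associations is withheld from the training
#' association set.
#'
#' @param cfg a [synth_config()].
#' @return list with `graph` (a `hetero_graph` of drug_target, ppi and
#'   disease_gene edges), `associations` (training positives, label 1),
#'   `truth` (block maps, planted and held-out positives), `compounds`,
#'   and `annotations` (drug_go/gene_go tables).
#' @export
gen_network <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  drugs <- node_id("drug", sprintf("D%03d", seq_len(cfg$n_drugs)))
  diseases <- node_id("disease", sprintf("Z%03d", seq_len(cfg$n_diseases)))
  proteins <- node_id("protein", sprintf("P%03d", seq_len(cfg$n_proteins)))
  b_drug <- block_of(cfg$n_drugs, cfg$n_blocks)
  b_dis <- block_of(cfg$n_diseases, cfg$n_blocks)
  b_prot <- block_of(cfg$n_proteins, cfg$n_blocks)

  dt <- sample_bipartite(drugs, proteins, b_drug, b_prot,
                         cfg$p_dt_within, cfg$p_dt_cross)
  dt$relation <- "drug_target"
  dg <- sample_bipartite(diseases, proteins, b_dis, b_prot,
                         cfg$p_dg_within, cfg$p_dg_cross)
  dg$relation <- "disease_gene"
  pp <- sample_bipartite(proteins, proteins, b_prot, b_prot,
                         cfg$p_ppi_within, cfg$p_ppi_cross)
  pp <- pp[pp$source < pp$target, , drop = FALSE]
  pp$relation <- "ppi"

  assoc <- sample_bipartite(drugs, diseases, b_drug, b_dis,
                            cfg$p_assoc_within, cfg$p_assoc_cross)
  if (!nrow(assoc)) stop("degenerate config: no associations planted")
  n_hold <- floor(cfg$heldout_frac * nrow(assoc))
  hold_idx <- if (n_hold > 0) sample(nrow(assoc), n_hold) else integer(0)
  held_out <- assoc[hold_idx, , drop = FALSE]
  training <- assoc[setdiff(seq_len(nrow(assoc)), hold_idx), , drop = FALSE]

  compounds <- gen_smiles(drugs, b_drug, seed = cfg$seed + 1)
  annotations <- gen_annotations(cfg, drugs, b_drug, proteins, b_prot,
                                 seed = cfg$seed + 2)
  graph <- assemble_graph(list(dt, pp, dg), compounds)
  truth <- list(
    blocks = setNames(c(b_drug, b_dis, b_prot),
                      c(drugs, diseases, proteins)),
    planted = assoc, held_out = held_out)
  associations <- data.frame(drug = training$source,
                             disease = training$target, label = 1L,
                             stringsAsFactors = FALSE)
  list(graph = graph, associations = associations, truth = truth,
       compounds = compounds, annotations = annotations, config = cfg)
}

# fragment pools; every fragment tokenizes and concatenations stay
# tokenizable, so round-trip through the tokenizer is guaranteed
SMILES_MOTIFS <- list(
  c("CC", "CCO", "C(C)O", "CCC", "C(O)C", "OCC"),            # alkanol
  c("CCl", "C(Cl)C", "CBr", "ClC", "BrC", "C(Br)Cl"),        # halide
  c("c1ccccc1", "Cc1ccccc1", "c1ccncc1", "C(=O)O", "N", "CN") # benzenoid
)

#' Generate block-correlated SMILES strings
#'
#' Each compound is a concatenation of 2-4 fragments drawn mostly from its
#' block's motif pool (alkanol, halide or benzenoid chemistry), so token
#' overlap within a block exceeds overlap across blocks. Every string is
#' tokenizable and round-trips through [tokenize_smiles()].
#'
#' @param ids drug node ids.
#' @param blocks integer block of each id.
#' @param seed RNG seed.
#' @return CompoundSet: named character vector id -> SMILES.
#' @export
gen_smiles <- function(ids, blocks, seed = 1) {
  stopifnot(length(ids) >= 1, length(blocks) == length(ids))
  set.seed(seed)
  pools <- SMILES_MOTIFS[((blocks - 1) %% length(SMILES_MOTIFS)) + 1]
  smi <- vapply(seq_along(ids), function(i) {
    k <- sample(2:4, 1)
    own <- pools[[i]]
    other <- unlist(SMILES_MOTIFS)
    frags <- ifelse(runif(k) < 0.85,
                    sample(own, k, replace = TRUE),
                    sample(other, k, replace = TRUE))
    paste(frags, collapse = "")
  }, character(1))
  out <- setNames(smi, ids)
  stopifnot(vapply(out, function(s)
    paste(tokenize_smiles(s), collapse = "") == s, logical(1)))
  out
}

#' Generate block-specific GO annotation tables
#'
#' GO terms are divided evenly among blocks; a drug or protein is annotated
#' to a term of its own block with probability `p_ann_within` and to other
#' terms with `p_ann_cross`. The gene table feeds [enrich_go()].
#'
#' @param cfg a [synth_config()].
#' @param drugs,proteins node ids.
#' @param b_drug,b_prot their blocks.
#' @param seed RNG seed.
#' @return list with data.frames `drug_go` and `gene_go` (columns
#'   `subject`, `term`).
#' @export
gen_annotations <- function(cfg, drugs, b_drug, proteins, b_prot, seed = 1) {
  set.seed(seed)
  terms <- node_id("go", sprintf("G%03d", seq_len(cfg$n_go)))
  b_term <- block_of(cfg$n_go, cfg$n_blocks)
  ann <- function(subjects, b_subj) {
    df <- sample_bipartite(subjects, terms, b_subj, b_term,
                           cfg$p_ann_within, cfg$p_ann_cross)
    data.frame(subject = df$source, term = df$target,
               stringsAsFactors = FALSE)
  }
  list(drug_go = ann(drugs, b_drug), gene_go = ann(proteins, b_prot))
}

#' Write a complete synthetic input bundle to disk
#'
#' Emits exactly the TSV formats the ingestion layer reads (edge lists per
#' relation, SMILES table, annotation tables) plus ground-truth files, so a
#' full pipeline run needs no external data.
#'
#' @param dir output directory (created if absent).
#' @param preset `"tiny"` (seconds) or `"default"` (minutes).
#' @param seed RNG seed.
#' @return invisibly, the [gen_network()] bundle with `$paths` added.
#' @export
make_fixture <- function(dir, preset = c("tiny", "default"), seed = 1) {
  preset <- match.arg(preset)
  cfg <- if (preset == "tiny") synth_config_tiny(seed) else
    synth_config(seed = seed)
  net <- gen_network(cfg)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  wtsv <- function(df, name, header = NULL) {
    p <- file.path(dir, name)
    con <- file(p, "w")
    if (!is.null(header)) writeLines(header, con)
    writeLines(do.call(paste, c(unname(as.list(df)), sep = "\t")), con)
    close(con)
    p
  }
  e <- net$graph$edges
  for (rel in c("drug_target", "ppi", "disease_gene")) {
    sub <- e[e$relation == rel, c("source", "target")]
    paths[[rel]] <- wtsv(sub, paste0(rel, ".tsv"), "source\ttarget")
  }
  paths$drug_disease <- wtsv(
    net$associations[, c("drug", "disease")], "drug_disease.tsv",
    "source\ttarget")
  paths$smiles <- wtsv(
    data.frame(id = names(net$compounds), smiles = unname(net$compounds)),
    "smiles.tsv")
  paths$gene_go <- wtsv(net$annotations$gene_go, "gene_go.tsv")
  paths$drug_go <- wtsv(net$annotations$drug_go, "drug_go.tsv")
  paths$blocks <- wtsv(
    data.frame(id = names(net$truth$blocks),
               block = unname(net$truth$blocks)), "blocks.tsv")
  paths$held_out <- wtsv(net$truth$held_out[, c("source", "target")],
                         "held_out.tsv")
  net$paths <- paths
  invisible(net)
}
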
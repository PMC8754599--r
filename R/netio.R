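# Typed heterogeneous network: ingestion, validation, assembly, enrichment.
#
# Node ids are namespaced "kind:label" strings, with kind drawn from the
# closed set {drug, protein, disease, go}. This stands in for database
# identifiers (MeSH, UniProt, GO accessions) without binding the package to
# any live resource.

NODE_KINDS <- c("drug", "protein", "disease", "go")

RELATIONS <- list(
  drug_target  = c(source = "drug",    target = "protein", directed = TRUE),
  ppi          = c(source = "protein", target = "protein", directed = FALSE),
  disease_gene = c(source = "disease", target = "protein", directed = TRUE),
  drug_disease = c(source = "drug",    target = "disease", directed = TRUE),
  drug_go      = c(source = "drug",    target = "go",      directed = TRUE)
)

#' Construct a namespaced node identifier
#'
#' @param kind one of `"drug"`, `"protein"`, `"disease"`, `"go"`.
#' @param label non-empty label without whitespace.
#' @return character id of the form `"kind:label"`.
#' @export
node_id <- function(kind, label) {
  kind <- match.arg(kind, NODE_KINDS)
  if (any(!nzchar(label)) || any(grepl("[[:space:]]", label)))
    stop("node label must be non-empty and contain no whitespace")
  paste0(kind, ":", label)
}

# Parse and validate "kind:label"; accepts the "prot" shorthand for protein.
parse_node_id <- function(id, where = NULL) {
  ctx <- if (is.null(where)) "" else paste0(" (", where, ")")
  m <- regmatches(id, regexec("^([A-Za-z]+):(\\S+)$", id))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad))
    stop("malformed node id ", sQuote(id[bad][1]), ctx,
         ": expected \"kind:label\" with no whitespace")
  kind <- vapply(m, `[`, "", 2L)
  kind[kind == "prot"] <- "protein"
  label <- vapply(m, `[`, "", 3L)
  unknown <- !(kind %in% NODE_KINDS)
  if (any(unknown))
    stop("unknown node kind ", sQuote(kind[unknown][1]), ctx,
         "; must be one of ", paste(NODE_KINDS, collapse = ", "))
  paste0(kind, ":", label)
}

#' Kind of a node id
#' @param id character vector of `"kind:label"` ids.
#' @return character vector of kinds.
#' @export
node_kind <- function(id) sub(":.*$", "", id)

#' Load a typed edge list from a two-column TSV
#'
#' Reads tab-separated `source<TAB>target` rows of namespaced node ids and
#' validates each endpoint kind against the requested relation. Duplicates
#' are retained; deduplication happens in [assemble_graph()].
#'
#' @param path path to the TSV file. A header line equal to
#'   `"source\ttarget"` is detected and skipped.
#' @param relation one of `drug_target`, `ppi`, `disease_gene`,
#'   `drug_disease`, `drug_go`.
#' @return data.frame with columns `source`, `target`, `relation`.
#' @export
load_edges <- function(path, relation) {
  relation <- match.arg(relation, names(RELATIONS))
  if (!file.exists(path)) stop("edge file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  offset <- 0L
  if (length(lines) && lines[1] == "source\ttarget") {
    lines <- lines[-1]
    offset <- 1L
  }
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty edge file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(parts, length, 1L)
  if (any(nf != 2L))
    stop("line ", which(nf != 2L)[1] + offset, " of ", path,
         ": expected 2 tab-separated fields, found ", nf[nf != 2L][1])
  src <- vapply(parts, `[`, "", 1L)
  tgt <- vapply(parts, `[`, "", 2L)
  spec <- RELATIONS[[relation]]
  validate_endpoints(src, tgt, relation, spec, path, offset)
  data.frame(source = parse_node_id(src), target = parse_node_id(tgt),
             relation = relation, stringsAsFactors = FALSE)
}

validate_endpoints <- function(src, tgt, relation, spec, path = "<memory>",
                               offset = 0L) {
  for (i in seq_along(src)) {
    where <- paste0(path, " line ", i + offset)
    s <- parse_node_id(src[i], where)
    t <- parse_node_id(tgt[i], where)
    if (node_kind(s) != spec[["source"]] || node_kind(t) != spec[["target"]])
      stop(where, ": relation ", relation, " requires ",
           spec[["source"]], " -> ", spec[["target"]], ", found ",
           node_kind(s), " -> ", node_kind(t))
    if (relation == "ppi" && s == t)
      stop(where, ": self-loop not allowed for ppi")
  }
  invisible(TRUE)
}

#' Load a compound table of SMILES strings
#'
#' @param path TSV of `drug id<TAB>SMILES`.
#' @return named character vector (a CompoundSet): names are drug node ids,
#'   values are SMILES strings.
#' @export
load_smiles <- function(path) {
  if (!file.exists(path)) stop("SMILES file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) && grepl("^(id|drug|compound)\tsmiles$", lines[1],
                             ignore.case = TRUE))
    lines <- lines[-1]
  if (!length(lines)) {
    hx_log("netio", "SMILES table ", path, " is empty")
    return(setNames(character(0), character(0)))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(parts, length, 1L)
  if (any(nf != 2L))
    stop("line ", which(nf != 2L)[1], " of ", path,
         ": expected 2 tab-separated fields")
  ids <- parse_node_id(vapply(parts, `[`, "", 1L), path)
  smi <- vapply(parts, `[`, "", 2L)
  if (anyDuplicated(ids))
    stop("duplicate compound id ", sQuote(ids[duplicated(ids)][1]),
         " in ", path)
  if (any(!nzchar(smi)))
    stop("empty SMILES for ", ids[!nzchar(smi)][1], " in ", path)
  setNames(smi, ids)
}

#' Load an annotation table (subject id, GO term id)
#'
#' @param path TSV of `subject<TAB>go term` where subject is a drug or
#'   protein node id and the term a `go:` node id.
#' @return data.frame with columns `subject`, `term`.
#' @export
load_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  df <- read.delim(path, header = FALSE, col.names = c("subject", "term"),
                   stringsAsFactors = FALSE)
  df$subject <- parse_node_id(df$subject, path)
  df$term <- parse_node_id(df$term, path)
  if (any(node_kind(df$term) != "go"))
    stop("annotation terms must be go: ids in ", path)
  unique(df)
}

#' Hypergeometric enrichment of annotation terms in a target set
#'
#' For each term with at least one member in `targets`, computes the exact
#' upper-tail hypergeometric probability of observing at least the seen
#' overlap when drawing `length(targets)` genes from a background of size
#' `length(background)` containing `K` annotated genes. Terms with
#' `pvalue < alpha` are flagged enriched; only those become drug-GO edges
#' downstream. Raw p-values are used (no multiplicity correction), matching
#' the conventional raw p < 0.01 annotation-selection rule.
#'
#' @param targets character vector of node ids (e.g. a drug's target set).
#' @param term_annotations named list mapping term id to the character
#'   vector of annotated node ids.
#' @param background character vector: the annotation universe.
#' @param alpha significance cutoff in (0, 1); default 0.01.
#' @return data.frame with columns `term`, `k`, `n`, `K`, `N`, `pvalue`,
#'   `enriched`, sorted by p-value.
#' @export
enrich_go <- function(targets, term_annotations, background, alpha = 0.01) {
  if (!length(background)) stop("empty background set")
  stopifnot(alpha > 0, alpha < 1)
  background <- unique(background)
  targets <- unique(targets)
  if (!all(targets %in% background))
    stop("targets must be a subset of the background")
  N <- length(background)
  n <- length(targets)
  res <- lapply(names(term_annotations), function(term) {
    ann <- unique(term_annotations[[term]])
    if (!all(ann %in% background))
      stop("annotated genes for ", term, " fall outside the background")
    K <- length(ann)
    k <- sum(targets %in% ann)
    if (k < 1) return(NULL)
    # upper tail P(X >= k): phyper counts <= so shift by one
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term, k = k, n = n, K = K, N = N, pvalue = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res))
    res <- data.frame(term = character(0), k = integer(0), n = integer(0),
                      K = integer(0), N = integer(0), pvalue = numeric(0))
  res$enriched <- res$pvalue < alpha
  res[order(res$pvalue, res$term), , drop = FALSE]
}

#' Assemble a validated heterogeneous graph
#'
#' Deduplicates edges (undirected ppi edges are stored once in lexicographic
#' order), collects the node set, and drops isolated nodes. Drug nodes
#' supplied in `compounds` but absent from every edge are dropped and
#' counted; drugs present in edges but missing a SMILES string are flagged.
#'
#' @param edge_lists list of data.frames from [load_edges()] (or one bound
#'   data.frame).
#' @param compounds optional CompoundSet from [load_smiles()].
#' @return an object of class `hetero_graph` with elements `nodes`, `edges`,
#'   `compounds`, `no_smiles` (drug ids lacking SMILES), `dropped` (count of
#'   isolated nodes removed).
#' @export
assemble_graph <- function(edge_lists, compounds = NULL) {
  edges <- if (is.data.frame(edge_lists)) edge_lists else
    do.call(rbind, edge_lists)
  if (is.null(edges) || !nrow(edges)) stop("no edges supplied")
  for (rel in unique(edges$relation)) {
    spec <- RELATIONS[[rel]]
    if (is.null(spec)) stop("unknown relation ", rel)
    idx <- edges$relation == rel
    validate_endpoints(edges$source[idx], edges$target[idx], rel, spec)
  }
  undir <- edges$relation %in%
    names(Filter(function(r) !as.logical(r[["directed"]]), RELATIONS))
  flip <- undir & edges$source > edges$target
  tmp <- edges$source[flip]
  edges$source[flip] <- edges$target[flip]
  edges$target[flip] <- tmp
  edges <- unique(edges)
  rownames(edges) <- NULL
  nodes <- sort(unique(c(edges$source, edges$target)))
  dropped <- 0L
  if (!is.null(compounds)) {
    orphans <- setdiff(names(compounds), nodes)
    dropped <- length(orphans)
    if (dropped)
      hx_log("netio", "dropped ", dropped, " isolated compound node(s)")
    compounds <- compounds[setdiff(names(compounds), orphans)]
  }
  drug_nodes <- nodes[node_kind(nodes) == "drug"]
  no_smiles <- if (is.null(compounds)) character(0) else
    setdiff(drug_nodes, names(compounds))
  if (length(no_smiles) && !is.null(compounds))
    hx_log("netio", length(no_smiles), " drug(s) lack SMILES; ",
           "structural embeddings unavailable for them")
  counts <- table(edges$relation)
  hx_log("netio", "assembled graph: ", length(nodes), " nodes; edges: ",
         paste(names(counts), counts, sep = "=", collapse = ", "))
  structure(list(nodes = nodes, edges = edges,
                 compounds = compounds %||% setNames(character(0), character(0)),
                 no_smiles = no_smiles, dropped = dropped),
            class = "hetero_graph")
}

#' @export
print.hetero_graph <- function(x, ...) {
  kinds <- table(node_kind(x$nodes))
  cat("hetero_graph:", length(x$nodes), "nodes (",
      paste(names(kinds), kinds, sep = "=", collapse = ", "), ")\n")
  rels <- table(x$edges$relation)
  cat("  edges:", paste(names(rels), rels, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Edges of one relation
#' @param graph a `hetero_graph`.
#' @param relation relation name.
#' @return data.frame of edges.
#' @export
relation_edges <- function(graph, relation) {
  relation <- match.arg(relation, names(RELATIONS))
  graph$edges[graph$edges$relation == relation, , drop = FALSE]
}

#' Undirected adjacency list over a set of relations
#'
#' Walks and aggregation traverse edges in both directions regardless of
#' the stored orientation.
#'
#' @param graph a `hetero_graph`.
#' @param relations character vector of relation names.
#' @return named list: node id -> sorted character vector of neighbours.
#' @export
adjacency_list <- function(graph, relations) {
  e <- graph$edges[graph$edges$relation %in% relations, , drop = FALSE]
  if (!nrow(e)) stop("no edges for relations ", paste(relations, collapse = ","))
  nodes <- sort(unique(c(e$source, e$target)))
  adj <- split(c(e$target, e$source), c(e$source, e$target))
  adj <- lapply(adj, function(v) sort(unique(v)))
  adj[nodes]
}

#' Write a heterogeneous graph to a sorted three-column TSV
#'
#' The output round-trips: reading each relation back with [load_edges()]
#' and reassembling yields an identical graph.
#'
#' @param graph a `hetero_graph`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_graph <- function(graph, path) {
  e <- graph$edges[order(graph$edges$relation, graph$edges$source,
                         graph$edges$target), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("source\ttarget\trelation", con)
  if (nrow(e))
    writeLines(paste(e$source, e$target, e$relation, sep = "\t"), con)
  invisible(path)
}

#' Read a graph written by [write_graph()]
#' @param path TSV path with columns source, target, relation.
#' @param compounds optional CompoundSet.
#' @return a `hetero_graph`.
#' @export
read_graph <- function(path, compounds = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!nrow(df)) stop("empty graph file: ", path)
  assemble_graph(df, compounds)
}

#' Build drug-GO edges from enrichment of drug target sets
#'
#' For each drug, tests its target proteins against gene-level GO
#' annotations and keeps terms enriched at `alpha`.
#'
#' @param drug_target data.frame of drug_target edges.
#' @param gene_go data.frame from [load_annotations()] (protein -> go).
#' @param alpha enrichment cutoff.
#' @param background background gene set; default all annotated genes.
#' @return list(edges = drug_go edge data.frame, report = per-drug
#'   enrichment tables).
#' @export
drug_go_edges <- function(drug_target, gene_go, alpha = 0.01,
                          background = NULL) {
  term_ann <- split(gene_go$subject, gene_go$term)
  background <- background %||% unique(gene_go$subject)
  targets_by_drug <- split(drug_target$target, drug_target$source)
  report <- list()
  rows <- list()
  for (drug in names(targets_by_drug)) {
    tg <- intersect(unique(targets_by_drug[[drug]]), background)
    if (!length(tg)) next
    res <- enrich_go(tg, term_ann, background, alpha)
    report[[drug]] <- res
    hit <- res$term[res$enriched]
    if (length(hit))
      rows[[drug]] <- data.frame(source = drug, target = hit,
                                 relation = "drug_go",
                                 stringsAsFactors = FALSE)
  }
  edges <- do.call(rbind, rows)
  if (is.null(edges))
    edges <- data.frame(source = character(0), target = character(0),
                        relation = character(0))
  rownames(edges) <- NULL
  list(edges = edges, report = report)
}
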
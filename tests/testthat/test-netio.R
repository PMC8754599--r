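test_that("load_edges validates ids and relations and preserves duplicates", {
  p <- write_tsv_lines("drug:D1\tprot:P1")
  e <- load_edges(p, "drug_target")
  expect_equal(nrow(e), 1)
  expect_equal(e$source, "drug:D1")
  expect_equal(e$target, "protein:P1")  # prot alias canonicalized

  expect_error(load_edges(p, "disease_gene"), "requires disease -> protein")

  p3 <- write_tsv_lines(c("drug:D1\tprot:P1", "drug:D2\tprot:P2",
                          "drug:D1\tprot:P1"))
  expect_equal(nrow(load_edges(p3, "drug_target")), 3)  # dedup deferred

  hdr <- write_tsv_lines(c("source\ttarget", "drug:D1\tprot:P1"))
  expect_equal(nrow(load_edges(hdr, "drug_target")), 1)

  expect_error(load_edges(write_tsv_lines("drug D1\tprot:P1"), "drug_target"),
               "line 1")
  expect_error(load_edges(write_tsv_lines(character(0)), "drug_target"),
               "empty")
  expect_error(load_edges(write_tsv_lines("prot:P1\tprot:P1"), "ppi"),
               "self-loop")
})

test_that("load_smiles enforces unique ids and non-empty strings", {
  p <- write_tsv_lines(c("drug:D1\tCCO", "drug:D2\tCCN"))
  cs <- load_smiles(p)
  expect_equal(cs, c("drug:D1" = "CCO", "drug:D2" = "CCN"))
  expect_error(load_smiles(write_tsv_lines(c("drug:D1\tCCO", "drug:D1\tC"))),
               "duplicate")
  expect_error(load_smiles(write_tsv_lines("drug:D1\t")), "2 tab-separated")
  empty <- tempfile(); file.create(empty)
  expect_length(suppressMessages(load_smiles(empty)), 0)
})

# independent oracle: enumerate every size-n subset of the background and
# count those containing at least k annotated members
enum_hyper_tail <- function(N, K, n, k) {
  subsets <- utils::combn(N, n)
  ann <- seq_len(K)
  mean(apply(subsets, 2, function(s) sum(s %in% ann) >= k))
}

test_that("enrichment p-values match subset enumeration and the closed form", {
  bg <- paste0("protein:g", 1:10)
  res <- enrich_go(bg[1:3], list("go:T" = bg[c(1:3, 5)]), bg, alpha = 0.01)
  expect_equal(res$pvalue, enum_hyper_tail(10, 4, 3, 3))
  expect_equal(res$pvalue, 4 / 120, tolerance = 1e-12)
  expect_false(res$enriched)  # 0.0333 > 0.01

  set.seed(42)
  for (i in 1:20) {
    N <- sample(4:12, 1)
    K <- sample(1:(N - 1), 1)
    n <- sample(1:(N - 1), 1)
    bg <- paste0("protein:x", seq_len(N))
    targets <- sample(bg, n)
    ann <- bg[seq_len(K)]
    r <- enrich_go(targets, list("go:A" = ann), bg)
    k <- sum(targets %in% ann)
    if (k >= 1)
      expect_equal(r$pvalue, enum_hyper_tail(N, K, n, k), tolerance = 1e-12)
    else expect_equal(nrow(r), 0)
  }

  # closed-form binomial-coefficient sum at a size enumeration cannot reach
  closed <- function(N, K, n, k)
    sum(vapply(k:min(n, K), function(j)
      choose(K, j) * choose(N - K, n - j), numeric(1))) / choose(N, n)
  bg <- paste0("protein:y", 1:5000)
  r <- enrich_go(bg[1:40], list("go:B" = bg[c(1:12, 100:150)]), bg)
  expect_equal(r$pvalue, closed(5000, 63, 40, 12), tolerance = 1e-12)

  # degenerate cases
  bg <- paste0("protein:z", 1:8)
  r <- enrich_go(bg, list("go:C" = bg[1:3]), bg)  # n = N: certainty
  expect_equal(r$pvalue, 1)
  expect_error(enrich_go("protein:a", list(), character(0)), "empty background")
})

test_that("assemble deduplicates, canonicalizes ppi, and drops orphans", {
  e1 <- data.frame(source = c("protein:B", "protein:A"),
                   target = c("protein:A", "protein:B"),
                   relation = "ppi")
  g <- suppressMessages(assemble_graph(e1))
  expect_equal(nrow(g$edges), 1)
  expect_true(g$edges$source < g$edges$target)

  dt <- data.frame(source = "drug:D1", target = "protein:A",
                   relation = "drug_target")
  cs <- c("drug:D1" = "CCO", "drug:ORPHAN" = "CC")
  g2 <- suppressMessages(assemble_graph(list(dt, e1), cs))
  expect_equal(g2$dropped, 1)
  expect_false("drug:ORPHAN" %in% g2$nodes)

  dt2 <- data.frame(source = "drug:D2", target = "protein:A",
                    relation = "drug_target")
  g3 <- suppressMessages(assemble_graph(list(dt, dt2, e1), cs))
  expect_equal(g3$no_smiles, "drug:D2")
})

test_that("write_graph round-trips through load and reassembly", {
  net <- tiny_net()
  g <- net$graph
  path <- tempfile(fileext = ".tsv")
  write_graph(g, path)
  g2 <- suppressMessages(read_graph(path, net$compounds))
  expect_equal(g2$nodes, g$nodes)
  expect_equal(g2$edges[order(g2$edges$relation, g2$edges$source, g2$edges$target), ],
               g$edges[order(g$edges$relation, g$edges$source, g$edges$target), ],
               ignore_attr = TRUE)
  # empty graph: header-only file round-trip refuses cleanly
  g$edges <- g$edges[0, ]
  write_graph(g, path)
  expect_equal(readLines(path), "source\ttarget\trelation")
})

test_that("every drug_go edge built from enrichment is significant", {
  net <- tiny_net()
  dt <- relation_edges(net$graph, "drug_target")
  dgo <- drug_go_edges(dt, net$annotations$gene_go, alpha = 0.01)
  expect_gt(nrow(dgo$edges), 0)
  for (i in seq_len(nrow(dgo$edges))) {
    rep <- dgo$report[[dgo$edges$source[i]]]
    expect_lt(rep$pvalue[rep$term == dgo$edges$target[i]], 0.01)
  }
})
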
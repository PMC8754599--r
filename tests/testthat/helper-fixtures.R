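# Shared fixtures, built lazily and cached for the whole run.

.hx_cache <- new.env(parent = emptyenv())

# The standard planted-block benchmark at its frozen study conditions.
seed11_bench <- function() {
  if (is.null(.hx_cache$bench)) {
    .hx_cache$bench <- suppressMessages(suppressWarnings(
      run_benchmark(seed = 11, dim = 32, ae_epochs = 40,
                    gnn_epochs = 150, trees = 500)))
  }
  .hx_cache$bench
}

# A tiny assembled network bundle for fast unit tests.
tiny_net <- function(seed = 5) {
  key <- paste0("tiny", seed)
  if (is.null(.hx_cache[[key]]))
    .hx_cache[[key]] <- suppressMessages(gen_network(synth_config_tiny(seed)))
  .hx_cache[[key]]
}

write_tsv_lines <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# SMILES with bracket atoms, two-letter halogens, %nn closures, aromatics
adversarial_smiles <- c(
  "ClCBr", "C[NH4+]", "c1ccccc1", "C%12CCCCCCCCCC%12C",
  "[13CH3]C(=O)O", "BrC(Cl)C[Se]C", "O=C(O)c1ccncc1", "C/C=C\\C",
  "[Na+].[Cl-]", "C1CC1%99CC%99", "c1ccc2ccccc2c1", "[nH]1cccc1"
)
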
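#' @useDynLib heterorx, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif setNames phyper predict var sd median quantile dist
#' @importFrom utils read.delim write.table head
NULL

hx_log <- function(module, ...) {
  msg <- paste0("[", module, "] ", paste0(..., collapse = ""))
  message(msg)
  invisible(msg)
}

#' Derive per-module seeds from a master seed
#'
#' Every stochastic stage of the pipeline draws its seed deterministically
#' from one master seed via fixed per-module offsets, so a single integer
#' reproduces an entire run while stages remain independently rerunnable.
#'
#' @param master integer master seed.
#' @return named integer vector of module seeds.
#' @export
derive_seeds <- function(master) {
  stopifnot(is.numeric(master), length(master) == 1, is.finite(master))
  master <- as.integer(master)
  offsets <- c(synth = 101L, smiles = 211L, walker = 307L, gnn = 401L,
               predictor = 503L, simspace = 601L)
  (master + offsets) %% .Machine$integer.max
}

# %||% as in rlang, for config defaults
`%||%` <- function(a, b) if (is.null(a)) b else a
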
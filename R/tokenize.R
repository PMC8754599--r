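# SMILES tokenization: longest-match over a fixed rule table.
#
# A strict per-character split would break two-letter organic-subset halogens
# (Cl, Br), bracket atoms and %nn ring closures, so those are single tokens.

# single characters legal outside brackets
SMILES_SINGLE <- c(
  "B", "C", "N", "O", "P", "S", "F", "I",
  "b", "c", "n", "o", "p", "s",
  as.character(0:9),
  "(", ")", "=", "#", "-", "+", "/", "\\", ".", "@", "*", ":", "$", "~"
)

RESERVED_TOKENS <- c("<pad>", "<bos>", "<eos>", "<unk>")

#' Tokenize a SMILES string
#'
#' Longest-match tokenization: bracket atoms `[...]` are one token, the
#' two-letter elements `Cl` and `Br` are one token, `%nn` ring closures are
#' one token, and every other character is its own token. Concatenating the
#' tokens reproduces the input exactly.
#'
#' @param smiles a single non-empty SMILES string.
#' @return character vector of tokens.
#' @export
tokenize_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1)
  if (!nzchar(smiles)) stop("empty SMILES string")
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  n <- length(chars)
  tokens <- character(0)
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("unclosed bracket atom at position ", i,
                      " in ", sQuote(smiles))
      tokens <- c(tokens, paste(chars[i:j], collapse = ""))
      i <- j + 1L
    } else if (ch == "%" ) {
      if (i + 2L > n || !all(grepl("[0-9]", chars[i + 1:2])))
        stop("malformed %nn ring closure at position ", i,
             " in ", sQuote(smiles))
      tokens <- c(tokens, paste(chars[i:(i + 2L)], collapse = ""))
      i <- i + 3L
    } else if (ch %in% c("C", "B") && i < n &&
               paste0(ch, chars[i + 1L]) %in% c("Cl", "Br")) {
      tokens <- c(tokens, paste0(ch, chars[i + 1L]))
      i <- i + 2L
    } else if (ch %in% SMILES_SINGLE) {
      tokens <- c(tokens, ch)
      i <- i + 1L
    } else {
      stop("character ", sQuote(ch), " at position ", i,
           " is outside the SMILES alphabet in ", sQuote(smiles))
    }
  }
  tokens
}

#' Build a token vocabulary from a corpus
#'
#' Indices are contiguous from 1 with the reserved symbols `<pad>`, `<bos>`,
#' `<eos>`, `<unk>` first, then corpus tokens sorted by decreasing frequency
#' (ties broken lexicographically), so identical corpora give identical
#' vocabularies.
#'
#' @param token_sequences list of character token vectors.
#' @return named integer vector: token -> index.
#' @export
build_vocab <- function(token_sequences) {
  if (!length(token_sequences)) stop("empty corpus")
  tab <- table(unlist(token_sequences))
  ord <- order(-as.integer(tab), names(tab))
  symbols <- c(RESERVED_TOKENS, names(tab)[ord])
  setNames(seq_along(symbols), symbols)
}

# Encode tokens to integer indices; unseen tokens map to <unk>.
encode_tokens <- function(tokens, vocab) {
  idx <- vocab[tokens]
  idx[is.na(idx)] <- vocab[["<unk>"]]
  unname(idx)
}
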
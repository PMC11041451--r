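#' Tokenize note text into sentences with character offsets
#'
#' Sentences are split on newlines and on periods followed by whitespace or
#' end of text (decimal points such as "1.2 cm" never split, because the
#' period is followed by a digit). Tokens are maximal letter runs, numbers
#' (with an optional decimal part), or single punctuation characters, so
#' "3mm" tokenizes as "3", "mm". Every token carries exact 0-based half-open
#' character offsets into the original text; tokenization is lossless in the
#' sense that slicing the text at the offsets reproduces each token surface.
#'
#' @param text a single character string (may be empty).
#' @return A list of sentences; each sentence is a list with elements
#'   `tokens` (character), `start`, `end` (integer, 0-based half-open offsets
#'   into `text`) and `sentence_index` (1-based).
#' @examples
#' s <- tokenize("3 mm GGO.")[[1]]
#' s$tokens  # "3" "mm" "GGO" "."
#' @export
tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  if (is.na(text) || !nzchar(text)) return(list())

  # sentence boundaries: newline, or '.' followed by whitespace / end of text
  bnd <- gregexpr("\\.(?=\\s)|\\.$|\\n", text, perl = TRUE)[[1]]
  cuts <- if (bnd[1] == -1L) integer(0) else as.integer(bnd)
  seg_start <- c(1L, cuts + 1L)
  seg_end <- c(cuts, nchar(text))
  keep <- seg_start <= seg_end
  seg_start <- seg_start[keep]; seg_end <- seg_end[keep]

  tok_re <- "[A-Za-z]+|[0-9]+(\\.[0-9]+)?|[^A-Za-z0-9[:space:]]"
  out <- list()
  idx <- 0L
  for (i in seq_along(seg_start)) {
    seg <- substr(text, seg_start[i], seg_end[i])
    m <- gregexpr(tok_re, seg, perl = TRUE)[[1]]
    if (m[1] == -1L) next
    len <- attr(m, "match.length")
    idx <- idx + 1L
    start0 <- as.integer(m) + seg_start[i] - 2L        # 0-based
    out[[idx]] <- list(
      tokens = substring(seg, as.integer(m), as.integer(m) + len - 1L),
      start = start0,
      end = start0 + len,
      sentence_index = idx)
  }
  out
}

#' Normalize tokens for embedding training
#'
#' Lowercases and keeps alphanumeric tokens only (the tokenization shared by
#' the query-expansion and tagging stages); punctuation is dropped.
#'
#' @param text a character string.
#' @return character vector of lowercase tokens, one element per token.
#' @export
embedding_tokens <- function(text) {
  toks <- unlist(lapply(tokenize(text), `[[`, "tokens"), use.names = FALSE)
  toks <- tolower(toks[grepl("[a-zA-Z0-9]", toks)])
  toks
}
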
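#' Detect and merge collocation bigrams in a tokenized corpus
#'
#' Token pairs (a, b) whose collocation score
#' `(count(ab) - min_count) * N / (count(a) * count(b))` exceeds `threshold`
#' (N = total token count of the corpus) are rewritten as a single token `"a_b"` in one
#' greedy left-to-right pass per sentence, so e.g. "ground glass" becomes
#' "ground_glass" before embedding training.
#'
#' @param corpus_tokens list of character vectors (one per sentence/note).
#' @param min_count minimum bigram count entering the score.
#' @param threshold score threshold; `Inf` leaves the corpus unchanged.
#' @return list with `corpus` (rewritten token lists) and `bigrams`
#'   (data.frame `token1`, `token2`, `score` of merged pairs, score
#'   descending).
#' @export
detect_bigrams <- function(corpus_tokens, min_count = 5, threshold = 10) {
  if (!length(corpus_tokens) || !sum(lengths(corpus_tokens)))
    stop("empty corpus")
  stopifnot(min_count >= 1)
  uni <- table(unlist(corpus_tokens, use.names = FALSE))
  pairs <- unlist(lapply(corpus_tokens, function(s) {
    if (length(s) < 2) return(character(0))
    paste(s[-length(s)], s[-1], sep = "\r")
  }), use.names = FALSE)
  if (!length(pairs))
    return(list(corpus = corpus_tokens,
                bigrams = data.frame(token1 = character(0),
                                     token2 = character(0),
                                     score = numeric(0))))
  bi <- table(pairs)
  N <- sum(uni)
  parts <- strsplit(names(bi), "\r", fixed = TRUE)
  a <- vapply(parts, `[`, character(1), 1)
  b <- vapply(parts, `[`, character(1), 2)
  score <- (as.numeric(bi) - min_count) * N /
    (as.numeric(uni[a]) * as.numeric(uni[b]))
  keep <- is.finite(score) & score > threshold
  merged <- data.frame(token1 = a[keep], token2 = b[keep],
                       score = score[keep], stringsAsFactors = FALSE)
  merged <- merged[order(-merged$score, merged$token1, merged$token2), ,
                   drop = FALSE]
  rownames(merged) <- NULL
  if (!nrow(merged))
    return(list(corpus = corpus_tokens, bigrams = merged))
  key <- paste(merged$token1, merged$token2, sep = "\r")
  corpus <- lapply(corpus_tokens, function(s) {
    if (length(s) < 2) return(s)
    out <- character(0); i <- 1L
    while (i <= length(s)) {
      if (i < length(s) && paste(s[i], s[i + 1], sep = "\r") %in% key) {
        out <- c(out, paste(s[i], s[i + 1], sep = "_"))
        i <- i + 2L
      } else {
        out <- c(out, s[i])
        i <- i + 1L
      }
    }
    out
  })
  list(corpus = corpus, bigrams = merged)
}

#' Train skip-gram word embeddings with negative sampling
#'
#' A from-scratch word2vec (skip-gram, negative sampling, dynamic window,
#' unigram^0.75 noise distribution, linearly decaying learning rate),
#' single-threaded and bit-for-bit reproducible under a fixed seed. Tokens
#' below `min_count` are dropped before training.
#'
#' @param corpus_tokens list of character vectors (run [detect_bigrams()]
#'   first for bigram-aware embeddings).
#' @param dim embedding dimension.
#' @param window maximum context window (actual window is sampled
#'   per position).
#' @param min_count minimum token frequency.
#' @param epochs training passes.
#' @param negative negative samples per context pair.
#' @param lr initial learning rate.
#' @param seed integer seed.
#' @return object of class `ggo_embeddings`: `vocabulary` (frequency-sorted),
#'   `vectors` (|V| x dim), and the training parameters.
#' @export
train_embeddings <- function(corpus_tokens, dim = 100, window = 5,
                             min_count = 5, epochs = 5, negative = 5,
                             lr = 0.025, seed = 1L) {
  if (!length(corpus_tokens) || !sum(lengths(corpus_tokens)))
    stop("empty corpus")
  counts <- table(unlist(corpus_tokens, use.names = FALSE))
  counts <- counts[counts >= min_count]
  if (!length(counts)) stop("vocabulary empty after min_count filtering")
  ord <- order(-as.numeric(counts), names(counts))
  vocab <- names(counts)[ord]
  freq <- as.numeric(counts)[ord]
  sents <- lapply(corpus_tokens, function(s) {
    ids <- match(s, vocab)
    as.integer(ids[!is.na(ids)])
  })
  sents <- sents[lengths(sents) > 1]
  if (!length(sents)) stop("no trainable sentences after filtering")
  noise <- freq^0.75
  cdf <- cumsum(noise) / sum(noise)
  W <- .sgns_train_cpp(sents, length(vocab), as.integer(dim),
                       as.integer(window), as.integer(negative),
                       as.integer(epochs), lr, cdf, as.integer(seed))
  rownames(W) <- vocab
  structure(list(vocabulary = vocab, vectors = W,
                 training_params = list(dim = dim, window = window,
                                        min_count = min_count,
                                        epochs = epochs, negative = negative,
                                        lr = lr, seed = seed)),
            class = "ggo_embeddings")
}

#' @export
print.ggo_embeddings <- function(x, ...) {
  cat("word2vec embedding table: ", length(x$vocabulary), " tokens x ",
      x$training_params$dim, " dims (window ", x$training_params$window,
      ", seed ", x$training_params$seed, ")\n", sep = "")
  invisible(x)
}

#' Cosine similarity between embedding rows
#'
#' @param table a `ggo_embeddings`.
#' @param a,b tokens in the vocabulary.
#' @return cosine similarity in \[-1, 1\].
#' @export
embedding_similarity <- function(table, a, b) {
  V <- table$vectors
  if (!a %in% rownames(V) || !b %in% rownames(V))
    stop("token not in vocabulary")
  va <- V[a, ]; vb <- V[b, ]
  sum(va * vb) / sqrt(sum(va^2) * sum(vb^2))
}

#' Expand a seed term list by embedding nearest neighbors
#'
#' For each in-vocabulary seed, takes the top-`k` cosine neighbors over the
#' whole vocabulary (rows L2-normalized before comparison); returns their
#' union with each term's best similarity across seeds, seeds themselves
#' excluded, sorted by similarity descending with lexicographic tie-breaks.
#' Out-of-vocabulary seeds are reported in the `oov` attribute, not fatal.
#' The result is the candidate list only; accepting terms is a manual step.
#'
#' @param seeds character vector of seed terms.
#' @param table a `ggo_embeddings`.
#' @param k neighbors per seed; `k = 0` gives an empty result, negative `k`
#'   is an error.
#' @param min_similarity drop candidates below this cosine similarity.
#' @return data.frame `term`, `similarity`, with attribute `oov`.
#' @export
expand_terms <- function(seeds, table, k = 20, min_similarity = -1) {
  if (k < 0) stop("k must be non-negative")
  stopifnot(inherits(table, "ggo_embeddings"))
  V <- table$vectors
  nrm <- sqrt(rowSums(V^2))
  nrm[nrm == 0] <- 1
  Vn <- V / nrm
  seeds <- unique(seeds)
  oov <- setdiff(seeds, rownames(V))
  seeds_in <- setdiff(seeds, oov)
  best <- numeric(0)
  if (k > 0) for (s in seeds_in) {
    sims <- as.numeric(Vn %*% Vn[s, ])
    names(sims) <- rownames(V)
    sims <- sims[!(names(sims) %in% seeds)]
    top <- sims[order(-sims, names(sims))][seq_len(min(k, length(sims)))]
    for (t in names(top))
      best[t] <- max(best[t], top[[t]], na.rm = TRUE)
  }
  best <- best[best >= min_similarity]
  out <- data.frame(term = if (length(best)) names(best) else character(0),
                    similarity = as.numeric(best), stringsAsFactors = FALSE)
  out <- out[order(-out$similarity, out$term), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "oov") <- oov
  out
}
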
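#' Linear-chain CRF: exact log-partition function
#'
#' Computes `log sum_y exp(score(y))` over all label sequences by the forward
#' algorithm in log space, where
#' `score(y) = sum_t emissions[t, y_t] + trans[start, y_1] +
#' sum_t trans[y_(t-1), y_t] + trans[y_T, stop]`.
#'
#' @param emissions numeric matrix, positions x labels (T x L).
#' @param transitions numeric matrix (L+2) x (L+2); rows are from-states,
#'   columns to-states; row L+1 is the start state, column L+2 the stop
#'   state. `-Inf` entries are allowed (masked transitions); `NaN` is an
#'   error.
#' @return the log-partition value (scalar).
#' @examples
#' # one position, two labels, zero scores: log(2)
#' crf_log_partition(matrix(0, 1, 2), matrix(0, 4, 4))
#' @export
crf_log_partition <- function(emissions, transitions) {
  emissions <- as.matrix(emissions)
  transitions <- as.matrix(transitions)
  .crf_log_partition_cpp(emissions, transitions)
}

#' Viterbi decoding of a linear-chain CRF
#'
#' Returns the label sequence with the highest score under the same scoring
#' as [crf_log_partition()]. Ties are broken deterministically toward the
#' lowest label index at each backtracking step.
#'
#' @inheritParams crf_log_partition
#' @return list with `path` (integer labels, 1-based) and `score`.
#' @export
viterbi_decode <- function(emissions, transitions) {
  .crf_viterbi_cpp(as.matrix(emissions), as.matrix(transitions))
}

#' BIO legality mask for CRF decoding
#'
#' Builds a (L+2) x (L+2) matrix of 0 / `-Inf` added to the transition scores
#' at decode time: transitions into `I-x` are illegal unless they come from
#' `B-x` or `I-x` (so `O -> I-x`, `B-x -> I-y`, `I-x -> I-y` for `x != y`,
#' and `start -> I-x` are all masked).
#'
#' @param labels the BIO label vector, e.g. [bio_label_space()].
#' @return numeric matrix of 0 and `-Inf`.
#' @export
bio_transition_mask <- function(labels = bio_label_space()) {
  L <- length(labels)
  mask <- matrix(0, L + 2, L + 2)
  inside <- grepl("^I-", labels)
  itypes <- sub("^I-", "", labels)
  for (j in which(inside)) {
    ok_from <- which(labels %in% paste0(c("B-", "I-"), itypes[j]))
    mask[setdiff(seq_len(L + 2), ok_from), j] <- -Inf
  }
  mask
}

#' Decode entity spans from BIO tags
#'
#' Maximal `B-x (I-x)*` runs become one span of type `x`, using the first and
#' last token character offsets; an `I-x` without a preceding `B-x`/`I-x`
#' leniently opens a new span.
#'
#' @param tags character vector of BIO labels, one per token.
#' @param sentence one element of [tokenize()] output (same length).
#' @return data.frame with columns `start`, `end`, `type` (character offsets,
#'   0-based half-open).
#' @export
spans_from_bio <- function(tags, sentence) {
  stopifnot(length(tags) == length(sentence$tokens))
  known <- bio_label_space()
  bad <- setdiff(unique(tags), known)
  if (length(bad)) stop("unknown tag(s): ", paste(bad, collapse = ", "))
  out <- list()
  cur_type <- NA_character_; cur_start <- NA_integer_; cur_end <- NA_integer_
  flush <- function() {
    if (!is.na(cur_type))
      out[[length(out) + 1L]] <<- data.frame(
        start = cur_start, end = cur_end, type = cur_type,
        stringsAsFactors = FALSE)
  }
  for (t in seq_along(tags)) {
    tg <- tags[t]
    if (tg == "O") { flush(); cur_type <- NA_character_; next }
    pre <- substr(tg, 1, 1); ty <- substr(tg, 3, nchar(tg))
    if (pre == "B" || is.na(cur_type) || ty != cur_type) {
      flush()
      cur_type <- ty
      cur_start <- sentence$start[t]
    }
    cur_end <- sentence$end[t]
  }
  flush()
  if (length(out)) do.call(rbind, out) else
    data.frame(start = integer(0), end = integer(0), type = character(0),
               stringsAsFactors = FALSE)
}

#' Encode gold entity spans of a sentence as BIO tags
#'
#' @param sentence one element of [tokenize()] output.
#' @param entities entity data.frame (`start`, `end`, `type`).
#' @return character vector of BIO labels, one per token.
#' @export
bio_from_spans <- function(sentence, entities) {
  tags <- rep("O", length(sentence$tokens))
  if (!nrow(entities)) return(tags)
  ents <- entities[order(entities$start), , drop = FALSE]
  for (i in seq_len(nrow(ents))) {
    hit <- which(sentence$start < ents$end[i] & sentence$end > ents$start[i])
    if (!length(hit)) next
    tags[hit] <- paste0("I-", ents$type[i])
    tags[hit[1]] <- paste0("B-", ents$type[i])
  }
  tags
}
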
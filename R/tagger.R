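#' @useDynLib ggonlp, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

.norm_token <- function(tok) {
  tok <- tolower(tok)
  tok[grepl("^[0-9]+(\\.[0-9]+)?$", tok)] <- "<num>"
  tok
}

.encode_sentence <- function(tokens, vocab) {
  ids <- match(.norm_token(tokens), vocab)
  ids[is.na(ids)] <- 1L   # <unk>
  ids
}

# Convert annotated notes into model sentences: word ids + BIO tag ids.
.notes_to_sentences <- function(notes, vocab, labels) {
  words <- list(); tags <- list(); meta <- list()
  for (ni in seq_along(notes)) {
    note <- notes[[ni]]
    for (s in tokenize(note$text)) {
      words[[length(words) + 1L]] <- .encode_sentence(s$tokens, vocab)
      bio <- bio_from_spans(s, note$entities)
      tags[[length(tags) + 1L]] <- match(bio, labels)
      meta[[length(meta) + 1L]] <- c(ni, s$sentence_index)
    }
  }
  list(words = words, tags = tags, meta = meta)
}

.init_params <- function(vocab_size, emb_dim, hidden, n_labels) {
  rmat <- function(r, c, sd) matrix(stats::rnorm(r * c, 0, sd), r, c)
  list(emb = rmat(vocab_size, emb_dim, 0.1),
       Wf = rmat(4 * hidden, emb_dim, 0.1),
       Uf = rmat(4 * hidden, hidden, 0.1),
       bf = matrix(0, 4 * hidden, 1),
       Wb = rmat(4 * hidden, emb_dim, 0.1),
       Ub = rmat(4 * hidden, hidden, 0.1),
       bb = matrix(0, 4 * hidden, 1),
       Wo = rmat(n_labels, 2 * hidden, 0.1),
       bo = matrix(0, n_labels, 1),
       trans = matrix(0, n_labels + 2, n_labels + 2))
}

.zeros_like <- function(params) lapply(params, function(p) p * 0)

#' Fit the Bi-LSTM-CRF entity tagger
#'
#' The sequence-labeling core of the pipeline: word embeddings feed a
#' bidirectional LSTM whose per-token outputs are mapped linearly to emission
#' scores over the 31-label BIO space; a linear-chain CRF output layer is
#' trained by exact negative log-likelihood (forward algorithm) with Adam.
#' Notes are split 80/20 into training and validation sets by a seeded
#' shuffle (by note, or by patient when `split = "patient"`); after every
#' epoch the held-out macro-F1 (exact span + type match) is recorded and the
#' best-validation checkpoint is kept, with early stopping.
#'
#' @param corpus list of annotated notes ([annotated_note()]) with gold
#'   entities; at least 5 notes.
#' @param embedding_dim,hidden_dim word-embedding and per-direction LSTM
#'   sizes.
#' @param epochs maximum training epochs.
#' @param lr,batch_size Adam learning rate and minibatch size (sentences).
#' @param patience early-stopping patience (epochs without validation
#'   macro-F1 improvement).
#' @param val_fraction held-out fraction (default 0.2).
#' @param split `"note"` (default) or `"patient"`.
#' @param seed integer seed controlling the split, initialization and
#'   shuffling; training is reproducible bit-for-bit under a fixed seed.
#' @param verbose print per-epoch progress.
#' @return an object of class `ggo_tagger` with elements `params` (best
#'   checkpoint), `vocab`, `labels`, `history` (per-epoch loss and validation
#'   micro/macro F1), `best_epoch` and the configuration.
#' @export
ggo_tagger <- function(corpus, embedding_dim = 24, hidden_dim = 24,
                       epochs = 20, lr = 1e-3, batch_size = 16, patience = 5,
                       val_fraction = 0.2, split = c("note", "patient"),
                       seed = 1L, verbose = FALSE) {
  split <- match.arg(split)
  if (length(corpus) < 5)
    stop("corpus must contain at least 5 notes for an 80/20 split")
  if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old, envir = .GlobalEnv))
  }
  set.seed(seed)

  n <- length(corpus)
  if (split == "note") {
    idx <- sample(n)
    n_val <- max(1L, floor(val_fraction * n))
    val_idx <- idx[seq_len(n_val)]
  } else {
    pids <- vapply(corpus, `[[`, character(1), "patient_id")
    up <- sample(unique(pids))
    n_valp <- max(1L, floor(val_fraction * length(up)))
    val_idx <- which(pids %in% up[seq_len(n_valp)])
  }
  train_idx <- setdiff(seq_len(n), val_idx)
  train_notes <- corpus[train_idx]; val_notes <- corpus[val_idx]

  toks <- unlist(lapply(train_notes, function(nt)
    .norm_token(unlist(lapply(tokenize(nt$text), `[[`, "tokens")))))
  vocab <- c("<unk>", sort(unique(toks)))
  labels <- bio_label_space()

  tr <- .notes_to_sentences(train_notes, vocab, labels)
  params <- .init_params(length(vocab), embedding_dim, hidden_dim,
                         length(labels))
  m <- .zeros_like(params); v <- .zeros_like(params)
  mask <- bio_transition_mask(labels)

  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        val_micro_f1 = numeric(0), val_macro_f1 = numeric(0))
  best <- list(macro = -Inf, params = params, epoch = 0L)
  stall <- 0L; step <- 0L
  for (ep in seq_len(epochs)) {
    ord <- sample(length(tr$words))
    res <- .bilstm_train_epoch_cpp(params, m, v, tr$words, tr$tags, ord,
                                   lr, 0.9, 0.999, 1e-8, batch_size, step)
    params <- res$params; m <- res$m; v <- res$v; step <- res$step
    model_now <- structure(list(params = params, vocab = vocab,
                                labels = labels, mask = mask),
                           class = "ggo_tagger")
    pred <- lapply(val_notes, function(nt) {
      p <- nt
      p$entities <- predict_entities(model_now, nt$text)
      p$relations <- empty_relations()
      p
    })
    sc <- score(pred, val_notes, mode = "exact")
    mic <- sc$f1[sc$semantic_type == "micro"]
    mac <- sc$f1[sc$semantic_type == "macro"]
    history <- rbind(history, data.frame(epoch = ep, loss = res$loss,
                                         val_micro_f1 = mic,
                                         val_macro_f1 = mac))
    if (verbose)
      message(sprintf("epoch %d: loss %.4f, val micro-F1 %.3f, macro-F1 %.3f",
                      ep, res$loss, mic, mac))
    if (mac > best$macro + 1e-9) {
      best <- list(macro = mac, params = params, epoch = ep)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= patience) break
    }
  }

  structure(list(params = best$params, vocab = vocab, labels = labels,
                 mask = mask, history = history, best_epoch = best$epoch,
                 val_macro_f1 = best$macro,
                 config = list(embedding_dim = embedding_dim,
                               hidden_dim = hidden_dim, epochs = epochs,
                               lr = lr, batch_size = batch_size,
                               patience = patience, seed = seed,
                               split = split, val_fraction = val_fraction),
                 n_train = length(train_idx), n_val = length(val_idx)),
            class = "ggo_tagger")
}

#' Predict entity spans in note text
#'
#' Tokenizes, runs the Bi-LSTM emissions and Viterbi decoding under the BIO
#' legality mask, and converts the tag sequence to character-offset entity
#' spans. Deterministic for fixed weights.
#'
#' @param model a fitted [ggo_tagger()].
#' @param text note text (a single string; empty text gives zero spans).
#' @return data.frame with `start`, `end`, `type`, `surface`.
#' @export
predict_entities <- function(model, text) {
  stopifnot(inherits(model, "ggo_tagger"))
  sents <- tokenize(text)
  out <- list()
  trans <- model$params$trans + model$mask
  for (s in sents) {
    ids <- .encode_sentence(s$tokens, model$vocab)
    em <- .bilstm_emissions_cpp(model$params, ids)
    dec <- .crf_viterbi_cpp(em, trans)
    sp <- spans_from_bio(model$labels[dec$path], s)
    if (nrow(sp)) out[[length(out) + 1L]] <- sp
  }
  if (!length(out))
    return(empty_entities())
  sp <- do.call(rbind, out)
  sp$surface <- substring(text, sp$start + 1L, sp$end)
  sp
}

#' Link attribute entities to their nearest GGO anchor
#'
#' Deterministic rule-based relation extraction: each attribute entity links
#' to the nearest GGO-term entity (pure or part-solid) within the same
#' sentence by character distance; ties go to the preceding anchor.
#' Attribute entities with no same-sentence anchor stay unlinked; temporal
#' entities take no relation (dates attach at the note level). All emitted
#' relations satisfy [validate_relation()].
#'
#' @param entities entity data.frame (`start`, `end`, `type`).
#' @param text the note text (used for sentence boundaries), or a
#'   pre-computed [tokenize()] result.
#' @return relation data.frame (`head`, `tail`, `type`, 1-based indices into
#'   `entities`).
#' @export
link_relations <- function(entities, text) {
  if (!nrow(entities)) return(empty_relations())
  sents <- if (is.character(text)) tokenize(text) else text
  bounds <- t(vapply(sents, function(s) c(min(s$start), max(s$end)),
                     numeric(2)))
  sent_of <- function(pos) {
    i <- which(bounds[, 1] <= pos & pos < bounds[, 2])
    if (length(i)) i[1] else NA_integer_
  }
  esent <- vapply(entities$start, sent_of, integer(1))
  anchors <- which(entities$type %in% .ggo_anchor_types())
  rels <- empty_relations()
  for (i in seq_len(nrow(entities))) {
    rt <- .relation_for_tail(entities$type[i])
    if (is.na(rt) || i %in% anchors) next
    cand <- anchors[esent[anchors] == esent[i] & !is.na(esent[i])]
    if (!length(cand)) next
    gap <- function(a) {
      if (entities$end[a] <= entities$start[i])
        entities$start[i] - entities$end[a]
      else if (entities$end[i] <= entities$start[a])
        entities$start[a] - entities$end[i]
      else 0L
    }
    d <- vapply(cand, gap, numeric(1))
    bestd <- min(d)
    tied <- cand[d == bestd]
    pick <- if (length(tied) > 1) {
      prec <- tied[entities$start[tied] <= entities$start[i]]
      if (length(prec)) prec[length(prec)] else tied[1]
    } else tied
    rels <- rbind(rels, data.frame(head = pick, tail = i, type = rt,
                                   stringsAsFactors = FALSE))
  }
  rels
}

#' Annotate notes with a fitted tagger
#'
#' @param object a `ggo_tagger`.
#' @param notes a list of notes (or a single `ggo_note`); their entities and
#'   relations are replaced by predictions.
#' @param ... unused.
#' @return list of annotated notes with predicted entities and rule-linked
#'   relations.
#' @export
predict.ggo_tagger <- function(object, notes, ...) {
  single <- inherits(notes, "ggo_note")
  if (single) notes <- list(notes)
  out <- lapply(notes, function(nt) {
    nt$entities <- predict_entities(object, nt$text)
    nt$relations <- link_relations(nt$entities, nt$text)
    nt
  })
  if (single) out[[1]] else out
}

#' @export
print.ggo_tagger <- function(x, ...) {
  cat("Bi-LSTM-CRF GGO entity tagger\n")
  cat(sprintf("  vocabulary: %d tokens; labels: %d; emb %d, hidden %d\n",
              length(x$vocab), length(x$labels),
              x$config$embedding_dim, x$config$hidden_dim))
  cat(sprintf("  trained on %d notes, validated on %d (split by %s, seed %d)\n",
              x$n_train, x$n_val, x$config$split, x$config$seed))
  cat(sprintf("  best validation macro-F1 %.3f at epoch %d\n",
              x$val_macro_f1, x$best_epoch))
  invisible(x)
}

#' @export
summary.ggo_tagger <- function(object, ...) {
  print(object)
  cat("\nTraining history:\n")
  print(object$history, row.names = FALSE)
  invisible(object$history)
}

#' @export
coef.ggo_tagger <- function(object, ...) {
  tr <- object$params$trans
  L <- length(object$labels)
  dimnames(tr) <- list(c(object$labels, "<start>", "<stop>"),
                       c(object$labels, "<start>", "<stop>"))
  tr[seq_len(L + 2), seq_len(L + 2)]
}

#' @export
plot.ggo_tagger <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  plot(h$epoch, h$loss, type = "b", xlab = "epoch",
       ylab = "mean sentence NLL", main = "CRF training loss", ...)
  plot(h$epoch, h$val_macro_f1, type = "b", xlab = "epoch", ylim = c(0, 1),
       ylab = "F1", main = "validation F1", ...)
  graphics::lines(h$epoch, h$val_micro_f1, type = "b", lty = 2)
  graphics::legend("bottomright", legend = c("macro", "micro"),
                   lty = c(1, 2), bty = "n")
  invisible(h)
}
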
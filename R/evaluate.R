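#' Round half away from zero (display rounding)
#'
#' Base `round()` rounds half to even; metric tables here display half-up
#' values (0.975 -> 0.98).
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Precision, recall and F1 from count triples
#'
#' The bookkeeping used to score the pipeline: `right` is the number of
#' entities the pipeline extracted that are correct according to the gold
#' standard (true positives), `predict` the number it extracted, `gold` the
#' number annotated. Precision = right/predict (0 when predict = 0), recall =
#' right/gold (0 when gold = 0), and F1 the harmonic mean
#' 2PR/(P+R) (0 when P + R = 0), always computed from the unrounded
#' precision and recall.
#'
#' @param right,predict,gold non-negative integer vectors (recycled).
#' @param semantic_type optional row labels.
#' @return data.frame with columns `semantic_type`, `right`, `predict`,
#'   `gold`, `precision`, `recall`, `f1` (unrounded).
#' @examples
#' metrics_from_counts(510, 535, 572)   # precision .95, recall .89, F1 .92
#' @export
metrics_from_counts <- function(right, predict, gold,
                                semantic_type = NA_character_) {
  if (any(right > predict) || any(right > gold))
    stop("right must not exceed predict or gold")
  precision <- ifelse(predict == 0, 0, right / predict)
  recall <- ifelse(gold == 0, 0, right / gold)
  f1 <- ifelse(precision + recall == 0, 0,
               2 * precision * recall / (precision + recall))
  data.frame(semantic_type = semantic_type, right = right, predict = predict,
             gold = gold, precision = precision, recall = recall, f1 = f1,
             stringsAsFactors = FALSE)
}

#' Match predicted against gold entity spans
#'
#' Greedy one-to-one matching in document order: predictions are visited by
#' increasing span start, and each takes the first unmatched gold entity of
#' the same type with an identical span (`mode = "exact"`) or any span
#' intersection (`mode = "overlap"`).
#'
#' @param pred,gold entity data.frames with `start`, `end`, `type`.
#' @param mode matching criterion.
#' @return data.frame of matched pairs (`pred_idx`, `gold_idx`, row indices
#'   into the inputs).
#' @export
match_entities <- function(pred, gold, mode = c("exact", "overlap")) {
  mode <- match.arg(mode)
  if (!nrow(pred) || !nrow(gold))
    return(data.frame(pred_idx = integer(0), gold_idx = integer(0)))
  po <- order(pred$start, pred$end)
  go <- order(gold$start, gold$end)
  taken <- rep(FALSE, nrow(gold))
  pairs <- list()
  for (pi in po) {
    for (gi in go) {
      if (taken[gi] || gold$type[gi] != pred$type[pi]) next
      hit <- if (mode == "exact")
        gold$start[gi] == pred$start[pi] && gold$end[gi] == pred$end[pi]
      else
        gold$start[gi] < pred$end[pi] && pred$start[pi] < gold$end[gi]
      if (hit) {
        taken[gi] <- TRUE
        pairs[[length(pairs) + 1L]] <- c(pi, gi)
        break
      }
    }
  }
  if (!length(pairs))
    return(data.frame(pred_idx = integer(0), gold_idx = integer(0)))
  m <- do.call(rbind, pairs)
  data.frame(pred_idx = m[, 1], gold_idx = m[, 2])
}

#' Score predicted annotations against a gold standard
#'
#' Pools right/predict/gold counts per entity semantic type over all notes
#' (note ids must align between the two corpora) and appends `micro` (pooled
#' counts) and `macro` (unweighted mean of per-type precision/recall/F1 over
#' types occurring in gold or predictions) aggregate rows.
#'
#' @param pred_notes,gold_notes lists of annotated notes with matching
#'   `note_id`s.
#' @param mode matching criterion, see [match_entities()].
#' @return a `ggo_metrics` data.frame, one row per semantic type plus the
#'   aggregates; print method displays values rounded half-up to 2 decimals.
#' @export
score <- function(pred_notes, gold_notes, mode = c("exact", "overlap")) {
  mode <- match.arg(mode)
  pid <- vapply(pred_notes, `[[`, character(1), "note_id")
  gid <- vapply(gold_notes, `[[`, character(1), "note_id")
  if (!identical(sort(pid), sort(gid)))
    stop("note ids do not align between predictions and gold standard")
  gold_notes <- gold_notes[match(pid, gid)]

  types <- ggo_entity_types()
  right <- predict <- gold <- stats::setNames(integer(length(types)), types)
  for (i in seq_along(pred_notes)) {
    pe <- pred_notes[[i]]$entities
    ge <- gold_notes[[i]]$entities
    mt <- match_entities(pe, ge, mode)
    predict <- predict + table(factor(pe$type, levels = types))
    gold <- gold + table(factor(ge$type, levels = types))
    if (nrow(mt))
      right <- right + table(factor(pe$type[mt$pred_idx], levels = types))
  }
  present <- predict > 0 | gold > 0
  rows <- metrics_from_counts(as.integer(right[present]),
                              as.integer(predict[present]),
                              as.integer(gold[present]),
                              semantic_type = types[present])
  micro <- metrics_from_counts(sum(right), sum(predict), sum(gold), "micro")
  macro <- data.frame(semantic_type = "macro", right = NA_integer_,
                      predict = NA_integer_, gold = NA_integer_,
                      precision = if (any(present)) mean(rows$precision) else 0,
                      recall = if (any(present)) mean(rows$recall) else 0,
                      f1 = if (any(present)) mean(rows$f1) else 0,
                      stringsAsFactors = FALSE)
  out <- rbind(rows, micro, macro)
  rownames(out) <- NULL
  class(out) <- c("ggo_metrics", "data.frame")
  out
}

#' @export
print.ggo_metrics <- function(x, ...) {
  y <- as.data.frame(x)
  y$precision <- round_half_up(y$precision, 2)
  y$recall <- round_half_up(y$recall, 2)
  y$f1 <- round_half_up(y$f1, 2)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Write a metrics table as CSV
#'
#' @param metrics a `ggo_metrics` data.frame.
#' @param path output file.
#' @export
write_metrics_csv <- function(metrics, path) {
  utils::write.csv(as.data.frame(metrics), path, row.names = FALSE)
  invisible(path)
}
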
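#' Construct and validate an annotated radiology note
#'
#' The unit record of the pipeline: note text plus metadata, entity spans and
#' relations. Character offsets are 0-based half-open over Unicode code
#' points; the stored `surface` of every entity must equal the slice of the
#' text at its offsets, and every relation must reference existing entities
#' and satisfy [validate_relation()].
#'
#' @param note_id,patient_id character scalars.
#' @param note_date a `Date` (or string coercible to one).
#' @param text note text.
#' @param entities data.frame with columns `start`, `end` (integer, 0-based
#'   half-open), `type` (entity type name), `surface`.
#' @param relations data.frame with columns `head`, `tail` (1-based row
#'   indices into `entities`) and `type` (relation type name).
#' @param validate check the invariants (default `TRUE`).
#' @return an object of class `ggo_note`.
#' @export
annotated_note <- function(note_id, patient_id = NA_character_,
                           note_date = as.Date(NA), text = "",
                           entities = empty_entities(),
                           relations = empty_relations(),
                           validate = TRUE) {
  note <- structure(
    list(note_id = as.character(note_id),
         patient_id = as.character(patient_id),
         note_date = as.Date(note_date),
         text = text,
         entities = as.data.frame(entities),
         relations = as.data.frame(relations)),
    class = "ggo_note")
  if (validate) validate_note(note)
  note
}

#' @rdname annotated_note
#' @export
empty_entities <- function() {
  data.frame(start = integer(0), end = integer(0),
             type = character(0), surface = character(0),
             stringsAsFactors = FALSE)
}

#' @rdname annotated_note
#' @export
empty_relations <- function() {
  data.frame(head = integer(0), tail = integer(0), type = character(0),
             stringsAsFactors = FALSE)
}

#' @rdname annotated_note
#' @param note a `ggo_note`.
#' @export
validate_note <- function(note) {
  e <- note$entities
  n <- nchar(note$text)
  if (nrow(e)) {
    if (any(e$start < 0L) || any(e$end > n) || any(e$start >= e$end))
      stop("note ", note$note_id,
           ": entity offsets must satisfy 0 <= start < end <= nchar(text)")
    sl <- substring(note$text, e$start + 1L, e$end)
    bad <- which(sl != e$surface)
    if (length(bad))
      stop("note ", note$note_id, ": entity ", bad[1],
           " surface does not match text slice ('", e$surface[bad[1]],
           "' vs '", sl[bad[1]], "')")
    unknown <- setdiff(unique(e$type), ggo_entity_types())
    if (length(unknown))
      stop("note ", note$note_id, ": unknown entity type(s): ",
           paste(unknown, collapse = ", "))
  }
  r <- note$relations
  if (nrow(r)) {
    if (any(r$head < 1L | r$head > nrow(e) | r$tail < 1L | r$tail > nrow(e)))
      stop("note ", note$note_id, ": relation references a missing entity")
    ok <- mapply(function(h, t, ty) validate_relation(e$type[h], e$type[t], ty),
                 r$head, r$tail, r$type)
    if (!all(ok))
      stop("note ", note$note_id, ": relation ", which(!ok)[1],
           " violates the schema")
  }
  invisible(note)
}

#' @export
print.ggo_note <- function(x, ...) {
  cat("<ggo_note ", x$note_id, "> patient ", x$patient_id, ", ",
      format(x$note_date), ", ", nchar(x$text), " chars, ",
      nrow(x$entities), " entities, ", nrow(x$relations), " relations\n",
      sep = "")
  invisible(x)
}

# ---- BRAT standoff ---------------------------------------------------------

#' Read and write BRAT standoff annotation files
#'
#' `write_brat()` writes a note as a `.txt`/`.ann` pair under `out_dir`,
#' with sequential entity ids `T1, T2, ...`, relation records
#' `R<i> <type> Arg1:T<head> Arg2:T<tail>` and note metadata (patient id,
#' note date) as a `#1 NoteMeta` comment line. `read_brat()` parses the pair
#' back; the two are inverse on valid notes. Unknown entity or relation
#' labels, out-of-range offsets and dangling `T` references are errors, never
#' silently repaired.
#'
#' @param txt_path,ann_path paths to the standoff pair.
#' @param note a `ggo_note`.
#' @param out_dir output directory (created if missing).
#' @return `read_brat()` returns a `ggo_note`; `write_brat()` returns
#'   `c(txt_path, ann_path)` invisibly.
#' @export
read_brat <- function(txt_path, ann_path) {
  if (!file.exists(txt_path)) stop("missing text file: ", txt_path)
  if (!file.exists(ann_path)) stop("missing annotation file: ", ann_path)
  text <- paste(readLines(txt_path, warn = FALSE, encoding = "UTF-8"),
                collapse = "\n")
  lines <- readLines(ann_path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  note_id <- sub("\\.txt$", "", basename(txt_path))
  patient_id <- NA_character_; note_date <- as.Date(NA)

  ents <- empty_entities(); tids <- character(0)
  rels <- empty_relations()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    tag <- substr(f[1], 1, 1)
    if (tag == "T") {
      if (length(f) < 3) stop("malformed T line: ", ln)
      hdr <- strsplit(f[2], " ", fixed = TRUE)[[1]]
      if (length(hdr) != 3) stop("malformed T header: ", ln)
      type <- hdr[1]
      if (!type %in% ggo_entity_types())
        stop("unknown entity label '", type, "' in line: ", ln)
      start <- as.integer(hdr[2]); end <- as.integer(hdr[3])
      if (is.na(start) || is.na(end) || start < 0 || end > nchar(text) ||
          start >= end)
        stop("offset outside text in line: ", ln)
      ents <- rbind(ents, data.frame(start = start, end = end, type = type,
                                     surface = f[3],
                                     stringsAsFactors = FALSE))
      tids <- c(tids, f[1])
    } else if (tag == "R") {
      if (length(f) < 2) stop("malformed R line: ", ln)
      hdr <- strsplit(f[2], " ", fixed = TRUE)[[1]]
      if (length(hdr) != 3) stop("malformed R header: ", ln)
      type <- hdr[1]
      if (!type %in% ggo_relation_types())
        stop("unknown relation label '", type, "' in line: ", ln)
      h <- sub("^Arg1:", "", hdr[2]); t <- sub("^Arg2:", "", hdr[3])
      hi <- match(h, tids); ti <- match(t, tids)
      if (is.na(hi) || is.na(ti))
        stop("relation references unknown entity id in line: ", ln)
      rels <- rbind(rels, data.frame(head = hi, tail = ti, type = type,
                                     stringsAsFactors = FALSE))
    } else if (tag == "#") {
      if (length(f) >= 3 && grepl("^NoteMeta", f[2])) {
        kv <- strsplit(strsplit(f[3], ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
        for (p in kv) {
          if (p[1] == "patient_id") patient_id <- p[2]
          if (p[1] == "note_date" && nzchar(p[2]) && p[2] != "NA")
            note_date <- as.Date(p[2])
        }
      }
    } else {
      stop("unsupported standoff record: ", ln)
    }
  }
  annotated_note(note_id, patient_id, note_date, text, ents, rels)
}

#' @rdname read_brat
#' @export
write_brat <- function(note, out_dir) {
  stopifnot(inherits(note, "ggo_note"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  txt_path <- file.path(out_dir, paste0(note$note_id, ".txt"))
  ann_path <- file.path(out_dir, paste0(note$note_id, ".ann"))
  writeLines(note$text, txt_path, useBytes = TRUE)
  e <- note$entities; r <- note$relations
  lines <- character(0)
  if (nrow(e))
    lines <- sprintf("T%d\t%s %d %d\t%s", seq_len(nrow(e)),
                     e$type, e$start, e$end, e$surface)
  if (nrow(r))
    lines <- c(lines, sprintf("R%d\t%s Arg1:T%d Arg2:T%d",
                              seq_len(nrow(r)), r$type, r$head, r$tail))
  lines <- c(lines, sprintf("#1\tNoteMeta\tpatient_id=%s;note_date=%s",
                            note$patient_id, format(note$note_date)))
  writeLines(lines, ann_path, useBytes = TRUE)
  invisible(c(txt_path, ann_path))
}

# ---- JSONL -----------------------------------------------------------------

#' Read and write note corpora as JSON lines
#'
#' One JSON object per line with fields `note_id`, `patient_id`, `note_date`
#' (ISO-8601), `text`, `entities` and `relations`. Round-trips losslessly
#' with [annotated_note()] objects.
#'
#' @param notes a list of `ggo_note` objects.
#' @param path file path.
#' @return `read_notes_jsonl()` returns a list of `ggo_note`;
#'   `write_notes_jsonl()` returns `path` invisibly.
#' @export
write_notes_jsonl <- function(notes, path) {
  lines <- vapply(notes, function(n) {
    jsonlite::toJSON(list(
      note_id = n$note_id, patient_id = n$patient_id,
      note_date = if (is.na(n$note_date)) NULL else format(n$note_date),
      text = n$text,
      entities = n$entities, relations = n$relations),
      auto_unbox = TRUE, dataframe = "rows", null = "null", digits = NA)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_notes_jsonl
#' @export
read_notes_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  lapply(seq_along(lines), function(i) {
    x <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
                  error = function(e)
                    stop("malformed JSON on line ", i, ": ",
                         conditionMessage(e)))
    ents <- if (is.null(x$entities) || !length(x$entities)) empty_entities()
            else as.data.frame(x$entities)
    rels <- if (is.null(x$relations) || !length(x$relations)) empty_relations()
            else as.data.frame(x$relations)
    annotated_note(x$note_id,
                   if (is.null(x$patient_id)) NA_character_ else x$patient_id,
                   if (is.null(x$note_date)) as.Date(NA)
                   else as.Date(x$note_date),
                   x$text, ents, rels)
  })
}

#' Write a whole corpus as BRAT standoff pairs
#'
#' @param notes list of `ggo_note`.
#' @param out_dir output directory.
#' @return invisibly, a character matrix of written paths.
#' @export
write_brat_corpus <- function(notes, out_dir) {
  invisible(t(vapply(notes, write_brat, character(2), out_dir = out_dir)))
}

#' @rdname write_brat_corpus
#' @export
read_brat_corpus <- function(dir) {
  txts <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  lapply(txts, function(p) read_brat(p, sub("\\.txt$", ".ann", p)))
}
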
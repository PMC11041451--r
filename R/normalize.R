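#' Normalize a size surface form to millimetres
#'
#' Accepts "3 mm", "1.2 cm", "3mm", spelled-out units, decimal commas, and
#' two-dimensional measurements ("8 x 5 mm"), for which the larger dimension
#' is returned. Centimetre values are converted to millimetres.
#'
#' @param surface character scalar.
#' @return size in millimetres, or `NA_real_` when no number and unit parse
#'   (the finding then keeps its raw surface and leaves `size_mm` unset).
#' @examples
#' normalize_size("1.2 cm")    # 12
#' normalize_size("8 x 5 mm")  # 8
#' @export
normalize_size <- function(surface) {
  s <- tolower(surface)
  s <- gsub("(?<=[0-9]),(?=[0-9])", ".", s, perl = TRUE)
  m <- gregexpr("[0-9]+(\\.[0-9]+)?", s)[[1]]
  if (m[1] == -1L) return(NA_real_)
  vals <- as.numeric(regmatches(s, list(m))[[1]])
  unit <- if (grepl("cm|centimet", s)) "cm"
          else if (grepl("mm|millimet", s)) "mm"
          else return(NA_real_)
  v <- max(vals)
  if (unit == "cm") v * 10 else v
}

#' Clinical size bins for GGO nodules
#'
#' Three groups: `lt6` (< 6 mm), `6to20` (6 to 20 mm, both boundaries
#' included) and `gt20` (> 20 mm), following nonsolid-nodule management
#' practice.
#'
#' @param size_mm positive size in millimetres.
#' @return one of `"lt6"`, `"6to20"`, `"gt20"` (NA in, NA out).
#' @export
bin_size <- function(size_mm) {
  if (length(size_mm) != 1) return(vapply(size_mm, bin_size, character(1)))
  if (is.na(size_mm)) return(NA_character_)
  if (size_mm <= 0) stop("size_mm must be positive")
  if (size_mm < 6) "lt6" else if (size_mm <= 20) "6to20" else "gt20"
}

.lobe_lexicon <- function() {
  list(RUL = c("right upper lobe", "rul"),
       RML = c("right middle lobe", "rml"),
       RLL = c("right lower lobe", "rll"),
       LUL = c("left upper lobe", "lul"),
       LLL = c("left lower lobe", "lll"))
}

#' Normalize a location surface form to (laterality, lobe)
#'
#' Two-level location normalization: the first level is right / left /
#' bilateral, the second the anatomic lobe (RUL, RML, RLL, LUL, LLL).
#' Keyword and abbreviation matching; "lingula" maps to the left lung with
#' unknown lobe; unmatched surfaces give (unknown, unknown).
#'
#' @param surface character scalar.
#' @return named character vector `c(laterality=, lobe=)`.
#' @examples
#' normalize_location("right upper lobe")  # right, RUL
#' @export
normalize_location <- function(surface) {
  s <- tolower(surface)
  for (lobe in names(.lobe_lexicon())) {
    pats <- .lobe_lexicon()[[lobe]]
    hit <- any(vapply(pats, function(p)
      grepl(paste0("\\b", p, "\\b"), s), logical(1)))
    if (hit) {
      lat <- if (substr(lobe, 1, 1) == "R") "right" else "left"
      return(c(laterality = lat, lobe = lobe))
    }
  }
  if (grepl("\\bboth\\b|bilateral", s))
    return(c(laterality = "bilateral", lobe = "unknown"))
  if (grepl("\\blingula", s))
    return(c(laterality = "left", lobe = "unknown"))
  if (grepl("\\bright\\b", s))
    return(c(laterality = "right", lobe = "unknown"))
  if (grepl("\\bleft\\b", s))
    return(c(laterality = "left", lobe = "unknown"))
  c(laterality = "unknown", lobe = "unknown")
}

#' Triage a potential-etiology entity into three subgroups
#'
#' `cause_infectious_inflammatory` maps to infectious/inflammatory,
#' `cause_neoplasm` to malignant, and `cause_hemorrhage` /
#' `cause_other_pulmonary` (benign pulmonary lesions such as
#' fibrosis/scarring and hemorrhage) to other — except that precancerous
#' conditions (atypical adenomatous hyperplasia, adenocarcinoma in situ) are
#' malignant regardless of the entity subtype.
#'
#' @param entity_type one of the four `cause_*` entity types.
#' @param surface the entity surface form.
#' @return `"infectious_inflammatory"`, `"malignant"` or `"other"`.
#' @export
normalize_etiology <- function(entity_type, surface = "") {
  if (!entity_type %in% c("cause_neoplasm", "cause_infectious_inflammatory",
                          "cause_hemorrhage", "cause_other_pulmonary"))
    stop("not a cause entity type: ", entity_type)
  s <- tolower(surface)
  if (grepl("atypical adenomatous hyperplasia|adenocarcinoma in situ", s))
    return("malignant")
  switch(entity_type,
         cause_infectious_inflammatory = "infectious_inflammatory",
         cause_neoplasm = "malignant",
         "other")
}

#' Normalize a quantity surface form
#'
#' Concept values (numerous, scattered, several, multiple) and integers >= 2
#' map to `multiple`; "a", "single", "solitary", "one" and the integer 1 map
#' to `single`.
#'
#' @param surface character scalar.
#' @return list with `quantity` ("single"/"multiple"/NA) and `count`
#'   (integer or NA).
#' @export
normalize_quantity <- function(surface) {
  s <- tolower(surface)
  n <- suppressWarnings(as.integer(gsub("[^0-9]", "", s)))
  if (!is.na(n) && nzchar(gsub("[^0-9]", "", s))) {
    return(list(quantity = if (n >= 2) "multiple" else "single", count = n))
  }
  if (grepl("numerous|scattered|several|multiple|many|innumerable", s))
    return(list(quantity = "multiple", count = NA_integer_))
  if (grepl("\\bsingle\\b|solitary|\\bone\\b|^an?$", s))
    return(list(quantity = "single", count = 1L))
  list(quantity = NA_character_, count = NA_integer_)
}

.resolution_lexicon <- function()
  c("resolved", "no longer seen", "no longer visualized", "resolution")

#' Normalize a status entity to better / stable / worsen / resolved
#'
#' `resolved` is a terminal status distinct from `better`: it is assigned
#' when a `status_better` span matches a resolution surface form
#' ("resolved", "no longer seen", ...).
#'
#' @param entity_type `status_better`, `status_stable` or `status_worsen`.
#' @param surface the span surface.
#' @return one of `"better"`, `"stable"`, `"worsen"`, `"resolved"`.
#' @export
normalize_status <- function(entity_type, surface = "") {
  if (!entity_type %in% c("status_better", "status_stable", "status_worsen"))
    stop("not a status entity type: ", entity_type)
  base <- sub("^status_", "", entity_type)
  if (base == "better" &&
      any(vapply(.resolution_lexicon(), grepl, logical(1),
                 x = tolower(surface), fixed = TRUE)))
    return("resolved")
  base
}

#' Normalize a temporal surface form to a calendar date
#'
#' Supports ISO (2019-03-02), US numeric (3/2/2019, 3/2/19) and written
#' ("March 2, 2019") dates. Two-digit years resolve to the century nearest
#' the note date. Relative expressions are unsupported and give `NA` with a
#' warning.
#'
#' @param surface character scalar.
#' @param note_date the note's date (anchor for two-digit years).
#' @return a `Date`, or `NA` with a warning when unparseable.
#' @export
normalize_temporal <- function(surface, note_date = Sys.Date()) {
  s <- trimws(surface)
  if (grepl("^\\d{4}-\\d{1,2}-\\d{1,2}$", s))
    return(as.Date(s))
  m <- regmatches(s, regexec("^(\\d{1,2})/(\\d{1,2})/(\\d{2,4})$", s))[[1]]
  if (length(m) == 4) {
    mo <- as.integer(m[2]); dy <- as.integer(m[3]); yr <- as.integer(m[4])
    if (nchar(m[4]) <= 2) {
      cand <- c(1900L, 2000L) + yr
      ref <- as.integer(format(note_date, "%Y"))
      yr <- cand[which.min(abs(cand - ref))]
    }
    return(as.Date(sprintf("%04d-%02d-%02d", yr, mo, dy)))
  }
  d <- as.Date(s, format = "%B %d, %Y")
  if (!is.na(d)) return(d)
  warning("unparseable date surface: '", surface, "'")
  as.Date(NA)
}

#' Assemble normalized GGO findings from an annotated note
#'
#' One finding per GGO-term entity (pure or part-solid), sorted by span
#' start. Attributes come from the note's relations through the normalizers:
#' size in millimetres with its clinical bin, two-level location, shape,
#' quantity, status (with resolution detection), solidity surface and the
#' etiology set. A temporal entity in the same sentence is attached as the
#' comparison date.
#'
#' @param note an annotated note with (gold or predicted) entities and
#'   relations.
#' @return data.frame with one row per GGO finding; list-free columns:
#'   `patient_id`, `note_id`, `note_date`, `span_start`, `ggo_kind`,
#'   `size_mm`, `size_bin`, `laterality`, `lobe`, `shape`, `quantity`,
#'   `status`, `etiologies` (";"-joined), `solidity`, `compared_date`.
#' @export
assemble_findings <- function(note) {
  e <- note$entities; r <- note$relations
  anchors <- which(e$type %in% .ggo_anchor_types())
  anchors <- anchors[order(e$start[anchors])]
  if (!length(anchors)) return(empty_findings())

  sents <- tokenize(note$text)
  bounds <- t(vapply(sents, function(s) c(min(s$start), max(s$end)),
                     numeric(2)))
  sent_of <- function(pos) {
    i <- which(bounds[, 1] <= pos & pos < bounds[, 2])
    if (length(i)) i[1] else NA_integer_
  }
  temporals <- which(e$type == "temporal")

  rows <- lapply(anchors, function(a) {
    tails <- if (nrow(r)) r$tail[r$head == a] else integer(0)
    ttypes <- e$type[tails]
    first_tail <- function(types) {
      i <- tails[ttypes %in% types]
      if (length(i)) i[1] else NA_integer_
    }
    size_i <- first_tail("ggo_size")
    loc_i <- first_tail("ggo_location")
    shape_i <- first_tail("ggo_shape_margin")
    qty_i <- first_tail("ggo_quantity")
    sol_i <- first_tail("ggo_solidity")
    stat_i <- first_tail(c("status_better", "status_stable", "status_worsen"))
    cause_i <- tails[ttypes %in% c("cause_neoplasm",
                                   "cause_infectious_inflammatory",
                                   "cause_hemorrhage", "cause_other_pulmonary")]

    size_mm <- if (is.na(size_i)) NA_real_ else normalize_size(e$surface[size_i])
    loc <- if (is.na(loc_i)) c(laterality = NA_character_, lobe = NA_character_)
           else normalize_location(e$surface[loc_i])
    shape <- if (is.na(shape_i)) NA_character_
      else if (grepl("spicul|irregul", tolower(e$surface[shape_i])))
        "irregular_spiculated"
      else "rounded_smooth"
    qty <- if (is.na(qty_i)) list(quantity = NA_character_, count = NA_integer_)
           else normalize_quantity(e$surface[qty_i])
    status <- if (is.na(stat_i)) NA_character_
              else normalize_status(e$type[stat_i], e$surface[stat_i])
    etio <- sort(unique(vapply(cause_i, function(ci)
      normalize_etiology(e$type[ci], e$surface[ci]), character(1))))

    asent <- sent_of(e$start[a])
    tsame <- temporals[vapply(e$start[temporals], sent_of, integer(1)) %in% asent]
    cmp_date <- if (length(tsame))
      suppressWarnings(normalize_temporal(e$surface[tsame[1]], note$note_date))
      else as.Date(NA)

    data.frame(
      patient_id = note$patient_id, note_id = note$note_id,
      note_date = note$note_date, span_start = e$start[a],
      ggo_kind = if (e$type[a] == "pure_ggo_term") "pure" else "part_solid",
      size_mm = size_mm, size_bin = bin_size(size_mm),
      laterality = unname(loc["laterality"]), lobe = unname(loc["lobe"]),
      shape = shape, quantity = qty$quantity, quantity_n = qty$count,
      status = status, etiologies = paste(etio, collapse = ";"),
      solidity = if (is.na(sol_i)) NA_character_ else e$surface[sol_i],
      compared_date = cmp_date, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @rdname assemble_findings
#' @export
empty_findings <- function() {
  data.frame(patient_id = character(0), note_id = character(0),
             note_date = as.Date(character(0)), span_start = integer(0),
             ggo_kind = character(0), size_mm = numeric(0),
             size_bin = character(0), laterality = character(0),
             lobe = character(0), shape = character(0),
             quantity = character(0), quantity_n = integer(0),
             status = character(0), etiologies = character(0),
             solidity = character(0),
             compared_date = as.Date(character(0)),
             stringsAsFactors = FALSE)
}

#' @rdname assemble_findings
#' @param notes list of annotated notes.
#' @export
findings_from_notes <- function(notes) {
  out <- lapply(notes, assemble_findings)
  out <- out[vapply(out, nrow, integer(1)) > 0]
  if (!length(out)) return(empty_findings())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
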
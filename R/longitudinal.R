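#' Build per-patient GGO timelines
#'
#' Groups normalized findings by patient into date-ordered timelines,
#' optionally attaching the lung-cancer diagnosis date from a patient
#' metadata table.
#'
#' @param findings a findings data.frame (see [assemble_findings()]).
#' @param patients optional data.frame with `patient_id` and
#'   `diagnosis_date`.
#' @return named list of `ggo_timeline` objects (`patient_id`,
#'   `diagnosis_date`, `dates` sorted increasing, `findings`).
#' @export
build_timelines <- function(findings, patients = NULL) {
  stopifnot(nrow(findings) > 0)
  split_f <- split(findings, findings$patient_id)
  lapply(split_f, function(f) {
    f <- f[order(f$note_date, f$span_start), , drop = FALSE]
    dx <- as.Date(NA)
    if (!is.null(patients)) {
      i <- match(f$patient_id[1], patients$patient_id)
      if (!is.na(i)) dx <- as.Date(patients$diagnosis_date[i])
    }
    structure(list(patient_id = f$patient_id[1], diagnosis_date = dx,
                   dates = sort(unique(f$note_date)), findings = f),
              class = "ggo_timeline")
  })
}

#' @export
print.ggo_timeline <- function(x, ...) {
  cat("<ggo_timeline ", x$patient_id, "> ", length(x$dates),
      " report date(s), ", nrow(x$findings), " finding(s)",
      if (!is.na(x$diagnosis_date))
        paste0(", diagnosed ", format(x$diagnosis_date)) else "",
      "\n", sep = "")
  invisible(x)
}

.findings_on <- function(tl, d) tl$findings[tl$findings$note_date == d, ,
                                            drop = FALSE]

#' Classify a patient's GGO persistence
#'
#' Persistent: multiple GGO report dates whose last date carries no resolved
#' finding, or a single report date with a worsening indication (worsen
#' status, or a solidity surface describing increase/new solid component).
#' Nonpersistent otherwise (terminal resolution, or a single unremarkable
#' report).
#'
#' @param timeline a `ggo_timeline`.
#' @return `"persistent"` or `"nonpersistent"`.
#' @export
classify_persistence <- function(timeline) {
  if (!length(timeline$dates)) stop("empty timeline")
  last <- .findings_on(timeline, timeline$dates[length(timeline$dates)])
  if (length(timeline$dates) >= 2) {
    if (any(last$status == "resolved", na.rm = TRUE)) return("nonpersistent")
    return("persistent")
  }
  worsening <- any(last$status == "worsen", na.rm = TRUE) ||
    any(grepl("increas|new solid|densit", tolower(last$solidity)), na.rm = TRUE)
  if (worsening) "persistent" else "nonpersistent"
}

#' Daily rollups of size and status
#'
#' When more than one size is reported on a day, the largest is used; when
#' more than one status change is reported, the most severe is selected with
#' the order worsen (increased) > stable > better (decreased). `resolved` is
#' terminal and is reported only when it is the sole status that day.
#'
#' @param findings_on_date findings data.frame restricted to one date (or a
#'   numeric/character vector of the values directly).
#' @return `rollup_daily_size()`: the largest size in mm or `NA`;
#'   `rollup_daily_status()`: one status or `NA`.
#' @export
rollup_daily_size <- function(findings_on_date) {
  v <- if (is.data.frame(findings_on_date)) findings_on_date$size_mm
       else findings_on_date
  v <- v[!is.na(v)]
  if (!length(v)) NA_real_ else max(v)
}

#' @rdname rollup_daily_size
#' @export
rollup_daily_status <- function(findings_on_date) {
  v <- if (is.data.frame(findings_on_date)) findings_on_date$status
       else findings_on_date
  v <- v[!is.na(v)]
  if (!length(v)) return(NA_character_)
  if (all(v == "resolved")) return("resolved")
  v <- v[v != "resolved"]
  for (s in c("worsen", "stable", "better")) if (s %in% v) return(s)
  NA_character_
}

#' First-to-last change in rolled-up GGO size
#'
#' Compares the daily-rollup size at the first and last dates carrying a
#' size. Requires at least two such dates (patients with size on a single
#' date are excluded); `increase` iff last > first + tau, `decrease` iff
#' last < first - tau, else `stable`.
#'
#' @param timeline a `ggo_timeline`.
#' @param tau tolerance in mm for "unchanged" (default 0).
#' @return `"increase"`, `"decrease"`, `"stable"`, or `NA` when fewer than
#'   two dates carry sizes.
#' @export
size_change <- function(timeline, tau = 0) {
  sizes <- vapply(timeline$dates,
                  function(d) rollup_daily_size(.findings_on(timeline, d)),
                  numeric(1))
  ok <- which(!is.na(sizes))
  if (length(ok) < 2) return(NA_character_)
  first <- sizes[ok[1]]; last <- sizes[ok[length(ok)]]
  if (last > first + tau) "increase"
  else if (last < first - tau) "decrease"
  else "stable"
}

#' Daily status sequence and longitudinal status outcome
#'
#' The daily sequence applies [rollup_daily_status()] per report date. The
#' outcome summarizes the notes after the first report date: `increased` if
#' any subsequent daily status is worsen; else `resolved` if the final
#' status is resolved; else `decreased` if any is better; else `stable`.
#'
#' @param timeline a `ggo_timeline`.
#' @param min_dates minimum number of report dates required (default 2).
#' @param tau size-change tolerance in mm, passed to [size_change()].
#' @return list of class `ggo_trajectory`: `daily_status_sequence`
#'   (data.frame date/status), `status_outcome` (or `NA` when the
#'   precondition is unmet or no subsequent status exists), `persistence`
#'   and `size_change`.
#' @export
status_trajectory <- function(timeline, min_dates = 2, tau = 0) {
  st <- vapply(timeline$dates,
               function(d) rollup_daily_status(.findings_on(timeline, d)),
               character(1))
  seq_df <- data.frame(date = timeline$dates, status = st)[!is.na(st), ,
                                                           drop = FALSE]
  outcome <- NA_character_
  if (length(timeline$dates) >= min_dates) {
    subs <- st[-1]
    subs <- subs[!is.na(subs)]
    if (length(subs)) {
      outcome <- if ("worsen" %in% subs) "increased"
        else if (subs[length(subs)] == "resolved") "resolved"
        else if ("better" %in% subs) "decreased"
        else "stable"
    }
  }
  structure(list(patient_id = timeline$patient_id,
                 daily_status_sequence = seq_df,
                 status_outcome = outcome,
                 persistence = classify_persistence(timeline),
                 size_change = size_change(timeline, tau)),
            class = "ggo_trajectory")
}

#' @export
print.ggo_trajectory <- function(x, ...) {
  cat("<ggo_trajectory ", x$patient_id, "> ", x$persistence,
      "; size change: ", x$size_change, "; status outcome: ",
      x$status_outcome, "\n", sep = "")
  invisible(x)
}

#' Pre-diagnosis stratification
#'
#' A patient belongs to the pregroup iff the first GGO report date falls
#' strictly before the lung-cancer diagnosis date (same-day reports are
#' post-diagnosis).
#'
#' @param timeline a `ggo_timeline` with a diagnosis date.
#' @return `TRUE`/`FALSE`, or `NA` with a warning when the diagnosis date is
#'   missing.
#' @export
stratify_pregroup <- function(timeline) {
  if (is.na(timeline$diagnosis_date)) {
    warning("missing diagnosis date for patient ", timeline$patient_id)
    return(NA)
  }
  timeline$dates[1] < timeline$diagnosis_date
}

#' Bin the interval from first GGO report to diagnosis
#'
#' Day-count convention: `lt6mo` for d < 183 days, `6mo_to_1yr` for
#' 183 <= d < 366, `1yr_to_3yr` for 366 <= d < 1096, `gt3yr` otherwise
#' (half-open on the right); the bins partition all non-negative intervals.
#'
#' @param first_ggo_date,diagnosis_date `Date`s with
#'   `first_ggo_date <= diagnosis_date`.
#' @return one of `"lt6mo"`, `"6mo_to_1yr"`, `"1yr_to_3yr"`, `"gt3yr"`.
#' @export
interval_bin <- function(first_ggo_date, diagnosis_date) {
  d <- as.integer(as.Date(diagnosis_date) - as.Date(first_ggo_date))
  if (any(d < 0)) stop("negative interval: first GGO report after diagnosis")
  cut(d, breaks = c(-1, 182, 365, 1095, Inf),
      labels = c("lt6mo", "6mo_to_1yr", "1yr_to_3yr", "gt3yr")) |>
    as.character()
}

#' Exclusive baseline size group of a patient
#'
#' The single size bin shared by all first-date findings that carry a size;
#' `"more_than_1"` when they span several bins; `NA` when no first-date
#' finding has a size.
#'
#' @param timeline a `ggo_timeline`.
#' @return a size bin, `"more_than_1"`, or `NA_character_`.
#' @export
exclusive_size_group <- function(timeline) {
  f <- .findings_on(timeline, timeline$dates[1])
  bins <- unique(f$size_bin[!is.na(f$size_bin)])
  if (!length(bins)) NA_character_
  else if (length(bins) == 1) bins
  else "more_than_1"
}

.count_block <- function(x, levels) {
  x <- x[!is.na(x)]
  n <- vapply(levels, function(l) sum(x == l), integer(1))
  denom <- length(x)
  data.frame(category = levels, n = n,
             pct = if (denom) round_half_up(100 * n / denom, 1) else 0,
             row.names = NULL, stringsAsFactors = FALSE)
}

.first_note_value <- function(f, col) {
  v <- unique(f[[col]][!is.na(f[[col]])])
  if (!length(v)) NA_character_
  else if (length(v) == 1) v
  else "more_than_1"
}

#' Patient-level cohort summary tables
#'
#' Computes the cohort characterization tables from per-patient timelines:
#' first-note distributions of location, etiology (including "more than 1
#' cause"), baseline size bins (including "more than 1 size"), status and
#' shape; longitudinal size-change and status-outcome distributions;
#' persistence; the pregroup interval table (patients whose first report
#' predates diagnosis, by exclusive baseline size group and interval bin);
#' and first-10-note status transition counts for a Sankey-style plot.
#' Percentages are over the block's denominator, at 1 decimal.
#'
#' @param timelines list of `ggo_timeline` ([build_timelines()]).
#' @param tau size-change tolerance in mm.
#' @return named list of data.frames.
#' @export
cohort_summary <- function(timelines, tau = 0) {
  stopifnot(length(timelines) >= 1)
  first_f <- lapply(timelines, function(tl) .findings_on(tl, tl$dates[1]))

  lat <- vapply(first_f, function(f) {
    v <- f$laterality[!is.na(f$laterality) & f$laterality != "unknown"]
    if (!length(v)) return(NA_character_)
    if ("bilateral" %in% v || all(c("left", "right") %in% v)) "bilateral"
    else if (length(unique(v)) == 1) unique(v) else "bilateral"
  }, character(1))
  etio <- vapply(first_f, function(f) {
    v <- unique(unlist(strsplit(f$etiologies[nzchar(f$etiologies)], ";")))
    if (!length(v)) NA_character_ else if (length(v) == 1) v else "more_than_1"
  }, character(1))
  sizeg <- vapply(timelines, exclusive_size_group, character(1))
  statg <- vapply(first_f, .first_note_value, character(1), col = "status")
  shapeg <- vapply(first_f, .first_note_value, character(1), col = "shape")

  traj <- lapply(timelines, status_trajectory, tau = tau)
  szch <- vapply(traj, `[[`, character(1), "size_change")
  stout <- vapply(traj, `[[`, character(1), "status_outcome")
  persist <- vapply(traj, `[[`, character(1), "persistence")

  pre <- vapply(timelines, function(tl)
    if (is.na(tl$diagnosis_date)) NA else suppressWarnings(
      stratify_pregroup(tl)), logical(1))
  pre_rows <- list()
  for (i in seq_along(timelines)) {
    if (!isTRUE(pre[i])) next
    g <- sizeg[i]
    if (is.na(g) || g == "more_than_1") next
    pre_rows[[length(pre_rows) + 1L]] <- data.frame(
      size_bin = g,
      interval = interval_bin(timelines[[i]]$dates[1],
                              timelines[[i]]$diagnosis_date),
      stringsAsFactors = FALSE)
  }
  interval_tab <- if (length(pre_rows)) {
    pr <- do.call(rbind, pre_rows)
    as.data.frame(table(size_bin = pr$size_bin, interval = pr$interval),
                  responseName = "n")
  } else data.frame(size_bin = character(0), interval = character(0),
                    n = integer(0))

  trans_rows <- list()
  for (tr in traj) {
    s <- utils::head(tr$daily_status_sequence$status, 10)
    if (length(s) >= 2)
      trans_rows[[length(trans_rows) + 1L]] <- data.frame(
        position = seq_len(length(s) - 1), from = s[-length(s)], to = s[-1],
        stringsAsFactors = FALSE)
  }
  transitions <- if (length(trans_rows)) {
    tt <- do.call(rbind, trans_rows)
    stats::aggregate(cbind(n = rep(1L, nrow(tt))) ~ position + from + to,
                     data = tt, FUN = sum)
  } else data.frame(position = integer(0), from = character(0),
                    to = character(0), n = integer(0))

  list(
    location = .count_block(lat, c("bilateral", "left", "right")),
    etiology = .count_block(etio, c("infectious_inflammatory", "malignant",
                                    "other", "more_than_1")),
    size = .count_block(sizeg, c("lt6", "6to20", "gt20", "more_than_1")),
    status = .count_block(statg, c("better", "stable", "worsen", "resolved",
                                   "more_than_1")),
    shape = .count_block(shapeg, c("irregular_spiculated", "rounded_smooth",
                                   "more_than_1")),
    size_change = .count_block(szch, c("increase", "decrease", "stable")),
    status_outcome = .count_block(stout, c("increased", "decreased", "stable",
                                           "resolved")),
    persistence = .count_block(persist, c("persistent", "nonpersistent")),
    pregroup_intervals = interval_tab,
    status_transitions = transitions)
}
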
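#' Default surface-form lexicon for the synthetic radiology corpus
#'
#' Maps each semantic value of the GGO ontology to the surface forms the
#' generator may render. Editing this list (e.g. adding local phrasing) is the
#' supported way to change the synthetic language; a value with an empty
#' surface list is a generation error.
#'
#' @return a named list of character vectors / nested lists.
#' @export
default_lexicon <- function() {
  list(
    pure_ggo_term = c("ground-glass opacity", "ground glass opacity",
                      "ground-glass nodule", "GGO",
                      "pure ground-glass nodule", "groundglass opacity"),
    pure_ggo_term_plural = c("ground-glass opacities", "ground glass opacities",
                             "ground-glass nodules", "GGOs"),
    part_solid_ggo_term = c("part-solid nodule", "part-solid ground-glass nodule",
                            "part solid GGO", "subsolid nodule"),
    part_solid_ggo_term_plural = c("part-solid nodules", "subsolid nodules",
                                   "part-solid ground-glass nodules"),
    lobe = list(RUL = c("right upper lobe", "RUL"),
                RML = c("right middle lobe", "RML"),
                RLL = c("right lower lobe", "RLL"),
                LUL = c("left upper lobe", "LUL"),
                LLL = c("left lower lobe", "LLL")),
    laterality = list(left = c("left lung"),
                      right = c("right lung"),
                      bilateral = c("both lungs", "bilateral lungs")),
    shape = list(irregular_spiculated = c("spiculated", "irregular"),
                 rounded_smooth = c("rounded", "smooth")),
    quantity = list(single = c("solitary", "single"),
                    multiple = c("Multiple", "Several", "Scattered",
                                 "Numerous")),
    status = list(better = c("decreased in size", "smaller than before",
                             "improved"),
                  stable = c("unchanged", "stable", "grossly stable"),
                  worsen = c("increased in size", "larger than before",
                             "progressed", "increased in density")),
    resolved = c("resolved", "no longer seen"),
    etiology = list(
      neoplasm = c("adenocarcinoma", "malignancy", "metastatic disease",
                   "adenocarcinoma in situ", "atypical adenomatous hyperplasia"),
      infectious_inflammatory = c("pneumonia", "infection",
                                  "inflammatory change"),
      hemorrhage = c("hemorrhage", "pulmonary hemorrhage"),
      other = c("fibrosis", "scarring", "atelectasis")),
    solidity = c("no solid component", "a small solid component",
                 "subsolid attenuation"),
    distractors = c("The heart is normal in size.",
                    "No pleural effusion or pneumothorax.",
                    "The airways are patent.",
                    "Mediastinal contours are unremarkable.",
                    "Degenerative changes are noted in the thoracic spine."),
    impressions = c("Findings as described above.",
                    "Follow-up imaging recommended.",
                    "Stable examination otherwise.")
  )
}

#' Configuration of the synthetic cohort generator
#'
#' Defines the study conditions the generator emulates: cohort size, notes
#' per patient, how often each GGO attribute is documented, the mix of latent
#' longitudinal trajectories, and the surface lexicon. Identical config and
#' seed give a byte-identical corpus.
#'
#' @param n_patients number of patients.
#' @param notes_per_patient integer vector of allowed note counts; patients
#'   whose latent trajectory needs two time points are given at least 2.
#' @param seed integer RNG seed.
#' @param attribute_frequencies named probabilities that an optional attribute
#'   (location, shape, quantity, cause, temporal, solidity) is documented for
#'   a finding.
#' @param trajectory_mix proportions over the latent classes increase,
#'   decrease, stable, resolved; must sum to 1.
#' @param part_solid_prob probability a patient's index nodule is part-solid.
#' @param pregroup_prob probability the first GGO report predates the lung
#'   cancer diagnosis date.
#' @param extra_finding_prob probability a note carries one additional
#'   (non-index) GGO finding without size/status spans.
#' @param date_style `"iso"` (2019-03-02) or `"us"` (3/2/2019) for dates
#'   rendered in the text.
#' @param lexicon surface lexicon, see [default_lexicon()].
#' @return object of class `ggo_gen_config`.
#' @export
generator_config <- function(n_patients = 50,
                             notes_per_patient = 1:5,
                             seed = 1L,
                             attribute_frequencies = c(
                               location = 0.85, shape = 0.4, quantity = 0.35,
                               cause = 0.5, temporal = 0.25, solidity = 0.15),
                             trajectory_mix = c(increase = 0.230,
                                                decrease = 0.024,
                                                stable = 0.723,
                                                resolved = 0.023),
                             part_solid_prob = 0.15,
                             pregroup_prob = 0.377,
                             extra_finding_prob = 0.35,
                             date_style = c("iso", "us"),
                             lexicon = default_lexicon()) {
  date_style <- match.arg(date_style)
  if (length(notes_per_patient) == 0)
    stop("notes_per_patient range is empty")
  if (any(attribute_frequencies < 0) || any(attribute_frequencies > 1))
    stop("attribute_frequencies must lie in [0, 1]")
  if (abs(sum(trajectory_mix) - 1) > 1e-9)
    stop("trajectory_mix must sum to 1")
  if (!setequal(names(trajectory_mix),
                c("increase", "decrease", "stable", "resolved")))
    stop("trajectory_mix needs the classes increase, decrease, stable, resolved")
  structure(list(n_patients = as.integer(n_patients),
                 notes_per_patient = as.integer(notes_per_patient),
                 seed = as.integer(seed),
                 attribute_frequencies = attribute_frequencies,
                 trajectory_mix = trajectory_mix,
                 part_solid_prob = part_solid_prob,
                 pregroup_prob = pregroup_prob,
                 extra_finding_prob = extra_finding_prob,
                 date_style = date_style,
                 lexicon = lexicon),
            class = "ggo_gen_config")
}

#' A latent GGO finding (generator truth)
#'
#' @param ggo_kind `"pure"` or `"part_solid"`.
#' @param size_mm positive size in millimetres, or `NA`.
#' @param lobe one of RUL, RML, RLL, LUL, LLL, or `NA`.
#' @param laterality left/right/bilateral, or `NA`; must be consistent with
#'   `lobe` (RUL/RML/RLL imply right, LUL/LLL imply left).
#' @param shape irregular_spiculated / rounded_smooth or `NA`.
#' @param quantity single / multiple or `NA`.
#' @param etiologies character subset of neoplasm, infectious_inflammatory,
#'   hemorrhage, other.
#' @param status better / stable / worsen / resolved, or `NA`.
#' @param solidity logical: mention a solidity phrase.
#' @param prior_date comparison date rendered as a temporal entity, or `NA`.
#' @return a list of class `ggo_latent`.
#' @export
latent_finding <- function(ggo_kind, size_mm = NA_real_, lobe = NA_character_,
                           laterality = NA_character_, shape = NA_character_,
                           quantity = NA_character_,
                           etiologies = character(0), status = NA_character_,
                           solidity = FALSE, prior_date = as.Date(NA)) {
  stopifnot(ggo_kind %in% c("pure", "part_solid"))
  if (!is.na(size_mm) && size_mm <= 0) stop("size_mm must be positive")
  lat_of_lobe <- c(RUL = "right", RML = "right", RLL = "right",
                   LUL = "left", LLL = "left")
  if (!is.na(lobe)) {
    expected <- lat_of_lobe[[lobe]]
    if (is.na(laterality)) laterality <- expected
    if (laterality != expected)
      stop("lobe ", lobe, " implies laterality ", expected)
  }
  structure(list(ggo_kind = ggo_kind, size_mm = size_mm, lobe = lobe,
                 laterality = laterality, shape = shape, quantity = quantity,
                 etiologies = etiologies, status = status,
                 solidity = solidity, prior_date = as.Date(prior_date)),
            class = "ggo_latent")
}

.pick <- function(surfaces, what) {
  if (length(surfaces) == 0)
    stop("lexicon has no surface form for: ", what)
  if (length(surfaces) == 1) surfaces else sample(surfaces, 1)
}

.render_size_surface <- function(size_mm) {
  style <- sample(c("mm", "cm", "two_dim"), 1, prob = c(0.6, 0.25, 0.15))
  if (style == "cm") {
    sprintf("%g cm", size_mm / 10)
  } else if (style == "two_dim") {
    minor <- max(1, round(size_mm * stats::runif(1, 0.4, 0.9)))
    sprintf("%g x %g mm", size_mm, minor)
  } else sprintf("%g mm", size_mm)
}

.render_date_surface <- function(d, style) {
  if (style == "us") format(d, "%m/%d/%Y") else format(d, "%Y-%m-%d")
}

# A segment is list(text=, type=NA or entity type). Sentences are segment
# lists; .emit() concatenates them tracking 0-based offsets.
.seg <- function(text, type = NA_character_) list(text = text, type = type)

.finding_segments <- function(lat, config) {
  lx <- config$lexicon
  anchor_type <- if (lat$ggo_kind == "pure") "pure_ggo_term"
                 else "part_solid_ggo_term"
  segs <- list()
  add <- function(s) segs[[length(segs) + 1L]] <<- s

  loc_surface <- NULL
  if (!is.na(lat$lobe)) {
    loc_surface <- .pick(lx$lobe[[lat$lobe]], lat$lobe)
  } else if (!is.na(lat$laterality)) {
    loc_surface <- .pick(lx$laterality[[lat$laterality]], lat$laterality)
  }

  if (!is.na(lat$status) && lat$status == "resolved") {
    add(.seg("The previously noted "))
    add(.seg(.pick(lx[[anchor_type]], anchor_type), anchor_type))
    if (!is.null(loc_surface)) {
      add(.seg(" in the "))
      add(.seg(loc_surface, "ggo_location"))
    }
    add(.seg(" has "))
    add(.seg(.pick(lx$resolved, "resolved"), "status_better"))
    add(.seg("."))
    return(segs)
  }

  multiple <- !is.na(lat$quantity) && lat$quantity == "multiple"
  if (multiple) {
    add(.seg(.pick(lx$quantity$multiple, "quantity multiple"), "ggo_quantity"))
    add(.seg(" "))
    if (!is.na(lat$shape)) {
      add(.seg(.pick(lx$shape[[lat$shape]], lat$shape), "ggo_shape_margin"))
      add(.seg(" "))
    }
    add(.seg(.pick(lx[[paste0(anchor_type, "_plural")]], anchor_type),
             anchor_type))
    add(.seg(" are seen"))
    if (!is.null(loc_surface)) {
      add(.seg(" in the "))
      add(.seg(loc_surface, "ggo_location"))
    }
    if (!is.na(lat$size_mm)) {
      add(.seg(", the largest measuring "))
      add(.seg(.render_size_surface(lat$size_mm), "ggo_size"))
    }
  } else {
    add(.seg("There is a "))
    if (!is.na(lat$quantity)) {   # quantity == "single"
      add(.seg(.pick(lx$quantity$single, "quantity single"), "ggo_quantity"))
      add(.seg(" "))
    }
    if (!is.na(lat$size_mm)) {
      add(.seg(.render_size_surface(lat$size_mm), "ggo_size"))
      add(.seg(" "))
    }
    if (!is.na(lat$shape)) {
      add(.seg(.pick(lx$shape[[lat$shape]], lat$shape), "ggo_shape_margin"))
      add(.seg(" "))
    }
    add(.seg(.pick(lx[[anchor_type]], anchor_type), anchor_type))
    if (!is.null(loc_surface)) {
      add(.seg(" in the "))
      add(.seg(loc_surface, "ggo_location"))
    }
  }
  if (!is.na(lat$status)) {
    add(.seg(", "))
    add(.seg(.pick(lx$status[[lat$status]], lat$status),
             paste0("status_", lat$status)))
  }
  if (!is.na(lat$prior_date)) {
    add(.seg(" compared to the prior CT of "))
    add(.seg(.render_date_surface(lat$prior_date, config$date_style),
             "temporal"))
  }
  if (length(lat$etiologies)) {
    add(.seg(", possibly related to "))
    first <- TRUE
    for (et in lat$etiologies) {
      if (!first) add(.seg(" or "))
      etype <- switch(et,
                      neoplasm = "cause_neoplasm",
                      infectious_inflammatory = "cause_infectious_inflammatory",
                      hemorrhage = "cause_hemorrhage",
                      other = "cause_other_pulmonary")
      add(.seg(.pick(lx$etiology[[et]], et), etype))
      first <- FALSE
    }
  }
  if (isTRUE(lat$solidity)) {
    add(.seg(", with "))
    add(.seg(.pick(lx$solidity, "solidity"), "ggo_solidity"))
  }
  add(.seg("."))
  segs
}

.relation_for_tail <- function(tail_type) {
  switch(tail_type,
         ggo_size = "has_size_info",
         ggo_quantity = "has_number_info",
         ggo_location = "has_location_info",
         ggo_shape_margin = "has_shape_margin_info",
         ggo_solidity = "has_solidity_info",
         status_better = , status_stable = , status_worsen = "has_status",
         cause_neoplasm = , cause_infectious_inflammatory = ,
         cause_hemorrhage = , cause_other_pulmonary = "has_potential_cause",
         NA_character_)   # temporal: attached at note level, no relation
}

#' Render one synthetic radiology note with gold annotations
#'
#' Assembles a FINDINGS/IMPRESSION note from lexicon templates: one sentence
#' per latent finding (each latent attribute surfaces as exactly one annotated
#' span linked to its GGO anchor), with distractor sentences interspersed.
#' Uses the current R RNG stream for surface choices.
#'
#' @param latents list of [latent_finding()] objects (at least one).
#' @param config a [generator_config()].
#' @param note_id,patient_id,note_date note metadata.
#' @return a [annotated_note()] with gold entities and relations.
#' @export
render_note <- function(latents, config, note_id = "note1",
                        patient_id = NA_character_,
                        note_date = as.Date(NA)) {
  if (length(latents) == 0) stop("render_note needs at least one latent finding")
  lx <- config$lexicon
  sentences <- list(list(.seg("FINDINGS:")))
  if (stats::runif(1) < 0.7)
    sentences[[length(sentences) + 1L]] <-
      list(.seg(.pick(lx$distractors, "distractor")))
  for (lat in latents) {
    sentences[[length(sentences) + 1L]] <- .finding_segments(lat, config)
    if (stats::runif(1) < 0.3)
      sentences[[length(sentences) + 1L]] <-
        list(.seg(.pick(lx$distractors, "distractor")))
  }
  sentences[[length(sentences) + 1L]] <-
    list(.seg(paste("IMPRESSION:", .pick(lx$impressions, "impression"))))

  # emit text, tracking offsets; sentences separated by newlines
  text <- ""
  pos <- 0L   # 0-based offset of next char
  ents <- list(); rels <- list()
  for (si in seq_along(sentences)) {
    if (si > 1L) { text <- paste0(text, "\n"); pos <- pos + 1L }
    anchor_idx <- NA_integer_
    pending <- list()   # attribute entity indices awaiting an anchor
    for (sg in sentences[[si]]) {
      n <- nchar(sg$text)
      if (!is.na(sg$type)) {
        ents[[length(ents) + 1L]] <- data.frame(
          start = pos, end = pos + n, type = sg$type, surface = sg$text,
          stringsAsFactors = FALSE)
        ei <- length(ents)
        if (sg$type %in% .ggo_anchor_types()) {
          anchor_idx <- ei
          for (p in pending) {
            rt <- .relation_for_tail(p$type)
            if (!is.na(rt))
              rels[[length(rels) + 1L]] <- data.frame(
                head = anchor_idx, tail = p$idx, type = rt,
                stringsAsFactors = FALSE)
          }
          pending <- list()
        } else if (!is.na(anchor_idx)) {
          rt <- .relation_for_tail(sg$type)
          if (!is.na(rt))
            rels[[length(rels) + 1L]] <- data.frame(
              head = anchor_idx, tail = ei, type = rt,
              stringsAsFactors = FALSE)
        } else {
          pending[[length(pending) + 1L]] <- list(idx = ei, type = sg$type)
        }
      }
      text <- paste0(text, sg$text)
      pos <- pos + n
    }
  }
  entities <- if (length(ents)) do.call(rbind, ents) else empty_entities()
  relations <- if (length(rels)) do.call(rbind, rels) else empty_relations()
  annotated_note(note_id, patient_id, note_date, text, entities, relations)
}

.draw_location <- function() {
  r <- stats::runif(1)
  if (r < 0.25) {
    list(lobe = NA_character_, laterality = "bilateral")
  } else {
    lobe <- sample(c("RUL", "LUL", "RLL", "LLL", "RML"), 1,
                   prob = c(0.30, 0.22, 0.18, 0.15, 0.15))
    list(lobe = lobe, laterality = NULL)  # derived in latent_finding()
  }
}

.draw_attrs <- function(config) {
  f <- config$attribute_frequencies
  loc <- if (stats::runif(1) < f[["location"]]) .draw_location() else NULL
  etio <- character(0)
  if (stats::runif(1) < f[["cause"]]) {
    ks <- c("infectious_inflammatory", "neoplasm", "other", "hemorrhage")
    n_et <- sample(1:2, 1, prob = c(0.7, 0.3))
    etio <- sample(ks, n_et, prob = c(0.45, 0.25, 0.2, 0.1))
  }
  list(
    lobe = if (is.null(loc)) NA_character_ else loc$lobe,
    laterality = if (is.null(loc)) NA_character_
                 else if (is.null(loc$laterality)) NA_character_
                 else loc$laterality,
    shape = if (stats::runif(1) < f[["shape"]])
              sample(c("irregular_spiculated", "rounded_smooth"), 1,
                     prob = c(0.8, 0.2)) else NA_character_,
    quantity = if (stats::runif(1) < f[["quantity"]])
                 sample(c("single", "multiple"), 1, prob = c(0.25, 0.75))
               else NA_character_,
    etiologies = etio,
    solidity = stats::runif(1) < f[["solidity"]],
    temporal = stats::runif(1) < f[["temporal"]])
}

#' Generate a synthetic patient cohort with known GGO trajectories
#'
#' Draws one latent trajectory class per patient (increase / decrease /
#' stable / resolved), emits date-ordered notes whose index finding realizes
#' that class, and returns both the annotated corpus and the latent truth.
#' Each note carries one index finding (the longitudinally tracked nodule;
#' its location, shape and kind are constant within a patient) and,
#' optionally, extra findings without size or status spans so that daily
#' rollups recover the constructed truth exactly. Patients constructed to be
#' persistent (multiple reports without terminal resolution, or a single
#' report with a worsening indication) and nonpersistent (resolution in the
#' last report, or a single unremarkable report) both occur.
#'
#' @param config a [generator_config()].
#' @return list with elements `corpus` (list of [annotated_note()]) and
#'   `truth`: `patients` (one row per patient: trajectory class, persistence,
#'   expected size change / status outcome, diagnosis date, pregroup flag)
#'   and `findings` (one row per latent finding).
#' @export
generate_cohort <- function(config = generator_config()) {
  stopifnot(inherits(config, "ggo_gen_config"))
  if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old, envir = .GlobalEnv))
  }
  set.seed(config$seed)

  corpus <- list()
  pat_rows <- list(); find_rows <- list()
  classes <- names(config$trajectory_mix)

  for (i in seq_len(config$n_patients)) {
    pid <- sprintf("P%05d", i)
    traj <- sample(classes, 1, prob = config$trajectory_mix)
    n_notes <- if (length(config$notes_per_patient) == 1)
      config$notes_per_patient else sample(config$notes_per_patient, 1)
    if (traj != "stable") n_notes <- max(2L, n_notes)

    first_date <- as.Date("2015-01-01") + sample(0:1825, 1)
    dates <- first_date
    if (n_notes > 1)
      dates <- first_date + c(0L, cumsum(sample(45:300, n_notes - 1,
                                                replace = TRUE)))
    # diagnosis date: strictly after the first report for pregroup patients
    if (stats::runif(1) < config$pregroup_prob) {
      bin <- sample(1:4, 1, prob = c(0.55, 0.10, 0.20, 0.15))
      d <- switch(bin, sample(1:182, 1), sample(183:365, 1),
                  sample(366:1095, 1), sample(1096:1800, 1))
      dx_date <- first_date + d
      pregroup <- TRUE
    } else {
      dx_date <- first_date - sample(0:365, 1)
      pregroup <- FALSE
    }

    kind <- if (stats::runif(1) < config$part_solid_prob) "part_solid" else "pure"
    base_size <- if (traj == "decrease") sample(10:30, 1) else sample(3:28, 1)
    sizes <- switch(traj,
      increase = base_size + cumsum(c(0L, sample(1:5, n_notes - 1, TRUE))),
      decrease = pmax(1L, base_size - cumsum(c(0L, sample(1:3, n_notes - 1, TRUE)))),
      stable   = rep(base_size, n_notes),
      resolved = c(rep(base_size, n_notes - 1), NA_integer_))
    statuses <- rep(NA_character_, n_notes)
    if (n_notes >= 2) {
      statuses[-1] <- switch(traj, increase = "worsen", decrease = "better",
                             stable = "stable", resolved = "stable")
      if (traj == "resolved") statuses[n_notes] <- "resolved"
    } else if (traj == "stable" && stats::runif(1) < 0.3) {
      statuses[1] <- "worsen"   # single report with a worsening indication
    }

    persistence <- if (traj == "resolved") "nonpersistent"
      else if (n_notes >= 2) "persistent"
      else if (identical(statuses[1], "worsen")) "persistent"
      else "nonpersistent"
    n_sized <- sum(!is.na(sizes))
    size_change <- if (n_sized >= 2)
      switch(traj, increase = "increase", decrease = "decrease", "stable")
      else NA_character_
    status_outcome <- if (n_notes >= 2)
      switch(traj, increase = "increased", decrease = "decreased",
             stable = "stable", resolved = "resolved")
      else NA_character_

    # index-finding attribute VALUES constant within patient (it is one
    # tracked nodule); whether an attribute is documented varies by note
    pat_loc <- .draw_location()
    pat_lobe <- pat_loc$lobe
    pat_lat <- if (is.null(pat_loc$laterality)) NA_character_
               else pat_loc$laterality
    pat_shape <- sample(c("irregular_spiculated", "rounded_smooth"), 1,
                        prob = c(0.8, 0.2))

    for (k in seq_len(n_notes)) {
      nid <- sprintf("%s_N%02d", pid, k)
      a <- .draw_attrs(config)   # per-note presence draw
      lat <- latent_finding(
        ggo_kind = kind,
        size_mm = as.numeric(sizes[k]),
        lobe = if (!is.na(a$lobe) || !is.na(a$laterality)) pat_lobe
               else NA_character_,
        laterality = if (!is.na(a$lobe) || !is.na(a$laterality))
                       pat_lat else NA_character_,
        shape = if (!is.na(a$shape)) pat_shape else NA_character_,
        quantity = a$quantity,
        etiologies = a$etiologies,
        status = statuses[k],
        solidity = a$solidity,
        prior_date = if (a$temporal && k > 1) dates[k - 1] else as.Date(NA))
      latents <- list(lat)
      if (!identical(statuses[k], "resolved") &&
          stats::runif(1) < config$extra_finding_prob) {
        ex <- .draw_attrs(config)
        latents[[2]] <- latent_finding(
          ggo_kind = sample(c("pure", "part_solid"), 1,
                            prob = c(0.85, 0.15)),
          lobe = ex$lobe, laterality = ex$laterality, shape = ex$shape,
          quantity = ex$quantity, etiologies = ex$etiologies,
          solidity = ex$solidity)
      }
      corpus[[length(corpus) + 1L]] <-
        render_note(latents, config, nid, pid, dates[k])
      for (j in seq_along(latents)) {
        l <- latents[[j]]
        find_rows[[length(find_rows) + 1L]] <- data.frame(
          patient_id = pid, note_id = nid, note_date = dates[k],
          is_index = j == 1L, ggo_kind = l$ggo_kind, size_mm = l$size_mm,
          lobe = l$lobe, laterality = l$laterality, shape = l$shape,
          quantity = l$quantity,
          etiologies = paste(l$etiologies, collapse = ";"),
          status = l$status, stringsAsFactors = FALSE)
      }
    }
    pat_rows[[length(pat_rows) + 1L]] <- data.frame(
      patient_id = pid, diagnosis_date = dx_date, trajectory_class = traj,
      n_notes = n_notes, first_ggo_date = first_date,
      persistence = persistence, size_change = size_change,
      status_outcome = status_outcome, pregroup = pregroup,
      stringsAsFactors = FALSE)
  }
  list(corpus = corpus,
       truth = list(patients = do.call(rbind, pat_rows),
                    findings = do.call(rbind, find_rows)))
}

#' Write generator truth tables as CSV
#'
#' @param truth the `truth` element of [generate_cohort()].
#' @param dir output directory.
#' @return invisibly, the written paths.
#' @export
write_cohort_truth <- function(truth, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pp <- file.path(dir, "patients.csv")
  fp <- file.path(dir, "findings.csv")
  utils::write.csv(truth$patients, pp, row.names = FALSE)
  utils::write.csv(truth$findings, fp, row.names = FALSE)
  invisible(c(pp, fp))
}
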
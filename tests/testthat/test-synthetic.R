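test_that("generator config validates its probability fields", {
  expect_error(generator_config(trajectory_mix = c(increase = 0.5,
                                                   decrease = 0.5,
                                                   stable = 0.5,
                                                   resolved = 0)),
               "sum to 1")
  expect_error(generator_config(attribute_frequencies = c(location = 1.2)),
               "\\[0, 1\\]")
  expect_error(generator_config(notes_per_patient = integer(0)), "empty")
})

test_that("latent findings enforce lobe/laterality consistency", {
  expect_error(latent_finding("pure", lobe = "RUL", laterality = "left"),
               "implies laterality")
  expect_identical(latent_finding("pure", lobe = "LLL")$laterality, "left")
  expect_error(latent_finding("pure", size_mm = -3), "positive")
})

test_that("rendered notes carry span-exact gold annotations", {
  n <- fixture_note()
  e <- n$entities
  expect_gt(nrow(e), 5)
  expect_identical(substring(n$text, e$start + 1L, e$end), e$surface)
  expect_true("pure_ggo_term" %in% e$type)
  expect_true("ggo_location" %in% e$type)
})

test_that("a missing lexicon surface form is a generation error", {
  cfg <- generator_config()
  cfg$lexicon$pure_ggo_term <- character(0)
  set.seed(1)
  expect_error(render_note(list(latent_finding("pure")), cfg),
               "no surface form")
  expect_error(render_note(list(), generator_config()), "at least one")
})

test_that("gold annotations across a cohort are span-exact and schema-valid", {
  ch <- shared_cohort()
  for (note in ch$corpus) {
    e <- note$entities
    expect_identical(substring(note$text, e$start + 1L, e$end), e$surface)
    r <- note$relations
    if (nrow(r)) {
      ok <- mapply(function(h, t, ty)
        validate_relation(e$type[h], e$type[t], ty), r$head, r$tail, r$type)
      expect_true(all(ok))
    }
  }
})

test_that("the corpus is byte-identical under a fixed seed", {
  cfg <- generator_config(n_patients = 12, seed = 99)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_notes_jsonl(generate_cohort(cfg)$corpus, f1)
  write_notes_jsonl(generate_cohort(cfg)$corpus, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # and truth tables too
  t1 <- generate_cohort(cfg)$truth$patients
  t2 <- generate_cohort(cfg)$truth$patients
  expect_identical(t1, t2)
})

test_that("latent trajectory classes realize their definitions", {
  ch <- shared_cohort()
  tt <- ch$truth
  for (pid in tt$patients$patient_id) {
    p <- tt$patients[tt$patients$patient_id == pid, ]
    idx <- tt$findings[tt$findings$patient_id == pid & tt$findings$is_index, ]
    idx <- idx[order(idx$note_date), ]
    sizes <- idx$size_mm[!is.na(idx$size_mm)]
    if (p$trajectory_class == "stable" && p$n_notes >= 2)
      expect_true(all(sizes == sizes[1]))
    if (p$trajectory_class == "increase")
      expect_gt(sizes[length(sizes)], sizes[1])
    if (p$trajectory_class == "decrease")
      expect_lt(sizes[length(sizes)], sizes[1])
    if (p$trajectory_class == "resolved") {
      expect_identical(idx$status[nrow(idx)], "resolved")
      expect_true(is.na(idx$size_mm[nrow(idx)]))
      # the resolution note has no other active GGO finding
      last_note <- tt$findings[tt$findings$note_id == idx$note_id[nrow(idx)], ]
      expect_identical(nrow(last_note), 1L)
      note <- Filter(function(n) n$note_id == idx$note_id[nrow(idx)],
                     ch$corpus)[[1]]
      expect_match(note$text, "resolved|no longer seen")
    }
  }
})

test_that("both persistent and nonpersistent patients occur", {
  ch <- shared_cohort()
  expect_setequal(unique(ch$truth$patients$persistence),
                  c("persistent", "nonpersistent"))
})

test_that("empirical attribute frequencies match the configuration (3 SE)", {
  # stable-only mix so every finding sentence uses the attribute templates
  cfg <- generator_config(
    n_patients = 380, seed = 17,
    trajectory_mix = c(increase = 0, decrease = 0, stable = 1, resolved = 0))
  ch <- generate_cohort(cfg)
  expect_gte(length(ch$corpus), 1000)
  rel_frac <- function(reltype) {
    hits <- 0L; anchors <- 0L
    for (n in ch$corpus) {
      a <- which(n$entities$type %in% c("pure_ggo_term", "part_solid_ggo_term"))
      anchors <- anchors + length(a)
      if (nrow(n$relations))
        hits <- hits + length(unique(n$relations$head[
          n$relations$type == reltype]))
    }
    c(frac = hits / anchors, n = anchors)
  }
  checks <- c(has_location_info = "location", has_shape_margin_info = "shape",
              has_number_info = "quantity", has_potential_cause = "cause",
              has_solidity_info = "solidity")
  for (rt in names(checks)) {
    p0 <- cfg$attribute_frequencies[[checks[[rt]]]]
    obs <- rel_frac(rt)
    se <- sqrt(p0 * (1 - p0) / obs["n"])
    expect_lt(abs(obs["frac"] - p0), 3 * se,
              label = paste(rt, "frequency deviation"))
  }
})
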
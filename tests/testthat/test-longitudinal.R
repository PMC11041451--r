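mk_timeline <- function(specs, dx = as.Date(NA), pid = "P1") {
  # specs: list of list(date=, size=, status=, solidity=)
  rows <- lapply(seq_along(specs), function(i) {
    s <- specs[[i]]
    f <- empty_findings()[0, ]
    data.frame(patient_id = pid, note_id = paste0("n", i),
               note_date = as.Date(s$date), span_start = 0L,
               ggo_kind = "pure",
               size_mm = if (is.null(s$size)) NA_real_ else s$size,
               size_bin = if (is.null(s$size)) NA_character_
                          else bin_size(s$size),
               laterality = NA_character_, lobe = NA_character_,
               shape = NA_character_, quantity = NA_character_,
               quantity_n = NA_integer_,
               status = if (is.null(s$status)) NA_character_ else s$status,
               etiologies = "",
               solidity = if (is.null(s$solidity)) NA_character_
                          else s$solidity,
               compared_date = as.Date(NA), stringsAsFactors = FALSE)
  })
  findings <- do.call(rbind, rows)
  patients <- data.frame(patient_id = pid, diagnosis_date = dx)
  build_timelines(findings, patients)[[1]]
}

test_that("persistence follows the multi-report / resolution / worsen rules", {
  tl <- mk_timeline(list(list(date = "2019-01-01", status = "stable"),
                         list(date = "2019-06-01", status = "stable"),
                         list(date = "2019-12-01", status = "stable")))
  expect_identical(classify_persistence(tl), "persistent")
  tl2 <- mk_timeline(list(list(date = "2019-01-01"),
                          list(date = "2019-06-01", status = "resolved")))
  expect_identical(classify_persistence(tl2), "nonpersistent")
  tl3 <- mk_timeline(list(list(date = "2019-01-01", status = "worsen")))
  expect_identical(classify_persistence(tl3), "persistent")
  tl4 <- mk_timeline(list(list(date = "2019-01-01", status = "stable")))
  expect_identical(classify_persistence(tl4), "nonpersistent")
  # solidity-change wording on a single report also counts as worsening
  tl5 <- mk_timeline(list(list(date = "2019-01-01",
                               solidity = "increasing density")))
  expect_identical(classify_persistence(tl5), "persistent")
})

test_that("daily rollups take the largest size and the worst status", {
  expect_equal(rollup_daily_size(c(3, 12)), 12)
  expect_true(is.na(rollup_daily_size(numeric(0))))
  expect_identical(rollup_daily_status(c("stable", "worsen")), "worsen")
  expect_identical(rollup_daily_status(c("better", "stable")), "stable")
  expect_identical(rollup_daily_status("resolved"), "resolved")
  # resolved is reported only when it is the sole status that day
  expect_identical(rollup_daily_status(c("resolved", "stable")), "stable")
  expect_true(is.na(rollup_daily_status(character(0))))
})

test_that("rollups are order-invariant within a day", {
  set.seed(31)
  for (i in 1:25) {
    sizes <- runif(sample(2:6, 1), 1, 30)
    expect_equal(rollup_daily_size(sizes),
                 rollup_daily_size(sample(sizes)))
    sts <- sample(c("better", "stable", "worsen", "resolved"),
                  sample(2:5, 1), replace = TRUE)
    expect_identical(rollup_daily_status(sts),
                     rollup_daily_status(sample(sts)))
  }
})

test_that("size change compares first and last rolled-up sizes", {
  tl <- mk_timeline(list(list(date = "2019-01-01", size = 5),
                         list(date = "2019-06-01", size = 8)))
  expect_identical(size_change(tl), "increase")
  tl2 <- mk_timeline(list(list(date = "2019-01-01", size = 8),
                          list(date = "2019-06-01", size = 8)))
  expect_identical(size_change(tl2), "stable")
  tl3 <- mk_timeline(list(list(date = "2019-01-01", size = 8),
                          list(date = "2019-06-01", size = 5)))
  expect_identical(size_change(tl3), "decrease")
  # a single sized date is excluded
  tl4 <- mk_timeline(list(list(date = "2019-01-01", size = 8),
                          list(date = "2019-06-01")))
  expect_true(is.na(size_change(tl4)))
  # tolerance tau widens the "unchanged" band
  expect_identical(size_change(tl, tau = 5), "stable")
})

test_that("status outcomes follow the any-worsen / final-resolved rules", {
  seqs <- list(
    list(c("stable", "stable", "worsen"), "increased"),
    list(c("stable", "stable"), "stable"),
    list(c("stable", "better"), "decreased"),
    list(c("stable", "better", "resolved"), "resolved"),
    # worsen on the FIRST date is not "subsequent"; the follow-up resolves
    list(c("worsen", "resolved"), "resolved"),
    list(c("stable", "worsen", "resolved"), "increased"))
  for (s in seqs) {
    specs <- lapply(seq_along(s[[1]]), function(i)
      list(date = as.Date("2019-01-01") + 90 * i, status = s[[1]][i]))
    tr <- status_trajectory(mk_timeline(specs))
    expect_identical(tr$status_outcome, s[[2]], info = paste(s[[1]],
                                                             collapse = ","))
  }
  one <- mk_timeline(list(list(date = "2019-01-01", status = "stable")))
  expect_true(is.na(status_trajectory(one)$status_outcome))
})

test_that("pregroup stratification is strict and warns without a diagnosis", {
  tl <- mk_timeline(list(list(date = "2018-01-01")), dx = "2018-06-01")
  expect_true(stratify_pregroup(tl))
  tl2 <- mk_timeline(list(list(date = "2018-06-01")), dx = "2018-06-01")
  expect_false(stratify_pregroup(tl2))
  tl3 <- mk_timeline(list(list(date = "2018-06-01")))
  expect_warning(p <- stratify_pregroup(tl3), "missing diagnosis")
  expect_true(is.na(p))
})

test_that("interval bins partition 0..5000 days at the documented boundaries", {
  d0 <- as.Date("2015-01-01")
  expect_identical(interval_bin(d0, d0), "lt6mo")
  expect_identical(interval_bin(d0, d0 + 182), "lt6mo")
  expect_identical(interval_bin(d0, d0 + 183), "6mo_to_1yr")
  expect_identical(interval_bin(d0, d0 + 366), "1yr_to_3yr")
  expect_identical(interval_bin(d0, d0 + 1095), "1yr_to_3yr")
  expect_identical(interval_bin(d0, d0 + 1096), "gt3yr")
  expect_error(interval_bin(d0, d0 - 1), "negative interval")
  bins <- interval_bin(d0, d0 + 0:5000)
  expect_false(anyNA(bins))
  expect_identical(sort(unique(bins)),
                   sort(c("lt6mo", "6mo_to_1yr", "1yr_to_3yr", "gt3yr")))
  # each day maps to exactly one bin (vector output has one value per day)
  expect_length(bins, 5001L)
})

test_that("exclusive size group agrees with a brute-force bin-set oracle", {
  tl <- mk_timeline(list(list(date = "2019-01-01", size = 3)))
  expect_identical(exclusive_size_group(tl), "lt6")
  set.seed(33)
  for (i in 1:30) {
    sizes <- sample(c(NA, runif(3, 1, 30)), sample(1:4, 1), replace = TRUE)
    specs <- list()
    for (s in sizes)
      specs[[length(specs) + 1]] <-
        if (is.na(s)) list(date = "2019-01-01")
        else list(date = "2019-01-01", size = s)
    tl <- mk_timeline(specs)
    # oracle: set of bins among sized first-date findings
    bins <- unique(na.omit(vapply(sizes, function(s)
      if (is.na(s)) NA_character_ else bin_size(s), character(1))))
    want <- if (!length(bins)) NA_character_
            else if (length(bins) == 1) bins else "more_than_1"
    expect_identical(exclusive_size_group(tl), want)
  }
  tl2 <- mk_timeline(list(list(date = "2019-01-01", size = 3),
                          list(date = "2019-01-01", size = 12)))
  expect_identical(exclusive_size_group(tl2), "more_than_1")
})

test_that("trajectory classification is pure (re-running is identical)", {
  tl <- mk_timeline(list(list(date = "2019-01-01", size = 5, status = "stable"),
                         list(date = "2019-06-01", size = 9,
                              status = "worsen")))
  t1 <- status_trajectory(tl); t2 <- status_trajectory(tl)
  expect_identical(t1, t2)
  expect_identical(t1$persistence, "persistent")
  expect_identical(t1$size_change, "increase")
  expect_identical(t1$status_outcome, "increased")
})

test_that("cohort summary counts are conserved within each block", {
  ch <- shared_cohort()
  f <- findings_from_notes(ch$corpus)
  tls <- build_timelines(f, ch$truth$patients)
  summ <- cohort_summary(tls)
  for (block in c("location", "etiology", "size", "status", "shape",
                  "size_change", "status_outcome", "persistence")) {
    b <- summ[[block]]
    expect_true(all(b$n >= 0))
    if (sum(b$n) > 0)
      expect_equal(sum(b$pct), 100, tolerance = 0.3)
  }
  expect_identical(sum(summ$persistence$n), length(tls))
  # status transitions only use the first 10 notes and known statuses
  expect_true(all(summ$status_transitions$position <= 9))
})

test_that("cohort distributions recover the generated trajectory mix", {
  cfg <- generator_config(n_patients = 250, seed = 71)
  ch <- generate_cohort(cfg)
  f <- findings_from_notes(ch$corpus)
  tls <- build_timelines(f, ch$truth$patients)
  traj <- lapply(tls, status_trajectory)
  out <- vapply(traj, `[[`, character(1), "status_outcome")
  out <- out[!is.na(out)]
  # among multi-note patients the outcome equals the latent class; only the
  # stable class can draw a single note (probability 1/|range|), so condition
  # the configured mix on having >= 2 notes before comparing within 3 SE
  p0 <- cfg$trajectory_mix[["stable"]]
  p1 <- 1 / length(cfg$notes_per_patient)
  p_exp <- p0 * (1 - p1) / (1 - p0 * p1)
  p_hat <- mean(out == "stable")
  se <- sqrt(p_exp * (1 - p_exp) / length(out))
  expect_lt(abs(p_hat - p_exp), 3 * se)
  # pregroup fraction matches its configured probability
  pre <- vapply(tls, function(tl) suppressWarnings(stratify_pregroup(tl)),
                logical(1))
  p_pre <- mean(pre, na.rm = TRUE)
  se_pre <- sqrt(0.377 * (1 - 0.377) / length(pre))
  expect_lt(abs(p_pre - 0.377), 3 * se_pre)
})
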
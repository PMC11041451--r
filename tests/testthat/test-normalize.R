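test_that("sizes normalize to millimetres with max-dimension rule", {
  expect_equal(normalize_size("3 mm"), 3)
  expect_equal(normalize_size("1.2 cm"), 12)
  expect_equal(normalize_size("8 x 5 mm"), 8)
  expect_equal(normalize_size("5 x 8 mm"), 8)
  expect_equal(normalize_size("1,5 cm"), 15)
  expect_equal(normalize_size("3mm"), 3)
  expect_equal(normalize_size("2 millimeters"), 2)
  expect_true(is.na(normalize_size("tiny nodule")))
  expect_true(is.na(normalize_size("3 inches")))
})

test_that("size bins put 6 and 20 in the middle group", {
  expect_identical(bin_size(5.9), "lt6")
  expect_identical(bin_size(6), "6to20")
  expect_identical(bin_size(20), "6to20")
  expect_identical(bin_size(20.1), "gt20")
  expect_error(bin_size(0), "positive")
})

test_that("size bins partition a 0.1-mm grid consistently with an interval scan", {
  grid <- seq(0.1, 40, by = 0.1)
  got <- bin_size(grid)
  # oracle: direct interval arithmetic
  oracle <- ifelse(grid < 6, "lt6", ifelse(grid <= 20, "6to20", "gt20"))
  expect_identical(got, oracle)
  expect_true(all(table(got) > 0))
})

test_that("normalize_size feeding bin_size never contradicts itself", {
  for (s in c("4 mm", "0.5 cm", "2.1 cm", "15 x 12 mm", "21 mm")) {
    v <- normalize_size(s)
    expect_identical(bin_size(v),
                     if (v < 6) "lt6" else if (v <= 20) "6to20" else "gt20")
  }
})

test_that("locations map to two levels", {
  expect_identical(unname(normalize_location("right upper lobe")),
                   c("right", "RUL"))
  expect_identical(unname(normalize_location("RUL")), c("right", "RUL"))
  expect_identical(unname(normalize_location("the left lower lobe")),
                   c("left", "LLL"))
  expect_identical(unname(normalize_location("lingula")),
                   c("left", "unknown"))
  expect_identical(unname(normalize_location("both lungs")),
                   c("bilateral", "unknown"))
  expect_identical(unname(normalize_location("right apex")),
                   c("right", "unknown"))
  expect_identical(unname(normalize_location("")),
                   c("unknown", "unknown"))
})

test_that("etiologies triage into three subgroups with precancerous override", {
  expect_identical(normalize_etiology("cause_neoplasm", "adenocarcinoma"),
                   "malignant")
  expect_identical(normalize_etiology("cause_infectious_inflammatory",
                                      "pneumonia"),
                   "infectious_inflammatory")
  expect_identical(normalize_etiology("cause_hemorrhage", "hemorrhage"),
                   "other")
  expect_identical(normalize_etiology("cause_other_pulmonary", "fibrosis"),
                   "other")
  # precancerous conditions count as malignant whatever the subtype
  expect_identical(normalize_etiology("cause_other_pulmonary",
                                      "adenocarcinoma in situ"),
                   "malignant")
  expect_identical(normalize_etiology("cause_hemorrhage",
                                      "atypical adenomatous hyperplasia"),
                   "malignant")
  expect_error(normalize_etiology("ggo_size", "3 mm"), "not a cause")
})

test_that("quantities map concept words and integers", {
  expect_identical(normalize_quantity("several")$quantity, "multiple")
  expect_identical(normalize_quantity("numerous")$quantity, "multiple")
  expect_identical(normalize_quantity("3 nodules"),
                   list(quantity = "multiple", count = 3L))
  expect_identical(normalize_quantity("1"),
                   list(quantity = "single", count = 1L))
  expect_identical(normalize_quantity("solitary")$quantity, "single")
})

test_that("status normalization distinguishes resolution from improvement", {
  expect_identical(normalize_status("status_better", "decreased in size"),
                   "better")
  expect_identical(normalize_status("status_better", "resolved"), "resolved")
  expect_identical(normalize_status("status_better", "no longer seen"),
                   "resolved")
  expect_identical(normalize_status("status_worsen", "larger"), "worsen")
  expect_error(normalize_status("temporal", "2019"), "not a status")
})

test_that("temporal normalization resolves formats and nearest century", {
  expect_identical(normalize_temporal("2019-03-02"), as.Date("2019-03-02"))
  expect_identical(normalize_temporal("3/2/19", as.Date("2019-06-01")),
                   as.Date("2019-03-02"))
  expect_identical(normalize_temporal("3/2/98", as.Date("2001-06-01")),
                   as.Date("1998-03-02"))
  expect_identical(normalize_temporal("March 2, 2019"), as.Date("2019-03-02"))
  expect_warning(d <- normalize_temporal("last year"), "unparseable")
  expect_true(is.na(d))
})

test_that("normalizers are pure and idempotent", {
  expect_identical(normalize_size("1.2 cm"), normalize_size("1.2 cm"))
  l1 <- normalize_location("right upper lobe")
  expect_identical(normalize_location("right upper lobe"), l1)
})

test_that("findings assemble one record per anchor with linked attributes", {
  n <- fixture_note()
  f <- assemble_findings(n)
  expect_identical(nrow(f), 1L)
  expect_identical(f$ggo_kind, "pure")
  expect_equal(f$size_mm, 12)
  expect_identical(f$size_bin, "6to20")
  expect_identical(f$lobe, "RUL")
  expect_identical(f$laterality, "right")
  expect_identical(f$shape, "irregular_spiculated")
  expect_identical(f$quantity, "multiple")
  expect_identical(f$status, "stable")
  expect_identical(f$etiologies, "infectious_inflammatory")
  expect_identical(f$compared_date, as.Date("2019-03-02"))
})

test_that("a bare GGO mention yields a finding with unset attributes", {
  set.seed(2)
  n <- render_note(list(latent_finding("part_solid")), generator_config(),
                   "bare", "P1", as.Date("2020-05-05"))
  f <- assemble_findings(n)
  expect_identical(nrow(f), 1L)
  expect_identical(f$ggo_kind, "part_solid")
  expect_true(is.na(f$size_mm) && is.na(f$lobe) && is.na(f$status))
})

test_that("multi-anchor notes keep attributes disjoint per finding", {
  set.seed(4)
  cfg <- generator_config()
  n <- render_note(list(
    latent_finding("pure", size_mm = 3, lobe = "LUL", status = "stable"),
    latent_finding("part_solid", size_mm = 22, lobe = "RLL",
                   status = "worsen")), cfg, "m", "P1", as.Date("2020-01-01"))
  f <- assemble_findings(n)
  expect_identical(nrow(f), 2L)
  expect_identical(f$ggo_kind, c("pure", "part_solid"))
  expect_equal(f$size_mm, c(3, 22))
  expect_identical(f$lobe, c("LUL", "RLL"))
  expect_identical(f$status, c("stable", "worsen"))
})

test_that("gold-entity assembly recovers latent truth for >= 95% of findings", {
  ch <- shared_cohort()
  f <- findings_from_notes(ch$corpus)
  truth <- ch$truth$findings
  truth <- truth[order(truth$note_id, !truth$is_index), ]
  f <- f[order(f$note_id, f$span_start), ]
  # index finding renders first in each note, so order aligns within note
  expect_identical(nrow(f), nrow(truth))
  ok <- mapply(function(i, j) {
    a <- f[i, ]; b <- truth[j, ]
    size_ok <- (is.na(a$size_mm) && is.na(b$size_mm)) ||
      isTRUE(all.equal(a$size_mm, b$size_mm))
    eq <- function(x, y) (is.na(x) && is.na(y)) || identical(x, y)
    kind_ok <- identical(a$ggo_kind, b$ggo_kind)
    lobe_ok <- eq(a$lobe, b$lobe) ||
      (is.na(b$lobe) && identical(a$lobe, "unknown"))
    status_ok <- eq(a$status, b$status) ||
      (identical(b$status, "resolved") && identical(a$status, "resolved"))
    size_ok && kind_ok && lobe_ok && status_ok
  }, seq_len(nrow(f)), seq_len(nrow(truth)))
  expect_gte(mean(ok), 0.95)
})
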
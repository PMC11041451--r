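# Shared small fitted model for prediction/link tests (trained once).
tiny_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ch <- generate_cohort(generator_config(n_patients = 40, seed = 21))
      cache <<- ggo_tagger(ch$corpus, epochs = 25, batch_size = 8,
                           lr = 2e-3, seed = 21)
    }
    cache
  }
})

test_that("training memorizes a repeated template note (training F1 = 1)", {
  n <- fixture_note()
  corpus <- lapply(1:50, function(i) { n$note_id <- paste0("c", i); n })
  model <- ggo_tagger(corpus, epochs = 30, batch_size = 4, lr = 2e-3,
                      patience = 30, seed = 3)
  pred <- predict(model, corpus)
  sc <- score(pred, corpus)
  expect_equal(sc$f1[sc$semantic_type == "micro"], 1)
})

test_that("full-batch training loss is non-increasing on a tiny corpus", {
  ch <- generate_cohort(generator_config(n_patients = 6, seed = 8))
  model <- ggo_tagger(ch$corpus, epochs = 10, batch_size = 10000,
                      lr = 5e-4, patience = 10, seed = 8)
  expect_true(all(diff(model$history$loss) <= 1e-8))
})

test_that("training is reproducible bit-for-bit under a fixed seed", {
  ch <- generate_cohort(generator_config(n_patients = 10, seed = 5))
  m1 <- ggo_tagger(ch$corpus, epochs = 3, seed = 5)
  m2 <- ggo_tagger(ch$corpus, epochs = 3, seed = 5)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)
})

test_that("a corpus below 5 notes cannot be split", {
  ch <- generate_cohort(generator_config(n_patients = 1, seed = 5))
  expect_error(ggo_tagger(ch$corpus[1]), "at least 5 notes")
})

test_that("predictions recover GGO term and location spans", {
  model <- tiny_model()
  sp <- predict_entities(model,
                         "There is a ground-glass opacity in the right upper lobe.")
  expect_true(any(sp$type == "pure_ggo_term" &
                    sp$surface == "ground-glass opacity"))
  expect_true(any(sp$type == "ggo_location" &
                    sp$surface == "right upper lobe"))
  expect_identical(nrow(predict_entities(model, "")), 0L)
  # out-of-domain text never crashes
  sp2 <- predict_entities(model, "Quarterly revenue grew by seven percent.")
  expect_true(is.data.frame(sp2))
})

test_that("prediction is deterministic for fixed weights", {
  model <- tiny_model()
  txt <- shared_cohort()$corpus[[2]]$text
  expect_identical(predict_entities(model, txt), predict_entities(model, txt))
})

test_that("relation linking anchors attributes to the nearest GGO term", {
  txt <- "There is a ground-glass opacity, 3 mm, in the right upper lobe."
  span <- function(s) {
    i <- regexpr(s, txt, fixed = TRUE)
    c(start = i - 1L, end = i - 1L + attr(i, "match.length"))
  }
  sp <- rbind(span("ground-glass opacity"), span("3 mm"),
              span("right upper lobe"))
  e <- data.frame(start = sp[, 1], end = sp[, 2],
                  type = c("pure_ggo_term", "ggo_size", "ggo_location"))
  r <- link_relations(e, txt)
  expect_identical(nrow(r), 2L)
  expect_true(all(r$head == 1L))
  expect_setequal(r$type, c("has_size_info", "has_location_info"))

  # attributes with no same-sentence anchor stay unlinked
  e2 <- data.frame(start = 0L, end = 4L, type = "ggo_size")
  expect_identical(nrow(link_relations(e2, "3 mm seen.")), 0L)
})

test_that("two findings in one sentence link to their own anchors", {
  ch <- shared_cohort()
  # construct a two-anchor sentence via the generator's own templates
  set.seed(9)
  cfg <- generator_config()
  lat1 <- latent_finding("pure", size_mm = 4, lobe = "LUL")
  lat2 <- latent_finding("part_solid", size_mm = 11, lobe = "RLL")
  n <- render_note(list(lat1, lat2), cfg, "two", "P1", as.Date("2020-01-01"))
  r <- link_relations(n$entities, n$text)
  # every linked pair must agree with the gold relations
  key <- function(df) paste(df$head, df$tail, df$type)
  expect_setequal(key(r), key(n$relations))
})

test_that("the fitted model exposes the standard methods", {
  model <- tiny_model()
  expect_output(print(model), "Bi-LSTM-CRF")
  expect_s3_class(summary(model), "data.frame")
  tr <- coef(model)
  expect_identical(dim(tr), c(33L, 33L))
  expect_identical(rownames(tr)[1], "O")
  f <- withr::local_tempfile(fileext = ".png")
  grDevices::png(f); plot(model); grDevices::dev.off()
  expect_true(file.size(f) > 0)
})

test_that("held-out metrics on a moderate corpus are strong for frequent types", {
  model <- tiny_model()
  expect_gt(model$val_macro_f1, 0.5)  # small-corpus smoke; full bar in acceptance
  ch <- generate_cohort(generator_config(n_patients = 15, seed = 77))
  pred <- predict(model, ch$corpus)
  sc <- score(pred, ch$corpus)
  for (ty in c("pure_ggo_term", "ggo_size", "ggo_location")) {
    expect_gte(sc$precision[sc$semantic_type == ty], 0.85)
    expect_gte(sc$recall[sc$semantic_type == ty], 0.85)
  }
})
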
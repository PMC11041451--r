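# Shared oracles and fixtures, built in code at test time.

# Brute-force linear-chain CRF: enumerate all |L|^T label sequences.
# Independent of the package's forward/Viterbi implementations.
crf_brute <- function(em, tr) {
  T_ <- nrow(em); L <- ncol(em)
  grid <- as.matrix(expand.grid(rep(list(seq_len(L)), T_)))
  sc <- apply(grid, 1, function(y) {
    s <- tr[L + 1, y[1]] + em[1, y[1]]
    if (T_ >= 2) for (t in 2:T_) s <- s + tr[y[t - 1], y[t]] + em[t, y[t]]
    s + tr[y[T_], L + 2]
  })
  mx <- max(sc)
  list(logZ = mx + log(sum(exp(sc - mx))),
       best_score = mx,
       best_path = as.integer(grid[which.max(sc), ]))
}

random_crf_instance <- function(max_len = 4, max_labels = 4) {
  T_ <- sample(seq_len(max_len), 1)
  L <- sample(seq_len(max_labels), 1)
  list(em = matrix(stats::rnorm(T_ * L), T_, L),
       tr = matrix(stats::rnorm((L + 2)^2), L + 2, L + 2))
}

# Small shared cohort so the many tests that need notes don't regenerate.
shared_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_cohort(generator_config(n_patients = 60, seed = 303))
    cache
  }
})

# A note with one fully attributed finding, fixed RNG, for IO/normalize tests.
fixture_note <- function(seed = 5, note_id = "note1", patient_id = "P1",
                         note_date = as.Date("2019-06-01")) {
  set.seed(seed)
  lat <- latent_finding("pure", size_mm = 12, lobe = "RUL",
                        shape = "irregular_spiculated", quantity = "multiple",
                        etiologies = "infectious_inflammatory",
                        status = "stable", solidity = TRUE,
                        prior_date = as.Date("2019-03-02"))
  render_note(list(lat), generator_config(), note_id, patient_id, note_date)
}
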
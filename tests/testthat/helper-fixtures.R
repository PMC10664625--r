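# Small shared fixtures, generated in code. Memoised so expensive objects
# are built once per test run.

.fix <- new.env()

memo <- function(key, make) {
  if (is.null(.fix[[key]])) .fix[[key]] <- make()
  .fix[[key]]
}

tiny_cohort <- function() {
  memo("tiny_cohort", function() {
    generate_cohort(phantom_config(
      n_patients = 4, class_counts = c(`1` = 2, `5` = 2), seed = 11))
  })
}

tiny_stack <- function() {
  memo("tiny_stack", function() build_flavor_stack(tiny_cohort()[[1]]))
}

random_image <- function(seed = 1, n = 60) {
  withr::with_seed(seed, matrix(stats::runif(n * n), n))
}
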
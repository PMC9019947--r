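# Shared small fixtures. Networks in tests are deliberately narrow so the
# whole suite trains in seconds; the architecture code is identical to the
# full-width default.

tiny_spec <- function(d, sizes = c(16L, 8L)) network_spec(d, sizes)

tiny_config <- function(...) {
  args <- utils::modifyList(
    list(alpha = 0.3, n_clusters = 3L, pretrain_epochs = 5L,
         joint_epochs = 4L, batch_size = 32L, seed = 42L),
    list(...))
  do.call(training_config, args)
}

small_cohort <- function(n = 200L, seed = 11L, ...) {
  generate_cohort(synthetic_spec(n_patients = n, vocab_size = 60L,
                                 signature_size = 5L, events_mean = 25,
                                 seed = seed, ...))
}

cohort_groups <- function(cohort, fm) {
  cohort$labels$group[match(fm$row_ids, cohort$labels$patient_id)]
}

random_embedding <- function(n, v, K, spread = 4) {
  centers <- matrix(rnorm(K * v, sd = spread), K, v)
  labels <- sample.int(K, n, replace = TRUE)
  list(Z = centers[labels, , drop = FALSE] + matrix(rnorm(n * v), n, v),
       true = labels)
}
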
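# Shared fixture builders. Everything is generated in code at test time;
# sizes are desk-scale (see the methods vignette for the test design).

# two-class cohort with a strong planted posterior gamma marker on O1+P3
high_snr_signatures <- function(amp = 20) {
  list(NC = class_signature("NC", list()),
       SZ = class_signature("SZ", list(
         signature_component(c("O1", "P3"), freq = 40, bandwidth = 4,
                             amplitude = amp))))
}

make_separable_cohort <- function(n_per_class = 8, duration = 8, seed = 101,
                                  amp = 20) {
  recs <- simulate_cohort(stats::setNames(c(n_per_class, n_per_class),
                                          c("NC", "SZ")),
                          duration = duration,
                          signatures = high_snr_signatures(amp),
                          seed = seed)
  preprocess_cohort(recs)
}

# the desk-scale training regime used by the heavier tests: the study's
# optimizer and schedule, with batch size and epoch budget reduced to the
# small synthetic cohorts
desk_tspec <- function(seed = 9, max_epochs = 100, patience = 25,
                       batch_size = 16) {
  train_spec(batch_size = batch_size, max_epochs = max_epochs,
             patience = patience, seed = seed)
}

# tiny epoch set with direct array construction (no simulator) for fast
# mechanical tests
tiny_epoch_set <- function(n_subjects = 4, epochs_per_subject = 3,
                           classes = c("NC", "SZ"), seed = 1) {
  set.seed(seed)
  n <- n_subjects * epochs_per_subject
  lab <- rep(rep_len(classes, n_subjects), each = epochs_per_subject)
  subj <- rep(sprintf("%s-%03d", rep_len(classes, n_subjects),
                      seq_len(n_subjects)), each = epochs_per_subject)
  epoch_set(array(rnorm(n * 64 * 250), c(n, 64, 250)), subj, lab)
}
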
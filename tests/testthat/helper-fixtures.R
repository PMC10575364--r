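# Shared fixtures, built in code at test time.
#
# The trained quality model is expensive (about a minute of CPU), so it is
# trained lazily once per test run and shared by every test that needs a
# trained model: a synthetic corpus of 20 subjects with mixed artifacts,
# subject-wise split, fixed seed.

.fixture_cache <- new.env(parent = emptyenv())

sqa_fixture <- function() {
  if (is.null(.fixture_cache$model)) {
    corpus <- sqa_corpus(n_subjects = 20, duration = 240, seed = 402)
    model <- train_sqa(build_sqa(seed = 7), corpus,
                       train_config(epochs = 40, seed = 7))
    .fixture_cache$corpus <- corpus
    .fixture_cache$model <- model
  }
  list(model = .fixture_cache$model, corpus = .fixture_cache$corpus)
}

# a clean rendered recording with its ground truth, small enough for fast
# per-test use
clean_recording <- function(mean_hr = 70, jitter_sd = 20, duration = 180,
                            fs = 100, seed = 11) {
  sp <- simulation_spec(mean_hr = mean_hr, jitter_sd = jitter_sd,
                        duration = duration, fs = fs, seed = seed)
  ibi <- generate_ibi_series(sp)
  list(spec = sp, ibi = ibi, record = render_ppg(ibi, fs, sp$template))
}

# end-to-end interval estimate from a record
estimate_ibi <- function(rec) {
  ibi_from_beats(detect_beats(bandpass(rec)), rec$fs,
                 duration = record_duration(rec))
}
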
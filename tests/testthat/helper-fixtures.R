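# Shared fixtures, built once per test run. Synthetic recordings use a
# 4 kHz rate: the envelope and STMHT windows are time constants (50 ms,
# ~1 s) and scale with fs, and everything in the 20-700 Hz heart-sound
# band is representable.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# a segmented murmur-free recording plus its ground truth
nm_segmented <- function() {
  fixture("nm_segmented", function() {
    rec <- generate_recording(cycle_spec(fs = 4000), n_cycles = 10, seed = 7)
    seg <- segment_recording(preprocess_trace(rec$trace))
    list(rec = rec, seg = seg)
  })
}

# feature matrices per class for the trained-pipeline tests
preset_features <- function(seeds, fs = 4000, n_cycles = 8) {
  presets <- class_presets(fs = fs)
  out <- lapply(names(presets), function(nm) {
    lapply(seeds, function(s) {
      rec <- generate_recording(presets[[nm]], n_cycles, seed = s)
      seg <- segment_recording(preprocess_trace(rec$trace))
      cycles_features(seg$cycles)
    })
  })
  names(out) <- names(presets)
  out
}
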
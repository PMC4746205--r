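# Heavy phantom sweeps used by the acceptance tests, computed once per run.
#
# Both sweeps use the study conditions: 64x64x64 grid at 4.42 mm voxels,
# 16 frames, 10 mm end-diastolic wall, 12 mm FWHM blur, no noise.

.sweep_cache <- new.env(parent = emptyenv())

# average-denominator percent difference, as used for the volume comparisons
pct_diff <- function(measured, truth) (measured - truth) / ((measured + truth) / 2) * 100

.run_sweep <- function(size_grid, seed) {
  common <- phantom_spec(120, 48, total_counts = 0)
  studies <- sweep_phantoms(size_grid, common, seed = seed)
  params <- edge_params()
  rows <- lapply(seq_along(studies), function(i) {
    eng <- lvquant:::.quantify_engine(studies[[i]], params)
    tr <- phantom_truth(studies[[i]])
    ff <- lvquant:::.lv_function(eng$vol_fixed)
    fc <- lvquant:::.lv_function(eng$vol_corrected)
    data.frame(edv_true = tr$edv, esv_true = tr$esv, ef_true = tr$ef,
               edv_fixed = ff$edv, esv_fixed = ff$esv, ef_fixed = ff$ef,
               edv_corrected = fc$edv, esv_corrected = fc$esv,
               ef_corrected = fc$ef, shift_mm = eng$shift_mm,
               small_fixed = ff$small_heart, small_corrected = fc$small_heart)
  })
  do.call(rbind, rows)
}

# eight sizes at fixed 60% ejection fraction (the small-heart size sweep)
size_sweep_records <- function() {
  if (is.null(.sweep_cache$size)) {
    esv <- c(10, 15, 20, 30, 45, 60, 80, 100)
    .sweep_cache$size <- .run_sweep(data.frame(edv = esv / 0.4, esv = esv),
                                    seed = 1)
  }
  .sweep_cache$size
}

# cohort-like grid where size and ejection fraction anti-correlate (small
# hearts have high EF, as in clinical populations rich in small hearts);
# this exposes the EF-dependent overestimation and the effect of the
# volume-dependent correction on it
ef_sweep_records <- function() {
  if (is.null(.sweep_cache$ef)) {
    edv <- c(90, 75, 60, 50, 40, 32)
    ef <- c(45, 50, 55, 60, 65, 70)
    .sweep_cache$ef <- .run_sweep(data.frame(edv = edv,
                                             esv = edv * (1 - ef / 100)),
                                  seed = 2)
  }
  .sweep_cache$ef
}
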
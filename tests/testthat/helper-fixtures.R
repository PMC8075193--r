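# Small fixtures shared across test files. Everything is built in code.

# A short design whose plateau and rest phases are fully developed: blocks are
# longer than the 32 s HRF kernel, so h(t) is exactly 1 well inside a block
# and exactly 0 well inside rest.
long_block_design <- function(n_blocks = 2, tr = 1) {
  make_block_design(lead_in = 40, n_blocks = n_blocks, on_duration = 60,
                    off_duration = 80, tr = tr,
                    n_volumes = ceiling((40 + n_blocks * 140 + 10) / tr))
}

# Flat (depth-constant) truth for signal-separation tests.
flat_truth <- function(n_depths = 3, baseline = 100, perfusion = 2,
                       bold_amplitude = 0, perfusion_amplitude = 0,
                       drift_slope = 0, noise_sd = 0) {
  laminar_truth(baseline_signal = rep(baseline, n_depths),
                baseline_perfusion = rep(perfusion, n_depths),
                bold_amplitude = bold_amplitude,
                perfusion_amplitude = perfusion_amplitude,
                drift_slope = drift_slope, noise_sd = noise_sd)
}

# Alternating parity starting at `first`.
alt_parity <- function(n, first = "control") {
  rep(if (first == "control") c("control", "label") else c("label", "control"),
      length.out = n)
}

# Volume indices (1-based) whose HRF envelope is exactly at plateau (h = 1)
# or exactly at rest (h = 0), with a one-volume guard on each side so the
# three-point surround operators see a locally constant envelope.
envelope_interior <- function(design, level = 1) {
  h <- hrf_envelope(design)
  idx <- which(abs(h - level) < 1e-12)
  idx[idx > 1 & idx < length(h) &
        abs(h[pmax(idx - 1, 1)] - level) < 1e-12 &
        abs(h[pmin(idx + 1, length(h))] - level) < 1e-12]
}
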
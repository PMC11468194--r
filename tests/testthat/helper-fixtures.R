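# Shared fixtures, memoised so expensive phantoms are built once per run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, .fixture_cache)) assign(key, builder(), .fixture_cache)
  get(key, .fixture_cache)
}

# small quiet phantom: no motion, modest noise
quiet_phantom <- function() memo("quiet", function()
  make_phantom(list(n_volumes = 20, motion_amp = 0, noise_pct = 0.5),
               seed = 101))

# noiseless static phantom (geometry / masking tests)
static_phantom <- function() memo("static", function()
  make_phantom(list(n_volumes = 12, motion_amp = 0, noise_pct = 0,
                    drift_pct = 0), seed = 102))

# single 3D brain-like image + grid
static_image <- function() {
  ph <- static_phantom()
  list(img = ph$data$data[, , , 1], grid = ph$data$grid,
       mask = ph$truth$brain_mask)
}

rms <- function(x) sqrt(mean(x^2))
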
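# Shared builders for small, fast synthetic scenes. All fixtures are
# generated in code; nothing is read from disk.

# Standard two-channel stalling schedule (PCNA-like decay + RPA1-like
# rise) with a shortened time axis unless stated otherwise.
hu_schedule <- function(t_treat = 15, t_washout = NA, t_end = 75) {
  kinetic_schedule(default_channels("HU"), t_treat = t_treat,
                   t_washout = t_washout, t_end = t_end)
}

# Small nucleus that still leaves room for three foci-free regions.
small_geometry <- function(dim = c(96L, 96L), n_foci = 8L, seed = 3L, ...) {
  scene_geometry(dim = dim, n_foci = n_foci, seed = seed, ...)
}

quiet_optics <- function(seed = 5L, ...) {
  optics_noise(photon_scale = 0, read_sigma = 0, seed = seed, ...)
}

noisy_optics <- function(seed = 5L, ...) optics_noise(seed = seed, ...)

# One noise-free rendered movie reused by several test files.
noise_free_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      geo <- small_geometry(dim = c(128L, 128L), n_foci = 14L)
      cache <<- list(sim = render_movie(hu_schedule(), geo, quiet_optics()),
                     geometry = geo)
    }
    cache
  }
})
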
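# shared fixtures: small, seeded simulations reused across test files

quiet_cetm <- function(...) {
  suppressWarnings(simulate_cetm(simulation_config(...)))
}

quiet_assess <- function(recording, ...) {
  suppressMessages(assess_depth(recording, ...))
}

# a noiseless CETM recording with default geometry, cached per session
noiseless_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- quiet_cetm(noise_sd_mmHg = 0, wander_amp_mmHg = 0, seed = 101)
    }
    cache
  }
})

noiseless_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- quiet_assess(noiseless_sim()$recording)
    cache
  }
})

# a default-noise CETM recording (1 mmHg noise, 3 mmHg wander)
noisy_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- quiet_cetm(seed = 202)
    cache
  }
})

# synthetic envelope helper for index-level tests
make_envelope <- function(sd, cp, amp, protocol = "cetm",
                          sd_contact = 0) {
  structure(data.frame(sd_mm = sd, cp_mmHg = cp, amplitude_mmHg = amp),
            class = c("amplitude_envelope", "data.frame"),
            protocol = protocol,
            cp_min_mmHg = min(cp), cp_max_mmHg = max(cp),
            sd_contact_mm = sd_contact, fs_hz = 200)
}
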
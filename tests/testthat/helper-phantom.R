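# Shared phantom fixtures, generated once per test run.

.ph_cache <- new.env(parent = emptyenv())

noiseless_spec <- function(n_frames = 220)
  phantom_spec(n_frames = n_frames,
               noise_sd = list(aorta = 0, segmental = 0,
                               vertebra = 0, background = 0))

get_phantom <- function(noiseless = TRUE, n_frames = 220, seed = 1) {
  key <- paste(noiseless, n_frames, seed)
  if (is.null(.ph_cache[[key]])) {
    spec <- if (noiseless) noiseless_spec(n_frames)
            else phantom_spec(n_frames = n_frames, seed = seed)
    .ph_cache[[key]] <- generate_phantom(spec)
  }
  .ph_cache[[key]]
}

# smooth second-pass-free plasma template for simulation tests
sim_template_cp <- function(ph = get_phantom()) {
  blood_to_plasma(ph$truth$aorta_cb_first_pass, ph$spec$hct)
}
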
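# Small geometries used across tests. The tiny config keeps every dynamic
# of the default generator (hazard, growth, jitter) but shrinks each record
# to 20,000 samples so unit tests run in milliseconds.
tiny_config <- function(...) {
  desk_config(record_duration = 0.005, ...)
}

# a record containing only the given class amplitudes (no noise floor)
pure_record <- function(config, amplitudes, seed = 1, intensity = 21980) {
  withr::with_seed(seed, {
    generate_pcd_record(config, 0, intensity, amplitudes = amplitudes)
  })
}

zero_amps <- c(low_frequency = 0, broadband = 0, subharmonic = 0)

amps <- function(low_frequency = 0, broadband = 0, subharmonic = 0) {
  c(low_frequency = low_frequency, broadband = broadband,
    subharmonic = subharmonic)
}
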
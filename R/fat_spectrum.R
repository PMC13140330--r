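#' Multi-peak fat spectrum
#'
#' Chemical-shift spectrum of triglyceride protons used by both the signal
#' generator and the water-fat separation, as relative amplitudes and
#' frequency offsets from water. Amplitudes are normalised to sum to 1.
#'
#' @param ppm chemical shifts of the fat peaks in ppm.
#' @param amplitude relative amplitudes (normalised internally).
#' @param field_mhz proton Larmor frequency in MHz (127.73 at 3 T); sets the
#'   Hz-per-ppm conversion.
#' @param water_ppm water resonance, default 4.7 ppm.
#' @return A tibble with columns `ppm`, `amplitude`, `freq_hz` (offset from
#'   water, negative for the methylene main peak).
#' @export
fat_spectrum <- function(ppm, amplitude, field_mhz = 127.73, water_ppm = 4.7) {
  stopifnot(length(ppm) == length(amplitude), length(ppm) >= 1,
            all(amplitude >= 0), sum(amplitude) > 0)
  amplitude <- amplitude / sum(amplitude)
  tibble::tibble(ppm = ppm, amplitude = amplitude,
                 freq_hz = (ppm - water_ppm) * field_mhz)
}

#' Default 8-peak triglyceride spectrum
#'
#' Standard subcutaneous-fat triglyceride model (methyl through olefinic
#' protons). The same table is the generator default and the separation
#' default, so model-matched simulations recover fat fractions exactly.
#'
#' @inheritParams fat_spectrum
#' @export
default_fat_spectrum <- function(field_mhz = 127.73) {
  fat_spectrum(
    ppm = c(0.90, 1.30, 1.60, 2.02, 2.24, 2.75, 4.20, 5.29),
    amplitude = c(0.088, 0.642, 0.058, 0.062, 0.058, 0.006, 0.039, 0.047),
    field_mhz = field_mhz
  )
}

# complex fat phasor at echo times te (seconds): sum_p a_p exp(i 2 pi f_p te)
fat_phasor <- function(spectrum, te_s) {
  vapply(te_s, function(t) sum(spectrum$amplitude * exp(2i * pi * spectrum$freq_hz * t)),
         complex(1))
}
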
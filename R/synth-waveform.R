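#' Synthesise a tone-evoked cochlear waveform
#'
#' Ground-truth generator for evoked-potential analysis: a sustained
#' baseline deviation (summating potential, DC) plus an AC component at
#' the stimulus frequency (cochlear microphonic) and Gaussian noise:
#' `w(t) = dc + ac * sin(2*pi*f*t + phase) + noise`.
#'
#' @param frequency stimulus frequency, Hz
#' @param ac_amplitude uV
#' @param dc_offset uV
#' @param noise_sd uV
#' @param duration s
#' @param rate sampling rate, Hz (> 2x `frequency`)
#' @param phase radians
#' @param seed integer RNG seed
#' @return list with `waveform` (uV), `time` (s), `rate`, and `truth`
#'   (`ac_amplitude`, `dc_offset`, `phase`, `frequency`, `noise_sd`)
#' @export
#' @examples
#' w <- synth_evoked_waveform(200, ac_amplitude = 50, dc_offset = 10,
#'                            noise_sd = 0, duration = 0.1, rate = 1e4)
#' cm_component(w$waveform, w$rate, 200)$amplitude   # 50
synth_evoked_waveform <- function(frequency, ac_amplitude = 50,
                                  dc_offset = 10, noise_sd = 1,
                                  duration = 0.1, rate = 1e4,
                                  phase = 0, seed = 1L) {
  if (rate <= 2 * frequency)
    stop("sampling rate must exceed twice the stimulus frequency")
  set.seed(seed)
  t <- seq(0, duration - 1 / rate, by = 1 / rate)
  w <- dc_offset + ac_amplitude * sin(2 * pi * frequency * t + phase) +
    rnorm(length(t), sd = noise_sd)
  list(waveform = w, time = t, rate = rate,
       truth = list(ac_amplitude = ac_amplitude, dc_offset = dc_offset,
                    phase = phase, frequency = frequency,
                    noise_sd = noise_sd, seed = seed))
}
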
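#' Optogenetic stimulation protocol
#'
#' A pulse train of short light pulses, as used to drive CsChrimson-expressing
#' presynaptic neurons: trains of 1, 5, 10, 20 or 30 pulses delivered at 30 Hz,
#' each pulse 2 ms long, starting at `onset_time` seconds into a repeat.
#'
#' @param n_pulses number of pulses (>= 1); the screen uses 1, 5, 10, 20, 30.
#' @param pulse_rate pulse repetition rate in Hz.
#' @param pulse_duration single-pulse duration in seconds.
#' @param onset_time train onset relative to the start of the repeat, seconds.
#' @return an object of class `cx_protocol`.
#' @examples
#' p <- stim_protocol(20)
#' train_duration(p)  # (20 - 1)/30 + 0.002
#' @export
stim_protocol <- function(n_pulses, pulse_rate = 30, pulse_duration = 0.002,
                          onset_time = 5) {
  stopifnot(length(n_pulses) == 1L, n_pulses >= 1, n_pulses == round(n_pulses),
            pulse_rate > 0, pulse_duration > 0, onset_time >= 0)
  structure(list(n_pulses = as.integer(n_pulses), pulse_rate = pulse_rate,
                 pulse_duration = pulse_duration, onset_time = onset_time),
            class = "cx_protocol")
}

#' Total duration of a pulse train
#'
#' `(n_pulses - 1) / pulse_rate + pulse_duration` seconds.
#' @param protocol a [stim_protocol()].
#' @export
train_duration <- function(protocol) {
  (protocol$n_pulses - 1) / protocol$pulse_rate + protocol$pulse_duration
}

#' The five stimulation strengths of the screen
#'
#' @param n_pulses pulse counts to include.
#' @param ... passed to [stim_protocol()].
#' @return list of `cx_protocol` objects.
#' @export
default_protocols <- function(n_pulses = c(1, 5, 10, 20, 30), ...) {
  lapply(n_pulses, stim_protocol, ...)
}

#' Sample a pulse train as a binary stimulus vector
#'
#' Renders the protocol on a regular time grid. Each pulse must occupy at
#' least one sample and be separated from its neighbours by at least one
#' zero sample, so that the vector has exactly `n_pulses` rising edges;
#' otherwise the sampling rate undersamples the train and an error is raised.
#'
#' @param protocol a [stim_protocol()].
#' @param sampling_rate grid rate in Hz.
#' @param duration total vector duration in seconds.
#' @return integer vector of 0/1 of length `round(duration * sampling_rate)`.
#' @export
make_pulse_train <- function(protocol, sampling_rate, duration) {
  stopifnot(inherits(protocol, "cx_protocol"), sampling_rate > 0, duration > 0)
  tl <- train_duration(protocol)
  if (protocol$onset_time + tl >= duration)
    stop(sprintf(
      "pulse train (onset %.3f s + train %.3f s) overflows the %.3f s repeat",
      protocol$onset_time, tl, duration))
  n <- round(duration * sampling_rate)
  starts <- protocol$onset_time + (seq_len(protocol$n_pulses) - 1) / protocol$pulse_rate
  s0 <- floor(starts * sampling_rate)
  s1 <- pmax(s0, ceiling((starts + protocol$pulse_duration) * sampling_rate) - 1)
  if (protocol$n_pulses > 1L && any(s0[-1] <= s1[-length(s1)] + 1L))
    stop(sprintf(
      "sampling rate %g Hz undersamples a %g Hz pulse train: pulses merge (pulse spacing %.4f s vs sampling interval %.4f s)",
      sampling_rate, protocol$pulse_rate, 1 / protocol$pulse_rate, 1 / sampling_rate))
  v <- integer(n)
  for (j in seq_len(protocol$n_pulses)) v[(s0[j]:min(s1[j], n - 1L)) + 1L] <- 1L
  v
}
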
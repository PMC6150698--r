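#' Phenomenological response class of a cell-type pair
#'
#' Describes the postsynaptic calcium response evoked by presynaptic
#' stimulation, in the taxonomy observed across the screen: strong or weak
#' excitation, inhibition visible as a dip from an elevated baseline,
#' post-stimulation rebound, or no response. The model is a per-pulse
#' difference-of-exponentials kernel summed over the pulse train, gated per
#' repeat by a Bernoulli reliability draw, on top of a slowly fluctuating
#' baseline (the preparation's spontaneous "brain state") and white noise.
#'
#' @param kind one of `"strong_excitation"`, `"weak_excitation"`,
#'   `"inhibition"`, `"rebound"`, `"none"`.
#' @param peak_amplitude signed peak response in dF/F0 units. Negative for
#'   inhibition. Defaults depend on `kind`.
#' @param rise_tau,decay_tau kernel time constants, seconds.
#' @param reliability probability that a given repeat responds at all.
#' @param baseline_level tonic dF/F0 level; inhibition requires a positive
#'   level, since a dip is only visible from an excited state.
#' @param baseline_drift_sd standard deviation of the slow baseline drift
#'   (random walk rescaled to this marginal sd), dF/F0 units.
#' @param noise_sd white (shot-like) noise sd, dF/F0 units.
#' @return an object of class `cx_response_class`.
#' @export
response_class <- function(kind = c("strong_excitation", "weak_excitation",
                                    "inhibition", "rebound", "none"),
                           peak_amplitude = NULL, rise_tau = 0.15,
                           decay_tau = 1.0, reliability = NULL,
                           baseline_level = NULL, baseline_drift_sd = 0.05,
                           noise_sd = 0.05) {
  kind <- match.arg(kind)
  defaults <- list(
    strong_excitation = list(amp = 1.2,  rel = 0.9, base = 0),
    weak_excitation   = list(amp = 0.3,  rel = 0.6, base = 0),
    inhibition        = list(amp = -0.8, rel = 0.9, base = 1.0),
    rebound           = list(amp = 0.8,  rel = 0.8, base = 0),
    none              = list(amp = 0,    rel = 1.0, base = 0))[[kind]]
  peak_amplitude <- peak_amplitude %||% defaults$amp
  reliability <- reliability %||% defaults$rel
  baseline_level <- baseline_level %||% defaults$base
  stopifnot(rise_tau > 0, decay_tau > 0,
            reliability >= 0, reliability <= 1,
            baseline_drift_sd >= 0, noise_sd >= 0)
  if (kind == "inhibition" && baseline_level <= 0)
    stop("inhibition requires baseline_level > 0: a dip is only visible from an excited state")
  if (kind == "inhibition" && peak_amplitude >= 0)
    stop("inhibition requires a negative peak_amplitude")
  structure(list(kind = kind, peak_amplitude = peak_amplitude,
                 rise_tau = rise_tau, decay_tau = decay_tau,
                 reliability = reliability, baseline_level = baseline_level,
                 baseline_drift_sd = baseline_drift_sd, noise_sd = noise_sd),
            class = "cx_response_class")
}

# Difference-of-exponentials kernel, normalized to unit peak, evaluated at t >= 0.
doe_kernel <- function(t, rise_tau, decay_tau) {
  if (abs(decay_tau - rise_tau) < 1e-12) rise_tau <- rise_tau * (1 - 1e-6)
  raw <- function(u) ifelse(u > 0, exp(-u / decay_tau) - exp(-u / rise_tau), 0)
  tpk <- log(decay_tau / rise_tau) * rise_tau * decay_tau / (decay_tau - rise_tau)
  raw(t) / raw(tpk)
}

#' Deterministic response waveform of a class under a protocol
#'
#' The per-pulse kernel is summed linearly over the pulse train and the sum is
#' normalized to unit peak, so the noiseless evoked extremum equals
#' `peak_amplitude` for every protocol. With a finite `saturation` ceiling the
#' linear per-pulse sum is instead passed through a soft `tanh` ceiling,
#' giving saturating summation at strong stimulation.
#'
#' Rebound classes respond with a positive kernel starting one `decay_tau`
#' after train offset rather than during the train.
#'
#' @param cls a [response_class()].
#' @param protocol a [stim_protocol()].
#' @param time sample times in seconds.
#' @param saturation optional soft amplitude ceiling (dF/F0); `NULL` for the
#'   protocol-normalized response.
#' @return numeric waveform (no baseline, no noise).
#' @export
response_waveform <- function(cls, protocol, time, saturation = NULL) {
  if (cls$kind == "none" || cls$peak_amplitude == 0) return(numeric(length(time)))
  starts <- protocol$onset_time +
    (seq_len(protocol$n_pulses) - 1) / protocol$pulse_rate
  if (cls$kind == "rebound")
    starts <- max(starts) + protocol$pulse_duration + cls$decay_tau
  s <- numeric(length(time))
  for (t0 in starts) s <- s + doe_kernel(time - t0, cls$rise_tau, cls$decay_tau)
  if (max(s) <= 0) return(numeric(length(time)))
  if (is.null(saturation)) {
    cls$peak_amplitude * s / max(s)
  } else {
    stopifnot(saturation > 0)
    sign(cls$peak_amplitude) * saturation *
      tanh(abs(cls$peak_amplitude) * s / saturation)
  }
}

#' Simulate one experimental repeat
#'
#' One ~16 s dF/F0 time series: tonic baseline + slow drift + (reliability-
#' gated) evoked response + white noise. All randomness is fixed by `seed`.
#'
#' @inheritParams response_waveform
#' @param sampling_rate imaging rate, Hz.
#' @param duration repeat length, seconds.
#' @param seed integer seed fixing the repeat's randomness.
#' @return list with `time`, `values`, `responded` (logical), `protocol`, `class`.
#' @export
simulate_repeat <- function(cls, protocol, sampling_rate = 10, duration = 16,
                            seed = 1, saturation = NULL) {
  stopifnot(inherits(cls, "cx_response_class"), inherits(protocol, "cx_protocol"),
            sampling_rate > 0, duration > 0)
  if (protocol$onset_time + train_duration(protocol) >= duration)
    stop("protocol overflows the repeat duration")
  n <- round(duration * sampling_rate)
  time <- (seq_len(n) - 1) / sampling_rate
  with_seed(seed, {
    responded <- stats::runif(1) < cls$reliability
    drift <- numeric(n)
    if (cls$baseline_drift_sd > 0) {
      rw <- cumsum(stats::rnorm(n))
      rw <- rw - mean(rw)
      s <- stats::sd(rw)
      if (s > 0) drift <- rw / s * cls$baseline_drift_sd
    }
    resp <- if (responded) response_waveform(cls, protocol, time, saturation)
            else numeric(n)
    noise <- if (cls$noise_sd > 0) stats::rnorm(n, 0, cls$noise_sd) else numeric(n)
    list(time = time, values = cls$baseline_level + drift + resp + noise,
         responded = responded, protocol = protocol, class = cls)
  })
}

#' Ground-truth connectome for a synthetic screen
#'
#' @param cell_types character vector of cell-type names (long-name grammar).
#' @param pairs data.frame with columns `pre`, `post` and a `class` list-column
#'   of [response_class()] objects (or a character `kind` column, converted
#'   with class defaults).
#' @param overlap_labels optional logical vector per pair; if missing, labels
#'   are derived from the type names with [overlap_label()]. Every planted
#'   pair with `kind != "none"` must be labeled overlapping.
#' @return object of class `cx_connectome`.
#' @export
connectome <- function(cell_types, pairs, overlap_labels = NULL) {
  stopifnot(is.data.frame(pairs), all(c("pre", "post") %in% names(pairs)))
  if (!"class" %in% names(pairs)) {
    stopifnot("kind" %in% names(pairs))
    pairs$class <- lapply(pairs$kind, response_class)
  }
  pairs$kind <- vapply(pairs$class, function(cl) cl$kind, character(1))
  if (is.null(overlap_labels)) {
    ann <- lapply(stats::setNames(cell_types, cell_types), parse_type_name)
    overlap_labels <- mapply(function(a, b) overlap_label(ann[[a]], ann[[b]])$overlapping,
                             pairs$pre, pairs$post)
  }
  stopifnot(length(overlap_labels) == nrow(pairs))
  pairs$overlapping <- as.logical(overlap_labels)
  bad <- pairs$kind != "none" & !pairs$overlapping
  if (any(bad))
    stop("planted responses on non-overlapping pairs: ",
         paste(pairs$pre[bad], pairs$post[bad], sep = "->", collapse = ", "),
         " (non-overlapping pairs form the null and must have kind 'none')")
  structure(list(cell_types = cell_types, pairs = pairs), class = "cx_connectome")
}

#' Packaged example connectome: the planted-recovery fixture
#'
#' Thirty cell-type pairs built from grammar-valid synthetic type names:
#' 10 anatomically overlapping pairs (4 strong excitatory, 2 inhibitory from
#' an elevated baseline, 4 unconnected) and 20 non-overlapping control pairs.
#' Overlap labels are computed from the names by the anatomy module.
#'
#' @return a `cx_connectome`.
#' @export
example_connectome <- function() {
  # Each tested pair shares one dedicated region where the pre type has
  # boutons and the post type has spines.
  ov <- data.frame(
    pre = c("PBG1-8.b-EBw.s", "FBl2.b-LAL.s", "EBt.b-GA.s", "NO1.b-LAL.s",
            "FBl5.b-SPS.s",   "GA.b-LAL.s",
            "LAL.b-SMP.s",    "SMP.b-FBl1.s", "Cre.b-NO2V.s", "SPS.b-AMP.s"),
    post = c("PBG2-9.s-FBl3.b", "FBl2.s-NO2D.b", "EBw.s-PB18.b", "NO1.s-SMP.b",
             "FBl5.s-IB.b",     "GA.s-Cre.b",
             "LAL.s-WED.b",     "SMP.s-BU.b",   "Cre.s-SPS.b",  "SPS.s-LAL.b"),
    kind = c(rep("strong_excitation", 4), rep("inhibition", 2), rep("none", 4)))
  # Control types: boutons only in {SMP, WED, IB, AMP, Cre}, spines only in
  # {LAL, BU, SPS, NO3A, FBl7}; the two alphabets are disjoint, so no control
  # pair can overlap in either direction.
  ctl <- c("SMP.b-LAL.s", "WED.b-BU.s", "IB.b-SPS.s", "AMP.b-NO3A.s",
           "Cre.b-FBl7.s", "SMP.b-BU.s", "WED.b-SPS.s", "IB.b-NO3A.s",
           "AMP.b-FBl7.s", "Cre.b-LAL.s")
  idx <- utils::combn(10, 2)
  ctl_pairs <- data.frame(pre = ctl[idx[1, ]], post = ctl[idx[2, ]],
                          kind = "none")[1:20, ]
  connectome(unique(c(ov$pre, ov$post, ctl)), rbind(ov, ctl_pairs))
}

#' Simulate a full synthetic screen
#'
#' For each pair, fly and stimulation protocol, one run of 4 repeats is
#' simulated. Per-repeat seeds are derived from the master seed by stable
#' hashing of (pair, fly, protocol, repeat), so the dataset is reproducible
#' and independent of generation order.
#'
#' @param gt a [connectome()].
#' @param n_flies flies per pair (the screen used at least 6).
#' @param protocols list of [stim_protocol()] objects.
#' @param sampling_rate imaging rate, Hz.
#' @param duration repeat length, seconds.
#' @param n_repeats repeats per run.
#' @param seed master seed.
#' @param saturation optional soft response ceiling, see [response_waveform()].
#' @return object of class `cx_dataset`: list with `time`, `runs` (metadata
#'   data.frame), `traces` (named list of n_samples x n_repeats matrices),
#'   `ground_truth`, `params`.
#' @export
simulate_experiment <- function(gt, n_flies = 6, protocols = default_protocols(),
                                sampling_rate = 10, duration = 16,
                                n_repeats = 4, seed = 1, saturation = NULL) {
  stopifnot(inherits(gt, "cx_connectome"), n_flies >= 1)
  if (nrow(gt$pairs) == 0) stop("empty connectome: no pairs to simulate")
  if (inherits(protocols, "cx_protocol")) protocols <- list(protocols)
  pairs <- gt$pairs
  pair_id <- sprintf("pair%02d", seq_len(nrow(pairs)))
  meta <- list(); traces <- list()
  for (i in seq_len(nrow(pairs))) {
    cls <- pairs$class[[i]]
    for (fly in seq_len(n_flies)) for (pr in protocols) {
      run_id <- sprintf("%s_fly%02d_p%02d", pair_id[i], fly, pr$n_pulses)
      m <- vapply(seq_len(n_repeats), function(r) {
        simulate_repeat(cls, pr, sampling_rate, duration,
                        seed = derive_seed(seed, pair_id[i], fly, pr$n_pulses, r),
                        saturation = saturation)$values
      }, numeric(round(duration * sampling_rate)))
      colnames(m) <- paste0("repeat", seq_len(n_repeats))
      traces[[run_id]] <- m
      meta[[run_id]] <- data.frame(
        run_id = run_id, pair_id = pair_id[i], pre = pairs$pre[i],
        post = pairs$post[i], fly = fly, n_pulses = pr$n_pulses,
        onset = pr$onset_time, overlapping = pairs$overlapping[i],
        kind = pairs$kind[i])
    }
  }
  runs <- do.call(rbind, meta)
  rownames(runs) <- NULL
  n <- round(duration * sampling_rate)
  structure(list(time = (seq_len(n) - 1) / sampling_rate, runs = runs,
                 traces = traces, ground_truth = gt,
                 params = list(n_flies = n_flies, sampling_rate = sampling_rate,
                               duration = duration, n_repeats = n_repeats,
                               seed = seed,
                               n_pulses = vapply(protocols, `[[`, 0, "n_pulses"))),
            class = "cx_dataset")
}

#' @export
print.cx_dataset <- function(x, ...) {
  cat(sprintf("cx_dataset: %d runs (%d pairs x %d flies x %d protocols), %d repeats of %d samples each\n",
              nrow(x$runs), length(unique(x$runs$pair_id)), x$params$n_flies,
              length(x$params$n_pulses), x$params$n_repeats, length(x$time)))
  invisible(x)
}
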
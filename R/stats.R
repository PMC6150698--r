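#' @name response-statistics
#' @title The repeat / run / pair statistic hierarchy
#'
#' @description
#' Responses are quantified at three levels. Per repeat: `Fpeak` (peak dF/F0,
#' the signed extremum of deviation from baseline, so inhibition from an
#' elevated baseline yields a negative excursion), `Tpeak` (time to peak
#' after stimulation onset), `ItoPeak` (integral of the baseline-subtracted
#' signal from onset to peak), `tau_half` (half-decay time after the peak),
#' `Fbase` (pre-stimulus baseline in dF/F0), and the baseline-normalized
#' `Fpeak_norm`, `ItoPeak_norm`. Per run (4 repeats on one fly): field-wise
#' medians and `R_within`, the mean pairwise correlation of the repeat
#' traces. Per pair (across flies, one stimulation protocol): medians of the
#' run medians, `R_between` (mean pairwise correlation of per-run average
#' transients, the screen's reliability measure) and `R_state` (correlation
#' of `ItoPeak` with `Fbase` across flies, a brain-state coupling index).
#' Finally, the integral statistics are scaled dataset-wide to `[-1, 1]` by
#' dividing positive values by the dataset maximum and negative values by the
#' magnitude of the dataset minimum.
NULL

#' Per-repeat response statistics
#'
#' @param values dF/F0 trace.
#' @param time sample times, seconds.
#' @param onset stimulation onset, seconds; the baseline window is every
#'   sample strictly before it.
#' @param fbase_floor floor on `Fbase` in the normalized statistics (division
#'   by a near-zero baseline is meaningless in dF/F0 units); when the floor
#'   binds, `floor_bound` is set.
#' @return one-row data.frame: `Fpeak`, `Tpeak`, `ItoPeak`, `tau_half`,
#'   `Fbase`, `Fpeak_norm`, `ItoPeak_norm`, `floor_bound`. `tau_half` is `NA`
#'   when the trace never returns to half of its peak deviation (or never
#'   deviates at all).
#' @export
repeat_stats <- function(values, time, onset, fbase_floor = 0.05) {
  stopifnot(length(values) == length(time))
  pre <- time < onset
  post <- which(time >= onset)
  if (!any(pre)) stop("no pre-stimulus samples: trace must cover a baseline window")
  if (length(post) == 0) stop("no post-onset samples in the trace")
  fbase <- mean(values[pre])
  dev <- values[post] - fbase
  ipk <- post[which.max(abs(dev))]
  fpeak <- values[ipk]
  tpeak <- time[ipk] - onset
  seg <- post[1]:ipk
  itopeak <- trapz(time[seg], values[seg] - fbase)
  tau_half <- NA_real_
  if (abs(fpeak - fbase) > 0 && ipk < length(values)) {
    after <- (ipk + 1):length(values)
    cross <- after[abs(values[after] - fbase) <= abs(fpeak - fbase) / 2]
    if (length(cross)) tau_half <- time[cross[1]] - time[ipk]
  }
  denom <- max(fbase, fbase_floor)
  data.frame(Fpeak = fpeak, Tpeak = tpeak, ItoPeak = itopeak,
             tau_half = tau_half, Fbase = fbase,
             Fpeak_norm = fpeak / denom, ItoPeak_norm = itopeak / denom,
             floor_bound = fbase < fbase_floor)
}

# mean pairwise Pearson correlation between the columns of a matrix,
# optionally excluding pairs from the same group; NA for < 2 usable columns.
mean_pairwise_cor <- function(m, groups = NULL, method = "pearson") {
  k <- ncol(m)
  if (k < 2) return(NA_real_)
  usable <- apply(m, 2, stats::sd) > 0
  if (sum(usable) < 2) return(NA_real_)
  cc <- suppressWarnings(stats::cor(m[, usable, drop = FALSE], method = method))
  g <- if (is.null(groups)) seq_len(k)[usable] else groups[usable]
  vals <- c()
  for (i in seq_len(ncol(cc) - 1)) for (j in (i + 1):ncol(cc))
    if (is.null(groups) || g[i] != g[j]) vals <- c(vals, cc[i, j])
  if (length(vals) == 0) NA_real_ else mean(vals)
}

#' Run-level statistics: medians over the repeats of one fly
#'
#' @param traces `n_samples x n_repeats` dF/F0 matrix (a run).
#' @param time,onset,fbase_floor see [repeat_stats()].
#' @param cor_method correlation type for `R_within`.
#' @return one-row data.frame of field-wise medians (undefined `tau_half`
#'   values excluded) plus `R_within`, the mean of the pairwise correlations
#'   between the repeat traces (`NA` when fewer than 2 usable repeats).
#' @export
run_stats <- function(traces, time, onset, fbase_floor = 0.05,
                      cor_method = "pearson") {
  stopifnot(is.matrix(traces))
  if (ncol(traces) != 4)
    warning(sprintf("run has %d repeats (expected 4)", ncol(traces)))
  per <- do.call(rbind, lapply(seq_len(ncol(traces)), function(r)
    repeat_stats(traces[, r], time, onset, fbase_floor)))
  med <- vapply(c("Fpeak", "Tpeak", "ItoPeak", "tau_half", "Fbase",
                  "Fpeak_norm", "ItoPeak_norm"),
                function(f) stats::median(per[[f]], na.rm = (f == "tau_half")),
                numeric(1))
  out <- as.data.frame(as.list(med))
  out$R_within <- mean_pairwise_cor(traces, method = cor_method)
  out$n_repeats <- ncol(traces)
  out
}

#' Pair-level statistics: medians across flies for one stimulation protocol
#'
#' Run medians are first aggregated within each fly (median over that fly's
#' runs), then the median across flies is taken. `R_between` is the mean
#' pairwise correlation between the per-run average transients, pairs of
#' runs from the same fly excluded. `R_state` correlates the per-fly
#' `ItoPeak` with the per-fly `Fbase`.
#'
#' @param run_table data.frame of [run_stats()] rows with a `fly` column.
#' @param run_traces list of the corresponding `n_samples x n_repeats`
#'   matrices.
#' @param cor_method correlation type.
#' @return one-row data.frame: medians (same column names as the run level),
#'   `R_within` (median across flies), `R_between`, `R_state`, `n_flies`.
#'   `R_between` and `R_state` are `NA` with a single fly.
#' @export
pair_stats <- function(run_table, run_traces, cor_method = "pearson") {
  stopifnot(nrow(run_table) == length(run_traces), "fly" %in% names(run_table))
  fields <- c("Fpeak", "Tpeak", "ItoPeak", "tau_half", "Fbase",
              "Fpeak_norm", "ItoPeak_norm", "R_within")
  flies <- unique(run_table$fly)
  by_fly <- do.call(rbind, lapply(flies, function(f) {
    rows <- run_table[run_table$fly == f, fields, drop = FALSE]
    as.data.frame(lapply(rows, stats::median, na.rm = TRUE))
  }))
  med <- vapply(fields, function(f) stats::median(by_fly[[f]], na.rm = TRUE),
                numeric(1))
  out <- as.data.frame(as.list(med))
  avg <- vapply(run_traces, rowMeans, numeric(nrow(run_traces[[1]])))
  out$R_between <- if (length(flies) < 2) NA_real_ else
    mean_pairwise_cor(avg, groups = run_table$fly, method = cor_method)
  out$R_state <- if (length(flies) < 2) NA_real_ else
    suppressWarnings(stats::cor(by_fly$ItoPeak, by_fly$Fbase,
                                method = cor_method))
  out$n_flies <- length(flies)
  out
}

#' Scale a signed statistic to cover `[-1, 1]` dataset-wide
#'
#' Positive values are divided by the dataset maximum, negative values by the
#' magnitude of the dataset minimum, zeros are unchanged; on any batch with
#' both signs present the extrema map exactly to +1 and -1.
#'
#' @param v numeric vector (the whole analysis batch).
#' @return scaled vector in `[-1, 1]` (all zeros stay zero; `NA`s pass
#'   through).
#' @export
scale_signed <- function(v) {
  out <- v
  pos <- which(!is.na(v) & v > 0)
  neg <- which(!is.na(v) & v < 0)
  if (length(pos)) out[pos] <- v[pos] / max(v[pos])
  if (length(neg)) out[neg] <- v[neg] / abs(min(v[neg]))
  out
}

#' Compute the full statistic hierarchy for a dataset
#'
#' @param dataset a `cx_dataset` (from [simulate_experiment()] or
#'   [read_dataset()]).
#' @param fbase_floor,cor_method see [repeat_stats()], [run_stats()].
#' @return list of data.frames `repeats`, `runs`, `pairs`; the run and pair
#'   tables carry dataset-scaled columns `ItoPeak_scaled` and
#'   `ItoPeak_norm_scaled`.
#' @export
screen_statistics <- function(dataset, fbase_floor = 0.05,
                              cor_method = "pearson") {
  runs <- dataset$runs
  time <- dataset$time
  rep_rows <- list(); run_rows <- list()
  for (i in seq_len(nrow(runs))) {
    id <- runs$run_id[i]
    m <- dataset$traces[[id]]
    onset <- runs$onset[i]
    per <- do.call(rbind, lapply(seq_len(ncol(m)), function(r)
      cbind(run_id = id, repeat_idx = r,
            repeat_stats(m[, r], time, onset, fbase_floor))))
    rep_rows[[id]] <- per
    run_rows[[id]] <- cbind(runs[i, c("run_id", "pair_id", "pre", "post",
                                      "fly", "n_pulses", "overlapping")],
                            run_stats(m, time, onset, fbase_floor, cor_method))
  }
  rep_tab <- do.call(rbind, rep_rows)
  run_tab <- do.call(rbind, run_rows)
  rownames(rep_tab) <- rownames(run_tab) <- NULL

  pair_rows <- list()
  for (pid in unique(run_tab$pair_id)) for (np in unique(run_tab$n_pulses)) {
    sel <- run_tab$pair_id == pid & run_tab$n_pulses == np
    if (!any(sel)) next
    sub <- run_tab[sel, , drop = FALSE]
    ps <- pair_stats(sub, dataset$traces[sub$run_id], cor_method)
    pair_rows[[paste(pid, np)]] <-
      cbind(sub[1, c("pair_id", "pre", "post", "n_pulses", "overlapping")], ps)
  }
  pair_tab <- do.call(rbind, pair_rows)
  rownames(pair_tab) <- NULL

  run_tab$ItoPeak_scaled <- scale_signed(run_tab$ItoPeak)
  run_tab$ItoPeak_norm_scaled <- scale_signed(run_tab$ItoPeak_norm)
  pair_tab$ItoPeak_scaled <- scale_signed(pair_tab$ItoPeak)
  pair_tab$ItoPeak_norm_scaled <- scale_signed(pair_tab$ItoPeak_norm)
  list(repeats = rep_tab, runs = run_tab, pairs = pair_tab)
}
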
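#' Construct a current-clamp sweep recording
#'
#' @param time_ms monotone time vector, ms, constant sampling interval.
#' @param voltage_mV voltage vector, mV, same length as `time_ms`.
#' @param current_pA injected step current, pA.
#' @param onset_ms,offset_ms step window, ms, inside the trace.
#' @return list of class `sweep_recording`.
#' @export
sweep_recording <- function(time_ms, voltage_mV, current_pA,
                            onset_ms, offset_ms) {
  if (length(time_ms) != length(voltage_mV))
    stop("time and voltage must have equal lengths")
  if (length(time_ms) < 2) stop("sweep too short")
  dt <- diff(time_ms)
  if (any(abs(dt - dt[1]) > 1e-9))
    stop("sampling interval must be constant within 1e-9 ms")
  if (onset_ms < time_ms[1] || offset_ms > time_ms[length(time_ms)] ||
      onset_ms >= offset_ms)
    stop("step window must lie inside the trace")
  structure(list(time_ms = time_ms, voltage_mV = voltage_mV,
                 current_pA = current_pA, onset_ms = onset_ms,
                 offset_ms = offset_ms, dt_ms = dt[1]),
            class = "sweep_recording")
}

#' Detect action potentials in a depolarizing sweep
#'
#' Marks one event per AP: the threshold is the first sample at which the
#' voltage slope reaches `dvdt_threshold` before the peak; the event stays
#' open until the voltage falls back below the threshold voltage, so a
#' double-peaked rise yields a single event whose peak is the global maximum;
#' the afterhyperpolarization (AHP) is the voltage minimum between the peak
#' and the next threshold (or the step offset).
#'
#' @param s a `sweep_recording`.
#' @param dvdt_threshold slope criterion, mV/ms (default 20).
#' @return data.frame with one row per AP: `threshold_time`,
#'   `threshold_voltage`, `peak_time`, `peak_voltage`, `ahp_time`,
#'   `ahp_voltage` (empty when no APs are present).
#' @export
detect_aps <- function(s, dvdt_threshold = 20) {
  t <- s$time_ms; v <- s$voltage_mV; dt <- s$dt_ms
  i0 <- which(t >= s$onset_ms)[1]
  i1 <- max(which(t <= s$offset_ms))
  dvdt <- c(diff(v) / dt, 0)

  empty <- data.frame(threshold_time = numeric(), threshold_voltage = numeric(),
                      peak_time = numeric(), peak_voltage = numeric(),
                      ahp_time = numeric(), ahp_voltage = numeric())
  thr_idx <- integer(); peak_idx <- integer(); end_idx <- integer()
  i <- i0
  while (i < i1) {
    if (dvdt[i] >= dvdt_threshold) {
      thr_v <- v[i]
      j <- i + 1
      while (j <= i1 && v[j] >= thr_v) j <- j + 1
      if (j > i + 1) {
        pk <- i + which.max(v[(i + 1):(j - 1)])
        if (v[pk] > thr_v) {
          thr_idx <- c(thr_idx, i)
          peak_idx <- c(peak_idx, pk)
          end_idx <- c(end_idx, min(j, i1))
        }
      }
      i <- j
    } else i <- i + 1
  }
  if (!length(thr_idx)) return(empty)

  ahp_idx <- integer(length(thr_idx))
  for (k in seq_along(thr_idx)) {
    lo <- peak_idx[k]
    hi <- if (k < length(thr_idx)) thr_idx[k + 1] - 1 else i1
    ahp_idx[k] <- lo + which.min(v[lo:hi]) - 1
  }
  data.frame(threshold_time = t[thr_idx], threshold_voltage = v[thr_idx],
             peak_time = t[peak_idx], peak_voltage = v[peak_idx],
             ahp_time = t[ahp_idx], ahp_voltage = v[ahp_idx])
}

#' Half-height width of one action potential
#'
#' The half level is the threshold voltage plus half the threshold-to-peak
#' amplitude. The trace from threshold to AHP is resampled onto `n_interp`
#' evenly spaced points by linear interpolation; the HHW is the time of the
#' last falling crossing of the half level minus the time of the first
#' rising crossing (crossing times refined linearly between interpolation
#' samples).
#'
#' @param s a `sweep_recording`.
#' @param event one row of the table from [detect_aps()].
#' @param n_interp number of interpolation points (default 1000).
#' @return HHW in ms.
#' @export
compute_hhw <- function(s, event, n_interp = 1000) {
  t0 <- event$threshold_time; t1 <- event$ahp_time
  if (!(t0 < event$peak_time && event$peak_time < t1))
    stop("malformed event: require threshold < peak < AHP in time")
  half <- event$threshold_voltage +
    (event$peak_voltage - event$threshold_voltage) / 2
  grid <- seq(t0, t1, length.out = n_interp)
  vi <- stats::approx(s$time_ms, s$voltage_mV, xout = grid)$y
  above <- vi >= half
  if (!any(above)) stop("malformed event: trace never reaches the half level")
  rise_k <- which(above)[1]
  fall_k <- which(above)[sum(above)]
  if (fall_k >= n_interp)
    stop("malformed event: trace does not recross the half level before the AHP")
  cross <- function(ka, kb) {
    ## linear refinement between adjacent interpolation samples
    if (vi[kb] == vi[ka]) return(grid[kb])
    grid[ka] + (half - vi[ka]) * (grid[kb] - grid[ka]) / (vi[kb] - vi[ka])
  }
  t_rise <- if (rise_k == 1) grid[1] else cross(rise_k - 1, rise_k)
  t_fall <- cross(fall_k, fall_k + 1)
  t_fall - t_rise
}

#' Train features from detected action potentials
#'
#' Interspike intervals from consecutive threshold times (ms), instantaneous
#' firing frequency `IFF = 1000/ISI` (Hz), maximal firing frequency
#' `MFF = max(IFF)`, and the arithmetic mean IFF.
#'
#' @param events AP table from [detect_aps()].
#' @return list with `isi_ms`, `iff_hz`, `mff_hz`, `mean_iff_hz`,
#'   `n_events`, and `defined` (FALSE when fewer than 2 events, in which case
#'   the ISI-derived fields are `NA`, not zero).
#' @export
compute_train_features <- function(events) {
  n <- nrow(events)
  if (n < 2)
    return(list(isi_ms = NA_real_, iff_hz = NA_real_, mff_hz = NA_real_,
                mean_iff_hz = NA_real_, n_events = n, defined = FALSE))
  isi <- diff(sort(events$threshold_time))
  iff <- 1000 / isi
  list(isi_ms = isi, iff_hz = iff, mff_hz = max(iff),
       mean_iff_hz = mean(iff), n_events = n, defined = TRUE)
}

#' Passive membrane properties from subthreshold sweeps
#'
#' The resting membrane potential is the mean voltage over the 50 ms before
#' step onset, averaged across sweeps. The input resistance is the
#' least-squares slope of the steady-state voltage deflection (mean of the
#' last 10% of the step window, relative to the pre-step baseline) against
#' the injected current, converted to megaohms.
#'
#' @param sweeps list of `sweep_recording` (hyperpolarizing / subthreshold).
#' @param baseline_ms pre-onset window for the baseline (default 50 ms).
#' @return list with `rmp_mV` and `input_resistance_MOhm`.
#' @export
compute_passive <- function(sweeps, baseline_ms = 50) {
  if (length(sweeps) < 2) stop("need >= 2 subthreshold sweeps")
  current <- vapply(sweeps, function(s) s$current_pA, 0)
  if (length(unique(current)) < 2)
    stop("input resistance undefined: all current steps identical")
  base <- vapply(sweeps, function(s) {
    sel <- s$time_ms >= (s$onset_ms - baseline_ms) & s$time_ms < s$onset_ms
    mean(s$voltage_mV[sel])
  }, 0)
  vss <- vapply(sweeps, function(s) {
    win <- s$offset_ms - s$onset_ms
    sel <- s$time_ms >= (s$offset_ms - 0.1 * win) & s$time_ms <= s$offset_ms
    mean(s$voltage_mV[sel])
  }, 0)
  dv <- vss - base
  slope <- stats::coef(stats::lm(dv ~ current))[["current"]]  # mV/pA = GOhm
  list(rmp_mV = mean(base), input_resistance_MOhm = slope * 1000)
}

#' Steady-state firing check
#'
#' A train is at steady state when the coefficient of variation of the last
#' half of its interspike intervals is below `cv_cut`. Cells that do not
#' reach steady-state firing are excluded from feature-based comparisons.
#'
#' @param events AP table from [detect_aps()] (needs >= 4 events).
#' @param cv_cut CV criterion (default 0.25).
#' @return logical; `FALSE` carries a `reason` attribute when the train is
#'   too short.
#' @export
steady_state_check <- function(events, cv_cut = 0.25) {
  n <- nrow(events)
  if (n < 4)
    return(structure(FALSE, reason = "too few events (need >= 4)"))
  isi <- diff(sort(events$threshold_time))
  last_half <- isi[(floor(length(isi) / 2) + 1):length(isi)]
  cv <- stats::sd(last_half) / mean(last_half)
  isTRUE(cv < cv_cut)
}

#' Classify a cell as SPN or FSI from its firing features
#'
#' Fast-spiking interneurons (FSIs) combine brief APs with high firing
#' rates; spiny projection neurons (SPNs) the opposite. A cell is FSI when
#' its mean HHW is below `hhw_cut` and its mean IFF above `iff_cut`, SPN
#' when both comparisons go the other way, and AMBIGUOUS otherwise (or when
#' steady-state firing was not reached). Default cuts sit midway between the
#' two populations' typical means.
#'
#' @param mean_hhw_ms mean half-height width, ms.
#' @param mean_iff_hz mean instantaneous firing frequency, Hz.
#' @param steady_state logical from [steady_state_check()].
#' @param hhw_cut ms (default 0.8).
#' @param iff_cut Hz (default 50).
#' @return `"SPN"`, `"FSI"`, or `"AMBIGUOUS"`.
#' @export
classify_cell <- function(mean_hhw_ms, mean_iff_hz, steady_state = TRUE,
                          hhw_cut = 0.8, iff_cut = 50) {
  if (!isTRUE(steady_state)) return("AMBIGUOUS")
  if (is.na(mean_hhw_ms) || is.na(mean_iff_hz)) return("AMBIGUOUS")
  if (mean_hhw_ms < hhw_cut && mean_iff_hz > iff_cut) return("FSI")
  if (mean_hhw_ms >= hhw_cut && mean_iff_hz <= iff_cut) return("SPN")
  "AMBIGUOUS"
}

#' Full feature extraction for one cell's sweep set
#'
#' Runs AP detection on depolarizing sweeps, HHW extraction per AP, train
#' features on the sweep with the most APs, passive properties on the
#' hyperpolarizing sweeps, the steady-state check, and classification.
#'
#' @param sweeps list of `sweep_recording` covering the step protocol.
#' @param dvdt_threshold mV/ms for [detect_aps()].
#' @param hhw_cut,iff_cut classification cuts, see [classify_cell()].
#' @param cv_cut steady-state criterion, see [steady_state_check()].
#' @return list with `mean_hhw_ms`, `mean_iff_hz`, `mff_hz`, `mean_isi_ms`,
#'   `rmp_mV`, `input_resistance_MOhm`, `steady_state`, `cell_class`,
#'   `n_aps`, and the per-sweep event tables.
#' @export
extract_features <- function(sweeps, dvdt_threshold = 20,
                             hhw_cut = 0.8, iff_cut = 50, cv_cut = 0.25) {
  depol <- Filter(function(s) s$current_pA > 0, sweeps)
  hyper <- Filter(function(s) s$current_pA < 0, sweeps)
  events <- lapply(depol, detect_aps, dvdt_threshold = dvdt_threshold)
  n_aps <- vapply(events, nrow, 0L)
  hhw <- unlist(lapply(seq_along(depol), function(i) {
    ev <- events[[i]]
    if (!nrow(ev)) return(numeric())
    vapply(seq_len(nrow(ev)), function(k) compute_hhw(depol[[i]], ev[k, ]), 0)
  }))
  best <- if (length(n_aps) && max(n_aps) >= 2) which.max(n_aps) else NA
  train <- if (!is.na(best)) compute_train_features(events[[best]]) else
    list(mff_hz = NA_real_, mean_iff_hz = NA_real_, isi_ms = NA_real_,
         defined = FALSE)
  steady <- if (!is.na(best)) steady_state_check(events[[best]], cv_cut) else
    structure(FALSE, reason = "no spiking sweep")
  passive <- if (length(hyper) >= 2) compute_passive(hyper) else
    list(rmp_mV = NA_real_, input_resistance_MOhm = NA_real_)
  mean_hhw <- if (length(hhw)) mean(hhw) else NA_real_
  list(mean_hhw_ms = mean_hhw,
       mean_iff_hz = train$mean_iff_hz,
       mff_hz = train$mff_hz,
       mean_isi_ms = if (isTRUE(train$defined)) mean(train$isi_ms) else NA_real_,
       rmp_mV = passive$rmp_mV,
       input_resistance_MOhm = passive$input_resistance_MOhm,
       steady_state = isTRUE(steady),
       cell_class = classify_cell(mean_hhw, train$mean_iff_hz, isTRUE(steady),
                                  hhw_cut, iff_cut),
       n_aps = n_aps, events = events)
}
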
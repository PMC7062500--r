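# Metrics layer: spike detection, waveform metrics, SPIKE-synchronization,
# potentiation index, and group statistics. Pure functions: identical
# traces in, identical tables out.

#' Construct a spike train
#'
#' @param times spike times, ms, strictly increasing
#' @param window observation window `c(t0, t1)`, ms
#' @return a `spike_train`
#' @export
spike_train <- function(times, window) {
  times <- as.numeric(times)
  stopifnot(length(window) == 2L, window[2] > window[1])
  if (is.unsorted(times, strictly = TRUE)) stop("spike times must be strictly increasing")
  if (length(times) && (times[1] < window[1] || times[length(times)] > window[2]))
    stop("spike times outside the observation window")
  structure(list(times = times, window = as.numeric(window)),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat("spike_train:", length(x$times), "spikes in [", x$window[1], ",",
      x$window[2], "] ms; MFR", round(mean_firing_rate(x), 2), "/s\n")
  invisible(x)
}

#' Detect spikes by threshold crossing
#'
#' One spike per contiguous supra-threshold excursion, timed at the upward
#' crossing with linear interpolation between samples.
#'
#' @param t uniformly spaced sample times, ms
#' @param v voltage trace, mV
#' @param threshold detection threshold, mV (somatic default 10)
#' @return a `spike_train`
#' @export
detect_spikes <- function(t, v, threshold = 10) {
  stopifnot(length(t) == length(v), length(t) >= 2L)
  dtv <- diff(t)
  if (max(abs(dtv - dtv[1])) > 1e-6 * dtv[1])
    stop("input error: trace is not uniformly sampled")
  above <- v >= threshold
  up <- which(!above[-length(above)] & above[-1])   # crossing between i, i+1
  times <- vapply(up, function(i) {
    t[i] + (threshold - v[i]) / (v[i + 1] - v[i]) * (t[i + 1] - t[i])
  }, numeric(1))
  if (above[1]) times <- c(t[1], times)             # starts supra-threshold
  spike_train(times, c(t[1], t[length(t)] + dtv[1]))
}

#' Spike half-width: duration above threshold
#'
#' The time `t1` at which voltage exceeds the threshold to the time `t2`
#' at which it falls back below it, with interpolated crossings — the
#' above-threshold duration, not the width at half-maximal amplitude.
#'
#' @param t,v uniformly sampled trace
#' @param threshold mV (default 10)
#' @param which_spike index of the supra-threshold excursion to measure
#' @return width in ms
#' @export
half_width <- function(t, v, threshold = 10, which_spike = 1L) {
  above <- v >= threshold
  if (!any(above)) stop("undefined-metric error: trace never crosses threshold")
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  exc <- which(r$values)
  if (which_spike > length(exc)) stop("undefined-metric error: fewer excursions than requested")
  i0 <- starts[exc[which_spike]]; i1 <- ends[exc[which_spike]]
  t_up <- if (i0 == 1L) t[1] else {
    t[i0 - 1] + (threshold - v[i0 - 1]) / (v[i0] - v[i0 - 1]) * (t[i0] - t[i0 - 1])
  }
  t_dn <- if (i1 == length(v)) t[length(t)] else {
    t[i1] + (v[i1] - threshold) / (v[i1] - v[i1 + 1]) * (t[i1 + 1] - t[i1])
  }
  t_dn - t_up
}

#' Absolute peak voltage of a trace
#' @param v voltage trace, mV
#' @return mV
#' @export
peak_amplitude <- function(v) {
  if (!length(v)) stop("input error: empty trace")
  max(v)
}

#' Time from stimulus onset to the absolute voltage peak
#'
#' @param t,v trace
#' @param stimulus_onset ms
#' @param mode `"peak"` (default: onset to absolute maximum) or
#'   `"threshold"` (onset to first crossing of `threshold`)
#' @param threshold mV, used by `mode = "threshold"`
#' @return ms
#' @export
depolarization_time <- function(t, v, stimulus_onset = 0, mode = c("peak", "threshold"),
                                threshold = 10) {
  mode <- match.arg(mode)
  keep <- t >= stimulus_onset
  if (!any(keep)) stop("input error: no samples after stimulus onset")
  tt <- t[keep]; vv <- v[keep]
  if (mode == "peak") return(tt[which.max(vv)] - stimulus_onset)
  st <- detect_spikes(tt, vv, threshold)
  if (!length(st$times)) stop("undefined-metric error: no threshold crossing")
  st$times[1] - stimulus_onset
}

#' Mean firing rate
#' @param train a `spike_train`
#' @return spikes per second
#' @export
mean_firing_rate <- function(train) {
  length(train$times) / (diff(train$window) / 1000)
}

# adaptive coincidence window around spike i of train x, paired with spike
# j of train y: half the minimum of the four neighbouring ISIs; boundary
# spikes use their single inner ISI; a train with < 2 spikes contributes
# no ISI (the partner's window rules, per the published convention)
.sync_tau <- function(x, i, y, j) {
  isis <- c()
  if (length(x) >= 2L) {
    if (i > 1L) isis <- c(isis, x[i] - x[i - 1L])
    if (i < length(x)) isis <- c(isis, x[i + 1L] - x[i])
  }
  if (length(y) >= 2L) {
    if (j > 1L) isis <- c(isis, y[j] - y[j - 1L])
    if (j < length(y)) isis <- c(isis, y[j + 1L] - y[j])
  }
  if (!length(isis)) return(Inf)
  min(isis) / 2
}

# coincidence indicator sum for spikes of x against y
.sync_count <- function(x, y) {
  if (!length(x)) return(0)
  sum(vapply(seq_along(x), function(i) {
    j <- which.min(abs(y - x[i]))
    as.numeric(abs(x[i] - y[j]) < .sync_tau(x, i, y, j))
  }, numeric(1)))
}

#' Pairwise SPIKE-synchronization value
#'
#' Parameter-free coincidence measure with the adaptive window: a spike
#' coincides if its nearest partner spike lies within half the minimum of
#' the four neighbouring inter-spike intervals. The pair value is the
#' fraction of coincident spikes over both trains.
#'
#' @param a,b `spike_train`s (or numeric vectors of spike times)
#' @return value in `[0, 1]`; 1 when either train is empty by convention
#'   of an undefined comparison being reported as NA
#' @export
spike_sync <- function(a, b) {
  x <- if (inherits(a, "spike_train")) a$times else as.numeric(a)
  y <- if (inherits(b, "spike_train")) b$times else as.numeric(b)
  if (!length(x) && !length(y)) return(NA_real_)
  if (!length(x) || !length(y)) return(0)
  (.sync_count(x, y) + .sync_count(y, x)) / (length(x) + length(y))
}

#' SPIKE-synchronization matrix
#'
#' @param trains list of `spike_train`s
#' @return symmetric matrix in `[0, 1]` with unit diagonal
#' @export
spike_sync_matrix <- function(trains) {
  n <- length(trains)
  if (n < 2L) stop("input error: need at least two spike trains")
  m <- diag(1, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      m[i, j] <- m[j, i] <- spike_sync(trains[[i]], trains[[j]])
    }
  }
  m
}

#' Potentiation index of a pairing experiment
#'
#' Default (calcium-based): peak synaptic `[Ca]i` in the paired condition
#' over peak `[Ca]i` in the EPSP-alone condition — postsynaptic calcium is
#' the plasticity-inducing signal. The voltage-based alternative compares
#' the paired peak against the linear sum of the two alone-condition peaks
#' (both measured as depolarization from rest).
#'
#' @param pairing a `ca1_pairing` from [run_stdp_pairing()]
#' @param method `"ca"` (default) or `"voltage"`
#' @param v_rest resting potential used by the voltage readout, mV
#' @return dimensionless index (1 = no potentiation); the chosen readout
#'   is recorded in `attr(, "method")`
#' @export
potentiation_index <- function(pairing, method = c("ca", "voltage"),
                               v_rest = NULL) {
  method <- match.arg(method)
  for (f in c("epsp_alone", "bap_alone", "paired")) {
    if (is.null(pairing[[f]])) stop("input error: missing condition '", f, "'")
  }
  if (method == "ca") {
    idx <- pairing$paired$peak_ca_mM / pairing$epsp_alone$peak_ca_mM
  } else {
    v_rest <- v_rest %||% -70
    lin <- (pairing$epsp_alone$peak_v_mV - v_rest) +
           (pairing$bap_alone$peak_v_mV - v_rest)
    idx <- (pairing$paired$peak_v_mV - v_rest) / lin
  }
  attr(idx, "method") <- method
  idx
}

#' Pairwise group comparisons: Mann-Whitney U and Tukey HSD
#'
#' Rank tests for every group pair at alpha 0.05, plus Tukey honest
#' significant difference intervals from a one-way fit; standard
#' implementations are delegated to `stats`.
#'
#' @param values numeric vector
#' @param groups group labels (same length)
#' @param alpha significance level
#' @return tidy data frame: group1, group2, statistic (U), p_mannwhitney,
#'   tukey_diff, tukey_lwr, tukey_upr, p_tukey, significant
#' @export
compare_groups <- function(values, groups, alpha = 0.05) {
  groups <- as.factor(groups)
  stopifnot(length(values) == length(groups), nlevels(groups) >= 2L)
  if (any(table(groups) < 3L)) stop("input error: each group needs n >= 3")
  lev <- levels(groups)
  degenerate <- stats::var(values) == 0
  tk <- NULL
  if (!degenerate) {
    fit <- stats::aov(values ~ groups)
    tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$groups
  }
  out <- list()
  for (i in seq_len(length(lev) - 1L)) {
    for (j in (i + 1L):length(lev)) {
      xi <- values[groups == lev[i]]; xj <- values[groups == lev[j]]
      if (stats::var(c(xi, xj)) == 0) {
        # degenerate (all-identical) samples: reported, not crashed
        w <- list(statistic = length(xi) * length(xj) / 2, p.value = 1)
      } else {
        w <- suppressWarnings(stats::wilcox.test(xi, xj, exact = FALSE))
      }
      key <- paste0(lev[j], "-", lev[i])
      tkrow <- if (!is.null(tk) && key %in% rownames(tk)) tk[key, ] else
        c(diff = mean(xj) - mean(xi), lwr = NA, upr = NA, `p adj` = NA)
      out[[length(out) + 1L]] <- data.frame(
        group1 = lev[i], group2 = lev[j],
        statistic = unname(w$statistic), p_mannwhitney = w$p.value,
        tukey_diff = unname(tkrow[1]), tukey_lwr = unname(tkrow[2]),
        tukey_upr = unname(tkrow[3]), p_tukey = unname(tkrow[4]),
        significant = !is.na(w$p.value) && w$p.value < alpha)
    }
  }
  do.call(rbind, out)
}
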
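# Steady-state evoked potential trials and spectral analysis.
#
# The network is driven with a periodic click train: each click is a
# near-synchronous AMPA volley onto the mid-apical compartment of a
# configured fraction of pyramidal cells (<= 1 ms uniform jitter). The
# simulated EEG is the population sum, over pyramidal cells, of absolute
# synaptic currents into apical-dendrite compartments; a mean-somatic-
# potential proxy is available as an alternative through `eeg_proxy`.

#' Describe a click-train drive
#'
#' @param frequency drive rate, Hz (20, 30 and 40 are the standard task
#'   frequencies; any positive rate is accepted).
#' @param g_max_nS peak conductance of one drive volley per cell.
#' @param fraction fraction of pyramidal cells receiving the drive.
#' @param jitter_ms per-cell, per-click uniform jitter.
#' @param duration_ms trial length.
#' @param transient_ms initial segment discarded by the analysis.
#' @param params parameter list supplying defaults.
#' @return object of class `hg_drive_spec`.
#' @export
drive_spec <- function(frequency = 40, g_max_nS = NULL, fraction = NULL,
                       jitter_ms = NULL, duration_ms = NULL,
                       transient_ms = NULL, params = default_params()) {
  d <- params$drive
  spec <- list(frequency = frequency,
               g_max_nS = g_max_nS %||% d$g_max_nS,
               fraction = fraction %||% d$fraction,
               jitter_ms = jitter_ms %||% d$jitter_ms,
               duration_ms = duration_ms %||% d$duration_ms,
               transient_ms = transient_ms %||% d$transient_ms)
  abort_if(spec$frequency <= 0, "drive frequency must be positive")
  abort_if(spec$duration_ms <= spec$transient_ms,
           "duration must exceed the transient discard")
  abort_if(spec$fraction < 0 || spec$fraction > 1,
           "drive fraction must be in [0, 1]")
  structure(spec, class = "hg_drive_spec")
}

#' Run one SSEP trial
#'
#' Simulates `duration_ms` of network activity under the click-train drive
#' and returns the simulated EEG together with every spike. Reproducible:
#' identical (network, drive, seed) triples give identical output.
#'
#' @param net an `hg_network`.
#' @param drive an [drive_spec()].
#' @param seed RNG seed (drive jitter and cell-subset selection).
#' @return object of class `hg_ssep_trial`: `trace` (an `hg_trace`),
#'   `spikes` (data.frame `cell`, `type`, `time_ms`) and `meta`.
#' @export
run_ssep_trial <- function(net, drive = drive_spec(), seed = 1L) {
  stopifnot(inherits(net, "hg_network"), inherits(drive, "hg_drive_spec"))
  p <- net$params
  dt <- p$integration$dt_ms
  n_steps <- as.integer(round(drive$duration_ms / dt))
  cc <- compile_network(net, dt)

  pyr <- net$cells$cell[net$cells$type == "pyramidal"]
  with_seed(seed, {
    n_drv <- round(drive$fraction * length(pyr))
    driven <- if (n_drv >= length(pyr)) pyr else sort(sample(pyr, n_drv))
    click_t <- seq(0, drive$duration_ms - 1e-9, by = 1000 / drive$frequency)
    nst0 <- length(cc$st_comp)
    if (length(driven) > 0 && drive$g_max_nS > 0 && length(click_t) > 0) {
      ak <- p$synapses$AMPA
      dcomp <- net$cells$drive_comp[driven]
      cc$st_comp <- c(cc$st_comp, as.integer(dcomp - 1L))
      cc$st_e <- c(cc$st_e, rep(ak$e_rev_mV, length(driven)))
      cc$st_tau1 <- c(cc$st_tau1, rep(ak$tau1_ms, length(driven)))
      cc$st_tau2 <- c(cc$st_tau2, rep(ak$tau2_ms, length(driven)))
      cc$st_nmda <- c(cc$st_nmda, rep(0L, length(driven)))
      cc$st_eeg <- c(cc$st_eeg, as.integer(net$eeg_comp[dcomp]))
      amt <- drive$g_max_nS * 1e-6 * dual_exp_norm(ak$tau1_ms, ak$tau2_ms)
      nev <- length(driven) * length(click_t)
      ev_state <- rep(nst0 + seq_along(driven) - 1L, times = length(click_t))
      ev_time <- rep(click_t, each = length(driven)) +
        runif(nev, 0, drive$jitter_ms)
      cc$ev_state <- as.integer(ev_state)
      cc$ev_step <- as.integer(round(ev_time / dt))
      cc$ev_amt <- rep(amt, nev)
    }
  })

  opts <- core_opts(dt = dt, n_steps = n_steps,
                    v_init = p$integration$v_init_mV,
                    spike_threshold = p$integration$spike_threshold_mV,
                    refractory_ms = p$integration$refractory_ms,
                    mg_mM = p$synapses$mg_mM, eeg = TRUE)
  out <- .sim_core(cc, opts)

  trace <- structure(list(
    t = seq_len(n_steps) * dt, x = out$eeg, dt = dt,
    meta = list(frequency = drive$frequency, seed = seed,
                duration_ms = drive$duration_ms,
                transient_ms = drive$transient_ms,
                network_seed = net$seed)), class = "hg_trace")
  spikes <- data.frame(cell = out$spike_cell,
                       type = net$cells$type[out$spike_cell],
                       time_ms = out$spike_time)
  structure(list(trace = trace, spikes = spikes,
                 meta = list(drive = unclass(drive), seed = seed,
                             n_cells = table(net$cells$type),
                             duration_ms = drive$duration_ms,
                             transient_ms = drive$transient_ms)),
            class = "hg_ssep_trial")
}

#' @export
print.hg_ssep_trial <- function(x, ...) {
  cat(sprintf("<hg_ssep_trial> %g Hz drive, %g ms, %d spikes\n",
              x$meta$drive$frequency, x$meta$duration_ms, nrow(x$spikes)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Spectral analysis

#' Welch power spectral density of a simulated EEG
#'
#' Discards the transient, removes the mean of each segment, applies the
#' window, and averages one-sided periodograms over 50 %-overlapping
#' segments. With a rectangular window and a single segment the integral
#' of the density equals the time-domain variance (Parseval).
#'
#' @param trace an `hg_trace` (or list with `x`, `dt`, `meta`).
#' @param segment_ms Welch segment length (default from the parameter
#'   file: 500 ms, i.e. 2 Hz resolution).
#' @param overlap fractional overlap between segments.
#' @param window `"hann"` or `"rect"`.
#' @param detrend subtract each segment's mean before transforming.
#' @param transient_ms overrides the trace's own transient metadata.
#' @return object of class `hg_spectrum` with `freq` (Hz), `power`
#'   (density, units^2/Hz) and `df`.
#' @export
power_spectrum <- function(trace, segment_ms = NULL, overlap = 0.5,
                           window = c("hann", "rect"), detrend = TRUE,
                           transient_ms = NULL) {
  window <- match.arg(window)
  dt <- trace$dt
  fs <- 1000 / dt
  if (is.null(transient_ms)) transient_ms <- trace$meta$transient_ms %||% 0
  x <- trace$x[trace$t > transient_ms]
  if (is.null(segment_ms)) {
    segment_ms <- min(500, length(x) * dt)
  }
  nseg <- as.integer(round(segment_ms / dt))
  abort_if(nseg < 2, "segment shorter than two samples")
  abort_if(length(x) < nseg,
           "trace (%d samples after transient) shorter than the %d-sample window",
           length(x), nseg)
  abort_if(length(x) * dt < 2 * 1000 / 20,
           "trace must span at least two cycles of the lowest (20 Hz) band")
  w <- if (window == "hann") {
    0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / nseg)
  } else rep(1, nseg)
  step <- max(1L, as.integer(round(nseg * (1 - overlap))))
  starts <- seq(1L, length(x) - nseg + 1L, by = step)
  acc <- numeric(nseg)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)]
    if (detrend) seg <- seg - mean(seg)
    X <- fft(seg * w)
    acc <- acc + Mod(X)^2
  }
  acc <- acc / length(starts)
  # one-sided density
  half <- floor(nseg / 2)
  psd <- acc[1:(half + 1)] / (fs * sum(w^2))
  if (nseg %% 2 == 0) {
    psd[2:half] <- 2 * psd[2:half]
  } else {
    psd[2:(half + 1)] <- 2 * psd[2:(half + 1)]
  }
  freq <- (0:half) * fs / nseg
  structure(list(freq = freq, power = psd, df = fs / nseg,
                 meta = c(trace$meta, list(segment_ms = segment_ms,
                                           window = window))),
            class = "hg_spectrum")
}

#' @export
print.hg_spectrum <- function(x, ...) {
  pk <- x$freq[which.max(x$power)]
  cat(sprintf("<hg_spectrum> %d bins, df = %.3g Hz, peak at %.3g Hz\n",
              length(x$freq), x$df, pk))
  invisible(x)
}

#' Band power around a target frequency
#'
#' Integral of the spectral density over `f +/- halfwidth`; with
#' `halfwidth = 0` the single nearest bin's power is returned.
#'
#' @param spectrum an `hg_spectrum`.
#' @param f centre frequency, Hz.
#' @param halfwidth half bandwidth, Hz (default 2).
#' @return scalar band power.
#' @export
band_power <- function(spectrum, f, halfwidth = 2) {
  abort_if(f < min(spectrum$freq) || f > max(spectrum$freq),
           "frequency %g Hz outside the spectrum range", f)
  if (halfwidth <= 0) {
    i <- which.min(abs(spectrum$freq - f))
    return(spectrum$power[i] * spectrum$df)
  }
  sel <- abs(spectrum$freq - f) <= halfwidth
  sum(spectrum$power[sel]) * spectrum$df
}

#' Band powers at the three task frequencies
#'
#' @param spectrum an `hg_spectrum`.
#' @param freqs frequencies, Hz.
#' @param halfwidth half bandwidth, Hz.
#' @return named numeric vector (names are the frequencies).
#' @export
band_powers <- function(spectrum, freqs = c(20, 30, 40), halfwidth = 2) {
  setNames(vapply(freqs, band_power, numeric(1), spectrum = spectrum,
                  halfwidth = halfwidth), as.character(freqs))
}

#' Average the EEG over consecutive stimulus cycles
#'
#' Folds the post-transient trace into consecutive windows of
#' `n_cycles / drive_freq` and averages them, exposing alternating-cycle
#' ("beat skipping") structure when every other response peak is depressed.
#'
#' @param trace an `hg_trace`.
#' @param drive_freq drive frequency, Hz.
#' @param n_cycles cycles per window (default 2).
#' @param transient_ms overrides the trace's transient metadata.
#' @return data.frame with `t` (ms within the window) and `value`.
#' @export
cycle_average <- function(trace, drive_freq, n_cycles = 2,
                          transient_ms = NULL) {
  dt <- trace$dt
  if (is.null(transient_ms)) transient_ms <- trace$meta$transient_ms %||% 0
  x <- trace$x[trace$t > transient_ms]
  period_ms <- n_cycles * 1000 / drive_freq
  nper <- as.integer(round(period_ms / dt))
  nwin <- floor(length(x) / nper)
  abort_if(nwin < 2,
           "trace must span at least %d cycles after the transient",
           4 * n_cycles)
  m <- matrix(x[seq_len(nwin * nper)], nrow = nper)
  data.frame(t = seq_len(nper) * dt, value = rowMeans(m))
}

#' Phase-binned spike histogram over consecutive cycles
#'
#' Bins spikes of one population by phase within windows of `n_cycles`
#' stimulus cycles and normalises to spike probability per cell per window;
#' also reports the population mean firing rate.
#'
#' @param spikes data.frame with `cell`, `type`, `time_ms` (as produced by
#'   [run_ssep_trial()]), or an `hg_ssep_trial`.
#' @param population `"pyramidal"`, `"PV"` (basket + chandelier) or `"CR"`
#'   (calretinin).
#' @param drive_freq drive frequency, Hz.
#' @param n_cycles cycles per window.
#' @param bins number of phase bins across the window.
#' @param n_cells population size (taken from the trial metadata when a
#'   trial object is given).
#' @param duration_ms,transient_ms analysis window.
#' @return list: `breaks` (ms), `prob` (per cell per window), `counts`,
#'   `rate_hz` (mean rate per cell).
#' @export
spike_histogram <- function(spikes, population = c("pyramidal", "PV", "CR"),
                            drive_freq, n_cycles = 2, bins = 40,
                            n_cells = NULL, duration_ms = NULL,
                            transient_ms = 0) {
  population <- match.arg(population)
  if (inherits(spikes, "hg_ssep_trial")) {
    meta <- spikes$meta
    duration_ms <- duration_ms %||% meta$duration_ms
    transient_ms <- meta$transient_ms %||% transient_ms
    if (is.null(n_cells)) {
      nc <- meta$n_cells
      n_cells <- switch(population,
                        pyramidal = nc[["pyramidal"]],
                        PV = nc[["basket"]] + nc[["chandelier"]],
                        CR = nc[["calretinin"]])
    }
    spikes <- spikes$spikes
  }
  abort_if(is.null(duration_ms), "duration_ms is required")
  abort_if(is.null(n_cells), "n_cells is required")
  types <- switch(population, pyramidal = "pyramidal",
                  PV = c("basket", "chandelier"), CR = "calretinin")
  tt <- spikes$time_ms[spikes$type %in% types & spikes$time_ms > transient_ms]
  period_ms <- n_cycles * 1000 / drive_freq
  nwin <- max(1, floor((duration_ms - transient_ms) / period_ms))
  phase <- (tt - transient_ms) %% period_ms
  phase <- phase[(tt - transient_ms) < nwin * period_ms]
  breaks <- seq(0, period_ms, length.out = bins + 1)
  counts <- if (length(phase)) {
    tabulate(findInterval(phase, breaks, rightmost.closed = TRUE),
             nbins = bins)
  } else rep(0L, bins)
  list(breaks = breaks, counts = counts,
       prob = counts / (nwin * n_cells),
       rate_hz = 1000 * length(tt) / (n_cells * (duration_ms - transient_ms)))
}
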
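#' Construct a four-channel PPG recording
#'
#' @param samples 4 x N numeric matrix (channels in rows, arbitrary units).
#' @param fs Sampling rate in Hz (default 50).
#' @param glucose Reference blood glucose level in mmol/L (> 0), or `NA`
#'   for an unlabeled recording.
#' @param subject_id,timestamp Metadata strings.
#' @return An object of class `"ppg_recording"`.
#' @export
ppg_recording <- function(samples, fs = 50, glucose,
                          subject_id = "S00", timestamp = "") {
  if (!is.matrix(samples) || nrow(samples) != 4L)
    stop("samples must be a 4 x N matrix (channels in rows)", call. = FALSE)
  if (!all(is.finite(samples)))
    stop("samples contain non-finite values", call. = FALSE)
  glucose <- as.numeric(glucose)
  if (length(glucose) != 1L || (!is.na(glucose) && glucose <= 0))
    stop("glucose must be a single positive value (mmol/L) or NA",
         call. = FALSE)
  structure(list(samples = unname(samples), fs = fs, glucose = glucose,
                 subject_id = as.character(subject_id),
                 timestamp = as.character(timestamp)),
            class = "ppg_recording")
}

#' @export
print.ppg_recording <- function(x, ...) {
  cat(sprintf("<ppg_recording> 4 x %d @ %g Hz, glucose %s mmol/L (%s)\n",
              ncol(x$samples), x$fs,
              if (is.na(x$glucose)) "NA" else sprintf("%.2f", x$glucose),
              x$subject_id))
  invisible(x)
}

#' Configuration for the synthetic PPG generator
#'
#' The generator emulates the statistical structure of four-channel
#' fingertip PPG acquisition (two NIR wavelengths x two sensor positions):
#' a single quasi-periodic pulsatile source (per-beat systolic peak plus a
#' delayed dicrotic wave, beat period from the heart rate with small
#' jitter) whose amplitude and width depend linearly on blood glucose,
#' mixed into four channels through a full-rank gain matrix on top of
#' per-channel DC offsets, plus independent Gaussian noise at a configured
#' SNR.  Because all four channels share the one pulsatile source, the
#' channel covariance of the noiseless signal has rank 1, so the leading
#' eigendirection carries all pulse (and hence glucose) information.
#'
#' @param n_recordings Number of recordings per dataset (default 100).
#' @param glucose_range Range the dataset's reference glucose values are
#'   drawn from, mmol/L (default 3.5--12, spanning hypo- to
#'   hyperglycemia).
#' @param heart_rate_range Per-recording heart rate range, bpm (default
#'   60--100).
#' @param duration_s Recording length in seconds (default 60).
#' @param fs Sampling rate in Hz (default 50); N = duration * fs = 3000
#'   samples at the defaults.
#' @param mixing_matrix Full-rank 4x4 channel-gain matrix; the effective
#'   per-channel pulse gains are its row sums.
#' @param dc_offset Per-channel DC levels (default `c(2.0, 1.8, 1.6, 1.4)`,
#'   distinct so the unit-medoid direction is informative).
#' @param snr_db Per-channel SNR of the additive Gaussian noise relative to
#'   the pulsatile (AC) power, in dB (default 10; `Inf` = noiseless).
#' @param glucose_effect Fractional pulse-amplitude change per mmol/L of
#'   glucose about `glucose_ref` (default 0.08); pulse width is coupled at
#'   0.3 times this coefficient.
#' @param wavelength_weights Per-channel multipliers on `glucose_effect`
#'   (default `c(1.25, 0.75, 1.25, 0.75)`: channels 1 and 3 share the more
#'   glucose-sensitive wavelength, 2 and 4 the less sensitive one).  NIR
#'   absorption by glucose is wavelength-dependent, so the pulse amplitude
#'   responds to glucose differently per wavelength; this puts glucose
#'   information into the channel-gain *direction* as well as the common
#'   amplitude, which is what makes ratio/direction features (the unit
#'   medoid in particular) informative.  All-equal weights reduce to a
#'   purely common-mode amplitude effect.
#' @param glucose_ref Glucose level at which the morphology coefficients
#'   are 1 (default 7 mmol/L).
#' @param seed Base RNG seed; recording `i` of a dataset uses
#'   `seed + i`, so datasets are reproducible element-wise.
#' @return An object of class `"gen_config"`.
#' @export
generator_config <- function(n_recordings = 100L,
                             glucose_range = c(3.5, 12),
                             heart_rate_range = c(60, 100),
                             duration_s = 60, fs = 50,
                             mixing_matrix = default_mixing_matrix(),
                             dc_offset = c(2.0, 1.8, 1.6, 1.4),
                             snr_db = 10,
                             glucose_effect = 0.08,
                             glucose_ref = 7,
                             wavelength_weights = c(1.25, 0.75, 1.25, 0.75),
                             seed = 1L) {
  stopifnot(length(glucose_range) == 2L, all(glucose_range > 0),
            diff(glucose_range) >= 0,
            length(heart_rate_range) == 2L, all(heart_rate_range > 0),
            duration_s > 0, fs > 0, length(dc_offset) == 4L,
            length(wavelength_weights) == 4L, all(wavelength_weights > 0),
            is.matrix(mixing_matrix), all(dim(mixing_matrix) == 4L))
  if (qr(mixing_matrix)$rank < 4L)
    stop("mixing_matrix must be full rank", call. = FALSE)
  if (is.na(snr_db)) stop("snr_db must be a number (or Inf)", call. = FALSE)
  structure(list(n_recordings = as.integer(n_recordings),
                 glucose_range = glucose_range,
                 heart_rate_range = heart_rate_range,
                 duration_s = duration_s, fs = fs,
                 mixing_matrix = mixing_matrix, dc_offset = dc_offset,
                 snr_db = snr_db, glucose_effect = glucose_effect,
                 glucose_ref = glucose_ref,
                 wavelength_weights = wavelength_weights,
                 seed = as.integer(seed)),
            class = "gen_config")
}

#' Default channel mixing matrix
#'
#' Diagonally dominant gains emulating two wavelengths at two sensor
#' positions with mild optical cross-talk; row sums (the effective channel
#' gains) are distinct and positive, and the matrix is full rank.
#'
#' @return A 4x4 numeric matrix.
#' @export
default_mixing_matrix <- function() {
  matrix(c(0.90, 0.05, 0.03, 0.02,
           0.05, 0.80, 0.02, 0.03,
           0.04, 0.02, 0.70, 0.04,
           0.02, 0.04, 0.05, 0.59),
         nrow = 4L, byrow = TRUE)
}

# Per-beat waveform on phase in [0, 1): systolic Gaussian peak plus a
# delayed, broader dicrotic wave; width_scale stretches both lobes.
pulse_waveform <- function(phase, width_scale = 1) {
  exp(-(phase - 0.22)^2 / (2 * (0.08 * width_scale)^2)) +
    0.45 * exp(-(phase - 0.55)^2 / (2 * (0.14 * width_scale)^2))
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate one synthetic four-channel PPG recording
#'
#' Builds a pulse train at a heart rate drawn from
#' `cfg$heart_rate_range` with 2% beat-period jitter, scales its amplitude
#' in channel `c` by
#' `1 + glucose_effect * wavelength_weights[c] * (glucose - glucose_ref)`
#' and its width (all channels) by
#' `1 + 0.3 * glucose_effect * (glucose - glucose_ref)`, mixes it into the
#' four channels (base gain = row sums of the mixing matrix) on top of the
#' DC offsets, and adds independent Gaussian noise per channel at
#' `cfg$snr_db` relative to that channel's pulsatile variance.  The clean
#' signal is a single source through fixed per-recording gains, so its
#' channel covariance has rank 1.  With `glucose_effect = 0` the output is
#' independent of `glucose`.
#'
#' @param cfg A [generator_config()].
#' @param glucose Reference glucose in mmol/L.
#' @param seed Integer seed for this recording's random draws.
#' @param subject_id,timestamp Metadata passed through to the recording.
#' @return A [ppg_recording()] of size 4 x (duration * fs).
#' @export
generate_recording <- function(cfg, glucose, seed,
                               subject_id = "S00", timestamp = "") {
  stopifnot(inherits(cfg, "gen_config"))
  glucose <- as.numeric(glucose)
  if (length(glucose) != 1L || is.na(glucose) || glucose <= 0)
    stop("glucose must be a single positive value (mmol/L)", call. = FALSE)
  n <- round(cfg$duration_s * cfg$fs)
  tt <- (seq_len(n) - 1) / cfg$fs
  amp <- 1 + cfg$glucose_effect * cfg$wavelength_weights *
    (glucose - cfg$glucose_ref)
  wid <- 1 + 0.3 * cfg$glucose_effect * (glucose - cfg$glucose_ref)
  if (any(amp <= 0) || wid <= 0)
    stop("glucose_effect * (glucose - glucose_ref) drives the pulse ",
         "morphology negative; reduce the coupling or the glucose range",
         call. = FALSE)
  with_seed(seed, {
    hr <- stats::runif(1, cfg$heart_rate_range[1], cfg$heart_rate_range[2])
    t_mean <- 60 / hr
    onsets <- -stats::runif(1) * t_mean       # random initial beat phase
    periods <- numeric(0)
    while (onsets[length(onsets)] < cfg$duration_s) {
      p <- t_mean * (1 + stats::rnorm(1, 0, 0.02))
      periods <- c(periods, p)
      onsets <- c(onsets, onsets[length(onsets)] + p)
    }
    beat <- findInterval(tt, onsets)
    phase <- (tt - onsets[beat]) / periods[beat]
    src <- pulse_waveform(phase, wid)
    gains <- amp * rowSums(cfg$mixing_matrix)
    clean <- cfg$dc_offset + gains %o% src    # 4 x n, rank-1 AC structure
    if (is.finite(cfg$snr_db)) {
      ac_sd <- apply(clean, 1L, stats::sd)
      noise_sd <- ac_sd / 10^(cfg$snr_db / 20)
      clean <- clean + noise_sd * matrix(stats::rnorm(4L * n), nrow = 4L)
    }
    ppg_recording(clean, fs = cfg$fs, glucose = glucose,
                  subject_id = subject_id, timestamp = timestamp)
  })
}

#' Generate a synthetic dataset of recordings
#'
#' Draws `cfg$n_recordings` glucose values uniformly from
#' `cfg$glucose_range` (using `cfg$seed`), then generates recording `i`
#' with seed `cfg$seed + i`.  The same configuration therefore always
#' yields the same dataset.
#'
#' @param cfg A [generator_config()].
#' @return A list of [ppg_recording()] objects (empty if
#'   `n_recordings = 0`).
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "gen_config"))
  if (cfg$n_recordings == 0L) return(list())
  glu <- with_seed(cfg$seed,
                   stats::runif(cfg$n_recordings,
                                cfg$glucose_range[1], cfg$glucose_range[2]))
  lapply(seq_len(cfg$n_recordings), function(i) {
    generate_recording(cfg, glu[i], seed = cfg$seed + i,
                       subject_id = sprintf("S%02d", ((i - 1) %% 18) + 1),
                       timestamp = sprintf("rec-%04d", i))
  })
}
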
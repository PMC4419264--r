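# Competition preprocessing chain: surface Laplacian (Hjorth
# nearest-neighbour subtraction) followed by sliding-window Welch PSD
# reduced to 2 Hz band powers between 8 and 30 Hz, 16 vectors/s.

#' Construct a raw multichannel EEG recording
#'
#' @param samples Numeric matrix, samples in rows, channels in columns
#'   (microvolts).
#' @param fs_hz Sampling rate in Hz (512 for the competition recordings).
#' @param channel_names Ordered channel names; default `ch1..chN`.
#' @param neighbor_map Named list mapping each channel to the channel
#'   names averaged by the Laplacian; `NULL` loads the default 8-channel
#'   10-20 map when the names match, otherwise it must be supplied.
#' @return An object of class `raw_recording`.
#' @export
raw_recording <- function(samples, fs_hz = 512,
                          channel_names = NULL, neighbor_map = NULL) {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  stopifnot(is.finite(fs_hz), fs_hz > 0)
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_len(ncol(samples)))
  if (length(channel_names) != ncol(samples))
    stop("channel_names length must match column count")
  if (is.null(neighbor_map) && setequal(channel_names, .eegfsel_channels))
    neighbor_map <- default_neighbor_map()
  if (!is.null(neighbor_map)) {
    unknown <- setdiff(unlist(neighbor_map), channel_names)
    if (length(unknown))
      stop("neighbor_map references unknown channels: ",
           paste(unknown, collapse = ", "))
  }
  structure(list(samples = samples, fs_hz = fs_hz,
                 channel_names = as.character(channel_names),
                 neighbor_map = neighbor_map),
            class = "raw_recording")
}

#' Default Hjorth neighbour map for the 8-channel 10-20 montage
#'
#' Nearest available neighbours among C3, Cz, C4, CP1, CP2, P3, Pz, P4;
#' shipped as JSON in `inst/extdata/montage8_neighbors.json`.
#'
#' @return Named list of neighbour channel names.
#' @export
default_neighbor_map <- function() {
  path <- system.file("extdata", "montage8_neighbors.json",
                      package = "eegfsel", mustWork = TRUE)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Surface-Laplacian spatial filter
#'
#' Hjorth form: each channel minus the mean of its mapped neighbours,
#' sample by sample. Sharpens local cortical activity by removing the
#' common component shared with surrounding electrodes.
#'
#' @param rec A [raw_recording()] with a neighbour map covering every
#'   channel.
#' @return A `raw_recording` of identical shape.
#' @export
surface_laplacian <- function(rec) {
  if (is.null(rec$neighbor_map))
    stop("recording has no neighbor_map; supply one to raw_recording()")
  out <- rec$samples
  for (ci in seq_along(rec$channel_names)) {
    ch <- rec$channel_names[ci]
    nb <- rec$neighbor_map[[ch]]
    if (is.null(nb) || !length(nb))
      stop("channel ", ch, " has no neighbors in the neighbor map")
    nbi <- match(nb, rec$channel_names)
    out[, ci] <- rec$samples[, ci] -
      rowMeans(rec$samples[, nbi, drop = FALSE])
  }
  raw_recording(out, rec$fs_hz, rec$channel_names, rec$neighbor_map)
}

#' Band-center grid
#'
#' Inclusive arithmetic grid of band-center frequencies; `(8, 30, 2)`
#' yields the 12 standard mu/beta bands 8, 10, ..., 30 Hz.
#'
#' @param band_lo,band_hi Lower/upper band centers in Hz.
#' @param res_hz Spacing in Hz; must divide `band_hi - band_lo`.
#' @return Numeric vector of band centers.
#' @export
band_grid <- function(band_lo = 8, band_hi = 30, res_hz = 2) {
  stopifnot(band_lo < band_hi, res_hz > 0)
  span <- band_hi - band_lo
  if (abs(span / res_hz - round(span / res_hz)) > 1e-9)
    stop("res_hz must divide band_hi - band_lo")
  seq(band_lo, band_hi, by = res_hz)
}

# One-sided Hann-tapered periodogram of a single window (per channel).
# Returns PSD at bin frequencies k * fs / n, k = 0..n/2.
.periodogram <- function(x, fs) {
  n <- length(x)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(n) / n)  # Hann
  xf <- stats::fft(x * w)
  nh <- floor(n / 2)
  p <- (Mod(xf[seq_len(nh + 1)])^2) / (fs * sum(w^2))
  # one-sided: double every bin except DC and (for even n) Nyquist
  dbl <- rep(2, nh + 1); dbl[1] <- 1
  if (n %% 2 == 0) dbl[nh + 1] <- 1
  p * dbl
}

#' Sliding-window Welch band-power features
#'
#' Applies a single Hann-tapered periodogram to each 1 s window (one
#' segment per window), slides the window by `hop_samples`, and reduces
#' each channel's PSD to band powers: the mean of the PSD bins whose
#' center lies in `[c - res/2, c + res/2)` for each band center `c`
#' (half-open on the upper side so adjacent bands never share a bin).
#' Features are ordered channel-major per [channel_band_index()]:
#' all bands of channel 1, then all bands of channel 2, and so on.
#'
#' With the competition settings (fs = 512, 1 s windows, 32-sample hop)
#' consecutive windows overlap by 93.75% and the output cadence is
#' 512/32 = 16 vectors per second.
#'
#' @param rec A [raw_recording()].
#' @param win_s Window length in seconds.
#' @param hop_samples Hop between window starts, in samples.
#' @param band_lo,band_hi,res_hz Band grid, see [band_grid()].
#' @param labels Optional per-window labels; default 0.
#' @return A [feature_session()] with `n_channels * n_bands` features
#'   per window.
#' @export
psd_features <- function(rec, win_s = 1, hop_samples = 32,
                         band_lo = 8, band_hi = 30, res_hz = 2,
                         labels = NULL) {
  fs <- rec$fs_hz
  nwin <- as.integer(round(fs * win_s))
  n <- nrow(rec$samples)
  if (n < nwin)
    stop("recording shorter than one analysis window (",
         n, " < ", nwin, " samples)")
  starts <- seq(1L, n - nwin + 1L, by = hop_samples)
  bands <- band_grid(band_lo, band_hi, res_hz)
  nch <- ncol(rec$samples)
  binf <- (seq_len(nwin %/% 2 + 1) - 1) * fs / nwin
  band_bins <- lapply(bands, function(c0) {
    which(binf >= c0 - res_hz / 2 & binf < c0 + res_hz / 2)
  })
  if (any(lengths(band_bins) == 0))
    stop("frequency resolution too coarse for the requested bands")
  feats <- matrix(0, nrow = length(starts), ncol = nch * length(bands))
  for (wi in seq_along(starts)) {
    s0 <- starts[wi]
    for (ci in seq_len(nch)) {
      p <- .periodogram(rec$samples[s0:(s0 + nwin - 1L), ci], fs)
      bp <- vapply(band_bins, function(b) mean(p[b]), numeric(1))
      feats[wi, ((ci - 1L) * length(bands) + 1L):(ci * length(bands))] <- bp
    }
  }
  if (is.null(labels)) labels <- rep(0L, length(starts))
  if (length(labels) == 1L) labels <- rep(labels, length(starts))
  feature_session(feats, labels,
                  vectors_per_second = as.integer(round(fs / hop_samples)),
                  session_id = "psd")
}

#' Window overlap of the sliding PSD analysis, in percent
#'
#' @param fs_hz Sampling rate.
#' @param win_s Window length in seconds.
#' @param hop_samples Hop between windows, in samples.
#' @return Overlap percentage between consecutive windows.
#' @export
window_overlap_percent <- function(fs_hz = 512, win_s = 1, hop_samples = 32) {
  nwin <- fs_hz * win_s
  100 * (nwin - hop_samples) / nwin
}
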
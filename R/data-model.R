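#' @useDynLib eegfsel, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats var rnorm runif
#' @importFrom utils head
"_PACKAGE"

# Channel/band layout of the precomputed competition feature vectors:
# 8 channels x 12 bands (8-30 Hz, 2 Hz apart), channel-major, 1-based.
.eegfsel_channels <- c("C3", "Cz", "C4", "CP1", "CP2", "P3", "Pz", "P4")
.eegfsel_bands_hz <- seq(8L, 30L, by = 2L)

#' Standard channel and band layout of the precomputed feature vectors
#'
#' The precomputed motor-imagery sessions carry one band-power value per
#' (channel, frequency band) pair: 8 channels (C3, Cz, C4, CP1, CP2, P3,
#' Pz, P4) times 12 bands (8, 10, ..., 30 Hz), laid out channel-major,
#' so feature 1 is C3 at 8 Hz and feature 96 is P4 at 30 Hz.
#'
#' @param channels Ordered character vector of channel names.
#' @param bands_hz Ordered numeric vector of band-center frequencies (Hz).
#' @return An object of class `channel_band_index`.
#' @export
#' @examples
#' idx <- channel_band_index()
#' feature_index("CP1", 10, idx)
channel_band_index <- function(channels = .eegfsel_channels,
                               bands_hz = .eegfsel_bands_hz) {
  stopifnot(length(channels) >= 1, length(bands_hz) >= 1,
            !anyDuplicated(channels), !anyDuplicated(bands_hz))
  structure(list(channels = as.character(channels),
                 bands_hz = as.numeric(bands_hz)),
            class = "channel_band_index")
}

#' Map a (channel, band) pair to its 1-based feature index
#'
#' `index = (row(channel) - 1) * n_bands + col(band)`, matching the
#' channel-major layout of the competition feature vectors.
#'
#' @param channel Channel name, e.g. `"C3"`.
#' @param freq_hz Band-center frequency in Hz, e.g. `10`.
#' @param index A [channel_band_index()].
#' @return Integer feature index in `1..n_channels*n_bands`.
#' @export
feature_index <- function(channel, freq_hz, index = channel_band_index()) {
  ci <- match(channel, index$channels)
  bi <- match(freq_hz, index$bands_hz)
  if (is.na(ci)) stop("unknown channel: ", channel)
  if (is.na(bi)) stop("unknown band frequency: ", freq_hz)
  as.integer((ci - 1L) * length(index$bands_hz) + bi)
}

#' Map a 1-based feature index back to its (channel, band) pair
#'
#' Exact inverse of [feature_index()].
#'
#' @param i Integer feature index (vectorised).
#' @param index A [channel_band_index()].
#' @return A data.frame with columns `feature`, `channel`, `freq_hz`.
#' @export
feature_to_channel_band <- function(i, index = channel_band_index()) {
  i <- as.integer(i)
  nb <- length(index$bands_hz)
  nmax <- nb * length(index$channels)
  if (any(is.na(i)) || any(i < 1L) || any(i > nmax))
    stop("feature index out of range 1..", nmax)
  data.frame(feature = i,
             channel = index$channels[(i - 1L) %/% nb + 1L],
             freq_hz = index$bands_hz[(i - 1L) %% nb + 1L],
             stringsAsFactors = FALSE)
}

#' Construct a labeled feature session
#'
#' A session is a sequence of per-window feature vectors (nonnegative
#' band powers) with one task label per window and a fixed cadence
#' (16 vectors per second for the competition data).
#'
#' @param features Numeric matrix, windows in rows, features in columns.
#' @param labels Integer task codes, one per row of `features`
#'   (the competition scheme uses 2 = LEFT, 3 = RIGHT, 7 = WORD).
#' @param vectors_per_second Positive integer cadence.
#' @param session_id Identifier string.
#' @return An object of class `feature_session`.
#' @export
feature_session <- function(features, labels, vectors_per_second = 16L,
                            session_id = "session") {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  labels <- as.integer(labels)
  if (nrow(features) != length(labels))
    stop("features row count (", nrow(features),
         ") differs from labels length (", length(labels), ")")
  if (anyNA(features) || any(!is.finite(features)))
    stop("non-finite feature values")
  if (any(features < 0))
    stop("negative feature values are not valid band powers")
  if (anyNA(labels)) stop("missing labels")
  vectors_per_second <- as.integer(vectors_per_second)
  stopifnot(length(vectors_per_second) == 1L, vectors_per_second >= 1L)
  structure(list(features = features,
                 labels = labels,
                 label_set = sort(unique(labels)),
                 vectors_per_second = vectors_per_second,
                 session_id = as.character(session_id)),
            class = "feature_session")
}

#' @export
print.feature_session <- function(x, ...) {
  cat(sprintf("<feature_session '%s': %d windows x %d features, %d vec/s, labels {%s}>\n",
              x$session_id, nrow(x$features), ncol(x$features),
              x$vectors_per_second, paste(x$label_set, collapse = ",")))
  invisible(x)
}

#' @export
dim.feature_session <- function(x) dim(x$features)

#' Restrict a session to a feature subset
#'
#' @param session A [feature_session()].
#' @param features Integer vector of 1-based feature indices to keep.
#' @return A `feature_session` with the selected columns, in the given order.
#' @export
subset_features <- function(session, features) {
  features <- as.integer(features)
  if (length(features) == 0) stop("empty feature subset")
  if (any(features < 1L) || any(features > ncol(session$features)))
    stop("feature index out of range")
  feature_session(session$features[, features, drop = FALSE],
                  session$labels, session$vectors_per_second,
                  session$session_id)
}

#' Construct a selection result
#'
#' Bundles the outcome of one selection run: the criterion/wrapper pair
#' used, the ordered candidate features with their accumulated scores,
#' the chosen subset, and the per-step evaluation trace (percent scale).
#'
#' @param method Tag, e.g. `"statistic+gmdh"`.
#' @param candidates Integer vector of candidate features, most relevant
#'   first.
#' @param scores Numeric vector of accumulated scores parallel to
#'   `candidates`.
#' @param selected Integer vector, the chosen subset (a sub-multiset of
#'   `candidates`).
#' @param trace Numeric vector of evaluation values in `[0, 100]`.
#' @param K Candidate-set size.
#' @param rho Cumulative-score threshold used in candidate selection.
#' @return An object of class `selection_result`.
#' @export
selection_result <- function(method, candidates, scores, selected,
                             trace = numeric(0), K = length(candidates),
                             rho = NA_real_) {
  candidates <- as.integer(candidates)
  selected <- as.integer(selected)
  if (!all(selected %in% candidates))
    stop("selected features must be a subset of the candidates")
  trace <- as.numeric(trace)
  if (length(trace) && (any(trace < 0) || any(trace > 100)))
    stop("trace values must lie in [0, 100] (percent scale)")
  structure(list(method = as.character(method),
                 candidates = candidates,
                 scores = as.numeric(scores),
                 selected = selected,
                 trace = trace,
                 K = as.integer(K),
                 rho = as.numeric(rho)),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result %s: K=%d candidates, selected {%s}%s>\n",
              x$method, x$K, paste(x$selected, collapse = ","),
              if (length(x$trace))
                sprintf(", final value %.2f%%", x$trace[length(x$trace)])
              else ""))
  invisible(x)
}
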
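# Session file readers/writers and the selection report format.
#
# Two on-disk dialects:
#   competition_ascii - one window per line, whitespace-separated floats,
#                       integer task label as the final column (the layout
#                       of the precomputed competition sessions);
#   csv               - header "f1,...,fM,label".

#' Load a feature session from disk
#'
#' @param path Path to the session file.
#' @param dialect `"competition_ascii"` (whitespace-delimited, label last)
#'   or `"csv"` (header `f1..fM,label`).
#' @param vectors_per_second Cadence recorded on the returned session.
#' @param session_id Identifier; defaults to the file name.
#' @return A [feature_session()].
#' @export
load_feature_session <- function(path,
                                 dialect = c("competition_ascii", "csv"),
                                 vectors_per_second = 16L,
                                 session_id = basename(path)) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "csv") {
    df <- utils::read.csv(path, check.names = FALSE)
    if (!"label" %in% names(df)) stop("csv dialect requires a 'label' column")
    lab <- df$label
    feats <- as.matrix(df[setdiff(names(df), "label")])
    return(feature_session(feats, lab, vectors_per_second, session_id))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty session file: ", path)
  toks <- strsplit(trimws(lines), "[[:space:]]+")
  arity <- length(toks[[1]])
  if (arity < 2) stop("line 1: expected at least one feature and a label")
  rows <- vector("list", length(toks))
  for (i in seq_along(toks)) {
    if (length(toks[[i]]) != arity)
      stop(sprintf("line %d: expected %d fields, found %d",
                   i, arity, length(toks[[i]])))
    v <- suppressWarnings(as.numeric(toks[[i]]))
    if (anyNA(v))
      stop(sprintf("line %d: non-numeric field", i))
    rows[[i]] <- v
  }
  m <- do.call(rbind, rows)
  feats <- m[, -arity, drop = FALSE]
  lab <- m[, arity]
  if (any(lab != round(lab)))
    stop("labels must be integer task codes")
  if (any(feats < 0)) {
    bad <- which(apply(feats < 0, 1, any))[1]
    stop(sprintf("line %d: negative feature value", bad))
  }
  feature_session(feats, as.integer(lab), vectors_per_second, session_id)
}

#' Write a feature session to disk
#'
#' Inverse of [load_feature_session()]; the round trip preserves feature
#' values to full double precision.
#'
#' @param session A [feature_session()].
#' @param path Output path.
#' @param dialect See [load_feature_session()].
#' @export
write_feature_session <- function(session, path,
                                  dialect = c("competition_ascii", "csv")) {
  dialect <- match.arg(dialect)
  feats <- session$features
  if (dialect == "csv") {
    df <- as.data.frame(feats)
    names(df) <- paste0("f", seq_len(ncol(feats)))
    df$label <- session$labels
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    txt <- apply(cbind(format(feats, digits = 17, trim = TRUE,
                              scientific = TRUE),
                       session$labels),
                 1, paste, collapse = " ")
    writeLines(txt, path)
  }
  invisible(path)
}

#' Write a selection report
#'
#' Persists a [selection_result()] as JSON, annotating each selected
#' feature with its channel and band name. The report is reloadable with
#' [read_selection_report()] without loss.
#'
#' @param result A [selection_result()].
#' @param path Output path.
#' @param index A [channel_band_index()] used to name features; pass
#'   `NULL` to omit channel/band names (non-standard feature arity).
#' @export
write_selection_report <- function(result, path,
                                   index = channel_band_index()) {
  named <- NULL
  if (!is.null(index) && length(result$selected)) {
    cb <- feature_to_channel_band(result$selected, index)
    named <- sprintf("%s-%gHz", cb$channel, cb$freq_hz)
  }
  obj <- list(method = result$method,
              rho = result$rho,
              K = result$K,
              candidates = result$candidates,
              scores = result$scores,
              selected = result$selected,
              selected_names = named,
              trace = result$trace)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a selection report written by [write_selection_report()]
#'
#' @param path Report path.
#' @return A [selection_result()].
#' @export
read_selection_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  selection_result(method = obj$method,
                   candidates = obj$candidates,
                   scores = obj$scores,
                   selected = if (length(obj$selected)) obj$selected else integer(0),
                   trace = if (length(obj$trace)) obj$trace else numeric(0),
                   K = obj$K,
                   rho = if (is.null(obj$rho)) NA_real_ else obj$rho)
}
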
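#' Event matrix
#'
#' The per-sample data unit: an events x channels numeric matrix with the
#' instrument channel names, the stain (marker) names, and a scale-state flag
#' that may only move forward along raw -> transformed -> standardized.
#'
#' @param values numeric matrix, events in rows.
#' @param channel_names instrument channel names (e.g. `"FL1-A"`, `"FSC-A"`).
#' @param marker_names stain names aligned with the channels; defaults to the
#'   channel names (the `$PnS` -> `$PnN` fallback rule).
#' @param scale_state one of `"raw"`, `"transformed"`, `"standardized"`.
#' @return an object of class `event_matrix`.
#' @export
event_matrix <- function(values, channel_names, marker_names = channel_names,
                         scale_state = "raw") {
  values <- as.matrix(values)
  if (any(!is.finite(values))) stopf("event_matrix: missing/non-finite values")
  if (ncol(values) != length(channel_names)) {
    stopf("event_matrix: %d columns but %d channel names",
          ncol(values), length(channel_names))
  }
  if (length(marker_names) != length(channel_names)) {
    stopf("event_matrix: marker/channel name length mismatch")
  }
  scale_state <- match.arg(scale_state, c("raw", "transformed", "standardized"))
  colnames(values) <- channel_names
  structure(
    list(values = values, channel_names = as.character(channel_names),
         marker_names = as.character(marker_names), scale_state = scale_state),
    class = "event_matrix"
  )
}

#' @export
print.event_matrix <- function(x, ...) {
  cat(sprintf("<event_matrix> %d events x %d channels [%s]\n",
              nrow(x$values), ncol(x$values), x$scale_state))
  cat("  markers:", paste(x$marker_names, collapse = ", "), "\n")
  invisible(x)
}

#' @noRd
n_events <- function(em) nrow(em$values)

#' Scatter channel names
#' @noRd
is_scatter_channel <- function(ch) grepl("^(FSC|SSC)", ch)

#' Spillover matrix
#'
#' A square mixing matrix over fluorescence channels. Rows are source
#' channels, so observed = true %*% S (the common FCS `$SPILLOVER`
#' convention); the diagonal is 1.
#'
#' @param S square numeric matrix with dimnames naming the channels.
#' @return class `spillover_matrix`.
#' @export
spillover_matrix <- function(S) {
  S <- as.matrix(S)
  if (nrow(S) != ncol(S)) stopf("spillover: matrix must be square")
  if (is.null(rownames(S))) stopf("spillover: channel dimnames required")
  if (max(abs(diag(S) - 1)) > 1e-12) stopf("spillover: diagonal must be 1")
  if (abs(det(S)) < 1e-12) stopf("spillover: matrix is singular")
  colnames(S) <- rownames(S)
  structure(S, class = c("spillover_matrix", "matrix", "array"))
}

#' Mix true intensities through a spillover matrix
#'
#' Applies observed = true %*% S to the fluorescence channels named in `S`;
#' other channels (scatter) pass through. This is the forward model that
#' [compensate()] inverts exactly.
#'
#' @param events an [event_matrix()] on the raw scale.
#' @param S a [spillover_matrix()].
#' @return a raw-scale `event_matrix` of observed intensities.
#' @export
mix_spillover <- function(events, S) {
  chs <- rownames(S)
  miss <- setdiff(chs, events$channel_names)
  if (length(miss)) stopf("mix_spillover: unknown channel(s): %s",
                          paste(miss, collapse = ", "))
  v <- events$values
  v[, chs] <- v[, chs, drop = FALSE] %*% unclass(S)
  event_matrix(v, events$channel_names, events$marker_names, events$scale_state)
}

#' Compensate fluorescence spillover
#'
#' Replaces the fluorescence columns by observed %*% solve(S), the exact
#' inverse of mixing by the spillover matrix. Scatter channels are untouched.
#'
#' @param events raw-scale [event_matrix()].
#' @param S a [spillover_matrix()] whose channels are a subset of the event
#'   channels.
#' @return compensated raw-scale `event_matrix`.
#' @export
compensate <- function(events, S) {
  if (events$scale_state != "raw") {
    stopf("compensate: expected raw-scale events, got %s", events$scale_state)
  }
  chs <- rownames(S)
  miss <- setdiff(chs, events$channel_names)
  if (length(miss)) stopf("compensate: unknown channel(s): %s",
                          paste(miss, collapse = ", "))
  Sinv <- tryCatch(solve(unclass(S)),
                   error = function(e) stopf("compensate: singular spillover matrix"))
  v <- events$values
  v[, chs] <- v[, chs, drop = FALSE] %*% Sinv
  event_matrix(v, events$channel_names, events$marker_names, "raw")
}

#' Apply the logicle transform to an event matrix
#'
#' Transforms all fluorescence channels with the given logicle parameters;
#' scatter channels (FSC*/SSC*) are left on their native linear scale. Moves
#' the scale state raw -> transformed.
#'
#' @param events raw-scale [event_matrix()].
#' @param p a [logicle_params()] object (or a named list of per-channel
#'   parameter objects).
#' @return transformed `event_matrix`.
#' @export
transform_events <- function(events, p = logicle_params()) {
  if (events$scale_state != "raw") {
    stopf("transform_events: expected raw-scale events")
  }
  v <- events$values
  for (j in seq_along(events$channel_names)) {
    ch <- events$channel_names[j]
    if (is_scatter_channel(ch)) next
    pj <- if (inherits(p, "logicle_params")) p else (p[[ch]] %||% logicle_params())
    v[, j] <- logicle(v[, j], pj)
  }
  event_matrix(v, events$channel_names, events$marker_names, "transformed")
}
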
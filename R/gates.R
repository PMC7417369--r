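#' Declarative gate
#'
#' A rectangle (one or two channels) with an action: `keep` retains events
#' inside the bounds, `exclude` removes events inside the bounds. Bounds
#' default to infinite (open) on each side.
#'
#' @param name gate label used in removal-count logs.
#' @param channels character vector of one or two channel names.
#' @param min,max numeric lower/upper bounds aligned with `channels`
#'   (`-Inf`/`Inf` for open sides).
#' @param action `"keep"` or `"exclude"`.
#' @return class `gate`.
#' @export
gate <- function(name, channels, min = rep(-Inf, length(channels)),
                 max = rep(Inf, length(channels)), action = c("keep", "exclude")) {
  action <- match.arg(action)
  stopifnot(length(channels) %in% 1:2,
            length(min) == length(channels), length(max) == length(channels))
  if (any(is.na(min)) || any(is.na(max))) stopf("gate '%s': NA bounds", name)
  structure(list(name = name, channels = as.character(channels),
                 min = as.numeric(min), max = as.numeric(max), action = action),
            class = "gate")
}

#' Apply an ordered gate set
#'
#' Gates are applied sequentially; events removed by an earlier gate are not
#' seen by later ones, so removal counts reproduce a manual sequential gating
#' tree. Retained events' values are never modified.
#'
#' @param events an [event_matrix()].
#' @param gates list of [gate()] objects.
#' @return list with `events` (filtered `event_matrix`), `removed` (named
#'   integer vector of per-gate removal counts) and `keep` (logical vector
#'   over the original events).
#' @export
apply_gates <- function(events, gates) {
  keep <- rep(TRUE, n_events(events))
  removed <- stats::setNames(integer(length(gates)),
                             vapply(gates, `[[`, "", "name"))
  for (gi in seq_along(gates)) {
    g <- gates[[gi]]
    miss <- setdiff(g$channels, events$channel_names)
    if (length(miss)) stopf("apply_gates: gate '%s' references unknown channel(s): %s",
                            g$name, paste(miss, collapse = ", "))
    inside <- rep(TRUE, n_events(events))
    for (ci in seq_along(g$channels)) {
      x <- events$values[, g$channels[ci]]
      inside <- inside & x >= g$min[ci] & x <= g$max[ci]
    }
    fail <- if (g$action == "keep") !inside else inside
    newly_removed <- keep & fail
    removed[gi] <- sum(newly_removed)
    keep <- keep & !fail
  }
  list(
    events = event_matrix(events$values[keep, , drop = FALSE],
                          events$channel_names, events$marker_names,
                          events$scale_state),
    removed = removed,
    keep = keep
  )
}

#' Preset exclusion gates
#'
#' The standard manual pre-gates of a thymocyte panel, expressed as
#' declarative rectangles: singlet selection on FSC-A vs FSC-W and
#' SSC-A vs SSC-W, debris/dead-cell exclusion on FSC-A vs SSC-A, optional
#' lineage-dump exclusion (CD3/CD14/CD19/CD56 high) and CD45 selection.
#'
#' @param fsc_w_max upper FSC-W bound for singlets.
#' @param ssc_w_max upper SSC-W bound for singlets.
#' @param scatter_min lower FSC-A/SSC-A bound below which events are debris.
#' @param lineage channels of a dump gate; events above `lineage_thresh`
#'   (transformed scale) in any of them are excluded when non-`NULL`.
#' @param lineage_thresh transformed-scale threshold for the dump gate.
#' @param cd45_min transformed-scale lower bound of a CD45 keep gate, or
#'   `NULL` to skip.
#' @return list of [gate()]s.
#' @export
preset_gates <- function(fsc_w_max = 150000, ssc_w_max = 150000,
                         scatter_min = 20000,
                         lineage = NULL, lineage_thresh = 2.5,
                         cd45_min = NULL) {
  gates <- list(
    gate("singlets_fsc", c("FSC-A", "FSC-W"), max = c(Inf, fsc_w_max)),
    gate("singlets_ssc", c("SSC-A", "SSC-W"), max = c(Inf, ssc_w_max)),
    gate("debris", c("FSC-A", "SSC-A"), min = c(scatter_min, scatter_min))
  )
  if (!is.null(lineage)) {
    for (ch in lineage) {
      gates <- c(gates, list(
        gate(paste0("lin_", ch), ch, min = lineage_thresh, action = "exclude")
      ))
    }
  }
  if (!is.null(cd45_min)) {
    gates <- c(gates, list(gate("cd45_pos", "CD45", min = cd45_min)))
  }
  gates
}

#' Read a gate set from JSON
#'
#' @param path JSON file: an array of objects with fields `name`, `channels`,
#'   optional `min`, `max`, and `action`.
#' @return list of [gate()]s.
#' @export
gates_from_json <- function(path) {
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(seq_len(nrow(spec)), function(i) {
    chs <- unlist(spec$channels[i])
    gate(spec$name[i], chs,
         min = if (!is.null(spec$min)) unlist(spec$min[i]) else rep(-Inf, length(chs)),
         max = if (!is.null(spec$max)) unlist(spec$max[i]) else rep(Inf, length(chs)),
         action = spec$action[i] %||% "keep")
  })
}
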
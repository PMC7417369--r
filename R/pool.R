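#' Per-sample metadata
#'
#' @param sample_id unique sample identifier.
#' @param age_days donor age in days at collection (>= 0).
#' @param batch acquisition-day label (the technical batch).
#' @param panel staining panel name.
#' @param fraction `"mnc"` (total mononuclear cells) or `"cd34"`
#'   (CD34-enriched).
#' @return class `sample_meta`.
#' @export
sample_meta <- function(sample_id, age_days, batch, panel,
                        fraction = c("mnc", "cd34")) {
  fraction <- match.arg(fraction)
  if (age_days < 0) stopf("sample_meta: age_days must be >= 0")
  if (!nzchar(batch)) stopf("sample_meta: batch label must be non-empty")
  structure(list(sample_id = as.character(sample_id),
                 age_days = as.numeric(age_days),
                 batch = as.character(batch), panel = as.character(panel),
                 fraction = fraction),
            class = "sample_meta")
}

#' Pool transformed samples and z-standardize selected markers
#'
#' Concatenates the transformed event matrices of all samples of one panel,
#' retains the requested marker subset (plus FSC-A/SSC-A if
#' `include_scatter`), and z-scores each retained column over the pooled
#' events with a single global mean and (population, i.e. divide-by-n)
#' standard deviation. Scatter channels are first min-max scaled onto the
#' logicle output range `[0, M]` so that their z-scores are commensurate with
#' the transformed fluorescence.
#'
#' @param samples list of `list(meta = sample_meta, events = event_matrix)`
#'   with transformed events.
#' @param marker_subset character vector of marker names to retain.
#' @param include_scatter append FSC-A and SSC-A to the subset.
#' @param scatter_top upper end of the scatter min-max range (the logicle
#'   `M`); default 4.5.
#' @return an object of class `pooled_dataset` with fields `values`
#'   (standardized events x markers), `transformed` (the same columns before
#'   z-scoring, for MFI profiling), `sample_id`, `batch`, `age_days`,
#'   `origin` (all `"full"` at creation), `markers`, `center`, `scale`.
#' @export
pool_and_standardize <- function(samples, marker_subset,
                                 include_scatter = FALSE, scatter_top = 4.5) {
  stopifnot(length(samples) >= 1)
  panels <- vapply(samples, function(s) s$meta$panel, character(1))
  if (length(unique(panels)) != 1) {
    stopf("pool_and_standardize: samples span several panels: %s",
          paste(unique(panels), collapse = ", "))
  }
  cols <- marker_subset
  if (include_scatter) cols <- c(cols, "FSC-A", "SSC-A")

  blocks <- lapply(samples, function(s) {
    em <- s$events
    if (em$scale_state != "transformed") {
      stopf("pool_and_standardize: sample %s is %s, expected transformed",
            s$meta$sample_id, em$scale_state)
    }
    idx <- match(cols, em$marker_names)
    if (anyNA(idx)) idx[is.na(idx)] <- match(cols[is.na(idx)], em$channel_names)
    if (anyNA(idx)) {
      stopf("pool_and_standardize: marker(s) not in panel: %s",
            paste(cols[is.na(idx)], collapse = ", "))
    }
    em$values[, idx, drop = FALSE]
  })
  v <- do.call(rbind, blocks)
  colnames(v) <- cols
  nper <- vapply(blocks, nrow, integer(1))
  sample_id <- rep(vapply(samples, function(s) s$meta$sample_id, character(1)), nper)
  batch <- rep(vapply(samples, function(s) s$meta$batch, character(1)), nper)
  age <- rep(vapply(samples, function(s) s$meta$age_days, numeric(1)), nper)

  # scatter -> [0, scatter_top] before z-scoring
  for (ch in intersect(c("FSC-A", "SSC-A"), cols)) {
    x <- v[, ch]
    rng <- range(x)
    if (rng[2] > rng[1]) {
      v[, ch] <- (x - rng[1]) / (rng[2] - rng[1]) * scatter_top
    } else {
      v[, ch] <- 0
    }
  }
  transformed <- v

  ctr <- colMeans(v)
  sdn <- sqrt(colMeans(sweep(v, 2, ctr)^2))  # population (n) variance
  zero <- sdn < 1e-12
  if (any(zero)) {
    stopf("pool_and_standardize: zero-variance marker(s): %s",
          paste(cols[zero], collapse = ", "))
  }
  z <- sweep(sweep(v, 2, ctr), 2, sdn, "/")

  structure(
    list(values = z, transformed = transformed,
         sample_id = sample_id, batch = batch, age_days = age,
         origin = rep("full", nrow(z)), markers = cols,
         center = ctr, scale = sdn),
    class = "pooled_dataset"
  )
}

#' @export
print.pooled_dataset <- function(x, ...) {
  cat(sprintf("<pooled_dataset> %d events x %d markers, %d samples, %d batches\n",
              nrow(x$values), length(x$markers),
              length(unique(x$sample_id)), length(unique(x$batch))))
  invisible(x)
}

#' Subset a pooled dataset by event index
#'
#' @param dataset a `pooled_dataset`.
#' @param idx integer event indices to retain.
#' @param origin optional origin tags for the retained events.
#' @return a `pooled_dataset` over the selected events.
#' @export
subset_pooled <- function(dataset, idx, origin = NULL) {
  out <- dataset
  out$values <- dataset$values[idx, , drop = FALSE]
  out$transformed <- dataset$transformed[idx, , drop = FALSE]
  out$sample_id <- dataset$sample_id[idx]
  out$batch <- dataset$batch[idx]
  out$age_days <- dataset$age_days[idx]
  out$origin <- origin %||% dataset$origin[idx]
  out
}
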
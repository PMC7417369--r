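# Acquisition-day batch correction: per-marker ordinary-least-squares
# residuals against a batch design, computed with limma's lmFit /
# residuals.MArrayLM machinery.

#' Batch design matrix
#'
#' Intercept plus reference-coded batch indicators for the per-event batch
#' labels of a pooled dataset.
#'
#' @param dataset a `pooled_dataset`.
#' @return list with `design` (events x coefficients matrix) and `batch`
#'   (factor of per-event labels).
#' @export
batch_design <- function(dataset) {
  b <- factor(dataset$batch)
  design <- if (nlevels(b) == 1) {
    matrix(1, length(b), 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    stats::model.matrix(~b)
  }
  colnames(design) <- c("(Intercept)",
                        if (nlevels(b) > 1) paste0("batch", levels(b)[-1]))
  if (qr(design)$rank < ncol(design)) {
    stopf("batch_design: design is rank deficient (collinear batch columns)")
  }
  list(design = design, batch = b)
}

#' Regress acquisition-day effects out of standardized markers
#'
#' For each marker column independently, fits ordinary least squares of the
#' column on the batch design and replaces values by the residuals (limma's
#' `lmFit` + `residuals.MArrayLM`). Per-batch column means are exactly equal
#' (zero) afterwards; the operation is idempotent. Residuals are not
#' re-standardized unless `restandardize = TRUE`.
#'
#' Only additive batch structure is removable by this model; multiplicative
#' gain differences between batches survive as residual variance.
#'
#' A warning is raised when batch is associated with donor age group
#' (breakpoint 548 days) at p < 0.05, since correcting a batch that
#' confounds age would also remove biology.
#'
#' @param dataset a standardized `pooled_dataset`.
#' @param design optional [batch_design()]; computed from the dataset when
#'   missing.
#' @param restandardize re-z-score the residual columns.
#' @return the corrected `pooled_dataset` (metadata unchanged).
#' @export
regress_out_batch <- function(dataset, design = NULL, restandardize = FALSE) {
  design <- design %||% batch_design(dataset)
  X <- dataset$values

  # batch-age association is a per-sample (not per-event) property
  smeta <- unique(data.frame(sample = dataset$sample_id, batch = dataset$batch,
                             age = dataset$age_days))
  if (length(unique(smeta$age)) > 1 && nlevels(design$batch) > 1) {
    grp <- factor(smeta$age > 548)
    if (nlevels(grp) > 1) {
      tab <- table(factor(smeta$batch), grp)
      pv <- tryCatch(suppressWarnings(stats::fisher.test(tab)$p.value),
                     error = function(e) 1)
      if (is.finite(pv) && pv < 0.05) {
        warnf("regress_out_batch: batch is associated with age group (p=%.3g); correction may remove age-related biology", pv)
      }
    }
  }

  fit <- limma::lmFit(t(X), design$design)
  res <- t(limma::residuals.MArrayLM(fit, t(X)))
  colnames(res) <- colnames(X)
  out <- dataset
  if (restandardize) {
    sdn <- sqrt(colMeans(sweep(res, 2, colMeans(res))^2))
    res <- sweep(sweep(res, 2, colMeans(res)), 2, pmax(sdn, 1e-12), "/")
  }
  out$values <- res
  out
}

#' Per-batch per-marker mean diagnostics
#'
#' @param before,after `pooled_dataset`s sharing events (pre/post
#'   correction).
#' @return data frame: batch, marker, mean_before, mean_after.
#' @export
batch_diagnostics <- function(before, after) {
  b <- factor(before$batch)
  rows <- lapply(levels(b), function(bl) {
    ix <- b == bl
    data.frame(batch = bl, marker = before$markers,
               mean_before = colMeans(before$values[ix, , drop = FALSE]),
               mean_after = colMeans(after$values[ix, , drop = FALSE]),
               row.names = NULL)
  })
  do.call(rbind, rows)
}
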
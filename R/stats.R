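# Population frequencies, F-measure benchmarking against reference gates,
# and age-group statistics with acquisition-day confounder adjustment.

#' Per-sample population frequencies
#'
#' For each sample, `fraction = (events labelled P and in denominator) /
#' (events in denominator)`. The denominator may be all events (`NULL`) or a
#' nested parent population defined by a label subset (e.g. restrict to the
#' CD3+TCRgd+ events before computing gamma-delta subset fractions).
#'
#' @param labels population label per event.
#' @param sample_ids sample id per event.
#' @param denominator optional character vector of labels forming the
#'   denominator population; default all events.
#' @param populations populations to report; default all labels seen.
#' @return data frame: sample x population matrix of fractions (long
#'   format columns `sample`, `population`, `frequency`).
#' @export
population_frequencies <- function(labels, sample_ids, denominator = NULL,
                                   populations = NULL) {
  stopifnot(length(labels) == length(sample_ids))
  populations <- populations %||% sort(unique(labels))
  rows <- list()
  for (s in unique(sample_ids)) {
    in_s <- sample_ids == s
    den <- if (is.null(denominator)) in_s else in_s & labels %in% denominator
    nden <- sum(den)
    if (nden == 0) {
      warnf("population_frequencies: empty denominator for sample %s", s)
      freq <- rep(NA_real_, length(populations))
    } else {
      freq <- vapply(populations, function(p) sum(den & labels == p) / nden,
                     numeric(1))
    }
    rows[[s]] <- data.frame(sample = s, population = populations,
                            frequency = freq, row.names = NULL)
  }
  do.call(rbind, rows)
}

#' Map candidate clusters onto reference population names
#'
#' The majority-overlap fallback used when no annotation map is supplied:
#' each cluster is mapped to the reference label it overlaps most; ties are
#' broken toward the larger reference class.
#'
#' @param cluster cluster id per event.
#' @param reference reference label per event.
#' @return named character vector cluster -> reference label.
#' @export
majority_overlap_map <- function(cluster, reference) {
  ref_sizes <- table(reference)
  out <- character(0)
  for (c in sort(unique(cluster))) {
    tab <- table(reference[cluster == c])
    best <- names(tab)[tab == max(tab)]
    if (length(best) > 1) best <- best[which.max(ref_sizes[best])]
    out[as.character(c)] <- best
  }
  out
}

#' F-measure report against reference labels
#'
#' One-vs-rest per population and per sample: precision `TP/(TP+FP)`, recall
#' `TP/(TP+FN)`, and their harmonic mean F (0 when precision + recall = 0,
#' including the case where the candidate predicts the population for zero
#' events). Populations absent from both candidate and reference in a sample
#' are omitted with a note column.
#'
#' @param candidate predicted population label per event.
#' @param reference reference (manual-gate or truth) label per event.
#' @param sample_ids sample id per event.
#' @param populations populations to score; default all reference labels.
#' @return data frame: sample, population, precision, recall, F.
#' @export
f_measure_report <- function(candidate, reference, sample_ids,
                             populations = NULL) {
  stopifnot(length(candidate) == length(reference),
            length(reference) == length(sample_ids))
  populations <- populations %||% sort(unique(reference))
  rows <- list()
  for (s in unique(sample_ids)) {
    ix <- sample_ids == s
    for (p in populations) {
      tp <- sum(ix & candidate == p & reference == p)
      fp <- sum(ix & candidate == p & reference != p)
      fn <- sum(ix & candidate != p & reference == p)
      if (tp + fp + fn == 0) next  # absent from both: omitted
      precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
      recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
      f <- if (precision + recall == 0) 0 else
        2 * precision * recall / (precision + recall)
      rows[[length(rows) + 1]] <- data.frame(sample = s, population = p,
                                             precision = precision,
                                             recall = recall, F = f)
    }
  }
  do.call(rbind, rows)
}

#' Age-group difference test with batch adjustment
#'
#' Per population, ordinary least squares of the per-sample frequency on the
#' group indicator plus acquisition-day (batch) indicators; two-sided t-test
#' on the group coefficient; p-values jointly adjusted across populations
#' (Benjamini-Hochberg by default).
#'
#' @param freq long frequency table from [population_frequencies()].
#' @param group named logical/character vector: sample -> group label (e.g.
#'   older than the 1.5-year breakpoint).
#' @param batch named character vector: sample -> acquisition day.
#' @param adjust_method multiple-testing method for [adjust_pvalues()].
#' @return data frame: population, estimate (group frequency difference),
#'   p_value, q_value.
#' @export
group_difference_test <- function(freq, group, batch,
                                  adjust_method = "BH") {
  pops <- unique(freq$population)
  res <- lapply(pops, function(p) {
    d <- freq[freq$population == p & !is.na(freq$frequency), ]
    g <- factor(group[d$sample])
    b <- factor(batch[d$sample])
    if (nlevels(g) < 2) stopf("group_difference_test: only one group for '%s'", p)
    if (min(table(g)) < 2) stopf("group_difference_test: < 2 samples in a group for '%s'", p)
    X <- if (nlevels(b) > 1) stats::model.matrix(~g + b) else stats::model.matrix(~g)
    if (qr(X)$rank < ncol(X)) {
      stopf("group_difference_test: group is confounded with batch for '%s' (rank-deficient design)", p)
    }
    fit <- stats::lm(d$frequency ~ X - 1)
    sm <- summary(fit)$coefficients
    gi <- grep("^Xg", rownames(sm))[1]
    data.frame(population = p, estimate = sm[gi, 1], p_value = sm[gi, 4])
  })
  out <- do.call(rbind, res)
  out$q_value <- adjust_pvalues(out$p_value, adjust_method)
  out
}

#' Paired population test
#'
#' Classical paired t-test between two per-sample frequency vectors:
#' `t = mean(d) / (sd(d)/sqrt(n))` with `n - 1` degrees of freedom,
#' two-sided.
#'
#' @param a,b numeric vectors over the same samples (`n >= 2`).
#' @return data frame: estimate (mean difference), t, df, p_value.
#' @export
paired_population_test <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  if (stats::sd(d) == 0) stopf("paired_population_test: zero-variance differences (t undefined)")
  tt <- stats::t.test(a, b, paired = TRUE)
  data.frame(estimate = mean(d), t = unname(tt$statistic),
             df = unname(tt$parameter), p_value = tt$p.value)
}

#' Multiple-testing adjustment
#'
#' Benjamini-Hochberg by default; Holm and Bonferroni available. Thin
#' wrapper over `stats::p.adjust` with input validation.
#'
#' @param p p-values in `[0, 1]`.
#' @param method `"BH"`, `"holm"` or `"bonferroni"`.
#' @return q-values in input order.
#' @export
adjust_pvalues <- function(p, method = c("BH", "holm", "bonferroni")) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1)) stopf("adjust_pvalues: p-values outside [0,1]")
  stats::p.adjust(p, method = method)
}

#' Loess trend of frequency against log2 age
#'
#' Tricube-weighted local polynomial regression (`stats::loess`, direct
#' surface) evaluated at the observed x.
#'
#' @param x predictor (log2 age in days).
#' @param y response (frequency).
#' @param span loess span in `(0, 1]`; default 1.
#' @param degree local polynomial degree; default 2.
#' @return fitted values at the observed `x`.
#' @export
loess_trend <- function(x, y, span = 1, degree = 2) {
  if (span <= 0 || span > 1) stopf("loess_trend: span must lie in (0, 1]")
  if (length(x) < degree + 2) stopf("loess_trend: need n >= degree + 2")
  fit <- stats::loess(y ~ x, span = span, degree = degree,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  as.numeric(stats::predict(fit, newdata = data.frame(x = x)))
}
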
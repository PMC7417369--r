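# Synthetic thymus cytometry cohorts with planted ground truth. Population
# intensities are Gaussian on the logicle (transformed) scale and mapped to
# the raw scale by the inverse biexponential, so that gates drawn on
# biexponential axes agree with the planted truth by construction.

#' Population specification
#'
#' @param name population name.
#' @param frequency fraction of the panel's events in `[0, 1]`.
#' @param marker_locations named numeric: per-marker mean on the transformed
#'   (logicle, decades) scale.
#' @param marker_scales named numeric or scalar: per-marker sd on the
#'   transformed scale (>= 0; 0 gives degenerate point populations).
#' @param panel panel name.
#' @param scatter_locations,scatter_scales named numeric over
#'   FSC-A/SSC-A/FSC-W/SSC-W on the raw scale.
#' @return class `population_spec`.
#' @export
population_spec <- function(name, frequency, marker_locations,
                            marker_scales = 0.18, panel,
                            scatter_locations = c("FSC-A" = 80000, "SSC-A" = 30000,
                                                  "FSC-W" = 60000, "SSC-W" = 60000),
                            scatter_scales = c("FSC-A" = 8000, "SSC-A" = 5000,
                                               "FSC-W" = 4000, "SSC-W" = 4000)) {
  if (frequency < 0 || frequency > 1) stopf("population %s: frequency outside [0,1]", name)
  if (length(marker_scales) == 1) {
    marker_scales <- stats::setNames(rep(marker_scales, length(marker_locations)),
                                     names(marker_locations))
  }
  if (any(marker_scales < 0)) stopf("population %s: negative scale", name)
  structure(list(name = name, frequency = frequency,
                 marker_locations = marker_locations,
                 marker_scales = marker_scales, panel = panel,
                 scatter_locations = scatter_locations,
                 scatter_scales = scatter_scales),
            class = "population_spec")
}

#' Cohort specification
#'
#' Bundles panels, populations, sample metadata, batch and age effects,
#' spillover and artifact rates into one reproducible recipe for a synthetic
#' cohort.
#'
#' @param panels named list: panel name -> character vector of fluorescence
#'   markers (scatter channels are implicit in every panel).
#' @param populations list of [population_spec()]s; per panel, frequencies
#'   must sum to 1 (tolerance 1e-9).
#' @param n_samples named integer: samples per fraction,
#'   e.g. `c(mnc = 26, cd34 = 35)`.
#' @param events_per_sample events per simulated sample (incl. artifacts).
#' @param panel_fraction named character: panel name -> `"mnc"`/`"cd34"`.
#' @param age_range_days samples are spread on a log2-day grid across this
#'   range.
#' @param n_batches number of acquisition days; samples are assigned
#'   round-robin, so batches are balanced over the age range.
#' @param age_effects list of `list(population, breakpoint_days, delta)`:
#'   frequency step added to the population for samples older than the
#'   breakpoint (other populations rescale proportionally).
#' @param batch_offsets,batch_gains numeric vectors (recycled over batches):
#'   additive offset / multiplicative gain applied to raw fluorescence of
#'   each batch. Gains default close to 1: only additive structure is
#'   removable by the linear batch correction downstream.
#' @param spillover_bleed off-diagonal spillover into adjacent channels.
#' @param doublet_rate,debris_rate artifact fractions in `[0, 0.5)`.
#' @param freq_jitter_sd sd of per-sample logit-scale jitter on population
#'   frequencies (biological between-donor variability).
#' @param master_seed integer master seed; all per-sample seeds derive from it.
#' @return class `cohort_spec`.
#' @export
cohort_spec <- function(panels, populations,
                        n_samples = c(mnc = 26, cd34 = 35),
                        events_per_sample = 4000,
                        panel_fraction = NULL,
                        age_range_days = c(1, 5110),
                        n_batches = 5,
                        age_effects = list(),
                        batch_offsets = c(-50, -25, 0, 25, 50),
                        batch_gains = c(0.92, 0.96, 1, 1.04, 1.08),
                        spillover_bleed = 0.03,
                        doublet_rate = 0.03, debris_rate = 0.05,
                        freq_jitter_sd = 0.15,
                        master_seed = 1L) {
  if (any(n_samples < 2)) stopf("cohort_spec: n_samples must be >= 2")
  if (doublet_rate < 0 || doublet_rate >= 0.5 ||
      debris_rate < 0 || debris_rate >= 0.5) {
    stopf("cohort_spec: artifact rates must lie in [0, 0.5)")
  }
  pop_panel <- vapply(populations, `[[`, "", "panel")
  for (pn in names(panels)) {
    fr <- sum(vapply(populations[pop_panel == pn], `[[`, 0, "frequency"))
    if (abs(fr - 1) > 1e-9) {
      stopf("cohort_spec: panel '%s' frequencies sum to %.12f, not 1", pn, fr)
    }
  }
  pop_names <- vapply(populations, `[[`, "", "name")
  for (ae in age_effects) {
    if (!ae$population %in% pop_names) {
      stopf("cohort_spec: age effect on unknown population '%s'", ae$population)
    }
  }
  panel_fraction <- panel_fraction %||%
    stats::setNames(ifelse(names(panels) == "cd34", "cd34", "mnc"), names(panels))
  structure(list(panels = panels, populations = populations,
                 n_samples = n_samples, events_per_sample = events_per_sample,
                 panel_fraction = panel_fraction,
                 age_range_days = age_range_days, n_batches = n_batches,
                 age_effects = age_effects,
                 batch_offsets = batch_offsets, batch_gains = batch_gains,
                 spillover_bleed = spillover_bleed,
                 doublet_rate = doublet_rate, debris_rate = debris_rate,
                 freq_jitter_sd = freq_jitter_sd,
                 master_seed = as.integer(master_seed)),
            class = "cohort_spec")
}

# Canonical transformed-scale levels (decades on a 0-4.5 display)
.lv <- c(neg = 0.8, lo = 2.4, hi = 3.5, vhi = 3.8)

#' Default synthetic thymus cohort specification
#'
#' Builds the study-shaped default cohort: five staining panels whose
#' retained marker sets match a thymocyte immunophenotyping design (CD34
#' progenitor panel; monocyte/macrophage; B-cell/DC; gamma-delta T-cell;
#' alpha-beta T-cell), 26 MNC and 35 CD34-enriched samples spanning birth to
#' 14 years on a log2-day age grid, acquisition-day batches, a rare
#' plasmacytoid-DC population at 0.2%, and a B-cell frequency step of +0.02
#' for donors older than 1.5 years (548 days).
#'
#' @param events_per_sample events per simulated sample; default 4000.
#' @param master_seed master seed; default 1.
#' @param b_cell_delta planted post-1.5-year B-cell frequency step.
#' @param ... further arguments passed to [cohort_spec()].
#' @return a [cohort_spec()].
#' @export
build_default_thymus_spec <- function(events_per_sample = 4000, master_seed = 1L,
                                      b_cell_delta = 0.02, ...) {
  L <- .lv
  panels <- list(
    cd34 = c("CD34", "CD44", "CD7", "CD5", "CD123", "LIN"),
    mono = c("CD14", "CD16", "HLA-DR"),
    bdc  = c("CX3CR1", "HLA-DR", "CD19", "CD1c", "CD123", "CD45"),
    gd   = c("TCRgd", "Vg9", "Vd1", "Vd2", "CD3"),
    ab   = c("CD4", "CD8b", "TCRab", "CD3", "CD69", "CD1a", "CD28")
  )
  loc <- function(panel, ...) {
    x <- c(...)
    # named level constants concatenate as "<marker>.<level>": strip the suffix
    if (length(x)) names(x) <- sub("\\.(neg|lo|hi|vhi)$", "", names(x))
    bad <- setdiff(names(x), panels[[panel]])
    if (length(bad)) stopf("unknown marker(s) for panel %s: %s", panel,
                           paste(bad, collapse = ", "))
    full <- stats::setNames(rep(L["neg"], length(panels[[panel]])), panels[[panel]])
    full[names(x)] <- x
    full
  }
  mono_scatter <- c("FSC-A" = 110000, "SSC-A" = 70000, "FSC-W" = 60000, "SSC-W" = 60000)
  pops <- list(
    # --- CD34-enriched progenitor panel ---
    population_spec("CD7-CD34+ progenitor", 0.05,
                    loc("cd34", CD34 = L["hi"], CD44 = L["hi"]), panel = "cd34"),
    population_spec("lin-CD34+CD1a-", 0.40,
                    loc("cd34", CD34 = L["hi"], CD44 = L["hi"], CD7 = L["hi"]),
                    panel = "cd34"),
    population_spec("lin-CD34+CD1a+", 0.45,
                    loc("cd34", CD34 = L["hi"], CD7 = L["hi"], CD5 = L["hi"]),
                    panel = "cd34"),
    population_spec("lin-CD44+CD123+ DC progenitor", 0.05,
                    loc("cd34", CD44 = L["hi"], CD123 = L["hi"], CD7 = L["lo"]),
                    panel = "cd34"),
    population_spec("lin+", 0.05,
                    loc("cd34", LIN = L["hi"], CD5 = L["lo"]), panel = "cd34"),
    # --- monocyte/macrophage panel (scatter is informative here) ---
    population_spec("thymocytes", 0.97, loc("mono"), panel = "mono"),
    population_spec("monocytes", 0.02,
                    loc("mono", CD14 = L["hi"], `HLA-DR` = L["hi"]),
                    panel = "mono", scatter_locations = mono_scatter),
    population_spec("macrophages", 0.01,
                    loc("mono", CD16 = L["hi"], `HLA-DR` = L["hi"]),
                    panel = "mono", scatter_locations = mono_scatter),
    # --- B-cell / dendritic-cell panel ---
    population_spec("T-lineage thymocytes", 0.96,
                    loc("bdc", CD45 = L["hi"]), panel = "bdc"),
    population_spec("B cells", 0.03,
                    loc("bdc", CD19 = L["hi"], `HLA-DR` = L["hi"], CD45 = L["hi"]),
                    panel = "bdc"),
    population_spec("pDC", 0.002,
                    loc("bdc", CD123 = L["hi"], `HLA-DR` = L["hi"], CD45 = L["hi"]),
                    panel = "bdc"),
    population_spec("cDC/macro", 0.008,
                    loc("bdc", CX3CR1 = L["hi"], `HLA-DR` = L["hi"],
                        CD1c = L["hi"], CD45 = L["hi"]),
                    panel = "bdc", scatter_locations = mono_scatter),
    # --- gamma-delta T-cell panel ---
    population_spec("TCRab thymocytes", 0.98,
                    loc("gd", CD3 = L["lo"]), panel = "gd"),
    population_spec("gd Vg9+Vd1-Vd2+", 0.008,
                    loc("gd", TCRgd = L["hi"], Vg9 = L["hi"], Vd2 = L["hi"],
                        CD3 = L["hi"]), panel = "gd"),
    population_spec("gd Vg9+Vd1+Vd2-", 0.006,
                    loc("gd", TCRgd = L["hi"], Vg9 = L["hi"], Vd1 = L["hi"],
                        CD3 = L["hi"]), panel = "gd"),
    population_spec("gd Vg9-Vd1+Vd2-", 0.003,
                    loc("gd", TCRgd = L["hi"], Vd1 = L["hi"], CD3 = L["hi"]),
                    panel = "gd"),
    population_spec("gd Vg9+Vd1-Vd2-", 0.002,
                    loc("gd", TCRgd = L["hi"], Vg9 = L["hi"], CD3 = L["hi"]),
                    panel = "gd"),
    population_spec("gd Vg9-Vd1-Vd2+", 0.001,
                    loc("gd", TCRgd = L["hi"], Vd2 = L["hi"], CD3 = L["hi"]),
                    panel = "gd"),
    # --- alpha-beta T-cell developmental panel (>= 10 populations) ---
    population_spec("DN CD3-", 0.02, loc("ab"), panel = "ab"),
    population_spec("ISP CD4+CD8b-CD3-", 0.04,
                    loc("ab", CD4 = L["hi"], CD1a = L["hi"]), panel = "ab"),
    population_spec("DP CD3-", 0.505,
                    loc("ab", CD4 = L["hi"], CD8b = L["hi"], CD1a = L["hi"]),
                    panel = "ab"),
    population_spec("DP CD3+", 0.25,
                    loc("ab", CD4 = L["hi"], CD8b = L["hi"], CD3 = L["hi"],
                        TCRab = L["hi"], CD1a = L["hi"], CD69 = L["lo"]),
                    panel = "ab"),
    population_spec("SP CD4+CD1a hi", 0.06,
                    loc("ab", CD4 = L["hi"], CD3 = L["hi"], TCRab = L["hi"],
                        CD1a = L["vhi"], CD69 = L["hi"], CD28 = L["hi"]),
                    panel = "ab"),
    population_spec("SP CD4+CD1a lo", 0.04,
                    loc("ab", CD4 = L["hi"], CD3 = L["hi"], TCRab = L["hi"],
                        CD1a = L["lo"], CD28 = L["hi"]), panel = "ab"),
    population_spec("SP CD8b+CD1a hi", 0.03,
                    loc("ab", CD8b = L["hi"], CD3 = L["hi"], TCRab = L["hi"],
                        CD1a = L["vhi"], CD69 = L["hi"], CD28 = L["hi"]),
                    panel = "ab"),
    population_spec("SP CD8b+CD1a lo", 0.02,
                    loc("ab", CD8b = L["hi"], CD3 = L["hi"], TCRab = L["hi"],
                        CD1a = L["lo"], CD28 = L["hi"]), panel = "ab"),
    population_spec("gd T cells", 0.02,
                    loc("ab", CD3 = L["hi"], CD69 = L["lo"]), panel = "ab"),
    population_spec("CD4-CD8b+CD3- minor", 0.015,
                    loc("ab", CD8b = L["hi"], CD1a = L["hi"]),
                    panel = "ab")
  )
  cohort_spec(panels = panels, populations = pops,
              events_per_sample = events_per_sample,
              age_effects = list(list(population = "B cells",
                                      breakpoint_days = 548, delta = b_cell_delta)),
              master_seed = master_seed, ...)
}

#' Default spillover matrix for a panel
#'
#' Unit diagonal with `bleed` into the next channel and `bleed/2` into the
#' previous one — the well-conditioned banded structure typical of an
#' ordered detector layout.
#'
#' @param spec a [cohort_spec()].
#' @param panel panel name.
#' @return a [spillover_matrix()] over the panel's fluorescence markers.
#' @export
spec_spillover <- function(spec, panel) {
  chs <- spec$panels[[panel]]
  k <- length(chs)
  S <- diag(k)
  b <- spec$spillover_bleed
  if (k > 1 && b > 0) {
    for (i in 1:(k - 1)) S[i, i + 1] <- b
    for (i in 2:k) S[i, i - 1] <- b / 2
  }
  dimnames(S) <- list(chs, chs)
  spillover_matrix(S)
}

#' Sample metadata table for one panel of the cohort
#' @noRd
spec_sample_meta <- function(spec, panel) {
  frac <- spec$panel_fraction[[panel]]
  n <- spec$n_samples[[frac]]
  ages <- round(2^seq(log2(spec$age_range_days[1]),
                      log2(spec$age_range_days[2]), length.out = n))
  batches <- paste0("day", (seq_len(n) - 1L) %% spec$n_batches + 1L)
  lapply(seq_len(n), function(i) {
    sample_meta(sprintf("%s_s%02d", panel, i), ages[i], batches[i], panel, frac)
  })
}

#' Age-adjusted population frequencies for one sample
#' @noRd
sample_frequencies_for <- function(spec, panel, age_days) {
  pops <- spec$populations[vapply(spec$populations, `[[`, "", "panel") == panel]
  f <- stats::setNames(vapply(pops, `[[`, 0, "frequency"),
                       vapply(pops, `[[`, "", "name"))
  for (ae in spec$age_effects) {
    if (ae$population %in% names(f) && age_days > ae$breakpoint_days) {
      target <- min(max(f[ae$population] + ae$delta, 0), 1)
      others <- setdiff(names(f), ae$population)
      f[others] <- f[others] * (1 - target) / sum(f[others])
      f[ae$population] <- target
    }
  }
  f / sum(f)
}

#' Simulate one synthetic sample
#'
#' Draws per-event population labels from the (age-adjusted, jittered)
#' frequencies, per-population Gaussian intensities on the transformed scale,
#' maps them to the raw scale by the inverse biexponential, applies the
#' batch gain/offset, mixes fluorescence through the spillover matrix, and
#' injects doublets (event-pair sums with FSC-W widened 1.8x) and debris
#' (low-scatter events) at the spec rates. Deterministic given the seed.
#'
#' @param spec a [cohort_spec()].
#' @param panel panel name.
#' @param sample_index 1-based index within the panel's cohort.
#' @param seed integer seed; defaults to the cohort-derived per-sample seed.
#' @return list with `meta` ([sample_meta()]), `events` (raw-scale
#'   [event_matrix()]), and `truth` (list: `event_labels`,
#'   `sample_frequencies`) — the oracle the downstream benchmarks use.
#' @export
simulate_sample <- function(spec, panel, sample_index, seed = NULL) {
  metas <- spec_sample_meta(spec, panel)
  if (sample_index < 1 || sample_index > length(metas)) {
    stopf("simulate_sample: sample_index %d outside 1..%d",
          sample_index, length(metas))
  }
  meta <- metas[[sample_index]]
  seed <- seed %||% derive_seed(spec$master_seed, match(panel, names(spec$panels)),
                                sample_index)
  pops <- spec$populations[vapply(spec$populations, `[[`, "", "panel") == panel]
  names(pops) <- vapply(pops, `[[`, "", "name")
  fl <- spec$panels[[panel]]
  scat <- c("FSC-A", "SSC-A", "FSC-W", "SSC-W")
  p <- logicle_params()

  with_seed(seed, {
    f <- sample_frequencies_for(spec, panel, meta$age_days)
    if (spec$freq_jitter_sd > 0) {
      lg <- log(f / (1 - f)) + stats::rnorm(length(f), 0, spec$freq_jitter_sd)
      f <- 1 / (1 + exp(-lg))
      f <- f / sum(f)
    }
    n_total <- spec$events_per_sample
    n_doub <- round(spec$doublet_rate * n_total)
    n_deb <- round(spec$debris_rate * n_total)
    n_real <- n_total - n_doub - n_deb

    labels <- sample(names(f), n_real, replace = TRUE, prob = f)
    tr <- matrix(0, n_real, length(fl), dimnames = list(NULL, fl))
    sc <- matrix(0, n_real, length(scat), dimnames = list(NULL, scat))
    for (pn in unique(labels)) {
      ix <- which(labels == pn)
      pp <- pops[[pn]]
      for (m in fl) {
        tr[ix, m] <- stats::rnorm(length(ix), pp$marker_locations[m],
                                  pp$marker_scales[m])
      }
      for (m in scat) {
        sc[ix, m] <- pmax(stats::rnorm(length(ix), pp$scatter_locations[m],
                                       pp$scatter_scales[m]), 1)
      }
    }
    raw <- apply(tr, 2, logicle_inverse, p = p)
    if (n_real == 1) raw <- matrix(raw, 1, dimnames = list(NULL, fl))

    # doublets: sums of random event pairs, FSC-W inflated 1.8x
    if (n_doub > 0) {
      i1 <- sample.int(n_real, n_doub, replace = TRUE)
      i2 <- sample.int(n_real, n_doub, replace = TRUE)
      d_raw <- raw[i1, , drop = FALSE] + raw[i2, , drop = FALSE]
      d_sc <- sc[i1, , drop = FALSE] + sc[i2, , drop = FALSE]
      d_sc[, "FSC-W"] <- 1.8 * (sc[i1, "FSC-W"] + sc[i2, "FSC-W"]) / 2
      d_sc[, "SSC-W"] <- (sc[i1, "SSC-W"] + sc[i2, "SSC-W"]) / 2
      raw <- rbind(raw, d_raw); sc <- rbind(sc, d_sc)
      labels <- c(labels, rep("doublet", n_doub))
    }
    # debris: low scatter, near-zero fluorescence
    if (n_deb > 0) {
      b_raw <- matrix(stats::rnorm(n_deb * length(fl), 30, 20), n_deb,
                      dimnames = list(NULL, fl))
      b_sc <- cbind(`FSC-A` = pmax(stats::rnorm(n_deb, 8000, 2500), 1),
                    `SSC-A` = pmax(stats::rnorm(n_deb, 6000, 2000), 1),
                    `FSC-W` = pmax(stats::rnorm(n_deb, 60000, 4000), 1),
                    `SSC-W` = pmax(stats::rnorm(n_deb, 60000, 4000), 1))
      raw <- rbind(raw, b_raw); sc <- rbind(sc, b_sc)
      labels <- c(labels, rep("debris", n_deb))
    }
    ord <- sample.int(length(labels))
    raw <- raw[ord, , drop = FALSE]; sc <- sc[ord, , drop = FALSE]
    labels <- labels[ord]

    # batch effect on raw fluorescence, then spillover mixing
    b_ix <- (sample_index - 1L) %% spec$n_batches + 1L
    gain <- rep_len(spec$batch_gains, spec$n_batches)[b_ix]
    offset <- rep_len(spec$batch_offsets, spec$n_batches)[b_ix]
    raw <- raw * gain + offset
    S <- spec_spillover(spec, panel)
    observed <- raw %*% unclass(S)

    em <- event_matrix(cbind(observed, sc), c(fl, scat), c(fl, scat), "raw")
    truth <- list(
      event_labels = labels,
      sample_frequencies = as.numeric(table(factor(labels, levels = unique(labels)))) /
        length(labels)
    )
    names(truth$sample_frequencies) <- unique(labels)
    truth$sample_frequencies <-
      truth$sample_frequencies[sort(names(truth$sample_frequencies))]
    list(meta = meta, events = em, truth = truth)
  })
}

#' Simulate a full cohort for one panel
#'
#' Per-sample seeds are derived from the master seed and the sample index,
#' so identical specs give bit-identical cohorts and any sample can be
#' regenerated in isolation. MNC panels carry `n_samples["mnc"]` samples
#' (default 26); the CD34-enriched panel `n_samples["cd34"]` (default 35).
#'
#' @param spec a [cohort_spec()].
#' @param panel panel name (default the first panel).
#' @return list of per-sample `list(meta, events, truth)`.
#' @export
simulate_cohort <- function(spec, panel = names(spec$panels)[1]) {
  if (!panel %in% names(spec$panels)) stopf("simulate_cohort: unknown panel '%s'", panel)
  n <- spec$n_samples[[spec$panel_fraction[[panel]]]]
  lapply(seq_len(n), function(i) simulate_sample(spec, panel, i))
}

#' Write a simulated cohort to disk
#'
#' One FCS 3.1 file per sample, a sidecar truth table
#' (`<sample>_truth.tsv`: event_index, population) and a cohort manifest
#' (`manifest.json`: sample id, age_days, batch, panel, seed).
#'
#' @param cohort output of [simulate_cohort()].
#' @param spec the generating [cohort_spec()].
#' @param panel panel name.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_cohort_fcs <- function(cohort, spec, panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  S <- spec_spillover(spec, panel)
  manifest <- lapply(seq_along(cohort), function(i) {
    s <- cohort[[i]]
    fcs <- file.path(dir, paste0(s$meta$sample_id, ".fcs"))
    write_fcs(s$events, fcs, spillover = S)
    write_tsv_out(data.frame(event_index = seq_along(s$truth$event_labels),
                             population = s$truth$event_labels),
                  file.path(dir, paste0(s$meta$sample_id, "_truth.tsv")))
    list(sample_id = s$meta$sample_id, age_days = s$meta$age_days,
         batch = s$meta$batch, panel = panel,
         seed = derive_seed(spec$master_seed,
                            match(panel, names(spec$panels)), i),
         fcs = basename(fcs))
  })
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE)
  invisible(mpath)
}
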
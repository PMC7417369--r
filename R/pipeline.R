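# End-to-end orchestration: simulate/ingest -> preprocess -> subsample ->
# (batch-correct) -> cluster -> annotate -> benchmark -> statistics, with
# reproducible seed fan-out and a run manifest.

#' Retained marker subsets per default panel
#'
#' The marker subsets carried into subsampling and KNN-graph construction
#' for each staining panel, and whether FSC-A/SSC-A accompany them.
#'
#' @param panel panel name.
#' @return list with `markers` and `scatter` (logical).
#' @export
panel_retained_markers <- function(panel) {
  switch(panel,
    cd34 = list(markers = c("CD34", "CD44", "CD7", "CD5", "CD123"), scatter = FALSE),
    mono = list(markers = c("CD14", "CD16", "HLA-DR"), scatter = TRUE),
    bdc  = list(markers = c("CX3CR1", "HLA-DR", "CD19", "CD1c", "CD123"), scatter = TRUE),
    gd   = list(markers = c("TCRgd", "Vg9", "Vd1", "Vd2"), scatter = TRUE),
    ab   = list(markers = c("CD4", "CD8b", "TCRab", "CD3", "CD69", "CD1a", "CD28"),
                scatter = FALSE),
    stopf("panel_retained_markers: unknown panel '%s'", panel)
  )
}

#' Default exclusion gates per panel
#'
#' Singlet and debris gates for every panel; a lineage dump gate for the
#' CD34-enriched panel; a CD45 keep gate for the B-cell/DC panel; a
#' CD3+TCRgd+ keep gate for the gamma-delta panel.
#'
#' @param panel panel name.
#' @return list of [gate()]s (applied to transformed events; scatter bounds
#'   are in raw units, fluorescence bounds in decades).
#' @export
panel_default_gates <- function(panel) {
  base <- preset_gates(fsc_w_max = 85000, ssc_w_max = 85000, scatter_min = 20000)
  extra <- switch(panel,
    cd34 = list(gate("lin_dump", "LIN", min = 2.5, action = "exclude")),
    bdc  = list(gate("cd45_pos", "CD45", min = 2.5)),
    gd   = list(gate("tcrgd_pos", "TCRgd", min = 2.5),
                gate("cd3_pos", "CD3", min = 2.5)),
    list()
  )
  c(base, extra)
}

#' Preset annotation rules per default panel
#'
#' Marker-profile rules (on scaled MFI, thresholds in `[0,1]`) identifying
#' each panel's populations: hi/lo patterns on the lineage-defining markers,
#' with a mid band separating CD1a-low from CD1a-high maturation stages in
#' the alpha-beta panel. Rules assume the panel's populations are all
#' represented among the clusters (min-max profile scaling needs both ends
#' of each marker); for very small runs prefer the majority-overlap mapping.
#'
#' @param panel panel name.
#' @return list of [annotation_rule()]s.
#' @export
panel_annotation_rules <- function(panel) {
  switch(panel,
    ab = list(
      annotation_rule("DN CD3-", CD4 = c("lo", .3), CD8b = c("lo", .3),
                      CD3 = c("lo", .3), CD1a = c("lo", .3), TCRab = c("lo", .3)),
      annotation_rule("ISP CD4+CD8b-CD3-", CD4 = c("hi", .7), CD8b = c("lo", .3),
                      CD3 = c("lo", .3), CD1a = c("hi", .7)),
      annotation_rule("DP CD3-", CD4 = c("hi", .7), CD8b = c("hi", .7),
                      CD3 = c("lo", .3)),
      annotation_rule("DP CD3+", CD4 = c("hi", .7), CD8b = c("hi", .7),
                      CD3 = c("hi", .7)),
      annotation_rule("SP CD4+CD1a hi", CD4 = c("hi", .7), CD8b = c("lo", .3),
                      CD3 = c("hi", .7), CD1a = c("hi", .85)),
      annotation_rule("SP CD4+CD1a lo", CD4 = c("hi", .7), CD8b = c("lo", .3),
                      CD3 = c("hi", .7), CD1a = list("mid", .3, .85)),
      annotation_rule("SP CD8b+CD1a hi", CD4 = c("lo", .3), CD8b = c("hi", .7),
                      CD3 = c("hi", .7), CD1a = c("hi", .85)),
      annotation_rule("SP CD8b+CD1a lo", CD4 = c("lo", .3), CD8b = c("hi", .7),
                      CD3 = c("hi", .7), CD1a = list("mid", .3, .85)),
      annotation_rule("gd T cells", CD4 = c("lo", .3), CD8b = c("lo", .3),
                      CD3 = c("hi", .7), TCRab = c("lo", .3)),
      annotation_rule("CD4-CD8b+CD3- minor", CD4 = c("lo", .3),
                      CD8b = c("hi", .7), CD3 = c("lo", .3), CD1a = c("hi", .7))
    ),
    bdc = list(
      annotation_rule("T-lineage thymocytes", `HLA-DR` = c("lo", .3),
                      CD19 = c("lo", .3)),
      annotation_rule("B cells", CD19 = c("hi", .7), `HLA-DR` = c("hi", .7)),
      annotation_rule("pDC", CD123 = c("hi", .7), `HLA-DR` = c("hi", .7),
                      CD19 = c("lo", .3)),
      annotation_rule("cDC/macro", CX3CR1 = c("hi", .7), CD1c = c("hi", .7),
                      `HLA-DR` = c("hi", .7))
    ),
    mono = list(
      annotation_rule("thymocytes", CD14 = c("lo", .3), CD16 = c("lo", .3),
                      `HLA-DR` = c("lo", .3)),
      annotation_rule("monocytes", CD14 = c("hi", .7), `HLA-DR` = c("hi", .7)),
      annotation_rule("macrophages", CD16 = c("hi", .7), CD14 = c("lo", .3),
                      `HLA-DR` = c("hi", .7))
    ),
    gd = list(
      annotation_rule("gd Vg9+Vd1-Vd2+", Vg9 = c("hi", .7), Vd1 = c("lo", .3),
                      Vd2 = c("hi", .7)),
      annotation_rule("gd Vg9+Vd1+Vd2-", Vg9 = c("hi", .7), Vd1 = c("hi", .7),
                      Vd2 = c("lo", .3)),
      annotation_rule("gd Vg9-Vd1+Vd2-", Vg9 = c("lo", .3), Vd1 = c("hi", .7),
                      Vd2 = c("lo", .3)),
      annotation_rule("gd Vg9+Vd1-Vd2-", Vg9 = c("hi", .7), Vd1 = c("lo", .3),
                      Vd2 = c("lo", .3)),
      annotation_rule("gd Vg9-Vd1-Vd2+", Vg9 = c("lo", .3), Vd1 = c("lo", .3),
                      Vd2 = c("hi", .7))
    ),
    cd34 = list(
      annotation_rule("CD7-CD34+ progenitor", CD34 = c("hi", .7),
                      CD7 = c("lo", .3), CD123 = c("lo", .3)),
      annotation_rule("lin-CD34+CD1a-", CD34 = c("hi", .7), CD7 = c("hi", .7),
                      CD44 = c("hi", .7)),
      annotation_rule("lin-CD34+CD1a+", CD34 = c("hi", .7), CD7 = c("hi", .7),
                      CD44 = c("lo", .3)),
      annotation_rule("lin-CD44+CD123+ DC progenitor", CD123 = c("hi", .7),
                      CD34 = c("lo", .3))
    ),
    stopf("panel_annotation_rules: unknown panel '%s'", panel)
  )
}

#' Default pipeline configuration
#'
#' @param panel panel to analyse; default `"bdc"` (the B-cell/DC panel that
#'   carries the planted age effect).
#' @param events_per_sample synthetic events per sample.
#' @param n_random,n_sketch subsampling budgets (default a 50:50 split of
#'   20000).
#' @param batch_correct regress out acquisition-day effects.
#' @param cluster_plan list of clustering rounds (see
#'   [iterative_subcluster()]); default one round at the panel defaults.
#' @param resolution Leiden resolution for the default single-round plan.
#' @param k KNN neighbourhood size for the default plan.
#' @param embed_umap compute the 2-D UMAP (reporting only).
#' @param breakpoint_days age-group breakpoint; default 548 (1.5 years).
#' @param master_seed master seed; every stage seed derives from it.
#' @param out_dir output directory.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(panel = "bdc", events_per_sample = 4000,
                            n_random = 10000, n_sketch = 10000,
                            batch_correct = TRUE, cluster_plan = NULL,
                            resolution = 1, k = 15,
                            embed_umap = FALSE,
                            breakpoint_days = 548,
                            master_seed = 1L, out_dir = tempfile("thymoflow_")) {
  structure(list(panel = panel, events_per_sample = events_per_sample,
                 n_random = n_random, n_sketch = n_sketch,
                 batch_correct = batch_correct,
                 cluster_plan = cluster_plan,
                 resolution = resolution, k = k,
                 embed_umap = embed_umap,
                 breakpoint_days = breakpoint_days,
                 master_seed = as.integer(master_seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' @noRd
validate_config <- function(config) {
  problems <- character(0)
  if (is.null(config$master_seed) || !is.finite(config$master_seed)) {
    problems <- c(problems, "master_seed missing")
  }
  known_panels <- c("cd34", "mono", "bdc", "gd", "ab")
  if (!config$panel %in% known_panels) {
    problems <- c(problems, sprintf("unknown panel '%s'", config$panel))
  } else {
    ret <- panel_retained_markers(config$panel)
    allowed <- c(ret$markers, if (ret$scatter) c("FSC-A", "SSC-A"))
    for (ri in seq_along(config$cluster_plan)) {
      bad <- setdiff(config$cluster_plan[[ri]]$markers %||% character(0), allowed)
      if (length(bad)) {
        problems <- c(problems,
                      sprintf("cluster round %d references unknown marker(s): %s",
                              ri, paste(bad, collapse = ", ")))
      }
    }
  }
  if ((config$n_random %||% 0) + (config$n_sketch %||% 0) < 1) {
    problems <- c(problems, "empty subsampling budget")
  }
  if (length(problems)) {
    stopf("invalid pipeline config:\n  - %s", paste(problems, collapse = "\n  - "))
  }
  invisible(TRUE)
}

#' Preprocess a simulated or loaded sample
#'
#' Compensate, logicle-transform, apply the panel gates; the truth labels
#' are filtered alongside the events.
#'
#' @param s `list(meta, events, truth)`.
#' @param spillover the [spillover_matrix()] to invert.
#' @param gates gate list for [apply_gates()].
#' @return `list(meta, events, truth, removed)` with transformed, gated
#'   events.
#' @export
preprocess_sample <- function(s, spillover, gates) {
  em <- compensate(s$events, spillover)
  em <- transform_events(em)
  ga <- apply_gates(em, gates)
  truth <- s$truth
  truth$event_labels <- truth$event_labels[ga$keep]
  list(meta = s$meta, events = ga$events, truth = truth, removed = ga$removed)
}

#' Run the full pipeline on a synthetic cohort
#'
#' Executes simulate -> preprocess -> pool/standardize -> subsample ->
#' (batch-correct) -> cluster -> map clusters to populations -> benchmark
#' against truth -> frequency statistics, writing every artifact plus a run
#' manifest to `config$out_dir`. Deterministic given the master seed:
#' re-running with an identical config reproduces the outputs byte for byte.
#'
#' @param config a [pipeline_config()].
#' @param spec optional [cohort_spec()]; default
#'   [build_default_thymus_spec()] at the config's size and seed.
#' @param rules optional list of [annotation_rule()]s; when `NULL`, clusters
#'   are mapped to populations by majority overlap with the truth labels.
#' @return the run manifest (list), invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config, spec = NULL, rules = NULL) {
  validate_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  spec <- spec %||% build_default_thymus_spec(
    events_per_sample = config$events_per_sample,
    master_seed = config$master_seed)
  panel <- config$panel
  counts <- list()

  cohort <- simulate_cohort(spec, panel)
  counts$simulated <- sum(vapply(cohort, function(s) n_events(s$events), 0))

  S <- spec_spillover(spec, panel)
  gates <- panel_default_gates(panel)
  pre <- lapply(cohort, preprocess_sample, spillover = S, gates = gates)
  counts$gated <- sum(vapply(pre, function(s) n_events(s$events), 0))

  ret <- panel_retained_markers(panel)
  pooled <- pool_and_standardize(pre, ret$markers, include_scatter = ret$scatter)
  truth_labels <- unlist(lapply(pre, function(s) s$truth$event_labels),
                         use.names = FALSE)

  sub <- combined_subsample(pooled, config$n_random, config$n_sketch,
                            derive_seed(config$master_seed, 101))
  dat <- subset_pooled(pooled, sub$indices, origin = sub$origin)
  truth_sub <- truth_labels[sub$indices]
  counts$subsampled <- nrow(dat$values)

  if (isTRUE(config$batch_correct)) {
    before <- dat
    dat <- regress_out_batch(dat)
    write_tsv_out(batch_diagnostics(before, dat),
                  file.path(config$out_dir, "batch_diagnostics.tsv"))
  }

  plan <- config$cluster_plan %||%
    list(list(targets = NULL, markers = NULL,
              k = config$k, resolution = config$resolution))
  assign <- iterative_subcluster(dat, plan,
                                 seed = derive_seed(config$master_seed, 102))
  prof <- cluster_profiles(assign, dat)

  ann <- if (!is.null(rules)) {
    annotate_clusters(prof, rules)
  } else {
    majority_overlap_map(assign$cluster, truth_sub)
  }
  assign$annotation <- ann
  pred_labels <- unname(ann[as.character(assign$cluster)])

  if (isTRUE(config$embed_umap)) {
    coords <- umap_embed(dat, seed = derive_seed(config$master_seed, 103))
    write_tsv_out(data.frame(event = seq_len(nrow(coords)), coords),
                  file.path(config$out_dir, "umap.tsv"))
  }

  write_tsv_out(
    data.frame(event = seq_len(nrow(dat$values)), sample = dat$sample_id,
               cluster = assign$cluster,
               lineage = unname(assign$lineage[as.character(assign$cluster)]),
               annotation = pred_labels, truth = truth_sub),
    file.path(config$out_dir, "clusters.tsv"))
  write_tsv_out(data.frame(cluster = rownames(prof$mfi), prof$mfi,
                           check.names = FALSE),
                file.path(config$out_dir, "cluster_profiles.tsv"))

  fm <- f_measure_report(pred_labels, truth_sub, dat$sample_id)
  write_tsv_out(fm, file.path(config$out_dir, "f_measures.tsv"))

  # frequencies come from the random-origin draw only: the sketch deliberately
  # enriches rare populations and would bias per-sample fractions
  rnd <- dat$origin %in% c("random", "both")
  if (!any(rnd)) rnd <- rep(TRUE, length(rnd))
  freq <- population_frequencies(pred_labels[rnd], dat$sample_id[rnd])
  write_tsv_out(freq, file.path(config$out_dir, "frequencies.tsv"))

  meta <- unique(data.frame(sample = dat$sample_id, batch = dat$batch,
                            age_days = dat$age_days))
  group <- stats::setNames(meta$age_days > config$breakpoint_days, meta$sample)
  batch <- stats::setNames(meta$batch, meta$sample)
  gt <- group_difference_test(freq, group, batch)
  write_tsv_out(gt, file.path(config$out_dir, "group_tests.tsv"))

  trend <- do.call(rbind, lapply(unique(freq$population), function(p) {
    d <- merge(freq[freq$population == p, ], meta, by = "sample")
    d <- d[order(d$age_days), ]
    data.frame(population = p, sample = d$sample, log2_age = log2(d$age_days),
               frequency = d$frequency,
               fitted = loess_trend(log2(d$age_days), d$frequency))
  }))
  write_tsv_out(trend, file.path(config$out_dir, "loess_trends.tsv"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("thymoflow")),
    panel = panel, master_seed = config$master_seed,
    config_hash = config_hash(config),
    event_counts = counts,
    n_clusters = length(unique(assign$cluster)),
    populations = sort(unique(pred_labels)),
    outputs = list.files(config$out_dir)
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' @noRd
config_hash <- function(config) {
  s <- jsonlite::toJSON(config[order(names(config))], auto_unbox = TRUE,
                        digits = NA, force = TRUE)
  v <- utf8ToInt(as.character(s))
  h <- 0
  for (x in v) h <- (h * 131 + x) %% 2147483647
  sprintf("%08x", as.integer(h))
}
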
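#' Default pipeline configuration
#'
#' Returns the pipeline parameter list with its documented defaults: the
#' 0.3 beta threshold, q-value cutoff 0.05, Fisher alpha 0.05, the
#' at-least-three-cancers recurrence rule, frequency filter bounds,
#' consensus-clustering settings and module-search settings.  `seed` is
#' mandatory for a run.
#'
#' @param seed Integer master seed.
#' @return Named list of parameters.
#' @export
default_run_config <- function(seed = 1) {
  list(threshold = 0.3, min_freq = 0.05, max_freq = 0.95,
       q_threshold = 0.05, alpha = 0.05, min_cancers = 3,
       k_range = 2:6, n_reps = 50, subsample = 0.8,
       n_perm = 200, min_size = 4, max_size = 50, top_n = 15,
       seed = seed)
}

#' Run the end-to-end CO/ME pipeline
#'
#' Executes the stages binarize, detect, filter, network, fem, cluster,
#' survive and clinical-assoc in order, writing each stage's artifact to
#' `out_dir` as deterministic TSV plus a machine-readable `summary.json`.
#' Re-running with identical inputs, parameters and seed reproduces every
#' artifact byte for byte.  When the frequent-event set comes out empty
#' (e.g. `min_cancers` exceeds the number of cancers), the downstream
#' stages are skipped with an explicit status instead of failing.
#'
#' @param inputs List with `beta` (probe matrix), `manifest`, `expr`,
#'   `clinical`, `annotation` — in-memory objects or file paths.
#' @param out_dir Output directory (created if needed).
#' @param config Parameter list from [default_run_config()].
#' @return Invisibly, the summary list.
#' @export
run_pipeline <- function(inputs, out_dir, config = default_run_config()) {
  if (is.null(config$seed)) stop("config$seed is mandatory")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  load_in <- function(x, reader) if (is.character(x)) reader(x) else x
  beta <- load_in(inputs$beta, function(p) read_matrix(p, "beta"))
  manifest <- load_in(inputs$manifest, read_manifest)
  expr <- load_in(inputs$expr, function(p) read_matrix(p, "expression"))
  clinical <- load_in(inputs$clinical, read_clinical)
  annotation <- load_in(inputs$annotation, read_gene_annotation)
  summary <- list(seed = config$seed,
                  parameters = config[setdiff(names(config), "seed")],
                  stages = list())
  note <- function(stage, ...) {
    summary$stages[[stage]] <<- list(...)
  }

  # --- binarize ---------------------------------------------------------
  gm <- aggregate_promoter(beta, manifest)
  write_matrix(gm, file.path(out_dir, "gene_meth.tsv"), id_col = "gene_id")
  bm_all <- binarize(gm, threshold = config$threshold)
  write_matrix(bm_all, file.path(out_dir, "binary.tsv"), id_col = "gene_id")
  note("binarize", n_genes = nrow(bm_all), n_samples = ncol(bm_all),
       threshold = config$threshold)

  cancers <- sort(unique(clinical$cancer_type))
  tumor_ids <- clinical$sample_id[clinical$is_tumor]

  # --- detect (per cancer, tumor samples only) --------------------------
  events_by_cancer <- list()
  bm_by_cancer <- list()
  for (cancer in cancers) {
    ids <- clinical$sample_id[clinical$cancer_type == cancer]
    ids <- intersect(ids, colnames(bm_all))
    bm_c <- bm_all[, ids, drop = FALSE]
    bm_by_cancer[[cancer]] <- bm_c
    bm_t <- bm_c[, intersect(ids, tumor_ids), drop = FALSE]
    bm_t <- filter_genes(bm_t, config$min_freq, config$max_freq)
    ev <- test_all_pairs(bm_t, q_threshold = config$q_threshold)
    events_by_cancer[[cancer]] <- ev
    called <- ev[ev$call != "none", , drop = FALSE]
    if (nrow(called) > 0) {
      tab <- tibble(gene_a = called$gene_a, gene_b = called$gene_b,
                    type = called$call, overlap = called$overlap,
                    expected = called$expected,
                    p_value = ifelse(called$call == "CO", called$p_co,
                                     called$p_me),
                    q_value = ifelse(called$call == "CO", called$q_co,
                                     called$q_me),
                    cancers = cancer)
      write_event_table(tab, file.path(out_dir,
                                       paste0("events_", cancer, ".tsv")))
    } else {
      write_event_table(tibble(gene_a = character(), gene_b = character(),
                               type = character(), overlap = integer(),
                               expected = numeric(), p_value = numeric(),
                               q_value = numeric(), cancers = character()),
                        file.path(out_dir, paste0("events_", cancer, ".tsv")))
    }
  }
  note("detect", n_cancers = length(cancers),
       n_events = vapply(events_by_cancer,
                         function(e) sum(e$call != "none"), integer(1)))

  # --- filter (Fisher + cross-cancer recurrence) ------------------------
  diff_ev <- differential_events(events_by_cancer, bm_by_cancer, clinical,
                                 alpha = config$alpha)
  .write_result_tsv(diff_ev[order(diff_ev$gene_a, diff_ev$gene_b,
                                  diff_ev$type, diff_ev$cancer), ],
                    file.path(out_dir, "differential.tsv"),
                    num_cols = c("p_value", "q_value", "p_fisher"))
  frequent <- suppressWarnings(select_frequent(diff_ev,
                                               min_cancers = config$min_cancers))
  .write_result_tsv(frequent, file.path(out_dir, "frequent.tsv"),
                    num_cols = character(0))
  note("filter", n_differential = sum(diff_ev$differential, na.rm = TRUE),
       n_frequent = nrow(frequent), min_cancers = config$min_cancers)

  if (nrow(frequent) == 0) {
    warning("empty frequent-event set; downstream stages skipped")
    for (st in c("network", "fem", "cluster", "survive", "clinical_assoc")) {
      note(st, status = "skipped_empty_frequent_set")
    }
    .write_summary(summary, out_dir)
    return(invisible(summary))
  }

  # --- network ----------------------------------------------------------
  net <- build_network(frequent)
  write_edge_list(net, file.path(out_dir, "edges.tsv"))
  hubs <- hub_table(net, annotation, top_n = config$top_n)
  .write_result_tsv(hubs, file.path(out_dir, "hubs.tsv"),
                    num_cols = "fraction_flagged")
  cgf <- cancer_gene_fraction(net, annotation)
  note("network", n_nodes = length(net$nodes), n_edges = nrow(net$edges),
       cancer_gene_fraction = cgf$fraction)

  # --- fem --------------------------------------------------------------
  is_tum <- colnames(gm) %in% tumor_ids
  t_meth <- differential_stats(gm, is_tum)
  t_expr <- differential_stats(expr[, colnames(gm), drop = FALSE], is_tum)
  stats <- node_statistics(t_meth, t_expr)
  modules <- detect_modules(net, stats, n_perm = config$n_perm,
                            min_size = config$min_size,
                            max_size = config$max_size,
                            seed = derive_seed(config$seed, 7001))
  mod_tab <- tibble(seed_gene = modules$seed_gene,
                    members = vapply(modules$members, paste,
                                     character(1), collapse = ","),
                    size = modules$size, score = modules$score,
                    p_perm = modules$p_perm)
  .write_result_tsv(mod_tab, file.path(out_dir, "modules.tsv"),
                    num_cols = c("score", "p_perm"))
  frac_hd <- if (nrow(modules) > 0) {
    module_direction_report(modules$members[[1]], stats)$fraction_hyper_down
  } else NA_real_
  note("fem", n_modules = nrow(modules),
       top_module_fraction_hyper_down = frac_hd)

  # --- cluster (pan-cancer, tumor samples) ------------------------------
  bm_tumor <- bm_all[, intersect(colnames(bm_all), tumor_ids), drop = FALSE]
  esm <- event_sample_matrix(frequent, bm_tumor)
  cr <- consensus_cluster(esm, k_range = config$k_range,
                          n_reps = config$n_reps,
                          subsample = config$subsample,
                          seed = derive_seed(config$seed, 8001))
  labels <- tidy(cr, k = cr$chosen_k$silhouette)
  .write_result_tsv(labels, file.path(out_dir, "clusters.tsv"),
                    num_cols = character(0))
  enrich <- cluster_event_enrichment(esm, setNames(labels$cluster,
                                                   labels$sample_id),
                                     top_n = config$top_n)
  .write_result_tsv(enrich, file.path(out_dir, "cluster_enrichment.tsv"),
                    num_cols = "p_hyper")
  note("cluster", chosen_k_silhouette = cr$chosen_k$silhouette,
       chosen_k_cdf_elbow = cr$chosen_k$cdf_elbow,
       avg_silhouette = unname(cr$silhouette[as.character(cr$chosen_k$silhouette)]))

  # --- survive ----------------------------------------------------------
  surv_cl <- dplyr::inner_join(labels, clinical, by = "sample_id")
  surv_cl <- surv_cl[!is.na(surv_cl$pfi_time) & surv_cl$pfi_time > 0, ]
  lr <- logrank_test(tibble(time = surv_cl$pfi_time,
                            event = surv_cl$pfi_event,
                            group = surv_cl$cluster))
  .write_result_tsv(lr, file.path(out_dir, "survival.tsv"),
                    num_cols = c("chi2", "p_value"))
  km <- kaplan_meier(tibble(time = surv_cl$pfi_time,
                            event = surv_cl$pfi_event,
                            group = as.character(surv_cl$cluster)))
  .write_result_tsv(km, file.path(out_dir, "km_curves.tsv"),
                    num_cols = "survival")
  note("survive", chi2 = lr$chi2, p_value = lr$p_value, df = lr$df)

  # --- clinical-assoc ---------------------------------------------------
  assoc <- clinical_associations(labels, clinical)
  .write_result_tsv(assoc, file.path(out_dir, "clinical_assoc.tsv"),
                    num_cols = c("statistic", "p_value"))
  note("clinical_assoc", n_features = nrow(assoc))

  .write_summary(summary, out_dir)
  invisible(summary)
}

.write_summary <- function(summary, out_dir) {
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
}

#' Write a synthetic cohort bundle to disk
#'
#' Writes every artifact of [simulate_cohort()] in the package's TSV
#' dialect, plus ground-truth tables.
#'
#' @param bundle Output of [simulate_cohort()].
#' @param dir Target directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix(bundle$beta, file.path(dir, "beta.tsv"), id_col = "probe_id")
  write_matrix(bundle$expr, file.path(dir, "expr.tsv"), id_col = "gene_id")
  .write_result_tsv(bundle$manifest, file.path(dir, "manifest.tsv"),
                    num_cols = character(0))
  clin <- bundle$clinical
  .write_result_tsv(clin[setdiff(colnames(clin), "subtype")],
                    file.path(dir, "clinical.tsv"),
                    num_cols = "pfi_time")
  .write_result_tsv(bundle$annotation, file.path(dir, "annotation.tsv"),
                    num_cols = character(0))
  .write_result_tsv(bundle$truth$pairs, file.path(dir, "truth_pairs.tsv"),
                    num_cols = character(0))
  truth_subtype <- tibble(sample_id = names(bundle$truth$subtype),
                          subtype = unname(bundle$truth$subtype))
  .write_result_tsv(truth_subtype, file.path(dir, "truth_subtypes.tsv"),
                    num_cols = character(0))
  invisible(dir)
}
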
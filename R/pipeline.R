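# End-to-end orchestration: simulate -> preprocess -> discover -> signature ->
# classify -> concordance -> pdx -> survival, with deterministic sub-seeding
# and TSV/GMT/JSON artifact output.

pipeline_defaults <- function() {
  list(
    seed = 1L,
    outdir = NULL,
    stages = c("simulate", "preprocess", "discover", "signature", "classify",
               "concordance", "pdx", "survival"),
    cohort = list(),
    preprocess = list(mean_min = 1, mad_min = 0.5, batch_correct = TRUE),
    discover = list(k_range = 2:6, iterations = 1000, subsample = 0.95,
                    gap_k_range = 1:8, n_refs = 50),
    signature = list(fdr_max = 0.01, top_n = 40, n_permutations = 1000),
    classifier = list(cv_folds = 5L),
    concordance = list(n_systems = 2L, agreement = 0.9, alpha = 0.001),
    pdx = list(),
    survival = list(follow_up = NULL)
  )
}

#' Assemble a validated pipeline configuration
#'
#' Merges user settings over the defaults; unknown keys are rejected. Stage
#' blocks `cohort` and `pdx` take the arguments of [cohort_spec()] and
#' [pdx_sim_spec()].
#'
#' @param ... Named settings overriding the defaults (nested lists merge by
#'   key).
#' @param yaml Optional path to a YAML file of settings, applied before
#'   `...`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(..., yaml = NULL) {
  cfg <- pipeline_defaults()
  apply_over <- function(base, user, path = "") {
    for (key in names(user)) {
      full <- paste0(path, key)
      if (!key %in% names(base)) {
        abort(sprintf("unknown configuration key '%s'", full))
      }
      if (is.list(base[[key]]) && !is.null(names(base[[key]])) && is.list(user[[key]])) {
        base[[key]] <- apply_over(base[[key]], user[[key]], paste0(full, "$"))
      } else {
        base[[key]] <- user[[key]]
      }
    }
    base
  }
  if (!is.null(yaml)) {
    cfg <- apply_over(cfg, yaml::read_yaml(yaml))
  }
  user <- list(...)
  if (length(user) && (is.null(names(user)) || any(names(user) == ""))) {
    abort("all configuration settings must be named")
  }
  cfg <- apply_over(cfg, user)
  bad <- setdiff(cfg$stages, pipeline_defaults()$stages)
  if (length(bad)) abort(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")))
  structure(cfg, class = "pipeline_config")
}

#' Run the subtyping pipeline end to end
#'
#' Executes the enabled stages in order on a synthetic cohort (or on matrices
#' supplied via `expression`/`clinical`), writing artifacts to
#' `config$outdir` when set and returning all intermediate results. All
#' randomness derives from `config$seed` through per-stage sub-seeds, so a
#' fixed seed yields bit-identical labels, signatures and network edge lists.
#'
#' @param config A [pipeline_config()].
#' @param expression Optional genes x samples matrix to analyse instead of a
#'   simulated cohort (requires `clinical` for the survival stage).
#' @param clinical Optional clinical tibble (`sample_id`, `batch`,
#'   `os_months`, `event`, ...).
#'
#' @return A named list of stage results (invisibly when writing to disk).
#' @export
run_pipeline <- function(config = pipeline_config(), expression = NULL,
                         clinical = NULL) {
  if (!inherits(config, "pipeline_config")) abort("config must be a pipeline_config()")
  seeds <- derive_seeds(config$seed, 8L)
  names(seeds) <- pipeline_defaults()$stages
  out <- list(config = config)
  outdir <- config$outdir
  if (!is.null(outdir)) dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  emit <- function(writer, object, file) {
    if (!is.null(outdir)) writer(object, file.path(outdir, file))
  }
  on <- function(stage) stage %in% config$stages
  log <- list(seed = config$seed, stages = config$stages)

  if (on("simulate") && is.null(expression)) {
    spec <- do.call(cohort_spec, utils::modifyList(list(seed = seeds[["simulate"]]),
                                                   config$cohort))
    out$cohort <- simulate_cohort(spec)
    expression <- out$cohort$expression
    clinical <- out$cohort$clinical
    emit(write_expression_tsv, expression, "expression.tsv")
    emit(function(x, p) readr::write_tsv(x, p), clinical, "clinical.tsv")
    emit(write_gmt, out$cohort$signature_genes, "truth_signatures.gmt")
    log$cohort <- unclass(spec)
  }
  if (is.null(expression)) abort("no expression input: enable the simulate stage or pass `expression`")

  working <- expression
  if (on("preprocess")) {
    pp <- config$preprocess
    working <- filter_genes(working, mean_min = pp$mean_min, mad_min = pp$mad_min)
    if (isTRUE(pp$batch_correct) && !is.null(clinical$batch) &&
        length(unique(clinical$batch)) > 1) {
      working <- batch_correct(working, setNames(clinical$batch, clinical$sample_id))
    }
    working <- median_center(working)
    out$preprocessed <- working
    emit(write_expression_tsv, working, "expression_preprocessed.tsv")
  }

  if (on("discover")) {
    dd <- config$discover
    out$consensus <- consensus_cluster(working, k_range = dd$k_range,
                                       iterations = dd$iterations,
                                       subsample = dd$subsample,
                                       seed = seeds[["discover"]])
    out$delta_area <- delta_area(out$consensus)
    out$gap <- gap_statistic(working, k_range = dd$gap_k_range,
                             n_refs = dd$n_refs, seed = seeds[["discover"]])
    k_opt <- attr(out$gap, "optimal_k")
    k_use <- min(max(k_opt, min(dd$k_range)), max(dd$k_range))
    out$optimal_k <- k_opt
    out$discovery_labels <- out$consensus[[paste0("k=", k_use)]]$labels
    emit(write_gap_tsv, out$gap, "gap_curve.tsv")
    emit(write_labels, out$discovery_labels, "labels_discovery.tsv")
    emit(write_consensus_tsv, out$consensus[[paste0("k=", k_use)]],
         "consensus_matrix.tsv")
    log$optimal_k <- k_opt
  }

  labels_for_signature <- out$discovery_labels %||%
    (if (!is.null(clinical$subtype_truth))
       tibble(sample_id = clinical$sample_id, label = clinical$subtype_truth)
     else NULL)

  if (on("signature")) {
    if (is.null(labels_for_signature)) abort("signature stage needs discovery labels")
    sg <- config$signature
    out$signature <- build_signature(working, labels_for_signature,
                                     fdr_max = sg$fdr_max, top_n = sg$top_n,
                                     n_permutations = sg$n_permutations,
                                     seed = seeds[["signature"]])
    emit(write_gmt,
         c(list(signature = as.character(out$signature)),
           attr(out$signature, "per_class")),
         "signature.gmt")
    log$signature_size <- length(out$signature)
  }

  if (on("classify")) {
    if (is.null(out$signature)) abort("classify stage needs the signature stage")
    out$classifier <- train_centroid_classifier(
      working, labels_for_signature, out$signature,
      cv_folds = config$classifier$cv_folds, seed = seeds[["classify"]]
    )
    out$classification <- classify(out$classifier, working)
    emit(write_model_json, out$classifier, "classifier.json")
    emit(write_labels, out$classification, "labels_classified.tsv")
  }

  if (on("concordance")) {
    if (is.null(labels_for_signature)) abort("concordance stage needs labels")
    cc <- config$concordance
    alt_seeds <- derive_seeds(seeds[["concordance"]], cc$n_systems)
    systems <- c(
      list(discovery = labels_for_signature),
      setNames(lapply(seq_len(cc$n_systems), function(i) {
        simulate_alternative_labeling(labels_for_signature, cc$agreement,
                                      seed = alt_seeds[i],
                                      prefix = paste0("Alt", i, "_"))
      }), paste0("alt", seq_len(cc$n_systems)))
    )
    out$network <- build_network(systems, alpha = cc$alpha)
    emit(write_edges_tsv, out$network, "network_edges.tsv")
    emit(write_graphml, out$network, "network.graphml")
  }

  if (on("pdx")) {
    spec <- do.call(pdx_sim_spec, utils::modifyList(list(seed = seeds[["pdx"]]),
                                                    config$pdx))
    sim <- simulate_pdx_pairs(spec)
    out$pdx <- list(
      sim = sim,
      fractions = species_fraction(sim$pairs),
      combined = combine_expression(sim$pairs, sim$homology)
    )
    comp <- compartment_expression(sim$pairs, sim$homology)
    out$pdx$compartment_genes <- select_compartment_genes(comp$human, comp$mouse)
    emit(function(x, p) readr::write_tsv(x, p), out$pdx$fractions,
         "pdx_species_fractions.tsv")
    emit(write_gmt, out$pdx$compartment_genes, "compartment_genes.gmt")
  }

  if (on("survival") && !is.null(clinical)) {
    surv_df <- dplyr::mutate(clinical,
                             group = labels_for_signature$label[
                               match(clinical$sample_id, labels_for_signature$sample_id)])
    out$km <- km_estimate(surv_df, follow_up = config$survival$follow_up)
    out$logrank <- logrank_test(surv_df, follow_up = config$survival$follow_up)
    out$clinical_tests <- purrr::imap_dfr(pdac_clinical_tables(), function(tab, nm) {
      dplyr::mutate(pearson_chisq(tab), variable = nm, .before = 1)
    })
    emit(function(x, p) readr::write_tsv(x, p), out$logrank, "logrank.tsv")
    emit(function(x, p) readr::write_tsv(x, p), out$clinical_tests,
         "clinical_tests.tsv")
  }

  if (!is.null(outdir)) {
    jsonlite::write_json(log, file.path(outdir, "run_log.json"),
                         auto_unbox = TRUE, digits = NA)
    return(invisible(out))
  }
  out
}
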
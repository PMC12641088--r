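#' Build and validate a pipeline configuration
#'
#' The pipeline runs features -> clustering -> region screen ->
#' discriminant search over either (a) a simulated cohort from
#' [cohort_spec()] / [cbf_spec()] or (b) response and CBF tables read
#' from CSV. Validation happens here, before any stage executes.
#'
#' @param responses_csv,cbf_csv input paths (ignored when `simulate`).
#' @param simulate generate the cohort instead of reading files.
#' @param cohort a `cohort_spec` (when simulating).
#' @param cbf a `cbf_spec` (when simulating).
#' @param standard standard scores data.frame; default the reference
#'   scores of [standard_scores_nd()] (when reading files, set to
#'   `"recompute"` to derive them from the ND participants).
#' @param k_range candidate cluster counts (default 2:6).
#' @param confidence ellipse coverage (default 0.95).
#' @param alpha,m screen family-wise level and test count (0.05, 24).
#' @param max_size discriminant search size cap (1 or 2).
#' @param prior LDA priors, "empirical" or "uniform".
#' @param n_restarts EM restarts (default 50).
#' @param out_dir output directory for stage CSVs and the summary.
#' @param seed global seed.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(responses_csv = NULL, cbf_csv = NULL,
                            simulate = is.null(responses_csv),
                            cohort = cohort_spec(seed = seed),
                            cbf = cbf_spec(seed = seed + 1L),
                            standard = standard_scores_nd(),
                            k_range = 2:6, confidence = 0.95,
                            alpha = 0.05, m = 24L, max_size = 2L,
                            prior = "empirical", n_restarts = 50L,
                            out_dir = tempfile("temporient_run_"),
                            seed = 1L) {
  cfg <- list(responses_csv = responses_csv, cbf_csv = cbf_csv,
              simulate = simulate, cohort = cohort, cbf = cbf,
              standard = standard, k_range = k_range,
              confidence = confidence, alpha = alpha, m = m,
              max_size = max_size, prior = prior,
              n_restarts = n_restarts, out_dir = out_dir,
              seed = as.integer(seed))
  if (!simulate) {
    if (is.null(responses_csv) || !file.exists(responses_csv)) {
      abort("config invalid: responses_csv missing or not found")
    }
    if (is.null(cbf_csv) || !file.exists(cbf_csv)) {
      abort("config invalid: cbf_csv missing or not found ",
            "(required by the discriminant stage)")
    }
  } else {
    stopifnot(inherits(cohort, "cohort_spec"), inherits(cbf, "cbf_spec"))
  }
  if (confidence <= 0 || confidence >= 1) abort("confidence must be in (0, 1)")
  if (alpha <= 0 || alpha >= 1) abort("alpha must be in (0, 1)")
  if (!max_size %in% 1:2) abort("max_size must be 1 or 2")
  class(cfg) <- "pipeline_config"
  cfg
}

write_stage_csv <- function(df, dir, name) {
  utils::write.csv(df, file.path(dir, name), row.names = FALSE, quote = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes every stage in order, writes one CSV per stage output under
#' `config$out_dir`, and finishes with `summary.json` holding the
#' selected number of clusters, cluster sizes, mean silhouette,
#' Bonferroni-significant regions, and the best discriminant model with
#' its hit rate. Identical config + seed produce byte-identical
#' outputs. On a stage error, partial outputs are kept next to a
#' `FAILED` marker naming the stage.
#'
#' @param config a `pipeline_config`.
#' @return (invisibly) a list with all stage objects and `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "input"
  result <- tryCatch({
    if (config$simulate) {
      sim <- gen_responses(config$cohort)
      responses <- sim$responses
      truth <- sim$truth
      labels_true <- stats::setNames(truth$regime, truth$participant_id)
      cbf_tab <- gen_cbf(labels_true, config$cbf)
      write_stage_csv(truth, config$out_dir, "truth.csv")
      write_stage_csv(as.data.frame(responses), config$out_dir,
                      "responses.csv")
      write_stage_csv(as.data.frame(cbf_tab), config$out_dir, "cbf.csv")
    } else {
      responses <- read_response_table(config$responses_csv)
      cbf_tab <- read_cbf_table(config$cbf_csv)
      truth <- NULL
    }
    standard <- if (identical(config$standard, "recompute")) {
      compute_standard_response(responses)
    } else {
      config$standard
    }

    stage <- "features"
    features <- extract_features(responses, standard)
    write_stage_csv(features, config$out_dir, "features.csv")
    inc <- features[features$included, , drop = FALSE]

    stage <- "clustering"
    pts <- as.matrix(inc[, c("slope", "dc")])
    rownames(pts) <- inc$participant_id
    sel <- select_cluster_count(pts, k_range = config$k_range,
                                seed = config$seed,
                                n_restarts = config$n_restarts)
    model <- sel$model
    assign_df <- data.frame(participant_id = inc$participant_id,
                            cluster = model$labels,
                            silhouette = model$silhouette,
                            round(model$posterior, 6))
    names(assign_df)[-(1:3)] <- paste0("posterior_", seq_len(model$K))
    write_stage_csv(assign_df, config$out_dir, "clusters.csv")
    write_stage_csv(sel$trace, config$out_dir, "silhouette_trace.csv")
    ell <- confidence_ellipses(model, config$confidence)
    ell_df <- do.call(rbind, lapply(seq_along(ell$ellipses), function(k) {
      e <- ell$ellipses[[k]]
      data.frame(cluster = k, center_slope = e$center[1],
                 center_dc = e$center[2], radius = e$radius,
                 cov_11 = e$covariance[1, 1], cov_12 = e$covariance[1, 2],
                 cov_22 = e$covariance[2, 2], area = e$area)
    }))
    write_stage_csv(ell_df, config$out_dir, "ellipses.csv")
    write_stage_csv(ell$overlap, config$out_dir, "ellipse_overlap.csv")

    stage <- "screen"
    labels <- stats::setNames(model$labels, inc$participant_id)
    cbf_mat <- cbf_matrix(cbf_tab)
    cbf_mat <- cbf_mat[intersect(rownames(cbf_mat), names(labels)), ,
                       drop = FALSE]
    screen <- screen_regions(cbf_mat, labels[rownames(cbf_mat)],
                             alpha = config$alpha, m = config$m)
    write_stage_csv(screen$table, config$out_dir, "screen.csv")

    stage <- "discriminant"
    search <- exhaustive_search(cbf_mat, labels[rownames(cbf_mat)],
                                max_size = config$max_size,
                                prior = config$prior)
    write_stage_csv(search$ranking, config$out_dir, "lda_ranking.csv")

    stage <- "summary"
    summary <- list(
      seed = config$seed,
      n_participants = nrow(features),
      n_included = nrow(inc),
      best_k = sel$best_k,
      cluster_sizes = as.vector(tabulate(model$labels, model$K)),
      mean_silhouette = model$mean_silhouette,
      silhouette_over_0.5 = mean(model$silhouette > 0.5),
      significant_regions = screen$significant_regions,
      n_significant = length(screen$significant_regions),
      best_model = search$ranking$feature_set[1],
      best_hit_rate = search$best$hit_rate,
      pair_beats_single = search$pair_beats_single)
    jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    list(responses = responses, truth = truth, features = features,
         selection = sel, model = model, ellipses = ell, screen = screen,
         search = search, summary = summary, out_dir = config$out_dir)
  }, error = function(e) {
    writeLines(paste0("stage: ", stage, "\n", conditionMessage(e)),
               file.path(config$out_dir, "FAILED"))
    abort("pipeline failed at stage '", stage, "': ", conditionMessage(e))
  })
  invisible(result)
}
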
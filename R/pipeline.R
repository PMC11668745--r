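#' Pipeline configuration
#'
#' Bundles every stage's settings for an end-to-end run. The global seed
#' fans out to per-stage seeds by fixed offsets (+1 cohort, +2 embedding,
#' +3 classifier, +4/+5 the two LSIRM fits), so stage-level reruns stay
#' reproducible.
#'
#' @param cohort a [cohort_spec()] to simulate, or the path of a manifest
#'   CSV readable by [read_cohort()].
#' @param input_type classifier input per subject: `"pearson"`,
#'   `"fisher_z"`, or a Mapper FCN over a `"linear"`, `"stochastic"` or
#'   `"topological"` embedding.
#' @param embed_params embedding hyperparameters (see [embed_rois()]).
#' @param mapper a [mapper_config()].
#' @param attn an [attn_config()] (its seed is overridden by the fan-out).
#' @param mcmc an [mcmc_config()] (seed overridden likewise).
#' @param selection_mode `"rank_sum"` or `"intersection"` for
#'   [top_quartile_rois()].
#' @param summary_threshold connectivity-ratio cutoff for
#'   [group_summary()].
#' @param out_dir output directory for artifacts (`NULL`: nothing
#'   written).
#' @param seed global seed.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort,
                            input_type = c("topological", "linear",
                                           "stochastic", "pearson",
                                           "fisher_z"),
                            embed_params = list(),
                            mapper = mapper_config(),
                            attn = attn_config(),
                            mcmc = mcmc_config(),
                            selection_mode = c("rank_sum", "intersection"),
                            summary_threshold = 0.2,
                            out_dir = NULL,
                            seed = 1L) {
  input_type <- match.arg(input_type)
  selection_mode <- match.arg(selection_mode)
  if (is.character(cohort) && !file.exists(cohort))
    stop("cohort manifest not found: ", cohort)
  stopifnot(inherits(cohort, "cohort_spec") || is.character(cohort),
            inherits(mapper, "mapper_config"),
            inherits(attn, "attn_config"), inherits(mcmc, "mcmc_config"),
            summary_threshold > 0, summary_threshold <= 1)
  structure(list(cohort = cohort, input_type = input_type,
                 embed_params = embed_params, mapper = mapper,
                 attn = attn, mcmc = mcmc,
                 selection_mode = selection_mode,
                 summary_threshold = summary_threshold,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

.stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full three-step fusion pipeline
#'
#' Step 1 builds per-subject connectivity inputs (correlation matrices
#' and Mapper FCNs). Step 2 trains the self-attention classifier with
#' cross-validation, extracts every subject's attention distribution
#' matrix, and forms each group's CV matrix and top-quartile ROI list.
#' Step 3 fits the LSIRM to each group matrix, aligns and summarizes the
#' latent ROI positions, categorizes ROIs across the two groups, and
#' builds thresholded group summary FCNs with the categorized ROIs'
#' direct-neighbor clusters. Artifacts land under
#' `out_dir/{step1,step2,step3}` when `out_dir` is set.
#'
#' @param cfg a [pipeline_config()].
#' @return run report: list with `cv_accuracy`, `comparison`,
#'   `top_rois` (per group), `categories` (count per category),
#'   `category_map`, `acceptance` (per group), `summary_edges` (per
#'   group), `clusters`, `warnings`, `seed`; full stage objects under
#'   `objects`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  out <- cfg$out_dir
  dirs <- NULL
  if (!is.null(out)) {
    dirs <- file.path(out, c("step1", "step2", "step3"))
    for (d1 in dirs) dir.create(d1, recursive = TRUE, showWarnings = FALSE)
  }
  warn <- character(0)

  # ---- cohort --------------------------------------------------------
  if (inherits(cfg$cohort, "cohort_spec")) {
    spec <- cfg$cohort
    spec$seed <- cfg$seed + 1L
    .stage_log("cohort", "simulating %d + %d subjects",
               spec$n_subjects_per_group[1], spec$n_subjects_per_group[2])
    cohort <- simulate_cohort(spec)
    if (!is.null(out)) write_cohort(cohort, file.path(dirs[1], "cohort"))
  } else {
    .stage_log("cohort", "reading %s", cfg$cohort)
    cohort <- read_cohort(cfg$cohort)
  }
  groups <- vapply(cohort, `[[`, character(1), "group")
  levs <- sort(unique(groups))
  if (length(levs) != 2L)
    stop("pipeline stage 'cohort' failed: need exactly two groups, got ",
         length(levs))
  labs <- cohort[[1]]$roi_labels

  # ---- step 1: connectivity representations --------------------------
  .stage_log("step1", "building %s inputs for %d subjects",
             cfg$input_type, length(cohort))
  emb_method <- if (cfg$input_type %in%
                    c("linear", "stochastic", "topological"))
    cfg$input_type else "topological"
  fcns <- vector("list", length(cohort))
  xs <- vector("list", length(cohort))
  for (i in seq_along(cohort)) {
    emb <- embed_rois(cohort[[i]], emb_method, cfg$embed_params,
                      seed = cfg$seed + 2L + i)
    fcns[[i]] <- mapper_fcn(emb, cfg$mapper)
    xs[[i]] <- switch(cfg$input_type,
      pearson = pearson_matrix(cohort[[i]])$values,
      fisher_z = fisher_z(pearson_matrix(cohort[[i]]))$values,
      fcns[[i]]$adjacency)
  }
  names(xs) <- vapply(cohort, `[[`, character(1), "subject_id")
  if (!is.null(out))
    for (i in seq_along(fcns))
      export_network(fcns[[i]],
                     edgelist_path = file.path(
                       dirs[1], paste0(names(xs)[i], "_fcn.csv")))

  # ---- step 2: attention + group representation ----------------------
  attn_cfg <- cfg$attn; attn_cfg$seed <- cfg$seed + 3L
  .stage_log("step2", "training self-attention (H = %d, %d-fold CV)",
             attn_cfg$n_heads, attn_cfg$cv_folds)
  fit <- train_and_extract(xs, groups, attn_cfg, roi_names = labs)
  .stage_log("step2", "CV accuracy %.3f", fit$cv_accuracy)
  if (fit$cv_accuracy < 0.65) {
    warn <- c(warn, sprintf(
      paste0("classifier CV accuracy %.3f is close to chance; ",
             "attention matrices may be uninformative"), fit$cv_accuracy))
    warning(warn[length(warn)])
  }
  by_group <- split(fit$attn_matrices, groups)
  gm <- lapply(by_group, build_group_matrix)
  tops <- lapply(gm, function(g)
    top_quartile_rois(g, by_group[[g$group]], mode = cfg$selection_mode))
  if (!is.null(out)) {
    idx <- data.frame(subject_id = names(xs), group = groups,
                      path = paste0(names(xs), "_attn.csv"))
    utils::write.csv(idx, file.path(dirs[2], "attention_index.csv"),
                     row.names = FALSE)
    for (i in seq_along(xs))
      write_matrix_csv(fit$attn_matrices[[i]]$values,
                       file.path(dirs[2], idx$path[i]))
    for (g in levs) {
      write_group_rep(gm[[g]], tops[[g]],
                      file.path(dirs[2], paste0("group_matrix_", g, ".csv")),
                      file.path(dirs[2], paste0("top_rois_", g, ".csv")))
    }
  }

  # ---- step 3: LSIRM + summary networks ------------------------------
  post <- list(); prox <- list(); summ <- list()
  for (k in 1:2) {
    g <- levs[k]
    mc <- cfg$mcmc; mc$seed <- cfg$seed + 3L + k
    .stage_log("step3", "LSIRM for group %s (%d iterations)",
               g, mc$n_iterations)
    post[[g]] <- run_lsirm(gm[[g]], mc)
    prox[[g]] <- origin_proximity(post[[g]])
    summ[[g]] <- group_summary(fcns[groups == g],
                               threshold = cfg$summary_threshold, group = g)
    if (!is.null(out)) {
      write_lsirm(post[[g]], file.path(dirs[3], paste0("lsirm_", g)))
      export_network(summ[[g]],
                     graphml_path = file.path(dirs[3],
                                              paste0("summary_", g, ".graphml")),
                     edgelist_path = file.path(dirs[3],
                                               paste0("summary_", g, ".csv")))
    }
  }
  cmap <- categorize_rois(tops[[levs[1]]], tops[[levs[2]]],
                          prox[[levs[1]]], prox[[levs[2]]],
                          roi_names = labs)
  clusters <- lapply(levs, function(g) extract_clusters(summ[[g]], cmap))
  names(clusters) <- levs
  if (!is.null(out)) {
    write_category_map(cmap, file.path(dirs[3], "roi_categories.csv"))
    for (g in levs)
      plot_summary_fcn(summ[[g]], cmap,
                       path = file.path(dirs[3],
                                        paste0("summary_", g, ".pdf")))
  }

  report <- list(
    seed = cfg$seed,
    comparison = levs,
    input_type = cfg$input_type,
    cv_accuracy = fit$cv_accuracy,
    fold_accuracies = fit$fold_accuracies,
    top_rois = lapply(tops, function(t) t$ranking$roi),
    n_top_rois = vapply(tops, function(t) nrow(t$ranking), integer(1)),
    categories = as.list(table(cmap$categories$category)),
    acceptance = lapply(post, `[[`, "acceptance"),
    summary_edges = vapply(summ, function(s) sum(s$adjacency) / 2,
                           numeric(1)),
    clusters = lapply(clusters, function(cl)
      lapply(cl, function(x) x[c("name", "roi", "category", "members")])),
    warnings = warn)
  if (!is.null(out)) {
    json <- jsonlite::toJSON(report, auto_unbox = TRUE, pretty = TRUE,
                             digits = NA)
    writeLines(json, file.path(out, "report.json"))
  }
  report$category_map <- cmap
  report$objects <- list(cohort = cohort, fcns = fcns, fit = fit,
                         group_matrices = gm, top_rois = tops,
                         posteriors = post, proximity = prox,
                         summaries = summ)
  report
}

#' Read / write a pipeline configuration as YAML
#'
#' The YAML mirrors the [pipeline_config()] arguments; nested sections
#' `mapper`, `attn` and `mcmc` take the corresponding constructor
#' arguments, and a `cohort` section either names a `manifest` or gives
#' [cohort_spec()] arguments. Round-trips losslessly through
#' [write_pipeline_yaml()].
#'
#' @param path YAML file path.
#' @return a [pipeline_config()].
#' @export
read_pipeline_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  cohort <- if (!is.null(y$cohort$manifest)) y$cohort$manifest
  else {
    a <- y$cohort
    a$n_subjects_per_group <- unlist(a$n_subjects_per_group)
    do.call(cohort_spec, a)
  }
  pipeline_config(
    cohort = cohort,
    input_type = y$input_type %||% "topological",
    embed_params = y$embed_params %||% list(),
    mapper = do.call(mapper_config, y$mapper %||% list()),
    attn = do.call(attn_config, y$attn %||% list()),
    mcmc = do.call(mcmc_config, y$mcmc %||% list()),
    selection_mode = y$selection_mode %||% "rank_sum",
    summary_threshold = y$summary_threshold %||% 0.2,
    out_dir = y$out_dir,
    seed = y$seed %||% 1L)
}

#' @rdname read_pipeline_yaml
#' @param cfg a [pipeline_config()].
#' @return for the writer, invisibly `path`.
#' @export
write_pipeline_yaml <- function(cfg, path) {
  strip <- function(x) unclass(x)
  y <- list(
    cohort = if (is.character(cfg$cohort)) list(manifest = cfg$cohort)
             else {
               co <- strip(cfg$cohort)
               # yaml drops names of atomic vectors; carry as a map
               co$n_subjects_per_group <- as.list(co$n_subjects_per_group)
               co
             },
    input_type = cfg$input_type,
    embed_params = cfg$embed_params,
    mapper = strip(cfg$mapper),
    attn = strip(cfg$attn)[setdiff(names(cfg$attn), "model_width")],
    mcmc = strip(cfg$mcmc),
    selection_mode = cfg$selection_mode,
    summary_threshold = cfg$summary_threshold,
    out_dir = cfg$out_dir,
    seed = cfg$seed)
  yaml::write_yaml(y, path)
  invisible(path)
}
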
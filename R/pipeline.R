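# Config-driven orchestration: fit -> svd -> contrasts -> select, each
# dataset (batch) fitted independently and contrasts never crossing
# datasets. Every stage writes its artifacts and a JSON manifest records
# parameters plus md5 hashes of all inputs and outputs, so a rerun with
# identical inputs and config is verifiably identical.

run_config_schema <- list(
  required = c("expression", "site_counts", "design", "out_dir", "seed"),
  optional = c("tf_map", "fit", "svd", "contrasts", "selection", "log_level")
)

#' Validate a YAML run configuration
#'
#' Parses, schema-checks and defaults a run config. Unknown top-level keys
#' are rejected; referenced input files must exist.
#'
#' @param path Path to a YAML file, or an already-parsed list.
#' @return A defaulted list of class `run_config`.
#' @export
validate_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), c(run_config_schema$required, run_config_schema$optional))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  miss <- setdiff(run_config_schema$required, names(cfg))
  if (length(miss))
    stop("missing config key(s): ", paste(miss, collapse = ", "), call. = FALSE)
  for (key in c("expression", "site_counts", "design", "tf_map")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]]))
      stop("config input does not exist: ", key, " = ", cfg[[key]], call. = FALSE)
  }
  cfg$seed <- as.integer(cfg$seed)
  fit <- cfg$fit %||% list()
  cfg$fit <- fit_config(
    ridge_penalty = fit$ridge_penalty %||% "cv",
    cv_folds = fit$cv_folds %||% 5L,
    cv_grid = fit$cv_grid %||% 10^seq(-4, 2, length.out = 7L),
    known_noise_sd = fit$known_noise_sd,
    drop_zero_motifs = fit$drop_zero_motifs %||% TRUE,
    seed = cfg$seed
  )
  sv <- cfg$svd %||% list()
  cfg$svd <- list(dataset = sv$dataset, orient = sv$orient %||% "max_abs_positive",
                  treated = sv$treated %||% "treated",
                  control = sv$control %||% "control")
  ct <- cfg$contrasts %||% list()
  cfg$contrasts <- list(threshold = ct$threshold %||% 2.0,
                        pairs = ct$pairs %||% list())
  sel <- cfg$selection %||% list()
  comps <- sel$components %||% list()
  cfg$selection <- list(
    dataset = sel$dataset, treated = sel$treated %||% "treated",
    control = sel$control %||% "control",
    components = lapply(comps, function(cc) {
      do.call(selection_config, cc[intersect(names(cc), names(formals(selection_config)))])
    })
  )
  class(cfg) <- "run_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Stages, in order: load and align the inputs; fit motif activities
#' independently per dataset; decompose the configured dataset's
#' activities into programs; compute the configured condition contrasts
#' (within-dataset only); select representative motifs per configured
#' component. All intermediate artifacts are written under `out_dir` and a
#' manifest (JSON) records each stage's parameters and the md5 of every
#' input and output file. Any stage error aborts the run; the manifest is
#' still written with the failure recorded.
#'
#' @param config A [validate_config()] result, a config list, or a YAML
#'   path.
#' @return The manifest, invisibly (list; also written to
#'   `out_dir/manifest.json`).
#' @export
run_analysis <- function(config) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  inputs <- c(expression = config$expression, site_counts = config$site_counts,
              design = config$design)
  if (!is.null(config$tf_map)) inputs["tf_map"] <- config$tf_map
  manifest <- list(
    seed = config$seed,
    inputs = as.list(tools::md5sum(inputs)),
    stages = list()
  )
  outputs <- character()
  stage <- function(name, params, fn) {
    rec <- list(stage = name, parameters = params, status = "ok")
    res <- tryCatch(fn(), error = function(e) {
      rec$status <<- "failed"; rec$error <<- conditionMessage(e); NULL
    })
    manifest$stages[[name]] <<- rec
    if (identical(rec$status, "failed")) {
      manifest$stages[[name]] <<- rec
      write_manifest(manifest, outputs, out)
      stop("pipeline stage '", name, "' failed: ", rec$error, call. = FALSE)
    }
    res
  }

  loaded <- stage("load", list(), function() {
    expr <- read_expression_matrix(config$expression)
    counts <- suppressWarnings(read_site_counts(config$site_counts))
    design <- read_sample_design(config$design)
    tfmap <- if (!is.null(config$tf_map)) read_motif_tf_map(config$tf_map)
    list(aligned = align_study(expr, counts, design), tfmap = tfmap)
  })
  al <- loaded$aligned

  tables <- stage("fit", list(ridge_penalty = config$fit$ridge_penalty,
                              cv_folds = config$fit$cv_folds,
                              seed = config$seed), function() {
    datasets <- unique(al$design$dataset)
    tabs <- lapply(datasets, function(ds) {
      ids <- al$design$sample_id[al$design$dataset == ds]
      tab <- suppressWarnings(
        fit_activities(al$expr[, ids, drop = FALSE], al$counts, config$fit))
      prefix <- file.path(out, paste0("activities_", ds))
      outputs <<- c(outputs, write_activity_table(tab, prefix))
      tab
    })
    names(tabs) <- datasets
    tabs
  })

  svd_ds <- config$svd$dataset %||% names(tables)[1L]
  decomp_bundle <- stage("svd", list(dataset = svd_ds, orient = config$svd$orient), function() {
    tab <- tables[[svd_ds]]
    if (is.null(tab)) stop("svd dataset not fitted: ", svd_ds)
    dec <- decompose_activities(tab)
    if (config$svd$orient == "treatment_positive")
      dec <- orient_components(dec, al$design, "treatment_positive",
                               config$svd$treated, config$svd$control)
    sc <- component_scores(dec)
    f_v <- file.path(out, "svd_v.tsv"); f_u <- file.path(out, "svd_u.tsv")
    f_l <- file.path(out, "svd_lambda.tsv")
    f_p <- file.path(out, "svd_projections.tsv")
    f_r <- file.path(out, "svd_correlations.tsv")
    kn <- paste0("k", seq_along(dec$lambda))
    write_tsv_matrix(`colnames<-`(dec$v, kn), f_v, "sample_id")
    write_tsv_matrix(`colnames<-`(dec$u, kn), f_u, "motif_id")
    utils::write.table(
      data.frame(component = kn, lambda = sprintf("%.15g", dec$lambda),
                 variance_fraction = sprintf("%.15g", dec$variance_fraction)),
      f_l, sep = "\t", quote = FALSE, row.names = FALSE)
    write_tsv_matrix(`colnames<-`(sc$projection, kn), f_p, "motif_id")
    write_tsv_matrix(`colnames<-`(sc$correlation, kn), f_r, "motif_id")
    outputs <<- c(outputs, f_v, f_u, f_l, f_p, f_r)
    list(decomp = dec, scores = sc)
  })

  stage("contrasts", list(threshold = config$contrasts$threshold,
                          n_pairs = length(config$contrasts$pairs)), function() {
    if (!length(config$contrasts$pairs)) return(NULL)
    rows <- lapply(config$contrasts$pairs, function(pr) {
      tab <- tables[[pr$dataset]]
      if (is.null(tab)) stop("contrast references unknown dataset: ", pr$dataset)
      s1 <- summarize_condition(tab, al$design,
                                condition_key(pr$dataset, pr$condition1, pr$time))
      s2 <- summarize_condition(tab, al$design,
                                condition_key(pr$dataset, pr$condition2, pr$time))
      contrast_table(s1, s2, config$contrasts$threshold)
    })
    res <- do.call(rbind, rows)
    res$z <- sprintf("%.15g", res$z)
    res$mean_1 <- sprintf("%.15g", res$mean_1)
    res$mean_2 <- sprintf("%.15g", res$mean_2)
    f <- file.path(out, "contrasts.tsv")
    utils::write.table(res, f, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <<- c(outputs, f)
    res
  })

  stage("select", list(n_components = length(config$selection$components)), function() {
    if (!length(config$selection$components)) return(NULL)
    sel_ds <- config$selection$dataset %||% svd_ds
    tab <- tables[[sel_ds]]
    tz <- tryCatch(
      timepoint_contrasts(tab, al$design, sel_ds,
                          config$selection$treated, config$selection$control),
      error = function(e) NULL)
    sels <- lapply(config$selection$components, function(sc_cfg) {
      select_representatives(decomp_bundle$scores, tab$motif_z,
                             loaded$tfmap, tz, sc_cfg)
    })
    rows <- do.call(rbind, lapply(sels, function(s) {
      if (!length(s$positive) && !length(s$negative)) return(NULL)
      data.frame(component = s$component,
                 direction = c(rep("positive", length(s$positive)),
                               rep("negative", length(s$negative))),
                 motif_id = c(s$positive, s$negative),
                 stringsAsFactors = FALSE)
    }))
    audit <- do.call(rbind, lapply(sels, function(s) {
      if (!nrow(s$audit)) return(NULL)
      cbind(component = s$component, s$audit)
    }))
    f1 <- file.path(out, "selection.tsv"); f2 <- file.path(out, "selection_audit.tsv")
    utils::write.table(rows %||% empty_selection_df(), f1, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(audit %||% cbind(component = integer(), empty_audit()),
                       f2, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <<- c(outputs, f1, f2)
    sels
  })

  write_manifest(manifest, outputs, out)
}

empty_selection_df <- function() {
  data.frame(component = integer(), direction = character(),
             motif_id = character(), stringsAsFactors = FALSE)
}

write_manifest <- function(manifest, outputs, out) {
  manifest$outputs <- as.list(tools::md5sum(unique(outputs)))
  names(manifest$outputs) <- basename(names(manifest$outputs))
  path <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(manifest)
}
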
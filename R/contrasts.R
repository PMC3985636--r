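# Differential motif activity between conditions: replicate-averaged
# activities with standard errors of the mean, a per-motif z-statistic
#   z_m = (Abar_m,c1 - Abar_m,c2) / sqrt(se1^2 + se2^2),
# and the categorical pathway-dependence / tumor-specificity calls used to
# interpret knockout and tumor studies. Contrasts never cross datasets, so
# batch effects cannot masquerade as regulatory changes.

#' Identify a condition cell of a study
#'
#' @param dataset Dataset (batch) label.
#' @param condition Condition label (e.g. "treated", "control", "KO").
#' @param time Optional time in days; when given, the cell is restricted to
#'   that timepoint.
#' @return A list of class `condition_key`.
#' @export
condition_key <- function(dataset, condition, time = NULL) {
  structure(list(dataset = dataset, condition = condition, time = time),
            class = "condition_key")
}

#' @export
format.condition_key <- function(x, ...) {
  paste0(x$dataset, "/", x$condition,
         if (!is.null(x$time)) paste0("@", x$time) else "")
}

#' Average motif activities over the replicates of one condition
#'
#' The condition mean is the arithmetic mean of the replicate activities;
#' its standard error combines the independent per-sample posteriors as
#' `sqrt(sum_r se_r^2) / R`.
#'
#' @param table An [activity_table()].
#' @param design Aligned sample design.
#' @param key A [condition_key()].
#' @return A list of class `condition_summary` with per-motif `mean`,
#'   `se`, the key and `n_replicates`.
#' @export
summarize_condition <- function(table, design, key) {
  stopifnot(inherits(table, "activity_table"), inherits(key, "condition_key"))
  sel <- design$dataset == key$dataset & design$condition == key$condition
  if (!is.null(key$time)) {
    if (!"time" %in% names(design)) stop("design has no time column", call. = FALSE)
    sel <- sel & !is.na(design$time) & design$time == key$time
  }
  ids <- intersect(design$sample_id[sel], table$sample_ids)
  if (!length(ids))
    stop("no samples match condition ", format(key), call. = FALSE)
  A <- table$activities[, ids, drop = FALSE]
  SE <- table$std_errors[, ids, drop = FALSE]
  R <- length(ids)
  structure(list(
    key = key,
    motif_ids = table$motif_ids,
    mean = rowMeans(A),
    se = sqrt(rowSums(SE^2)) / R,
    n_replicates = R,
    sample_ids = ids
  ), class = "condition_summary")
}

#' Differential-activity z-statistic between two conditions
#'
#' Highly positive z indicates the motif's predicted targets are
#' upregulated in the first condition relative to the second, beyond what
#' other motifs explain. Both conditions must come from the same dataset;
#' cross-dataset contrasts are refused as batch-confounded.
#'
#' @param s1,s2 [summarize_condition()] results from the same dataset.
#' @return Named per-motif numeric vector of z values.
#' @export
differential_z <- function(s1, s2) {
  stopifnot(inherits(s1, "condition_summary"), inherits(s2, "condition_summary"))
  if (!identical(s1$key$dataset, s2$key$dataset))
    stop("batch-confounded contrast: conditions come from different datasets", call. = FALSE)
  if (!identical(s1$motif_ids, s2$motif_ids))
    stop("condition summaries cover different motif sets", call. = FALSE)
  (s1$mean - s2$mean) / sqrt(s1$se^2 + s2$se^2)
}

#' Classify motifs as up/down/not-significant from z values
#'
#' @param z Per-motif z vector.
#' @param threshold Positive cutoff; default 2.0 (two-sided ~95%).
#' @return Character vector in `{"up", "down", "ns"}`, named by motif.
#' @export
classify_motifs <- function(z, threshold = 2.0) {
  if (threshold <= 0) stop("threshold must be > 0", call. = FALSE)
  calls <- ifelse(z >= threshold, "up", ifelse(z <= -threshold, "down", "ns"))
  stats::setNames(calls, names(z))
}

#' Pathway-dependence call from wild-type and knockout treatment contrasts
#'
#' A motif whose treatment response is present in wild type but vanishes in
#' the pathway knockout is "downstream" of that pathway; a response present
#' in both with the same sign is "independent" of it.
#'
#' @param call_wt,call_ko Calls from [classify_motifs()] for the
#'   treated-vs-control contrast in WT and KO animals (same dataset each).
#' @return Character vector in `{"downstream", "independent", "none"}`.
#' @export
dependency_call <- function(call_wt, call_ko) {
  one <- function(wt, ko) {
    if (wt == "ns") return("none")
    if (ko == "ns") return("downstream")
    if (wt == ko) "independent" else "none"
  }
  stats::setNames(mapply(one, call_wt, call_ko, USE.NAMES = FALSE), names(call_wt))
}

#' Tumor-specificity call from promoted and non-promoted tumor contrasts
#'
#' Motifs dysregulated only in promoted tumors (tumor vs surrounding
#' tissue) are promotion-specific regulators; motifs dysregulated in both
#' tumor types reflect general tumor biology.
#'
#' @param call_promoted,call_nonpromoted Calls from [classify_motifs()]
#'   for the two tumor-vs-surrounding contrasts.
#' @return Character vector in `{"promoted_specific", "shared", "none"}`.
#' @export
tumor_specificity_call <- function(call_promoted, call_nonpromoted) {
  one <- function(p, np) {
    if (p != "ns" && np == "ns") return("promoted_specific")
    if (p != "ns" && np != "ns") return("shared")
    "none"
  }
  stats::setNames(mapply(one, call_promoted, call_nonpromoted, USE.NAMES = FALSE),
                  names(call_promoted))
}

#' Per-timepoint treated-vs-control z matrix for a kinetic study
#'
#' Convenience wrapper computing the differential-activity z at every
#' timepoint of a kinetic design; feeds the per-timepoint pattern filter
#' of the motif selection stage.
#'
#' @param table An [activity_table()].
#' @param design Aligned design with a `time` column.
#' @param dataset Dataset label.
#' @param treated,control Condition labels.
#' @return Motif x timepoint numeric matrix of z values, columns named by
#'   time and sorted by increasing time.
#' @export
timepoint_contrasts <- function(table, design, dataset,
                                treated = "treated", control = "control") {
  if (!"time" %in% names(design)) stop("kinetic contrasts need a time column", call. = FALSE)
  sub <- design[design$dataset == dataset & !is.na(design$time), , drop = FALSE]
  times <- sort(unique(sub$time))
  if (!length(times)) stop("no timepoints in dataset ", dataset, call. = FALSE)
  z <- vapply(times, function(tt) {
    differential_z(
      summarize_condition(table, design, condition_key(dataset, treated, tt)),
      summarize_condition(table, design, condition_key(dataset, control, tt))
    )
  }, numeric(length(table$motif_ids)))
  dimnames(z) <- list(table$motif_ids, as.character(times))
  z
}

#' Tabulate a contrast as a long data frame
#'
#' @param s1,s2 Condition summaries (same dataset).
#' @param threshold Classification cutoff.
#' @return `data.frame` with motif, means, z and call.
#' @export
contrast_table <- function(s1, s2, threshold = 2.0) {
  z <- differential_z(s1, s2)
  data.frame(
    motif_id = s1$motif_ids,
    contrast = paste(format(s1$key), "vs", format(s2$key)),
    mean_1 = s1$mean,
    mean_2 = s2$mean,
    z = z,
    call = classify_motifs(z, threshold),
    threshold = threshold,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}
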
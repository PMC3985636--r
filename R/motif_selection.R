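# Representative-motif selection per program component: motifs are ranked
# by BOTH projection and correlation (high rank in one alone is not
# representative), then refined by (i) an overall-significance filter on
# the motif z, (ii) a cognate-TF expression filter (a motif whose TFs are
# all below the log2-expression cutoff cannot act), and (iii) a
# per-timepoint differential-z pattern filter matching the component's
# temporal character. Every removal is recorded in an audit trail.

#' Selection configuration for one program component
#'
#' @param component Component index k.
#' @param top_n Candidate list depth per direction (default 10).
#' @param min_motif_z Overall-significance cutoff; by convention stricter
#'   for high-variance components (3.0 for components 1-2, 1.5 beyond).
#' @param min_tf_log_expression TF expression cutoff in log2 units
#'   (default 6.0).
#' @param timepoint_rule One of `"sustained"` (significant at
#'   `min_timepoints_hit` of the timepoints), `"day_first"`, `"day_last"`,
#'   `"none"`.
#' @param timepoint_z_threshold Per-timepoint |z| cutoff (default 2.0).
#' @param min_timepoints_hit Timepoints required under `"sustained"`
#'   (default 4, of the 7-timepoint kinetic design).
#' @param direction_sign When TRUE, qualifying per-timepoint z must match
#'   the candidate's cluster sign; when FALSE, |z| is used.
#' @return A list of class `selection_config`.
#' @export
selection_config <- function(component = 1L, top_n = 10L,
                             min_motif_z = if (component <= 2L) 3.0 else 1.5,
                             min_tf_log_expression = 6.0,
                             timepoint_rule = c("sustained", "day_first", "day_last", "none"),
                             timepoint_z_threshold = 2.0,
                             min_timepoints_hit = 4L,
                             direction_sign = FALSE) {
  timepoint_rule <- match.arg(timepoint_rule)
  if (min_motif_z < 0 || timepoint_z_threshold < 0)
    stop("thresholds must be >= 0", call. = FALSE)
  if (top_n < 1L) stop("top_n must be >= 1", call. = FALSE)
  structure(list(component = as.integer(component), top_n = as.integer(top_n),
                 min_motif_z = min_motif_z,
                 min_tf_log_expression = min_tf_log_expression,
                 timepoint_rule = timepoint_rule,
                 timepoint_z_threshold = timepoint_z_threshold,
                 min_timepoints_hit = as.integer(min_timepoints_hit),
                 direction_sign = isTRUE(direction_sign)),
            class = "selection_config")
}

#' Rank motifs against a component by projection and correlation jointly
#'
#' Positive candidates are the intersection of the top-n motifs by
#' projection and the top-n by correlation (both descending); negative
#' candidates analogously with ascending order. Within each list, motifs
#' are ordered by |projection| descending, ties broken by |correlation|,
#' then motif id. Requiring high rank in both scores excludes
#' large-activity motifs whose profile does not actually resemble the
#' component, and tiny-activity motifs that correlate by accident.
#'
#' @param scores A [component_scores()] result.
#' @param k Component index.
#' @param top_n List depth per direction.
#' @return List with character vectors `positive` and `negative`.
#' @export
rank_by_component <- function(scores, k, top_n = 10L) {
  stopifnot(inherits(scores, "component_scores"))
  if (k < 1L || k > ncol(scores$projection)) stop("component index out of range", call. = FALSE)
  p <- scores$projection[, k]
  r <- scores$correlation[, k]
  ids <- scores$motif_ids
  top <- function(v, decreasing) ids[order(v, ids, decreasing = c(decreasing, FALSE),
                                           method = "radix")][seq_len(min(top_n, length(v)))]
  tidy <- function(cand) {
    cand[order(-abs(p[cand]), -abs(r[cand]), cand, method = "radix")]
  }
  # a positive representative must score positive in BOTH measures (and
  # symmetrically for negative ones); this also keeps the clusters
  # disjoint when top_n approaches the number of motifs
  pos <- intersect(top(p, TRUE), top(r, TRUE))
  pos <- pos[p[pos] > 0 & r[pos] > 0]
  neg <- intersect(top(p, FALSE), top(r, FALSE))
  neg <- neg[p[neg] < 0 & r[neg] < 0]
  list(positive = tidy(pos), negative = tidy(neg))
}

#' Overall-significance filter
#'
#' Keeps candidates whose overall motif z meets the cutoff; removals are
#' appended to the audit trail.
#'
#' @param candidates Character vector of motif ids.
#' @param motif_z Named per-motif z vector.
#' @param min_z Cutoff (>= 0).
#' @param audit Existing audit `data.frame` to append to.
#' @return List with `kept` and `audit`.
#' @export
apply_significance_filter <- function(candidates, motif_z, min_z, audit = empty_audit()) {
  if (min_z < 0) stop("min_z must be >= 0", call. = FALSE)
  keep <- motif_z[candidates] >= min_z
  audit <- add_audit(audit, candidates[!keep], "significance",
                     sprintf("motif z %.3g < %.3g", motif_z[candidates[!keep]], min_z))
  list(kept = candidates[keep], audit = audit)
}

#' Cognate-TF expression filter
#'
#' A motif is kept iff at least one cognate TF has mean log2 expression at
#' or above the cutoff across samples (motifs represent TF families; one
#' expressed member suffices). Motifs absent from the map are kept with a
#' warning.
#'
#' @param candidates Character vector of motif ids.
#' @param tfmap List as from [read_motif_tf_map()].
#' @param min_expr Log2 expression cutoff (default 6.0).
#' @param audit Existing audit trail.
#' @return List with `kept` and `audit`.
#' @export
apply_expression_filter <- function(candidates, tfmap, min_expr = 6.0,
                                    audit = empty_audit()) {
  mean_expr <- rowMeans(tfmap$tf_expr)
  keep <- logical(length(candidates))
  reason <- character(length(candidates))
  for (i in seq_along(candidates)) {
    tfs <- tfmap$map$tf_id[tfmap$map$motif_id == candidates[i]]
    tfs <- intersect(tfs, names(mean_expr))
    if (!length(tfs)) {
      warning("motif absent from TF map, kept: ", candidates[i], call. = FALSE)
      keep[i] <- TRUE
    } else if (any(mean_expr[tfs] >= min_expr)) {
      keep[i] <- TRUE
    } else {
      reason[i] <- sprintf("all cognate TFs below log2 expression %.3g (max %.3g)",
                           min_expr, max(mean_expr[tfs]))
    }
  }
  audit <- add_audit(audit, candidates[!keep], "tf_expression", reason[!keep])
  list(kept = candidates[keep], audit = audit)
}

#' Per-timepoint differential-activity pattern filter
#'
#' Checks that a candidate's treated-vs-control z pattern across
#' timepoints matches the component's temporal character: `sustained`
#' requires |z| (or signed z, with `direction_sign`) past the threshold at
#' a minimum number of timepoints; `day_first` / `day_last` require it at
#' the first / last timepoint.
#'
#' @param candidates Character vector of motif ids.
#' @param tz Motif x timepoint z matrix from [timepoint_contrasts()].
#' @param config A [selection_config()].
#' @param signs Optional named vector of cluster signs (+1/-1) per
#'   candidate, used when `direction_sign` is enabled.
#' @param audit Existing audit trail.
#' @return List with `kept` and `audit`.
#' @export
apply_timepoint_pattern_filter <- function(candidates, tz, config,
                                           signs = NULL, audit = empty_audit()) {
  rule <- config$timepoint_rule
  if (rule == "none") return(list(kept = candidates, audit = audit))
  thr <- config$timepoint_z_threshold
  if (rule == "sustained" && config$min_timepoints_hit > ncol(tz))
    stop("rule requires more timepoints than the design provides", call. = FALSE)
  keep <- logical(length(candidates))
  for (i in seq_along(candidates)) {
    zrow <- tz[candidates[i], ]
    qual <- if (config$direction_sign && !is.null(signs))
      zrow * signs[[candidates[i]]] >= thr else abs(zrow) >= thr
    keep[i] <- switch(rule,
      sustained = sum(qual) >= config$min_timepoints_hit,
      day_first = qual[1L],
      day_last  = qual[length(qual)])
  }
  audit <- add_audit(audit, candidates[!keep], "timepoint_pattern",
                     sprintf("z pattern fails '%s' rule at |z| >= %.3g", rule, thr))
  list(kept = candidates[keep], audit = audit)
}

empty_audit <- function() {
  data.frame(motif_id = character(), stage = character(), reason = character(),
             stringsAsFactors = FALSE)
}

add_audit <- function(audit, motifs, stage, reason) {
  if (!length(motifs)) return(audit)
  rbind(audit, data.frame(motif_id = motifs, stage = stage,
                          reason = if (length(reason)) reason else "",
                          stringsAsFactors = FALSE))
}

#' Select representative motifs for a program component
#'
#' Composition of the ranking and the three refinement filters, applied in
#' the fixed order ranking -> significance -> TF expression -> timepoint
#' pattern, separately for the positively and negatively correlated
#' clusters. The audit trail attributes every removed candidate to the
#' filter that removed it.
#'
#' @param scores A [component_scores()] result.
#' @param motif_z Named per-motif overall z (from the activity table).
#' @param tfmap Motif-TF map with expression, or NULL to skip the filter.
#' @param tz Motif x timepoint z matrix, or NULL to skip the pattern rule.
#' @param config A [selection_config()].
#' @return List of class `motif_selection` with `positive`, `negative`,
#'   `audit` and the config.
#' @export
select_representatives <- function(scores, motif_z, tfmap = NULL, tz = NULL,
                                   config = selection_config()) {
  cand <- rank_by_component(scores, config$component, config$top_n)
  audit <- empty_audit()
  run_side <- function(ids, sign) {
    st <- apply_significance_filter(ids, motif_z, config$min_motif_z, empty_audit())
    if (!is.null(tfmap)) {
      st2 <- apply_expression_filter(st$kept, tfmap, config$min_tf_log_expression, st$audit)
    } else st2 <- st
    if (!is.null(tz) && config$timepoint_rule != "none") {
      signs <- stats::setNames(rep(sign, length(st2$kept)), st2$kept)
      st3 <- apply_timepoint_pattern_filter(st2$kept, tz, config, signs, st2$audit)
    } else st3 <- st2
    st3
  }
  pos <- run_side(cand$positive, +1)
  neg <- run_side(cand$negative, -1)
  audit <- rbind(pos$audit, neg$audit)
  structure(list(component = config$component,
                 positive = pos$kept, negative = neg$kept,
                 candidates = cand, audit = audit, config = config),
            class = "motif_selection")
}

#' @export
print.motif_selection <- function(x, ...) {
  cat(sprintf("motif_selection (component %d): %d positive, %d negative, %d removed\n",
              x$component, length(x$positive), length(x$negative), nrow(x$audit)))
  invisible(x)
}

#' Correlation between a motif's activity and its TFs' expression
#'
#' Pearson correlation, across samples, between the motif activity profile
#' and the log2 expression profile of each cognate TF. A positive
#' correlation supports the TF driving the motif's activity. TFs whose
#' profile (or the activity profile) has zero variance are reported as NA.
#'
#' @param table An [activity_table()].
#' @param tfmap Motif-TF map whose `tf_expr` covers the table's samples.
#' @param motif Motif id.
#' @return Named numeric vector, one entry per cognate TF.
#' @export
tf_expression_activity_correlation <- function(table, tfmap, motif) {
  stopifnot(inherits(table, "activity_table"))
  if (!motif %in% table$motif_ids) stop("unknown motif: ", motif, call. = FALSE)
  if (!all(table$sample_ids %in% colnames(tfmap$tf_expr)))
    stop("TF expression does not cover the activity table's samples", call. = FALSE)
  a <- table$activities[motif, ]
  tfs <- tfmap$map$tf_id[tfmap$map$motif_id == motif]
  tfs <- intersect(tfs, rownames(tfmap$tf_expr))
  vapply(stats::setNames(tfs, tfs), function(tf) {
    e <- tfmap$tf_expr[tf, table$sample_ids]
    if (stats::sd(a) == 0 || stats::sd(e) == 0) return(NA_real_)
    stats::cor(a, e)
  }, numeric(1L))
}
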
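# Synthetic studies with planted ground truth. The generator draws from the
# same linear model the fitter assumes:
#   e_ps = c_p + n_s + sum_m N_pm A_ms + eps_ps
# with activities composed as A = W B from a small orthonormal basis B of
# characteristic temporal programs (postnatal development decay, sustained
# treated/control offset, first-day transient divergence, late divergence)
# plus Gaussian noise. Recovery of A, of span(B) and of planted
# representative motifs is therefore an identity as noise -> 0, which is
# what makes every downstream stage testable.

#' Configuration for the synthetic-study generator
#'
#' Defaults emulate a 7-timepoint treated/control kinetic design sampled at
#' days 1, 3, 7, 14, 28, 57 and 91 with one replicate (14 samples), 500
#' promoters, 20 motifs, Poisson site counts with mean 0.5 per cell, four
#' temporal programs and expression noise at 0.1 times the standard
#' deviation of the regulatory signal term.
#'
#' @param n_promoters,n_motifs Problem size.
#' @param design_spec List: `type` "kinetic" (with `timepoints`,
#'   `conditions`, `replicates`, `dataset`) or "two_group" (with
#'   `conditions`, `replicates`, `dataset`).
#' @param n_programs Number of planted programs K.
#' @param shapes Character vector of built-in program shapes (in
#'   `development_decay`, `sustained_offset`, `transient_first`,
#'   `late_divergence`) or a K x sample numeric matrix of custom raw
#'   profiles.
#' @param program_assignment Integer vector (length `n_motifs`): program
#'   index loaded by each motif, 0 for a decoy that loads nothing. Default
#'   cycles motifs over the programs (every motif carries signal).
#' @param signal_scale Loading magnitude scale.
#' @param activity_noise_sd Optional within-motif activity noise SD.
#' @param site_rate Poisson mean per site-count cell (mu).
#' @param noise_sd Expression noise SD in log2 units, or NULL to use
#'   `noise_sd_relative`.
#' @param noise_sd_relative Expression noise as a fraction of the SD of
#'   the signal term `N %*% A_true` (default 0.1).
#' @param baseline_mean,baseline_sd Promoter basal level law (log2 units).
#' @param sample_offset_sd Per-sample normalization offset SD.
#' @param tf_expressed Logical vector (length `n_motifs`): whether each
#'   motif's synthetic cognate TF is expressed above the 6.0 cutoff.
#' @param tf_track_activity When TRUE, expressed TFs' expression profiles
#'   track their motif's activity (for correlation tests).
#' @param seed Mandatory integer seed.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_promoters = 500L, n_motifs = 20L,
                             design_spec = list(type = "kinetic",
                                                timepoints = c(1, 3, 7, 14, 28, 57, 91),
                                                conditions = c("treated", "control"),
                                                replicates = 1L,
                                                dataset = "kinetic"),
                             n_programs = 4L,
                             shapes = c("development_decay", "sustained_offset",
                                        "transient_first", "late_divergence"),
                             program_assignment = NULL,
                             signal_scale = 1.0,
                             activity_noise_sd = 0,
                             site_rate = 0.5,
                             noise_sd = NULL,
                             noise_sd_relative = 0.1,
                             baseline_mean = 7, baseline_sd = 1.5,
                             sample_offset_sd = 0.1,
                             tf_expressed = rep(TRUE, n_motifs),
                             tf_track_activity = TRUE,
                             seed) {
  if (missing(seed)) stop("generator seed is mandatory", call. = FALSE)
  if (n_promoters < 1L || n_motifs < 1L || n_programs < 1L)
    stop("counts must be >= 1", call. = FALSE)
  if (!is.null(noise_sd) && noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (site_rate <= 0) stop("site_rate must be > 0", call. = FALSE)
  if (is.null(program_assignment))
    program_assignment <- (seq_len(n_motifs) - 1L) %% n_programs + 1L
  if (length(program_assignment) != n_motifs)
    stop("program_assignment must have one entry per motif", call. = FALSE)
  if (any(program_assignment < 0L | program_assignment > n_programs))
    stop("program_assignment entries must be in 0..n_programs", call. = FALSE)
  if (length(tf_expressed) != n_motifs)
    stop("tf_expressed must have one entry per motif", call. = FALSE)
  structure(list(n_promoters = as.integer(n_promoters),
                 n_motifs = as.integer(n_motifs),
                 design_spec = design_spec, n_programs = as.integer(n_programs),
                 shapes = shapes, program_assignment = as.integer(program_assignment),
                 signal_scale = signal_scale, activity_noise_sd = activity_noise_sd,
                 site_rate = site_rate, noise_sd = noise_sd,
                 noise_sd_relative = noise_sd_relative,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 sample_offset_sd = sample_offset_sd,
                 tf_expressed = tf_expressed,
                 tf_track_activity = isTRUE(tf_track_activity),
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Generate a sample design from a design spec
#'
#' Kinetic specs produce one sample per (condition, time, replicate);
#' two-group specs one per (condition, replicate).
#'
#' @param config A [generator_config()] (only `design_spec` is used).
#' @return A validated design `data.frame`.
#' @export
generate_design <- function(config) {
  spec <- config$design_spec
  if (is.null(spec$type)) stop("empty design spec", call. = FALSE)
  ds <- if (is.null(spec$dataset)) "study1" else spec$dataset
  reps <- if (is.null(spec$replicates)) 1L else as.integer(spec$replicates)
  if (spec$type == "kinetic") {
    if (!length(spec$timepoints) || !length(spec$conditions))
      stop("kinetic spec needs timepoints and conditions", call. = FALSE)
    g <- expand.grid(replicate = seq_len(reps), condition = spec$conditions,
                     time = spec$timepoints, stringsAsFactors = FALSE)
    d <- data.frame(
      sample_id = sprintf("%s_%s_d%g_r%d", ds, g$condition, g$time, g$replicate),
      dataset = ds, condition = g$condition, time = g$time,
      replicate = g$replicate, stringsAsFactors = FALSE)
  } else if (spec$type == "two_group") {
    if (!length(spec$conditions)) stop("two-group spec needs conditions", call. = FALSE)
    g <- expand.grid(replicate = seq_len(reps), condition = spec$conditions,
                     stringsAsFactors = FALSE)
    d <- data.frame(
      sample_id = sprintf("%s_%s_r%d", ds, g$condition, g$replicate),
      dataset = ds, condition = g$condition,
      replicate = g$replicate, stringsAsFactors = FALSE)
  } else stop("unknown design spec type: ", spec$type, call. = FALSE)
  validate_sample_design(d)
}

#' Generate a Poisson site-count matrix
#'
#' Independent Poisson(`site_rate`) draws per cell. All-zero motif columns
#' are redrawn (they would be unidentifiable); if the column-centered
#' matrix cannot reach full column rank in 100 attempts (e.g. fewer
#' promoters than motifs) an error is raised. The condition number of the
#' centered matrix is attached as attribute `"condition_number"`.
#'
#' @param config A [generator_config()]. The caller controls the RNG
#'   state ([generate_study()] seeds once); call `set.seed()` first for a
#'   reproducible standalone matrix.
#' @return Promoter x motif count matrix.
#' @export
generate_site_counts <- function(config) {
  P <- config$n_promoters; M <- config$n_motifs
  N <- matrix(stats::rpois(P * M, config$site_rate), P, M,
              dimnames = list(sprintf("p%04d", seq_len(P)),
                              sprintf("motif_%02d", seq_len(M))))
  for (attempt in seq_len(100L)) {
    zero <- colSums(N) == 0
    if (any(zero))
      N[, zero] <- stats::rpois(P * sum(zero), config$site_rate)
    Nc <- sweep(N, 2L, colMeans(N), "-")
    sv <- svd(Nc, nu = 0, nv = 0)$d
    if (!any(colSums(N) == 0) && sv[length(sv)] > 1e-8 * sv[1L]) {
      attr(N, "condition_number") <- sv[1L] / sv[length(sv)]
      return(N)
    }
    N <- matrix(stats::rpois(P * M, config$site_rate), P, M, dimnames = dimnames(N))
  }
  stop("could not generate a full-column-rank site-count matrix in 100 attempts",
       call. = FALSE)
}

# raw (un-orthogonalized) built-in shape vectors over the design's samples
raw_program_shape <- function(shape, design) {
  cond <- design$condition
  if (shape %in% c("development_decay", "transient_first", "late_divergence") &&
      !"time" %in% names(design))
    stop("kinetic program shapes need a design with timepoints", call. = FALSE)
  tr <- ifelse(cond %in% c("treated", "PB"), 1, -1)
  switch(shape,
    development_decay = ifelse(design$time <= 14, 1, -1),
    sustained_offset  = tr,
    transient_first   = ifelse(design$time == min(design$time), tr, 0),
    late_divergence   = ifelse(design$time >= sort(unique(design$time), decreasing = TRUE)[2L],
                               tr, 0),
    stop("unknown program shape: ", shape, call. = FALSE))
}

#' Generate an orthonormal basis of characteristic program profiles
#'
#' Builds the raw shape vectors over the design's samples, mean-centers
#' each, and orthonormalizes them by stable sequential (modified
#' Gram-Schmidt) orthogonalization, preserving row order. The built-in
#' kinetic shapes mirror a postnatal-development decay (drop after two
#' weeks, identical in both arms), a sustained treated/control offset, a
#' first-timepoint-only divergence, and a divergence over the last month.
#'
#' @param design Sample design.
#' @param shapes Character vector of built-in shapes, or a K x sample
#'   numeric matrix of raw profiles.
#' @return K x sample matrix `B` with orthonormal, mean-centered rows.
#' @export
generate_program_profiles <- function(design, shapes) {
  S <- nrow(design)
  B <- if (is.matrix(shapes)) shapes else
    t(vapply(shapes, raw_program_shape, numeric(S), design = design))
  K <- nrow(B)
  if (K > S - 1L) stop("more programs than samples - 1", call. = FALSE)
  B <- B - rowMeans(B)
  for (k in seq_len(K)) {
    v <- B[k, ]
    if (k > 1L) for (j in seq_len(k - 1L)) v <- v - sum(v * B[j, ]) * B[j, ]
    nv <- sqrt(sum(v^2))
    if (nv < 1e-10)
      stop("program shape ", k, " is linearly dependent on earlier shapes", call. = FALSE)
    B[k, ] <- v / nv
  }
  rownames(B) <- if (is.matrix(shapes)) rownames(shapes) else shapes
  colnames(B) <- design$sample_id
  B
}

#' Plant motif activities as sparse combinations of program profiles
#'
#' Each signal motif loads on exactly one program with a magnitude drawn
#' around `signal_scale` and a random sign; decoy motifs
#' (`program_assignment == 0`) load nothing. `A_true = W B`, exactly
#' row-centered because the basis rows are. Optional within-motif Gaussian
#' activity noise is added after the composition (and re-centered).
#'
#' @param B Orthonormal program basis (K x sample).
#' @param config A [generator_config()]. RNG state is the caller's.
#' @return List with `A_true` (motif x sample) and loadings `W`
#'   (motif x K).
#' @export
generate_activities <- function(B, config) {
  M <- config$n_motifs; K <- nrow(B)
  W <- matrix(0, M, K, dimnames = list(sprintf("motif_%02d", seq_len(M)), rownames(B)))
  for (m in seq_len(M)) {
    k <- config$program_assignment[m]
    if (k > 0L)
      W[m, k] <- config$signal_scale * sample(c(-1, 1), 1L) * stats::runif(1L, 0.5, 1.5)
  }
  A <- W %*% B
  if (config$activity_noise_sd > 0) {
    A <- A + matrix(stats::rnorm(length(A), 0, config$activity_noise_sd),
                    nrow(A), ncol(A))
    A <- A - rowMeans(A)
  }
  list(A_true = A, W = W)
}

#' Generate an expression matrix from planted activities
#'
#' `e_ps = c_p + n_s + sum_m N_pm A_ms + eps_ps` with promoter baselines
#' `c_p ~ N(baseline_mean, baseline_sd)`, small per-sample offsets and
#' Gaussian expression noise. When `noise_sd` is NULL it is resolved as
#' `noise_sd_relative` times the SD of the signal term entries.
#'
#' @param counts Site-count matrix (promoters x motifs).
#' @param A_true Planted activities (motifs x samples).
#' @param config A [generator_config()]. RNG state is the caller's.
#' @return List with `expr`, `c_p`, `sample_offsets`, `noise_sd`.
#' @export
generate_expression <- function(counts, A_true, config) {
  P <- nrow(counts); S <- ncol(A_true)
  signal <- counts %*% A_true
  noise_sd <- if (!is.null(config$noise_sd)) config$noise_sd else
    config$noise_sd_relative * stats::sd(as.vector(signal))
  c_p <- stats::rnorm(P, config$baseline_mean, config$baseline_sd)
  n_s <- stats::rnorm(S, 0, config$sample_offset_sd)
  eps <- if (noise_sd > 0)
    matrix(stats::rnorm(P * S, 0, noise_sd), P, S) else matrix(0, P, S)
  expr <- signal + c_p + rep(n_s, each = P) + eps
  dimnames(expr) <- list(rownames(counts), colnames(A_true))
  list(expr = expr, c_p = c_p, sample_offsets = n_s, noise_sd = noise_sd)
}

# synthetic cognate-TF map: one TF per motif; expressed TFs sit around
# log2 expression 8 (tracking their motif's activity when configured),
# unexpressed TFs around 4, below the 6.0 cutoff
generate_tf_map <- function(A_true, config) {
  M <- nrow(A_true); S <- ncol(A_true)
  tf_ids <- sprintf("TF_%02d", seq_len(M))
  base <- ifelse(config$tf_expressed, 8, 4)
  expr <- matrix(base, M, S, dimnames = list(tf_ids, colnames(A_true)))
  if (config$tf_track_activity) {
    track <- A_true / pmax(apply(A_true, 1L, stats::sd), 1e-8)
    expr <- expr + ifelse(config$tf_expressed, 0.5, 0) * track
  }
  expr <- expr + matrix(stats::rnorm(M * S, 0, 0.05), M, S)
  list(map = data.frame(motif_id = rownames(A_true), tf_id = tf_ids,
                        stringsAsFactors = FALSE),
       tf_expr = expr)
}

#' Generate a complete synthetic study with ground truth
#'
#' One seeded call produces a mutually consistent bundle: design, site
#' counts, planted program basis and activities, expression matrix, a
#' synthetic motif-TF map, and the `synthetic_truth` record needed to
#' score recovery. Identical configs give byte-identical bundles.
#'
#' @param config A [generator_config()].
#' @return List with `expr`, `counts`, `design`, `tfmap`, `truth`.
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  design <- generate_design(config)
  counts <- generate_site_counts(config)
  B <- generate_program_profiles(design, config$shapes)
  act <- generate_activities(B, config)
  ex <- generate_expression(counts, act$A_true, config)
  tfmap <- generate_tf_map(act$A_true, config)
  truth <- structure(list(
    A_true = act$A_true, B = B, W = act$W,
    c_p = ex$c_p, sample_offsets = ex$sample_offsets,
    noise_sd = ex$noise_sd, seed = config$seed,
    program_assignment = config$program_assignment
  ), class = "synthetic_truth")
  list(expr = ex$expr, counts = counts, design = design,
       tfmap = tfmap, truth = truth)
}

#' Write a synthetic study bundle as TSV files
#'
#' @param study A [generate_study()] bundle.
#' @param dir Output directory (created if needed).
#' @return Named character vector of paths, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    expression = file.path(dir, "expression.tsv"),
    site_counts = file.path(dir, "site_counts.tsv"),
    design = file.path(dir, "design.tsv"),
    tf_map = file.path(dir, "tf_map.tsv"),
    truth_activities = file.path(dir, "truth_activities.tsv")
  )
  write_expression_matrix(study$expr, paths[["expression"]])
  write_site_counts(study$counts, paths[["site_counts"]])
  write_sample_design(study$design, paths[["design"]])
  write_motif_tf_map(study$tfmap, paths[["tf_map"]])
  write_tsv_matrix(study$truth$A_true, paths[["truth_activities"]], "motif_id")
  invisible(paths)
}
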
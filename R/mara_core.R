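# Motif activity response analysis: the promoter log-expression e_ps is
# modelled as e_ps = c_p + n_s + sum_m N_pm A_ms + noise, with c_p the basal
# activity of promoter p, n_s a per-sample normalization constant, N_pm the
# predicted binding-site count and A_ms the latent motif activity. The two
# nuisance blocks are eliminated exactly by double-centering E and
# column-centering N; the remaining per-sample ridge problem
#   min_A ||E~_s - N~ A_s||^2 + lambda ||A_s||^2
# is solved through the economy SVD of N~.

#' Construct an activity table
#'
#' Container for fitted motif activities `A_ms` (log2-expression units per
#' binding site), their posterior standard errors and the per-motif overall
#' significance z.
#'
#' @param activities Motif x sample numeric matrix with dimnames.
#' @param std_errors Matching matrix of standard errors, all > 0.
#' @param motif_z Per-motif significance (may be NA before
#'   [motif_significance()] is applied).
#' @param fit_meta List of fit metadata (penalty, residual variance,
#'   centering offsets, row means removed post-fit).
#' @return An object of class `activity_table`.
#' @export
activity_table <- function(activities, std_errors,
                           motif_z = rep(NA_real_, nrow(activities)),
                           fit_meta = list()) {
  stopifnot(is.matrix(activities), is.matrix(std_errors),
            identical(dim(activities), dim(std_errors)))
  if (is.null(rownames(activities)) || is.null(colnames(activities)))
    stop("activity table needs motif and sample identifiers", call. = FALSE)
  if (!all(is.finite(std_errors)) || any(std_errors <= 0))
    stop("standard errors must be finite and > 0", call. = FALSE)
  structure(list(
    motif_ids  = rownames(activities),
    sample_ids = colnames(activities),
    activities = activities,
    std_errors = std_errors,
    motif_z    = stats::setNames(as.numeric(motif_z), rownames(activities)),
    fit_meta   = fit_meta
  ), class = "activity_table")
}

#' @export
print.activity_table <- function(x, ...) {
  cat(sprintf("activity_table: %d motifs x %d samples\n",
              length(x$motif_ids), length(x$sample_ids)))
  if (!is.null(x$fit_meta$ridge_penalty))
    cat(sprintf("  ridge penalty %.3g, residual sd %.4g\n",
                x$fit_meta$ridge_penalty, sqrt(x$fit_meta$residual_variance)))
  invisible(x)
}

#' Fit configuration for motif activity inference
#'
#' @param ridge_penalty Positive ridge penalty, or `"cv"` to select it by
#'   promoter-fold cross-validation over `cv_grid`.
#' @param cv_folds Number of promoter folds (default 5).
#' @param cv_grid Candidate penalties, default 7 log-spaced points over
#'   1e-4..1e2.
#' @param known_noise_sd Optional known residual standard deviation; when
#'   supplied it replaces the pooled residual-variance estimate in the
#'   error bars.
#' @param drop_zero_motifs Drop all-zero site-count columns before fitting
#'   (default TRUE; they are unidentifiable).
#' @param seed Integer seed controlling the cross-validation fold split.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(ridge_penalty = "cv", cv_folds = 5L,
                       cv_grid = 10^seq(-4, 2, length.out = 7L),
                       known_noise_sd = NULL, drop_zero_motifs = TRUE,
                       seed = 1L) {
  if (identical(ridge_penalty, "cv")) {
    if (!length(cv_grid)) stop("cv_grid must be non-empty when ridge_penalty = 'cv'", call. = FALSE)
    if (any(cv_grid <= 0)) stop("cv_grid values must be > 0", call. = FALSE)
  } else {
    if (!is.numeric(ridge_penalty) || length(ridge_penalty) != 1L || ridge_penalty <= 0)
      stop("ridge_penalty must be a single value > 0 or 'cv'", call. = FALSE)
  }
  if (cv_folds < 2L) stop("cv_folds must be >= 2", call. = FALSE)
  if (!is.null(known_noise_sd) && known_noise_sd <= 0)
    stop("known_noise_sd must be > 0", call. = FALSE)
  structure(list(ridge_penalty = ridge_penalty, cv_folds = as.integer(cv_folds),
                 cv_grid = as.numeric(cv_grid), known_noise_sd = known_noise_sd,
                 drop_zero_motifs = isTRUE(drop_zero_motifs),
                 seed = as.integer(seed)),
            class = "fit_config")
}

#' Double-center an expression matrix
#'
#' Removes the per-promoter basal level and the per-sample normalization
#' constant by subtracting row and column means (grand mean added back
#' once). The stored offsets reconstruct the input exactly.
#'
#' @param expr Numeric matrix with >= 2 rows and >= 2 columns.
#' @return List with `centered` (every row and column mean 0) and
#'   `offsets` (promoter_means, sample_means, grand_mean).
#' @export
double_center <- function(expr) {
  stopifnot(is.matrix(expr), is.numeric(expr))
  if (nrow(expr) < 2L || ncol(expr) < 2L)
    stop("double centering needs at least 2 promoters and 2 samples", call. = FALSE)
  if (!all(is.finite(expr))) stop("non-finite values in expression matrix", call. = FALSE)
  g <- mean(expr)
  rm <- rowMeans(expr)
  cm <- colMeans(expr)
  centered <- expr - outer(rm, rep(1, ncol(expr))) -
    outer(rep(1, nrow(expr)), cm) + g
  dimnames(centered) <- dimnames(expr)
  list(centered = centered,
       offsets = list(promoter_means = rm, sample_means = cm, grand_mean = g))
}

# column-center the site-count matrix; returns centered matrix and means
center_counts <- function(counts) {
  cm <- colMeans(counts)
  list(centered = sweep(counts, 2L, cm, "-"), column_means = cm)
}

#' Select the ridge penalty by promoter-fold cross-validation
#'
#' Promoters are split into `cv_folds` folds (seeded, deterministic).
#' For each candidate penalty, activities are fitted on the training
#' promoters and the held-out promoters' centered expression is predicted
#' from their centered site counts; the penalty minimizing the mean
#' held-out squared error is returned.
#'
#' @param expr Aligned expression matrix.
#' @param counts Aligned site-count matrix.
#' @param config A [fit_config()] with `cv_grid` and `seed`.
#' @return The selected penalty (a single number from the grid).
#' @export
choose_ridge_penalty <- function(expr, counts, config = fit_config()) {
  grid <- config$cv_grid
  if (!length(grid)) stop("empty cv_grid", call. = FALSE)
  if (length(grid) == 1L) return(grid)
  P <- nrow(expr)
  if (P < config$cv_folds) stop("fewer promoters than cross-validation folds", call. = FALSE)
  dc <- double_center(expr)
  cc <- center_counts(counts)
  E <- dc$centered; N <- cc$centered
  folds <- local({
    set.seed(config$seed)
    sample(rep_len(seq_len(config$cv_folds), P))
  })
  err <- vapply(grid, function(lam) {
    se <- 0; n <- 0
    for (f in seq_len(config$cv_folds)) {
      test <- folds == f
      Ntr <- N[!test, , drop = FALSE]
      A <- ridge_solve(Ntr, E[!test, , drop = FALSE], lam)$A
      pred <- N[test, , drop = FALSE] %*% A
      se <- se + sum((E[test, , drop = FALSE] - pred)^2)
      n <- n + sum(test) * ncol(E)
    }
    se / n
  }, numeric(1L))
  grid[which.min(err)]
}

# economy-SVD ridge solve: A = V diag(d/(d^2+lam)) U' E, with unscaled
# posterior covariance V diag(1/(d^2+lam)) V' and hat-trace sum d^2/(d^2+lam)
ridge_solve <- function(N, E, lambda) {
  sv <- svd(N)
  keep <- sv$d > max(sv$d[1L], 1) * .Machine$double.eps * max(dim(N))
  d <- sv$d[keep]
  U <- sv$u[, keep, drop = FALSE]
  V <- sv$v[, keep, drop = FALSE]
  shrink <- d / (d^2 + lambda)
  A <- V %*% (shrink * crossprod(U, E))
  rownames(A) <- colnames(N); colnames(A) <- colnames(E)
  # full M x M inverse of (N'N + lambda I): rank-deficient directions get 1/lambda
  M <- ncol(N)
  inv <- V %*% ((1 / (d^2 + lambda)) * t(V))
  if (sum(keep) < M) {
    proj <- diag(M) - tcrossprod(V)
    inv <- inv + proj / lambda
  }
  list(A = A, inv_gram = inv, hat_trace = sum(d^2 / (d^2 + lambda)))
}

#' Infer motif activities from expression and site counts
#'
#' Solves, independently for each sample, the ridge-regularized linear
#' model of promoter expression on predicted binding-site counts. The
#' expression matrix is double-centered and the site-count matrix
#' column-centered, which eliminates the promoter basal levels and sample
#' normalization constants at the exact least-squares optimum. Standard
#' errors come from the Gaussian posterior covariance
#' `sigma2 * (N'N + lambda I)^-1` with `sigma2` the residual variance
#' pooled over samples (degrees of freedom `P*S - S*M_eff`, `M_eff` the
#' trace of the hat matrix). Activity rows are re-centered to zero mean
#' across samples; the removed means are stored in `fit_meta$row_means`.
#'
#' @param expr Aligned expression matrix (promoters x samples).
#' @param counts Aligned site-count matrix (promoters x motifs).
#' @param config A [fit_config()].
#' @return An [activity_table()] with per-motif significance filled in.
#' @export
fit_activities <- function(expr, counts, config = fit_config()) {
  validate_expression_matrix(expr)
  suppressWarnings(validate_site_counts(counts))
  if (!identical(rownames(expr), rownames(counts)))
    stop("expression and site counts are not aligned on promoters", call. = FALSE)
  dropped <- character()
  if (config$drop_zero_motifs) {
    zero <- colSums(counts != 0) == 0L
    if (any(zero)) {
      dropped <- colnames(counts)[zero]
      warning("dropping all-zero motif column(s): ", paste(dropped, collapse = ", "),
              call. = FALSE)
      counts <- counts[, !zero, drop = FALSE]
    }
  }
  if (!ncol(counts)) stop("no informative motifs: all site-count columns are zero", call. = FALSE)

  lambda <- config$ridge_penalty
  if (identical(lambda, "cv")) lambda <- choose_ridge_penalty(expr, counts, config)
  if (!is.numeric(lambda) || lambda <= 0) stop("ridge penalty must be > 0", call. = FALSE)

  dc <- double_center(expr)
  cc <- center_counts(counts)
  E <- dc$centered
  N <- cc$centered
  P <- nrow(E); S <- ncol(E); M <- ncol(N)

  fit <- ridge_solve(N, E, lambda)
  A <- fit$A
  if (!all(is.finite(A)))
    stop("non-finite activity solution for motif block: ",
         paste(colnames(N)[!is.finite(rowSums(A))], collapse = ", "), call. = FALSE)

  resid <- E - N %*% A
  df <- P * S - S * fit$hat_trace
  sigma2 <- if (!is.null(config$known_noise_sd)) config$known_noise_sd^2 else
    sum(resid^2) / max(df, 1)
  se_m <- sqrt(pmax(sigma2 * diag(fit$inv_gram), .Machine$double.xmin))
  SE <- matrix(se_m, nrow = M, ncol = S, dimnames = dimnames(A))

  row_means <- rowMeans(A)
  A <- A - row_means

  tab <- activity_table(A, SE, fit_meta = list(
    ridge_penalty = lambda,
    residual_variance = sigma2,
    hat_trace = fit$hat_trace,
    centering = c(dc$offsets, list(site_count_column_means = cc$column_means)),
    row_means = row_means,
    dropped_motifs = dropped
  ))
  motif_significance(tab)
}

#' Per-motif overall significance
#'
#' The z-score quantifying how significantly a motif explains expression
#' variation across samples: the root-mean-square of the per-sample
#' signal-to-noise ratios, `z_m = sqrt(mean_s (A_ms / se_ms)^2)`.
#'
#' @param table An [activity_table()].
#' @return The table with `motif_z` filled in.
#' @export
motif_significance <- function(table) {
  stopifnot(inherits(table, "activity_table"))
  if (any(table$std_errors <= 0)) stop("standard errors must be > 0", call. = FALSE)
  z <- sqrt(rowMeans((table$activities / table$std_errors)^2))
  table$motif_z <- stats::setNames(z, table$motif_ids)
  table
}
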
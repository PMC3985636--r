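# SVD of the motif-activity matrix A (motifs x samples): A = U Lambda V'.
# The right singular vectors v_k are orthonormal "characteristic activity
# profiles" — independent regulatory programs shared by many motifs. Because
# every activity row is mean-centered across samples, the v_k are
# mean-centered too, so the projections P = U Lambda and the Pearson
# correlations rho_ik = P_ik / ||A_i|| both fall out of the decomposition.

#' Decompose a motif-activity matrix into regulatory programs
#'
#' Thin SVD of the motif x sample activity matrix with components ordered
#' by non-increasing singular value and signs canonicalized by
#' [orient_components()] (`max_abs_positive`). Singular values below
#' `1e-12 * lambda_1` are reported as exactly zero (numerical rank
#' control).
#'
#' @param table An [activity_table()] (rows mean-centered, as the fitter
#'   guarantees), or a bare numeric matrix of activities.
#' @return A list of class `program_decomposition` with `u` (motif x
#'   component), `lambda` (singular values), `v` (sample x component,
#'   orthonormal columns), `variance_fraction` and ids.
#' @export
decompose_activities <- function(table) {
  A <- if (inherits(table, "activity_table")) table$activities else table
  stopifnot(is.matrix(A), is.numeric(A))
  if (!all(is.finite(A))) stop("non-finite activities", call. = FALSE)
  if (ncol(A) < 2L) stop("need at least 2 samples for a decomposition", call. = FALSE)
  sv <- svd(A)
  lambda <- sv$d
  # numerical rank control: components at relative machine scale are noise
  # of the factorization, and their right vectors need not be mean-centered
  keep <- lambda >= 1e-12 * lambda[1L]
  lambda <- lambda[keep]
  f <- if (sum(lambda^2) > 0) lambda^2 / sum(lambda^2) else rep(0, length(lambda))
  dec <- structure(list(
    motif_ids = rownames(A),
    sample_ids = colnames(A),
    u = `dimnames<-`(sv$u[, keep, drop = FALSE], list(rownames(A), NULL)),
    lambda = lambda,
    v = `dimnames<-`(sv$v[, keep, drop = FALSE], list(colnames(A), NULL)),
    variance_fraction = f,
    sign_convention = "raw"
  ), class = "program_decomposition")
  orient_components(dec, mode = "max_abs_positive")
}

#' @export
print.program_decomposition <- function(x, ...) {
  cat(sprintf("program_decomposition: %d motifs x %d samples, %d components\n",
              length(x$motif_ids), length(x$sample_ids), length(x$lambda)))
  cat("  variance fractions:",
      paste(sprintf("%.3f", utils::head(x$variance_fraction, 6L)), collapse = " "),
      if (length(x$lambda) > 6L) "..." else "", "\n")
  invisible(x)
}

#' Cumulative variance explained by the leading components
#'
#' @param decomp A [decompose_activities()] result.
#' @param k Number of leading components (1 <= k <= number available).
#' @return Sum of the first `k` variance fractions, in `[0, 1]`.
#' @export
variance_explained <- function(decomp, k) {
  stopifnot(inherits(decomp, "program_decomposition"))
  if (k < 1L || k > length(decomp$lambda))
    stop("component count k out of range", call. = FALSE)
  sum(decomp$variance_fraction[seq_len(k)])
}

#' Projections and correlations of motifs on program components
#'
#' The projection of motif i on component k is `P_ik = (U Lambda)_ik`,
#' scale-sensitive; the Pearson correlation `rho_ik = P_ik /
#' sqrt(sum_j P_ij^2)` is scale-free. Motifs with a numerically zero
#' activity profile get `rho = 0` by convention. High rank in both is
#' required for representativeness: a motif with large activities can have
#' a large projection on a component its profile does not resemble, and a
#' motif with tiny activities can correlate perfectly while projecting
#' weakly.
#'
#' @param decomp A [decompose_activities()] result.
#' @return List of class `component_scores` with matrices `projection`
#'   and `correlation` (motif x component).
#' @export
component_scores <- function(decomp) {
  stopifnot(inherits(decomp, "program_decomposition"))
  P <- decomp$u %*% diag(decomp$lambda, nrow = length(decomp$lambda))
  norms <- sqrt(rowSums(P^2))
  rho <- P / ifelse(norms > 0, norms, 1)
  rho[norms == 0, ] <- 0
  dimnames(P) <- dimnames(rho) <- list(decomp$motif_ids, NULL)
  structure(list(motif_ids = decomp$motif_ids, projection = P,
                 correlation = rho),
            class = "component_scores")
}

#' Canonicalize the signs of a decomposition
#'
#' The sign of each singular-vector pair is arbitrary; flipping `u_k` and
#' `v_k` together leaves the reconstruction unchanged. `max_abs_positive`
#' makes the largest-magnitude entry of each right vector positive
#' (deterministic without design metadata); `treatment_positive` makes the
#' mean of each right vector over treated samples at least that over
#' controls (readable signs for treated/control studies).
#'
#' @param decomp A `program_decomposition`.
#' @param design Sample design (needed for `treatment_positive`).
#' @param mode `"max_abs_positive"` or `"treatment_positive"`.
#' @param treated,control Condition labels for `treatment_positive`.
#' @return The re-oriented decomposition (idempotent).
#' @export
orient_components <- function(decomp, design = NULL,
                              mode = c("max_abs_positive", "treatment_positive"),
                              treated = "treated", control = "control") {
  mode <- match.arg(mode)
  v <- decomp$v
  if (mode == "max_abs_positive") {
    flip <- vapply(seq_len(ncol(v)), function(k) {
      idx <- which.max(abs(v[, k]))
      v[idx, k] < 0
    }, logical(1L))
  } else {
    if (is.null(design) || !all(c(treated, control) %in% design$condition))
      stop("treatment_positive orientation needs a design with treated/control labels",
           call. = FALSE)
    tr <- design$sample_id[design$condition == treated]
    co <- design$sample_id[design$condition == control]
    tr <- intersect(tr, decomp$sample_ids)
    co <- intersect(co, decomp$sample_ids)
    flip <- vapply(seq_len(ncol(v)), function(k) {
      mean(v[tr, k]) < mean(v[co, k])
    }, logical(1L))
  }
  sgn <- ifelse(flip, -1, 1)
  decomp$v <- sweep(v, 2L, sgn, "*")
  decomp$u <- sweep(decomp$u, 2L, sgn, "*")
  decomp$sign_convention <- mode
  decomp
}

#' Plot-ready long table of program profiles
#'
#' One row per (component, sample) holding the right-singular-vector entry
#' `v_ks` with the sample's time and condition, for plotting program
#' activity against time with treated and control samples distinguished.
#'
#' @param decomp A `program_decomposition`.
#' @param design Aligned design covering the decomposition's samples.
#' @param k Components to tabulate (default all).
#' @return `data.frame` with columns component, sample_id, time,
#'   condition, v.
#' @export
component_profile_table <- function(decomp, design, k = seq_along(decomp$lambda)) {
  stopifnot(inherits(decomp, "program_decomposition"))
  idx <- match(decomp$sample_ids, design$sample_id)
  if (anyNA(idx)) stop("design does not cover all decomposition samples", call. = FALSE)
  has_time <- "time" %in% names(design)
  if (has_time && anyNA(design$time[idx]))
    stop("missing time for samples of a kinetic design", call. = FALSE)
  out <- do.call(rbind, lapply(k, function(kk) {
    data.frame(
      component = kk,
      sample_id = decomp$sample_ids,
      time = if (has_time) design$time[idx] else NA_real_,
      condition = design$condition[idx],
      v = decomp$v[, kk],
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' Principal angles between two subspaces
#'
#' Angles (degrees) between the column spans of two bases; used to score
#' recovery of planted program subspaces.
#'
#' @param X,Y Matrices whose columns span the subspaces (same row count).
#' @return Numeric vector of angles in degrees, non-decreasing.
#' @export
principal_angles <- function(X, Y) {
  qx <- qr.Q(qr(X))
  qy <- qr.Q(qr(Y))
  s <- svd(crossprod(qx, qy))$d
  s <- pmin(pmax(s, -1), 1)
  sort(acos(s) * 180 / pi)
}
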
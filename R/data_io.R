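# ---- internal TSV matrix plumbing -------------------------------------------
# Dialect: UTF-8, tab-separated, '.' decimal, mandatory header row, first
# column holds row identifiers, no quoting. Numbers are written with 15
# significant digits so write/read round-trips are lossless well past 1e-12.

read_tsv_matrix <- function(path, id_name = "id") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "")
  if (ncol(raw) < 2L) stop("matrix file needs an id column and at least one data column: ", path, call. = FALSE)
  ids <- raw[[1L]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) stop("duplicated row ids in ", path, ": ", paste(dup, collapse = ", "), call. = FALSE)
  cols <- colnames(raw)[-1L]
  dupc <- unique(cols[duplicated(cols)])
  if (length(dupc)) stop("duplicated column ids in ", path, ": ", paste(dupc, collapse = ", "), call. = FALSE)
  body <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  bad <- which(!is.finite(num), arr.ind = TRUE)
  if (nrow(bad)) {
    i <- bad[1L, 1L]; j <- bad[1L, 2L]
    stop(sprintf("non-numeric or missing value in %s at row '%s', column '%s' (cell \"%s\")",
                 path, ids[i], cols[j], body[i, j]), call. = FALSE)
  }
  dimnames(num) <- list(ids, cols)
  num
}

write_tsv_matrix <- function(x, path, id_name) {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c(id_name, colnames(x)), collapse = "\t"), con)
  body <- apply(x, 1L, function(r) paste(sprintf("%.15g", r), collapse = "\t"))
  writeLines(paste(rownames(x), body, sep = "\t"), con)
  invisible(path)
}

#' Read a promoter-by-sample log-expression matrix
#'
#' Reads a tab-separated matrix of log2 expression values (RMA-like units)
#' with promoter identifiers in the first column and sample identifiers in
#' the header row. Row and column order are preserved from the file.
#'
#' @param path Path to a TSV file.
#' @return A numeric matrix (promoters x samples) with `dimnames`.
#' @export
read_expression_matrix <- function(path) {
  x <- read_tsv_matrix(path, "promoter_id")
  validate_expression_matrix(x)
}

#' Write a promoter-by-sample expression matrix
#'
#' @param x Numeric matrix with promoter row names and sample column names.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  validate_expression_matrix(x)
  write_tsv_matrix(x, path, "promoter_id")
}

validate_expression_matrix <- function(x) {
  stopifnot(is.matrix(x), is.numeric(x))
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("expression matrix needs promoter and sample identifiers", call. = FALSE)
  if (anyDuplicated(rownames(x))) stop("duplicated promoter ids", call. = FALSE)
  if (anyDuplicated(colnames(x))) stop("duplicated sample ids", call. = FALSE)
  if (!all(is.finite(x))) stop("expression matrix contains missing or non-finite values", call. = FALSE)
  x
}

#' Read a promoter-by-motif predicted binding-site count matrix
#'
#' Counts are the expected numbers of functional transcription-factor
#' binding sites per promoter, produced upstream by probabilistic TFBS
#' prediction; they must be non-negative but need not be integers.
#' Motif columns that are entirely zero are retained with a warning:
#' dropping them is a modelling decision made by [fit_activities()].
#'
#' @param path Path to a TSV file (promoters x motifs).
#' @return A numeric matrix with `dimnames`.
#' @export
read_site_counts <- function(path) {
  x <- read_tsv_matrix(path, "promoter_id")
  validate_site_counts(x)
}

#' Write a site-count matrix
#' @param x Numeric matrix, promoters x motifs, non-negative.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_site_counts <- function(x, path) {
  validate_site_counts(x)
  write_tsv_matrix(x, path, "promoter_id")
}

validate_site_counts <- function(x) {
  stopifnot(is.matrix(x), is.numeric(x))
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("site-count matrix needs promoter and motif identifiers", call. = FALSE)
  if (anyDuplicated(rownames(x))) stop("duplicated promoter ids", call. = FALSE)
  if (anyDuplicated(colnames(x))) stop("duplicated motif ids", call. = FALSE)
  if (!all(is.finite(x))) stop("site-count matrix contains missing or non-finite values", call. = FALSE)
  neg <- which(x < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    i <- neg[1L, 1L]; j <- neg[1L, 2L]
    stop(sprintf("negative site count at promoter '%s', motif '%s'",
                 rownames(x)[i], colnames(x)[j]), call. = FALSE)
  }
  zero <- colnames(x)[colSums(x) == 0]
  if (length(zero))
    warning("all-zero site-count columns retained: ", paste(zero, collapse = ", "), call. = FALSE)
  x
}

#' Read a sample design table
#'
#' The design encodes the study structure: one row per sample with its
#' dataset (batch) label, experimental condition, optional time in days,
#' replicate index and optional genotype. Missing replicate indices are
#' filled with a running index within each (dataset, condition, time) cell.
#'
#' @param path Path to a TSV file with required columns `sample_id`,
#'   `dataset`, `condition` and optional `time`, `replicate`, `genotype`.
#' @return A `data.frame` with one row per sample, file order preserved.
#' @export
read_sample_design <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.delim(path, header = TRUE, sep = "\t",
                         colClasses = "character", check.names = FALSE,
                         quote = "", comment.char = "")
  validate_sample_design(d)
}

#' Write a sample design table
#' @param design A validated design `data.frame`.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_sample_design <- function(design, path) {
  out <- design
  if ("time" %in% names(out)) out$time <- sprintf("%.15g", out$time)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

validate_sample_design <- function(d) {
  req <- c("sample_id", "dataset", "condition")
  miss <- setdiff(req, names(d))
  if (length(miss)) stop("design lacks required column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  dup <- unique(d$sample_id[duplicated(d$sample_id)])
  if (length(dup)) stop("duplicated sample_id in design: ", paste(dup, collapse = ", "), call. = FALSE)
  if ("time" %in% names(d)) {
    tm <- suppressWarnings(as.numeric(d$time))
    bad <- d$time != "" & !is.na(d$time) & is.na(tm)
    if (any(bad)) stop("non-numeric time value(s): ", paste(d$time[bad], collapse = ", "), call. = FALSE)
    if (any(tm < 0, na.rm = TRUE)) stop("negative time value in design", call. = FALSE)
    d$time <- tm
  }
  if ("replicate" %in% names(d)) {
    rp <- suppressWarnings(as.integer(d$replicate))
    if (any(!is.na(rp) & rp < 1L)) stop("replicate index must be >= 1", call. = FALSE)
    d$replicate <- rp
  } else {
    d$replicate <- NA_integer_
  }
  cell <- paste(d$dataset, d$condition, if ("time" %in% names(d)) d$time else "")
  for (cl in unique(cell)) {
    idx <- which(cell == cl)
    if (anyNA(d$replicate[idx])) d$replicate[idx] <- seq_along(idx)
  }
  rownames(d) <- NULL
  d
}

#' Align expression, site counts and design to a common study
#'
#' Restricts promoters to the intersection of the expression and site-count
#' matrices (expression-file order) and samples to those present in both
#' the expression matrix and the design, preserving the design's sample
#' order. Dropped identifiers are attached as the `"dropped"` attribute.
#'
#' @param expr Expression matrix (promoters x samples).
#' @param counts Site-count matrix (promoters x motifs).
#' @param design Sample design `data.frame`.
#' @return A list with elements `expr`, `counts`, `design`, aligned.
#' @export
align_study <- function(expr, counts, design) {
  validate_expression_matrix(expr)
  suppressWarnings(validate_site_counts(counts))
  promoters <- intersect(rownames(expr), rownames(counts))
  if (!length(promoters)) stop("no promoters shared between expression and site counts", call. = FALSE)
  samples <- design$sample_id[design$sample_id %in% colnames(expr)]
  if (!length(samples)) stop("no samples shared between expression and design", call. = FALSE)
  dropped <- list(
    promoters_expr  = setdiff(rownames(expr), promoters),
    promoters_counts = setdiff(rownames(counts), promoters),
    samples_expr    = setdiff(colnames(expr), samples),
    samples_design  = setdiff(design$sample_id, samples)
  )
  out <- list(
    expr   = expr[promoters, samples, drop = FALSE],
    counts = counts[promoters, , drop = FALSE],
    design = design[match(samples, design$sample_id), , drop = FALSE]
  )
  rownames(out$design) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Read a motif-to-TF map with TF expression
#'
#' Long-format TSV with columns `motif_id`, `tf_id` followed by one column
#' per sample holding the TF's log2 expression. A motif may map to several
#' TFs (motifs typically represent the binding specificity of a TF family).
#'
#' @param path Path to the TSV file.
#' @return A list with `map` (data.frame motif_id, tf_id) and `tf_expr`
#'   (TF x sample numeric matrix).
#' @export
read_motif_tf_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.delim(path, header = TRUE, sep = "\t",
                         colClasses = "character", check.names = FALSE,
                         quote = "", comment.char = "")
  if (!all(c("motif_id", "tf_id") %in% names(d)))
    stop("motif-TF map needs columns motif_id and tf_id", call. = FALSE)
  samp <- setdiff(names(d), c("motif_id", "tf_id"))
  expr <- NULL
  if (length(samp)) {
    expr <- as.matrix(d[, samp, drop = FALSE])
    expr <- array(suppressWarnings(as.numeric(expr)), dim = dim(expr),
                  dimnames = list(d$tf_id, samp))
    if (!all(is.finite(expr))) stop("non-numeric TF expression value in map", call. = FALSE)
    expr <- expr[!duplicated(rownames(expr)), , drop = FALSE]
  }
  list(map = data.frame(motif_id = d$motif_id, tf_id = d$tf_id,
                        stringsAsFactors = FALSE),
       tf_expr = expr)
}

#' Write a motif-to-TF map
#' @param tfmap List as returned by [read_motif_tf_map()].
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_motif_tf_map <- function(tfmap, path) {
  m <- tfmap$map
  if (!is.null(tfmap$tf_expr)) {
    e <- tfmap$tf_expr[m$tf_id, , drop = FALSE]
    e <- as.data.frame(apply(e, 2L, function(x) sprintf("%.15g", x)),
                       stringsAsFactors = FALSE)
    m <- cbind(m, e)
  }
  utils::write.table(m, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write an activity table as a TSV triplet
#'
#' Writes `<prefix>_activities.tsv` (motif x sample activities),
#' `<prefix>_stderr.tsv` (posterior standard errors) and
#' `<prefix>_motif_z.tsv` (per-motif overall significance). Numbers carry
#' 15 significant digits so the paired reader round-trips losslessly.
#'
#' @param table An [activity_table()].
#' @param prefix Path prefix for the three files.
#' @return Character vector of the three paths, invisibly.
#' @export
write_activity_table <- function(table, prefix) {
  stopifnot(inherits(table, "activity_table"))
  if (!length(table$motif_ids)) stop("empty motif set: nothing to write", call. = FALSE)
  pa <- paste0(prefix, "_activities.tsv")
  ps <- paste0(prefix, "_stderr.tsv")
  pz <- paste0(prefix, "_motif_z.tsv")
  write_tsv_matrix(table$activities, pa, "motif_id")
  write_tsv_matrix(table$std_errors, ps, "motif_id")
  zd <- data.frame(motif_id = table$motif_ids,
                   z = sprintf("%.15g", table$motif_z))
  utils::write.table(zd, pz, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(c(pa, ps, pz))
}

#' Read an activity table written by [write_activity_table()]
#' @param prefix Path prefix used at write time.
#' @return An [activity_table()].
#' @export
read_activity_table <- function(prefix) {
  a <- read_tsv_matrix(paste0(prefix, "_activities.tsv"), "motif_id")
  s <- read_tsv_matrix(paste0(prefix, "_stderr.tsv"), "motif_id")
  zd <- utils::read.delim(paste0(prefix, "_motif_z.tsv"), header = TRUE,
                          sep = "\t", check.names = FALSE)
  z <- as.numeric(zd$z)
  names(z) <- zd$motif_id
  activity_table(a, s, z[rownames(a)])
}
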
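# fixture builders shared across test files; everything is generated in
# code so tests carry no data files

tiny_expr <- function(P = 3L, S = 2L, seed = 1L) {
  set.seed(seed)
  matrix(round(rnorm(P * S, 7, 1), 4), P, S,
         dimnames = list(paste0("p", seq_len(P)), paste0("s", seq_len(S))))
}

tiny_counts <- function(P = 3L, M = 2L, seed = 2L) {
  set.seed(seed)
  matrix(rpois(P * M, 1) + ifelse(row(matrix(0, P, M)) == 1L, 1, 0), P, M,
         dimnames = list(paste0("p", seq_len(P)), paste0("m", seq_len(M))))
}

kinetic_design <- function(times = c(1, 3, 7, 14, 28, 57, 91), reps = 1L,
                           dataset = "kinetic") {
  g <- expand.grid(replicate = seq_len(reps), condition = c("treated", "control"),
                   time = times, stringsAsFactors = FALSE)
  data.frame(sample_id = sprintf("%s_%s_d%g_r%d", dataset, g$condition, g$time, g$replicate),
             dataset = dataset, condition = g$condition, time = g$time,
             replicate = g$replicate, stringsAsFactors = FALSE)
}

random_activity_table <- function(M = 5L, S = 4L, seed = 3L) {
  set.seed(seed)
  A <- matrix(rnorm(M * S), M, S,
              dimnames = list(paste0("m", seq_len(M)), paste0("s", seq_len(S))))
  A <- A - rowMeans(A)
  SE <- matrix(runif(M * S, 0.1, 0.5), M, S, dimnames = dimnames(A))
  motif_significance(activity_table(A, SE))
}

write_matrix_fixture <- function(x, path) {
  maraprog::write_expression_matrix(x, path)
}

# condition summaries with exactly known means/SEs, for contrast tests
manual_summary <- function(means, ses, dataset = "d1", condition = "c") {
  structure(list(
    key = condition_key(dataset, condition),
    motif_ids = names(means) %||% paste0("m", seq_along(means)),
    mean = unname(means), se = unname(ses),
    n_replicates = 1L, sample_ids = "x"
  ), class = "condition_summary")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
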
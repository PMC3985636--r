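make_scores <- function(P, R, ids = sprintf("m%02d", seq_len(nrow(P)))) {
  dimnames(P) <- dimnames(R) <- list(ids, NULL)
  structure(list(motif_ids = ids, projection = P, correlation = R),
            class = "component_scores")
}

test_that("ranking requires high rank in both projection and correlation", {
  # m1 leads both scores; m2 projects highly but correlates poorly; m3 the
  # reverse; m4 strongly negative in both
  P <- cbind(c(10, 9, 0.1, -8, 0.5, 0.2))
  R <- cbind(c(0.95, 0.10, 0.90, -0.92, 0.05, 0.02))
  sc <- make_scores(P, R)
  out <- rank_by_component(sc, 1, top_n = 2)
  expect_true("m01" %in% out$positive)
  expect_false("m02" %in% out$positive)  # projection-only motif excluded
  expect_false("m03" %in% out$positive)  # correlation-only motif excluded
  expect_identical(out$negative, "m04")
})

test_that("ranking agrees with independently recomputed Pearson ranks", {
  set.seed(23)
  A <- matrix(rnorm(20 * 10), 20, 10,
              dimnames = list(sprintf("m%02d", 1:20), paste0("s", 1:10)))
  A <- A - rowMeans(A)
  dec <- decompose_activities(A)
  sc <- component_scores(dec)
  out <- rank_by_component(sc, 2, top_n = 5)
  # oracle: direct correlation and projection, ranked independently
  p <- drop(A %*% dec$v[, 2]); r <- drop(cor(t(A), dec$v[, 2]))
  top_p <- names(sort(p, decreasing = TRUE))[1:5]
  top_r <- names(sort(r, decreasing = TRUE))[1:5]
  want_pos <- Filter(function(m) p[m] > 0 && r[m] > 0, intersect(top_p, top_r))
  expect_setequal(out$positive, want_pos)
  bot_p <- names(sort(p))[1:5]; bot_r <- names(sort(r))[1:5]
  want_neg <- Filter(function(m) p[m] < 0 && r[m] < 0, intersect(bot_p, bot_r))
  expect_setequal(out$negative, want_neg)
  expect_length(intersect(out$positive, out$negative), 0)
})

test_that("significance filter is monotone and audited", {
  z <- c(m1 = 5, m2 = 2.9, m3 = 3.0, m4 = 0.4)
  out <- apply_significance_filter(names(z), z, 3.0)
  expect_equal(out$kept, c("m1", "m3"))  # boundary value kept (>=)
  expect_setequal(out$audit$motif_id, c("m2", "m4"))
  expect_true(all(out$audit$stage == "significance"))
  # min_z = 0 is the identity; raising the cutoff never adds motifs
  expect_equal(apply_significance_filter(names(z), z, 0)$kept, names(z))
  kept_sets <- lapply(c(0, 1, 3, 6), function(m) apply_significance_filter(names(z), z, m)$kept)
  for (i in seq_len(length(kept_sets) - 1))
    expect_true(all(kept_sets[[i + 1]] %in% kept_sets[[i]]))
})

test_that("TF expression filter applies the any-TF rule at the 6.0 cutoff", {
  tfmap <- list(
    map = data.frame(motif_id = c("mA", "mB", "mC", "mC"),
                     tf_id = c("TF1", "TF2", "TF3", "TF4"),
                     stringsAsFactors = FALSE),
    tf_expr = matrix(c(5.9, 5.9, 6.1, 6.1, 3.0, 3.0, 7.0, 7.0), 4, 2,
                     byrow = TRUE,
                     dimnames = list(paste0("TF", 1:4), c("s1", "s2"))))
  out <- apply_expression_filter(c("mA", "mB", "mC"), tfmap, 6.0)
  expect_equal(out$kept, c("mB", "mC"))  # mA at 5.9 removed; mC kept via TF4
  expect_equal(out$audit$motif_id, "mA")
  expect_true(grepl("tf_expression", out$audit$stage))
  expect_warning(apply_expression_filter("unknown", tfmap, 6.0), "absent from TF map")
})

test_that("timepoint pattern rules behave per rule and threshold", {
  tz <- rbind(
    m_sus  = c(2.5, 2.5, -0.1, 2.5, 0.2, 2.5, 0.1),  # exactly 4 of 7
    m_thin = c(2.5, 2.5, 0.0, 2.5, 0.0, 0.0, 0.0),   # only 3 of 7
    m_last = c(0, 0, 0, 0, 0, 0, 3.2),
    m_zero = rep(0, 7))
  colnames(tz) <- as.character(c(1, 3, 7, 14, 28, 57, 91))
  cfg_s <- selection_config(3, timepoint_rule = "sustained",
                            timepoint_z_threshold = 2, min_timepoints_hit = 4)
  out <- apply_timepoint_pattern_filter(rownames(tz), tz, cfg_s)
  expect_equal(out$kept, "m_sus")

  cfg_f <- selection_config(3, timepoint_rule = "day_first", timepoint_z_threshold = 2)
  expect_equal(apply_timepoint_pattern_filter(rownames(tz), tz, cfg_f)$kept,
               c("m_sus", "m_thin"))
  cfg_l <- selection_config(4, timepoint_rule = "day_last", timepoint_z_threshold = 2)
  expect_equal(apply_timepoint_pattern_filter(rownames(tz), tz, cfg_l)$kept, "m_last")
  # all-zero z removed under every rule
  for (cfg in list(cfg_s, cfg_f, cfg_l))
    expect_false("m_zero" %in% apply_timepoint_pattern_filter("m_zero", tz, cfg)$kept)
  # direction_sign: a negative-cluster candidate needs negative z
  cfg_d <- selection_config(3, timepoint_rule = "day_last",
                            timepoint_z_threshold = 2, direction_sign = TRUE)
  expect_equal(apply_timepoint_pattern_filter("m_last", tz, cfg_d,
                                              signs = c(m_last = -1))$kept,
               character(0))
  expect_error(apply_timepoint_pattern_filter("m_sus", tz,
    selection_config(1, timepoint_rule = "sustained", min_timepoints_hit = 9)),
    "more timepoints")
})

test_that("full selection recovers planted sustained motifs among decoys", {
  # 3 signal motifs on the sustained program with expressed TFs, 2 loaded
  # decoys with unexpressed TFs, 18 silent decoys
  assign <- c(rep(2L, 5L), rep(0L, 18L))
  expressed <- c(TRUE, TRUE, TRUE, FALSE, FALSE, rep(TRUE, 18L))
  cfg <- generator_config(n_promoters = 400, n_motifs = 23,
                          design_spec = list(type = "kinetic",
                                             timepoints = c(1, 3, 7, 14, 28, 57, 91),
                                             conditions = c("treated", "control"),
                                             replicates = 2L, dataset = "kinetic"),
                          program_assignment = assign, tf_expressed = expressed,
                          signal_scale = 2, noise_sd = 0.05, seed = 424)
  st <- generate_study(cfg)
  tab <- fit_activities(st$expr, st$counts, fit_config(ridge_penalty = 1e-4, seed = 1))
  dec <- decompose_activities(tab)
  sc <- component_scores(dec)
  tz <- timepoint_contrasts(tab, st$design, "kinetic")
  sel_cfg <- selection_config(component = 1, min_motif_z = 1.5,
                              timepoint_rule = "sustained")
  # the sustained program dominates this study: it is component 1
  sel <- select_representatives(sc, tab$motif_z, st$tfmap, tz, sel_cfg)
  found <- sort(c(sel$positive, sel$negative))
  expect_identical(found, sprintf("motif_%02d", 1:3))
  # the two loaded-but-unexpressed decoys were removed by the TF filter
  unexpr <- sprintf("motif_%02d", 4:5)
  expect_true(all(unexpr %in% sel$audit$motif_id[sel$audit$stage == "tf_expression"]))
  # silent decoys that surfaced as candidates were removed for lack of
  # signal (overall significance or the per-timepoint pattern), never by
  # the TF filter
  cand <- unlist(sel$candidates)
  silent <- intersect(sprintf("motif_%02d", 6:23), cand)
  silent_stages <- sel$audit$stage[sel$audit$motif_id %in% silent]
  expect_true(all(silent_stages %in% c("significance", "timepoint_pattern")))
  # audit covers every removed candidate
  expect_equal(nrow(sel$audit), length(cand) - length(found))

  # disabling all filters returns the raw ranking
  off <- selection_config(component = 1, min_motif_z = 0, timepoint_rule = "none")
  sel0 <- select_representatives(sc, tab$motif_z, NULL, NULL, off)
  expect_identical(sel0$positive, sel0$candidates$positive)
  expect_identical(sel0$negative, sel0$candidates$negative)
})

test_that("selection is deterministic and early filters commute", {
  set.seed(31)
  A <- matrix(rnorm(15 * 10), 15, 10,
              dimnames = list(sprintf("m%02d", 1:15), paste0("s", 1:10)))
  A <- A - rowMeans(A)
  sc <- component_scores(decompose_activities(A))
  z <- setNames(runif(15, 0, 6), rownames(A))
  tfmap <- list(map = data.frame(motif_id = rownames(A),
                                 tf_id = paste0("TF", 1:15), stringsAsFactors = FALSE),
                tf_expr = matrix(runif(15 * 2, 4, 8), 15, 2,
                                 dimnames = list(paste0("TF", 1:15), c("s1", "s2"))))
  cfg <- selection_config(1, min_motif_z = 2, timepoint_rule = "none")
  s1 <- select_representatives(sc, z, tfmap, NULL, cfg)
  s2 <- select_representatives(sc, z, tfmap, NULL, cfg)
  expect_identical(s1[c("positive", "negative")], s2[c("positive", "negative")])
  # significance-then-expression equals expression-then-significance
  cand <- s1$candidates$positive
  a <- apply_expression_filter(apply_significance_filter(cand, z, 2)$kept, tfmap, 6)$kept
  b <- apply_significance_filter(apply_expression_filter(cand, tfmap, 6)$kept, z, 2)$kept
  expect_setequal(a, b)
})

test_that("TF expression / motif activity correlation matches the formula", {
  cfg <- generator_config(n_promoters = 200, n_motifs = 6, seed = 55)
  st <- generate_study(cfg)
  tab <- fit_activities(st$expr, st$counts, fit_config(ridge_penalty = 0.01, seed = 1))
  r <- tf_expression_activity_correlation(tab, st$tfmap, "motif_01")
  e <- st$tfmap$tf_expr["TF_01", tab$sample_ids]
  expect_equal(unname(r["TF_01"]), cor(tab$activities["motif_01", ], e),
               tolerance = 1e-12)
  # tracking TFs correlate positively with their motif's activity
  expect_gt(r[["TF_01"]], 0.5)

  # a TF profile equal to the activity profile correlates exactly 1;
  # a constant TF profile is reported as NA
  tfmap <- st$tfmap
  tfmap$tf_expr["TF_01", ] <- tab$activities["motif_01", colnames(tfmap$tf_expr)]
  tfmap$tf_expr["TF_02", ] <- 7
  expect_equal(unname(tf_expression_activity_correlation(tab, tfmap, "motif_01")["TF_01"]), 1,
               tolerance = 1e-12)
  expect_true(is.na(tf_expression_activity_correlation(tab, tfmap, "motif_02")["TF_02"]))
})
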
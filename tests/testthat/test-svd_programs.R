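row_centered_matrix <- function(M, S, seed) {
  set.seed(seed)
  A <- matrix(rnorm(M * S), M, S,
              dimnames = list(paste0("m", seq_len(M)), paste0("s", seq_len(S))))
  A - rowMeans(A)
}

test_that("decomposition basics: ordering, orthonormality, reconstruction", {
  A <- row_centered_matrix(50, 14, seed = 41)
  dec <- decompose_activities(A)
  expect_true(all(diff(dec$lambda) <= 1e-12))
  G <- crossprod(dec$v)
  expect_lt(max(abs(G - diag(ncol(G)))), 1e-10)
  expect_lt(abs(sum(dec$variance_fraction) - 1), 1e-10)
  # right singular vectors inherit the rows' mean-centering
  expect_lt(max(abs(colMeans(dec$v))), 1e-9)
  rec <- dec$u %*% diag(dec$lambda) %*% t(dec$v)
  expect_lt(norm(A - rec, "F") / norm(A, "F"), 1e-10)
})

test_that("closed-form cases: rank-1 and diagonal matrices", {
  a <- c(1, 2, 3); b <- c(1, -1, 0, 0)
  A <- outer(a, b)
  dimnames(A) <- list(paste0("m", 1:3), paste0("s", 1:4))
  dec <- decompose_activities(A)
  expect_equal(sum(dec$lambda > 1e-10), 1L)
  expect_equal(dec$variance_fraction[1], 1)

  D <- diag(c(4, 3))
  dimnames(D) <- list(c("m1", "m2"), c("s1", "s2"))
  decd <- decompose_activities(D)
  expect_equal(decd$lambda, c(4, 3))
  expect_equal(decd$variance_fraction, c(16, 9) / 25)
  expect_equal(variance_explained(decd, 1), 0.64)
  expect_equal(variance_explained(decd, 2), 1.0)
  expect_error(variance_explained(decd, 3), "out of range")
})

test_that("cumulative variance explained is monotone and reaches 1", {
  A <- row_centered_matrix(30, 10, seed = 6)
  dec <- decompose_activities(A)
  cum <- vapply(seq_along(dec$lambda), variance_explained, numeric(1), decomp = dec)
  expect_true(all(diff(cum) >= -1e-12))
  expect_equal(cum[length(cum)], 1, tolerance = 1e-10)
})

test_that("projections and correlations obey the SVD identities", {
  A <- row_centered_matrix(30, 10, seed = 19)
  dec <- decompose_activities(A)
  sc <- component_scores(dec)
  # P = U Lambda, and P_ik = a_i . v_k
  expect_equal(sc$projection, A %*% dec$v, tolerance = 1e-10, ignore_attr = TRUE)
  # rho identity vs direct Pearson correlation (the mean-centering makes
  # the plain cor() coincide with the SVD-derived values)
  direct <- cor(t(A), dec$v)
  expect_lt(max(abs(sc$correlation - direct)), 1e-10)
  expect_true(all(abs(sc$correlation) <= 1 + 1e-12))

  # breaking row-centering breaks the identity (negative control)
  A2 <- A + 0.8
  dec2 <- decompose_activities(A2)
  sc2 <- component_scores(dec2)
  direct2 <- cor(t(A2), dec2$v)
  expect_gt(max(abs(sc2$correlation - direct2)), 1e-6)
})

test_that("a motif aligned with one program projects only on it; small motifs can still correlate", {
  d <- kinetic_design()
  B <- generate_program_profiles(d, c("sustained_offset", "development_decay"))
  A <- rbind(5 * B[1, ], 3 * B[2, ], 1e-3 * B[1, ])
  rownames(A) <- c("big1", "big2", "tiny1")
  dec <- decompose_activities(A)
  sc <- component_scores(dec)
  k1 <- which.max(abs(sc$projection["big1", ]))
  expect_equal(unname(abs(sc$projection["big1", k1])), 5, tolerance = 1e-10)
  expect_equal(unname(abs(sc$correlation["big1", k1])), 1, tolerance = 1e-10)
  expect_lt(abs(sc$correlation["big1", -k1][1]), 1e-8)
  # tiny-activity motif: projection tiny, correlation still 1 in magnitude
  expect_lt(abs(sc$projection["tiny1", k1]), 0.01)
  expect_equal(unname(abs(sc$correlation["tiny1", k1])), 1, tolerance = 1e-8)
})

test_that("orientation is canonical, idempotent and reconstruction-preserving", {
  A <- row_centered_matrix(12, 8, seed = 51)
  dec <- decompose_activities(A)
  # max_abs_positive: the dominant entry of each right vector is positive
  for (k in seq_along(dec$lambda))
    expect_gte(dec$v[which.max(abs(dec$v[, k])), k], 0)
  expect_equal(orient_components(dec, mode = "max_abs_positive"), dec)

  # flipping arbitrary components then re-orienting restores the original
  flipped <- dec
  flipped$u[, c(1, 3)] <- -flipped$u[, c(1, 3)]
  flipped$v[, c(1, 3)] <- -flipped$v[, c(1, 3)]
  expect_equal(orient_components(flipped, mode = "max_abs_positive"), dec)

  rec0 <- dec$u %*% diag(dec$lambda) %*% t(dec$v)
  rec1 <- flipped$u %*% diag(flipped$lambda) %*% t(flipped$v)
  expect_lt(max(abs(rec0 - rec1)), 1e-12)
})

test_that("treatment_positive orientation follows the design labels", {
  d <- kinetic_design()
  set.seed(3)
  A <- matrix(rnorm(10 * nrow(d)), 10, nrow(d),
              dimnames = list(paste0("m", 1:10), d$sample_id))
  A <- A - rowMeans(A)
  dec <- orient_components(decompose_activities(A), d, "treatment_positive")
  tr <- d$sample_id[d$condition == "treated"]
  co <- d$sample_id[d$condition == "control"]
  for (k in seq_along(dec$lambda))
    expect_gte(mean(dec$v[tr, k]) - mean(dec$v[co, k]), -1e-12)
  expect_error(orient_components(dec, d[0, ], "treatment_positive"), "treated/control")
})

test_that("planted program subspace is recovered within 5 degrees", {
  cfg <- generator_config(n_promoters = 400, n_motifs = 40,
                          program_assignment = rep(1:4, each = 10),
                          noise_sd = 0.0, activity_noise_sd = 0.05, seed = 2024)
  st <- generate_study(cfg)
  # decompose the planted-plus-noise activities directly: program recovery
  # is a property of the SVD stage, independent of the fitter
  dec <- decompose_activities(st$truth$A_true)
  ang <- principal_angles(t(st$truth$B), dec$v[, 1:4])
  expect_true(all(ang < 5))
  expect_true(all(diff(dec$variance_fraction) <= 1e-12))
  expect_lt(abs(sum(dec$variance_fraction) - 1), 1e-10)
})

test_that("profile tables carry V entries with design metadata and round-trip", {
  d <- kinetic_design()
  A <- row_centered_matrix(8, nrow(d), seed = 9)
  colnames(A) <- d$sample_id
  dec <- decompose_activities(A)
  pt <- component_profile_table(dec, d, k = 1:2)
  expect_equal(nrow(pt), 2L * nrow(d))
  expect_setequal(unique(pt$condition), c("treated", "control"))
  expect_equal(pt$v[pt$component == 1], unname(dec$v[, 1]))

  f <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(pt, f, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- utils::read.delim(f)
  expect_equal(back$v, pt$v, tolerance = 1e-12)

  d2 <- d; d2$time <- NULL
  expect_error(component_profile_table(dec, d2, 1), NA)  # two-group designs allowed
  d3 <- d; d3$time[2] <- NA
  expect_error(component_profile_table(dec, d3, 1), "missing time")
})
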
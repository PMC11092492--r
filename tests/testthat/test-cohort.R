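test_that("score normalization maps bounds to the unit interval", {
  expect_equal(normalize_scores(c(60, 90, 120), 60, 120), c(0, 0.5, 1))
  # affine shift of inputs and bounds leaves outputs unchanged
  v <- c(71, 88, 103)
  expect_equal(normalize_scores(v, 60, 120),
               normalize_scores(v + 17, 60 + 17, 120 + 17))
  expect_error(normalize_scores(1, 5, 5), "degenerate")
})

test_that("behavioral distance is a symmetric L1 distance", {
  expect_equal(behavioral_distance(0.5, 0.5), 0)
  expect_equal(behavioral_distance(1, 0), 1)
  x <- runif(10); y <- runif(10)
  expect_equal(behavioral_distance(x, y), behavioral_distance(y, x))
  expect_true(all(behavioral_distance(x, y) >= 0))
})

test_that("matching recovers the generating gain for self-built cohorts", {
  sweep <- analytic_sweep()
  b <- range(sweep$curves$accuracy)
  it <- 500
  cv <- sweep$curves[sweep$curves$iteration == it, ]
  cohort <- tibble::tibble(
    subject_id = paste0("M", seq_len(nrow(cv))),
    score = normalize_scores(cv$accuracy, b[1], b[2]),
    group = "TD")
  attr(cohort, "score_bounds") <- c(0, 1)   # scores already on model scale
  m <- match_cohort(sweep, cohort)
  at_it <- m$table[m$table$iteration == it, ]
  expect_equal(at_it$best_gain, cv$gain)
  expect_equal(at_it$distance, rep(0, nrow(cv)))
})

test_that("tied distances break toward the lower gain", {
  sweep <- analytic_sweep(gains = c(1, 2), iters = c(0, 100))
  sweep$curves$accuracy <- c(0.2, 0.4, 0.2, 0.4)  # both gains identical
  cohort <- tibble::tibble(subject_id = "s1", score = 0.3, group = "TD")
  attr(cohort, "score_bounds") <- c(0, 1)
  m <- match_cohort(sweep, cohort)
  expect_true(all(m$table$best_gain == 1))
})

test_that("reference iteration is the argmin of mean distance, earliest on ties", {
  m <- structure(list(table = tibble::tibble(
    iteration = rep(c(100, 200, 300), each = 2),
    subject_id = rep(c("a", "b"), 3),
    group = "TD",
    best_gain = 1,
    distance = c(0.3, 0.3, 0.1, 0.1, 0.2, 0.2))), class = "gt_match")
  expect_equal(select_reference_iteration(m), 200)
  m$table$distance <- rep(0.2, 6)
  expect_equal(select_reference_iteration(m), 100)
})

test_that("synthetic cohorts have the requested structure and are seeded", {
  sweep <- analytic_sweep()
  coh <- generate_synthetic_cohort(24, 21, sweep, iteration = 500,
                                   noise_sd = 0.02, seed = 9)
  expect_equal(nrow(coh), 45)
  expect_true(all(coh$group[coh$score < 90] == "MLD"))
  expect_true(all(coh$true_gain %in% gain_grid()))
  coh2 <- generate_synthetic_cohort(24, 21, sweep, iteration = 500,
                                    noise_sd = 0.02, seed = 9)
  expect_identical(coh, coh2)
  expect_error(generate_synthetic_cohort(0, 5, sweep, 500), "positive")
})

test_that("noiseless synthetic cohorts are recovered exactly", {
  sweep <- analytic_sweep()
  coh <- generate_synthetic_cohort(24, 21, sweep, iteration = 500,
                                   noise_sd = 0, seed = 4)
  m <- match_cohort(sweep, coh)
  at_ref <- m$table[m$table$iteration == 500, ]
  expect_equal(at_ref$best_gain[order(at_ref$subject_id)],
               coh$true_gain[order(coh$subject_id)])
  expect_true(all(at_ref$distance < 1e-12))
})

test_that("gain recovery tolerates moderate score noise", {
  # recovery is assessed at the iteration where the gain grid spans the
  # accuracy range (the matching regime)
  sweep <- analytic_sweep()
  coh <- generate_synthetic_cohort(24, 21, sweep, iteration = 1000,
                                   noise_sd = 0.05, seed = 11)
  m <- match_cohort(sweep, coh)
  at_ref <- m$table[m$table$iteration == 1000, ]
  err <- abs(at_ref$best_gain[order(at_ref$subject_id)] -
               coh$true_gain[order(coh$subject_id)])
  expect_gte(mean(err <= 0.25), 0.8)
  # matched groups separate in gain as constructed
  expect_gt(mean(at_ref$best_gain[at_ref$group == "MLD"]),
            mean(at_ref$best_gain[at_ref$group == "TD"]))
})

test_that("permutation control exceeds the fitted distance for matched cohorts", {
  sweep <- analytic_sweep()
  coh <- generate_synthetic_cohort(24, 21, sweep, iteration = 500,
                                   noise_sd = 0.02, seed = 5)
  m <- match_cohort(sweep, coh)
  pc <- permutation_control(m, sweep, n_perm = 200, seed = 1, iteration = 500)
  expect_gt(pc$perm_mean, pc$fitted_mean)
  expect_lt(pc$p_value, 0.05)
  pc2 <- permutation_control(m, sweep, n_perm = 200, seed = 1, iteration = 500)
  expect_identical(pc$perm, pc2$perm)
})

test_that("cohort files round-trip with group labels recomputed", {
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(subject_id = c("a", "b"),
                              score = c(85, 95),
                              group = c("MLD", "TD")),
                   path, row.names = FALSE)
  coh <- read_cohort(path)
  expect_equal(coh$group, c("MLD", "TD"))
  # wrong stored labels are fixed with a warning
  utils::write.csv(data.frame(subject_id = "a", score = 85, group = "TD"),
                   path, row.names = FALSE)
  expect_warning(coh2 <- read_cohort(path), "relabeled")
  expect_equal(coh2$group, "MLD")
  utils::write.csv(data.frame(id = 1), path, row.names = FALSE)
  expect_error(read_cohort(path), "lacks column")
})
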
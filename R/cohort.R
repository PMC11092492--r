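# Cohort matching ("digital twins"): each subject's normalized achievement
# score is matched, at every evaluated iteration, to the gain level whose
# normalized test accuracy is nearest in L1 distance. Model accuracies are
# normalized by the min/max over the entire sweep (all gains x all evaluated
# iterations); subject scores by the cohort's recorded normalization bounds.

#' Min-max normalization
#'
#' @param values numeric vector.
#' @param lo,hi normalization bounds; `hi > lo`.
#' @return `(values - lo) / (hi - lo)`.
#' @export
normalize_scores <- function(values, lo, hi) {
  if (!is.finite(lo) || !is.finite(hi) || hi <= lo)
    abort("degenerate normalization range: `hi` must exceed `lo`")
  (values - lo) / (hi - lo)
}

#' Behavioral distance between a model and a subject
#'
#' Manhattan (L1) distance between the two normalized scores; for scalar
#' scores this is the absolute difference.
#'
#' @param norm_model,norm_subject normalized scores in \[0, 1\].
#' @return nonnegative scalar (vectorized).
#' @export
behavioral_distance <- function(norm_model, norm_subject) {
  abs(norm_model - norm_subject)
}

#' Read a cohort table
#'
#' Reads a CSV with columns `subject_id, score, group`. Group membership is
#' recomputed from the achievement threshold and cross-checked against the
#' stored labels.
#'
#' @param path CSV path.
#' @param threshold achievement score below which a subject is labeled
#'   `"MLD"`, default 90.
#' @return a cohort tibble (`subject_id`, `score`, `group`).
#' @export
read_cohort <- function(path, threshold = 90) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "score", "group")
  miss <- setdiff(need, names(df))
  if (length(miss))
    abort(paste0("cohort file lacks column(s): ", paste(miss, collapse = ", ")))
  recomputed <- ifelse(df$score < threshold, "MLD", "TD")
  if (!all(recomputed == df$group))
    warn("cohort group labels disagree with the score threshold; relabeled")
  as_tibble(df) %>% mutate(group = recomputed)
}

sweep_accuracy_bounds <- function(sweep) {
  range(sweep$curves$accuracy)
}

cohort_bounds <- function(cohort) {
  b <- attr(cohort, "score_bounds")
  if (is.null(b)) b <- range(cohort$score)
  b
}

#' Match every subject to its best-fitting gain at every iteration
#'
#' For each evaluated iteration of the sweep and each subject, finds the
#' gain minimizing the behavioral distance between the model's normalized
#' test accuracy and the subject's normalized score. Ties break toward the
#' lower gain.
#'
#' @param sweep a [sweep_gains()] result.
#' @param cohort a cohort tibble ([read_cohort()] or
#'   [generate_synthetic_cohort()]).
#' @return a `gt_match` object: tibble `table` with one row per
#'   (iteration, subject): `best_gain`, `distance`, plus cohort and
#'   normalization metadata.
#' @export
match_cohort <- function(sweep, cohort) {
  stopifnot(inherits(sweep, "gt_sweep"))
  if (nrow(cohort) == 0) abort("empty cohort")
  if (nrow(sweep$curves) == 0) abort("empty sweep")
  b <- sweep_accuracy_bounds(sweep)
  curves <- sweep$curves %>%
    mutate(norm_acc = normalize_scores(.data$accuracy, b[1], b[2]))
  cb <- cohort_bounds(cohort)
  subj_norm <- normalize_scores(cohort$score, cb[1], cb[2])
  tab <- purrr::map_dfr(unique(curves$iteration), function(it) {
    cv <- curves[curves$iteration == it, ]
    cv <- cv[order(cv$gain), ]
    d <- outer(cv$norm_acc, subj_norm,
               function(m, s) behavioral_distance(m, s))
    best <- apply(d, 2, which.min)       # first minimum = lowest gain
    tibble(iteration = it, subject_id = cohort$subject_id,
           group = cohort$group, best_gain = cv$gain[best],
           distance = d[cbind(best, seq_along(subj_norm))])
  })
  structure(list(table = tab, cohort = cohort,
                 model_bounds = b, subject_bounds = cb,
                 gains = sort(unique(curves$gain))),
            class = "gt_match")
}

#' @export
print.gt_match <- function(x, ...) {
  cat("<gt_match> ", length(unique(x$table$subject_id)), " subjects x ",
      length(unique(x$table$iteration)), " iterations; reference iteration ",
      select_reference_iteration(x), "\n", sep = "")
  invisible(x)
}

#' Mean behavioral distance per iteration
#'
#' @param match a [match_cohort()] result.
#' @return tibble of `iteration`, `mean_distance` (and per-group means).
#' @export
match_distance_profile <- function(match) {
  stopifnot(inherits(match, "gt_match"))
  match$table %>%
    group_by(.data$iteration) %>%
    summarise(mean_distance = mean(.data$distance), .groups = "drop")
}

#' Reference iteration of a matched cohort
#'
#' The evaluated iteration minimizing the cohort-mean behavioral distance;
#' ties break toward the earliest iteration.
#'
#' @param match a [match_cohort()] result.
#' @return integer iteration.
#' @export
select_reference_iteration <- function(match) {
  prof <- match_distance_profile(match)
  as.integer(prof$iteration[which.min(prof$mean_distance)])
}

#' Permutation control for the cohort matching
#'
#' At the reference iteration, repeatedly assigns every subject a uniformly
#' random gain from the grid and computes the resulting mean behavioral
#' distance, giving the null distribution the fitted matching is compared
#' against.
#'
#' @param match a [match_cohort()] result.
#' @param sweep the sweep the match was computed from.
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @param iteration iteration at which to permute; defaults to the
#'   reference iteration.
#' @return list with `perm` (tibble of per-permutation mean distance),
#'   `fitted_mean`, `perm_mean`, `perm_sd`, and the one-sided `p_value`
#'   for the fitted mean being lower than the null.
#' @export
permutation_control <- function(match, sweep, n_perm = 1000L, seed = 1L,
                                iteration = NULL) {
  stopifnot(inherits(match, "gt_match"), n_perm >= 1)
  if (is.null(iteration)) iteration <- select_reference_iteration(match)
  b <- match$model_bounds
  cv <- sweep$curves[sweep$curves$iteration == iteration, ]
  cv <- cv[order(cv$gain), ]
  norm_acc <- normalize_scores(cv$accuracy, b[1], b[2])
  cb <- match$subject_bounds
  subj_norm <- normalize_scores(match$cohort$score, cb[1], cb[2])
  ns <- length(subj_norm)
  means <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_perm), function(i) {
      g <- sample.int(nrow(cv), ns, replace = TRUE)
      mean(behavioral_distance(norm_acc[g], subj_norm))
    }, numeric(1))
  })
  fitted <- mean(match$table$distance[match$table$iteration == iteration])
  list(perm = tibble(perm = seq_len(n_perm), mean_distance = means),
       fitted_mean = fitted, perm_mean = mean(means), perm_sd = sd(means),
       p_value = (1 + sum(means <= fitted)) / (n_perm + 1),
       iteration = iteration)
}

#' Generate a synthetic achievement cohort from a trained sweep
#'
#' Stands in for an empirical cohort: draws a true gain per subject
#' (typically-developing subjects from the lower part of the grid, subjects
#' with a mathematical learning disability from the upper part, emulating
#' the reported group means near 2.05 and 3.77), reads off the model's
#' normalized test accuracy at that gain and iteration, adds Gaussian score
#' noise, and maps scores to an achievement-like scale on which the MLD/TD
#' threshold of 90 falls between the groups. The generating gains are kept
#' in the `true_gain` column for parameter-recovery checks, and the affine
#' scale anchors are recorded as the cohort's normalization bounds so that
#' score normalization is exactly invertible.
#'
#' @param n_td,n_mld group sizes (defaults 24 and 21, a 45-subject cohort).
#' @param sweep a trained [sweep_gains()] result.
#' @param iteration evaluated iteration at which scores are generated.
#' @param noise_sd Gaussian noise SD on the normalized accuracy scale.
#' @param seed RNG seed.
#' @param td_gain_mean,mld_gain_mean,gain_sd truncated-normal gain priors.
#' @return a cohort tibble (`subject_id`, `score`, `group`, `true_gain`)
#'   with attribute `score_bounds`.
#' @export
generate_synthetic_cohort <- function(n_td = 24L, n_mld = 21L, sweep,
                                      iteration, noise_sd = 0.02, seed = 1L,
                                      td_gain_mean = 2.05,
                                      mld_gain_mean = 3.77,
                                      gain_sd = 0.55) {
  if (n_td <= 0 || n_mld <= 0) abort("group sizes must be positive")
  stopifnot(inherits(sweep, "gt_sweep"))
  cv <- sweep$curves[sweep$curves$iteration == iteration, ]
  if (nrow(cv) == 0) abort(paste0("iteration ", iteration, " not evaluated"))
  cv <- cv[order(cv$gain), ]
  b <- sweep_accuracy_bounds(sweep)
  norm_acc <- normalize_scores(cv$accuracy, b[1], b[2])
  rtruncnorm <- function(n, mean, sd, lo, hi) {
    out <- numeric(0)
    while (length(out) < n) {
      x <- rnorm(n, mean, sd)
      out <- c(out, x[x >= lo & x <= hi])
    }
    out[seq_len(n)]
  }
  withr::with_seed(as.integer(seed), {
    g_td <- rtruncnorm(n_td, td_gain_mean, gain_sd, min(cv$gain), max(cv$gain))
    g_mld <- rtruncnorm(n_mld, mld_gain_mean, gain_sd, min(cv$gain), max(cv$gain))
    snap <- function(g) cv$gain[vapply(g, function(x)
      which.min(abs(cv$gain - x)), integer(1))]
    true_gain <- c(snap(g_td), snap(g_mld))
    x <- norm_acc[match(true_gain, cv$gain)] +
      rnorm(n_td + n_mld, 0, noise_sd)
    # achievement-like scale: place the group threshold (90) midway between
    # the noiseless group boundaries; 60 achievement points per unit of
    # normalized accuracy
    x_td_min <- min(norm_acc[match(snap(g_td), cv$gain)])
    x_mld_max <- max(norm_acc[match(snap(g_mld), cv$gain)])
    midpoint <- (x_td_min + x_mld_max) / 2
    slope <- 60
    score <- 90 + slope * (x - midpoint)
    cohort <- tibble(
      subject_id = sprintf("S%03d", seq_len(n_td + n_mld)),
      score = score,
      group = ifelse(score < 90, "MLD", "TD"),
      true_gain = true_gain
    )
    attr(cohort, "score_bounds") <-
      c(90 + slope * (0 - midpoint), 90 + slope * (1 - midpoint))
    cohort
  })
}
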
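# broom-style tidiers for the package's fitted objects.

#' Tidy a gain sweep into its learning curves
#'
#' @param x a `gt_sweep`.
#' @param ... unused.
#' @return tibble with `gain`, `iteration`, `accuracy`.
#' @export
tidy.gt_sweep <- function(x, ...) as_tibble(x$curves)

#' One-row-per-gain summary of a sweep
#'
#' @param x a `gt_sweep`.
#' @param theta accuracy criterion for iterations-to-threshold.
#' @param ... unused.
#' @return tibble with `gain`, `final_accuracy`, `iterations_to_threshold`.
#' @export
glance.gt_sweep <- function(x, theta = 0.95, ...) sweep_summary(x, theta)

#' Tidy a cohort match
#'
#' @param x a `gt_match`.
#' @param ... unused.
#' @return tibble with one row per (iteration, subject).
#' @export
tidy.gt_match <- function(x, ...) as_tibble(x$table)

#' One-row summary of a cohort match
#'
#' @param x a `gt_match`.
#' @param ... unused.
#' @return tibble with the reference iteration, its mean distance, and the
#'   per-group mean matched gains there.
#' @export
glance.gt_match <- function(x, ...) {
  ref <- select_reference_iteration(x)
  at_ref <- x$table[x$table$iteration == ref, ]
  tibble(reference_iteration = ref,
         mean_distance = mean(at_ref$distance),
         mean_gain_mld = mean(at_ref$best_gain[at_ref$group == "MLD"]),
         mean_gain_td = mean(at_ref$best_gain[at_ref$group == "TD"]),
         n_subjects = nrow(at_ref))
}

#' Tidy a group comparison
#'
#' @param x a `gt_groupstats`.
#' @param ... unused.
#' @return one-row tibble with means, t, p, Cohen's d (and Pearson r when a
#'   covariate was given).
#' @export
tidy.gt_groupstats <- function(x, ...) {
  out <- tibble(mean_a = x$mean_a, mean_b = x$mean_b,
                sd_a = x$sd_a, sd_b = x$sd_b,
                n_a = x$n_a, n_b = x$n_b,
                t = x$t, p_value = x$p_value, cohens_d = x$cohens_d)
  if (!is.null(x$pearson)) {
    out$pearson_r <- x$pearson$r
    out$pearson_p <- x$pearson$p
  }
  out
}
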
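# Group statistics, remediation ("catch-up training") analysis, and the
# end-to-end experiment orchestration.

#' Welch group comparison with effect size
#'
#' Welch two-sample t-test plus Cohen's d with pooled standard deviation
#' (sign convention: group a minus group b). When a paired continuous
#' covariate is supplied, also the Pearson correlation of `values_a` with it.
#'
#' @param values_a,values_b numeric vectors (n >= 2 each).
#' @param covariate optional numeric vector paired with `values_a`.
#' @return a `gt_groupstats` object (one-row tibble via [tidy()]).
#' @export
group_compare <- function(values_a, values_b, covariate = NULL) {
  if (length(values_a) < 2 || length(values_b) < 2)
    abort("each group needs at least two values")
  va <- stats::var(values_a); vb <- stats::var(values_b)
  if (va == 0 && vb == 0) {
    if (mean(values_a) == mean(values_b)) {
      tt <- list(statistic = c(t = 0), p.value = 1)
      d <- 0
    } else {
      abort("zero variance in both groups: Cohen's d undefined")
    }
  } else {
    tt <- t.test(values_a, values_b)
    na <- length(values_a); nb <- length(values_b)
    pooled <- sqrt(((na - 1) * va + (nb - 1) * vb) / (na + nb - 2))
    d <- (mean(values_a) - mean(values_b)) / pooled
  }
  r <- NULL
  if (!is.null(covariate)) {
    ct <- cor.test(values_a, covariate)
    r <- list(r = unname(ct$estimate), p = ct$p.value)
  }
  structure(list(
    mean_a = mean(values_a), mean_b = mean(values_b),
    sd_a = sd(values_a), sd_b = sd(values_b),
    n_a = length(values_a), n_b = length(values_b),
    t = unname(tt$statistic), p_value = tt$p.value, cohens_d = d,
    pearson = r), class = "gt_groupstats")
}

#' @export
print.gt_groupstats <- function(x, ...) {
  cat(sprintf("<gt_groupstats> mean %.3f vs %.3f | t = %.2f, p = %.3g, d = %.2f\n",
              x$mean_a, x$mean_b, x$t, x$p_value, x$cohens_d))
  invisible(x)
}

#' Additional training needed to reach the typically-developing benchmark
#'
#' For each matched model of the below-threshold (MLD) group, finds the
#' evaluated iteration at or beyond the reference iteration whose test
#' accuracy is closest to the median accuracy of the TD-matched models at
#' the reference iteration (ties toward the earlier iteration).
#'
#' @param match a [match_cohort()] result.
#' @param sweep the trained [sweep_gains()] the match came from.
#' @param reference_iteration defaults to [select_reference_iteration()].
#' @return a tibble, one row per MLD subject: matched gain, target TD median
#'   accuracy, `catchup_iteration`, `additional_iterations`,
#'   `percent_additional`, and a `reached` flag (FALSE when the curve ends
#'   before approaching the target and the last iteration was used).
#' @export
extra_training_to_reference <- function(match, sweep,
                                        reference_iteration = NULL) {
  stopifnot(inherits(match, "gt_match"), inherits(sweep, "gt_sweep"))
  if (is.null(reference_iteration))
    reference_iteration <- select_reference_iteration(match)
  tab <- match$table[match$table$iteration == reference_iteration, ]
  if (nrow(tab) == 0) abort("reference iteration not present in the match")
  acc_at <- function(g, it) {
    cv <- sweep$curves
    cv$accuracy[cv$gain == g & cv$iteration == it]
  }
  td <- tab[tab$group == "TD", ]
  if (nrow(td) == 0) abort("no TD subjects at the reference iteration")
  td_median <- median(vapply(td$best_gain, acc_at, numeric(1),
                             it = reference_iteration))
  mld <- tab[tab$group == "MLD", ]
  purrr::map_dfr(seq_len(nrow(mld)), function(i) {
    g <- mld$best_gain[i]
    cv <- sweep$curves[sweep$curves$gain == g &
                         sweep$curves$iteration >= reference_iteration, ]
    cv <- cv[order(cv$iteration), ]
    best <- which.min(abs(cv$accuracy - td_median))  # first = earliest tie
    it <- cv$iteration[best]
    tibble(subject_id = mld$subject_id[i], gain = g,
           td_median_accuracy = td_median,
           catchup_iteration = it,
           additional_iterations = it - reference_iteration,
           percent_additional = 100 * (it - reference_iteration) /
             reference_iteration,
           reached = best < nrow(cv) ||
             abs(cv$accuracy[best] - td_median) <=
               abs(diff(range(cv$accuracy))) / max(1, nrow(cv) - 1))
  })
}

#' Run the full digital-twin experiment
#'
#' Orchestrates the pipeline: stimulus generation, the gain sweep, synthetic
#' (or supplied) cohort matching, behavioral / representational / manifold
#' analyses at the reference iteration, and the remediation analysis. All
#' summary tables are written as CSV under `out_dir` together with a
#' manifest (configuration and seeds) from which the run can be reproduced.
#'
#' @param config list as produced by [experiment_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with all result tables.
#' @export
run_experiment <- function(config = experiment_config(), out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      abort(paste0("stage '", name, "' failed: ", conditionMessage(e))))
  }
  save_csv <- function(x, file) {
    if (!is.null(out_dir))
      utils::write.csv(x, file.path(out_dir, file), row.names = FALSE)
  }
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  ds <- stage("stimuli", build_stimulus_dataset(
    config$variants_per_problem, seed = config$seed))
  cfg <- train_config(batch_size = config$batch_size,
                      lr = config$lr,
                      eval_every = config$eval_every,
                      max_iterations = config$max_iterations,
                      seed = config$seed)
  sweep <- stage("sweep", sweep_gains(ds, config$gains, cfg,
                                      arch_config(config$width_scale),
                                      net_seed = config$seed))
  save_csv(sweep$curves, "curves.csv")
  save_csv(sweep_summary(sweep), "sweep_summary.csv")
  cohort <- if (!is.null(config$cohort_file))
    stage("cohort", read_cohort(config$cohort_file))
  else
    stage("cohort", generate_synthetic_cohort(
      config$n_td, config$n_mld, sweep,
      iteration = config$cohort_iteration %||%
        sweep$curves$iteration[which.min(abs(
          sweep$curves$iteration - max(sweep$curves$iteration) / 2))],
      noise_sd = config$cohort_noise_sd, seed = config$seed))
  match <- stage("match", match_cohort(sweep, cohort))
  ref <- select_reference_iteration(match)
  save_csv(match$table, "match.csv")
  perm <- stage("permutation",
                permutation_control(match, sweep, config$n_perm,
                                    seed = config$seed))
  behav <- stage("behavior", sweep_behavior(sweep, ref, ds))
  save_csv(behav, "behavior.csv")
  nrs <- stage("representation", purrr::map_dfr(sweep$runs, function(r)
    network_nrs(checkpoint_network(r, ref), ds, layers = config$nrs_layers)))
  save_csv(nrs, "nrs_blocks.csv")
  geom <- stage("manifolds", purrr::map_dfr(sweep$runs, function(r)
    network_manifolds(checkpoint_network(r, ref), ds,
                      layer = config$manifold_layer,
                      n_samples = config$manifold_samples,
                      seed = config$seed)))
  save_csv(geom, "manifold_geometry.csv")
  remed <- stage("remediation", extra_training_to_reference(match, sweep, ref))
  save_csv(remed, "remediation.csv")
  manifest <- c(config, list(reference_iteration = ref,
                             package_version =
                               as.character(utils::packageVersion("gaintwin"))))
  if (!is.null(out_dir))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(list(dataset = ds, sweep = sweep, cohort = cohort, match = match,
                 reference_iteration = ref, permutation = perm,
                 behavior = behav, nrs = nrs, manifolds = geom,
                 remediation = remed, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Experiment configuration
#'
#' Defaults follow the study conditions (17-gain grid, 100 variants per
#' problem, batch 100, evaluation every 100 iterations); the `"desk"`
#' profile shrinks widths, variants and iterations so the full pipeline runs
#' on a single CPU.
#'
#' @param profile `"full"` (the full-scale study conditions) or `"desk"`
#'   (single-CPU scale).
#' @param ... overrides of individual fields.
#' @return named list of settings.
#' @export
experiment_config <- function(profile = c("full", "desk"), ...) {
  profile <- match.arg(profile)
  base <- list(
    seed = 1L, gains = gain_grid(),
    variants_per_problem = 100L, width_scale = 1,
    batch_size = 100L, lr = 1e-3, eval_every = 100L, max_iterations = 3800L,
    n_td = 24L, n_mld = 21L, cohort_noise_sd = 0.02,
    cohort_iteration = NULL, cohort_file = NULL, n_perm = 1000L,
    nrs_layers = c("V1", "V2", "V3", "IPS"), manifold_layer = "IPS",
    manifold_samples = 200L)
  if (profile == "desk") {
    base$variants_per_problem <- 20L
    base$width_scale <- 0.25
    base$batch_size <- 50L
    base$lr <- 2e-3
    base$eval_every <- 50L
    base$max_iterations <- 1000L
    base$n_perm <- 500L
  }
  utils::modifyList(base, list(...))
}
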
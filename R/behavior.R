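# Behavioral response analytics: trueness (numerical systematic error),
# precision (imprecision), and the effective number of distinct responses
# (exponential of the entropy of the emitted-response distribution).

#' Per-result response profile
#'
#' Summarises a set of responses against their expected results: for every
#' expected result level r in 0..18, the mean response, the population
#' standard deviation of the response and the item count; plus the marginal
#' distribution of emitted responses.
#'
#' @param responses integer responses in 0..18, one per item.
#' @param expected integer expected results in 0..18, same length.
#' @return a `response_profile`: list with `by_level` (tibble of `expected`,
#'   `mean_response`, `sd_response`, `n`) and `distribution` (tibble of
#'   `response`, `p`).
#' @export
response_profile <- function(responses, expected) {
  if (length(responses) != length(expected))
    abort("`responses` and `expected` must have equal length")
  if (length(responses) == 0) abort("empty response set")
  if (any(responses < 0 | responses > 18 | expected < 0 | expected > 18))
    abort("responses and expected results must lie in 0..18")
  by_level <- tibble(expected = expected, response = responses) %>%
    group_by(.data$expected) %>%
    summarise(mean_response = mean(.data$response),
              sd_response = sqrt(mean((.data$response -
                                         mean(.data$response))^2)),
              n = dplyr::n(), .groups = "drop")
  counts <- tabulate(responses + 1L, nbins = 19L)
  structure(list(by_level = by_level,
                 distribution = tibble(response = 0:18,
                                       p = counts / sum(counts))),
            class = "response_profile")
}

check_profile_levels <- function(profile) {
  missing <- setdiff(0:18, profile$by_level$expected)
  if (length(missing))
    abort(paste0("no responses observed for expected result level(s): ",
                 paste(missing, collapse = ", ")))
  invisible(profile)
}

#' Numerical systematic error (lack of trueness)
#'
#' Mean over expected-result levels of the absolute distance between the
#' level's mean response and the level itself.
#'
#' @param profile a [response_profile()].
#' @return nonnegative scalar.
#' @export
systematic_error <- function(profile) {
  stopifnot(inherits(profile, "response_profile"))
  check_profile_levels(profile)
  mean(abs(profile$by_level$mean_response - profile$by_level$expected))
}

#' Numerical imprecision (response variability)
#'
#' Mean over expected-result levels of the within-level population standard
#' deviation of the response.
#'
#' @param profile a [response_profile()].
#' @return nonnegative scalar.
#' @export
imprecision <- function(profile) {
  stopifnot(inherits(profile, "response_profile"))
  check_profile_levels(profile)
  mean(profile$by_level$sd_response)
}

#' Effective number of distinct responses
#'
#' The exponential of the (natural-log) entropy of the marginal response
#' distribution: 1 when a single response is ever used, 19 when all 19
#' answers are used uniformly.
#'
#' @param profile a [response_profile()].
#' @return scalar in \[1, 19\].
#' @export
effective_responses <- function(profile) {
  stopifnot(inherits(profile, "response_profile"))
  p <- profile$distribution$p
  p <- p[p > 0]
  exp(-sum(p * log(p)))
}

#' Behavioral metrics of a set of responses
#'
#' Convenience wrapper computing accuracy, systematic error, imprecision and
#' effective response count in one tibble row.
#'
#' @inheritParams response_profile
#' @return one-row tibble.
#' @export
behavior_metrics <- function(responses, expected) {
  prof <- response_profile(responses, expected)
  tibble(accuracy = mean(responses == expected),
         systematic_error = systematic_error(prof),
         imprecision = imprecision(prof),
         effective_responses = effective_responses(prof))
}

#' Behavioral metrics across a gain sweep
#'
#' Computes [behavior_metrics()] for every gain at one evaluated iteration
#' of a sweep (test-split responses stored during training).
#'
#' @param sweep a [sweep_gains()] result trained with `store_responses`.
#' @param iteration evaluated iteration.
#' @param dataset the stimulus dataset the sweep was trained on.
#' @return tibble with one row per gain.
#' @export
sweep_behavior <- function(sweep, iteration, dataset) {
  stopifnot(inherits(sweep, "gt_sweep"))
  key <- as.character(iteration)
  purrr::map_dfr(sweep$runs, function(r) {
    if (is.null(r$responses[[key]]))
      abort(paste0("no stored responses at iteration ", iteration))
    dplyr::bind_cols(tibble(gain = r$gain, iteration = iteration),
                     behavior_metrics(r$responses[[key]],
                                      dataset$test_meta$result))
  })
}
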
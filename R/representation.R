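# Neural representational similarity (NRS): per-layer mean activation
# pattern for each of the 380 problems, the 380 x 380 Pearson correlation
# matrix across units, block averages (add-sub, add-add, sub-sub), and the
# transform for comparing model NRS with Fisher-z values from fMRI.

#' Per-problem mean response matrix of one layer
#'
#' Averages a layer's unit activations over all test variants of each
#' problem, rows in the canonical problem order (additions before
#' subtractions, ascending result, ascending first operand).
#'
#' @param activations numeric matrix, one row per stimulus (as returned by
#'   [forward_collect()] for one layer).
#' @param meta stimulus metadata with a `problem_id` column (a stimulus
#'   dataset's `test_meta`).
#' @param n_problems number of problems in the canonical order.
#' @return matrix `n_problems x units`.
#' @export
mean_response_matrix <- function(activations, meta, n_problems = 380L) {
  stopifnot(nrow(activations) == nrow(meta))
  ids <- sort(unique(meta$problem_id))
  missing <- setdiff(seq_len(n_problems), ids)
  if (length(missing))
    abort(paste0("no test variants recorded for problem id(s): ",
                 paste(utils::head(missing, 5), collapse = ", ")))
  out <- rowsum(activations, group = meta$problem_id, reorder = TRUE)
  counts <- as.vector(table(factor(meta$problem_id,
                                   levels = seq_len(n_problems))))
  out / counts
}

#' Representational similarity matrix
#'
#' Pairwise Pearson correlation, across units, between the mean response
#' patterns of every pair of problems. Zero-variance units are dropped
#' (with a warning count); rows whose remaining pattern still has zero
#' variance yield `NA` entries.
#'
#' @param meanresp a [mean_response_matrix()].
#' @return symmetric correlation matrix with unit diagonal.
#' @export
similarity_matrix <- function(meanresp) {
  v <- apply(meanresp, 2, stats::var)
  drop <- !is.finite(v) | v == 0
  if (any(drop)) {
    if (all(drop)) abort("all units have zero variance across problems")
    warn(paste0(sum(drop), " zero-variance unit(s) dropped before NRS"))
    meanresp <- meanresp[, !drop, drop = FALSE]
  }
  rv <- apply(meanresp, 1, stats::var)
  M <- suppressWarnings(cor(t(meanresp)))
  M[rv == 0, ] <- NA_real_
  M[, rv == 0] <- NA_real_
  diag(M) <- 1
  M
}

#' Block averages of an NRS matrix
#'
#' Mean similarity between every addition-subtraction problem pair
#' (`add_sub`), and over unordered distinct pairs within each operation
#' (`add_add`, `sub_sub`; self-similarities excluded). Assumes canonical
#' problem ordering with `n_add` additions first.
#'
#' @param M a [similarity_matrix()].
#' @param n_add number of addition problems leading the ordering.
#' @return tibble with `add_sub`, `add_add`, `sub_sub`.
#' @export
block_nrs <- function(M, n_add = 190L) {
  n <- nrow(M)
  if (n_add >= n) abort("n_add must be smaller than the matrix dimension")
  ai <- seq_len(n_add); si <- (n_add + 1L):n
  off_mean <- function(B) {
    diag(B) <- NA_real_
    mean(B, na.rm = TRUE)
  }
  cross <- M[ai, si]
  n_und <- sum(is.na(cross))
  if (n_und > 0) warn(paste0(n_und, " undefined entries excluded from NRS blocks"))
  tibble(add_sub = mean(cross, na.rm = TRUE),
         add_add = off_mean(M[ai, ai]),
         sub_sub = off_mean(M[si, si]))
}

#' Layer-wise NRS blocks of a trained network
#'
#' Convenience pipeline: forward the test split, average per problem,
#' correlate, and reduce to block means for every layer.
#'
#' @param net a `gain_network`.
#' @param dataset the stimulus dataset.
#' @param layers which layers to analyse.
#' @return tibble with one row per layer: gain, layer, add_sub, add_add,
#'   sub_sub.
#' @export
network_nrs <- function(net, dataset, layers = c("V1", "V2", "V3", "IPS")) {
  fc <- forward_collect(net, dataset$test_pixels, layers = layers)
  purrr::map_dfr(layers, function(ly) {
    mr <- mean_response_matrix(fc$activations[[ly]], dataset$test_meta,
                               nrow(dataset$problems))
    dplyr::bind_cols(tibble(gain = net$gain, layer = ly),
                     block_nrs(similarity_matrix(mr),
                               sum(dataset$problems$operator == "add")))
  })
}

#' Compare model NRS with Fisher-z fMRI values
#'
#' Empirical similarity values reported on the Fisher-z scale are mapped
#' back to correlation units with the hyperbolic tangent and correlated
#' (Pearson) with the paired model values. A shuffled-pairing baseline
#' gives the null distribution of the correlation.
#'
#' @param model data frame with `subject_id` and `model_nrs` (correlation
#'   units).
#' @param fmri data frame with `subject_id` and `z_add_sub` (Fisher z).
#' @param n_shuffle number of random pairings for the baseline.
#' @param seed RNG seed for the baseline.
#' @return list with `table` (paired tibble), `r`, `p_value`, and
#'   `shuffle_r` (numeric vector of baseline correlations).
#' @export
fisher_compare <- function(model, fmri, n_shuffle = 1000L, seed = 1L) {
  if (!all(model$subject_id %in% fmri$subject_id) ||
      !all(fmri$subject_id %in% model$subject_id))
    abort("model and fMRI tables must cover the same subjects")
  tab <- left_join(as_tibble(model), as_tibble(fmri), by = "subject_id") %>%
    mutate(fmri_nrs = tanh(.data$z_add_sub))
  ct <- cor.test(tab$model_nrs, tab$fmri_nrs)
  shuffle_r <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_shuffle), function(i)
      cor(tab$model_nrs, sample(tab$fmri_nrs)), numeric(1))
  })
  list(table = tab, r = unname(ct$estimate), p_value = ct$p.value,
       shuffle_r = shuffle_r)
}
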
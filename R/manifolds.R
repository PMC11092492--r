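# Result-manifold geometry. The 380 per-problem mean activation vectors of
# a layer partition into 19 point clouds, one per numerical result (each of
# 20 problems). Capacity, radius and dimensionality follow the mean-field
# theory of linear manifold classification: for random Gaussian directions
# t, the anchor point of a manifold is the convex-hull point solving a small
# quadratic program; capacity is the inverse mean squared anchor field,
# radius and dimensionality are anchor statistics. An empirical
# random-dichotomy oracle (exact separability via a min-norm-point
# certificate) validates the estimator.

#' Group per-problem responses into result manifolds
#'
#' @param meanresp a [mean_response_matrix()] (`n_problems x units`).
#' @param problems problem table in the same canonical order.
#' @return a `manifold_set`: list of 19 point matrices (rows = problems
#'   sharing that result), names `"0"`..`"18"`.
#' @export
extract_result_manifolds <- function(meanresp, problems) {
  if (nrow(meanresp) != nrow(problems))
    abort("response matrix rows and problem table rows differ")
  sets <- lapply(setNames(0:18, as.character(0:18)), function(r)
    meanresp[problems$result == r, , drop = FALSE])
  if (any(vapply(sets, nrow, integer(1)) == 0))
    abort("every result value 0..18 needs at least one problem")
  structure(sets, class = "manifold_set")
}

#' @export
print.manifold_set <- function(x, ...) {
  cat("<manifold_set> ", length(x), " manifolds, ",
      paste(range(vapply(x, nrow, integer(1))), collapse = "-"),
      " points each, ambient dimension ", ncol(x[[1]]), "\n", sep = "")
  invisible(x)
}

# (D+1)-dimensional representation of one manifold: residual coordinates in
# its own subspace scaled by the center norm, plus a constant coordinate 1.
manifold_embedding <- function(points, global_center, tol = 1e-10) {
  m <- nrow(points)
  ctr <- colMeans(points) - global_center
  nc <- sqrt(sum(ctr^2))
  if (nc < tol) nc <- 1          # degenerate: manifold centered at origin
  resid <- sweep(points, 2, colMeans(points))
  sv <- svd(resid, nu = min(m, ncol(points)), nv = 0)
  keep <- which(sv$d > tol * max(sv$d, 1))
  coords <- if (length(keep)) sv$u[, keep, drop = FALSE] %*%
    diag(sv$d[keep], nrow = length(keep)) else
      matrix(0, m, 0)
  rbind(t(coords) / nc, rep(1, m))   # (D+1) x m
}

#' Mean-field manifold geometry
#'
#' Estimates the classification capacity, mean anchor radius, mean anchor
#' dimensionality and center correlation of a manifold set. For each
#' manifold and each of `n_samples` Gaussian directions, the anchor point on
#' the convex hull is found by a quadratic program (margin `kappa`);
#' capacity is the inverse of the mean squared anchor field, radius the
#' root-mean-square anchor norm in subspace coordinates (relative to the
#' center norm), and dimensionality the mean squared alignment between the
#' Gaussian direction and the unit anchor. Deterministic given `seed`.
#'
#' @param ms a [extract_result_manifolds()] set.
#' @param n_samples Gaussian directions per manifold.
#' @param kappa separation margin (default 0).
#' @param seed RNG seed.
#' @return a `manifold_geometry` tibble row: `capacity`, `radius`,
#'   `dimension`, `center_correlation`.
#' @export
manifold_geometry_mft <- function(ms, n_samples = 200L, kappa = 0,
                                  seed = 1L) {
  stopifnot(inherits(ms, "manifold_set"))
  if (any(vapply(ms, nrow, integer(1)) < 1)) abort("empty manifold")
  global_center <- colMeans(do.call(rbind, lapply(ms, colMeans)))
  res <- withr::with_seed(as.integer(seed), {
    purrr::map_dfr(ms, function(pts) {
      S <- manifold_embedding(pts, global_center)
      D1 <- nrow(S)
      Tm <- matrix(rnorm(D1 * n_samples), D1, n_samples)
      an <- mft_anchor_cpp(S, Tm, kappa, 4000L, 1e-10)
      A <- an$anchors
      D <- D1 - 1L
      res_norm2 <- if (D > 0)
        colSums(A[seq_len(D), , drop = FALSE]^2) else rep(0, n_samples)
      a_norm2 <- res_norm2 + A[D1, ]^2
      ok <- a_norm2 > 0
      align2 <- (colSums(A * Tm)[ok])^2 / a_norm2[ok]
      tibble(alpha_inv = mean(an$F),
             radius = sqrt(mean(res_norm2)),
             dimension = mean(align2))
    })
  })
  tibble(capacity = 1 / mean(res$alpha_inv),
         radius = mean(res$radius),
         dimension = mean(res$dimension),
         center_correlation = center_correlation(ms))
}

#' Empirical manifold capacity by random dichotomies
#'
#' Directly measures how hard the manifolds are to separate: for each
#' ambient subsample size N on a grid, draws random balanced dichotomies of
#' the P manifolds and checks exact linear separability (all points of a
#' manifold on its assigned side of a homogeneous hyperplane) via a
#' min-norm-point-in-hull certificate. Capacity is P divided by the
#' interpolated size at which half the dichotomies are separable.
#'
#' @param ms a `manifold_set`.
#' @param n_dichotomies dichotomies per grid size.
#' @param grid feature subsample sizes; defaults to a bracket around P/2.
#' @param seed RNG seed.
#' @return list with `capacity`, `crossing_n`, and `fractions` (tibble of
#'   `n_features`, `frac_separable`).
#' @export
capacity_empirical <- function(ms, n_dichotomies = 40L, grid = NULL,
                               seed = 1L) {
  stopifnot(inherits(ms, "manifold_set"))
  P <- length(ms)
  if (P < 2) abort("need at least two manifolds")
  ambient <- ncol(ms[[1]])
  if (is.null(grid)) {
    grid <- unique(pmin(ambient, pmax(2L, round(P / seq(0.5, 3, by = 0.25)))))
  }
  grid <- sort(unique(as.integer(grid)))
  if (max(grid) > ambient)
    abort("feature grid exceeds the ambient dimension")
  all_pts <- do.call(rbind, ms)
  all_pts <- sweep(all_pts, 2, colMeans(all_pts))
  mani_of <- rep(seq_len(P), vapply(ms, nrow, integer(1)))
  fractions <- withr::with_seed(as.integer(seed), {
    purrr::map_dfr(grid, function(nf) {
      sep <- vapply(seq_len(n_dichotomies), function(i) {
        feats <- sample.int(ambient, nf)
        lab <- rep(-1L, P)
        lab[sample.int(P, P %/% 2L)] <- 1L
        Z <- t(all_pts[, feats, drop = FALSE] * lab[mani_of])
        min_norm_hull_cpp(Z, 20000L, 1e-16)$separable
      }, logical(1))
      tibble(n_features = nf, frac_separable = mean(sep))
    })
  })
  f <- fractions$frac_separable
  n <- fractions$n_features
  above <- which(f >= 0.5)
  below <- which(f < 0.5)
  if (length(above) == 0 || length(below) == 0)
    abort("separability grid does not bracket the 50% crossing; widen `grid`")
  i_hi <- min(above)                 # smallest N with frac >= .5
  i_lo <- max(below[below < i_hi])
  crossing <- n[i_lo] + (0.5 - f[i_lo]) * (n[i_hi] - n[i_lo]) /
    (f[i_hi] - f[i_lo])
  list(capacity = P / crossing, crossing_n = crossing, fractions = fractions)
}

#' Alignment of manifold centers
#'
#' Mean absolute cosine similarity between manifold centroids after
#' subtracting the global centroid: 0 for mutually orthogonal centers,
#' 1 when all centers are collinear.
#'
#' @param ms a `manifold_set`.
#' @return scalar in \[0, 1\].
#' @export
center_correlation <- function(ms) {
  stopifnot(inherits(ms, "manifold_set"))
  if (length(ms) < 2) abort("need at least two manifolds")
  ctrs <- do.call(rbind, lapply(ms, colMeans))
  ctrs <- sweep(ctrs, 2, colMeans(ctrs))
  nrm <- sqrt(rowSums(ctrs^2))
  keep <- nrm > 1e-12
  if (!all(keep)) warn(paste0(sum(!keep), " zero-norm center(s) excluded"))
  ctrs <- ctrs[keep, , drop = FALSE] / nrm[keep]
  cs <- tcrossprod(ctrs)
  mean(abs(cs[upper.tri(cs)]))
}

#' Result-manifold geometry of a trained network layer
#'
#' Convenience pipeline from a network to the mean-field geometry of one
#' layer's 19 result manifolds on the test split.
#'
#' @param net a `gain_network`.
#' @param dataset the stimulus dataset.
#' @param layer layer name (default `"IPS"`).
#' @param ... passed to [manifold_geometry_mft()].
#' @return one-row tibble with gain, layer and the geometry columns.
#' @export
network_manifolds <- function(net, dataset, layer = "IPS", ...) {
  fc <- forward_collect(net, dataset$test_pixels, layers = layer)
  mr <- mean_response_matrix(fc$activations[[layer]], dataset$test_meta,
                             nrow(dataset$problems))
  ms <- extract_result_manifolds(mr, dataset$problems)
  dplyr::bind_cols(tibble(gain = net$gain, layer = layer),
                   manifold_geometry_mft(ms, ...))
}
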
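# Shared fixtures. Heavy objects are built once per test session and cached.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# tiny stimulus dataset: 2 variants/problem (380 train + 380 test images)
tiny_dataset <- function() {
  fixture("tiny_dataset", function() build_stimulus_dataset(2, seed = 42))
}

# an analytic sweep (no training): accuracy rises linearly with iteration,
# more slowly for higher gain, so that at the final iteration the gain grid
# spans most of the accuracy range with even spacing (the regime the
# behavioral matching is designed for)
analytic_sweep <- function(gains = gain_grid(), iters = seq(0, 1000, 100)) {
  curves <- purrr::map_dfr(gains, function(g) {
    frac <- (5 - g) / 4                     # 1 at G = 1, 0 at G = 5
    tibble::tibble(gain = g, iteration = iters,
                   accuracy = 0.05 + 0.93 * (iters / max(iters)) *
                     (0.1 + 0.9 * frac))
  })
  structure(list(gains = gains, curves = curves, runs = NULL,
                 cfg = list(eval_every = 100L)),
            class = "gt_sweep")
}

# deterministically trained micro-sweep used by several analysis tests
micro_arch <- function() arch_config(width_scale = 1/16)

# --- synthetic manifold sets for the geometry oracles ---

make_manifold_set <- function(points_list) {
  structure(points_list, class = "manifold_set")
}

# P point-manifolds (each cloud one repeated point) in general position
point_manifold_set <- function(P = 12, N = 40, m = 4, seed = 1) {
  withr::with_seed(seed, {
    make_manifold_set(lapply(seq_len(P), function(i) {
      ctr <- rnorm(N)
      matrix(ctr, m, N, byrow = TRUE)
    }))
  })
}

# ellipsoid-like manifolds: center + random points in a D-dim subspace
ellipsoid_manifold_set <- function(P = 10, N = 120, D = 3, radius = 0.4,
                                   m = 12, seed = 2) {
  withr::with_seed(seed, {
    make_manifold_set(lapply(seq_len(P), function(i) {
      ctr <- rnorm(N); ctr <- ctr / sqrt(sum(ctr^2))
      basis <- qr.Q(qr(matrix(rnorm(N * D), N, D)))
      coef <- matrix(rnorm(m * D), m, D)
      coef <- coef / sqrt(rowSums(coef^2))       # on the sphere
      sweep(radius * coef %*% t(basis), 2, ctr, "+")
    }))
  })
}
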
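# Gain-modulated recurrent convolutional network with four areas
# (V1, V2, V3, IPS). Each area is a recurrent block: an input convolution,
# a weight-shared recurrent convolution applied over `recurrence` time steps,
# batch normalization with permanently frozen affine parameters (scale 1,
# shift 0), and a gain-modulated rectification y = G * max(0, x). A global
# average pool over the final IPS time step feeds a 19-way linear decoder
# (answers 0..18).
#
# Internally activations live as C x (H*W*N) matrices (see src/kernels.cpp).

#' Gain-modulated rectifier
#'
#' The package's model of neural excitability: `y = G * max(0, x)`. With
#' `G = 1` this is the ordinary rectifier.
#'
#' @param x numeric vector/array.
#' @param G positive gain.
#' @return same shape as `x`.
#' @export
gain_relu <- function(x, G) {
  if (!is.numeric(G) || length(G) != 1 || G <= 0)
    abort("gain `G` must be a positive scalar")
  G * pmax(x, 0)
}

#' Network architecture configuration
#'
#' Four recurrent areas with channel widths scaled by `width_scale`.
#' `width_scale = 1` is the full-size model; `0.25` is the "desk" profile
#' used for CPU-scale runs; the test suite uses smaller scales still. All
#' qualitative gain effects are width-robust; only absolute iteration counts
#' change with scale.
#'
#' @param width_scale positive channel multiplier.
#' @param channels_base base channel widths for (V1, V2, V3, IPS).
#' @param recurrence time steps per area (>= 1).
#' @param output_classes number of decoder classes (answers), 19.
#' @return an `arch_config` object.
#' @export
arch_config <- function(width_scale = 1,
                        channels_base = c(64L, 128L, 256L, 512L),
                        recurrence = c(1L, 2L, 2L, 2L),
                        output_classes = 19L) {
  if (length(channels_base) != 4 || length(recurrence) != 4 ||
      any(recurrence < 1) || width_scale <= 0)
    abort("invalid architecture configuration")
  structure(list(
    layers = c("V1", "V2", "V3", "IPS"),
    channels = pmax(1L, as.integer(round(channels_base * width_scale))),
    recurrence = as.integer(recurrence),
    kernel = c(3L, 3L, 3L, 3L),
    stride = c(2L, 1L, 1L, 1L),
    width_scale = width_scale,
    output_classes = as.integer(output_classes)
  ), class = "arch_config")
}

# spatial dimensions after each area (conv stride then ceil-mode 2x2 pool)
arch_dims <- function(arch, H = 28L, W = 140L) {
  out <- vector("list", 4)
  for (l in 1:4) {
    k <- arch$kernel[l]; s <- arch$stride[l]; p <- k %/% 2L
    H <- (H + 2L * p - k) %/% s + 1L
    W <- (W + 2L * p - k) %/% s + 1L
    out[[l]] <- c(H = H, W = W)            # pre-pool dims (analysis units)
    H <- (H + 1L) %/% 2L; W <- (W + 1L) %/% 2L
  }
  out
}

#' Build a randomly initialized gain network
#'
#' Weights are He-initialized from `seed`; there is no pre-training. The
#' batch-normalization affine parameters are frozen at scale 1 / shift 0 and
#' never appear among the trainable parameters, so the input to every
#' rectification is standardized to mean 0 and variance 1. The same gain `G`
#' multiplies every rectification in every area and recurrence step.
#'
#' @param arch an [arch_config()].
#' @param gain positive excitability G.
#' @param seed integer seed.
#' @return a `gain_network` object.
#' @export
build_network <- function(arch = arch_config(), gain = 1, seed = 1L) {
  if (!inherits(arch, "arch_config")) abort("`arch` must be an arch_config")
  if (!is.numeric(gain) || length(gain) != 1 || gain <= 0)
    abort("`gain` must be a positive scalar")
  withr::with_seed(as.integer(seed), {
    params <- list()
    cin <- 3L
    for (l in 1:4) {
      cout <- arch$channels[l]; k <- arch$kernel[l]
      fan <- k * k * cin
      params[[paste0("Win", l)]] <-
        matrix(rnorm(cout * fan, 0, sqrt(2 / fan)), cout, fan)
      if (arch$recurrence[l] > 1) {
        fanr <- 9L * cout
        params[[paste0("Wrec", l)]] <-
          matrix(rnorm(cout * fanr, 0, sqrt(2 / fanr)), cout, fanr)
      }
      cin <- cout
    }
    dims <- arch_dims(arch)
    hw_ips <- prod((dims[[4]] + 1L) %/% 2L)   # post-pool IPS map size
    nfeat <- cin * hw_ips
    params$Wd <- matrix(rnorm(arch$output_classes * nfeat,
                              0, sqrt(1 / nfeat)), arch$output_classes, nfeat)
    params$bd <- numeric(arch$output_classes)
    # one set of running statistics per recurrence step (the steps see
    # different input distributions); affine parameters do not exist at all
    bn <- lapply(1:4, function(l)
      lapply(seq_len(arch$recurrence[l]), function(t)
        list(mean = numeric(arch$channels[l]),
             var = rep(1, arch$channels[l]))))
    structure(list(arch = arch, gain = gain, seed = as.integer(seed),
                   params = params, bn = bn, iter = 0L),
              class = "gain_network")
  })
}

#' @export
print.gain_network <- function(x, ...) {
  cat("<gain_network> G = ", x$gain, ", channels ",
      paste(x$arch$channels, collapse = "/"),
      ", recurrence ", paste(x$arch$recurrence, collapse = "/"),
      ", trained ", x$iter, " iterations\n", sep = "")
  invisible(x)
}

# images (28 x 140 x 3 x N) -> internal C x (H*W*N) matrix
pix_to_mat <- function(X) {
  d <- dim(X)
  if (length(d) == 3) { X <- array(X, c(d, 1L)); d <- dim(X) }
  if (length(d) != 4 || d[1] != 28 || d[2] != 140 || d[3] != 3)
    abort("stimulus batch must have shape 28 x 140 x 3 x N")
  m <- aperm(X, c(3, 1, 2, 4))
  dim(m) <- c(3L, 28L * 140L * d[4])
  m
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

# Full forward pass. mode "train" uses batch statistics (and returns updated
# running statistics); mode "eval" uses the stored running statistics.
# collect = TRUE also returns the final-time-step activations of every area.
# cache = TRUE retains every intermediate needed for backpropagation.
net_forward <- function(net, X, mode = c("eval", "train"),
                        collect = FALSE, cache = FALSE,
                        collect_layers = c("V1", "V2", "V3", "IPS")) {
  mode <- match.arg(mode)
  arch <- net$arch; G <- net$gain; p <- net$params
  xm <- if (is.matrix(X)) X else pix_to_mat(X)
  N <- as.integer(ncol(xm) / (28L * 140L))
  H <- 28L; W <- 140L
  x <- px_to_f(xm)
  bn <- net$bn
  caches <- if (cache) vector("list", 4) else NULL
  acts <- if (collect) vector("list", 4) else NULL
  for (l in 1:4) {
    k <- arch$kernel[l]; s <- arch$stride[l]; pd <- k %/% 2L
    Tn <- arch$recurrence[l]
    cf <- conv_fwd_f(x, p[[paste0("Win", l)]], H, W, N, k, k, s, pd, cache)
    u <- cf$y
    Ho <- (H + 2L * pd - k) %/% s + 1L
    Wo <- (W + 2L * pd - k) %/% s + 1L
    h <- NULL
    steps <- if (cache) vector("list", Tn) else NULL
    for (t in seq_len(Tn)) {
      reccols <- NULL
      if (t == 1) {
        a <- u
      } else {
        rf <- conv_fwd_f(h, p[[paste0("Wrec", l)]], Ho, Wo, N,
                         3L, 3L, 1L, 1L, cache)
        a <- add_f(u, rf$y)
        reccols <- rf$cols
      }
      if (mode == "train") {
        st <- bn_stats_f(a)
        mu <- as.vector(st$mean); v <- as.vector(st$var)
        bn[[l]][[t]]$mean <- (1 - BN_MOMENTUM) * bn[[l]][[t]]$mean +
          BN_MOMENTUM * mu
        bn[[l]][[t]]$var <- (1 - BN_MOMENTUM) * bn[[l]][[t]]$var +
          BN_MOMENTUM * v
      } else {
        mu <- bn[[l]][[t]]$mean
        v <- bn[[l]][[t]]$var
      }
      br <- bn_relu_fwd_f(a, mu, v, G, BN_EPS, cache)
      h <- br$h
      if (cache)
        steps[[t]] <- list(xhat = br$xhat, var = v, reccols = reccols)
    }
    if (collect && arch$layers[l] %in% collect_layers) {
      hm <- f_to_num(h)
      acts[[l]] <- t(`dim<-`(hm, c(length(hm) %/% N, N)))
    }
    pool <- maxpool2_fwd_f(h, Ho, Wo, N, cache)
    if (cache)
      caches[[l]] <- list(incols = cf$cols, H = H, W = W, Ho = Ho, Wo = Wo,
                          steps = steps, pool_idx = pool$idx)
    x <- pool$y
    H <- (Ho + 1L) %/% 2L; W <- (Wo + 1L) %/% 2L
  }
  # decoder reads the flattened pooled IPS map (position-sensitive readout:
  # operand order matters for subtraction)
  feat <- f_to_num(x)
  dim(feat) <- c(length(feat) %/% N, N)
  logits <- p$Wd %*% feat + p$bd
  out <- list(logits = logits, N = N)
  if (collect) {
    names(acts) <- arch$layers
    out$activations <- acts[!vapply(acts, is.null, logical(1))]
  }
  if (cache) {
    out$caches <- caches
    out$feat <- feat
    out$feat_hw <- H * W
  }
  if (mode == "train") out$bn <- bn
  out
}

#' Forward pass with layer activations
#'
#' Runs a batch of stimuli through the network in evaluation mode and
#' returns the 19-class logits, the responses (argmax class, 0..18), and the
#' final-recurrence-step activations of each area flattened per stimulus.
#'
#' @param net a [build_network()] object.
#' @param pixels stimulus array `28 x 140 x 3 x N` (or a single image).
#' @param layers which areas to collect activations for (memory control).
#' @return list with `logits` (N x 19 matrix), `responses` (integer vector,
#'   0..18) and `activations` (named list of N x units matrices for the
#'   requested layers).
#' @export
forward_collect <- function(net, pixels,
                            layers = c("V1", "V2", "V3", "IPS")) {
  stopifnot(inherits(net, "gain_network"))
  fw <- net_forward(net, pixels, mode = "eval", collect = TRUE,
                    collect_layers = layers)
  list(logits = t(fw$logits),
       responses = max.col(t(fw$logits), ties.method = "first") - 1L,
       activations = fw$activations)
}

#' The excitability grid
#'
#' `G = 1 + 0.25 k` for `k = 0..16`: 17 gain levels from 1 to 5.
#'
#' @param k integer vector of grid indices.
#' @return numeric vector of gains.
#' @export
gain_grid <- function(k = 0:16) 1 + 0.25 * k
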
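# Training: cross-entropy over the 19 answers, Adam, evaluation of the
# held-out test split at iteration 0 and on a fixed cadence. Backpropagation
# goes through the recurrence (weight-shared), the frozen-affine batch
# normalization (batch statistics), the gain rectifications, and the pools.

#' Training configuration
#'
#' @param batch_size stimuli per optimizer step.
#' @param lr Adam learning rate.
#' @param eval_every evaluate the test split every this many iterations.
#' @param max_iterations total optimizer steps.
#' @param seed seed for batch shuffling.
#' @param store_responses keep per-item test responses at each evaluation.
#' @param store_checkpoints keep a weight snapshot at each evaluation.
#' @param eval_subset optional number of test stimuli to evaluate on (a
#'   fixed seeded subsample, at least 380 recommended); `NULL` evaluates the
#'   full test split.
#' @param stop_at_accuracy optional accuracy at which training stops early
#'   (the crossing evaluation is kept); `NULL` trains to `max_iterations`.
#' @return a `train_config` list.
#' @export
train_config <- function(batch_size = 100L, lr = 1e-3, eval_every = 100L,
                         max_iterations = 3800L, seed = 1L,
                         store_responses = TRUE, store_checkpoints = TRUE,
                         eval_subset = NULL, stop_at_accuracy = NULL) {
  stopifnot(batch_size >= 1, eval_every >= 1, max_iterations >= 0)
  structure(list(batch_size = as.integer(batch_size), lr = lr,
                 eval_every = as.integer(eval_every),
                 max_iterations = as.integer(max_iterations),
                 seed = as.integer(seed),
                 store_responses = store_responses,
                 store_checkpoints = store_checkpoints,
                 eval_subset = eval_subset,
                 stop_at_accuracy = stop_at_accuracy),
            class = "train_config")
}

softmax_xent <- function(logits, y) {
  # logits: K x N; y: integer class index 1..K
  N <- ncol(logits)
  m <- apply(logits, 2, max)
  e <- exp(sweep(logits, 2, m))
  P <- sweep(e, 2, colSums(e), "/")
  idx <- cbind(y, seq_len(N))
  loss <- -mean(log(pmax(P[idx], 1e-300)))
  dP <- P
  dP[idx] <- dP[idx] - 1
  list(loss = loss, dlogits = dP / N)
}

# One forward/backward pass; returns loss and gradients for all parameters.
# Backpropagates through the pools, the weight-shared recurrence, the frozen
# batch normalization (batch statistics) and the gain rectifications, using
# the im2col matrices cached by the forward pass.
net_grad <- function(net, X, y) {
  arch <- net$arch; G <- net$gain; p <- net$params
  fw <- net_forward(net, X, mode = "train", cache = TRUE)
  sm <- softmax_xent(fw$logits, y)
  grads <- list()
  N <- fw$N
  # decoder (affine map on the flattened pooled IPS features)
  grads$Wd <- sm$dlogits %*% t(fw$feat)
  grads$bd <- rowSums(sm$dlogits)
  dfeat <- t(p$Wd) %*% sm$dlogits
  cips <- arch$channels[4]
  dim(dfeat) <- c(cips, (nrow(dfeat) %/% cips) * N)
  dx <- px_to_f(dfeat)
  for (l in 4:1) {
    cc <- fw$caches[[l]]
    k <- arch$kernel[l]; s <- arch$stride[l]; pd <- k %/% 2L
    Tn <- arch$recurrence[l]
    cin <- if (l == 1) 3L else arch$channels[l - 1L]
    dh <- maxpool2_bwd_f(dx, cc$pool_idx, cc$Ho, cc$Wo, N)
    du <- NULL
    dWrec <- if (Tn > 1) 0 else NULL
    for (t in Tn:1) {
      st <- cc$steps[[t]]
      da <- bn_relu_bwd_f(dh, st$xhat, st$var, G, BN_EPS)
      du <- if (is.null(du)) da else accum_f(du, da)
      if (t > 1) {
        bw <- conv_bwd_f(p[[paste0("Wrec", l)]], da, st$reccols,
                         arch$channels[l], cc$Ho, cc$Wo, N,
                         3L, 3L, 1L, 1L, TRUE)
        dWrec <- dWrec + bw$dW
        dh <- bw$dX
      }
    }
    if (Tn > 1) grads[[paste0("Wrec", l)]] <- dWrec
    bw <- conv_bwd_f(p[[paste0("Win", l)]], du, cc$incols,
                     cin, cc$H, cc$W, N, k, k, s, pd, l > 1)
    grads[[paste0("Win", l)]] <- bw$dW
    if (l > 1) dx <- bw$dX
  }
  list(loss = sm$loss, grads = grads, bn = fw$bn)
}

adam_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  ct1 <- 1 - b1^state$t; ct2 <- 1 - b2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / ct1) / (sqrt(state$v[[nm]] / ct2) + eps)
  }
  list(params = params, state = state)
}

#' Evaluate a network on labeled stimuli
#'
#' @param net a `gain_network`.
#' @param pixels stimulus array `28 x 140 x 3 x N`.
#' @param expected integer results (0..18) per stimulus.
#' @param batch evaluation minibatch size (memory control only).
#' @return list with `accuracy` (fraction correct) and `responses`
#'   (integer vector 0..18, argmax of the logits).
#' @export
evaluate_network <- function(net, pixels, expected, batch = 400L) {
  N <- dim(pixels)[4]
  if (is.null(N) || N == 0) abort("empty stimulus set")
  stopifnot(length(expected) == N)
  responses <- integer(N)
  for (i0 in seq(1L, N, by = batch)) {
    i1 <- min(i0 + batch - 1L, N)
    fw <- net_forward(net, pixels[, , , i0:i1, drop = FALSE], mode = "eval")
    responses[i0:i1] <- max.col(t(fw$logits), ties.method = "first") - 1L
    if ((i0 %/% batch) %% 5L == 4L) gc(verbose = FALSE, full = FALSE)
  }
  list(accuracy = mean(responses == expected), responses = responses)
}

#' Train one gain network on a stimulus dataset
#'
#' One iteration is one Adam step on one shuffled minibatch of training
#' stimuli. The held-out test split is evaluated at iteration 0 and every
#' `eval_every` iterations; weight snapshots (checkpoints) are stored at
#' each evaluation point so that representations can be re-derived at any
#' point on the learning curve.
#'
#' @param net a [build_network()] object.
#' @param dataset a [build_stimulus_dataset()] object.
#' @param cfg a [train_config()].
#' @return a `gt_run` object: `curve` (tibble of iteration and test
#'   accuracy), `responses` (evaluation x item matrix, if stored),
#'   `checkpoints` (named list of parameter snapshots), `net` (final state).
#' @export
train_model <- function(net, dataset, cfg = train_config()) {
  stopifnot(inherits(net, "gain_network"), inherits(dataset, "stim_dataset"))
  ntr <- dim(dataset$train_pixels)[4]
  if (ntr == 0) abort("empty training split")
  test_px <- dataset$test_pixels
  test_y <- dataset$test_meta$result
  if (!is.null(cfg$eval_subset) &&
      cfg$eval_subset < dim(test_px)[4]) {
    sub <- withr::with_seed(cfg$seed + 777L,
                            sort(sample.int(dim(test_px)[4],
                                            cfg$eval_subset)))
    test_px <- test_px[, , , sub, drop = FALSE]
    test_y <- test_y[sub]
  }
  state <- adam_init(net$params)
  eval_iters <- if (cfg$max_iterations >= cfg$eval_every)
    unique(c(0L, seq.int(cfg$eval_every, cfg$max_iterations,
                         by = cfg$eval_every)))
  else 0L
  curve <- numeric(0); iters <- integer(0)
  responses <- if (cfg$store_responses) list() else NULL
  checkpoints <- if (cfg$store_checkpoints) list() else NULL
  take_eval <- function(it) {
    ev <- evaluate_network(net, test_px, test_y)
    iters <<- c(iters, it); curve <<- c(curve, ev$accuracy)
    if (cfg$store_responses) responses[[as.character(it)]] <<- ev$responses
    if (cfg$store_checkpoints)
      checkpoints[[as.character(it)]] <<-
        list(params = net$params, bn = net$bn, iter = it)
    ev$accuracy
  }
  withr::with_seed(cfg$seed + net$seed, {
    take_eval(0L)
    order_pool <- sample.int(ntr)
    pos <- 1L
    it <- 0L
    while (it < cfg$max_iterations) {
      it <- it + 1L
      if (pos + cfg$batch_size - 1L > ntr) {
        order_pool <- sample.int(ntr)
        pos <- 1L
      }
      idx <- order_pool[pos:(pos + cfg$batch_size - 1L)]
      pos <- pos + cfg$batch_size
      gr <- net_grad(net, dataset$train_pixels[, , , idx, drop = FALSE],
                     dataset$train_meta$result[idx] + 1L)
      if (!is.finite(gr$loss))
        abort(paste0("non-finite loss at iteration ", it,
                     " (gain ", net$gain, ")"))
      upd <- adam_step(net$params, gr$grads, state, cfg$lr)
      net$params <- upd$params
      state <- upd$state
      net$bn <- gr$bn
      net$iter <- it
      # native float buffers are freed by finalizers; R cannot see their
      # size, so trigger minor collections regularly
      if (it %% 20L == 0L) gc(verbose = FALSE, full = FALSE)
      if (it %% cfg$eval_every == 0L) {
        acc <- take_eval(it)
        if (!is.null(cfg$stop_at_accuracy) &&
            acc >= cfg$stop_at_accuracy) break
      }
    }
  })
  structure(list(gain = net$gain,
                 curve = tibble(gain = net$gain, iteration = iters,
                                accuracy = curve),
                 responses = responses, checkpoints = checkpoints,
                 net = net, cfg = cfg),
            class = "gt_run")
}

#' First evaluated iteration reaching an accuracy threshold
#'
#' @param curve a `gt_run`, or a data frame with `iteration` and `accuracy`.
#' @param theta accuracy threshold in (0, 1].
#' @return smallest evaluated iteration with accuracy >= `theta`, or
#'   `NA_integer_` when the threshold is never reached.
#' @export
iterations_to_threshold <- function(curve, theta = 0.95) {
  if (inherits(curve, "gt_run")) curve <- curve$curve
  stopifnot(theta > 0, theta <= 1)
  hit <- curve$iteration[curve$accuracy >= theta]
  if (length(hit) == 0) NA_integer_ else as.integer(min(hit))
}

#' Train one model per excitability level
#'
#' Runs an independent training run for every gain on the identical dataset
#' and seed policy, producing one learning curve per gain.
#'
#' @param dataset a [build_stimulus_dataset()] object.
#' @param gains gain levels; defaults to the 17-level grid [gain_grid()].
#' @param cfg a [train_config()].
#' @param arch an [arch_config()].
#' @param net_seed weight-initialization seed shared by all runs.
#' @param progress print one line per finished gain.
#' @return a `gt_sweep` object: `curves` (tibble gain x iteration x
#'   accuracy), `runs` (list of `gt_run`), `gains`, `arch`, `cfg`.
#' @export
sweep_gains <- function(dataset, gains = gain_grid(), cfg = train_config(),
                        arch = arch_config(), net_seed = 1L,
                        progress = FALSE) {
  if (length(gains) == 0) abort("empty gain grid")
  runs <- vector("list", length(gains))
  for (i in seq_along(gains)) {
    net <- build_network(arch, gain = gains[i], seed = net_seed)
    runs[[i]] <- tryCatch(train_model(net, dataset, cfg),
      error = function(e)
        abort(paste0("training failed for gain ", gains[i], ": ",
                     conditionMessage(e))))
    if (progress)
      message(sprintf("gain %.2f done (final acc %.3f)", gains[i],
                      utils::tail(runs[[i]]$curve$accuracy, 1)))
  }
  names(runs) <- as.character(gains)
  structure(list(gains = gains,
                 curves = bind_rows(lapply(runs, `[[`, "curve")),
                 runs = runs, arch = arch, cfg = cfg,
                 dataset_seed = dataset$seed),
            class = "gt_sweep")
}

#' @export
print.gt_sweep <- function(x, ...) {
  cat("<gt_sweep> ", length(x$gains), " gains (",
      min(x$gains), "-", max(x$gains), "), ",
      max(x$curves$iteration), " iterations, eval every ",
      x$cfg$eval_every, "\n", sep = "")
  invisible(x)
}

#' Summary table of a gain sweep
#'
#' @param x a `gt_sweep`.
#' @param theta accuracy threshold for iterations-to-criterion.
#' @return tibble with one row per gain: final accuracy, iterations to
#'   threshold (NA when not reached).
#' @export
sweep_summary <- function(x, theta = 0.95) {
  stopifnot(inherits(x, "gt_sweep"))
  purrr::map_dfr(x$runs, function(r)
    tibble(gain = r$gain,
           final_accuracy = utils::tail(r$curve$accuracy, 1),
           iterations_to_threshold =
             iterations_to_threshold(r, theta)))
}

# restore a checkpointed state of a run's network
checkpoint_network <- function(run, iteration) {
  key <- as.character(iteration)
  if (is.null(run$checkpoints[[key]]))
    abort(paste0("no checkpoint at iteration ", iteration))
  net <- run$net
  net$params <- run$checkpoints[[key]]$params
  net$bn <- run$checkpoints[[key]]$bn
  net$iter <- as.integer(iteration)
  net
}
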
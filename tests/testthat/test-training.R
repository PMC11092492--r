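test_that("evaluation computes argmax responses and order-invariant accuracy", {
  ds <- tiny_dataset()
  net <- build_network(micro_arch(), 1, seed = 5)
  ev <- evaluate_network(net, ds$test_pixels[, , , 1:60, drop = FALSE],
                         ds$test_meta$result[1:60])
  expect_length(ev$responses, 60)
  expect_equal(ev$accuracy, mean(ev$responses == ds$test_meta$result[1:60]))
  ord <- sample(60)
  ev2 <- evaluate_network(net, ds$test_pixels[, , , ord, drop = FALSE],
                          ds$test_meta$result[ord])
  expect_equal(ev2$accuracy, ev$accuracy)
  expect_equal(ev2$responses, ev$responses[ord])
  expect_error(evaluate_network(net, ds$test_pixels[, , , integer(0),
                                                    drop = FALSE],
                                integer(0)), "empty")
})

test_that("degenerate runs produce a single evaluation at iteration 0", {
  ds <- tiny_dataset()
  net <- build_network(micro_arch(), 1, seed = 1)
  run <- train_model(net, ds, train_config(max_iterations = 0, seed = 1))
  expect_equal(run$curve$iteration, 0L)
  expect_gte(run$curve$accuracy, 0.02)
  expect_lte(run$curve$accuracy, 0.09)
})

test_that("training is reproducible and checkpoints restore stored accuracy", {
  ds <- tiny_dataset()
  cfg <- train_config(batch_size = 20, eval_every = 3, max_iterations = 6,
                      seed = 7)
  r1 <- train_model(build_network(micro_arch(), 1.5, seed = 2), ds, cfg)
  r2 <- train_model(build_network(micro_arch(), 1.5, seed = 2), ds, cfg)
  expect_identical(r1$curve, r2$curve)
  expect_identical(r1$net$params, r2$net$params)
  # every checkpoint reproduces its stored accuracy exactly
  for (key in names(r1$checkpoints)) {
    net <- gaintwin:::checkpoint_network(r1, as.integer(key))
    ev <- evaluate_network(net, ds$test_pixels, ds$test_meta$result)
    expect_equal(ev$accuracy,
                 r1$curve$accuracy[r1$curve$iteration == as.integer(key)])
  }
})

test_that("iterations to threshold finds the first crossing", {
  curve <- tibble::tibble(iteration = c(0L, 100L),
                          accuracy = c(0.05, 0.96))
  expect_equal(iterations_to_threshold(curve, 0.95), 100L)
  never <- tibble::tibble(iteration = c(0L, 100L), accuracy = c(0.1, 0.5))
  expect_true(is.na(iterations_to_threshold(never, 0.95)))
  # appending later evaluations cannot change the answer
  longer <- dplyr::bind_rows(curve,
                             tibble::tibble(iteration = 200L, accuracy = 0.99))
  expect_equal(iterations_to_threshold(longer, 0.95), 100L)
  expect_error(iterations_to_threshold(curve, 0), "theta > 0")
})

test_that("gain sweeps run one model per gain over a shared dataset", {
  ds <- tiny_dataset()
  cfg <- train_config(batch_size = 20, eval_every = 4, max_iterations = 4,
                      seed = 3)
  sw <- sweep_gains(ds, gains = c(1, 3), cfg, micro_arch())
  expect_s3_class(sw, "gt_sweep")
  expect_equal(unique(sw$curves$gain), c(1, 3))
  expect_equal(nrow(sw$curves), 4)          # 2 gains x 2 evaluations
  expect_true(all(sw$curves$accuracy >= 0 & sw$curves$accuracy <= 1))
  sm <- sweep_summary(sw)
  expect_equal(nrow(sm), 2)
  expect_error(sweep_gains(ds, gains = numeric(0), cfg), "empty")
  expect_equal(nrow(tidy(sw)), 4)
  expect_equal(nrow(glance(sw)), 2)
})

test_that("softmax cross-entropy matches a direct computation", {
  set.seed(1)
  logits <- matrix(rnorm(19 * 7), 19, 7)
  y <- sample(19, 7, replace = TRUE)
  sm <- gaintwin:::softmax_xent(logits, y)
  p <- apply(logits, 2, function(l) exp(l - max(l)) / sum(exp(l - max(l))))
  expect_equal(sm$loss, -mean(log(p[cbind(y, 1:7)])))
  # gradient sums to zero per item and matches finite differences
  expect_equal(colSums(sm$dlogits), rep(0, 7), tolerance = 1e-12)
  eps <- 1e-6
  l2 <- logits; l2[3, 2] <- l2[3, 2] + eps
  num <- (gaintwin:::softmax_xent(l2, y)$loss - sm$loss) / eps
  expect_equal(sm$dlogits[3, 2], num, tolerance = 1e-4)
})
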
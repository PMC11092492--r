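test_that("gain rectification follows y = G * max(0, x)", {
  expect_equal(gain_relu(-2, 1), 0)
  expect_equal(gain_relu(2, 3), 6)
  x <- rnorm(100)
  expect_equal(gain_relu(x, 1), pmax(x, 0))     # G = 1 is the plain rectifier
  expect_equal(gain_relu(x, 2.5), 2.5 * pmax(x, 0))
  expect_error(gain_relu(1, 0), "positive")
  expect_error(gain_relu(1, -1), "positive")
})

test_that("the excitability grid spans 1..5 in 17 steps", {
  g <- gain_grid()
  expect_length(g, 17)
  expect_equal(g[1], 1)
  expect_equal(g[17], 5)
  expect_equal(gain_grid(6), 2.5)
  expect_equal(diff(g), rep(0.25, 16))
})

test_that("network construction is seeded and validates inputs", {
  arch <- micro_arch()
  n1 <- build_network(arch, 2, seed = 3)
  n2 <- build_network(arch, 2, seed = 3)
  expect_identical(n1$params, n2$params)
  n3 <- build_network(arch, 2, seed = 4)
  expect_false(identical(n1$params, n3$params))
  expect_error(build_network(arch, gain = 0), "positive")
  expect_error(build_network(list(), 1), "arch_config")
  expect_error(arch_config(width_scale = -1), "invalid")
  # 19-way decoder
  expect_equal(nrow(n1$params$Wd), 19)
})

test_that("forward pass returns nonnegative activations and valid responses", {
  ds <- tiny_dataset()
  net <- build_network(micro_arch(), 1.5, seed = 1)
  px <- ds$test_pixels[, , , 1:25, drop = FALSE]
  fc <- forward_collect(net, px)
  expect_equal(dim(fc$logits), c(25, 19))
  expect_true(all(fc$responses >= 0 & fc$responses <= 18))
  expect_named(fc$activations, c("V1", "V2", "V3", "IPS"))
  for (a in fc$activations) {
    expect_equal(nrow(a), 25)
    expect_true(all(a >= 0))
  }
  # deterministic given weights and inputs
  fc2 <- forward_collect(net, px)
  expect_identical(fc$logits, fc2$logits)
  expect_error(forward_collect(net, array(0, c(28, 100, 3, 2))), "shape")
})

test_that("gain scales activations of a single rectification stage", {
  x <- matrix(rnorm(100), 10)
  expect_equal(gain_relu(x, 2), 2 * gain_relu(x, 1))
  # in the network, doubling G doubles the first layer's rectified output
  # for the same standardized input
  z <- rnorm(50)
  expect_equal(gain_relu(z, 4) / 2, gain_relu(z, 2))
})

test_that("normalization parameters stay frozen through training", {
  ds <- tiny_dataset()
  net <- build_network(micro_arch(), 2, seed = 2)
  cfg <- train_config(batch_size = 20, eval_every = 5, max_iterations = 5,
                      seed = 1, store_checkpoints = FALSE,
                      store_responses = FALSE)
  run <- train_model(net, ds, cfg)
  # there are no affine normalization parameters among the trainables at all
  expect_false(any(grepl("bn|gamma|beta|scale|shift",
                         names(run$net$params))))
  # the set of trainable parameter names is unchanged by training
  expect_identical(names(run$net$params), names(net$params))
  # batch-norm running statistics exist (one set per recurrence step) but
  # carry no affine transform
  expect_named(run$net$bn[[1]][[1]], c("mean", "var"))
})

test_that("untrained networks respond near chance on a balanced test set", {
  ds <- tiny_dataset()
  accs <- vapply(c(1, 2.5, 5), function(G) {
    net <- build_network(micro_arch(), G, seed = 11)
    evaluate_network(net, ds$test_pixels, ds$test_meta$result)$accuracy
  }, numeric(1))
  expect_true(all(accs >= 0.02 & accs <= 0.09))
})
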
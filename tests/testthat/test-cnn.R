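# Shallow 1D-kernel CNN.

test_that("dimension chain at defaults: 93x32 -> 30x30 -> 30x3 -> 90 -> 2", {
  model <- cnn_init(cnn_config(), c(93L, 32L))
  expect_equal(model$conv_len, 30L)
  expect_equal(model$pooled_len, 3L)
  expect_equal(dim(model$conv_w), c(93L * 3L, 30L))
  expect_equal(dim(model$fc_w), c(90L, 2L))
  img <- matrix(runif(93 * 32), 93, 32)
  maps <- conv_forward(img, model)
  expect_equal(dim(maps), c(30L, 30L))
  pooled <- maxpool(maps, 10)
  expect_equal(dim(pooled), c(30L, 3L))
  p <- cnn_forward(img, model)
  expect_equal(length(p), 2L)
  expect_equal(sum(p), 1)
})

test_that("convolution is a valid correlation with bias and ReLU", {
  model <- cnn_init(cnn_config(n_kernels = 2, pool_factor = 2), c(4L, 8L))
  model$conv_w[] <- 0
  model$conv_b[] <- 0
  img <- matrix(rnorm(32), 4, 8)
  expect_true(all(conv_forward(img, model) == 0))
  # a kernel equal to an isolated image patch peaks at the patch position
  img2 <- matrix(0, 4, 8)
  patch <- matrix(abs(rnorm(12)) + 0.5, 4, 3)
  pos <- 5L
  img2[, pos:(pos + 2)] <- patch
  model$conv_w[, 1] <- as.vector(patch)
  maps <- conv_forward(img2, model)
  expect_equal(which.max(maps[1, ]), pos)
  expect_equal(max(maps[1, ]), sum(patch^2))
  # negative bias is clipped by ReLU
  model$conv_w[] <- 0
  model$conv_b[] <- -1
  expect_true(all(conv_forward(img2, model) == 0))
  expect_error(conv_forward(matrix(0, 5, 8), model), "height")
})

test_that("ReLU and max-pooling behave as defined", {
  expect_equal(relu(c(-2, 0, 3)), c(0, 0, 3))
  expect_equal(as.vector(maxpool(matrix(1:30, 1), 10)), c(10, 20, 30))
  expect_equal(as.vector(maxpool(matrix(7, 2, 20), 10)), rep(7, 4))
  # the trailing remainder is discarded, not padded
  expect_equal(ncol(maxpool(matrix(1:35, 1, 35), 10)), 3L)
  expect_error(maxpool(matrix(1:5, 1), 10), "shorter")
})

test_that("softmax outputs are calibrated at the degenerate corners", {
  model <- cnn_init(cnn_config(n_kernels = 2, pool_factor = 2), c(4L, 8L))
  model$conv_w[] <- 0; model$conv_b[] <- 0
  model$fc_w[] <- 0; model$fc_b[] <- 0
  img <- matrix(runif(32), 4, 8)
  expect_equal(unname(cnn_forward(img, model)), c(0.5, 0.5))
  model$fc_b <- c(200, -200)
  expect_equal(unname(cnn_forward(img, model)), c(1, 0), tolerance = 1e-12)
})

test_that("analytic gradients match central finite differences", {
  cfg <- cnn_config(n_kernels = 3, kernel_time_width = 3, pool_factor = 2,
                    batch_size = 4, epochs = 1, seed = 2)
  set.seed(5)
  imgs <- lapply(1:4, function(i) matrix(runif(54), 6, 9))
  y <- c(1L, 2L, 1L, 2L)
  model <- cnn_init(cfg, c(6L, 9L))
  Zcat <- do.call(cbind, lapply(imgs, micwt:::im2col, kw = 3L))
  analytic <- micwt:::cnn_loss_grad(model, Zcat, y)$grads
  for (nm in c("conv_w", "conv_b", "fc_w", "fc_b"))
    expect_lt(max_rel_err(numeric_grad(model, Zcat, y, nm), analytic[[nm]]),
              1e-4)
})

test_that("training separates linearly separable data and shrinks the loss", {
  imgs <- toy_images(20, seed = 1)
  cfg <- cnn_config(n_kernels = 4, pool_factor = 4, batch_size = 10,
                    epochs = 60, learning_rate = 0.05, seed = 3)
  model <- cnn_train(imgs, config = cfg)
  expect_length(model$loss_history, 60L)
  expect_lt(mean(tail(model$loss_history, 10)),
            mean(head(model$loss_history, 10)))
  pred <- predict(model, imgs)
  expect_equal(mean(pred$labels == vapply(imgs, `[[`, "", "label")), 1)
})

test_that("training is deterministic under a fixed seed", {
  imgs <- toy_images(12, seed = 2)
  cfg <- cnn_config(n_kernels = 3, pool_factor = 4, batch_size = 6,
                    epochs = 15, seed = 9)
  m1 <- cnn_train(imgs, config = cfg)
  m2 <- cnn_train(imgs, config = cfg)
  expect_identical(m1$loss_history, m2$loss_history)
  expect_identical(m1$conv_w, m2$conv_w)
})

test_that("kernel order permutation leaves the network function unchanged", {
  model <- cnn_init(cnn_config(n_kernels = 5, pool_factor = 3, seed = 4),
                    c(8L, 15L))
  img <- matrix(runif(120), 8, 15)
  set.seed(6)
  perm <- sample(5L)
  model2 <- model
  model2$conv_w <- model$conv_w[, perm]
  model2$conv_b <- model$conv_b[perm]
  P <- model$pooled_len
  idx <- as.vector(sapply(0:(P - 1L), function(k) perm + 5L * k))
  model2$fc_w <- model$fc_w[idx, ]
  expect_equal(conv_forward(img, model2), conv_forward(img, model)[perm, ])
  expect_equal(cnn_forward(img, model2), cnn_forward(img, model))
})

test_that("prediction is consistent with the forward pass and tie-breaks to class 1", {
  imgs <- toy_images(6, seed = 3)
  cfg <- cnn_config(n_kernels = 3, pool_factor = 4, batch_size = 3,
                    epochs = 30, seed = 1)
  model <- cnn_train(imgs, config = cfg)
  pred <- predict(model, imgs)
  expect_equal(pred$probabilities[2, ], cnn_forward(imgs[[2]], model))
  # symmetric all-zero model: equal logits, first class wins the tie
  z <- cnn_init(cnn_config(n_kernels = 3, pool_factor = 4), c(12L, 16L))
  z$conv_w[] <- 0; z$conv_b[] <- 0; z$fc_w[] <- 0; z$fc_b[] <- 0
  predz <- predict(z, imgs)
  expect_true(all(predz$labels == z$classes[1]))
})

test_that("degenerate training inputs are rejected", {
  imgs <- toy_images(4, seed = 4)
  one_class <- lapply(imgs, function(im) { im$label <- "left"; im })
  expect_error(cnn_train(one_class, config = cnn_config()), "2 classes")
  expect_error(cnn_train(imgs[1], config = cnn_config()), "at least 2")
  expect_error(cnn_init(cnn_config(pool_factor = 100), c(12L, 16L)), "pool_factor")
})
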
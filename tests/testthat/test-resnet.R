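small_cfg <- function(n_classes = 3L, seed = 1L, size = 16L,
                      filters = c(4L, 4L, 6L, 6L, 8L), ...) {
  resnet_config(n_classes = n_classes, input_size = c(size, size, 1L),
                filters = filters, seed = seed, ...)
}

test_that("the architecture audit counts exactly 12 weight layers", {
  net <- build_resnet12(resnet_config(seed = 1))
  audit <- net$layer_audit
  expect_equal(sum(audit$counted), 12L)
  expect_equal(sum(!audit$counted), 2L)  # the two projection shortcuts
  expect_equal(sum(audit$kind == "dense"), 1L)
})

test_that("parameter count matches an independent per-layer tally", {
  net <- build_resnet12(resnet_config(n_classes = 5, seed = 2))
  f <- c(16, 16, 32, 32, 64)
  conv <- function(k, cin, cout) k * k * cin * cout + cout
  bn <- function(c) 2 * c
  expected <-
    conv(3, 1, f[1]) + bn(f[1]) +                          # stem
    conv(3, f[1], f[2]) + bn(f[2]) + conv(3, f[2], f[2]) + bn(f[2]) +
    conv(3, f[2], f[3]) + bn(f[3]) + conv(3, f[3], f[3]) + bn(f[3]) +
    conv(1, f[2], f[3]) + bn(f[3]) +                       # proj 1
    conv(3, f[3], f[4]) + bn(f[4]) + conv(3, f[4], f[4]) + bn(f[4]) +
    conv(3, f[4], f[5]) + bn(f[5]) + conv(3, f[5], f[5]) + bn(f[5]) +
    conv(1, f[4], f[5]) + bn(f[5]) +                       # proj 2
    conv(3, f[5], f[5]) + bn(f[5]) + conv(3, f[5], f[5]) + bn(f[5]) +
    f[5] * 5 + 5                                           # dense head
  expect_equal(count_parameters(net), expected)
})

test_that("softmax outputs are probability vectors, even on a zero image", {
  net <- build_resnet12(small_cfg(n_classes = 4, seed = 3))
  imgs <- array(0, c(16, 16, 1, 2))
  imgs[, , 1, 2] <- matrix(runif(256), 16, 16)
  p <- predict_resnet(net, imgs)
  expect_equal(dim(p), c(2L, 4L))
  expect_equal(rowSums(p), c(1, 1), tolerance = 1e-6)
  expect_true(all(p >= 0))
})

test_that("an identity block with zeroed convolutions passes ReLU(x) through", {
  net <- build_resnet12(small_cfg(seed = 4))
  for (id in c("block1.conv1", "block1.conv2")) {
    p <- get(id, envir = net$params)
    p$W[] <- 0; p$b[] <- 0
    assign(id, p, envir = net$params)
  }
  blk <- net$arch$mods[[5]]  # block1, the first identity block
  set.seed(5)
  A <- matrix(rnorm(4 * 4 * 3 * 4), 4 * 4 * 3, 4)  # H=4, W=4, N=3, C=4
  act <- fcbtrace:::act_spatial(A, 4L, 4L, 4L, 3L)
  out <- fcbtrace:::forward_module(blk, act, net, training = TRUE)$act$A
  expect_equal(out, pmax(A, 0), tolerance = 1e-12)
})

test_that("inputs below the downsampling factor are rejected", {
  expect_error(resnet_config(input_size = c(8, 8, 1)), "downsampling")
  net <- build_resnet12(small_cfg(seed = 6))
  expect_error(predict_resnet(net, array(0, c(20, 20, 1, 1))),
               "does not match")
})

test_that("two images from two classes are memorized", {
  net <- build_resnet12(small_cfg(n_classes = 2, seed = 7))
  set.seed(8)
  imgs <- array(0, c(16, 16, 1, 2))
  imgs[, , 1, 1] <- matrix(runif(256), 16, 16)
  imgs[, , 1, 2] <- matrix(runif(256), 16, 16)
  lab <- factor(c("x", "y"))
  fit <- train_resnet(net, imgs, lab, epochs = 60, batch_size = 2,
                      seed = 8, stop_at_perfect = FALSE)
  expect_equal(tail(fit$curves$train_acc, 1), 1)
  conf <- evaluate_resnet(fit$net, imgs, lab)
  expect_equal(diag(conf), c(x = 1L, y = 1L))
})

test_that("training curves have one row per epoch and finite losses", {
  net <- build_resnet12(small_cfg(n_classes = 2, seed = 9))
  set.seed(9)
  imgs <- array(runif(16 * 16 * 4), c(16, 16, 1, 4))
  lab <- factor(rep(c("x", "y"), 2))
  fit <- train_resnet(net, imgs, lab, test_images = imgs, test_labels = lab,
                      epochs = 5, batch_size = 2, seed = 9,
                      stop_at_perfect = FALSE)
  expect_equal(nrow(fit$curves), 5L)
  expect_true(all(is.finite(fit$curves$train_loss)))
  expect_true(all(is.finite(fit$curves$test_loss)))
})

test_that("fixed seeds reproduce identical training trajectories", {
  run <- function() {
    net <- build_resnet12(small_cfg(n_classes = 2, seed = 11))
    set.seed(12)
    imgs <- array(runif(16 * 16 * 6), c(16, 16, 1, 6))
    train_resnet(net, imgs, factor(rep(c("x", "y"), 3)), epochs = 3,
                 batch_size = 2, seed = 13, stop_at_perfect = FALSE)$curves
  }
  expect_identical(run(), run())
})

test_that("test accuracy rises with class effect size (multi-seed median)", {
  acc_at <- function(effect, seeds) {
    vapply(seeds, function(sd) {
      gen <- generator_config(effect_size = effect, seed = sd)
      rep <- run_traceability(traceability_config(
        generator = gen, image_size = 32L, split_seed = sd,
        resnet = resnet_config(input_size = c(32L, 32L, 1L), seed = sd,
                               epochs = 15L)))
      rep$best_test_acc
    }, numeric(1))
  }
  seeds <- 1:3
  weak <- median(acc_at(0.05, seeds))
  strong <- median(acc_at(1, seeds))
  expect_gte(strong, weak)
  expect_gt(strong, 0.6)
})

test_that("confusion metrics match the per-sample tally oracle", {
  set.seed(15)
  for (i in 1:5) {
    conf <- matrix(rpois(25, 3), 5, 5)
    m <- confusion_metrics(conf)
    o <- oracle_metrics(conf)
    expect_equal(m$accuracy, o$accuracy)
    expect_equal(m$per_class$precision, o$precision)
    expect_equal(m$per_class$sensitivity, o$sensitivity)
    expect_equal(m$per_class$specificity, o$specificity)
    expect_equal(sum(m$per_class$tp), sum(diag(conf)))
  }
})

test_that("accuracy is invariant under class relabeling of the confusion", {
  set.seed(16)
  conf <- matrix(rpois(25, 4), 5, 5)
  perm <- sample(5)
  expect_equal(confusion_metrics(conf[perm, perm])$accuracy,
               confusion_metrics(conf)$accuracy)
})

test_that("perfect and pathological confusions give the right flags", {
  perfect <- diag(4L)
  m <- confusion_metrics(perfect)
  expect_equal(m$accuracy, 1)
  expect_equal(m$per_class$precision, rep(1, 4))
  expect_equal(m$macro, c(precision = 1, sensitivity = 1, specificity = 1))
  # a never-predicted class has 0/0 precision: NaN + flag, not an error
  conf <- rbind(c(2, 0), c(1, 0))
  m2 <- confusion_metrics(conf)
  expect_true(is.nan(m2$per_class$precision[2]))
  expect_true(m2$undefined[2, "precision"])
  expect_error(confusion_metrics(matrix(0, 2, 2)), "empty")
})

test_that("the reported external-validation confusion scores 86.667%", {
  m <- confusion_metrics(fixture_confusion())
  expect_equal(m$accuracy, 13 / 15)
  expect_equal(round(100 * m$accuracy, 3), 86.667)
})

test_that("curve smoothing follows the exponential recurrence", {
  expect_equal(smooth_curve(c(0, 1), alpha = 0.6), c(0, 0.4))
  expect_equal(smooth_curve(rep(0.7, 5), alpha = 0.6), rep(0.7, 5))
  v <- c(0.2, 0.9, 0.4, 0.6)
  expect_equal(smooth_curve(v, alpha = 0), v)
  s <- smooth_curve(v, alpha = 0.6)
  expect_equal(s[3], 0.6 * s[2] + 0.4 * v[3])
  expect_true(all(s >= min(v) & s <= max(v)))
  expect_error(smooth_curve(v, alpha = 1), "alpha")
})
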
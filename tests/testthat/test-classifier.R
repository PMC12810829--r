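# CNN architecture arithmetic, training behaviour, masked evaluation and the
# template surrogate.

test_that("layer shape arithmetic matches the reference architecture", {
  full <- cnn_spec(input_shape = c(80L, 80L, 80L))
  expect_equal(attr(model_shapes(full), "flat_length"), 32000L)
  desk <- cnn_spec(input_shape = c(24L, 24L, 24L))
  expect_equal(attr(model_shapes(desk), "flat_length"), 3 * 3 * 3 * 32)
  expect_error(cnn_spec(input_shape = c(10L, 10L, 10L)), "divisible")
})

test_that("forward pass produces a valid softmax and mirrored class symmetry", {
  m <- build_model(cnn_spec(input_shape = c(8L, 8L, 8L)), seed = 2)
  clf <- structure(list(model = m), class = "cnn_classifier")
  set.seed(1)
  vols <- replicate(3, array(rnorm(8^3), dim = c(8, 8, 8)), simplify = FALSE)
  pr <- predict(clf, vols, type = "prob")
  expect_true(all(pr >= 0))
  expect_equal(rowSums(pr), rep(1, 3), tolerance = 1e-6)

  # swapping the output units swaps the class probabilities exactly
  m2 <- m
  m2$params$W2 <- m$params$W2[, 2:1]
  m2$params$b2 <- m$params$b2[2:1]
  clf2 <- structure(list(model = m2), class = "cnn_classifier")
  pr2 <- predict(clf2, vols, type = "prob")
  expect_equal(pr2, pr[, 2:1], tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("backpropagated gradients match finite differences", {
  m <- build_model(cnn_spec(input_shape = c(8L, 8L, 8L), fc_width = 32L), seed = 5)
  set.seed(5)
  x <- array(rnorm(8^3), dim = c(8, 8, 8))
  fwd <- gashap:::cnn_forward(m, x, keep_cache = TRUE)
  pr <- gashap:::softmax(fwd$logits)
  dlog <- pr
  dlog[1] <- dlog[1] - 1
  g <- gashap:::cnn_backward(m, fwd, dlog, want_input_grad = TRUE)
  loss <- function(mm, xx) -log(gashap:::softmax(gashap:::cnn_forward(mm, xx)$logits)[1])
  eps <- 1e-5
  for (nm in c("Wc1", "Wc3", "W1", "b2")) {
    i <- min(7L, length(m$params[[nm]]))
    mp <- m; mp$params[[nm]][i] <- mp$params[[nm]][i] + eps
    mn <- m; mn$params[[nm]][i] <- mn$params[[nm]][i] - eps
    num <- (loss(mp, x) - loss(mn, x)) / (2 * eps)
    expect_equal(g[[nm]][i], num, tolerance = 1e-5)
  }
  i <- 137L
  xp <- x; xp[i] <- xp[i] + eps
  xn <- x; xn[i] <- xn[i] - eps
  expect_equal(g$input[i], (loss(m, xp) - loss(m, xn)) / (2 * eps), tolerance = 1e-5)
})

test_that("training learns a separable cohort and is seed-deterministic", {
  tc <- tiny_cohort(shape = c(8L, 8L, 8L), R = 5L, signal = 1:2, effect = 3,
                    n = 10L, seed = 7L)
  spec <- cnn_spec(input_shape = c(8L, 8L, 8L),
                   conv_blocks = list(c(3L, 4L), c(3L, 8L), c(3L, 8L)),
                   fc_width = 64L, dropout_keep = 1)
  cfg <- train_config(max_epochs = 60L, batch_size = 8L, seed = 21L)
  clf <- train_cnn(build_model(spec, seed = 21L), tc$cohort, cfg)
  expect_lte(nrow(clf$history), 60L)
  ev <- dataset_split(tc$cohort, c("val", "test"))
  acc <- mean(predict(clf, ev$volumes, type = "class") == ev$classes)
  expect_gte(acc, 0.75)

  clf2 <- train_cnn(build_model(spec, seed = 21L), tc$cohort, cfg)
  expect_identical(clf$history, clf2$history)
  expect_equal(clf$model$params$W2, clf2$model$params$W2)
})

test_that("near-null effect yields chance-level accuracy", {
  sp <- synthetic_spec(shape = c(8L, 8L, 8L), R = 5L, signal_regions = 1:2,
                       effect_size = 1e-6, n_per_class = 20L, seed = 31L)
  atlas <- generate_atlas(sp)
  ds <- generate_cohort(atlas, sp)
  tcl <- template_classifier(ds)
  ev <- dataset_split(ds, c("val", "test"))
  acc <- mean(predict(tcl, ev$volumes, type = "class") == ev$classes)
  # 12 evaluation samples: the 95% binomial band around 0.5 is wide
  expect_gte(acc, 0.5 - 1.96 * sqrt(0.25 / length(ev$classes)) - 1e-9)
  expect_lte(acc, 0.5 + 1.96 * sqrt(0.25 / length(ev$classes)) + 1e-9)
})

test_that("early stopping halts after `patience` non-improving epochs", {
  tc <- tiny_cohort(shape = c(8L, 8L, 8L), R = 4L, n = 3L, seed = 2L)
  spec <- cnn_spec(input_shape = c(8L, 8L, 8L),
                   conv_blocks = list(c(3L, 2L), c(3L, 2L), c(3L, 2L)),
                   fc_width = 8L)
  clf <- train_cnn(build_model(spec, seed = 1L), tc$cohort,
                   train_config(max_epochs = 50L, patience = 1L, seed = 1L),
                   eval_override = function(model, epoch) list(loss = 1, acc = 0.5))
  expect_equal(nrow(clf$history), 2L)
})

test_that("masked accuracy follows the confusion-count definition", {
  cc <- gashap:::confusion(pred = c(1, 1, 1, 1, 0, 0, 0, 0),
                           truth = c(1, 1, 1, 0, 0, 0, 1, 1))
  expect_identical(as.integer(cc$counts), c(3L, 1L, 2L, 2L))
  expect_equal(cc$f1, 5 / 8)

  tc <- tiny_cohort(shape = c(8L, 8L, 8L), R = 4L, effect = 3, n = 6L, seed = 9L)
  tcl <- template_classifier(tc$cohort)
  tr <- dataset_split(tc$cohort, "train")
  ones <- array(1L, dim = c(8, 8, 8))
  plain <- mean(predict(tcl, tr$volumes, type = "class") == tr$classes)
  masked <- masked_accuracy(tcl, tr$volumes, tr$classes, ones)
  expect_equal(masked$f1, plain)                       # identity mask
  expect_equal(sum(masked$counts), length(tr$classes))
  sep <- template_classifier(tc$cohort)
  allc <- masked_accuracy(sep, tr$volumes, tr$classes, ones)
  expect_lte(allc$f1, 1)
})

test_that("the template surrogate is linear with an exact input gradient", {
  tc <- tiny_cohort(shape = c(8L, 8L, 8L), R = 4L, effect = 3, n = 6L, seed = 13L)
  tcl <- template_classifier(tc$cohort)
  v <- tc$cohort$volumes[[1]]
  g1 <- input_gradient(tcl, v, target_class = 1L)
  expect_equal(as.numeric(g1), as.numeric(tcl$w))
  expect_equal(as.numeric(input_gradient(tcl, v, 0L)), -as.numeric(tcl$w))
  fn <- gashap:::classifier_margin_fn(tcl, 1L)
  expect_equal(fn(v), sum(tcl$w * v) + tcl$b)
})
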
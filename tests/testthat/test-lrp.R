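test_that("output seeding masks every class but the explained one", {
  expect_equal(seed_output_relevance(c(1.4, -0.2, 0.3), 1), c(1.4, 0, 0))
  expect_equal(seed_output_relevance(c(1.4, -0.2, 0.3), 3), c(0, 0, 0.3))
  expect_equal(sum(seed_output_relevance(c(1.4, -0.2, 0.3), 2)), -0.2)
  expect_error(seed_output_relevance(c(1, 2, 3), 4), "out of range")
})

test_that("dense propagation reproduces hand-evaluated shares", {
  # identity layer passes relevance through
  expect_equal(lrp_dense(c(2, 3), diag(2), c(0, 0), c(2, 3),
                         lrp_config("lrp0")), c(2, 3))
  # z = 1*1 + 3*1 = 4; shares 1/4 and 3/4 of R = 4
  expect_equal(lrp_dense(c(1, 3), matrix(1, 2, 1), 0, 4,
                         lrp_config("lrp0")), c(1, 3))
  # epsilon inflates the denominator to 4.4 and absorbs relevance
  r_eps <- lrp_dense(c(1, 3), matrix(1, 2, 1), 0, 4,
                     lrp_config("lrp_epsilon", 0.4))
  expect_equal(r_eps, c(4 / 4.4, 12 / 4.4))
  expect_lt(sum(r_eps), 4)
  expect_error(lrp_dense(c(1, 1), matrix(c(1, -1), 2, 1), 0, 2,
                         lrp_config("lrp0")), "epsilon")
})

test_that("conv propagation equals dense propagation on the unrolled matrix", {
  withr::with_seed(31, {
    for (i in 1:10) {
      L <- sample(4:9, 1); K <- sample(2:3, 1)
      C_in <- sample(1:3, 1); C_out <- sample(1:3, 1)
      a <- matrix(runif(L * C_in, 0.1, 1), L, C_in)
      W <- array(rnorm(K * C_in * C_out), c(K, C_in, C_out))
      b <- rnorm(C_out)
      L_out <- L - K + 1
      r_up <- matrix(rnorm(L_out * C_out), L_out, C_out)
      cfg <- lrp_config("lrp_epsilon", 1e-2)
      got <- lrp_conv1d(a, W, b, r_up, cfg)
      # oracle: explicit unrolled weight matrix + dense rule
      Wd <- unroll_conv_matrix(W, L)
      bd <- rep(b, each = L_out)
      want <- lrp_dense(as.numeric(a), Wd, bd, as.numeric(r_up), cfg)
      expect_equal(as.numeric(got), want, tolerance = 1e-12)
    }
  })
  # scalar identity kernel passes relevance through
  a <- matrix(c(5, 7), 2, 1)
  W1 <- array(1, c(1, 1, 1))
  expect_equal(as.numeric(lrp_conv1d(a, W1, 0, matrix(c(2, 3), 2, 1),
                                     lrp_config("lrp0"))), c(2, 3))
  # zero kernel contributes nothing under the epsilon rule
  W0 <- array(0, c(2, 1, 1))
  expect_equal(as.numeric(lrp_conv1d(a, W0, 0, matrix(1, 1, 1),
                                     lrp_config("lrp_epsilon", 0.1))), c(0, 0))
})

test_that("max-pool redistribution is winner-takes-all with tie splitting", {
  expect_equal(as.numeric(lrp_maxpool(matrix(c(3, 1), 2, 1),
                                      matrix(5), 2)), c(5, 0))
  expect_equal(as.numeric(lrp_maxpool(matrix(c(2, 2), 2, 1),
                                      matrix(4), 2)), c(2, 2))
  withr::with_seed(8, {
    a <- matrix(runif(12 * 3), 12, 3)
    r_up <- matrix(rnorm(6 * 3), 6, 3)
    low <- lrp_maxpool(a, r_up, 2)
    expect_equal(sum(low), sum(r_up))  # conservation through pooling
  })
})

test_that("ReLU passes relevance through unchanged", {
  expect_equal(lrp_relu(numeric(4)), numeric(4))
  expect_equal(lrp_relu(c(1, 2, 3)), c(1, 2, 3))
  expect_equal(lrp_relu(c(-1, 0, 2)), c(-1, 0, 2))
})

test_that("recorded traces agree with prediction and list every layer", {
  spec <- network_spec(input_length = 24, blocks = c(3L, 4L),
                       fc_sizes = c(6L, 3L))
  m <- build_network(spec, seed = 2)
  x <- runif(24)
  tr <- record_activations(m, x)
  expect_equal(unname(tr$logits),
               as.numeric(predict(m, matrix(x, 1), type = "logits")))
  types <- vapply(m$layers, function(l) l$type, "")
  expect_identical(sum(types == "conv"), 2L)
  expect_identical(sum(types == "pool"), 2L)
  expect_identical(sum(types == "dense"), 2L)
  tr2 <- record_activations(m, x)
  expect_identical(tr$caches, tr2$caches)  # purity
})

test_that("the default four-block network has the reference layer inventory", {
  m <- build_network(network_spec(), seed = 1)
  types <- vapply(m$layers, function(l) l$type, "")
  expect_identical(as.integer(table(types)[c("conv", "pool", "dense")]),
                   c(4L, 4L, 2L))
  expect_identical(sum(types == "dropout"), 1L)
})

test_that("relevance conservation holds for bias-free networks at eps = 0", {
  net <- dense_network(c(3, 5, 4, 3), seed = 7, bias = FALSE)
  withr::with_seed(12, x <- runif(3))
  rel <- explain(net, x, class = 2, cfg = lrp_config("lrp0"))
  cr <- conservation_report(rel)
  seed_val <- cr$relevance_sum[cr$type == "output"]
  expect_true(all(abs(cr$deficit) <= 1e-9 * max(abs(seed_val), 1e-12)))
  expect_equal(sum(rel$relevance), seed_val, tolerance = 1e-9)
})

test_that("LRP-0 equals gradient x input on bias-free ReLU networks", {
  withr::with_seed(17, {
    for (i in 1:20) {
      sizes <- c(sample(3:6, 1), sample(4:8, 1), sample(3:6, 1),
                 sample(2:4, 1))
      net <- dense_network(sizes, seed = i, bias = FALSE)
      x <- runif(sizes[1], -1, 1)
      cl <- sample(sizes[length(sizes)], 1)
      rel <- explain(net, x, class = cl, cfg = lrp_config("lrp0"))
      gi <- dense_logit_gradient(net, x, cl) * x
      expect_equal(rel$relevance, unname(gi), tolerance = 1e-6)
    }
  })
})

test_that("zero input yields zero relevance everywhere", {
  net <- dense_network(c(4, 5, 3), seed = 3, bias = FALSE)
  rel <- explain(net, rep(0, 4), class = 1, cfg = lrp_config("lrp_epsilon"))
  expect_equal(rel$relevance, rep(0, 4))
})

test_that("per-class maps differ and each seed equals its own logit", {
  tt <- tiny_trained_model()
  x <- tt$x[1, ]
  logits <- predict(tt$model, matrix(x, 1), type = "logits")
  rels <- lapply(1:3, function(cl) explain(tt$model, x, class = cl))
  for (cl in 1:3) {
    cr <- conservation_report(rels[[cl]])
    expect_equal(cr$relevance_sum[cr$type == "output"],
                 unname(logits[1, cl]))
  }
  expect_false(isTRUE(all.equal(rels[[1]]$relevance, rels[[2]]$relevance)))
})

test_that("increasing epsilon weakly shrinks every relevance magnitude", {
  # all-positive activations and weights keep every denominator positive
  withr::with_seed(23, {
    net <- dense_network(c(4, 6, 3), seed = 5, bias = FALSE)
    for (li in seq_along(net$layers)) {
      if (!is.null(net$layers[[li]]$W)) {
        net$layers[[li]]$W <- abs(net$layers[[li]]$W)
      }
    }
    x <- runif(4, 0.1, 1)
    eps_grid <- c(0, 1e-3, 1e-2, 1e-1, 1)
    mags <- sapply(eps_grid, function(e) {
      cfg <- if (e == 0) lrp_config("lrp0") else lrp_config("lrp_epsilon", e)
      abs(explain(net, x, class = 1, cfg = cfg)$relevance)
    })
    for (j in seq_len(ncol(mags) - 1)) {
      expect_true(all(mags[, j + 1] <= mags[, j] + 1e-12))
    }
  })
})

test_that("epsilon-rule deficits shrink totals monotonically down the net", {
  # with all-positive denominators each step can only absorb relevance
  withr::with_seed(29, {
    net <- dense_network(c(4, 6, 5, 3), seed = 9, bias = FALSE)
    for (li in seq_along(net$layers)) {
      if (!is.null(net$layers[[li]]$W)) {
        net$layers[[li]]$W <- abs(net$layers[[li]]$W)
      }
    }
    x <- runif(4, 0.1, 1)
    rel <- explain(net, x, class = 1, cfg = lrp_config("lrp_epsilon", 0.05))
    cr <- conservation_report(rel)
    sums <- rev(cr$relevance_sum)  # output first
    expect_true(all(diff(sums) <= 1e-12))
  })
})
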
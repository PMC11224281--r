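arch_tiny <- capsnet_architecture()

test_that("architecture reports derived counts and enforces the cap", {
  expect_equal(arch_tiny$conv_out_height, 7L)
  expect_equal(arch_tiny$primary_caps, 49L)
  # 4*3*3 conv weights + 4 biases + 49*2 maps of 8x4 + 2*8 class biases
  expect_equal(arch_tiny$n_params, 36 + 4 + 49 * 2 * 8 * 4 + 16)
  expect_error(capsnet_architecture(input_height = 64, input_width = 64,
                                    conv_filters = 16, primary_dim = 4),
               "smaller architecture")
  expect_error(capsnet_architecture(input_channels = 3), "grayscale")
  expect_error(capsnet_architecture(conv_filters = 6, primary_dim = 4),
               "divide")
})

test_that("pack/unpack is a round-trip identity and layout is consistent", {
  lay <- capsnet_layout(arch_tiny)
  expect_equal(sum(lay$length), arch_tiny$n_params)
  expect_equal(lay$offset, cumsum(c(0, lay$length[-4])))
  set.seed(5)
  for (rep in 1:5) {
    v <- rnorm(arch_tiny$n_params)
    parts <- capsnet_unpack(v, arch_tiny)
    expect_equal(dim(parts$caps_w), c(8L, 4L, 49L, 2L))
    expect_identical(capsnet_pack(parts, arch_tiny), v)
  }
  expect_error(capsnet_unpack(rnorm(10), arch_tiny), "expected")
})

test_that("squash has the closed-form length and fixes the zero vector", {
  expect_equal(squash(c(0, 0, 0)), c(0, 0, 0))
  v1 <- squash(c(1, 0))
  expect_equal(sqrt(sum(v1^2)), 0.5)
  v3 <- squash(c(0, 3))
  expect_equal(sqrt(sum(v3^2)), 0.9)
  # direction preserved
  s <- c(2, -1, 0.5)
  expect_equal(squash(s) / sqrt(sum(squash(s)^2)), s / sqrt(sum(s^2)))
})

test_that("coupling coefficients are a row softmax", {
  expect_equal(coupling_coefficients(matrix(0, 1, 2))[1, ], c(0.5, 0.5))
  expect_equal(coupling_coefficients(matrix(c(log(3), 0), 1))[1, ],
               c(0.75, 0.25))
  set.seed(2)
  b <- matrix(rnorm(30), 10, 3)
  cc <- coupling_coefficients(b)
  expect_equal(rowSums(cc), rep(1, 10))
  expect_true(all(cc > 0))
})

test_that("dynamic routing keeps couplings normalized and norms below 1", {
  set.seed(9)
  u_hat <- array(rnorm(6 * 2 * 4), c(6, 2, 4))
  out <- dynamic_routing(u_hat, iterations = 3)
  expect_equal(rowSums(out$state$c), rep(1, 6))
  expect_true(all(sqrt(rowSums(out$v^2)) < 1))
  # deterministic given u_hat
  out2 <- dynamic_routing(u_hat, iterations = 3)
  expect_identical(out$v, out2$v)
  # one pass with zero logits: uniform couplings 1/2, so
  # v_j = squash(0.5 * sum_i u_hat[j|i])
  one <- dynamic_routing(u_hat, iterations = 1)
  for (j in 1:2) {
    expect_equal(one$v[j, ], squash(0.5 * colSums(u_hat[, j, ])),
                 tolerance = 1e-12)
  }
})

test_that("identical predictions across primary capsules give parallel outputs", {
  u <- c(1, -0.5, 0.25, 0)
  u_hat <- array(0, c(5, 2, 4))
  for (i in 1:5) for (j in 1:2) u_hat[i, j, ] <- u
  out <- dynamic_routing(u_hat, iterations = 3)
  for (j in 1:2) {
    v <- out$v[j, ]
    cosang <- sum(v * u) / (sqrt(sum(v^2)) * sqrt(sum(u^2)))
    expect_equal(cosang, 1, tolerance = 1e-10)
  }
  expect_equal(out$state$c, matrix(0.5, 5, 2))
})

test_that("margin loss matches hand-evaluated cases", {
  expect_equal(margin_loss(c(0.9, 0.1), c(1, 0)), 0)
  expect_equal(margin_loss(c(0.4, 0.1), c(1, 0)), 0.25)
  expect_equal(margin_loss(c(0.9, 0.3), c(1, 0)), 0.02)
  # sums the two contributions
  expect_equal(margin_loss(c(0.4, 0.3), c(1, 0)), 0.25 + 0.02)
  # all-zero lengths: present class contributes m_plus^2, absent nothing
  expect_equal(margin_loss(c(0, 0), c(1, 0)), 0.81)
  expect_error(margin_loss(c(0.5, 0.5), c(1, 0), m_plus = 0.1, m_minus = 0.9))
})

test_that("compiled forward pass matches the R-composed reference", {
  set.seed(31)
  X <- matrix(runif(3 * 256), 3, 256)
  p <- runif(arch_tiny$n_params, -1, 1)
  fast <- capsnet_forward(X, p, arch_tiny)
  for (s in 1:3) {
    img <- matrix(X[s, ], 16, 16)
    expect_equal(fast[s, ], ref_capsnet_lengths(img, p, arch_tiny),
                 tolerance = 1e-10)
  }
})

test_that("forward pass behaves at the boundary cases", {
  set.seed(4)
  X <- matrix(runif(2 * 256), 2, 256)
  zero <- capsnet_forward(X, rep(0, arch_tiny$n_params), arch_tiny)
  expect_equal(as.numeric(zero), rep(0, 4))
  p <- runif(arch_tiny$n_params, -1, 1)
  lens <- capsnet_forward(X, p, arch_tiny)
  expect_true(all(lens >= 0 & lens < 1))
  expect_identical(capsnet_forward(X, p, arch_tiny), lens)
  expect_error(capsnet_forward(matrix(0, 2, 100), p, arch_tiny), "matrix")
})

test_that("fitness is a mean margin loss: duplication-invariant and >= 0", {
  set.seed(6)
  X <- matrix(runif(4 * 256), 4, 256)
  y <- c(1L, 2L, 1L, 2L)
  p <- runif(arch_tiny$n_params, -1, 1)
  f1 <- capsnet_fitness(p, X, y, arch_tiny)
  f2 <- capsnet_fitness(p, rbind(X, X), c(y, y), arch_tiny)
  expect_equal(f1, f2, tolerance = 1e-12)
  expect_gte(f1, 0)
  # agrees with margin_loss applied to the forward lengths
  lens <- capsnet_forward(X, p, arch_tiny)
  expect_equal(f1, margin_loss(lens, y), tolerance = 1e-12)
  expect_error(capsnet_fitness(p, X[0, , drop = FALSE], integer(0), arch_tiny),
               "empty")
})

test_that("all-zero parameters give the analytic margin loss", {
  set.seed(8)
  X <- matrix(runif(5 * 256), 5, 256)
  y <- c(1L, 2L, 1L, 2L, 1L)
  f <- capsnet_fitness(rep(0, arch_tiny$n_params), X, y, arch_tiny)
  expect_equal(f, 0.9^2)   # one present class at length 0 per sample
})

test_that("class prediction is argmax with lowest-index ties", {
  expect_equal(predict_class(c(0.9, 0.1)), 1L)
  expect_equal(predict_class(c(0.1, 0.9)), 2L)
  expect_equal(predict_class(c(0.5, 0.5)), 1L)
  expect_equal(predict_class(rbind(c(0.2, 0.8), c(0.7, 0.3))), c(2L, 1L))
})

test_that("training is reproducible and improves on the initial population", {
  d <- tiny_smear_data(6, seed = 11)
  opts <- osprey_options("mop", pop_size = 5, iterations = 5)
  m1 <- train_capsnet(d, arch_tiny, opts, seed = 21)
  m2 <- train_capsnet(d, arch_tiny, opts, seed = 21)
  expect_identical(m1$params, m2$params)
  expect_lte(m1$loss, m1$result$history[1])
  expect_s3_class(predict(m1, d), "factor")
  expect_length(predict(m1, d, type = "prob"), nrow(d))
  gl <- glance(m1)
  expect_equal(gl$margin_loss, m1$loss)
})
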
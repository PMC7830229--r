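test_that("concatenation joins TS consecutive rows and shrinks the batch", {
  m18 <- matrix(rnorm(18 * 4), 18, 4)
  expect_equal(nrow(concat_rows(m18, 3)), 16L)
  expect_equal(ncol(concat_rows(m18, 3)), 12L)
  expect_identical(concat_rows(m18, 1), m18)
  m5 <- matrix(1:10, 5, 2)
  c3 <- concat_rows(m5, 3)
  expect_equal(nrow(c3), 3L)
  expect_equal(c3[1, ], c(m5[1, ], m5[2, ], m5[3, ]))
  expect_error(concat_rows(m5, 6), "too small")
})

test_that("label-count pooling sums TS consecutive rows and conserves counts", {
  expect_equal(pool_label_counts(rbind(c(1, 0), c(0, 1), c(1, 0)), 3),
               matrix(c(2, 1), 1))
  m <- matrix(sample(0:5, 24, replace = TRUE), 8, 3)
  expect_identical(pool_label_counts(m, 1), m)
  p <- pool_label_counts(m, 4)
  expect_equal(nrow(p), 5L)
  ## every pooled row sum is TS times the (constant) input row sum
  m2 <- matrix(2L, 6, 2)
  expect_true(all(rowSums(pool_label_counts(m2, 3)) == 3 * 4))
})

test_that("majority vote takes the arg-max and breaks ties reproducibly", {
  expect_equal(majority_vote(c(5, 2, 1)), 0L)
  expect_equal(majority_vote(c(0, 0, 7)), 2L)
  expect_error(majority_vote(c(0, 0, 0)), "all-zero")
  expect_equal(majority_vote(c(3, 3), seed = 11), majority_vote(c(3, 3), seed = 11))
  ## uniform tie-breaking over many seeds
  draws <- vapply(1:10000, function(s) majority_vote(c(3, 3), seed = s),
                  integer(1))
  expect_equal(mean(draws), 0.5, tolerance = 0.04)  # +/- 0.02 on the frequency
})

test_that("forward pass drops L*(TS-1) rows and produces softmax rows", {
  params <- dtcn_params(c(224, 20, 20, 20, 2), ts = 5, seed = 1)
  batch <- matrix(rnorm(18 * 224), 18, 224)
  fwd <- forward_dtcn(params, batch)
  expect_equal(nrow(fwd$probs), 6L)
  expect_lt(max(abs(rowSums(fwd$probs) - 1)), 1e-12)
  expect_error(forward_dtcn(params, batch[1:10, ]), "B >= 13")
})

test_that("a TS = 1 network reproduces the plain MLP forward pass", {
  params <- dtcn_params(c(6, 5, 4, 3), ts = 1, seed = 3)
  X <- matrix(rnorm(8 * 6), 8, 6)
  fwd <- forward_dtcn(params, X)
  oracle <- mlp_forward_oracle(params$W, params$b, X)
  expect_equal(max(abs(fwd$probs - oracle$probs)), 0, tolerance = 1e-14)
})

test_that("pooled counts stay row-aligned with activations at every layer", {
  b <- make_test_batch(B = 12, n_in = 6, K = 3, w = 4)
  params <- dtcn_params(c(6, 5, 4, 3), ts = 3, seed = 2)
  fwd <- forward_dtcn(params, b)
  expect_equal(nrow(fwd$pooled_counts), nrow(fwd$probs))
  expect_true(all(rowSums(fwd$pooled_counts) == 4 * 3^2))
})

test_that("gradient routing is the adjoint of concatenation and conserves delta", {
  expect_identical(gradient_route(diag(4), 1, 4), diag(4))
  set.seed(9)
  for (rep in 1:20) {
    ts <- sample(1:4, 1)
    H <- sample(1:6, 1)
    pre <- ts + sample(0:8, 1)
    A <- matrix(rnorm(pre * H), pre, H)
    G <- matrix(rnorm((pre - ts + 1) * ts * H), pre - ts + 1, ts * H)
    routed <- gradient_route(G, ts, pre)
    ## conservation of total delta
    expect_equal(sum(routed), sum(G), tolerance = 1e-12)
    ## adjoint inner-product identity <concat(A), G> = <A, route(G)>
    expect_equal(sum(concat_rows(A, ts) * G), sum(A * routed),
                 tolerance = 1e-10)
  }
  expect_error(gradient_route(matrix(0, 3, 4), 2, 7), "mismatch")
})

test_that("weights-only parameter count includes the TS fan-in factor", {
  expect_equal(param_count(c(224, 23, 23, 20, 2), 1), 6181L)
  expect_equal(param_count(c(224, 31, 31, 20, 2), 1), 8565L)
  expect_equal(param_count(c(224, 20, 20, 20, 2), 2), 6160L)
})

test_that("complexity-matched plain networks widen all but the last hidden layer", {
  expect_equal(equivalent_dbn_config(c(224, 20, 20, 20, 2), 2), c(23, 23, 20))
  expect_equal(equivalent_dbn_config(c(224, 20, 20, 20, 2), 5), c(31, 31, 20))
  expect_equal(equivalent_dbn_config(c(224, 20, 20, 20, 2), 1), c(20, 20, 20))
})
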
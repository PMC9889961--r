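test_that("ann_spec validates dimension chaining", {
  a <- make_random_ann(c(2, 3, 1), seed = 1)
  expect_identical(dim(a$layers[[1]]$W), c(3L, 2L))
  expect_identical(dim(a$layers[[2]]$W), c(1L, 3L))
  expect_error(
    ann_spec(inputs = data.frame(id = c("x1", "x2"), min = 0, max = 1),
             layers = list(list(W = matrix(0, 3, 2), b = c(0, 0),
                                activation = "tanh")),
             outputs = data.frame(kind = "parameter", id = "y")),
    "ANN_SHAPE_MISMATCH")
  expect_error(
    ann_spec(inputs = data.frame(id = "x1", min = 0, max = 1),
             layers = list(list(W = matrix(0, 1, 1), b = 0,
                                activation = "relu")),
             outputs = data.frame(kind = "parameter", id = "y")),
    "UNSUPPORTED_ACTIVATION")
  expect_error(
    ann_spec(inputs = data.frame(id = "x1", min = 1, max = 1),
             layers = list(list(W = matrix(0, 1, 1), b = 0,
                                activation = "linear")),
             outputs = data.frame(kind = "parameter", id = "y")),
    "max > min")
})

test_that("forward pass: degenerate cases have closed-form outputs", {
  zero <- ann_spec(
    inputs = data.frame(id = c("x1", "x2"), min = c(0, 0), max = c(1, 1)),
    layers = list(list(W = matrix(0, 3, 2), b = rep(0, 3), activation = "tanh"),
                  list(W = matrix(0, 1, 3), b = 0, activation = "linear")),
    outputs = data.frame(kind = "parameter", id = "y"))
  expect_identical(ann_forward(zero, c(0.3, 0.9)), 0)
  expect_identical(ann_forward(zero, c(100, -5)), 0)

  one <- ann_spec(
    inputs = data.frame(id = "x", min = 0, max = 1),
    layers = list(list(W = matrix(2, 1, 1), b = 1, activation = "linear")),
    outputs = data.frame(kind = "parameter", id = "y"))
  expect_identical(ann_forward(one, 0.5), 2)
  expect_error(ann_forward(one, c(1, 2)), "expected 1 inputs")
})

test_that("forward pass matches a matrix-free loop evaluator at random points", {
  # oracle: scalar loops only, no matrix algebra
  loop_forward <- function(a, x) {
    v <- numeric(nrow(a$inputs))
    for (i in seq_along(v)) {
      v[i] <- (x[i] - a$inputs$min[i]) / (a$inputs$max[i] - a$inputs$min[i])
    }
    for (ly in a$layers) {
      nxt <- numeric(nrow(ly$W))
      for (i in seq_along(nxt)) {
        s <- ly$b[i]
        for (j in seq_along(v)) s <- s + ly$W[i, j] * v[j]
        nxt[i] <- if (ly$activation == "tanh") tanh(s) else s
      }
      v <- nxt
    }
    v
  }
  a <- make_random_ann(c(3, 4, 2), seed = 21)
  set.seed(22)
  for (i in 1:100) {
    x <- runif(3, -1, 2)
    expect_lt(max(abs(ann_forward(a, x) - loop_forward(a, x))), 1e-13)
  }
})

test_that("the ASCII weight container stores and loads networks losslessly", {
  set.seed(31)
  for (i in 1:10) {
    shape <- c(sample(1:3, 1), sample(2:6, 1), sample(1:2, 1))
    a <- make_random_ann(shape, seed = 100 + i)
    txt <- write_ann_weights(a)
    b <- load_ann_weights(txt)
    expect_identical(b$layers, a$layers)
    expect_identical(b$inputs, a$inputs)
    expect_identical(b$outputs$id, a$outputs$id)
  }
  path <- withr::local_tempfile(fileext = ".annw")
  a <- make_random_ann(c(2, 3, 1), seed = 5)
  write_ann_weights(a, path)
  expect_identical(load_ann_weights(path)$layers, a$layers)
})

test_that("malformed containers are rejected with the shape/activation codes", {
  a <- make_random_ann(c(2, 3, 1), seed = 5)
  txt <- write_ann_weights(a)
  expect_error(load_ann_weights(sub("b_1 : values=[^\n]*",
                                    "b_1 : values=0 0", txt)),
               "ANN_SHAPE_MISMATCH")
  expect_error(load_ann_weights(sub("activation=tanh", "activation=selu", txt)),
               "UNSUPPORTED_ACTIVATION")
  expect_error(load_ann_weights("garbage"), "ANNW")
})
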
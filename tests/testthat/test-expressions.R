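test_that("infix parsing honours precedence and associativity", {
  e <- parse_infix("k1*S/(Km+S)")
  expect_true(expr_identical(
    e,
    e_call("/", e_call("*", e_sym("k1"), e_sym("S")),
           e_call("+", e_sym("Km"), e_sym("S")))))
  expect_true(expr_identical(parse_infix("tanh(0)"),
                             e_call("tanh", e_num(0))))
  # power is right-associative: 2^3^2 = 2^(3^2) = 512
  expect_equal(eval_expr(parse_infix("2^3^2")), 512)
  # unary minus binds tighter than power
  expect_equal(eval_expr(parse_infix("-2^2")), 4)
  expect_equal(eval_expr(parse_infix("2^-1")), 0.5)
  # pow() is the same node as ^
  expect_true(expr_identical(parse_infix("pow(a,b)"), parse_infix("a^b")))
})

test_that("infix syntax errors carry a 1-based column and unknown functions fail", {
  expect_error(parse_infix("a + "), "column 5")
  expect_error(parse_infix("a @ b"), "column 3")
  expect_error(parse_infix("sinh(x)"), "unknown function 'sinh'")
  expect_error(parse_infix(""), "empty")
  expect_error(parse_infix("(a+b"), "expected '\\)'")
})

test_that("writer inserts parentheses only where structure demands them", {
  cases <- list(
    list(e_call("*", e_call("+", e_sym("a"), e_sym("b")), e_sym("c")), "(a+b)*c"),
    list(e_call("tanh", e_call("*", e_sym("w"), e_sym("x"))), "tanh(w*x)"),
    list(e_call("-", e_sym("a"), e_call("+", e_sym("b"), e_sym("c"))), "a-(b+c)"),
    list(e_call("+", e_call("-", e_sym("a"), e_sym("b")), e_sym("c")), "a-b+c"),
    list(e_call("^", e_call("^", e_sym("a"), e_sym("b")), e_sym("c")), "(a^b)^c"),
    list(e_call("^", e_sym("a"), e_call("^", e_sym("b"), e_sym("c"))), "a^b^c"),
    list(e_call("neg", e_call("^", e_sym("x"), e_num(2))), "-(x^2)"),
    list(e_call("^", e_call("neg", e_sym("x")), e_num(2)), "-x^2"))
  for (cs in cases) expect_identical(write_infix(cs[[1]]), cs[[2]])
})

test_that("infix round-trip is the identity on random trees", {
  set.seed(42)
  for (i in 1:1000) {
    e <- rand_expr(depth = sample(2:8, 1))
    s <- write_infix(e)
    expect_true(expr_identical(parse_infix(s), e), label = s)
  }
})

test_that("evaluation matches an independent shunting-yard oracle", {
  set.seed(7)
  env <- list(a = 1.3, b = 0.7, c = 2.1, d = 0.4, e = 1.9, f = 0.9)
  checked <- 0L
  for (i in 1:200) {
    ex <- rand_expr(depth = sample(2:6, 1), funcs = FALSE)
    s <- write_infix(ex)
    mine <- eval_expr(ex, env)
    oracle <- shunting_yard_eval(s, env)
    if (is.finite(mine) && is.finite(oracle)) {
      expect_equal(mine, oracle, tolerance = 1e-12, label = s)
      checked <- checked + 1L
    } else {
      expect_identical(is.finite(mine), is.finite(oracle), label = s)
    }
  }
  expect_gt(checked, 150L)
})

test_that("evaluator semantics: piecewise, relations, IEEE division", {
  expect_identical(eval_expr(parse_infix("tanh(0)")), 0)
  expect_equal(eval_expr(parse_infix("k*S/(Km+S)"), c(k = 2, S = 1, Km = 1)), 1)
  pw <- parse_infix("piecewise(1, lt(x, 2), 3, geq(x, 5), 0)")
  expect_equal(eval_expr(pw, c(x = 1)), 1)
  expect_equal(eval_expr(pw, c(x = 7)), 3)
  expect_equal(eval_expr(pw, c(x = 3)), 0)
  expect_identical(eval_expr(parse_infix("1/0")), Inf)
  expect_error(eval_expr(parse_infix("x+1"), list()), "unbound symbol 'x'")
})

test_that("compiled R-language evaluation agrees with the tree walker", {
  set.seed(11)
  env <- list(a = 0.8, b = 1.7, c = 0.3, d = 2.2, e = 0.5, f = 1.1)
  for (i in 1:100) {
    ex <- rand_expr(depth = sample(2:6, 1))
    # ln/sqrt of negative subterms legitimately yield NaN in random trees
    v1 <- suppressWarnings(eval_expr(ex, env))
    v2 <- suppressWarnings(eval(expr_to_lang(ex), env))
    if (is.finite(v1) || is.finite(v2)) {
      expect_equal(v1, v2, tolerance = 1e-14, label = write_infix(ex))
    }
  }
})

test_that("numeric literals serialize to shortest round-trip decimals", {
  for (x in c(0, 1, 0.5, 1 / 3, 2 / 7, 1e-9, 6.02e23, pi)) {
    expect_identical(as.numeric(fmt_dbl(x)), x)
  }
  expect_identical(fmt_dbl(0.5), "0.5")
  expect_identical(fmt_dbl(2), "2")
})
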
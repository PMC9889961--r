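mm_with_ann <- function(seed = 3, shape = c(2, 3, 1)) {
  m <- make_toy_model("michaelis-menten-pathway", seed = seed)
  a <- make_random_ann(shape, seed = seed, input_ids = c("S", "P"),
                       bounds = data.frame(min = c(0, 0), max = c(3, 3)),
                       outputs = data.frame(kind = "reaction-rate", id = "v1",
                                            factor = NA_character_))
  list(m = m, a = a)
}

test_that("hybridize generates the formula-determined counts", {
  x <- mm_with_ann()
  hy <- hybridize(x$m, x$a)
  # 2-3-1 network: weights 3*2 + 1*3, biases 3 + 1 -> 13 trainable constants
  wb <- Filter(function(p) p$origin %in% c("ml-weight", "ml-bias"),
               hy$model$parameters)
  expect_identical(length(wb), 13L)
  # assignment rules: 2 scaled inputs + 3 hidden + 1 output = 6 new
  expect_identical(length(hy$model$assignment_rules) -
                     length(x$m$assignment_rules), 6L)
  # nothing removed
  expect_true(all(names(x$m$parameters) %in% names(hy$model$parameters)))
  expect_identical(names(hy$model$species), names(x$m$species))
  # targeted law replaced by the output symbol
  expect_identical(write_infix(hy$model$reactions$v1$law), "annY_1")
  expect_identical(nrow(check_consistency(hy$model)), 0L)
})

test_that("compiled assignment rules reproduce ann_forward to 1e-12", {
  set.seed(77)
  for (i in 1:5) {
    x <- mm_with_ann(seed = i, shape = c(2, sample(2:5, 1), 1))
    hy <- hybridize(x$m, x$a)
    sys <- build_rhs(hy$model)
    for (j in 1:20) {
      st <- stats::setNames(runif(2, 0, 3), c("S", "P"))
      d <- sys$derived(0, st[sys$state_ids])
      expect_lt(abs(d[["annY_1"]] -
                    ann_forward(x$a, st[x$a$inputs$id])), 1e-12)
    }
  }
})

test_that("zero-weight networks drive targeted rates to the bias path", {
  x <- mm_with_ann()
  a0 <- x$a
  for (l in seq_along(a0$layers)) {
    a0$layers[[l]]$W[] <- 0
    a0$layers[[l]]$b[] <- 0
  }
  hy <- hybridize(x$m, a0)
  sys <- build_rhs(hy$model)
  d <- sys$derived(0, stats::setNames(c(1, 1), sys$state_ids))
  expect_identical(d[["annY_1"]], 0)
})

test_that("dehybridize is the exact inverse of hybridize", {
  x <- mm_with_ann(seed = 8)
  hy <- hybridize(x$m, x$a)
  parts <- dehybridize(hy$model, hy$plan)
  # weights bit-equal
  expect_identical(parts$ann$layers, x$a$layers)
  expect_identical(parts$ann$inputs, x$a$inputs)
  # mechanistic model restored
  expect_identical(names(parts$model$parameters), names(x$m$parameters))
  expect_true(expr_identical(parts$model$reactions$v1$law,
                             x$m$reactions$v1$law))
  # and hybridizing again reproduces the hybrid model byte-for-byte
  hy2 <- hybridize(parts$model, parts$ann)
  expect_identical(serialize_hmod(hy2$model), serialize_hmod(hy$model))
  # mutated plan symbols are reported by name
  broken <- hy$model
  broken$parameters[["annW_1_1_1"]] <- NULL
  expect_error(dehybridize(broken, hy$plan), "annW_1_1_1")
})

test_that("generated ids avoid collisions via deterministic suffixing", {
  x <- mm_with_ann()
  m <- x$m
  m$parameters[["annY_1"]] <- kin_parameter("annY_1", 99)  # collides
  hy <- hybridize(m, x$a)
  expect_identical(hy$plan$suffix, "_h1")
  expect_true("annY_1_h1" %in% vapply(hy$model$assignment_rules, `[[`,
                                      character(1), "variable"))
  expect_identical(write_infix(hy$model$reactions$v1$law), "annY_1_h1")
  expect_identical(nrow(check_consistency(hy$model)), 0L)
})

test_that("a declared multiplicative factor is retained in the rewired rate", {
  x <- mm_with_ann()
  a <- x$a
  a$outputs$factor <- "P"
  hy <- hybridize(x$m, a)
  expect_identical(write_infix(hy$model$reactions$v1$law), "annY_1*P")
  parts <- dehybridize(hy$model, hy$plan)
  expect_identical(parts$ann$outputs$factor, "P")
})

test_that("recover_plan finds the compiled structure in a round-tripped SBML", {
  x <- mm_with_ann(seed = 12)
  hy <- hybridize(x$m, x$a)
  back <- read_sbml(write_sbml(hy$model))$model
  plan <- recover_plan(back)
  expect_false(is.null(plan))
  expect_identical(plan$layer_sizes, hy$plan$layer_sizes)
  expect_identical(plan$activations, hy$plan$activations)
  parts <- dehybridize(back, plan)
  expect_identical(parts$ann$layers, x$a$layers)
  expect_identical(parts$ann$inputs$min, x$a$inputs$min)
  expect_identical(parts$ann$inputs$max, x$a$inputs$max)
  # a purely mechanistic model has no plan
  expect_null(recover_plan(x$m))
})

test_that("unknown inputs or targets are rejected up front", {
  x <- mm_with_ann()
  a <- x$a
  a$inputs$id[1] <- "nosuch"
  expect_error(hybridize(x$m, a), "nosuch")
  a <- x$a
  a$outputs$id <- "vmissing"
  expect_error(hybridize(x$m, a), "vmissing")
})
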
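toy2 <- function() {
  kinetic_model(
    "toy2",
    compartments = list(kin_compartment("cell", size = 1)),
    species = list(kin_species("A", "cell", init = 1),
                   kin_species("B", "cell", init = 0)),
    parameters = list(kin_parameter("k", 0.5)),
    reactions = list(kin_reaction("v1", reactants = c(A = 1),
                                  products = c(B = 1), law = "k*A")))
}

test_that("a well-formed model passes consistency; defects are coded report rows", {
  expect_identical(nrow(check_consistency(toy2())), 0L)

  m <- toy2()
  m$reactions[["v1"]]$reactants <- c(X = 1)
  rep <- check_consistency(m)
  expect_false(report_ok(rep))
  expect_true(any(rep$code == "DANGLING_REF" & rep$location == "v1"))

  m <- toy2()
  m$reactions[["v1"]]$law <- parse_infix("kmissing*A")
  rep <- check_consistency(m)
  expect_true(any(rep$code == "DANGLING_REF" & grepl("kmissing", rep$message)))

  m <- toy2()
  m$parameters[["A"]] <- kin_parameter("A", 1)
  expect_true(any(check_consistency(m)$code == "DUPLICATE_ID"))

  m <- toy2()
  m$compartments[["cell"]]$size <- -2
  expect_true(any(check_consistency(m)$code == "NEGATIVE_SIZE"))

  m <- toy2()
  m$parameters[["a"]] <- kin_parameter("a", 0, constant = FALSE)
  m$parameters[["b"]] <- kin_parameter("b", 0, constant = FALSE)
  m$assignment_rules <- list(kin_assignment_rule("a", "b+1"),
                             kin_assignment_rule("b", "a+1"))
  expect_true(any(check_consistency(m)$code == "ASSIGNMENT_CYCLE"))

  # a rate rule on a reaction-determined species conflicts
  m <- toy2()
  m$rate_rules <- list(kin_rate_rule("A", "k"))
  expect_true(any(check_consistency(m)$code == "RULE_CONFLICT"))
})

test_that("check_consistency is idempotent and side-effect free", {
  m <- toy2()
  r1 <- check_consistency(m)
  r2 <- check_consistency(m)
  expect_identical(r1, r2)
  expect_identical(write_infix(m$reactions[["v1"]]$law), "k*A")
})

test_that("assignment rules topo-sort with stable ties", {
  mk <- function(rules) {
    m <- toy2()
    for (v in c("out", "h1", "h2", "x")) {
      m$parameters[[v]] <- kin_parameter(v, 0, constant = FALSE)
    }
    m$assignment_rules <- rules
    m
  }
  ord <- topo_order_assignments(mk(list(
    kin_assignment_rule("out", "h1+h2"),
    kin_assignment_rule("h1", "tanh(x)"),
    kin_assignment_rule("h2", "tanh(x)"))))
  expect_identical(vapply(ord, `[[`, character(1), "variable"),
                   c("h1", "h2", "out"))
  # independent rules keep declaration order
  ord <- topo_order_assignments(mk(list(
    kin_assignment_rule("h2", "tanh(x)"),
    kin_assignment_rule("h1", "tanh(x)"))))
  expect_identical(vapply(ord, `[[`, character(1), "variable"), c("h2", "h1"))
  expect_error(topo_order_assignments(list(
    kin_assignment_rule("a", "b"), kin_assignment_rule("b", "a"))), "cycle")
})

test_that("random rule DAGs topo-sort validly (brute-force edge check)", {
  set.seed(5)
  for (rep_i in 1:25) {
    n <- sample(5:30, 1)
    vars <- paste0("v", seq_len(n))
    # random DAG: each rule depends on a subset of later-declared variables
    rules <- lapply(seq_len(n), function(i) {
      deps <- if (i < n) sample(vars[seq(i + 1L, n)],
                                size = sample(0:min(3, n - i), 1)) else character(0)
      expr <- if (length(deps) == 0L) e_num(1) else {
        out <- e_sym(deps[1L])
        for (d in deps[-1L]) out <- e_call("+", out, e_sym(d))
        out
      }
      kin_assignment_rule(vars[i], expr)
    })
    ord <- topo_order_assignments(sample(rules))
    pos <- match(vapply(ord, `[[`, character(1), "variable"), vars)
    for (j in seq_along(ord)) {
      for (d in intersect(expr_symbols(ord[[j]]$expr), vars)) {
        expect_lt(which(pos == match(d, vars)), j)
      }
    }
  }
})
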
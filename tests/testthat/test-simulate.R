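test_that("right-hand side follows stoichiometric flux summation", {
  m <- kinetic_model(
    "ab",
    compartments = list(kin_compartment("cell", size = 1)),
    species = list(kin_species("A", "cell", init = 1),
                   kin_species("B", "cell", init = 0)),
    parameters = list(kin_parameter("k", 1)),
    reactions = list(kin_reaction("v1", reactants = c(A = 1),
                                  products = c(B = 1), law = "k*A")))
  sys <- build_rhs(m)
  dy <- sys$rhs(0, c(A = 1, B = 0))
  expect_identical(dy[["A"]], -1)
  expect_identical(dy[["B"]], 1)

  # boundary species never move through reactions
  m$species$A$boundary <- TRUE
  sys <- build_rhs(m)
  expect_identical(sys$state_ids, "B")
  expect_identical(sys$rhs(0, c(B = 0))[["B"]], 1)
})

test_that("compartment size divides flux contributions", {
  m <- kinetic_model(
    "vol",
    compartments = list(kin_compartment("big", size = 2)),
    species = list(kin_species("A", "big", init = 1)),
    parameters = list(kin_parameter("k", 1)),
    reactions = list(kin_reaction("v1", reactants = c(A = 1), law = "k*A")))
  sys <- build_rhs(m)
  expect_identical(sys$rhs(0, c(A = 1))[["A"]], -0.5)
})

test_that("RHS matches a finite-difference flux-summation oracle on random networks", {
  # oracle: numeric derivative of the integrated amount via direct flux
  # arithmetic on randomly generated mass-action networks
  set.seed(55)
  for (rep_i in 1:10) {
    n_sp <- 5L
    sp_ids <- paste0("s", seq_len(n_sp))
    n_rx <- sample(3:6, 1)
    rxs <- list()
    ks <- list()
    for (r in seq_len(n_rx)) {
      from <- sample(sp_ids, 1)
      to <- sample(setdiff(sp_ids, from), 1)
      k <- round(runif(1, 0.1, 2), 4)
      ks[[paste0("k", r)]] <- k
      rxs[[r]] <- kin_reaction(paste0("v", r),
                               reactants = stats::setNames(1, from),
                               products = stats::setNames(1, to),
                               law = paste0("k", r, "*", from))
    }
    m <- kinetic_model(
      paste0("net", rep_i),
      compartments = list(kin_compartment("cell", size = 1)),
      species = lapply(sp_ids, function(s) kin_species(s, "cell", init = runif(1, 0.1, 2))),
      parameters = lapply(names(ks), function(kn) kin_parameter(kn, ks[[kn]])),
      reactions = rxs)
    sys <- build_rhs(m)
    y <- vapply(sys$state_ids, function(s) m$species[[s]]$init, numeric(1))
    dy <- sys$rhs(0, y)
    # oracle derivative per species: sum of signed k*reactant fluxes
    for (s in sys$state_ids) {
      acc <- 0
      for (r in seq_len(n_rx)) {
        from <- names(rxs[[r]]$reactants)
        flux <- ks[[paste0("k", r)]] * y[[from]]
        if (from == s) acc <- acc - flux
        if (names(rxs[[r]]$products) == s) acc <- acc + flux
      }
      expect_equal(dy[[s]], acc, tolerance = 1e-12)
    }
  }
})

test_that("exponential decay matches its closed form", {
  traj <- run_model(make_decay_model(), t_end = 2, n_points = 101)
  a_t2 <- traj$state[101, "A"]
  expect_lt(abs(a_t2 - exp(-1)), 1e-6)
  # full-curve check against A0 * exp(-k t)
  expect_lt(max(abs(traj$state[, "A"] - exp(-0.5 * traj$time))), 1e-6)
})

test_that("closed reversible pair conserves total mass along the trajectory", {
  m <- make_toy_model("reversible-pair", seed = 17)
  traj <- run_model(m, t_end = 10)
  total <- traj$state[, "A"] + traj$state[, "B"]
  expect_lt(max(abs(total - total[1])), 1e-8)
})

test_that("the stiff two-timescale toy integrates without failure", {
  m <- make_toy_model("stiff-pair", seed = 23)
  traj <- run_model(m, t_end = 5)
  expect_true(all(is.finite(traj$state)))
  # mass conservation A + B + C
  total <- rowSums(traj$state)
  expect_lt(max(abs(total - total[1])), 1e-6)
})

test_that("rate rules integrate alongside reactions", {
  m <- make_toy_model("chain", seed = 29)
  traj <- run_model(m, t_end = 5)
  expect_true("Z" %in% colnames(traj$state))
  expect_gt(max(traj$state[, "Z"]), 0)
})

test_that("simulation is reproducible and grids behave", {
  m <- make_toy_model("chain", seed = 1)
  t1 <- run_model(m, t_end = 3, n_points = 50)
  t2 <- run_model(m, t_end = 3, n_points = 50)
  expect_identical(t1$state, t2$state)
  expect_identical(length(t1$time), 50L)
})

test_that("trajectory comparison is symmetric and detects perturbations", {
  m <- make_toy_model("chain", seed = 1)
  t1 <- run_model(m, t_end = 3)
  expect_identical(compare_trajectories(t1, t1)$max, 0)
  t2 <- t1
  t2$state[40, "B"] <- t2$state[40, "B"] + 1e-3
  cmp12 <- compare_trajectories(t1, t2, tol = 1e-8)
  expect_false(cmp12$pass)
  expect_equal(cmp12$max, 1e-3, tolerance = 1e-6)
  expect_identical(compare_trajectories(t2, t1)$max, cmp12$max)
  # column order is irrelevant
  t3 <- t1
  perm <- rev(seq_len(ncol(t3$state)))
  t3$state <- t3$state[, perm, drop = FALSE]
  expect_identical(compare_trajectories(t1, t3)$max, 0)
  t4 <- run_model(m, t_end = 3, n_points = 60)
  expect_error(compare_trajectories(t1, t4), "grids")
})

test_that("CSV export writes ids as header and one row per point", {
  path <- withr::local_tempfile(fileext = ".csv")
  m <- make_decay_model()
  write_trajectory_csv(run_model(m, t_end = 2, n_points = 11), path)
  df <- utils::read.csv(path)
  expect_identical(names(df), c("time", "A"))
  expect_identical(nrow(df), 11L)
  expect_lt(abs(df$A[11] - exp(-1)), 1e-6)
})
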
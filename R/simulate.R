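# Deterministic ODE simulation of kinetic models (mechanistic or hybrid).
# Assignment rules are algebraic: re-evaluated inside the right-hand side
# at every integrator call, never lagged. Species derivatives follow
# stoichiometric flux summation; compartment sizes divide reaction flux
# contributions; rate rules add their term directly.

#' Assemble the ODE right-hand side of a kinetic model
#'
#' State variables are the species determined by reactions (non-boundary,
#' non-constant, not assignment-ruled) plus every rate-rule variable.
#' Expressions are compiled once to R calls; assignment rules are
#' evaluated in topological order before any flux.
#'
#' @param m A consistent `kinetic_model`.
#' @return A list with `state_ids`, `derived_ids` (assignment-rule
#'   variables), `init` (named initial state), and `rhs(t, y)` returning
#'   the named derivative vector; `derived(t, y)` returns the
#'   assignment-rule values at a state.
#' @export
build_rhs <- function(m) {
  rep <- check_consistency(m)
  if (!report_ok(rep)) stop("model is not consistent", call. = FALSE)

  assigned <- vapply(m$assignment_rules, `[[`, character(1), "variable")
  rated <- vapply(m$rate_rules, `[[`, character(1), "variable")

  reaction_species <- unique(unlist(lapply(m$reactions, function(rx) {
    c(names(rx$reactants), names(rx$products))
  })))
  dynamic_species <- names(m$species)[vapply(names(m$species), function(s) {
    sp <- m$species[[s]]
    s %in% reaction_species && !sp$boundary && !sp$constant && !(s %in% assigned)
  }, logical(1))]
  state_ids <- unique(c(dynamic_species, rated))

  init <- vapply(state_ids, function(v) {
    if (v %in% names(m$species)) m$species[[v]]$init
    else m$parameters[[v]]$value
  }, numeric(1))

  base_env <- new.env(parent = baseenv())
  for (cp in m$compartments) assign(cp$id, cp$size, envir = base_env)
  for (p in m$parameters) assign(p$id, p$value, envir = base_env)
  for (sp in m$species) assign(sp$id, sp$init, envir = base_env)

  ordered_rules <- topo_order_assignments(m)
  rule_vars <- vapply(ordered_rules, `[[`, character(1), "variable")
  rule_lang <- lapply(ordered_rules, function(r) expr_to_lang(r$expr))
  law_lang <- lapply(m$reactions, function(rx) expr_to_lang(rx$law))
  rate_lang <- lapply(m$rate_rules, function(r) expr_to_lang(r$expr))

  comp_of <- vapply(names(m$species), function(s) m$species[[s]]$compartment,
                    character(1))

  # per-reaction signed stoichiometry restricted to state species
  rx_effects <- lapply(m$reactions, function(rx) {
    eff <- numeric(0)
    for (i in seq_along(rx$reactants)) {
      s <- names(rx$reactants)[i]
      if (s %in% dynamic_species) eff[s] <- (eff[s] %||% 0) - rx$reactants[[i]]
    }
    for (i in seq_along(rx$products)) {
      s <- names(rx$products)[i]
      if (s %in% dynamic_species) eff[s] <- (eff[s] %||% 0) + rx$products[[i]]
    }
    eff
  })

  fill_env <- function(t, y) {
    for (i in seq_along(state_ids)) {
      assign(state_ids[i], y[[i]], envir = base_env)
    }
    assign("time", t, envir = base_env)
    assign("t", t, envir = base_env)
    for (i in seq_along(rule_lang)) {
      assign(rule_vars[i], eval(rule_lang[[i]], base_env), envir = base_env)
    }
  }

  rhs <- function(t, y) {
    fill_env(t, y)
    dy <- stats::setNames(numeric(length(state_ids)), state_ids)
    for (i in seq_along(law_lang)) {
      flux <- eval(law_lang[[i]], base_env)
      eff <- rx_effects[[i]]
      for (j in seq_along(eff)) {
        s <- names(eff)[j]
        vol <- get(comp_of[[s]], envir = base_env)
        dy[[s]] <- dy[[s]] + eff[[j]] * flux / vol
      }
    }
    for (i in seq_along(rate_lang)) {
      dy[[rated[i]]] <- dy[[rated[i]]] + eval(rate_lang[[i]], base_env)
    }
    dy
  }

  derived <- function(t, y) {
    fill_env(t, y)
    stats::setNames(vapply(rule_vars, function(v) get(v, envir = base_env),
                           numeric(1)), rule_vars)
  }

  list(state_ids = state_ids, derived_ids = rule_vars, init = init,
       rhs = rhs, derived = derived)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || is.na(a)) b else a

#' Simulate a kinetic model
#'
#' Deterministic adaptive integration with `deSolve::lsoda` (stiff-capable,
#' switching automatically between stiff and non-stiff methods) on an
#' equally spaced time grid.
#'
#' @param m A consistent `kinetic_model`.
#' @param t_end Final time (> 0); integration starts at 0.
#' @param n_points Number of grid points including both endpoints.
#' @param rtol,atol Relative/absolute integrator tolerances.
#' @return A `hyb_trajectory`: list with `time`, `state` (matrix, one
#'   column per state variable) and `derived` (matrix, one column per
#'   assignment-rule variable; zero columns if none).
#' @export
run_model <- function(m, t_end, n_points = 100L, rtol = 1e-8, atol = 1e-10) {
  stopifnot(t_end > 0, n_points >= 2L)
  sys <- build_rhs(m)
  times <- seq(0, t_end, length.out = n_points)
  if (length(sys$state_ids) == 0L) {
    state <- matrix(numeric(0), nrow = n_points, ncol = 0L)
  } else {
    f <- function(t, y, parms) list(unname(sys$rhs(t, y)))
    sol <- deSolve::lsoda(y = sys$init, times = times, func = f, parms = NULL,
                          rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1L] < 0L) {
      stop("integration failed near t = ", max(sol[, 1L]), call. = FALSE)
    }
    state <- unname(sol[, -1L, drop = FALSE])
    colnames(state) <- sys$state_ids
    if (any(!is.finite(state))) {
      stop("non-finite values in trajectory", call. = FALSE)
    }
  }
  nd <- length(sys$derived_ids)
  derived <- matrix(NA_real_, nrow = n_points, ncol = nd,
                    dimnames = list(NULL, sys$derived_ids))
  if (nd > 0L) {
    for (i in seq_len(n_points)) {
      derived[i, ] <- sys$derived(times[i], state[i, ])
    }
  }
  structure(list(time = times, state = state, derived = derived),
            class = "hyb_trajectory")
}

#' @export
print.hyb_trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d points, t in [%g, %g]\n", length(x$time),
              min(x$time), max(x$time)))
  cat("  state: ", paste(colnames(x$state), collapse = ", "), "\n", sep = "")
  if (ncol(x$derived) > 0L) {
    cat("  derived: ", paste(colnames(x$derived), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
as.data.frame.hyb_trajectory <- function(x, ...) {
  data.frame(time = x$time, x$state, x$derived, check.names = FALSE)
}

#' Export a trajectory as CSV
#'
#' Header row of column ids (`time` first), one row per time point.
#'
#' @param traj A `hyb_trajectory`.
#' @param path Output path (written atomically).
#' @return The path, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  df <- as.data.frame(traj)
  lines <- c(paste(colnames(df), collapse = ","),
             apply(df, 1L, function(row) {
               paste(vapply(row, fmt_dbl, character(1)), collapse = ",")
             }))
  atomic_write(paste0(paste(lines, collapse = "\n"), "\n"), path)
  invisible(path)
}

#' Compare two trajectories on a shared grid
#'
#' @param t1,t2 `hyb_trajectory` objects on identical time grids.
#' @param tol Pass threshold for the maximum absolute difference.
#' @return List with `per_column` (named max-abs differences over the
#'   shared columns), `max` (their maximum; 0 when no shared columns) and
#'   `pass` (`max <= tol`).
#' @export
compare_trajectories <- function(t1, t2, tol = 1e-8) {
  if (length(t1$time) != length(t2$time) ||
      max(abs(t1$time - t2$time)) > 1e-12 * max(1, max(abs(t1$time)))) {
    stop("time grids differ", call. = FALSE)
  }
  m1 <- cbind(t1$state, t1$derived)
  m2 <- cbind(t2$state, t2$derived)
  shared <- intersect(colnames(m1), colnames(m2))
  per <- vapply(shared, function(cn) max(abs(m1[, cn] - m2[, cn])), numeric(1))
  mx <- if (length(per) == 0L) 0 else max(per)
  list(per_column = per, max = mx, pass = mx <= tol)
}
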
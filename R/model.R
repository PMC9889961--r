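# In-memory mechanistic model shared by the SBML and HMOD readers/writers.
#
# A kinetic_model is a plain list of named component lists, each keyed by id.
# There is a single flat identifier namespace across compartments, species,
# parameters and reactions; SBML-local kinetic-law parameters are hoisted
# into it on read.

PARAM_ORIGINS <- c("mechanistic", "ml-weight", "ml-bias", "ml-scaling")

#' Compartment constructor
#'
#' @param id Identifier.
#' @param size Positive volume (arbitrary units).
#' @param constant Logical; compartments are constant by default.
#' @param name Display name (free text).
#' @return A compartment record.
#' @export
kin_compartment <- function(id, size = 1, constant = TRUE, name = id) {
  list(id = id, name = name, size = as.numeric(size), constant = isTRUE(constant))
}

#' Species constructor
#'
#' @param id Identifier.
#' @param compartment Id of the containing compartment.
#' @param init Initial concentration (non-negative).
#' @param boundary Logical boundary-condition flag: boundary species are
#'   not changed by reaction stoichiometry.
#' @param constant Logical; constant species never change at all.
#' @param name Display name.
#' @return A species record.
#' @export
kin_species <- function(id, compartment, init = 0, boundary = FALSE,
                        constant = FALSE, name = id) {
  list(id = id, name = name, compartment = compartment,
       init = as.numeric(init), boundary = isTRUE(boundary),
       constant = isTRUE(constant))
}

#' Parameter constructor
#'
#' @param id Identifier.
#' @param value Numeric value.
#' @param constant Logical; non-constant parameters may be governed by rules.
#' @param origin One of `mechanistic`, `ml-weight`, `ml-bias`, `ml-scaling`;
#'   tags constants generated by ANN compilation.
#' @return A parameter record.
#' @export
kin_parameter <- function(id, value, constant = TRUE, origin = "mechanistic") {
  origin <- match.arg(origin, PARAM_ORIGINS)
  list(id = id, value = as.numeric(value), constant = isTRUE(constant),
       origin = origin)
}

#' Reaction constructor
#'
#' @param id Identifier.
#' @param reactants,products Named numeric vectors (names = species ids,
#'   values = positive stoichiometries); may be empty.
#' @param law Kinetic law, a `hyb_expr` or infix string.
#' @param reversible Logical flag (informational; the law carries the math).
#' @return A reaction record.
#' @export
kin_reaction <- function(id, reactants = numeric(0), products = numeric(0),
                         law, reversible = FALSE) {
  if (is.character(law)) law <- parse_infix(law)
  list(id = id, reactants = reactants, products = products,
       reversible = isTRUE(reversible), law = law)
}

#' Rate-rule constructor
#'
#' @param variable Id of the species or parameter whose time derivative
#'   the rule sets.
#' @param expr A `hyb_expr` or infix string.
#' @return A rate-rule record.
#' @export
kin_rate_rule <- function(variable, expr) {
  if (is.character(expr)) expr <- parse_infix(expr)
  list(variable = variable, expr = expr)
}

#' Assignment-rule constructor
#'
#' @param variable Id of the species or parameter set algebraically.
#' @param expr A `hyb_expr` or infix string.
#' @return An assignment-rule record.
#' @export
kin_assignment_rule <- function(variable, expr) {
  if (is.character(expr)) expr <- parse_infix(expr)
  list(variable = variable, expr = expr)
}

#' Kinetic model constructor
#'
#' @param id Model identifier.
#' @param compartments,species,parameters,reactions Lists of records from
#'   the corresponding constructors (any order; re-keyed by id).
#' @param rate_rules,assignment_rules Lists of rule records; assignment
#'   rules keep declaration order, which must admit a topological order.
#' @param name Display name.
#' @param notes Free-text notes carried through conversions.
#' @return A `kinetic_model` object.
#' @export
kinetic_model <- function(id, compartments = list(), species = list(),
                          parameters = list(), reactions = list(),
                          rate_rules = list(), assignment_rules = list(),
                          name = id, notes = "") {
  key_by_id <- function(lst) {
    if (length(lst) == 0L) return(stats::setNames(list(), character(0)))
    stats::setNames(lst, vapply(lst, `[[`, character(1), "id"))
  }
  structure(list(
    id = id, name = name,
    compartments = key_by_id(compartments),
    species = key_by_id(species),
    parameters = key_by_id(parameters),
    reactions = key_by_id(reactions),
    rate_rules = rate_rules,
    assignment_rules = assignment_rules,
    notes = notes), class = "kinetic_model")
}

#' @export
print.kinetic_model <- function(x, ...) {
  cat(sprintf("<kinetic_model> %s (%s)\n", x$id,
              if (nzchar(x$name)) x$name else "unnamed"))
  cat(sprintf("  compartments: %d  species: %d  parameters: %d  reactions: %d\n",
              length(x$compartments), length(x$species),
              length(x$parameters), length(x$reactions)))
  cat(sprintf("  rate rules: %d  assignment rules: %d\n",
              length(x$rate_rules), length(x$assignment_rules)))
  invisible(x)
}

model_ids <- function(m) {
  c(names(m$compartments), names(m$species), names(m$parameters),
    names(m$reactions))
}

## ---- validation report -----------------------------------------------------

#' Build a validation report
#'
#' @param severity,code,location,message Parallel character vectors (may be
#'   empty). Entries are sorted by location then code for deterministic
#'   output.
#' @return A `hyb_report`, a data.frame with one row per issue.
#' @export
validation_report <- function(severity = character(0), code = character(0),
                              location = character(0), message = character(0)) {
  df <- data.frame(severity = severity, code = code, location = location,
                   message = message, stringsAsFactors = FALSE)
  if (nrow(df) > 0L) df <- df[order(df$location, df$code), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("hyb_report", "data.frame")
  df
}

report_add <- function(report, severity, code, location, message) {
  validation_report(c(report$severity, severity), c(report$code, code),
                    c(report$location, location), c(report$message, message))
}

rbind_reports <- function(...) {
  parts <- list(...)
  validation_report(
    unlist(lapply(parts, `[[`, "severity")),
    unlist(lapply(parts, `[[`, "code")),
    unlist(lapply(parts, `[[`, "location")),
    unlist(lapply(parts, `[[`, "message")))
}

#' Does a report contain no errors?
#'
#' @param report A `hyb_report`.
#' @return TRUE if no ERROR-severity entries are present (warnings allowed).
#' @export
report_ok <- function(report) {
  !any(report$severity == "ERROR")
}

#' @export
print.hyb_report <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("<validation report> clean\n")
  } else {
    cat(sprintf("<validation report> %d issue(s)\n", nrow(x)))
    for (i in seq_len(nrow(x))) {
      cat(sprintf("  %s %s [%s] %s\n", x$severity[i], x$code[i],
                  x$location[i], x$message[i]))
    }
  }
  invisible(x)
}

## ---- consistency -----------------------------------------------------------

#' Check the internal consistency of a kinetic model
#'
#' Detects duplicate identifiers, dangling cross-references, unresolved
#' symbols in kinetic laws and rules, variables determined twice (rate
#' rule vs reactions vs assignment rule), assignment-rule cycles,
#' non-positive compartment sizes, negative initial concentrations and
#' non-positive stoichiometries. Problems are report rows, never errors.
#'
#' @param m A `kinetic_model`.
#' @return A `hyb_report`; empty iff the model is consistent.
#' @export
check_consistency <- function(m) {
  sev <- character(0); code <- character(0); loc <- character(0); msg <- character(0)
  note <- function(s, c, l, t) {
    sev <<- c(sev, s); code <<- c(code, c); loc <<- c(loc, l); msg <<- c(msg, t)
  }

  ids <- model_ids(m)
  dup <- unique(ids[duplicated(ids)])
  for (d in dup) note("ERROR", "DUPLICATE_ID", d, "identifier declared more than once")

  known <- unique(ids)
  resolvable <- function(e) setdiff(expr_symbols(e), known)

  for (cp in m$compartments) {
    if (!is.finite(cp$size) || cp$size <= 0) {
      note("ERROR", "NEGATIVE_SIZE", cp$id, "compartment size must be > 0")
    }
  }
  for (sp in m$species) {
    if (!sp$compartment %in% names(m$compartments)) {
      note("ERROR", "DANGLING_REF", sp$id,
           paste0("unknown compartment '", sp$compartment, "'"))
    }
    if (!is.finite(sp$init) || sp$init < 0) {
      note("ERROR", "NEGATIVE_CONCENTRATION", sp$id,
           "initial concentration must be >= 0")
    }
  }
  for (rx in m$reactions) {
    for (side in c("reactants", "products")) {
      st <- rx[[side]]
      for (i in seq_along(st)) {
        spid <- names(st)[i]
        if (!spid %in% names(m$species)) {
          note("ERROR", "DANGLING_REF", rx$id,
               paste0("unknown species '", spid, "' in ", side))
        }
        if (!is.finite(st[[i]]) || st[[i]] <= 0) {
          note("ERROR", "BAD_STOICHIOMETRY", rx$id,
               paste0("stoichiometry for '", spid, "' must be > 0"))
        }
      }
    }
    for (u in resolvable(rx$law)) {
      note("ERROR", "DANGLING_REF", rx$id,
           paste0("kinetic law references undeclared symbol '", u, "'"))
    }
  }

  assigned <- vapply(m$assignment_rules, `[[`, character(1), "variable")
  rated <- vapply(m$rate_rules, `[[`, character(1), "variable")
  reaction_determined <- unique(unlist(lapply(m$reactions, function(rx) {
    sp <- c(names(rx$reactants), names(rx$products))
    sp[vapply(sp, function(s) {
      rec <- m$species[[s]]
      !is.null(rec) && !rec$boundary && !rec$constant
    }, logical(1))]
  })))

  dup_assign <- unique(assigned[duplicated(assigned)])
  for (d in dup_assign) note("ERROR", "DUPLICATE_RULE", d, "variable assigned by two rules")
  dup_rate <- unique(rated[duplicated(rated)])
  for (d in dup_rate) note("ERROR", "DUPLICATE_RULE", d, "variable rate-ruled twice")

  for (rr in m$rate_rules) {
    v <- rr$variable
    if (!v %in% known) {
      note("ERROR", "DANGLING_REF", v, "rate rule targets undeclared variable")
    }
    if (v %in% assigned) {
      note("ERROR", "RULE_CONFLICT", v, "variable has both rate and assignment rules")
    }
    if (v %in% reaction_determined) {
      note("ERROR", "RULE_CONFLICT", v,
           "variable determined by both reactions and a rate rule")
    }
    for (u in resolvable(rr$expr)) {
      note("ERROR", "DANGLING_REF", v,
           paste0("rate rule references undeclared symbol '", u, "'"))
    }
  }
  for (ar in m$assignment_rules) {
    v <- ar$variable
    if (!v %in% known) {
      note("ERROR", "DANGLING_REF", v, "assignment rule targets undeclared variable")
    }
    if (v %in% reaction_determined) {
      note("ERROR", "RULE_CONFLICT", v,
           "variable determined by both reactions and an assignment rule")
    }
    for (u in resolvable(ar$expr)) {
      note("ERROR", "DANGLING_REF", v,
           paste0("assignment rule references undeclared symbol '", u, "'"))
    }
  }

  cyc <- assignment_cycle(m$assignment_rules)
  if (!is.null(cyc)) {
    note("ERROR", "ASSIGNMENT_CYCLE", cyc[1L],
         paste0("assignment rules form a cycle: ", paste(cyc, collapse = " -> ")))
  }

  validation_report(sev, code, loc, msg)
}

# Returns NULL if acyclic, else a character vector tracing one cycle.
assignment_cycle <- function(rules) {
  vars <- vapply(rules, `[[`, character(1), "variable")
  deps <- lapply(rules, function(r) intersect(expr_symbols(r$expr), vars))
  names(deps) <- vars
  state <- stats::setNames(rep(0L, length(vars)), vars)  # 0 new, 1 open, 2 done
  stack <- character(0)
  found <- NULL
  visit <- function(v) {
    if (!is.null(found)) return()
    if (state[[v]] == 1L) {
      i <- match(v, stack)
      found <<- c(stack[seq(i, length(stack))], v)
      return()
    }
    if (state[[v]] == 2L) return()
    state[[v]] <<- 1L
    stack <<- c(stack, v)
    for (d in deps[[v]]) visit(d)
    stack <<- stack[-length(stack)]
    state[[v]] <<- 2L
  }
  for (v in vars) visit(v)
  found
}

#' Topologically order the assignment rules
#'
#' Orders rules so that every assignment-determined symbol a rule reads is
#' computed earlier. Stable: ties are broken by declaration order (Kahn's
#' algorithm with a declaration-ordered frontier).
#'
#' @param m A `kinetic_model` (or a bare list of assignment-rule records).
#' @return The reordered list of assignment rules.
#' @export
topo_order_assignments <- function(m) {
  rules <- if (inherits(m, "kinetic_model")) m$assignment_rules else m
  n <- length(rules)
  if (n <= 1L) return(rules)
  vars <- vapply(rules, `[[`, character(1), "variable")
  cyc <- assignment_cycle(rules)
  if (!is.null(cyc)) {
    stop("assignment rules form a cycle: ", paste(cyc, collapse = " -> "),
         call. = FALSE)
  }
  deps <- lapply(rules, function(r) intersect(expr_symbols(r$expr), vars))
  placed <- rep(FALSE, n)
  out <- vector("list", n)
  k <- 0L
  while (k < n) {
    progressed <- FALSE
    for (i in seq_len(n)) {
      if (placed[i]) next
      if (all(deps[[i]] %in% vars[placed])) {
        k <- k + 1L
        out[[k]] <- rules[[i]]
        placed[i] <- TRUE
        progressed <- TRUE
      }
    }
    if (!progressed) stop("assignment rules form a cycle", call. = FALSE)
  }
  out
}
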
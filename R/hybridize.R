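# Compile a feedforward ANN into SBML-encodable constructs: every weight
# and bias becomes a constant parameter, every scaled input / hidden node /
# output node becomes an assignment rule, and targeted reaction rates are
# replaced by the output-node symbol (optionally times a retained
# mechanistic factor). The resulting model is a hybrid semiparametric
# model expressible in plain SBML.

#' Compile an ANN into a kinetic model
#'
#' Adds one constant parameter per weight (`annW_<l>_<i>_<j>`, origin
#' `ml-weight`) and bias (`annB_<l>_<i>`, origin `ml-bias`), one
#' assignment rule per scaled input (`annX_<i>`), hidden node
#' (`annH_<l>_<i>`) and output node (`annY_<k>`), and rewires each output
#' target: a `reaction-rate` target's kinetic law becomes `annY_<k>`
#' (times the declared factor, if any); a `parameter` target becomes
#' non-constant and assignment-ruled to `annY_<k>`. Generated ids that
#' would collide with existing ids get a deterministic `_h1`, `_h2`, ...
#' suffix (applied to the whole generated family).
#'
#' @param m A consistent `kinetic_model`.
#' @param a An `ann_spec` whose input ids are species/parameters of `m`
#'   and whose output targets exist in `m`.
#' @return A list with elements `model` (the hybrid `kinetic_model`) and
#'   `plan` (a `hybridization_plan` needed by [dehybridize()]).
#' @export
hybridize <- function(m, a) {
  validate_ann(a)
  rep <- check_consistency(m)
  if (!report_ok(rep)) stop("model is not consistent", call. = FALSE)
  for (id in a$inputs$id) {
    if (!id %in% c(names(m$species), names(m$parameters))) {
      stop("ANN input '", id, "' is not a species or parameter of the model",
           call. = FALSE)
    }
  }
  for (k in seq_len(nrow(a$outputs))) {
    kind <- a$outputs$kind[k]; tid <- a$outputs$id[k]
    pool <- if (kind == "reaction-rate") names(m$reactions) else names(m$parameters)
    if (!tid %in% pool) {
      stop("ANN output target ", kind, " '", tid, "' not found in model",
           call. = FALSE)
    }
  }

  shape <- ann_shape(a)
  n_in <- shape[1L]
  n_layers <- length(a$layers)

  # deterministic suffix making the whole generated family collision-free
  existing <- model_ids(m)
  gen_ids_with <- function(sfx) {
    ids <- character(0)
    for (i in seq_len(n_in)) ids <- c(ids, paste0("annX_", i, sfx))
    for (l in seq_len(n_layers)) {
      sz <- nrow(a$layers[[l]]$W)
      for (i in seq_len(sz)) {
        ids <- c(ids, paste0("annB_", l, "_", i, sfx))
        for (j in seq_len(ncol(a$layers[[l]]$W))) {
          ids <- c(ids, paste0("annW_", l, "_", i, "_", j, sfx))
        }
        node <- if (l == n_layers) paste0("annY_", i, sfx)
                else paste0("annH_", l, "_", i, sfx)
        ids <- c(ids, node)
      }
    }
    ids
  }
  sfx <- ""
  tries <- 0L
  while (any(gen_ids_with(sfx) %in% existing)) {
    tries <- tries + 1L
    if (tries > 99L) stop("could not find a collision-free id suffix", call. = FALSE)
    sfx <- paste0("_h", tries)
  }
  gid <- function(...) paste0(..., sfx)

  new_params <- list()
  new_rules <- list()

  # scaled inputs: annX_i := (x_i - min_i) / (max_i - min_i)
  for (i in seq_len(n_in)) {
    scaled <- e_call("/",
      e_call("-", e_sym(a$inputs$id[i]), e_const(a$inputs$min[i])),
      e_call("-", e_const(a$inputs$max[i]), e_const(a$inputs$min[i])))
    new_rules[[length(new_rules) + 1L]] <-
      kin_assignment_rule(gid("annX_", i), scaled)
    new_params[[length(new_params) + 1L]] <-
      kin_parameter(gid("annX_", i), 0, constant = FALSE, origin = "ml-scaling")
  }

  prev_syms <- vapply(seq_len(n_in), function(i) gid("annX_", i), character(1))
  for (l in seq_len(n_layers)) {
    ly <- a$layers[[l]]
    sz <- nrow(ly$W)
    node_syms <- character(sz)
    for (i in seq_len(sz)) {
      node <- if (l == n_layers) gid("annY_", i) else gid("annH_", l, "_", i)
      node_syms[i] <- node
      terms <- NULL
      for (j in seq_len(ncol(ly$W))) {
        wid <- gid("annW_", l, "_", i, "_", j)
        new_params[[length(new_params) + 1L]] <-
          kin_parameter(wid, ly$W[i, j], origin = "ml-weight")
        term <- e_call("*", e_sym(wid), e_sym(prev_syms[j]))
        terms <- if (is.null(terms)) term else e_call("+", terms, term)
      }
      bid <- gid("annB_", l, "_", i)
      new_params[[length(new_params) + 1L]] <-
        kin_parameter(bid, ly$b[i], origin = "ml-bias")
      affine <- e_call("+", terms, e_sym(bid))
      body <- if (ly$activation == "tanh") e_call("tanh", affine) else affine
      new_rules[[length(new_rules) + 1L]] <- kin_assignment_rule(node, body)
      new_params[[length(new_params) + 1L]] <-
        kin_parameter(node, 0, constant = FALSE, origin = "ml-scaling")
    }
    prev_syms <- node_syms
  }

  original_laws <- list()
  h <- m
  for (p in new_params) {
    # node-value holders double as parameters so assignment targets exist;
    # weight/bias parameters are the trainable constants
    h$parameters[[p$id]] <- p
  }
  for (k in seq_len(nrow(a$outputs))) {
    ysym <- gid("annY_", k)
    fac <- a$outputs$factor[k]
    value <- if (is.na(fac)) e_sym(ysym) else
      e_call("*", e_sym(ysym), parse_infix(fac))
    if (a$outputs$kind[k] == "reaction-rate") {
      rid <- a$outputs$id[k]
      original_laws[[rid]] <- h$reactions[[rid]]$law
      h$reactions[[rid]]$law <- value
    } else {
      pid <- a$outputs$id[k]
      original_laws[[pid]] <- NULL
      h$parameters[[pid]]$constant <- FALSE
      new_rules[[length(new_rules) + 1L]] <- kin_assignment_rule(pid, value)
    }
  }
  h$assignment_rules <- c(h$assignment_rules, new_rules)
  h$assignment_rules <- topo_order_assignments(h$assignment_rules)

  plan <- structure(list(
    suffix = sfx,
    input_ids = a$inputs$id,
    bounds = a$inputs[, c("min", "max"), drop = FALSE],
    layer_sizes = vapply(a$layers, function(l) nrow(l$W), integer(1)),
    activations = vapply(a$layers, `[[`, character(1), "activation"),
    outputs = a$outputs,
    param_ids = vapply(new_params, `[[`, character(1), "id"),
    rule_ids = vapply(new_rules, `[[`, character(1), "variable"),
    original_laws = original_laws), class = "hybridization_plan")

  final_rep <- check_consistency(h)
  if (!report_ok(final_rep)) {
    stop("internal error: hybridized model is inconsistent", call. = FALSE)
  }
  list(model = h, plan = plan)
}

#' @export
print.hybridization_plan <- function(x, ...) {
  cat("<hybridization_plan> shape ",
      paste(c(length(x$input_ids), x$layer_sizes), collapse = "-"),
      if (nzchar(x$suffix)) paste0(", suffix '", x$suffix, "'"), "\n", sep = "")
  cat("  ", length(x$param_ids), " generated parameters, ",
      length(x$rule_ids), " generated rules\n", sep = "")
  invisible(x)
}

#' Split a hybrid model back into mechanistic model + ANN
#'
#' Inverse of [hybridize()]: reads the weight/bias values back out of the
#' generated parameters (bit-exact), removes every generated parameter and
#' rule, restores the original kinetic laws recorded in the plan (a plan
#' recovered from a foreign hybrid SBML has none; the reaction then gets a
#' literal-0 placeholder law that re-hybridization overwrites).
#'
#' @param m A hybrid `kinetic_model` containing the plan's generated symbols.
#' @param plan A `hybridization_plan`.
#' @return A list with elements `model` (mechanistic `kinetic_model`) and
#'   `ann` (the recovered `ann_spec`).
#' @export
dehybridize <- function(m, plan) {
  missing <- setdiff(plan$param_ids, names(m$parameters))
  rule_vars <- vapply(m$assignment_rules, `[[`, character(1), "variable")
  missing <- c(missing, setdiff(plan$rule_ids, rule_vars))
  if (length(missing) > 0L) {
    stop("model lacks generated symbols from the plan: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  sfx <- plan$suffix
  gid <- function(...) paste0(..., sfx)
  n_in <- length(plan$input_ids)
  n_layers <- length(plan$layer_sizes)

  # scaling bounds: prefer exact literals from the annX rules
  bounds <- plan$bounds
  for (i in seq_len(n_in)) {
    r <- m$assignment_rules[[match(gid("annX_", i), rule_vars)]]
    bx <- extract_scaling_bounds(r$expr)
    if (!is.null(bx)) {
      bounds$min[i] <- bx[1L]
      bounds$max[i] <- bx[2L]
    }
  }

  layers <- vector("list", n_layers)
  prev <- n_in
  for (l in seq_len(n_layers)) {
    sz <- plan$layer_sizes[l]
    W <- matrix(NA_real_, nrow = sz, ncol = prev)
    b <- numeric(sz)
    for (i in seq_len(sz)) {
      for (j in seq_len(prev)) {
        W[i, j] <- m$parameters[[gid("annW_", l, "_", i, "_", j)]]$value
      }
      b[i] <- m$parameters[[gid("annB_", l, "_", i)]]$value
    }
    layers[[l]] <- list(W = W, b = b, activation = plan$activations[l])
    prev <- sz
  }

  a <- ann_spec(
    inputs = data.frame(id = plan$input_ids, min = bounds$min,
                        max = bounds$max, stringsAsFactors = FALSE),
    layers = layers, outputs = plan$outputs)

  mm <- m
  mm$parameters <- mm$parameters[setdiff(names(mm$parameters), plan$param_ids)]
  mm$assignment_rules <- mm$assignment_rules[!rule_vars %in% plan$rule_ids]
  for (k in seq_len(nrow(plan$outputs))) {
    if (plan$outputs$kind[k] == "reaction-rate") {
      rid <- plan$outputs$id[k]
      law <- plan$original_laws[[rid]]
      mm$reactions[[rid]]$law <- if (is.null(law)) e_num(0) else law
    } else {
      pid <- plan$outputs$id[k]
      mm$parameters[[pid]]$constant <- TRUE
    }
  }
  list(model = mm, ann = a)
}

# matches (x - min)/(max - min) with numeric-literal bounds; returns
# c(min, max) or NULL
extract_scaling_bounds <- function(e) {
  lit <- function(x) {
    if (x$kind == "num") return(x$value)
    if (x$kind == "call" && x$name == "neg" && x$args[[1L]]$kind == "num") {
      return(-x$args[[1L]]$value)
    }
    NULL
  }
  if (e$kind != "call" || e$name != "/") return(NULL)
  numr <- e$args[[1L]]; den <- e$args[[2L]]
  if (numr$kind != "call" || numr$name != "-") return(NULL)
  if (den$kind != "call" || den$name != "-") return(NULL)
  mn <- lit(numr$args[[2L]])
  mx <- lit(den$args[[1L]])
  mn2 <- lit(den$args[[2L]])
  if (is.null(mn) || is.null(mx) || is.null(mn2)) return(NULL)
  if (!identical(mn, mn2)) return(NULL)
  c(mn, mx)
}

#' Recognize the generated ANN structure inside a hybrid model
#'
#' Scans a model for the `annX_/annH_/annY_/annW_/annB_` symbol families
#' written by [hybridize()] (any deterministic collision suffix) and
#' reconstructs a `hybridization_plan`, enabling a hybrid SBML document to
#' be split back into mechanistic + ANN parts with [dehybridize()].
#'
#' @param m A `kinetic_model`.
#' @return A `hybridization_plan`, or `NULL` when no generated structure
#'   is found.
#' @export
recover_plan <- function(m) {
  rule_vars <- vapply(m$assignment_rules, `[[`, character(1), "variable")
  ym <- regmatches(rule_vars, regexec("^annY_([0-9]+)(_h[0-9]+)?$", rule_vars))
  yhits <- which(vapply(ym, length, integer(1)) == 3L)
  if (length(yhits) == 0L) return(NULL)
  sfx <- ym[[yhits[1L]]][3L]
  esc <- function(s) gsub("([][{}()+*^$\\\\.|?])", "\\\\\\1", s)
  sx <- esc(sfx)

  grab <- function(re) {
    mm <- regmatches(rule_vars, regexec(re, rule_vars))
    hits <- which(vapply(mm, length, integer(1)) > 1L)
    list(idx = hits, m = mm[hits])
  }
  xs <- grab(paste0("^annX_([0-9]+)", sx, "$"))
  n_in <- length(xs$idx)
  if (n_in == 0L) return(NULL)

  hs <- grab(paste0("^annH_([0-9]+)_([0-9]+)", sx, "$"))
  hidden_layers <- if (length(hs$idx) > 0L) {
    ls <- as.integer(vapply(hs$m, `[[`, character(1), 2L))
    is <- as.integer(vapply(hs$m, `[[`, character(1), 3L))
    vapply(seq_len(max(ls)), function(l) max(is[ls == l]), integer(1))
  } else integer(0)
  n_out <- length(grab(paste0("^annY_([0-9]+)", sx, "$"))$idx)
  layer_sizes <- c(hidden_layers, n_out)
  n_layers <- length(layer_sizes)

  # input ids from the annX rule expressions; activations from node bodies
  gid <- function(...) paste0(..., sfx)
  input_ids <- character(n_in)
  for (i in seq_len(n_in)) {
    r <- m$assignment_rules[[match(gid("annX_", i), rule_vars)]]
    syms <- expr_symbols(r$expr)
    if (length(syms) != 1L) return(NULL)
    input_ids[i] <- syms
  }
  activations <- character(n_layers)
  for (l in seq_len(n_layers)) {
    node <- if (l == n_layers) gid("annY_", 1L) else gid("annH_", l, "_", 1L)
    r <- m$assignment_rules[[match(node, rule_vars)]]
    activations[l] <- if (r$expr$kind == "call" && r$expr$name == "tanh") "tanh"
                      else "linear"
  }

  # output targets: reactions whose whole law is annY_k (optionally *factor),
  # or parameters assignment-ruled to annY_k
  outputs <- data.frame(kind = character(0), id = character(0),
                        factor = character(0), stringsAsFactors = FALSE)
  for (k in seq_len(n_out)) {
    ysym <- gid("annY_", k)
    found <- FALSE
    for (rx in m$reactions) {
      law <- rx$law
      if (law$kind == "sym" && law$name == ysym) {
        outputs <- rbind(outputs, data.frame(kind = "reaction-rate", id = rx$id,
                                             factor = NA_character_))
        found <- TRUE; break
      }
      if (law$kind == "call" && law$name == "*" &&
          law$args[[1L]]$kind == "sym" && law$args[[1L]]$name == ysym) {
        outputs <- rbind(outputs, data.frame(
          kind = "reaction-rate", id = rx$id,
          factor = write_infix(law$args[[2L]])))
        found <- TRUE; break
      }
    }
    if (!found) {
      for (j in seq_along(m$assignment_rules)) {
        r <- m$assignment_rules[[j]]
        if (r$variable %in% rule_vars[grepl("^ann", rule_vars)]) next
        if (r$expr$kind == "sym" && r$expr$name == ysym) {
          outputs <- rbind(outputs, data.frame(kind = "parameter",
                                               id = r$variable,
                                               factor = NA_character_))
          found <- TRUE; break
        }
      }
    }
    if (!found) return(NULL)
  }

  param_ids <- character(0)
  rule_ids <- character(0)
  for (i in seq_len(n_in)) {
    rule_ids <- c(rule_ids, gid("annX_", i))
    param_ids <- c(param_ids, gid("annX_", i))
  }
  prev <- n_in
  for (l in seq_len(n_layers)) {
    sz <- layer_sizes[l]
    for (i in seq_len(sz)) {
      node <- if (l == n_layers) gid("annY_", i) else gid("annH_", l, "_", i)
      rule_ids <- c(rule_ids, node)
      param_ids <- c(param_ids, node)
      for (j in seq_len(prev)) {
        param_ids <- c(param_ids, gid("annW_", l, "_", i, "_", j))
      }
      param_ids <- c(param_ids, gid("annB_", l, "_", i))
    }
    prev <- sz
  }
  if (!all(param_ids %in% names(m$parameters))) return(NULL)

  # parameter-targeted outputs add one non-generated rule each; include it
  for (k in seq_len(nrow(outputs))) {
    if (outputs$kind[k] == "parameter") {
      rule_ids <- c(rule_ids, outputs$id[k])
    }
  }

  structure(list(
    suffix = sfx,
    input_ids = input_ids,
    bounds = data.frame(min = rep(NA_real_, n_in), max = rep(NA_real_, n_in)),
    layer_sizes = layer_sizes,
    activations = activations,
    outputs = outputs,
    param_ids = param_ids,
    rule_ids = rule_ids,
    original_laws = list()), class = "hybridization_plan")
}
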
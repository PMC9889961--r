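# Seed-deterministic generators of toy mechanistic models, random ANNs,
# rate-mimicking ANNs (random-feature least squares) and a malformed-file
# corpus, so every test and check runs without downloads.

TOY_KINDS <- c("chain", "reversible-pair", "michaelis-menten-pathway",
               "stiff-pair")

#' Generate a toy mechanistic model
#'
#' All kinds use a single compartment of size 1.0 and seeded parameter
#' draws, so the same seed yields byte-identical serializations.
#'
#' * `chain`: A -> B -> 0 mass action (k1, k2 in U\[0.1, 2\]), plus a
#'   species Z fed by a rate rule `k2*B - kz*Z` (exercises rate rules).
#' * `reversible-pair`: A <-> B with law `kf*A - kr*B`; conserves A + B.
#' * `michaelis-menten-pathway`: S -> P with law `Vmax*sat` where the
#'   assignment rule `sat := S/(Km+S)` holds the saturation fraction,
#'   then P -> 0 mass action (exercises assignment rules).
#' * `stiff-pair`: A -> B (k in U\[500, 2000\]) then B -> C (U\[0.1, 1\]);
#'   two well-separated timescales.
#'
#' @param kind One of `chain`, `reversible-pair`,
#'   `michaelis-menten-pathway`, `stiff-pair`.
#' @param seed Integer seed for the parameter draws.
#' @return A consistent `kinetic_model`.
#' @export
make_toy_model <- function(kind = TOY_KINDS, seed = 1L) {
  kind <- match.arg(kind)
  withr::with_seed(seed, {
    cp <- kin_compartment("cell", size = 1)
    switch(kind,
      "chain" = {
        k <- stats::runif(3, 0.1, 2)
        kinetic_model(
          paste0("chain_", seed),
          compartments = list(cp),
          species = list(kin_species("A", "cell", init = 1),
                         kin_species("B", "cell", init = 0),
                         kin_species("Z", "cell", init = 0)),
          parameters = list(kin_parameter("k1", k[1]),
                            kin_parameter("k2", k[2]),
                            kin_parameter("kz", k[3])),
          reactions = list(
            kin_reaction("v1", reactants = c(A = 1), products = c(B = 1),
                         law = "k1*A"),
            kin_reaction("v2", reactants = c(B = 1), law = "k2*B")),
          rate_rules = list(kin_rate_rule("Z", "k2*B - kz*Z")))
      },
      "reversible-pair" = {
        k <- stats::runif(2, 0.1, 2)
        a0 <- stats::runif(1, 0.5, 2)
        b0 <- stats::runif(1, 0, 1)
        kinetic_model(
          paste0("revpair_", seed),
          compartments = list(cp),
          species = list(kin_species("A", "cell", init = a0),
                         kin_species("B", "cell", init = b0)),
          parameters = list(kin_parameter("kf", k[1]),
                            kin_parameter("kr", k[2])),
          reactions = list(
            kin_reaction("v1", reactants = c(A = 1), products = c(B = 1),
                         law = "kf*A - kr*B", reversible = TRUE)))
      },
      "michaelis-menten-pathway" = {
        vmax <- stats::runif(1, 0.5, 2)
        km <- stats::runif(1, 0.2, 1)
        k2 <- stats::runif(1, 0.1, 0.5)
        s0 <- stats::runif(1, 1, 3)
        kinetic_model(
          paste0("mmpath_", seed),
          compartments = list(cp),
          species = list(kin_species("S", "cell", init = s0),
                         kin_species("P", "cell", init = 0)),
          parameters = list(kin_parameter("Vmax", vmax),
                            kin_parameter("Km", km),
                            kin_parameter("k2", k2),
                            kin_parameter("sat", 0, constant = FALSE)),
          reactions = list(
            kin_reaction("v1", reactants = c(S = 1), products = c(P = 1),
                         law = "Vmax*sat"),
            kin_reaction("v2", reactants = c(P = 1), law = "k2*P")),
          assignment_rules = list(kin_assignment_rule("sat", "S/(Km+S)")))
      },
      "stiff-pair" = {
        kf <- stats::runif(1, 500, 2000)
        ks <- stats::runif(1, 0.1, 1)
        kinetic_model(
          paste0("stiff_", seed),
          compartments = list(cp),
          species = list(kin_species("A", "cell", init = 1),
                         kin_species("B", "cell", init = 0),
                         kin_species("C", "cell", init = 0)),
          parameters = list(kin_parameter("kf", kf),
                            kin_parameter("ks", ks)),
          reactions = list(
            kin_reaction("v1", reactants = c(A = 1), products = c(B = 1),
                         law = "kf*A"),
            kin_reaction("v2", reactants = c(B = 1), products = c(C = 1),
                         law = "ks*B")))
      })
  })
}

#' Generate a random feedforward ANN
#'
#' Weights and biases drawn from U(-1, 1); tanh on hidden layers, linear
#' output layer.
#'
#' @param shape Integer vector of layer sizes, inputs first (e.g.
#'   `c(2, 3, 1)` for a 2-3-1 network).
#' @param seed Integer seed.
#' @param input_ids Model symbols fed to the network (default
#'   `x1, x2, ...` with scaling bounds \[0, 1\]).
#' @param outputs Optional outputs data.frame (`kind`, `id`, `factor`);
#'   default targets parameters `yout1, ...`.
#' @param bounds Optional data.frame with `min`, `max` per input.
#' @return An `ann_spec`.
#' @export
make_random_ann <- function(shape, seed = 1L, input_ids = NULL,
                            outputs = NULL, bounds = NULL) {
  stopifnot(length(shape) >= 2L, all(shape >= 1L))
  n_in <- shape[1L]
  if (is.null(input_ids)) input_ids <- paste0("x", seq_len(n_in))
  if (is.null(bounds)) bounds <- data.frame(min = rep(0, n_in), max = rep(1, n_in))
  n_out <- shape[length(shape)]
  if (is.null(outputs)) {
    outputs <- data.frame(kind = rep("parameter", n_out),
                          id = paste0("yout", seq_len(n_out)),
                          factor = NA_character_, stringsAsFactors = FALSE)
  }
  withr::with_seed(seed, {
    layers <- list()
    prev <- n_in
    for (l in seq(2L, length(shape))) {
      sz <- shape[l]
      layers[[l - 1L]] <- list(
        W = matrix(stats::runif(sz * prev, -1, 1), nrow = sz, ncol = prev),
        b = stats::runif(sz, -1, 1),
        activation = if (l == length(shape)) "linear" else "tanh")
      prev <- sz
    }
    ann_spec(inputs = data.frame(id = input_ids, min = bounds$min,
                                 max = bounds$max, stringsAsFactors = FALSE),
             layers = layers, outputs = outputs)
  })
}

#' Fit an ANN that mimics a reaction's rate law
#'
#' Samples the reaction's true rate over the state-space box spanned by a
#' mechanistic trajectory (bounds padded 5%), builds random tanh hidden
#' features and fits only the linear output layer by least squares
#' (extreme-learning-machine style; no iterative training). The achieved
#' maximum absolute fit error over the samples is recorded in
#' `metadata$fit_error`.
#'
#' @param m A consistent `kinetic_model`.
#' @param reaction_id Id of the reaction whose law the ANN should mimic.
#' @param n_hidden Number of hidden tanh units (>= 1).
#' @param seed Integer seed (drives the random features and sample points).
#' @param t_end,n_samples Trajectory horizon for the state box and number
#'   of sampled states for the fit.
#' @return An `ann_spec` targeting `reaction_id`, with `metadata$fit_error`.
#' @export
make_rate_mimicking_ann <- function(m, reaction_id, n_hidden = 20L, seed = 1L,
                                    t_end = 10, n_samples = 200L) {
  stopifnot(n_hidden >= 1L)
  rx <- m$reactions[[reaction_id]]
  if (is.null(rx)) stop("unknown reaction '", reaction_id, "'", call. = FALSE)

  # resolve the law down to state symbols: inline assignment rules
  law <- rx$law
  repeat {
    assigned <- vapply(m$assignment_rules, `[[`, character(1), "variable")
    hit <- intersect(expr_symbols(law), assigned)
    if (length(hit) == 0L) break
    mapping <- stats::setNames(
      lapply(hit, function(v) m$assignment_rules[[match(v, assigned)]]$expr), hit)
    law <- expr_substitute(law, mapping)
  }
  traj <- run_model(m, t_end = t_end, n_points = 100L)
  cols <- colnames(traj$state)
  input_ids <- intersect(expr_symbols(law), cols)
  if (length(input_ids) == 0L) {
    stop("law of '", reaction_id, "' depends on no state variable", call. = FALSE)
  }
  lo <- vapply(input_ids, function(cn) min(traj$state[, cn]), numeric(1))
  hi <- vapply(input_ids, function(cn) max(traj$state[, cn]), numeric(1))
  pad <- pmax(0.05 * (hi - lo), 1e-6)
  lo <- lo - pad
  hi <- hi + pad

  const_env <- c(
    lapply(m$parameters, `[[`, "value"),
    lapply(m$compartments, `[[`, "size"),
    lapply(m$species, `[[`, "init"))

  withr::with_seed(seed, {
    n_in <- length(input_ids)
    X <- matrix(stats::runif(n_samples * n_in), nrow = n_samples)
    X <- sweep(sweep(X, 2L, hi - lo, "*"), 2L, lo, "+")
    y <- apply(X, 1L, function(row) {
      env <- const_env
      env[input_ids] <- as.list(row)
      eval_expr(law, env)
    })
    # random tanh features on the scaled inputs
    W1 <- matrix(stats::runif(n_hidden * n_in, -2, 2), nrow = n_hidden)
    b1 <- stats::runif(n_hidden, -1, 1)
    Xs <- sweep(sweep(X, 2L, lo, "-"), 2L, hi - lo, "/")
    H <- tanh(Xs %*% t(W1) + matrix(b1, n_samples, n_hidden, byrow = TRUE))
    # minimum-norm least squares via truncated SVD: random tanh features of
    # a low-dimensional input are near-collinear, which defeats plain QR
    coefs <- svd_lstsq(cbind(1, H), y)
    W2 <- matrix(coefs[-1L], nrow = 1L)
    b2 <- coefs[[1L]]
    pred <- as.numeric(H %*% t(W2)) + b2
    fit_error <- max(abs(pred - y))

    ann_spec(
      inputs = data.frame(id = input_ids, min = lo, max = hi,
                          stringsAsFactors = FALSE),
      layers = list(list(W = W1, b = b1, activation = "tanh"),
                    list(W = W2, b = b2, activation = "linear")),
      outputs = data.frame(kind = "reaction-rate", id = reaction_id,
                           factor = NA_character_, stringsAsFactors = FALSE),
      metadata = list(fit_error = fit_error, n_samples = n_samples))
  })
}

#' Generate the malformed-file corpus
#'
#' One file per validator error code (12 HMOD, 4 SBML) plus two pristine
#' controls. Deterministic: texts are fixed literals.
#'
#' @param dir Optional directory; when given, files are written there.
#' @return data.frame with columns `filename`, `format`, `code`
#'   (expected first error code, `NA` for the pristine controls) and
#'   `text`.
#' @export
make_malformed_corpus <- function(dir = NULL) {
  h <- function(...) paste(c(...), collapse = "\n")
  base_top <- c("HMOD/1", "model : id=toy, name=toy",
                "[COMPARTMENTS]", "cell : size=1, constant=true, name=cell")
  base_sp <- c("[SPECIES]",
               "A : compartment=cell, init=1, boundary=false, constant=false, name=A")
  base_par <- c("[PARAMETERS]", "k1 : value=0.5, constant=true, origin=mechanistic")
  base_rx <- c("[REACTIONS]",
               "v1 : reversible=false, reactants=A:1, products=none, law=k1*A")
  pristine_hmod <- h(base_top, base_sp, base_par, base_rx)

  ml_ok <- c("[ML]",
             "input_1 : id=A, min=0, max=2",
             "layer_1 : size=2, activation=tanh",
             "w_1_1 : values=0.5", "w_1_2 : values=-0.25",
             "b_1 : values=0.1 -0.1",
             "layer_2 : size=1, activation=linear",
             "w_2_1 : values=1 -1", "b_2 : values=0",
             "output_1 : target=reaction:v1")

  entries <- list(
    list("bad_non_ascii.hmod", "hmod", "NON_ASCII",
         h(base_top, base_sp, base_par, "[REACTIONS]",
           "v1 : reversible=false, reactants=A:1, products=none, law=k1*A # µM")),
    list("bad_header.hmod", "hmod", "BAD_HEADER",
         h("HMOD/9", "model : id=toy, name=toy")),
    list("bad_unknown_block.hmod", "hmod", "UNKNOWN_BLOCK",
         h(base_top, base_sp, "[WEATHER]", "sunny : value=1")),
    list("bad_order.hmod", "hmod", "ORDER_VIOLATION",
         h("HMOD/1", "model : id=toy, name=toy", base_sp[1], base_sp[2],
           "[COMPARTMENTS]", "cell : size=1, constant=true, name=cell")),
    list("bad_record.hmod", "hmod", "BAD_RECORD",
         h(base_top, "this line is not a record")),
    list("bad_identifier.hmod", "hmod", "BAD_IDENTIFIER",
         h("HMOD/1", "model : id=toy, name=toy", "[COMPARTMENTS]",
           "2cell : size=1, constant=true, name=bad")),
    list("bad_number.hmod", "hmod", "BAD_NUMBER",
         h("HMOD/1", "model : id=toy, name=toy", "[COMPARTMENTS]",
           "cell : size=one, constant=true, name=cell")),
    list("bad_missing_field.hmod", "hmod", "MISSING_FIELD",
         h("HMOD/1", "model : id=toy, name=toy", "[COMPARTMENTS]",
           "cell : constant=true, name=cell")),
    list("bad_duplicate_id.hmod", "hmod", "DUPLICATE_ID",
         h(base_top, base_sp, "A : compartment=cell, init=2, boundary=false, constant=false, name=A")),
    list("bad_dangling_ref.hmod", "hmod", "DANGLING_REF",
         h(base_top, base_sp, base_par, "[REACTIONS]",
           "v1 : reversible=false, reactants=A:1, products=none, law=k9*A")),
    list("bad_expression.hmod", "hmod", "BAD_EXPRESSION",
         h(base_top, base_sp, base_par, "[REACTIONS]",
           "v1 : reversible=false, reactants=A:1, products=none, law=k1*(A")),
    list("bad_ann_shape.hmod", "hmod", "ANN_SHAPE_MISMATCH",
         h(pristine_hmod, "[ML]",
           "input_1 : id=A, min=0, max=2",
           "layer_1 : size=3, activation=tanh",
           "w_1_1 : values=0.5 0.5", "w_1_2 : values=0.1 0.1",
           "b_1 : values=0.1 0.2 0.3",
           "layer_2 : size=1, activation=linear",
           "w_2_1 : values=1 1 1", "b_2 : values=0",
           "output_1 : target=reaction:v1")),
    list("bad_activation.hmod", "hmod", "UNSUPPORTED_ACTIVATION",
         h(pristine_hmod, "[ML]",
           "input_1 : id=A, min=0, max=2",
           "layer_1 : size=1, activation=relu",
           "w_1_1 : values=0.5", "b_1 : values=0.1",
           "output_1 : target=reaction:v1")),
    list("pristine.hmod", "hmod", NA_character_,
         h(pristine_hmod, ml_ok)),

    list("bad_namespace.xml", "sbml", "BAD_NAMESPACE",
         '<?xml version="1.0"?><notsbml xmlns="http://example.org/ns"><model id="m"/></notsbml>'),
    list("bad_duplicate_id.xml", "sbml", "DUPLICATE_ID", h(
      '<?xml version="1.0" encoding="UTF-8"?>',
      paste0('<sbml xmlns="', SBML_L3V2_NS, '" level="3" version="2">'),
      '  <model id="m">',
      '    <listOfCompartments><compartment id="c" size="1" constant="true"/></listOfCompartments>',
      '    <listOfSpecies>',
      '      <species id="A" compartment="c" initialConcentration="1" boundaryCondition="false" constant="false"/>',
      '      <species id="A" compartment="c" initialConcentration="2" boundaryCondition="false" constant="false"/>',
      '    </listOfSpecies>',
      '  </model>', '</sbml>')),
    list("bad_dangling_ref.xml", "sbml", "DANGLING_REF", h(
      '<?xml version="1.0" encoding="UTF-8"?>',
      paste0('<sbml xmlns="', SBML_L3V2_NS, '" level="3" version="2">'),
      '  <model id="m">',
      '    <listOfCompartments><compartment id="c" size="1" constant="true"/></listOfCompartments>',
      '    <listOfSpecies>',
      '      <species id="A" compartment="c" initialConcentration="1" boundaryCondition="false" constant="false"/>',
      '    </listOfSpecies>',
      '    <listOfReactions><reaction id="v1" reversible="false">',
      '      <listOfReactants><speciesReference species="A" stoichiometry="1" constant="true"/></listOfReactants>',
      '      <kineticLaw><math xmlns="http://www.w3.org/1998/Math/MathML"><apply><times/><ci>kmissing</ci><ci>A</ci></apply></math></kineticLaw>',
      '    </reaction></listOfReactions>',
      '  </model>', '</sbml>')),
    list("bad_missing_attr.xml", "sbml", "MISSING_ATTR", h(
      '<?xml version="1.0" encoding="UTF-8"?>',
      paste0('<sbml xmlns="', SBML_L3V2_NS, '" level="3" version="2">'),
      '  <model id="m">',
      '    <listOfCompartments><compartment id="c" size="1" constant="true"/></listOfCompartments>',
      '    <listOfSpecies>',
      '      <species id="A" initialConcentration="1" boundaryCondition="false" constant="false"/>',
      '    </listOfSpecies>',
      '  </model>', '</sbml>')),
    list("bad_math.xml", "sbml", "BAD_MATH", h(
      '<?xml version="1.0" encoding="UTF-8"?>',
      paste0('<sbml xmlns="', SBML_L3V2_NS, '" level="3" version="2">'),
      '  <model id="m">',
      '    <listOfCompartments><compartment id="c" size="1" constant="true"/></listOfCompartments>',
      '    <listOfSpecies>',
      '      <species id="A" compartment="c" initialConcentration="1" boundaryCondition="false" constant="false"/>',
      '    </listOfSpecies>',
      '    <listOfReactions><reaction id="v1" reversible="false">',
      '      <kineticLaw><math xmlns="http://www.w3.org/1998/Math/MathML"><apply><factorial/><ci>A</ci></apply></math></kineticLaw>',
      '    </reaction></listOfReactions>',
      '  </model>', '</sbml>')),
    list("pristine.xml", "sbml", NA_character_,
         write_sbml(make_toy_model("chain", seed = 1L)))
  )

  df <- data.frame(
    filename = vapply(entries, `[[`, character(1), 1L),
    format = vapply(entries, `[[`, character(1), 2L),
    code = vapply(entries, `[[`, character(1), 3L),
    text = vapply(entries, function(e) paste0(e[[4L]], "\n"), character(1)),
    stringsAsFactors = FALSE)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (i in seq_len(nrow(df))) {
      atomic_write(df$text[i], file.path(dir, df$filename[i]))
    }
  }
  df
}

# minimum-norm least-squares solution of A x ~= y, singular values below
# rcond * max(d) truncated
svd_lstsq <- function(A, y, rcond = 1e-10) {
  sv <- svd(A)
  keep <- sv$d > rcond * sv$d[1L]
  coef <- sv$v[, keep, drop = FALSE] %*%
    ((crossprod(sv$u[, keep, drop = FALSE], y)) / sv$d[keep])
  as.numeric(coef)
}
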
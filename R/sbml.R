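# SBML subset reader/writer.
#
# Write target is Level 3 Version 2; read accepts Level 2 (Version >= 3) and
# Level 3 documents. Only the constructs representable in kinetic_model are
# mapped; events and constraints are dropped with a warning entry. Species
# quantities are canonically concentrations: initialAmount inputs are
# divided by the compartment size on read.

SBML_L3V2_NS <- "http://www.sbml.org/sbml/level3/version2/core"

xattr <- function(node, name) xml2::xml_attr(node, name)

xml_escape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  s <- gsub(">", "&gt;", s, fixed = TRUE)
  gsub('"', "&quot;", s, fixed = TRUE)
}

sbml_level <- function(doc) {
  ns <- xml2::xml_ns(doc)
  root_ns <- tryCatch(xml2::xml_attr(xml2::xml_root(doc), "xmlns"),
                      error = function(e) NA)
  uri <- as.character(ns)[1L]
  m <- regmatches(uri, regexec("sbml/level(\\d+)", uri))[[1L]]
  if (length(m) == 2L) as.integer(m[2L]) else NA_integer_
}

# children of `node` with local name `name` (namespace-agnostic)
xkids <- function(node, name) {
  if (is.null(node)) return(list())
  kids <- xml2::xml_children(node)
  kids[vapply(kids, function(k) xname(k) == name, logical(1))]
}

xkid1 <- function(node, name) {
  k <- xkids(node, name)
  if (length(k) == 0L) NULL else k[[1L]]
}

#' Read an SBML document into a kinetic model
#'
#' Maps compartments, species, parameters, reactions (kinetic laws via the
#' content-MathML parser) and rate/assignment rules. Kinetic-law local
#' parameters are hoisted to global parameters with ids
#' `<reactionId>__<localId>` and the law rewritten accordingly. Species
#' declared with `initialAmount` are converted to concentrations using the
#' compartment size. Unsupported elements (events, constraints, function
#' definitions) yield WARN entries with code `UNSUPPORTED_DROPPED`.
#'
#' @param x Path to an SBML file, an XML string, or an `xml2` document.
#' @return A list with elements `model` (a `kinetic_model`) and `report`
#'   (a `hyb_report`).
#' @export
read_sbml <- function(x) {
  doc <- as_xml_doc(x)
  root <- xml2::xml_root(doc)
  if (xname(root) != "sbml") {
    stop("not an SBML document: root element is <", xname(root), ">", call. = FALSE)
  }
  lvl <- sbml_level(doc)
  if (is.na(lvl)) stop("root element is not in an SBML namespace", call. = FALSE)
  if (!lvl %in% c(2L, 3L)) stop("unsupported SBML level ", lvl, call. = FALSE)

  model_node <- xkid1(root, "model")
  if (is.null(model_node)) stop("SBML document has no <model> element", call. = FALSE)

  rep <- validation_report()
  warn <- function(code, loc, msg) rep <<- report_add(rep, "WARN", code, loc, msg)

  mid <- xattr(model_node, "id")
  if (is.na(mid)) mid <- "model"
  mname <- xattr(model_node, "name")
  if (is.na(mname)) mname <- mid

  notes <- ""
  notes_node <- xkid1(model_node, "notes")
  if (!is.null(notes_node)) notes <- trimws(xml2::xml_text(notes_node))

  for (unsup in c("listOfEvents", "listOfConstraints", "listOfFunctionDefinitions")) {
    if (!is.null(xkid1(model_node, unsup))) {
      warn("UNSUPPORTED_DROPPED", unsup,
           paste0("<", unsup, "> is not supported and was dropped"))
    }
  }

  comps <- lapply(xkids(xkid1(model_node, "listOfCompartments"), "compartment"),
    function(nd) {
      id <- req_attr(nd, "id", "compartment")
      size <- as.numeric(xattr(nd, "size"))
      if (is.na(size)) size <- 1
      nm <- xattr(nd, "name")
      kin_compartment(id, size = size,
                      constant = !identical(xattr(nd, "constant"), "false"),
                      name = if (is.na(nm)) id else nm)
    })

  comp_sizes <- stats::setNames(
    vapply(comps, `[[`, numeric(1), "size"),
    vapply(comps, `[[`, character(1), "id"))

  species <- lapply(xkids(xkid1(model_node, "listOfSpecies"), "species"),
    function(nd) {
      id <- req_attr(nd, "id", "species")
      compartment <- req_attr(nd, "compartment", paste0("species '", id, "'"))
      conc <- as.numeric(xattr(nd, "initialConcentration"))
      if (is.na(conc)) {
        amt <- as.numeric(xattr(nd, "initialAmount"))
        if (!is.na(amt)) {
          vol <- comp_sizes[[compartment]]
          if (is.null(vol) || is.na(vol)) vol <- 1
          conc <- amt / vol
        } else {
          conc <- 0
        }
      }
      nm <- xattr(nd, "name")
      kin_species(id, compartment, init = conc,
                  boundary = identical(xattr(nd, "boundaryCondition"), "true"),
                  constant = identical(xattr(nd, "constant"), "true"),
                  name = if (is.na(nm)) id else nm)
    })

  params <- lapply(xkids(xkid1(model_node, "listOfParameters"), "parameter"),
    function(nd) {
      id <- req_attr(nd, "id", "parameter")
      val <- as.numeric(xattr(nd, "value"))
      if (is.na(val)) val <- 0
      origin <- "mechanistic"
      pn <- xkid1(nd, "notes")
      if (!is.null(pn)) {
        txt <- trimws(xml2::xml_text(pn))
        if (txt %in% PARAM_ORIGINS) origin <- txt
      }
      kin_parameter(id, val,
                    constant = !identical(xattr(nd, "constant"), "false"),
                    origin = origin)
    })

  reactions <- list()
  for (nd in xkids(xkid1(model_node, "listOfReactions"), "reaction")) {
    id <- req_attr(nd, "id", "reaction")
    side <- function(list_name) {
      refs <- xkids(xkid1(nd, list_name), "speciesReference")
      st <- vapply(refs, function(r) {
        s <- as.numeric(xattr(r, "stoichiometry"))
        if (is.na(s)) 1 else s
      }, numeric(1))
      names(st) <- vapply(refs, function(r) req_attr(r, "species", "speciesReference"),
                          character(1))
      st
    }
    kl <- xkid1(nd, "kineticLaw")
    if (is.null(kl)) stop("reaction '", id, "' has no kineticLaw", call. = FALSE)
    math <- xkid1(kl, "math")
    if (is.null(math)) stop("kineticLaw of '", id, "' has no <math>", call. = FALSE)
    law <- parse_mathml(math)
    # hoist local parameters into the global namespace
    loc_lists <- c(xkids(kl, "listOfLocalParameters"), xkids(kl, "listOfParameters"))
    for (ll in loc_lists) {
      for (lp in xml2::xml_children(ll)) {
        lid <- req_attr(lp, "id", paste0("local parameter of '", id, "'"))
        gid <- paste0(id, "__", lid)
        val <- as.numeric(xattr(lp, "value"))
        if (is.na(val)) val <- 0
        params[[length(params) + 1L]] <- kin_parameter(gid, val)
        law <- expr_substitute(law, stats::setNames(gid, lid))
      }
    }
    reactions[[length(reactions) + 1L]] <-
      kin_reaction(id, reactants = side("listOfReactants"),
                   products = side("listOfProducts"), law = law,
                   reversible = identical(xattr(nd, "reversible"), "true"))
  }

  rate_rules <- list()
  assignment_rules <- list()
  for (nd in xkids(xkid1(model_node, "listOfRules"), "assignmentRule")) {
    v <- req_attr(nd, "variable", "assignmentRule")
    assignment_rules[[length(assignment_rules) + 1L]] <-
      kin_assignment_rule(v, parse_mathml(xkid1(nd, "math")))
  }
  for (nd in xkids(xkid1(model_node, "listOfRules"), "rateRule")) {
    v <- req_attr(nd, "variable", "rateRule")
    rate_rules[[length(rate_rules) + 1L]] <-
      kin_rate_rule(v, parse_mathml(xkid1(nd, "math")))
  }
  for (nd in xkids(xkid1(model_node, "listOfRules"), "algebraicRule")) {
    warn("UNSUPPORTED_DROPPED", "algebraicRule",
         "algebraic rules are not supported and were dropped")
  }

  m <- kinetic_model(mid, compartments = comps, species = species,
                     parameters = params, reactions = reactions,
                     rate_rules = rate_rules,
                     assignment_rules = assignment_rules,
                     name = mname, notes = notes)
  list(model = m, report = rep)
}

req_attr <- function(node, name, what) {
  v <- xattr(node, name)
  if (is.na(v)) {
    stop("missing required attribute '", name, "' on ", what, call. = FALSE)
  }
  v
}

as_xml_doc <- function(x) {
  if (inherits(x, "xml_document")) return(x)
  if (is.character(x) && length(x) == 1L) {
    if (grepl("^\\s*<", x)) return(xml2::read_xml(x))
    if (!file.exists(x)) stop("file not found: ", x, call. = FALSE)
    return(xml2::read_xml(x))
  }
  stop("expected an xml2 document, XML string or file path", call. = FALSE)
}

## ---- writer ----------------------------------------------------------------

#' Write a kinetic model as SBML Level 3 Version 2
#'
#' Refuses inconsistent models (see [check_consistency()]). Assignment
#' rules are emitted in topological order; parameters with an `ml-*`
#' origin carry a notes tag marking them as machine-learning constants so
#' the information survives a round trip.
#'
#' @param m A `kinetic_model`.
#' @param path Optional output file path; when given, the document is
#'   written atomically (temp file + rename).
#' @return The SBML document as a character string (invisibly when `path`
#'   is given).
#' @export
write_sbml <- function(m, path = NULL) {
  rep <- check_consistency(m)
  if (!report_ok(rep)) {
    stop("refusing to write inconsistent model:\n",
         paste(sprintf("  %s %s [%s] %s", rep$severity, rep$code,
                       rep$location, rep$message), collapse = "\n"),
         call. = FALSE)
  }
  out <- character(0)
  push <- function(...) out <<- c(out, paste0(...))
  math_block <- function(e, indent) {
    paste0(indent, write_mathml(e))
  }

  push('<?xml version="1.0" encoding="UTF-8"?>')
  push('<sbml xmlns="', SBML_L3V2_NS, '" level="3" version="2">')
  push('  <model id="', xml_escape(m$id), '" name="', xml_escape(m$name), '">')
  if (nzchar(m$notes)) {
    push('    <notes><body xmlns="http://www.w3.org/1999/xhtml"><p>',
         xml_escape(m$notes), "</p></body></notes>")
  }
  if (length(m$compartments) > 0L) {
    push("    <listOfCompartments>")
    for (cp in m$compartments) {
      push('      <compartment id="', cp$id, '" name="', xml_escape(cp$name),
           '" size="', fmt_dbl(cp$size), '" spatialDimensions="3" constant="',
           tolower(cp$constant), '"/>')
    }
    push("    </listOfCompartments>")
  }
  if (length(m$species) > 0L) {
    push("    <listOfSpecies>")
    for (sp in m$species) {
      push('      <species id="', sp$id, '" name="', xml_escape(sp$name),
           '" compartment="', sp$compartment,
           '" initialConcentration="', fmt_dbl(sp$init),
           '" hasOnlySubstanceUnits="false" boundaryCondition="',
           tolower(sp$boundary), '" constant="', tolower(sp$constant), '"/>')
    }
    push("    </listOfSpecies>")
  }
  if (length(m$parameters) > 0L) {
    push("    <listOfParameters>")
    for (p in m$parameters) {
      if (p$origin == "mechanistic") {
        push('      <parameter id="', p$id, '" value="', fmt_dbl(p$value),
             '" constant="', tolower(p$constant), '"/>')
      } else {
        push('      <parameter id="', p$id, '" value="', fmt_dbl(p$value),
             '" constant="', tolower(p$constant), '">')
        push('        <notes><body xmlns="http://www.w3.org/1999/xhtml"><p>',
             p$origin, "</p></body></notes>")
        push("      </parameter>")
      }
    }
    push("    </listOfParameters>")
  }
  rules <- c(
    lapply(topo_order_assignments(m), function(r) list(kind = "assignmentRule", r = r)),
    lapply(m$rate_rules, function(r) list(kind = "rateRule", r = r)))
  if (length(rules) > 0L) {
    push("    <listOfRules>")
    for (item in rules) {
      push('      <', item$kind, ' variable="', item$r$variable, '">')
      push(math_block(item$r$expr, "        "))
      push("      </", item$kind, ">")
    }
    push("    </listOfRules>")
  }
  if (length(m$reactions) > 0L) {
    push("    <listOfReactions>")
    for (rx in m$reactions) {
      push('      <reaction id="', rx$id, '" reversible="',
           tolower(rx$reversible), '">')
      side <- function(st, tag) {
        if (length(st) == 0L) return()
        push("        <", tag, ">")
        for (i in seq_along(st)) {
          push('          <speciesReference species="', names(st)[i],
               '" stoichiometry="', fmt_dbl(st[[i]]), '" constant="true"/>')
        }
        push("        </", tag, ">")
      }
      side(rx$reactants, "listOfReactants")
      side(rx$products, "listOfProducts")
      push("        <kineticLaw>")
      push(math_block(rx$law, "          "))
      push("        </kineticLaw>")
      push("      </reaction>")
    }
    push("    </listOfReactions>")
  }
  push("  </model>")
  push("</sbml>")
  txt <- paste0(paste(out, collapse = "\n"), "\n")
  if (!is.null(path)) {
    atomic_write(txt, path)
    return(invisible(txt))
  }
  txt
}

## ---- structural validator --------------------------------------------------

#' Structurally validate an SBML document
#'
#' Checks the namespace, presence of a model element, required attributes,
#' identifier syntax, duplicate ids, MathML parseability and symbol
#' resolution of kinetic laws and rules. All findings are report entries;
#' an empty report means the document reads without warnings.
#'
#' @param x Path, XML string or `xml2` document.
#' @return A `hyb_report`.
#' @export
validate_sbml_structure <- function(x) {
  doc <- tryCatch(as_xml_doc(x), error = function(e) e)
  if (inherits(doc, "error")) {
    return(validation_report("ERROR", "NOT_XML", "document",
                             conditionMessage(doc)))
  }
  root <- xml2::xml_root(doc)
  if (xname(root) != "sbml" || is.na(sbml_level(doc))) {
    return(validation_report("ERROR", "BAD_NAMESPACE", "document",
                             "root element is not SBML"))
  }
  rep <- validation_report()
  note <- function(s, c, l, t) rep <<- report_add(rep, s, c, l, t)

  model_node <- xkid1(root, "model")
  if (is.null(model_node)) {
    return(report_add(rep, "ERROR", "MISSING_ELEMENT", "sbml",
                      "no <model> element"))
  }

  ids <- character(0)
  collect_id <- function(nd, what, attr = "id") {
    id <- xattr(nd, attr)
    if (is.na(id)) {
      note("ERROR", "MISSING_ATTR", what,
           paste0("missing required '", attr, "' attribute"))
      return(NA_character_)
    }
    if (!grepl(ID_RE, id)) {
      note("ERROR", "BAD_IDENTIFIER", what, paste0("invalid id '", id, "'"))
    }
    ids <<- c(ids, id)
    id
  }
  for (nd in xkids(xkid1(model_node, "listOfCompartments"), "compartment")) {
    collect_id(nd, "compartment")
  }
  for (nd in xkids(xkid1(model_node, "listOfSpecies"), "species")) {
    id <- collect_id(nd, "species")
    if (!is.na(id) && is.na(xattr(nd, "compartment"))) {
      note("ERROR", "MISSING_ATTR", id, "species without 'compartment' attribute")
    }
  }
  for (nd in xkids(xkid1(model_node, "listOfParameters"), "parameter")) {
    collect_id(nd, "parameter")
  }
  rx_nodes <- xkids(xkid1(model_node, "listOfReactions"), "reaction")
  for (nd in rx_nodes) collect_id(nd, "reaction")

  dup <- unique(ids[duplicated(ids)])
  for (d in dup) note("ERROR", "DUPLICATE_ID", d, "identifier declared more than once")

  check_math <- function(container, loc) {
    math <- xkid1(container, "math")
    if (is.null(math)) {
      note("ERROR", "MISSING_ELEMENT", loc, "no <math> element")
      return()
    }
    e <- tryCatch(parse_mathml(math), error = function(err) err)
    if (inherits(e, "error")) {
      note("ERROR", "BAD_MATH", loc, conditionMessage(e))
      return()
    }
    # local parameters also count as in scope
    local_ids <- vapply(
      c(xkids(xkid1(container, "listOfLocalParameters"), "localParameter"),
        xkids(xkid1(container, "listOfParameters"), "parameter")),
      function(lp) {
        v <- xattr(lp, "id")
        if (is.na(v)) "" else v
      }, character(1))
    for (u in setdiff(expr_symbols(e), c(ids, local_ids, "time", "t"))) {
      note("ERROR", "DANGLING_REF", loc,
           paste0("math references undefined symbol '", u, "'"))
    }
  }
  for (nd in rx_nodes) {
    id <- xattr(nd, "id")
    kl <- xkid1(nd, "kineticLaw")
    if (is.null(kl)) {
      note("ERROR", "MISSING_ELEMENT", if (is.na(id)) "reaction" else id,
           "reaction without kineticLaw")
    } else {
      check_math(kl, if (is.na(id)) "reaction" else id)
    }
  }
  for (nd in c(xkids(xkid1(model_node, "listOfRules"), "assignmentRule"),
               xkids(xkid1(model_node, "listOfRules"), "rateRule"))) {
    v <- xattr(nd, "variable")
    if (is.na(v)) {
      note("ERROR", "MISSING_ATTR", xname(nd), "rule without 'variable' attribute")
      next
    }
    check_math(nd, v)
  }
  rep
}

atomic_write <- function(text, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tmp <- tempfile(tmpdir = dir, fileext = ".tmp")
  con <- file(tmp, open = "wb")
  ok <- FALSE
  tryCatch({
    writeChar(text, con, eos = NULL)
    close(con)
    ok <- TRUE
  }, finally = if (!ok && isOpen(con)) close(con))
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}
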
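# HMOD text format: parser, canonical serializer and validator.
# The normative grammar is HMOD-SPEC.md at the repository root.

HMOD_BLOCK_ORDER <- c("COMPARTMENTS", "SPECIES", "PARAMETERS", "REACTIONS",
                      "RATE_RULES", "ASSIGNMENT_RULES", "ML")

read_text_lines <- function(x) {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    return(readLines(x, warn = FALSE))
  }
  if (length(x) == 1L) return(strsplit(x, "\n", fixed = TRUE)[[1L]])
  as.character(x)
}

strip_comments <- function(lines) {
  sub("#.*$", "", lines)
}

parse_strict_number <- function(s) {
  s <- trimws(s)
  if (!grepl("^[+-]?(?:[0-9]+(?:\\.[0-9]*)?|\\.[0-9]+)(?:[eE][+-]?[0-9]+)?$", s)) {
    return(NA_real_)
  }
  as.numeric(s)
}

parse_number_list <- function(s) {
  parts <- strsplit(trimws(s), "[ \t]+")[[1L]]
  vapply(parts, parse_strict_number, numeric(1), USE.NAMES = FALSE)
}

parse_bool <- function(s) {
  s <- trimws(s)
  if (s == "true") return(TRUE)
  if (s == "false") return(FALSE)
  NA
}

# `id : field=value, field=value` -> list(id, fields, line); on failure
# list(id = NULL, line, message)
parse_record_line <- function(line, lineno) {
  # the id token is any run of non-blank, non-separator characters;
  # identifier syntax is enforced by the caller (BAD_IDENTIFIER, not
  # BAD_RECORD, for things like `2cell : ...`)
  m <- regexec("^\\s*([^\\s:,=]+)\\s*:\\s*(.*)$", line, perl = TRUE)
  g <- regmatches(line, m)[[1L]]
  if (length(g) != 3L) {
    return(list(id = NULL, line = lineno,
                message = paste0("not a record line: '", trimws(line), "'")))
  }
  id <- g[2L]
  rest <- g[3L]
  # field starts: `key=` at string start or after a comma
  starts <- gregexpr("(?:^|,)\\s*([A-Za-z_][A-Za-z0-9_]*)=", rest, perl = TRUE)[[1L]]
  if (starts[1L] == -1L) {
    if (nzchar(trimws(rest))) {
      return(list(id = NULL, line = lineno,
                  message = paste0("record '", id, "' has no field=value pairs")))
    }
    return(list(id = id, fields = stats::setNames(character(0), character(0)),
                line = lineno))
  }
  keys <- character(0); vals <- character(0)
  n <- length(starts)
  for (i in seq_len(n)) {
    seg_start <- starts[i]
    seg_end <- if (i < n) starts[i + 1L] - 1L else nchar(rest)
    seg <- substr(rest, seg_start, seg_end)
    seg <- sub("^,", "", seg)
    eq <- regexpr("=", seg, fixed = TRUE)
    keys <- c(keys, trimws(substr(seg, 1L, eq - 1L)))
    v <- substr(seg, eq + 1L, nchar(seg))
    vals <- c(vals, trimws(sub(",\\s*$", "", v)))
  }
  list(id = id, fields = stats::setNames(vals, keys), line = lineno)
}

#' Parse an HMOD document
#'
#' Problems never raise conditions: everything is collected into the
#' report, and the model/ann slots are `NULL` when errors make the
#' document unusable. Expressions are parsed with [parse_infix()]; after
#' structural parsing the assembled model is run through
#' [check_consistency()] and those findings are merged into the report.
#'
#' @param x Path to an `.hmod` file or the document text.
#' @return A list with elements `model` (a `kinetic_model` or `NULL`),
#'   `ann` (an `ann_spec` or `NULL`) and `report` (a `hyb_report`).
#' @export
parse_hmod <- function(x) {
  raw_lines <- read_text_lines(x)
  rep <- validation_report()
  note <- function(s, c, l, t) rep <<- report_add(rep, s, c, l, t)
  fail <- function() list(model = NULL, ann = NULL, report = rep)

  for (i in seq_along(raw_lines)) {
    if (any(utf8ToInt(enc2utf8(raw_lines[i])) > 127L)) {
      note("ERROR", "NON_ASCII", sprintf("file:%04d", i),
           "non-ASCII byte in line")
    }
  }
  if (!report_ok(rep)) return(fail())

  lines <- strip_comments(raw_lines)
  idx <- which(nzchar(trimws(lines)))
  if (length(idx) == 0L) {
    note("ERROR", "BAD_HEADER", "file:0000", "empty document")
    return(fail())
  }
  header <- trimws(lines[idx[1L]])
  hm <- regmatches(header, regexec("^HMOD/([0-9]+)$", header))[[1L]]
  if (length(hm) != 2L) {
    note("ERROR", "BAD_HEADER", sprintf("file:%04d", idx[1L]),
         paste0("expected 'HMOD/1' header, got '", header, "'"))
    return(fail())
  }
  if (hm[2L] != "1") {
    note("ERROR", "BAD_HEADER", sprintf("file:%04d", idx[1L]),
         paste0("unsupported HMOD major version ", hm[2L]))
    return(fail())
  }
  idx <- idx[-1L]

  model_id <- NULL; model_name <- NULL
  block <- NULL
  seen_blocks <- character(0)
  comps <- list(); species <- list(); params <- list(); reactions <- list()
  rate_rules <- list(); assignment_rules <- list()
  ml_records <- list()
  defined <- character(0)

  locate <- function(i) sprintf("%s:%04d", if (is.null(block)) "file"
                                else tolower(block), i)

  expect_bool <- function(r, field, default = NA) {
    f <- r$fields
    if (!field %in% names(f)) {
      if (!is.na(default)) return(default)
      note("ERROR", "MISSING_FIELD", locate(r$line),
           paste0("record '", r$id, "' lacks field '", field, "'"))
      return(NA)
    }
    b <- parse_bool(f[[field]])
    if (is.na(b)) {
      note("ERROR", "BAD_RECORD", locate(r$line),
           paste0("field '", field, "' must be true or false"))
    }
    b
  }
  expect_num <- function(r, field) {
    f <- r$fields
    if (!field %in% names(f)) {
      note("ERROR", "MISSING_FIELD", locate(r$line),
           paste0("record '", r$id, "' lacks field '", field, "'"))
      return(NA_real_)
    }
    v <- parse_strict_number(f[[field]])
    if (is.na(v)) {
      note("ERROR", "BAD_NUMBER", locate(r$line),
           paste0("field '", field, "' is not a number: '", f[[field]], "'"))
    }
    v
  }
  expect_str <- function(r, field, default = NULL) {
    f <- r$fields
    if (!field %in% names(f)) {
      if (!is.null(default)) return(default)
      note("ERROR", "MISSING_FIELD", locate(r$line),
           paste0("record '", r$id, "' lacks field '", field, "'"))
      return(NA_character_)
    }
    f[[field]]
  }
  expect_expr <- function(r, field) {
    s <- expect_str(r, field)
    if (is.na(s)) return(NULL)
    e <- tryCatch(parse_infix(s), error = function(err) err)
    if (inherits(e, "error")) {
      note("ERROR", "BAD_EXPRESSION", locate(r$line),
           paste0("cannot parse '", s, "': ", conditionMessage(e)))
      return(NULL)
    }
    e
  }
  check_new_id <- function(id, lineno) {
    if (!grepl(ID_RE, id)) {
      note("ERROR", "BAD_IDENTIFIER", locate(lineno),
           paste0("invalid identifier '", id, "'"))
      return(FALSE)
    }
    if (id %in% defined) {
      note("ERROR", "DUPLICATE_ID", locate(lineno),
           paste0("identifier '", id, "' already defined"))
      return(FALSE)
    }
    defined <<- c(defined, id)
    TRUE
  }
  check_ref <- function(id, lineno, what) {
    if (!id %in% defined) {
      note("ERROR", "DANGLING_REF", locate(lineno),
           paste0(what, " references undefined identifier '", id, "'"))
      return(FALSE)
    }
    TRUE
  }
  parse_stoich <- function(s, lineno, what) {
    s <- trimws(s)
    if (s == "none" || !nzchar(s)) return(numeric(0))
    parts <- strsplit(s, "[ \t]+")[[1L]]
    out <- numeric(0)
    for (p in parts) {
      kv <- strsplit(p, ":", fixed = TRUE)[[1L]]
      if (length(kv) != 2L) {
        note("ERROR", "BAD_RECORD", locate(lineno),
             paste0(what, " entry must be species:stoichiometry, got '", p, "'"))
        next
      }
      st <- parse_strict_number(kv[2L])
      if (is.na(st)) {
        note("ERROR", "BAD_NUMBER", locate(lineno),
             paste0("bad stoichiometry '", kv[2L], "'"))
        next
      }
      check_ref(kv[1L], lineno, what)
      out[kv[1L]] <- st
    }
    out
  }

  for (i in idx) {
    line <- trimws(lines[i])
    bm <- regmatches(line, regexec("^\\[([A-Za-z_]+)\\]$", line))[[1L]]
    if (length(bm) == 2L) {
      b <- bm[2L]
      if (!b %in% HMOD_BLOCK_ORDER) {
        note("ERROR", "UNKNOWN_BLOCK", sprintf("file:%04d", i),
             paste0("unknown block [", b, "]"))
        block <- b  # records inside are still attributed somewhere
        next
      }
      pos <- match(b, HMOD_BLOCK_ORDER)
      prev_pos <- if (length(seen_blocks) == 0L) 0L else
        max(match(seen_blocks, HMOD_BLOCK_ORDER))
      if (b %in% seen_blocks) {
        note("ERROR", "ORDER_VIOLATION", sprintf("file:%04d", i),
             paste0("block [", b, "] appears twice"))
      } else if (pos <= prev_pos) {
        note("ERROR", "ORDER_VIOLATION", sprintf("file:%04d", i),
             paste0("block [", b, "] out of order"))
      }
      seen_blocks <- c(seen_blocks, b)
      block <- b
      next
    }

    r <- parse_record_line(lines[i], i)
    if (is.null(r$id)) {
      note("ERROR", "BAD_RECORD", locate(i), r$message)
      next
    }

    if (is.null(block)) {
      if (r$id == "model") {
        if (!is.null(model_id)) {
          note("ERROR", "BAD_RECORD", locate(i), "duplicate model line")
          next
        }
        model_id <- expect_str(r, "id")
        model_name <- expect_str(r, "name", default = model_id)
        if (!is.na(model_id) && !grepl(ID_RE, model_id)) {
          note("ERROR", "BAD_IDENTIFIER", locate(i),
               paste0("invalid model id '", model_id, "'"))
        }
      } else {
        note("ERROR", "ORDER_VIOLATION", locate(i),
             paste0("record '", r$id, "' before any block header"))
      }
      next
    }

    switch(block,
      COMPARTMENTS = {
        if (check_new_id(r$id, i)) {
          comps[[length(comps) + 1L]] <- kin_compartment(
            r$id, size = expect_num(r, "size"),
            constant = expect_bool(r, "constant", default = TRUE),
            name = expect_str(r, "name", default = r$id))
        }
      },
      SPECIES = {
        cid <- expect_str(r, "compartment")
        if (!is.na(cid)) check_ref(cid, i, paste0("species '", r$id, "'"))
        if (check_new_id(r$id, i)) {
          species[[length(species) + 1L]] <- kin_species(
            r$id, compartment = cid, init = expect_num(r, "init"),
            boundary = expect_bool(r, "boundary", default = FALSE),
            constant = expect_bool(r, "constant", default = FALSE),
            name = expect_str(r, "name", default = r$id))
        }
      },
      PARAMETERS = {
        origin <- expect_str(r, "origin", default = "mechanistic")
        if (!origin %in% PARAM_ORIGINS) {
          note("ERROR", "BAD_RECORD", locate(i),
               paste0("unknown parameter origin '", origin, "'"))
          origin <- "mechanistic"
        }
        if (check_new_id(r$id, i)) {
          params[[length(params) + 1L]] <- kin_parameter(
            r$id, value = expect_num(r, "value"),
            constant = expect_bool(r, "constant", default = TRUE),
            origin = origin)
        }
      },
      REACTIONS = {
        law <- expect_expr(r, "law")
        reactants <- parse_stoich(expect_str(r, "reactants", default = "none"),
                                  i, "reactants")
        products <- parse_stoich(expect_str(r, "products", default = "none"),
                                 i, "products")
        if (!is.null(law)) {
          for (u in setdiff(expr_symbols(law), defined)) {
            note("ERROR", "DANGLING_REF", locate(i),
                 paste0("law references undefined identifier '", u, "'"))
          }
        }
        if (check_new_id(r$id, i) && !is.null(law)) {
          reactions[[length(reactions) + 1L]] <- kin_reaction(
            r$id, reactants = reactants, products = products, law = law,
            reversible = expect_bool(r, "reversible", default = FALSE))
        }
      },
      RATE_RULES = {
        e <- expect_expr(r, "expr")
        check_ref(r$id, i, "rate rule")
        if (!is.null(e)) {
          for (u in setdiff(expr_symbols(e), defined)) {
            note("ERROR", "DANGLING_REF", locate(i),
                 paste0("expr references undefined identifier '", u, "'"))
          }
          rate_rules[[length(rate_rules) + 1L]] <- kin_rate_rule(r$id, e)
        }
      },
      ASSIGNMENT_RULES = {
        e <- expect_expr(r, "expr")
        check_ref(r$id, i, "assignment rule")
        if (!is.null(e)) {
          vars_so_far <- c(defined,
                           vapply(assignment_rules, `[[`, character(1), "variable"))
          for (u in setdiff(expr_symbols(e), vars_so_far)) {
            note("ERROR", "DANGLING_REF", locate(i),
                 paste0("expr references undefined identifier '", u, "'"))
          }
          assignment_rules[[length(assignment_rules) + 1L]] <-
            kin_assignment_rule(r$id, e)
        }
      },
      ML = {
        ml_records[[length(ml_records) + 1L]] <- r
      },
      {
        # records inside an unknown block: already reported at the header
      })
  }

  if (is.null(model_id) || is.na(model_id)) {
    note("ERROR", "BAD_HEADER", "file:0000", "missing 'model :' line")
  }
  if (!report_ok(rep)) return(fail())

  m <- kinetic_model(model_id, compartments = comps, species = species,
                     parameters = params, reactions = reactions,
                     rate_rules = rate_rules,
                     assignment_rules = assignment_rules,
                     name = model_name)

  ann <- NULL
  if (length(ml_records) > 0L) {
    res <- ann_records_to_spec(ml_records, loc_prefix = "ml")
    rep <- rbind_reports(rep, res$report)
    ann <- res$ann
    if (!is.null(ann)) {
      for (iid in ann$inputs$id) {
        if (!iid %in% c(names(m$species), names(m$parameters))) {
          note("ERROR", "DANGLING_REF", "ml",
               paste0("ann input '", iid, "' is not a species or parameter"))
        }
      }
      for (k in seq_len(nrow(ann$outputs))) {
        pool <- if (ann$outputs$kind[k] == "reaction-rate") names(m$reactions)
                else names(m$parameters)
        if (!ann$outputs$id[k] %in% pool) {
          note("ERROR", "DANGLING_REF", "ml",
               paste0("ann output target '", ann$outputs$id[k], "' not found"))
        }
      }
    }
  }

  rep <- rbind_reports(rep, check_consistency(m))
  if (!report_ok(rep)) return(list(model = NULL, ann = NULL, report = rep))
  list(model = m, ann = ann, report = rep)
}

#' Serialize a kinetic model (plus optional ANN) to canonical HMOD text
#'
#' Canonical form: fixed block order, stable field order, one space
#' around `:` and after `,`, shortest round-trip numerics, assignment
#' rules in topological order, no comments. Serialization is
#' byte-deterministic: the same model yields the same text.
#'
#' @param m A consistent `kinetic_model`.
#' @param ann Optional `ann_spec` written as the `[ML]` block.
#' @param path Optional output path (written atomically).
#' @return HMOD text (invisibly when `path` is given).
#' @export
serialize_hmod <- function(m, ann = NULL, path = NULL) {
  rep <- check_consistency(m)
  if (!report_ok(rep)) {
    stop("refusing to serialize inconsistent model:\n",
         paste(sprintf("  %s %s [%s] %s", rep$severity, rep$code,
                       rep$location, rep$message), collapse = "\n"),
         call. = FALSE)
  }
  out <- c("HMOD/1",
           sprintf("model : id=%s, name=%s", m$id, m$name))
  if (length(m$compartments) > 0L) {
    out <- c(out, "[COMPARTMENTS]")
    for (cp in m$compartments) {
      out <- c(out, sprintf("%s : size=%s, constant=%s, name=%s", cp$id,
                            fmt_dbl(cp$size), tolower(cp$constant), cp$name))
    }
  }
  if (length(m$species) > 0L) {
    out <- c(out, "[SPECIES]")
    for (sp in m$species) {
      out <- c(out, sprintf(
        "%s : compartment=%s, init=%s, boundary=%s, constant=%s, name=%s",
        sp$id, sp$compartment, fmt_dbl(sp$init), tolower(sp$boundary),
        tolower(sp$constant), sp$name))
    }
  }
  if (length(m$parameters) > 0L) {
    out <- c(out, "[PARAMETERS]")
    for (p in m$parameters) {
      out <- c(out, sprintf("%s : value=%s, constant=%s, origin=%s", p$id,
                            fmt_dbl(p$value), tolower(p$constant), p$origin))
    }
  }
  if (length(m$reactions) > 0L) {
    out <- c(out, "[REACTIONS]")
    stoich_str <- function(st) {
      if (length(st) == 0L) return("none")
      paste(sprintf("%s:%s", names(st),
                    vapply(unname(st), fmt_dbl, character(1))), collapse = " ")
    }
    for (rx in m$reactions) {
      out <- c(out, sprintf(
        "%s : reversible=%s, reactants=%s, products=%s, law=%s", rx$id,
        tolower(rx$reversible), stoich_str(rx$reactants),
        stoich_str(rx$products), write_infix(rx$law)))
    }
  }
  if (length(m$rate_rules) > 0L) {
    out <- c(out, "[RATE_RULES]")
    for (rr in m$rate_rules) {
      out <- c(out, sprintf("%s : expr=%s", rr$variable, write_infix(rr$expr)))
    }
  }
  if (length(m$assignment_rules) > 0L) {
    out <- c(out, "[ASSIGNMENT_RULES]")
    for (ar in topo_order_assignments(m)) {
      out <- c(out, sprintf("%s : expr=%s", ar$variable, write_infix(ar$expr)))
    }
  }
  if (!is.null(ann)) {
    out <- c(out, "[ML]", ann_spec_to_records(ann))
  }
  txt <- paste0(paste(out, collapse = "\n"), "\n")
  if (grepl("[^\\x01-\\x7F]", txt, perl = TRUE)) {
    stop("model contains non-ASCII text; HMOD is ASCII-only", call. = FALSE)
  }
  if (!is.null(path)) {
    atomic_write(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Validate an HMOD document
#'
#' Runs the full parser in report-only mode: line grammar per block,
#' identifier syntax, definition-before-use, numeric and expression
#' parseability, ml-block shape consistency, then model-level
#' consistency. An empty report means [parse_hmod()] succeeds cleanly.
#'
#' @param x Path to an `.hmod` file or the document text.
#' @return A `hyb_report`.
#' @export
validate_hmod <- function(x) {
  parse_hmod(x)$report
}
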
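# Feedforward ANN specification: layer weights/biases, activations,
# input/output variable mappings and min-max input scaling. Weights arrive
# trained; no training happens here.

ANN_ACTIVATIONS <- c("tanh", "linear")

#' Feedforward ANN specification
#'
#' @param inputs data.frame with columns `id` (model symbol fed to the
#'   network), `min`, `max` (min-max scaling bounds, `max > min`); inputs
#'   are scaled to `[0,1]` before the first layer.
#' @param layers List of layers, each `list(W, b, activation)`: `W` a
#'   matrix with `rows = this layer size`, `cols = previous layer size`
#'   (first layer: number of inputs), `b` a bias vector of length `rows`,
#'   `activation` either `"tanh"` or `"linear"`.
#' @param outputs data.frame with columns `kind` (`"reaction-rate"` or
#'   `"parameter"`), `id` (target in the model) and optionally `factor`
#'   (infix string for a retained multiplicative mechanistic factor, or
#'   `NA`). One row per node of the last layer.
#' @param metadata Free-form list (e.g. recorded fit error for
#'   rate-mimicking networks).
#' @return An `ann_spec` object.
#' @export
ann_spec <- function(inputs, layers, outputs, metadata = list()) {
  inputs <- as.data.frame(inputs, stringsAsFactors = FALSE)
  outputs <- as.data.frame(outputs, stringsAsFactors = FALSE)
  if (!"factor" %in% names(outputs)) outputs$factor <- NA_character_
  a <- structure(list(inputs = inputs, layers = layers, outputs = outputs,
                      metadata = metadata), class = "ann_spec")
  validate_ann(a)
  a
}

validate_ann <- function(a) {
  stopifnot(nrow(a$inputs) >= 1L, length(a$layers) >= 1L)
  if (any(a$inputs$max <= a$inputs$min)) {
    stop("input scaling requires max > min", call. = FALSE)
  }
  prev <- nrow(a$inputs)
  for (l in seq_along(a$layers)) {
    ly <- a$layers[[l]]
    if (!ly$activation %in% ANN_ACTIVATIONS) {
      stop("UNSUPPORTED_ACTIVATION: '", ly$activation, "' in layer ", l,
           call. = FALSE)
    }
    if (!is.matrix(ly$W) || ncol(ly$W) != prev) {
      stop("ANN_SHAPE_MISMATCH: layer ", l, " weight matrix must have ",
           prev, " columns", call. = FALSE)
    }
    if (length(ly$b) != nrow(ly$W)) {
      stop("ANN_SHAPE_MISMATCH: layer ", l, " bias length ", length(ly$b),
           " != layer size ", nrow(ly$W), call. = FALSE)
    }
    prev <- nrow(ly$W)
  }
  if (nrow(a$outputs) != prev) {
    stop("ANN_SHAPE_MISMATCH: ", nrow(a$outputs),
         " outputs declared but last layer has ", prev, " nodes",
         call. = FALSE)
  }
  invisible(a)
}

ann_shape <- function(a) {
  c(nrow(a$inputs), vapply(a$layers, function(l) nrow(l$W), integer(1)))
}

#' @export
print.ann_spec <- function(x, ...) {
  cat("<ann_spec> shape ", paste(ann_shape(x), collapse = "-"),
      ", activations ", paste(vapply(x$layers, `[[`, character(1), "activation"),
                              collapse = "/"), "\n", sep = "")
  cat("  inputs: ", paste(x$inputs$id, collapse = ", "), "\n", sep = "")
  cat("  outputs: ", paste(paste0(x$outputs$kind, ":", x$outputs$id),
                           collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Forward pass of a feedforward ANN
#'
#' Inputs are given in model units; each is min-max scaled to `[0,1]`
#' using the bounds stored in the spec, then each layer computes
#' `activation(W %*% prev + b)`.
#'
#' @param a An `ann_spec`.
#' @param x Numeric vector, one value per input, in the order of
#'   `a$inputs` (names, if present, are ignored).
#' @return Numeric vector of last-layer values, one per output.
#' @export
ann_forward <- function(a, x) {
  x <- as.numeric(x)
  if (length(x) != nrow(a$inputs)) {
    stop("expected ", nrow(a$inputs), " inputs, got ", length(x), call. = FALSE)
  }
  v <- (x - a$inputs$min) / (a$inputs$max - a$inputs$min)
  for (ly in a$layers) {
    v <- as.numeric(ly$W %*% v + ly$b)
    if (ly$activation == "tanh") v <- tanh(v)
  }
  v
}

## ---- portable ASCII weight container (.annw) -------------------------------

# The container reuses the HMOD ml-block record grammar with an ANNW/1
# header line; see HMOD-SPEC.md.

#' Store an ANN spec in the portable ASCII weight container
#'
#' @param a An `ann_spec`.
#' @param path Optional output path (written atomically). When omitted the
#'   container text is returned.
#' @return Container text (invisibly when `path` is given).
#' @export
write_ann_weights <- function(a, path = NULL) {
  txt <- paste0(paste(c("ANNW/1", ann_spec_to_records(a)), collapse = "\n"), "\n")
  if (!is.null(path)) {
    atomic_write(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Load an ANN spec from the portable ASCII weight container
#'
#' @param x Path to a `.annw` file or the container text itself.
#' @return An `ann_spec`.
#' @export
load_ann_weights <- function(x) {
  lines <- read_text_lines(x)
  lines <- strip_comments(lines)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L || trimws(lines[nonblank[1L]]) != "ANNW/1") {
    stop("not an ANNW/1 container", call. = FALSE)
  }
  body <- lines[setdiff(nonblank, nonblank[1L])]
  records <- lapply(seq_along(body), function(i) {
    parse_record_line(body[[i]], i)
  })
  res <- ann_records_to_spec(records, loc_prefix = "annw")
  if (!report_ok(res$report)) {
    stop("invalid ANN container:\n",
         paste(sprintf("  %s %s [%s] %s", res$report$severity, res$report$code,
                       res$report$location, res$report$message), collapse = "\n"),
         call. = FALSE)
  }
  res$ann
}

# records -> character lines, canonical order and formatting
ann_spec_to_records <- function(a) {
  out <- character(0)
  for (i in seq_len(nrow(a$inputs))) {
    out <- c(out, sprintf("input_%d : id=%s, min=%s, max=%s", i,
                          a$inputs$id[i], fmt_dbl(a$inputs$min[i]),
                          fmt_dbl(a$inputs$max[i])))
  }
  for (l in seq_along(a$layers)) {
    ly <- a$layers[[l]]
    out <- c(out, sprintf("layer_%d : size=%d, activation=%s", l,
                          nrow(ly$W), ly$activation))
    for (r in seq_len(nrow(ly$W))) {
      out <- c(out, sprintf("w_%d_%d : values=%s", l, r,
                            paste(vapply(ly$W[r, ], fmt_dbl, character(1)),
                                  collapse = " ")))
    }
    out <- c(out, sprintf("b_%d : values=%s", l,
                          paste(vapply(ly$b, fmt_dbl, character(1)),
                                collapse = " ")))
  }
  for (k in seq_len(nrow(a$outputs))) {
    kind_tag <- if (a$outputs$kind[k] == "reaction-rate") "reaction" else "parameter"
    line <- sprintf("output_%d : target=%s:%s", k, kind_tag, a$outputs$id[k])
    if (!is.na(a$outputs$factor[k])) {
      line <- paste0(line, ", factor=", a$outputs$factor[k])
    }
    out <- c(out, line)
  }
  out
}

# Parsed records (from parse_record_line) -> ann_spec + report.
# Shared by the HMOD [ML] block and the .annw container.
ann_records_to_spec <- function(records, loc_prefix = "ml") {
  rep <- validation_report()
  note <- function(s, c, l, t) rep <<- report_add(rep, s, c, l, t)
  loc <- function(r) sprintf("%s:%04d", loc_prefix, r$line)

  inputs <- list(); layer_sizes <- integer(0); activations <- character(0)
  wrows <- list(); biases <- list(); outputs <- list()

  for (r in records) {
    if (is.null(r$id)) {
      note("ERROR", "BAD_RECORD", sprintf("%s:%04d", loc_prefix, r$line),
           r$message)
      next
    }
    f <- r$fields
    need <- function(field) {
      if (!field %in% names(f)) {
        note("ERROR", "MISSING_FIELD", loc(r),
             paste0("record '", r$id, "' lacks field '", field, "'"))
        return(NA_character_)
      }
      f[[field]]
    }
    num <- function(field) {
      v <- need(field)
      if (is.na(v)) return(NA_real_)
      x <- parse_strict_number(v)
      if (is.na(x)) {
        note("ERROR", "BAD_NUMBER", loc(r),
             paste0("field '", field, "' is not a number: '", v, "'"))
      }
      x
    }
    if (grepl("^input_[0-9]+$", r$id)) {
      idx <- as.integer(sub("^input_", "", r$id))
      id <- need("id"); mn <- num("min"); mx <- num("max")
      inputs[[idx]] <- list(id = id, min = mn, max = mx, line = r$line)
    } else if (grepl("^layer_[0-9]+$", r$id)) {
      idx <- as.integer(sub("^layer_", "", r$id))
      sz <- num("size"); act <- need("activation")
      if (!is.na(act) && !act %in% ANN_ACTIVATIONS) {
        note("ERROR", "UNSUPPORTED_ACTIVATION", loc(r),
             paste0("unknown activation '", act, "'"))
      }
      layer_sizes[idx] <- as.integer(sz)
      activations[idx] <- act
    } else if (grepl("^w_[0-9]+_[0-9]+$", r$id)) {
      parts <- as.integer(strsplit(sub("^w_", "", r$id), "_")[[1L]])
      v <- need("values")
      row <- if (is.na(v)) numeric(0) else parse_number_list(v)
      if (anyNA(row)) {
        note("ERROR", "BAD_NUMBER", loc(r), "unparseable value in weight row")
        row <- row[!is.na(row)]
      }
      key <- paste(parts, collapse = "_")
      wrows[[key]] <- row
    } else if (grepl("^b_[0-9]+$", r$id)) {
      idx <- as.integer(sub("^b_", "", r$id))
      v <- need("values")
      bb <- if (is.na(v)) numeric(0) else parse_number_list(v)
      if (anyNA(bb)) {
        note("ERROR", "BAD_NUMBER", loc(r), "unparseable value in bias vector")
        bb <- bb[!is.na(bb)]
      }
      biases[[idx]] <- bb
    } else if (grepl("^output_[0-9]+$", r$id)) {
      idx <- as.integer(sub("^output_", "", r$id))
      tg <- need("target")
      kind <- NA_character_; tid <- NA_character_
      if (!is.na(tg)) {
        tparts <- strsplit(tg, ":", fixed = TRUE)[[1L]]
        if (length(tparts) != 2L || !tparts[1L] %in% c("reaction", "parameter")) {
          note("ERROR", "BAD_RECORD", loc(r),
               paste0("target must be reaction:<id> or parameter:<id>, got '",
                      tg, "'"))
        } else {
          kind <- if (tparts[1L] == "reaction") "reaction-rate" else "parameter"
          tid <- tparts[2L]
        }
      }
      fac <- if ("factor" %in% names(f)) f[["factor"]] else NA_character_
      if (!is.na(fac)) {
        ok <- tryCatch({parse_infix(fac); TRUE}, error = function(e) FALSE)
        if (!ok) note("ERROR", "BAD_EXPRESSION", loc(r),
                      paste0("unparseable factor expression '", fac, "'"))
      }
      outputs[[idx]] <- list(kind = kind, id = tid, factor = fac, line = r$line)
    } else {
      note("ERROR", "BAD_RECORD", loc(r),
           paste0("unknown ml record '", r$id, "'"))
    }
  }

  if (!report_ok(rep)) return(list(ann = NULL, report = rep))

  gloc <- loc_prefix
  if (length(inputs) == 0L || any(vapply(inputs, is.null, logical(1)))) {
    note("ERROR", "MISSING_FIELD", gloc, "ml block declares no (or gapped) inputs")
  }
  if (length(layer_sizes) == 0L || anyNA(layer_sizes)) {
    note("ERROR", "MISSING_FIELD", gloc, "ml block declares no (or gapped) layers")
  }
  if (!report_ok(rep)) return(list(ann = NULL, report = rep))

  for (i in seq_along(inputs)) {
    if (!is.na(inputs[[i]]$min) && !is.na(inputs[[i]]$max) &&
        inputs[[i]]$max <= inputs[[i]]$min) {
      note("ERROR", "BAD_RECORD", sprintf("%s:%04d", loc_prefix, inputs[[i]]$line),
           "input scaling requires max > min")
    }
  }

  prev <- length(inputs)
  layers <- vector("list", length(layer_sizes))
  for (l in seq_along(layer_sizes)) {
    sz <- layer_sizes[l]
    W <- matrix(NA_real_, nrow = sz, ncol = prev)
    for (r in seq_len(sz)) {
      key <- paste(l, r, sep = "_")
      row <- wrows[[key]]
      if (is.null(row)) {
        note("ERROR", "ANN_SHAPE_MISMATCH", gloc,
             sprintf("missing weight row w_%d_%d", l, r))
      } else if (length(row) != prev) {
        note("ERROR", "ANN_SHAPE_MISMATCH", gloc,
             sprintf("w_%d_%d has %d values, expected %d", l, r,
                     length(row), prev))
      } else {
        W[r, ] <- row
      }
    }
    extra <- names(wrows)[grepl(paste0("^", l, "_"), names(wrows))]
    if (length(extra) > sz) {
      note("ERROR", "ANN_SHAPE_MISMATCH", gloc,
           sprintf("layer %d declares size %d but %d weight rows given", l,
                   sz, length(extra)))
    }
    b <- if (l <= length(biases)) biases[[l]] else NULL
    if (is.null(b)) {
      note("ERROR", "ANN_SHAPE_MISMATCH", gloc, sprintf("missing bias b_%d", l))
      b <- rep(NA_real_, sz)
    } else if (length(b) != sz) {
      note("ERROR", "ANN_SHAPE_MISMATCH", gloc,
           sprintf("b_%d has %d values, expected %d", l, length(b), sz))
    }
    layers[[l]] <- list(W = W, b = b, activation = activations[l])
    prev <- sz
  }
  if (length(outputs) == 0L || any(vapply(outputs, is.null, logical(1)))) {
    note("ERROR", "MISSING_FIELD", gloc, "ml block declares no (or gapped) outputs")
  } else if (length(outputs) != prev) {
    note("ERROR", "ANN_SHAPE_MISMATCH", gloc,
         sprintf("%d outputs declared but last layer has %d nodes",
                 length(outputs), prev))
  }
  if (!report_ok(rep)) return(list(ann = NULL, report = rep))

  a <- ann_spec(
    inputs = data.frame(id = vapply(inputs, `[[`, character(1), "id"),
                        min = vapply(inputs, `[[`, numeric(1), "min"),
                        max = vapply(inputs, `[[`, numeric(1), "max"),
                        stringsAsFactors = FALSE),
    layers = layers,
    outputs = data.frame(kind = vapply(outputs, `[[`, character(1), "kind"),
                         id = vapply(outputs, `[[`, character(1), "id"),
                         factor = vapply(outputs, `[[`, character(1), "factor"),
                         stringsAsFactors = FALSE))
  list(ann = a, report = rep)
}
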
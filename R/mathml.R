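# Content-MathML subset <-> hyb_expr, as embedded in SBML <math> elements.

MATHML_NS <- "http://www.w3.org/1998/Math/MathML"

#' Parse a content-MathML element into an expression
#'
#' Accepts the content-MathML dialect used in SBML kinetic laws and rules:
#' `apply`, `ci`, `cn` (integer, real, e-notation, rational), `plus`,
#' `minus` (unary and binary), `times`, `divide`, `power`, `exp`, `ln`,
#' `log` (with optional `logbase`), `root` (degree 2), `tanh`, `abs`,
#' `min`, `max`, `piecewise` and the relational operators. N-ary `plus`
#' and `times` are folded left-associatively.
#'
#' @param x An `xml2` node or document whose (first) element is `<math>`
#'   or a content-MathML expression element, or a character string of XML.
#' @return A `hyb_expr`.
#' @export
parse_mathml <- function(x) {
  if (is.character(x)) x <- xml2::read_xml(x)
  if (inherits(x, "xml_document")) x <- xml2::xml_root(x)
  node <- x
  if (xname(node) == "math") {
    kids <- xml2::xml_children(node)
    if (length(kids) != 1L) stop("<math> must contain exactly one expression element")
    node <- kids[[1L]]
  }
  mathml_node_to_expr(node)
}

mathml_node_to_expr <- function(node) {
  name <- xname(node)
  if (name == "ci") {
    id <- trimws(xml2::xml_text(node))
    if (!grepl(ID_RE, id)) stop("invalid identifier in <ci>: '", id, "'")
    return(e_sym(id))
  }
  if (name == "cn") {
    return(parse_cn(node))
  }
  if (name == "apply") {
    kids <- xml2::xml_children(node)
    if (length(kids) == 0L) stop("empty <apply>")
    return(parse_apply(kids))
  }
  if (name == "piecewise") {
    return(parse_piecewise(node))
  }
  stop("unsupported MathML element <", name, ">")
}

parse_cn <- function(node) {
  type <- xml2::xml_attr(node, "type")
  if (!is.na(type) && type == "e-notation") {
    parts <- xml2::xml_contents(node)
    txt <- vapply(parts, xml2::xml_text, character(1))
    sep_idx <- which(vapply(parts, xml2::xml_name, character(1)) == "sep")
    if (length(sep_idx) != 1L) stop("malformed e-notation <cn>")
    mant <- as.numeric(trimws(paste(txt[seq_len(sep_idx - 1L)], collapse = "")))
    ex <- as.numeric(trimws(paste(txt[seq(sep_idx + 1L, length(txt))], collapse = "")))
    val <- mant * 10^ex
  } else if (!is.na(type) && type == "rational") {
    parts <- xml2::xml_contents(node)
    txt <- vapply(parts, xml2::xml_text, character(1))
    sep_idx <- which(vapply(parts, xml2::xml_name, character(1)) == "sep")
    if (length(sep_idx) != 1L) stop("malformed rational <cn>")
    num <- as.numeric(trimws(paste(txt[seq_len(sep_idx - 1L)], collapse = "")))
    den <- as.numeric(trimws(paste(txt[seq(sep_idx + 1L, length(txt))], collapse = "")))
    val <- num / den
  } else {
    val <- suppressWarnings(as.numeric(trimws(xml2::xml_text(node))))
  }
  if (is.na(val)) stop("unparseable numeric literal in <cn>")
  e_const(val)
}

MATHML_OP_MAP <- c(plus = "+", minus = "-", times = "*", divide = "/",
                   power = "^", exp = "exp", ln = "ln", tanh = "tanh",
                   abs = "abs", min = "min", max = "max",
                   lt = "lt", leq = "leq", gt = "gt", geq = "geq",
                   eq = "eq", neq = "neq")

parse_apply <- function(kids) {
  head <- kids[[1L]]
  op <- xname(head)
  args_nodes <- kids[-1L]
  n <- length(args_nodes)

  if (op == "log") {
    base <- 10
    if (n >= 1L && xname(args_nodes[[1L]]) == "logbase") {
      base_expr <- mathml_node_to_expr(xml2::xml_child(args_nodes[[1L]]))
      if (base_expr$kind != "num") stop("non-numeric logbase")
      base <- base_expr$value
      args_nodes <- args_nodes[-1L]
      n <- n - 1L
    }
    if (n != 1L) stop("<log> takes one argument")
    arg <- mathml_node_to_expr(args_nodes[[1L]])
    if (base == 10) return(e_call("log10", arg))
    # log_b(x) = ln(x)/ln(b)
    return(e_call("/", e_call("ln", arg), e_call("ln", e_const(base))))
  }
  if (op == "root") {
    if (n >= 1L && xname(args_nodes[[1L]]) == "degree") {
      deg_expr <- mathml_node_to_expr(xml2::xml_child(args_nodes[[1L]]))
      if (deg_expr$kind != "num" || deg_expr$value != 2) {
        stop("only square <root> is supported")
      }
      args_nodes <- args_nodes[-1L]
      n <- n - 1L
    }
    if (n != 1L) stop("<root> takes one argument")
    return(e_call("sqrt", mathml_node_to_expr(args_nodes[[1L]])))
  }
  if (!op %in% names(MATHML_OP_MAP)) {
    stop("unsupported MathML operator <", op, ">")
  }
  mapped <- MATHML_OP_MAP[[op]]
  args <- lapply(args_nodes, mathml_node_to_expr)

  if (op == "minus") {
    if (n == 1L) return(e_call("neg", args[[1L]]))
    if (n == 2L) return(e_call("-", args[[1L]], args[[2L]]))
    stop("<minus> takes one or two arguments")
  }
  if (op %in% c("plus", "times")) {
    if (n == 0L) return(e_num(if (op == "plus") 0 else 1))
    if (n == 1L) return(args[[1L]])
    out <- args[[1L]]
    for (i in seq(2L, n)) out <- e_call(mapped, out, args[[i]])
    return(out)
  }
  one <- c("exp", "ln", "tanh", "abs")
  if (op %in% one && n != 1L) stop("<", op, "> takes one argument")
  two <- c("divide", "power", "lt", "leq", "gt", "geq", "eq", "neq")
  if (op %in% two && n != 2L) stop("<", op, "> takes two arguments")
  if (op %in% c("min", "max") && n != 2L) stop("<", op, "> takes two arguments here")
  e_call(mapped, args)
}

parse_piecewise <- function(node) {
  args <- list()
  otherwise <- NULL
  for (kid in xml2::xml_children(node)) {
    kn <- xname(kid)
    if (kn == "piece") {
      parts <- xml2::xml_children(kid)
      if (length(parts) != 2L) stop("<piece> needs value and condition")
      args[[length(args) + 1L]] <- mathml_node_to_expr(parts[[1L]])
      args[[length(args) + 1L]] <- mathml_node_to_expr(parts[[2L]])
    } else if (kn == "otherwise") {
      otherwise <- mathml_node_to_expr(xml2::xml_child(kid))
    } else {
      stop("unsupported element <", kn, "> inside <piecewise>")
    }
  }
  if (length(args) == 0L) stop("empty <piecewise>")
  if (!is.null(otherwise)) args[[length(args) + 1L]] <- otherwise
  e_call("piecewise", args)
}

## ---- writer ----------------------------------------------------------------

#' Serialize an expression to content MathML
#'
#' Emits a `<math>` element in the MathML namespace, valid inside an SBML
#' `<math>` slot. `log10` is written as `log` with explicit `logbase` 10;
#' `sqrt` as a default-degree `root`; unary minus as a one-argument
#' `minus` apply.
#'
#' @param e A `hyb_expr`.
#' @param as_string If TRUE (default) return the XML as a character
#'   string; otherwise an `xml2` document.
#' @return Character string or `xml2` document.
#' @export
write_mathml <- function(e, as_string = TRUE) {
  s <- paste0('<math xmlns="', MATHML_NS, '">', expr_to_mathml(e), "</math>")
  if (as_string) s else xml2::read_xml(s)
}

expr_to_mathml <- function(e) {
  switch(e$kind,
    num = cn_to_mathml(e$value),
    sym = paste0("<ci> ", e$name, " </ci>"),
    call = call_to_mathml(e))
}

cn_to_mathml <- function(v) {
  s <- fmt_dbl(v)
  if (grepl("[eE]", s)) {
    parts <- strsplit(s, "[eE]", fixed = FALSE)[[1L]]
    return(paste0('<cn type="e-notation"> ', parts[1L], " <sep/> ",
                  parts[2L], " </cn>"))
  }
  if (v == floor(v) && abs(v) < 2^31 && !grepl("\\.", s)) {
    return(paste0('<cn type="integer"> ', s, " </cn>"))
  }
  paste0("<cn> ", s, " </cn>")
}

INFIX_TO_MATHML <- c("+" = "plus", "-" = "minus", "*" = "times",
                     "/" = "divide", "^" = "power",
                     exp = "exp", ln = "ln", tanh = "tanh", abs = "abs",
                     min = "min", max = "max",
                     lt = "lt", leq = "leq", gt = "gt", geq = "geq",
                     eq = "eq", neq = "neq")

call_to_mathml <- function(e) {
  name <- e$name
  kids <- function(args) paste(vapply(args, expr_to_mathml, character(1)),
                               collapse = "")
  if (name == "neg") {
    return(paste0("<apply><minus/>", expr_to_mathml(e$args[[1L]]), "</apply>"))
  }
  if (name == "sqrt") {
    return(paste0("<apply><root/>", expr_to_mathml(e$args[[1L]]), "</apply>"))
  }
  if (name == "log10") {
    return(paste0('<apply><log/><logbase><cn type="integer"> 10 </cn></logbase>',
                  expr_to_mathml(e$args[[1L]]), "</apply>"))
  }
  if (name == "piecewise") {
    n <- length(e$args)
    npairs <- n %/% 2L
    pieces <- character(0)
    for (i in seq_len(npairs)) {
      pieces <- c(pieces, paste0("<piece>", expr_to_mathml(e$args[[2L * i - 1L]]),
                                 expr_to_mathml(e$args[[2L * i]]), "</piece>"))
    }
    if (n %% 2L == 1L) {
      pieces <- c(pieces, paste0("<otherwise>", expr_to_mathml(e$args[[n]]),
                                 "</otherwise>"))
    }
    return(paste0("<piecewise>", paste(pieces, collapse = ""), "</piecewise>"))
  }
  if (!name %in% names(INFIX_TO_MATHML)) {
    stop("cannot write '", name, "' to MathML")
  }
  paste0("<apply><", INFIX_TO_MATHML[[name]], "/>", kids(e$args), "</apply>")
}

# local element name, prefix stripped (tolerates prefixed MathML)
xname <- function(node) sub("^.*:", "", xml2::xml_name(node))
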
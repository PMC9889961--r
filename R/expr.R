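# Expression trees for kinetic-law and rule mathematics.
#
# A hyb_expr is one of
#   num  : non-negative numeric literal (negatives are neg(|x|), see e_const)
#   sym  : identifier [A-Za-z_][A-Za-z0-9_]*
#   call : operator or function applied to child expressions
#
# Operators are call nodes named "+", "-", "*", "/", "^" (binary) and "neg"
# (unary).  The function set is closed: exp, ln, log10, sqrt, tanh, abs,
# min, max, piecewise, plus the relational operators lt, leq, gt, geq, eq,
# neq needed inside piecewise conditions (relations evaluate to 1/0).

HYB_FUNCTIONS <- c("pow", "exp", "ln", "log10", "sqrt", "tanh", "abs",
                   "min", "max", "piecewise",
                   "lt", "leq", "gt", "geq", "eq", "neq")
HYB_BINARY_OPS <- c("+", "-", "*", "/", "^")
ID_RE <- "^[A-Za-z_][A-Za-z0-9_]*$"

#' Construct a numeric literal expression node
#'
#' @param value A single finite numeric value. Must be non-negative; use
#'   [e_const()] for values of unknown sign.
#' @return A `hyb_expr` number node.
#' @export
e_num <- function(value) {
  value <- as.numeric(value)
  stopifnot(length(value) == 1L, is.finite(value), value >= 0)
  structure(list(kind = "num", value = value), class = "hyb_expr")
}

#' Construct a symbol expression node
#'
#' @param name Identifier matching `[A-Za-z_][A-Za-z0-9_]*`.
#' @return A `hyb_expr` symbol node.
#' @export
e_sym <- function(name) {
  stopifnot(is.character(name), length(name) == 1L, grepl(ID_RE, name))
  structure(list(kind = "sym", name = name), class = "hyb_expr")
}

#' Construct an operator or function-call expression node
#'
#' @param name Operator (`+ - * / ^ neg`) or a supported function name.
#' @param ... Child expressions (`hyb_expr`).
#' @return A `hyb_expr` call node.
#' @export
e_call <- function(name, ...) {
  args <- list(...)
  if (length(args) == 1L && is.list(args[[1L]]) && !inherits(args[[1L]], "hyb_expr")) {
    args <- args[[1L]]
  }
  stopifnot(all(vapply(args, inherits, logical(1), "hyb_expr")))
  if (name %in% HYB_BINARY_OPS) {
    if (length(args) != 2L) stop("operator '", name, "' takes exactly two arguments")
  } else if (name == "neg") {
    if (length(args) != 1L) stop("'neg' takes exactly one argument")
  } else if (!name %in% HYB_FUNCTIONS) {
    stop("unknown function '", name, "'")
  }
  if (name == "pow") name <- "^"
  structure(list(kind = "call", name = name, args = args), class = "hyb_expr")
}

#' Numeric constant of any sign as an expression
#'
#' Negative values are represented as `neg(|x|)` so that infix
#' serialization round-trips structurally.
#'
#' @param x A single finite numeric value.
#' @return A `hyb_expr`.
#' @export
e_const <- function(x) {
  if (x < 0) e_call("neg", e_num(-x)) else e_num(x)
}

#' @export
print.hyb_expr <- function(x, ...) {
  cat("<hyb_expr> ", write_infix(x), "\n", sep = "")
  invisible(x)
}

#' Test structural equality of two expressions
#'
#' @param a,b `hyb_expr` objects.
#' @return TRUE if the trees are node-for-node identical.
#' @export
expr_identical <- function(a, b) {
  if (a$kind != b$kind) return(FALSE)
  switch(a$kind,
    num = identical(a$value, b$value),
    sym = identical(a$name, b$name),
    call = {
      if (a$name != b$name || length(a$args) != length(b$args)) return(FALSE)
      for (i in seq_along(a$args)) {
        if (!expr_identical(a$args[[i]], b$args[[i]])) return(FALSE)
      }
      TRUE
    })
}

#' Symbols referenced by an expression
#'
#' @param e A `hyb_expr`.
#' @return Character vector of distinct symbol names, in first-use order.
#' @export
expr_symbols <- function(e) {
  out <- character(0)
  walk <- function(x) {
    if (x$kind == "sym") {
      out[[length(out) + 1L]] <<- x$name
    } else if (x$kind == "call") {
      for (a in x$args) walk(a)
    }
  }
  walk(e)
  unique(out)
}

#' Substitute symbols in an expression
#'
#' @param e A `hyb_expr`.
#' @param mapping Named character vector or named list of `hyb_expr`; each
#'   symbol whose name appears in `names(mapping)` is replaced.
#' @return The rewritten `hyb_expr`.
#' @export
expr_substitute <- function(e, mapping) {
  if (e$kind == "sym") {
    if (e$name %in% names(mapping)) {
      rep <- mapping[[e$name]]
      if (is.character(rep)) return(e_sym(rep))
      return(rep)
    }
    return(e)
  }
  if (e$kind == "call") {
    e$args <- lapply(e$args, expr_substitute, mapping = mapping)
  }
  e
}

## ---- number formatting ----------------------------------------------------

# shortest decimal that reads back to exactly the same double (<= 17 sig digits)
fmt_dbl <- function(x) {
  stopifnot(length(x) == 1L)
  if (!is.finite(x)) return(as.character(x))
  if (x == 0) return("0")
  for (d in 1:17) {
    s <- sprintf("%.*g", d, x)
    if (as.numeric(s) == x) return(s)
  }
  sprintf("%.17g", x)
}

## ---- infix tokenizer / parser ---------------------------------------------

NUM_RE <- "^(?:[0-9]+(?:\\.[0-9]*)?|\\.[0-9]+)(?:[eE][+-]?[0-9]+)?"

tokenize_infix <- function(text) {
  toks <- list()
  i <- 1L
  n <- nchar(text)
  while (i <= n) {
    rest <- substr(text, i, n)
    ch <- substr(text, i, i)
    if (grepl("^[ \t]", ch)) {
      i <- i + 1L
      next
    }
    m <- regmatches(rest, regexpr(NUM_RE, rest))
    if (length(m) == 1L && nzchar(m)) {
      toks[[length(toks) + 1L]] <- list(type = "num", value = m, col = i)
      i <- i + nchar(m)
      next
    }
    m <- regmatches(rest, regexpr("^[A-Za-z_][A-Za-z0-9_]*", rest))
    if (length(m) == 1L && nzchar(m)) {
      toks[[length(toks) + 1L]] <- list(type = "ident", value = m, col = i)
      i <- i + nchar(m)
      next
    }
    if (ch %in% c("+", "-", "*", "/", "^", "(", ")", ",")) {
      toks[[length(toks) + 1L]] <- list(type = ch, value = ch, col = i)
      i <- i + 1L
      next
    }
    stop(sprintf("syntax error at column %d: unexpected character '%s'", i, ch),
         call. = FALSE)
  }
  toks
}

#' Parse an infix expression string
#'
#' Standard precedence: `+ -` < `* /` < `^` (right-associative) < unary
#' minus, so `-2^2` is `(-2)^2` and `2^3^2` is `2^(3^2)`. Function
#' application requires parentheses; an identifier followed by `(` must be
#' a supported function name.
#'
#' @param text Non-empty infix expression string.
#' @return A `hyb_expr`.
#' @export
#' @examples
#' parse_infix("k1*S/(Km+S)")
#' parse_infix("tanh(w*x + b)")
parse_infix <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(trimws(text))) stop("empty expression", call. = FALSE)
  toks <- tokenize_infix(text)
  pos <- 1L
  end_col <- nchar(text) + 1L

  peek <- function() if (pos <= length(toks)) toks[[pos]] else NULL
  advance <- function() {
    t <- toks[[pos]]
    pos <<- pos + 1L
    t
  }
  fail <- function(msg, tok = peek()) {
    col <- if (is.null(tok)) end_col else tok$col
    stop(sprintf("syntax error at column %d: %s", col, msg), call. = FALSE)
  }

  parse_expr <- function() {
    e <- parse_term()
    repeat {
      t <- peek()
      if (is.null(t) || !(t$type %in% c("+", "-"))) return(e)
      advance()
      e <- e_call(t$type, e, parse_term())
    }
  }
  parse_term <- function() {
    e <- parse_power()
    repeat {
      t <- peek()
      if (is.null(t) || !(t$type %in% c("*", "/"))) return(e)
      advance()
      e <- e_call(t$type, e, parse_power())
    }
  }
  parse_power <- function() {
    base <- parse_unary()
    t <- peek()
    if (!is.null(t) && t$type == "^") {
      advance()
      return(e_call("^", base, parse_power()))  # right-associative
    }
    base
  }
  parse_unary <- function() {
    t <- peek()
    if (!is.null(t) && t$type == "-") {
      advance()
      return(e_call("neg", parse_unary()))
    }
    if (!is.null(t) && t$type == "+") {  # unary plus: no-op
      advance()
      return(parse_unary())
    }
    parse_atom()
  }
  parse_atom <- function() {
    t <- peek()
    if (is.null(t)) fail("unexpected end of expression")
    if (t$type == "num") {
      advance()
      return(e_num(as.numeric(t$value)))
    }
    if (t$type == "ident") {
      advance()
      nxt <- peek()
      if (!is.null(nxt) && nxt$type == "(") {
        if (!t$value %in% HYB_FUNCTIONS) {
          fail(sprintf("unknown function '%s'", t$value), t)
        }
        advance()
        args <- list()
        if (!is.null(peek()) && peek()$type != ")") {
          repeat {
            args[[length(args) + 1L]] <- parse_expr()
            nt <- peek()
            if (is.null(nt)) fail("unclosed function call")
            if (nt$type == ",") {
              advance()
              next
            }
            break
          }
        }
        cl <- peek()
        if (is.null(cl) || cl$type != ")") fail("expected ')'")
        advance()
        return(check_arity(t, args))
      }
      return(e_sym(t$value))
    }
    if (t$type == "(") {
      advance()
      e <- parse_expr()
      cl <- peek()
      if (is.null(cl) || cl$type != ")") fail("expected ')'")
      advance()
      return(e)
    }
    fail(sprintf("unexpected '%s'", t$value), t)
  }
  check_arity <- function(tok, args) {
    name <- tok$value
    n <- length(args)
    one <- c("exp", "ln", "log10", "sqrt", "tanh", "abs")
    two <- c("pow", "min", "max", "lt", "leq", "gt", "geq", "eq", "neq")
    if (name %in% one && n != 1L) fail(sprintf("'%s' takes 1 argument", name), tok)
    if (name %in% two && n != 2L) fail(sprintf("'%s' takes 2 arguments", name), tok)
    if (name == "piecewise" && n < 2L) {
      fail("'piecewise' needs at least a value and a condition", tok)
    }
    e_call(name, args)
  }

  e <- parse_expr()
  if (!is.null(peek())) fail(sprintf("unexpected '%s'", peek()$value))
  e
}

## ---- infix writer ----------------------------------------------------------

expr_prec <- function(e) {
  if (e$kind != "call") return(5L)
  switch(e$name,
    "+" = , "-" = 1L,
    "*" = , "/" = 2L,
    "^" = 3L,
    "neg" = 4L,
    5L)  # function call: atom-like
}

#' Serialize an expression to infix text
#'
#' Parentheses are inserted only where precedence requires; the output
#' re-parses to a structurally identical tree.
#'
#' @param e A `hyb_expr`.
#' @return Infix string.
#' @export
#' @examples
#' write_infix(parse_infix("(a+b)*c"))
write_infix <- function(e) {
  stopifnot(inherits(e, "hyb_expr"))
  switch(e$kind,
    num = fmt_dbl(e$value),
    sym = e$name,
    call = write_infix_call(e))
}

write_infix_call <- function(e) {
  p <- expr_prec(e)
  wrap <- function(child, need) {
    s <- write_infix(child)
    if (need) paste0("(", s, ")") else s
  }
  if (e$name %in% HYB_BINARY_OPS) {
    lp <- expr_prec(e$args[[1L]])
    rp <- expr_prec(e$args[[2L]])
    if (e$name == "^") {
      # right-associative; left operand at unary level
      left <- wrap(e$args[[1L]], lp <= p && lp != 4L)
      right <- wrap(e$args[[2L]], rp < p)
      return(paste0(left, "^", right))
    }
    left <- wrap(e$args[[1L]], lp < p)
    # right child with equal precedence needs parens (left associativity)
    right <- wrap(e$args[[2L]], rp < p || (rp == p && e$args[[2L]]$kind == "call" &&
                                             e$args[[2L]]$name %in% HYB_BINARY_OPS))
    return(paste0(left, e$name, right))
  }
  if (e$name == "neg") {
    cp <- expr_prec(e$args[[1L]])
    return(paste0("-", wrap(e$args[[1L]], cp < p)))
  }
  paste0(e$name, "(", paste(vapply(e$args, write_infix, character(1)),
                            collapse = ", "), ")")
}

## ---- evaluator -------------------------------------------------------------

#' Evaluate an expression in a numeric environment
#'
#' IEEE double arithmetic; division by zero yields `Inf`/`NaN` per IEEE.
#' `piecewise(v1, c1, v2, c2, ..., otherwise)` returns the value of the
#' first condition evaluating non-zero, else the trailing `otherwise`
#' value; relations return 1 or 0.
#'
#' @param e A `hyb_expr`.
#' @param env Named list or named numeric vector binding every symbol in `e`.
#' @return A single numeric value.
#' @export
#' @examples
#' eval_expr(parse_infix("k*S/(Km+S)"), c(k = 2, S = 1, Km = 1))
eval_expr <- function(e, env = list()) {
  env <- as.list(env)
  eval_rec(e, env)
}

eval_rec <- function(e, env) {
  switch(e$kind,
    num = e$value,
    sym = {
      v <- env[[e$name]]
      if (is.null(v)) stop("unbound symbol '", e$name, "'", call. = FALSE)
      as.numeric(v)
    },
    call = {
      name <- e$name
      if (name == "piecewise") {
        n <- length(e$args)
        npairs <- n %/% 2L
        for (i in seq_len(npairs)) {
          cond <- eval_rec(e$args[[2L * i]], env)
          if (cond != 0) return(eval_rec(e$args[[2L * i - 1L]], env))
        }
        if (n %% 2L == 1L) return(eval_rec(e$args[[n]], env))
        return(NaN)  # no branch true and no otherwise
      }
      a <- vapply(e$args, eval_rec, numeric(1), env = env)
      switch(name,
        "+" = a[1L] + a[2L],
        "-" = a[1L] - a[2L],
        "*" = a[1L] * a[2L],
        "/" = a[1L] / a[2L],
        "^" = a[1L]^a[2L],
        "neg" = -a[1L],
        "exp" = exp(a[1L]),
        "ln" = log(a[1L]),
        "log10" = log10(a[1L]),
        "sqrt" = sqrt(a[1L]),
        "tanh" = tanh(a[1L]),
        "abs" = abs(a[1L]),
        "min" = min(a),
        "max" = max(a),
        "lt" = as.numeric(a[1L] < a[2L]),
        "leq" = as.numeric(a[1L] <= a[2L]),
        "gt" = as.numeric(a[1L] > a[2L]),
        "geq" = as.numeric(a[1L] >= a[2L]),
        "eq" = as.numeric(a[1L] == a[2L]),
        "neq" = as.numeric(a[1L] != a[2L]),
        stop("unknown function '", name, "'", call. = FALSE))
    })
}

# Compile a hyb_expr to an R language object for fast repeated evaluation
# inside the ODE right-hand side. Semantics match eval_expr.
expr_to_lang <- function(e) {
  switch(e$kind,
    num = e$value,
    sym = as.name(e$name),
    call = {
      name <- e$name
      args <- lapply(e$args, expr_to_lang)
      if (name == "piecewise") {
        n <- length(args)
        npairs <- n %/% 2L
        out <- if (n %% 2L == 1L) args[[n]] else NaN
        for (i in rev(seq_len(npairs))) {
          out <- call("if", call("!=", args[[2L * i]], 0),
                      args[[2L * i - 1L]], out)
        }
        return(out)
      }
      fn <- switch(name,
        "+" = "+", "-" = "-", "*" = "*", "/" = "/", "^" = "^",
        "neg" = return(call("-", args[[1L]])),
        "ln" = "log",
        "lt" = return(call("as.numeric", call("<", args[[1L]], args[[2L]]))),
        "leq" = return(call("as.numeric", call("<=", args[[1L]], args[[2L]]))),
        "gt" = return(call("as.numeric", call(">", args[[1L]], args[[2L]]))),
        "geq" = return(call("as.numeric", call(">=", args[[1L]], args[[2L]]))),
        "eq" = return(call("as.numeric", call("==", args[[1L]], args[[2L]]))),
        "neq" = return(call("as.numeric", call("!=", args[[1L]], args[[2L]]))),
        name)
      as.call(c(as.name(fn), args))
    })
}
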
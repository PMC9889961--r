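# Independent oracles used against the package implementation.

# Shunting-yard evaluator for operator-only infix strings (+ - * / ^,
# unary minus, parentheses, numbers, symbols). Written independently of
# parse_infix/eval_expr: tokens go through an explicit operator stack to
# RPN, then a value stack. Precedence: + - < * / < ^ (right-assoc) <
# unary minus.
shunting_yard_eval <- function(text, env = list()) {
  toks <- list()
  i <- 1L
  n <- nchar(text)
  prev_type <- "start"
  while (i <= n) {
    ch <- substr(text, i, i)
    if (ch == " ") { i <- i + 1L; next }
    rest <- substr(text, i, n)
    mnum <- regmatches(rest, regexpr("^[0-9]+(\\.[0-9]*)?([eE][+-]?[0-9]+)?", rest))
    if (length(mnum) == 1L && nzchar(mnum)) {
      toks[[length(toks) + 1L]] <- list(t = "num", v = as.numeric(mnum))
      i <- i + nchar(mnum); prev_type <- "value"; next
    }
    mid <- regmatches(rest, regexpr("^[A-Za-z_][A-Za-z0-9_]*", rest))
    if (length(mid) == 1L && nzchar(mid)) {
      toks[[length(toks) + 1L]] <- list(t = "sym", v = mid)
      i <- i + nchar(mid); prev_type <- "value"; next
    }
    if (ch == "-" && prev_type %in% c("start", "op", "open")) {
      toks[[length(toks) + 1L]] <- list(t = "op", v = "u-")
    } else if (ch %in% c("+", "-", "*", "/", "^")) {
      toks[[length(toks) + 1L]] <- list(t = "op", v = ch)
    } else if (ch == "(") {
      toks[[length(toks) + 1L]] <- list(t = "open")
    } else if (ch == ")") {
      toks[[length(toks) + 1L]] <- list(t = "close")
    } else {
      stop("oracle: bad character ", ch)
    }
    prev_type <- switch(ch, "(" = "open", ")" = "value", "op")
    i <- i + 1L
  }
  prec <- c("+" = 1, "-" = 1, "*" = 2, "/" = 2, "^" = 3, "u-" = 4)
  right <- c("^", "u-")
  out <- list(); ops <- list()
  for (tk in toks) {
    if (tk$t %in% c("num", "sym")) {
      out[[length(out) + 1L]] <- tk
    } else if (tk$t == "op") {
      while (length(ops) > 0L) {
        top <- ops[[length(ops)]]
        if (top$t == "open") break
        if (prec[[top$v]] > prec[[tk$v]] ||
            (prec[[top$v]] == prec[[tk$v]] && !(tk$v %in% right))) {
          out[[length(out) + 1L]] <- top
          ops[[length(ops)]] <- NULL
        } else break
      }
      ops[[length(ops) + 1L]] <- tk
    } else if (tk$t == "open") {
      ops[[length(ops) + 1L]] <- tk
    } else {
      while (length(ops) > 0L && ops[[length(ops)]]$t != "open") {
        out[[length(out) + 1L]] <- ops[[length(ops)]]
        ops[[length(ops)]] <- NULL
      }
      if (length(ops) == 0L) stop("oracle: unbalanced parens")
      ops[[length(ops)]] <- NULL
    }
  }
  while (length(ops) > 0L) {
    if (ops[[length(ops)]]$t == "open") stop("oracle: unbalanced parens")
    out[[length(out) + 1L]] <- ops[[length(ops)]]
    ops[[length(ops)]] <- NULL
  }
  stack <- numeric(0)
  for (tk in out) {
    if (tk$t == "num") {
      stack <- c(stack, tk$v)
    } else if (tk$t == "sym") {
      v <- env[[tk$v]]
      if (is.null(v)) stop("oracle: unbound ", tk$v)
      stack <- c(stack, as.numeric(v))
    } else if (tk$v == "u-") {
      stack[length(stack)] <- -stack[length(stack)]
    } else {
      b <- stack[length(stack)]; a <- stack[length(stack) - 1L]
      stack <- stack[seq_len(length(stack) - 2L)]
      stack <- c(stack, switch(tk$v, "+" = a + b, "-" = a - b,
                               "*" = a * b, "/" = a / b, "^" = a^b))
    }
  }
  if (length(stack) != 1L) stop("oracle: bad expression")
  stack
}

# Random expression-tree generator for property tests. `funcs = FALSE`
# restricts to operator nodes (what the shunting-yard oracle handles).
rand_expr <- function(depth = 5L, funcs = TRUE, syms = letters[1:6]) {
  if (depth <= 0L || stats::runif(1) < 0.35) {
    if (stats::runif(1) < 0.5) {
      return(e_num(round(stats::runif(1, 0, 9), 3)))
    }
    return(e_sym(sample(syms, 1L)))
  }
  pool <- c("+", "-", "*", "/", "^", "neg")
  if (funcs) pool <- c(pool, "exp", "ln", "sqrt", "tanh", "abs", "min", "max")
  op <- sample(pool, 1L)
  if (op == "neg") return(e_call("neg", rand_expr(depth - 1L, funcs, syms)))
  if (op %in% c("exp", "ln", "sqrt", "tanh", "abs")) {
    return(e_call(op, rand_expr(depth - 1L, funcs, syms)))
  }
  e_call(op, rand_expr(depth - 1L, funcs, syms),
         rand_expr(depth - 1L, funcs, syms))
}

# hand-built two-species decay fixture: A -> 0 at rate k*A, k = 0.5
make_decay_model <- function() {
  kinetic_model(
    "decay",
    compartments = list(kin_compartment("cell", size = 1)),
    species = list(kin_species("A", "cell", init = 1)),
    parameters = list(kin_parameter("k", 0.5)),
    reactions = list(kin_reaction("v1", reactants = c(A = 1), law = "k*A")))
}
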
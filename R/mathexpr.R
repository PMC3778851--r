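# Expression trees for MathML content markup ---------------------------------
#
# A `mathexpr` is a plain tagged list.  Numeric literals are carried as exact
# decimal strings so that values survive untouched into the decimal evaluation
# context (no binary-float round trip).

MX_OPS <- c("add", "sub", "mul", "div", "pow")
MX_FUNS <- c("exp", "ln", "log", "root")
MX_RELS <- c("lt", "leq", "gt", "geq", "eq", "neq")

new_mathexpr <- function(x) structure(x, class = "mathexpr")

#' Construct expression-tree nodes
#'
#' Low-level constructors for the expression trees (`mathexpr` objects) that
#' carry all model and scheme formulas: numeric literals, variable references,
#' derivative references, unary negation, binary arithmetic, the elementary
#' functions `exp`, `ln`, `log` (base 10, or explicit base) and `root`
#' (square root, or explicit degree), relational tests, and piecewise
#' definitions.  Numbers are stored as exact decimal strings.
#'
#' @param value A number or a decimal string such as `"3.0"`.
#' @param name,var,bvar Variable identifiers.
#' @param op For [mx_op()] one of `add`, `sub`, `mul`, `div`, `pow`; for
#'   [mx_rel()] one of `lt`, `leq`, `gt`, `geq`, `eq`, `neq`.
#' @param a,b,x Child `mathexpr` nodes.
#' @param fn One of `exp`, `ln`, `log`, `root`.
#' @param args List of child nodes.  `log` takes `(x)` for base 10 or
#'   `(base, x)`; `root` takes `(x)` for the square root or `(degree, x)`.
#' @param pieces List of `list(cond = , value = )` pairs, conditions built
#'   with [mx_rel()].
#' @param otherwise Optional fallback branch.
#' @return A `mathexpr` object.
#' @examples
#' e <- mx_op("sub", mx_var("x"), mx_op("div", mx_var("r"), mx_num("3.0")))
#' free_variables(e)
#' @name mathexpr
NULL

#' @rdname mathexpr
#' @export
mx_num <- function(value) {
  if (is.numeric(value)) {
    stopifnot(length(value) == 1, is.finite(value))
    value <- num_to_decimal_string(value)
  }
  stopifnot(is.character(value), length(value) == 1)
  if (!grepl("^[+-]?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?$", value))
    stop("not a decimal numeral: '", value, "'", call. = FALSE)
  new_mathexpr(list(k = "num", value = value))
}

#' @rdname mathexpr
#' @export
mx_var <- function(name) {
  stopifnot(is.character(name), length(name) == 1, nzchar(name))
  new_mathexpr(list(k = "var", name = name))
}

#' @rdname mathexpr
#' @export
mx_deriv <- function(var, bvar) {
  stopifnot(is.character(var), is.character(bvar))
  new_mathexpr(list(k = "deriv", var = var, bvar = bvar))
}

#' @rdname mathexpr
#' @export
mx_neg <- function(a) {
  stopifnot(inherits(a, "mathexpr"))
  new_mathexpr(list(k = "neg", a = a))
}

#' @rdname mathexpr
#' @export
mx_op <- function(op, a, b) {
  op <- match.arg(op, MX_OPS)
  stopifnot(inherits(a, "mathexpr"), inherits(b, "mathexpr"))
  new_mathexpr(list(k = "op", op = op, a = a, b = b))
}

#' @rdname mathexpr
#' @export
mx_call <- function(fn, args) {
  fn <- match.arg(fn, MX_FUNS)
  stopifnot(is.list(args), length(args) >= 1)
  nmax <- if (fn %in% c("log", "root")) 2L else 1L
  if (length(args) > nmax)
    stop("function '", fn, "' takes at most ", nmax, " argument(s)", call. = FALSE)
  lapply(args, function(a) stopifnot(inherits(a, "mathexpr")))
  new_mathexpr(list(k = "call", fn = fn, args = args))
}

#' @rdname mathexpr
#' @export
mx_rel <- function(op, a, b) {
  op <- match.arg(op, MX_RELS)
  stopifnot(inherits(a, "mathexpr"), inherits(b, "mathexpr"))
  new_mathexpr(list(k = "rel", op = op, a = a, b = b))
}

#' @rdname mathexpr
#' @export
mx_piecewise <- function(pieces, otherwise = NULL) {
  stopifnot(is.list(pieces), length(pieces) >= 1)
  lapply(pieces, function(p) {
    stopifnot(is.list(p), inherits(p$cond, "mathexpr"), inherits(p$value, "mathexpr"))
  })
  if (!is.null(otherwise)) stopifnot(inherits(otherwise, "mathexpr"))
  new_mathexpr(list(k = "piecewise", pieces = pieces, otherwise = otherwise))
}

# shortest decimal spelling that round-trips to the same double, so that a
# value like 1e-5 enters the decimal context as exactly 0.00001 rather than
# as the 17-digit expansion of its binary approximation
num_to_decimal_string <- function(x) {
  for (d in 1:17) {
    s <- formatC(x, digits = d, format = "g", mode = "double")
    if (as.numeric(s) == x) return(s)
  }
  s
}

is_mathexpr <- function(x) inherits(x, "mathexpr")

#' Free variables of an expression
#'
#' Collects the identifiers referenced by an expression tree.  A derivative
#' reference contributes both the differentiated variable and the bound
#' (time) variable.
#'
#' @param e A `mathexpr`.
#' @return A character vector of unique identifiers (empty if none).
#' @export
free_variables <- function(e) {
  stopifnot(is_mathexpr(e))
  out <- character(0)
  walk <- function(n) {
    switch(n$k,
      num = NULL,
      var = out[[length(out) + 1L]] <<- n$name,
      deriv = { out[[length(out) + 1L]] <<- n$var; out[[length(out) + 1L]] <<- n$bvar },
      neg = walk(n$a),
      op = , rel = { walk(n$a); walk(n$b) },
      call = lapply(n$args, walk),
      piecewise = {
        lapply(n$pieces, function(p) { walk(p$cond); walk(p$value) })
        if (!is.null(n$otherwise)) walk(n$otherwise)
      },
      stop("corrupt expression node kind '", n$k, "'", call. = FALSE)
    )
    invisible(NULL)
  }
  walk(e)
  unique(out)
}

# rename variable references according to a named character map (old -> new);
# names absent from the map are left untouched
rename_vars <- function(e, map) {
  walk <- function(n) {
    switch(n$k,
      num = n,
      var = { if (!is.na(map[n$name])) n$name <- unname(map[n$name]); n },
      deriv = {
        if (!is.na(map[n$var])) n$var <- unname(map[n$var])
        if (!is.na(map[n$bvar])) n$bvar <- unname(map[n$bvar])
        n
      },
      neg = { n$a <- walk(n$a); n },
      op = , rel = { n$a <- walk(n$a); n$b <- walk(n$b); n },
      call = { n$args <- lapply(n$args, walk); n },
      piecewise = {
        n$pieces <- lapply(n$pieces, function(p) {
          p$cond <- walk(p$cond); p$value <- walk(p$value); p
        })
        if (!is.null(n$otherwise)) n$otherwise <- walk(n$otherwise)
        n
      }
    )
  }
  new_mathexpr(walk(e))
}

# structural equality with an optional variable-name bijection (alpha map);
# numeric literals compare by numeric value, not spelling
expr_equal <- function(a, b, var_map = NULL) {
  eq <- function(x, y) {
    if (x$k != y$k) return(FALSE)
    switch(x$k,
      num = dec_cmp(x$value, y$value) == 0L,
      var = {
        if (is.null(var_map)) x$name == y$name
        else !is.na(var_map[x$name]) && unname(var_map[x$name]) == y$name
      },
      deriv = x$var == y$var && x$bvar == y$bvar,
      neg = eq(x$a, y$a),
      op = , rel = x$op == y$op && eq(x$a, y$a) && eq(x$b, y$b),
      call = x$fn == y$fn && length(x$args) == length(y$args) &&
        all(mapply(eq, x$args, y$args)),
      piecewise = {
        if (length(x$pieces) != length(y$pieces)) return(FALSE)
        po <- all(mapply(function(p, q) eq(p$cond, q$cond) && eq(p$value, q$value),
                         x$pieces, y$pieces))
        oo <- (is.null(x$otherwise) && is.null(y$otherwise)) ||
          (!is.null(x$otherwise) && !is.null(y$otherwise) && eq(x$otherwise, y$otherwise))
        po && oo
      }
    )
  }
  eq(a, b)
}

# infix rendering, used for printing, equation listings and code emission;
# dialect "text" uses ^ and sqrt(), "r" is valid R, "c" is valid C99
render_expr <- function(e, dialect = c("text", "r", "c")) {
  dialect <- match.arg(dialect)
  prec_of <- c(add = 1, sub = 1, mul = 2, div = 2, pow = 3)
  paren <- function(s, need) if (need) paste0("(", s, ")") else s
  walk <- function(n, ctx) {
    switch(n$k,
      num = {
        v <- n$value
        if (dialect == "c" && !grepl("[.eE]", v)) v <- paste0(v, ".0")
        v
      },
      var = n$name,
      deriv = paste0("d", n$var, "/d", n$bvar),
      neg = paren(paste0("-", walk(n$a, 4)), ctx > 2),
      op = {
        p <- prec_of[[n$op]]
        if (n$op == "pow") {
          if (dialect == "c") {
            paste0("pow(", walk(n$a, 0), ", ", walk(n$b, 0), ")")
          } else {
            paren(paste0(walk(n$a, p + 1), "^", walk(n$b, p)), ctx > p)
          }
        } else {
          sym <- c(add = " + ", sub = " - ", mul = "*", div = "/")[[n$op]]
          lhs <- walk(n$a, p)
          rhs <- walk(n$b, p + if (n$op %in% c("sub", "div")) 1 else 0)
          paren(paste0(lhs, sym, rhs), ctx > p)
        }
      },
      call = render_call(n, walk, dialect),
      rel = {
        sym <- c(lt = " < ", leq = " <= ", gt = " > ", geq = " >= ",
                 eq = " == ", neq = " != ")[[n$op]]
        paste0("(", walk(n$a, 0), sym, walk(n$b, 0), ")")
      },
      piecewise = render_piecewise(n, walk, dialect)
    )
  }
  walk(e, 0)
}

render_call <- function(n, walk, dialect) {
  a <- vapply(n$args, walk, "", ctx = 0)
  switch(n$fn,
    exp = paste0("exp(", a[[1]], ")"),
    ln = paste0(if (dialect == "text") "ln(" else "log(", a[[1]], ")"),
    log = if (length(a) == 1) {
      paste0("log10(", a[[1]], ")")
    } else if (dialect == "c") {
      paste0("(log(", a[[2]], ")/log(", a[[1]], "))")
    } else if (dialect == "r") {
      paste0("log(", a[[2]], ", base = ", a[[1]], ")")
    } else {
      paste0("log(", a[[2]], ", ", a[[1]], ")")
    },
    root = if (length(a) == 1) {
      paste0("sqrt(", a[[1]], ")")
    } else if (dialect == "c") {
      paste0("pow(", a[[2]], ", 1.0/(", a[[1]], "))")
    } else {
      paste0("(", a[[2]], ")^(1/(", a[[1]], "))")
    }
  )
}

render_piecewise <- function(n, walk, dialect) {
  if (dialect == "c") {
    out <- ""
    for (p in n$pieces)
      out <- paste0(out, walk(p$cond, 0), " ? ", walk(p$value, 0), " : ")
    tail_v <- if (!is.null(n$otherwise)) walk(n$otherwise, 0) else "(0.0/0.0)"
    paste0("(", out, tail_v, ")")
  } else if (dialect == "r") {
    out <- ""
    for (p in n$pieces)
      out <- paste0(out, "if (", walk(p$cond, 0), ") ", walk(p$value, 0), " else ")
    tail_v <- if (!is.null(n$otherwise)) walk(n$otherwise, 0) else "NaN"
    paste0("(", out, tail_v, ")")
  } else {
    parts <- vapply(n$pieces, function(p)
      paste0(walk(p$value, 0), " if ", walk(p$cond, 0)), "")
    if (!is.null(n$otherwise))
      parts <- c(parts, paste0(walk(n$otherwise, 0), " otherwise"))
    paste0("{ ", paste(parts, collapse = "; "), " }")
  }
}

#' @export
print.mathexpr <- function(x, ...) {
  cat("<mathexpr> ", render_expr(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.mathexpr <- function(x, ...) render_expr(x)

# Bytecode compilation --------------------------------------------------------

OPC <- c(LOAD = 1L, LIT = 2L, ADD = 3L, SUB = 4L, MUL = 5L, DIV = 6L,
         POW = 7L, NEG = 8L, EXP = 9L, LN = 10L, LOG10 = 11L, LOGB = 12L,
         ROOT2 = 13L, ROOTN = 14L, POWI = 15L, LT = 16L, LE = 17L, GT = 18L,
         GE = 19L, EQ = 20L, NEQ = 21L, JZ = 22L, JMP = 23L, NOCASE = 24L)

new_lit_pool <- function() {
  env <- new.env(parent = emptyenv())
  env$values <- character(0)
  env
}

lit_index <- function(pool, value) {
  # 0-based index into the literal pool, deduplicated by spelling
  i <- match(value, pool$values)
  if (is.na(i)) {
    pool$values <- c(pool$values, value)
    i <- length(pool$values)
  }
  i - 1L
}

# compile one expression to a 2-column (op, arg) integer matrix; slot_map is a
# named integer vector of 0-based slot indices; pool accumulates literals
compile_expr <- function(e, slot_map, pool) {
  ops <- integer(0)
  args <- integer(0)
  emit <- function(op, arg = 0L) {
    ops[[length(ops) + 1L]] <<- op
    args[[length(args) + 1L]] <<- as.integer(arg)
    length(ops)  # 1-based position of this instruction
  }
  patch <- function(pos, target) args[[pos]] <<- as.integer(target)
  here <- function() length(ops)  # 0-based index of the *next* instruction
  walk <- function(n) {
    switch(n$k,
      num = emit(OPC[["LIT"]], lit_index(pool, n$value)),
      var = {
        ix <- slot_map[n$name]
        if (is.na(ix))
          stop("unbound variable '", n$name, "' in expression", call. = FALSE)
        emit(OPC[["LOAD"]], ix)
      },
      deriv = stop("derivative reference cannot appear in an evaluated expression",
                   call. = FALSE),
      neg = { walk(n$a); emit(OPC[["NEG"]]) },
      op = {
        if (n$op == "pow") {
          k <- pow_int_exponent(n$b)
          if (!is.null(k)) {
            walk(n$a)
            emit(OPC[["POWI"]], k)
          } else {
            walk(n$a); walk(n$b); emit(OPC[["POW"]])
          }
        } else {
          walk(n$a); walk(n$b)
          emit(OPC[[c(add = "ADD", sub = "SUB", mul = "MUL", div = "DIV")[[n$op]]]])
        }
      },
      call = {
        if (n$fn == "exp") { walk(n$args[[1]]); emit(OPC[["EXP"]]) }
        else if (n$fn == "ln") { walk(n$args[[1]]); emit(OPC[["LN"]]) }
        else if (n$fn == "log") {
          if (length(n$args) == 1) { walk(n$args[[1]]); emit(OPC[["LOG10"]]) }
          else { walk(n$args[[1]]); walk(n$args[[2]]); emit(OPC[["LOGB"]]) }
        } else {  # root
          if (length(n$args) == 1) { walk(n$args[[1]]); emit(OPC[["ROOT2"]]) }
          else { walk(n$args[[1]]); walk(n$args[[2]]); emit(OPC[["ROOTN"]]) }
        }
      },
      rel = {
        walk(n$a); walk(n$b)
        emit(OPC[[c(lt = "LT", leq = "LE", gt = "GT", geq = "GE",
                    eq = "EQ", neq = "NEQ")[[n$op]]]])
      },
      piecewise = {
        end_jumps <- integer(0)
        for (p in n$pieces) {
          walk(p$cond)
          jz <- emit(OPC[["JZ"]])
          walk(p$value)
          end_jumps <- c(end_jumps, emit(OPC[["JMP"]]))
          patch(jz, here())
        }
        if (!is.null(n$otherwise)) walk(n$otherwise) else emit(OPC[["NOCASE"]])
        for (j in end_jumps) patch(j, here())
      }
    )
    invisible(NULL)
  }
  walk(e)
  cbind(op = ops, arg = args)
}

pow_int_exponent <- function(b) {
  if (b$k == "num") {
    v <- suppressWarnings(as.numeric(b$value))
    if (is.finite(v) && v == round(v) && abs(v) <= 1e6) return(as.integer(v))
  }
  if (b$k == "neg") {
    k <- pow_int_exponent(b$a)
    if (!is.null(k)) return(-k)
  }
  NULL
}

#' Evaluate an expression at given variable bindings
#'
#' Evaluates an expression tree in either IEEE double precision or a decimal
#' floating-point context of `precision` significant digits (every operation
#' rounds half-even to the context).  Division by zero and domain violations
#' (logarithm of a non-positive value, even root of a negative value) raise
#' errors rather than producing `NaN`.
#'
#' @param e A `mathexpr`.
#' @param bindings Named vector (numeric, or character decimal strings) giving
#'   a value for every free variable of `e`.
#' @param precision `"double"` (the default) or an integer number of decimal
#'   significant digits between 1 and 50.
#' @return A double in double mode; a decimal string carrying the full context
#'   precision in decimal mode.
#' @examples
#' e <- mx_op("pow", mx_var("x"), mx_num(3))
#' evaluate_expr(e, c(x = 2))
#' evaluate_expr(e, c(x = "2"), precision = 32)
#' @export
evaluate_expr <- function(e, bindings = c(), precision = "double") {
  stopifnot(is_mathexpr(e))
  digits <- parse_precision(precision)
  fv <- free_variables(e)
  missing_v <- setdiff(fv, names(bindings))
  if (length(missing_v) > 0)
    stop("unbound variable(s): ", paste(missing_v, collapse = ", "), call. = FALSE)
  vals <- bindings_to_strings(bindings)
  slot_map <- stats::setNames(seq_along(vals) - 1L, names(vals))
  pool <- new_lit_pool()
  code <- compile_expr(e, slot_map, pool)
  res <- cpp_eval_expr(code, pool$values, unname(vals), digits)
  if (nzchar(res$error)) stop("evaluation error: ", res$error, call. = FALSE)
  if (digits == 0) res$value else res$chr
}

parse_precision <- function(precision) {
  if (identical(precision, "double") || is.null(precision)) return(0L)
  if (is.character(precision) && grepl("^decimal:[0-9]+$", precision))
    precision <- as.integer(sub("^decimal:", "", precision))
  if (is.numeric(precision) && length(precision) == 1 &&
      precision == round(precision) && precision >= 1 && precision <= 50)
    return(as.integer(precision))
  stop("precision must be \"double\" or an integer between 1 and 50",
       call. = FALSE)
}

bindings_to_strings <- function(bindings) {
  if (length(bindings) == 0) return(stats::setNames(character(0), character(0)))
  if (is.numeric(bindings)) {
    stats::setNames(vapply(bindings, num_to_decimal_string, ""), names(bindings))
  } else if (is.character(bindings)) {
    bindings
  } else if (is.list(bindings)) {
    stats::setNames(vapply(bindings, function(v) {
      if (is.numeric(v)) num_to_decimal_string(v) else as.character(v)
    }, ""), names(bindings))
  } else {
    stop("bindings must be a named numeric or character vector", call. = FALSE)
  }
}

# Decimal scalar helpers ------------------------------------------------------

#' Decimal floating-point scalar arithmetic
#'
#' Direct access to the package's decimal arithmetic context, mainly useful
#' for building closed-form reference values at a given precision (for
#' example the stability polynomial of a scheme, or \eqn{(1-\delta)^n} for
#' repeated Euler steps on \eqn{dx/dt = -x}).  All values are decimal strings;
#' each operation rounds half-even to `digits` significant digits.
#'
#' @param op One of `"add"`, `"sub"`, `"mul"`, `"div"`, `"pow"`.
#' @param fn One of `"neg"`, `"sqrt"`, `"exp"`, `"ln"`.
#' @param a,b Decimal strings (or numbers).
#' @param digits Context precision, 1 to 50 significant digits.
#' @return A decimal string; `dec_cmp()` returns -1, 0 or 1.
#' @examples
#' dec_op("div", "2", "3", 7)
#' dec_cmp("0.1", "0.10")
#' @export
dec_op <- function(op, a, b, digits) {
  cpp_dec_op(op, as_dec_string(a), as_dec_string(b), as.integer(digits))
}

#' @rdname dec_op
#' @export
dec_fun <- function(fn, a, digits) {
  cpp_dec_fun(fn, as_dec_string(a), as.integer(digits))
}

#' @rdname dec_op
#' @export
dec_cmp <- function(a, b) {
  cpp_dec_cmp(as_dec_string(a), as_dec_string(b))
}

as_dec_string <- function(x) {
  if (is.numeric(x)) num_to_decimal_string(x) else as.character(x)
}
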
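# MathML content markup <-> mathexpr -----------------------------------------

tecgen_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "tecgen_error")))
}

#' Parse a MathML content-markup element into an expression tree
#'
#' Supports the content-markup subset used by the model and scheme dialects:
#' `apply` with `plus`, `minus` (unary or binary), `times`, `divide`, `power`,
#' `exp`, `ln`, `log` (optional `logbase`), `root` (optional `degree`), the
#' relations `lt`, `leq`, `gt`, `geq`, `eq`, `neq`, differentiation (`diff`
#' with a `bvar`), `piecewise`, `ci` and `cn` (kept as exact decimal strings,
#' including `e-notation`).  Any other element is a hard error: downstream
#' symbolic rewriting must never meet unknown nodes.
#'
#' @param node An `xml2` element (namespace prefixes are ignored).
#' @return A `mathexpr`.
#' @export
parse_mathml_expr <- function(node) {
  if (inherits(node, "xml_document")) node <- xml2::xml_root(node)
  stopifnot(inherits(node, "xml_node"))
  mathml_to_expr(node)
}

mathml_name <- function(node) sub("^.*:", "", xml2::xml_name(node))

mathml_to_expr <- function(node) {
  nm <- mathml_name(node)
  kids <- xml2::xml_children(node)
  switch(nm,
    math = {
      if (length(kids) != 1)
        tecgen_stop("<math> must wrap exactly one expression", "tecgen_parse_error")
      mathml_to_expr(kids[[1]])
    },
    cn = parse_cn(node),
    ci = mx_var(trimws(xml2::xml_text(node))),
    apply = parse_apply(node, kids),
    piecewise = parse_piecewise_node(kids),
    tecgen_stop(paste0("unsupported MathML element <", nm, ">"),
                "tecgen_unsupported_error")
  )
}

parse_cn <- function(node) {
  type <- xml2::xml_attr(node, "type")
  if (!is.na(type) && type == "e-notation") {
    # <cn type="e-notation">mantissa<sep/>exponent</cn>
    contents <- xml2::xml_contents(node)
    texts <- trimws(vapply(contents, xml2::xml_text, ""))
    is_sep <- vapply(contents, function(x) xml2::xml_name(x) == "sep", TRUE)
    texts <- texts[!is_sep & nzchar(texts)]
    if (length(texts) != 2)
      tecgen_stop("malformed e-notation <cn>", "tecgen_parse_error")
    return(mx_num(paste0(texts[[1]], "e", texts[[2]])))
  }
  if (!is.na(type) && type != "real" && type != "integer")
    tecgen_stop(paste0("unsupported <cn> type '", type, "'"),
                "tecgen_unsupported_error")
  mx_num(trimws(xml2::xml_text(node)))
}

parse_apply <- function(node, kids) {
  if (length(kids) < 1)
    tecgen_stop("empty <apply>", "tecgen_parse_error")
  op <- mathml_name(kids[[1]])
  args <- kids[-1]
  n <- length(args)
  fold <- function(op2, xs) Reduce(function(a, b) mx_op(op2, a, b), xs)
  ex <- function(i) mathml_to_expr(args[[i]])
  all_ex <- function() lapply(seq_len(n), ex)
  switch(op,
    plus = {
      if (n == 0) mx_num("0") else fold("add", all_ex())
    },
    minus = {
      if (n == 1) mx_neg(ex(1))
      else if (n == 2) mx_op("sub", ex(1), ex(2))
      else tecgen_stop("<minus> takes one or two arguments", "tecgen_parse_error")
    },
    times = {
      if (n < 1) tecgen_stop("<times> needs arguments", "tecgen_parse_error")
      fold("mul", all_ex())
    },
    divide = {
      if (n != 2) tecgen_stop("<divide> takes two arguments", "tecgen_parse_error")
      mx_op("div", ex(1), ex(2))
    },
    power = {
      if (n != 2) tecgen_stop("<power> takes two arguments", "tecgen_parse_error")
      mx_op("pow", ex(1), ex(2))
    },
    exp = mx_call("exp", list(ex(1))),
    ln = mx_call("ln", list(ex(1))),
    log = parse_log(args),
    root = parse_root(args),
    diff = parse_diff(args),
    eq = mx_rel("eq", ex(1), ex(2)),
    neq = mx_rel("neq", ex(1), ex(2)),
    lt = mx_rel("lt", ex(1), ex(2)),
    leq = mx_rel("leq", ex(1), ex(2)),
    gt = mx_rel("gt", ex(1), ex(2)),
    geq = mx_rel("geq", ex(1), ex(2)),
    tecgen_stop(paste0("unsupported MathML element <", op, ">"),
                "tecgen_unsupported_error")
  )
}

parse_log <- function(args) {
  nms <- vapply(args, mathml_name, "")
  if (nms[[1]] == "logbase") {
    base <- mathml_to_expr(xml2::xml_children(args[[1]])[[1]])
    mx_call("log", list(base, mathml_to_expr(args[[2]])))
  } else {
    mx_call("log", list(mathml_to_expr(args[[1]])))
  }
}

parse_root <- function(args) {
  nms <- vapply(args, mathml_name, "")
  if (nms[[1]] == "degree") {
    degree <- mathml_to_expr(xml2::xml_children(args[[1]])[[1]])
    mx_call("root", list(degree, mathml_to_expr(args[[2]])))
  } else {
    mx_call("root", list(mathml_to_expr(args[[1]])))
  }
}

parse_diff <- function(args) {
  nms <- vapply(args, mathml_name, "")
  bi <- which(nms == "bvar")
  if (length(bi) != 1)
    tecgen_stop("<diff> needs exactly one <bvar>", "tecgen_parse_error")
  bvar_kids <- xml2::xml_children(args[[bi]])
  if (length(bvar_kids) != 1 || mathml_name(bvar_kids[[1]]) != "ci")
    tecgen_stop("<bvar> must hold a single <ci>", "tecgen_parse_error")
  target <- args[[setdiff(seq_along(args), bi)[1]]]
  if (mathml_name(target) != "ci")
    tecgen_stop("<diff> target must be a <ci>", "tecgen_unsupported_error")
  mx_deriv(trimws(xml2::xml_text(target)), trimws(xml2::xml_text(bvar_kids[[1]])))
}

parse_piecewise_node <- function(kids) {
  pieces <- list()
  otherwise <- NULL
  for (k in kids) {
    nm <- mathml_name(k)
    kk <- xml2::xml_children(k)
    if (nm == "piece") {
      if (length(kk) != 2)
        tecgen_stop("<piece> must hold value and condition", "tecgen_parse_error")
      pieces[[length(pieces) + 1L]] <-
        list(cond = mathml_to_expr(kk[[2]]), value = mathml_to_expr(kk[[1]]))
    } else if (nm == "otherwise") {
      otherwise <- mathml_to_expr(kk[[1]])
    } else {
      tecgen_stop(paste0("unsupported element <", nm, "> in <piecewise>"),
                  "tecgen_unsupported_error")
    }
  }
  mx_piecewise(pieces, otherwise)
}

# serialization ---------------------------------------------------------------

#' Serialize an expression tree to MathML content markup
#'
#' Inverse of [parse_mathml_expr()]; parsing the output yields a structurally
#' identical tree (numeric literals keep their spelling).
#'
#' @param e A `mathexpr`.
#' @param indent Indentation prefix applied to every line.
#' @return A character scalar of MathML content markup (no `<math>` wrapper).
#' @export
serialize_mathml <- function(e, indent = "") {
  stopifnot(is_mathexpr(e))
  paste0(mathml_lines(e, indent), collapse = "\n")
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

mathml_lines <- function(e, ind) {
  wrap <- function(op, children) {
    c(paste0(ind, "<apply><", op, "/>"),
      unlist(lapply(children, mathml_lines, ind = paste0(ind, "  "))),
      paste0(ind, "</apply>"))
  }
  switch(e$k,
    num = paste0(ind, "<cn>", xml_escape(e$value), "</cn>"),
    var = paste0(ind, "<ci>", xml_escape(e$name), "</ci>"),
    deriv = c(
      paste0(ind, "<apply><diff/>"),
      paste0(ind, "  <bvar><ci>", xml_escape(e$bvar), "</ci></bvar>"),
      paste0(ind, "  <ci>", xml_escape(e$var), "</ci>"),
      paste0(ind, "</apply>")
    ),
    neg = wrap("minus", list(e$a)),
    op = wrap(c(add = "plus", sub = "minus", mul = "times",
                div = "divide", pow = "power")[[e$op]], list(e$a, e$b)),
    rel = wrap(e$op, list(e$a, e$b)),
    call = serialize_call(e, ind),
    piecewise = serialize_piecewise(e, ind)
  )
}

serialize_call <- function(e, ind) {
  ind2 <- paste0(ind, "  ")
  if (e$fn %in% c("exp", "ln") || length(e$args) == 1) {
    c(paste0(ind, "<apply><", e$fn, "/>"),
      unlist(lapply(e$args, mathml_lines, ind = ind2)),
      paste0(ind, "</apply>"))
  } else {
    qualifier <- if (e$fn == "log") "logbase" else "degree"
    c(paste0(ind, "<apply><", e$fn, "/>"),
      paste0(ind2, "<", qualifier, ">"),
      mathml_lines(e$args[[1]], paste0(ind2, "  ")),
      paste0(ind2, "</", qualifier, ">"),
      mathml_lines(e$args[[2]], ind2),
      paste0(ind, "</apply>"))
  }
}

serialize_piecewise <- function(e, ind) {
  ind2 <- paste0(ind, "  ")
  out <- paste0(ind, "<piecewise>")
  for (p in e$pieces) {
    out <- c(out, paste0(ind2, "<piece>"),
             mathml_lines(p$value, paste0(ind2, "  ")),
             mathml_lines(p$cond, paste0(ind2, "  ")),
             paste0(ind2, "</piece>"))
  }
  if (!is.null(e$otherwise)) {
    out <- c(out, paste0(ind2, "<otherwise>"),
             mathml_lines(e$otherwise, paste0(ind2, "  ")),
             paste0(ind2, "</otherwise>"))
  }
  c(out, paste0(ind, "</piecewise>"))
}
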
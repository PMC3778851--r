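# ODE solving scheme description (TecML) -------------------------------------
#
# A scheme is an ordered list of typed statements over stage-indexed symbol
# vectors: the differential variable vector xi_0..xi_N (xi_0 bound to the
# state at time t, xi_N to the state at t + delta), derivative vectors
# kappa_1..kappa_N, temporal (arithmetic) vectors iota_i, stage times tau_i,
# the time step delta and the model constants zeta.  Statement kinds:
#
#   input        xi_0   = xi^t                (one per scheme)
#   time_input   tau_0  = t
#   arith        iota_i = g(xi_i, tau_i, ...) (unfolded from the model)
#   deriv        kappa_{i+1} = f(xi_i, iota_i, tau_i, ...)
#   stage_update xi_j   = <explicit formula over xi_k, kappa_k, delta>
#   time_update  tau_j  = <explicit formula over tau_k, delta>
#   output       xi^{t+delta} = xi_N, or an explicit combine formula
#
# Explicitness is definition-before-use over the stage-indexed symbols;
# implicit schemes fail validation.

TEC_KINDS <- c("input", "time_input", "arith", "deriv", "stage_update",
               "time_update", "output")
TEC_KIND_XML <- c(input = "input-binding", time_input = "time-binding",
                  arith = "arith-eval", deriv = "deriv-eval",
                  stage_update = "stage-update", time_update = "time-update",
                  output = "output-binding")
TEC_ROLES <- c(xi = "diffvar", kappa = "derivativevar", iota = "arithvar",
               tau = "timevar", delta = "deltatimevar", zeta = "constvar")

tec_statement <- function(kind, stage = NA_integer_, expr = NULL) {
  kind <- match.arg(kind, TEC_KINDS)
  if (!is.null(expr)) stopifnot(is_mathexpr(expr))
  list(kind = kind, stage = as.integer(stage), expr = expr)
}

#' Construct an ODE solving scheme
#'
#' @param name Scheme name.
#' @param n_stages Number of stages (the index of the output differential
#'   vector; Heun's method has 2, classical Runge-Kutta 4).
#' @param statements Ordered list of statements (see the package vignette for
#'   the statement algebra); usually produced by [parse_tecml()] or
#'   [builtin_scheme()].
#' @return A `tec_scheme` object.
#' @export
tec_scheme <- function(name, n_stages, statements) {
  structure(list(name = name, n_stages = as.integer(n_stages),
                 statements = statements),
            class = "tec_scheme")
}

#' @export
print.tec_scheme <- function(x, ...) {
  cat("<tec_scheme> ", x$name, " (", x$n_stages, " stage",
      if (x$n_stages != 1) "s", ")\n", sep = "")
  for (s in x$statements) {
    lhs <- switch(s$kind,
      input = "xi_0 = xi^t",
      time_input = "tau_0 = t",
      arith = paste0("iota_", s$stage, " = g(...)"),
      deriv = paste0("kappa_", s$stage + 1L, " = f(...)"),
      stage_update = paste0("xi_", s$stage, " = ", render_expr(s$expr)),
      time_update = paste0("tau_", s$stage, " = ", render_expr(s$expr)),
      output = if (is.null(s$expr)) paste0("xi^{t+delta} = xi_", x$n_stages)
               else paste0("xi^{t+delta} = ", render_expr(s$expr))
    )
    cat("  ", lhs, "\n", sep = "")
  }
  invisible(x)
}

# symbols legal in stage-update / time-update / output formulas
scheme_symbol_stage <- function(name) {
  m <- regmatches(name, regexec("^(xi|kappa|iota|tau)_([0-9]+)$", name))[[1]]
  if (length(m) == 3) list(base = m[[2]], stage = as.integer(m[[3]]))
  else if (name == "delta") list(base = "delta", stage = NA_integer_)
  else if (name == "t") list(base = "t", stage = NA_integer_)
  else NULL
}

#' Validate an ODE solving scheme
#'
#' Empty diagnostics iff the scheme invariants hold: exactly one input and
#' one output binding, stage indices within range, all statement formulas
#' restricted to scheme symbols, and definition-before-use over the
#' stage-indexed symbols (which is what makes the scheme explicit; implicit
#' schemes are rejected here).
#'
#' @param s A [tec_scheme()].
#' @return Diagnostics tibble (see [validate_model()]).
#' @export
validate_scheme <- function(s) {
  stopifnot(inherits(s, "tec_scheme"))
  d <- diag_rows()
  N <- s$n_stages
  if (N < 1) diag_add(d, "error", "validate_scheme", "scheme must have >= 1 stage")
  kinds <- vapply(s$statements, `[[`, "", "kind")
  if (sum(kinds == "input") != 1)
    diag_add(d, "error", "validate_scheme",
             paste0("scheme must have exactly one input binding (found ",
                    sum(kinds == "input"), ")"))
  if (sum(kinds == "output") != 1)
    diag_add(d, "error", "validate_scheme",
             paste0("scheme must have exactly one output binding (found ",
                    sum(kinds == "output"), ")"))
  has_arith <- any(kinds == "arith")
  defined <- character(0)
  for (i in seq_along(s$statements)) {
    st <- s$statements[[i]]
    where <- paste0("statement ", i, " (", TEC_KIND_XML[[st$kind]], ")")
    need <- character(0)
    defines <- character(0)
    if (st$kind %in% c("arith", "deriv", "stage_update", "time_update")) {
      if (is.na(st$stage) || st$stage < 0 || st$stage > N) {
        diag_add(d, "error", "validate_scheme",
                 paste0(where, ": stage index out of range 0..", N))
        next
      }
    }
    switch(st$kind,
      input = defines <- "xi_0",
      time_input = defines <- "tau_0",
      arith = {
        need <- c(paste0("xi_", st$stage), paste0("tau_", st$stage))
        defines <- paste0("iota_", st$stage)
      },
      deriv = {
        need <- c(paste0("xi_", st$stage), paste0("tau_", st$stage),
                  if (has_arith) paste0("iota_", st$stage))
        defines <- paste0("kappa_", st$stage + 1L)
        if (st$stage + 1L > N)
          diag_add(d, "error", "validate_scheme",
                   paste0(where, ": defines kappa_", st$stage + 1L,
                          " beyond the last stage"))
      },
      stage_update = , time_update = , output = {
        if (st$kind != "output" || !is.null(st$expr)) {
          if (is.null(st$expr)) {
            if (st$kind != "output") {
              diag_add(d, "error", "validate_scheme",
                       paste0(where, ": missing update formula"))
              next
            }
          }
        }
        expr <- st$expr
        if (st$kind == "output" && is.null(expr))
          expr <- mx_var(paste0("xi_", N))
        for (v in free_variables(expr)) {
          sym <- scheme_symbol_stage(v)
          if (is.null(sym)) {
            diag_add(d, "error", "validate_scheme",
                     paste0(where, ": '", v, "' is not a scheme symbol"))
          } else if (sym$base %in% c("xi", "kappa", "iota", "tau")) {
            need <- c(need, v)
            if (!is.na(sym$stage) && sym$stage > N)
              diag_add(d, "error", "validate_scheme",
                       paste0(where, ": stage index of '", v,
                              "' exceeds the stage count ", N))
          }
        }
        if (st$kind == "stage_update") defines <- paste0("xi_", st$stage)
        if (st$kind == "time_update") defines <- paste0("tau_", st$stage)
      }
    )
    for (v in unique(need)) {
      if (!(v %in% defined))
        diag_add(d, "error", "validate_scheme",
                 paste0(where, ": uses '", v, "' before it is defined"))
    }
    defined <- union(defined, defines)
  }
  diag_result(d)
}

# parsing ---------------------------------------------------------------------

#' Parse a TecML scheme document
#'
#' Dialect: root `<tecml name="..." stages="N">`, an optional `<symbols>`
#' block declaring the role of each symbol family (checked against the fixed
#' role table: `xi` diffvar, `kappa` derivativevar, `iota` arithvar, `tau`
#' timevar, `delta` deltatimevar, `zeta` constvar), then `<step>` elements in
#' execution order with `kind` (`input-binding`, `time-binding`,
#' `arith-eval`, `deriv-eval`, `stage-update`, `time-update`,
#' `output-binding`) and `stage` attributes; stage updates embed their
#' formula as MathML content markup over the symbol names `xi_0`, `kappa_1`,
#' `tau_0`, `delta`, ...
#'
#' @param document TecML text, a file path, or an `xml2` document.
#' @param check If `TRUE` (default) stop on any validation error.
#' @return A [tec_scheme()] with attribute `"diagnostics"`.
#' @export
parse_tecml <- function(document, check = TRUE) {
  doc <- read_xml_input(document)
  xml2::xml_ns_strip(doc)
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "tecml")
    tecgen_stop("root element must be <tecml>", "tecgen_parse_error")
  name <- xml2::xml_attr(root, "name")
  if (is.na(name)) name <- "unnamed"
  stages <- suppressWarnings(as.integer(xml2::xml_attr(root, "stages")))
  if (is.na(stages))
    tecgen_stop("<tecml> needs an integer 'stages' attribute", "tecgen_parse_error")

  for (sym in xml2::xml_find_all(root, "./symbols/symbol")) {
    base <- xml2::xml_attr(sym, "base")
    role <- xml2::xml_attr(sym, "role")
    if (is.na(base) || is.na(role) || is.na(TEC_ROLES[base]) ||
        TEC_ROLES[[base]] != role)
      tecgen_stop(paste0("symbol/role mismatch: base '", base, "' with role '",
                         role, "'"), "tecgen_scheme_error")
  }

  kind_map <- stats::setNames(names(TEC_KIND_XML), unname(TEC_KIND_XML))
  statements <- list()
  for (step in xml2::xml_find_all(root, "./step")) {
    kx <- xml2::xml_attr(step, "kind")
    kind <- kind_map[kx]
    if (is.na(kind))
      tecgen_stop(paste0("unknown step kind '", kx, "'"), "tecgen_scheme_error")
    stage <- suppressWarnings(as.integer(xml2::xml_attr(step, "stage")))
    math <- xml2::xml_find_first(step, "./math")
    expr <- NULL
    if (!inherits(math, "xml_missing")) expr <- parse_mathml_expr(math)
    statements[[length(statements) + 1L]] <- tec_statement(kind, stage, expr)
  }
  s <- tec_scheme(name, stages, statements)
  diag <- validate_scheme(s)
  attr(s, "diagnostics") <- diag
  if (check) stop_on_diag(diag, "tecgen_scheme_error")
  s
}

#' Serialize a scheme to TecML
#'
#' Inverse of [parse_tecml()].
#'
#' @param s A [tec_scheme()].
#' @return TecML text.
#' @export
serialize_tecml <- function(s) {
  stopifnot(inherits(s, "tec_scheme"))
  out <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    paste0("<tecml name=\"", xml_escape(s$name), "\" stages=\"", s$n_stages, "\">"),
    "  <symbols>",
    vapply(names(TEC_ROLES), function(b)
      paste0("    <symbol base=\"", b, "\" role=\"", TEC_ROLES[[b]], "\"/>"), ""),
    "  </symbols>"
  )
  for (st in s$statements) {
    attrs <- paste0(" kind=\"", TEC_KIND_XML[[st$kind]], "\"")
    if (!is.na(st$stage)) attrs <- paste0(attrs, " stage=\"", st$stage, "\"")
    if (is.null(st$expr)) {
      out <- c(out, paste0("  <step", attrs, "/>"))
    } else {
      out <- c(out,
        paste0("  <step", attrs, ">"),
        "    <math xmlns=\"http://www.w3.org/1998/Math/MathML\">",
        mathml_lines(st$expr, "      "),
        "    </math>",
        "  </step>")
    }
  }
  paste(c(out, "</tecml>", ""), collapse = "\n")
}

scheme_equal <- function(a, b) {
  if (a$n_stages != b$n_stages) return(FALSE)
  if (length(a$statements) != length(b$statements)) return(FALSE)
  for (i in seq_along(a$statements)) {
    x <- a$statements[[i]]; y <- b$statements[[i]]
    if (x$kind != y$kind) return(FALSE)
    if (!identical(is.na(x$stage), is.na(y$stage))) return(FALSE)
    if (!is.na(x$stage) && x$stage != y$stage) return(FALSE)
    if (is.null(x$expr) != is.null(y$expr)) return(FALSE)
    if (!is.null(x$expr) && !expr_equal(x$expr, y$expr)) return(FALSE)
  }
  TRUE
}

# built-in schemes ------------------------------------------------------------

#' Pinned built-in ODE solving schemes
#'
#' Returns one of the four shipped explicit schemes: `"euler"` (one stage),
#' `"modified_euler"` (Heun predictor-corrector, two stages), `"rk2"`
#' (midpoint, two stages) and `"rk4"` (classical fourth-order Runge-Kutta).
#'
#' The statement encodings are pinned conventions and part of the package's
#' data: the Euler scheme carries its time update as a counted statement; the
#' modified Euler scheme keeps the final corrector and the output bindings as
#' separate statements; the classical Runge-Kutta scheme folds its final
#' combine into the output bindings.  Under these conventions the
#' FitzHugh-Nagumo fixture expands to 11 / 16 / 26 scalar assignments for
#' Euler / modified Euler / RK4.
#'
#' @param name Scheme name.
#' @return A [tec_scheme()].
#' @examples
#' builtin_scheme("modified_euler")
#' @export
builtin_scheme <- function(name) {
  name <- match.arg(name, c("euler", "modified_euler", "rk2", "rk4"))
  v <- function(x) mx_var(x)
  num <- function(x) mx_num(x)
  add <- function(a, b) mx_op("add", a, b)
  mul <- function(a, b) mx_op("mul", a, b)
  xi <- function(k) v(paste0("xi_", k))
  kap <- function(k) v(paste0("kappa_", k))
  tau <- function(k) v(paste0("tau_", k))
  delta <- v("delta")
  half <- num("0.5")
  st <- tec_statement

  statements <- switch(name,
    euler = list(
      st("input", 0L), st("time_input", 0L),
      st("arith", 0L), st("deriv", 0L),
      st("stage_update", 1L, add(xi(0), mul(kap(1), delta))),
      st("time_update", 1L, add(tau(0), delta)),
      st("output")
    ),
    modified_euler = list(
      st("input", 0L), st("time_input", 0L),
      st("arith", 0L), st("deriv", 0L),
      st("stage_update", 1L, add(xi(0), mul(kap(1), delta))),
      st("time_update", 1L, add(tau(0), delta)),
      st("arith", 1L), st("deriv", 1L),
      st("stage_update", 2L,
         add(xi(0), mul(mul(half, add(kap(1), kap(2))), delta))),
      st("output")
    ),
    rk2 = list(
      st("input", 0L), st("time_input", 0L),
      st("arith", 0L), st("deriv", 0L),
      st("stage_update", 1L, add(xi(0), mul(kap(1), mul(half, delta)))),
      st("time_update", 1L, add(tau(0), mul(half, delta))),
      st("arith", 1L), st("deriv", 1L),
      st("stage_update", 2L, add(xi(0), mul(kap(2), delta))),
      st("output")
    ),
    rk4 = list(
      st("input", 0L), st("time_input", 0L),
      st("arith", 0L), st("deriv", 0L),
      st("stage_update", 1L, add(xi(0), mul(mul(half, kap(1)), delta))),
      st("time_update", 1L, add(tau(0), mul(half, delta))),
      st("arith", 1L), st("deriv", 1L),
      st("stage_update", 2L, add(xi(0), mul(mul(half, kap(2)), delta))),
      st("time_update", 2L, add(tau(0), mul(half, delta))),
      st("arith", 2L), st("deriv", 2L),
      st("stage_update", 3L, add(xi(0), mul(kap(3), delta))),
      st("time_update", 3L, add(tau(0), delta)),
      st("arith", 3L), st("deriv", 3L),
      st("output", expr = add(xi(0), mul(mul(
        mx_op("div", num("1"), num("6")),
        add(add(add(kap(1), mul(num("2"), kap(2))), mul(num("2"), kap(3))),
            kap(4))), delta)))
    )
  )
  n_stages <- switch(name, euler = 1L, modified_euler = 2L, rk2 = 2L, rk4 = 4L)
  s <- tec_scheme(name, n_stages, statements)
  stopifnot(nrow(diag_errors(validate_scheme(s))) == 0)
  s
}
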
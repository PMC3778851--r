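# Stage 2: source-code emission ----------------------------------------------

#' Code generation options
#'
#' Driver settings for [emit_source()]: the target language, arithmetic
#' precision, the time window and step, output stride, and the numeric
#' bindings baked into the generated program.
#'
#' @param target `"r"` (standalone R script) or `"c"` (C99, standard library
#'   only).
#' @param precision `"double"`; decimal contexts are executed by
#'   [interpret()], not by emitted standalone sources.
#' @param t_start,t_end Simulation window; `t_end > t_start`.
#' @param delta Time step (> 0).
#' @param stride Output every `stride` steps (>= 1).
#' @param init Named values for the state variables.
#' @param consts Named values for the model constants.
#' @param columns Output column order; default all state variables in
#'   declaration order (time is always first).
#' @return A `codegen_options` object.
#' @export
codegen_options <- function(target = c("r", "c"), precision = "double",
                            t_start = 0, t_end = 20, delta = 0.01, stride = 1L,
                            init = c(), consts = c(), columns = NULL) {
  target <- match.arg(target)
  stopifnot(delta > 0, t_end > t_start, stride >= 1)
  structure(list(target = target, precision = precision, t_start = t_start,
                 t_end = t_end, delta = delta, stride = as.integer(stride),
                 init = init, consts = consts, columns = columns),
            class = "codegen_options")
}

#' Emit runnable simulation source code for a flat program
#'
#' Generates a self-contained single-cell simulation: constants and initial
#' values are baked in as literals, the flat program's assignments run in
#' order inside a fixed-step time loop, output bindings feed back into the
#' next step's inputs, and time plus the state variables are written as CSV
#' to standard output every `stride` steps (full double precision, `%.17g`).
#' Emission is deterministic: identical program and options give identical
#' bytes.
#'
#' @param p A `flat_program` (see [expand()]).
#' @param opts A [codegen_options()].
#' @return Source text (single string).  The equations appear between the
#'   `equations` and `advance` marker comments, one statement per line.
#' @export
emit_source <- function(p, opts) {
  stopifnot(inherits(p, "flat_program"), inherits(opts, "codegen_options"))
  stop_on_diag(check_well_formed(p), "tecgen_expand_error")
  if (length(p$diffvars) == 0)
    tecgen_stop("program has no state variables: not simulable",
                "tecgen_emit_error")
  if (!identical(opts$precision, "double"))
    tecgen_stop(paste0("emitted standalone sources are double precision; ",
                       "use interpret() for decimal contexts"),
                "tecgen_emit_error")
  missing_init <- setdiff(p$diffvars, names(opts$init))
  missing_const <- setdiff(p$consts, names(opts$consts))
  if (length(missing_init) + length(missing_const) > 0)
    tecgen_stop(paste0("unbound values: ",
                       paste(c(missing_init, missing_const), collapse = ", ")),
                "tecgen_emit_error")
  columns <- opts$columns %||% p$diffvars
  stopifnot(all(columns %in% p$diffvars))
  n_steps <- steps_in_window(opts$t_start, opts$t_end, opts$delta)
  lit <- function(x) num_to_decimal_string(as.numeric(x))
  if (opts$target == "r") emit_r(p, opts, columns, n_steps, lit)
  else emit_c(p, opts, columns, n_steps, lit)
}

steps_in_window <- function(t_start, t_end, delta) {
  n <- round((t_end - t_start) / delta)
  if (n < 1 || abs(n * delta - (t_end - t_start)) > 1e-9 * max(1, abs(t_end)))
    tecgen_stop("the window t_start..t_end must be a whole number of steps",
                "tecgen_emit_error")
  n
}

emit_r <- function(p, opts, columns, n_steps, lit) {
  tv_in <- if (!is.na(p$time_variable)) paste0(p$time_variable, "_in") else NULL
  row_vars <- c(tv_in %||% "0", paste0(columns, "_in"))
  row_expr <- paste0("cat(paste(sprintf(\"%.17g\", c(",
                     paste(row_vars, collapse = ", "),
                     ")), collapse = \",\"), \"\\n\", sep = \"\")")
  src <- c(
    "#!/usr/bin/env Rscript",
    paste0("# single-cell simulation: model '", p$model_name,
           "' with scheme '", p$scheme_name, "'"),
    "# generated code: do not edit",
    "",
    vapply(p$consts, function(v)
      paste0(v, " <- ", lit(opts$consts[[v]])), ""),
    vapply(p$diffvars, function(v)
      paste0(v, "_in <- ", lit(opts$init[[v]])), ""),
    if (!is.null(tv_in)) paste0(tv_in, " <- ", lit(opts$t_start)),
    paste0("delta <- ", lit(opts$delta)),
    paste0("n_steps <- ", n_steps),
    paste0("stride <- ", opts$stride),
    "",
    paste0("cat(\"t,", paste(columns, collapse = ","), "\\n\")"),
    row_expr,
    "for (step in seq_len(n_steps)) {",
    "  # equations",
    vapply(p$assignments, function(a)
      paste0("  ", a$lhs, " <- ", render_expr(a$rhs, "r")), ""),
    "  # advance",
    vapply(p$diffvars, function(v)
      paste0("  ", v, "_in <- ", p$outputs[[v]]), ""),
    if (!is.null(tv_in)) paste0("  ", tv_in, " <- ", tv_in, " + delta"),
    paste0("  if (step %% stride == 0) ", row_expr),
    "}",
    ""
  )
  paste(src, collapse = "\n")
}

emit_c <- function(p, opts, columns, n_steps, lit) {
  tv_in <- if (!is.na(p$time_variable)) paste0(p$time_variable, "_in") else NULL
  scalars <- vapply(p$assignments, `[[`, "", "lhs")
  fmt <- paste(rep("%.17g", length(columns) + 1), collapse = ",")
  row_vars <- paste(c(tv_in %||% "0.0", paste0(columns, "_in")), collapse = ", ")
  row_stmt <- paste0("printf(\"", fmt, "\\n\", ", row_vars, ");")
  clit <- function(x) {
    s <- lit(x)
    if (!grepl("[.eE]", s)) paste0(s, ".0") else s
  }
  src <- c(
    paste0("/* single-cell simulation: model '", p$model_name,
           "' with scheme '", p$scheme_name, "'"),
    "   generated code: do not edit */",
    "#include <stdio.h>",
    "#include <math.h>",
    "",
    "int main(void) {",
    vapply(p$consts, function(v)
      paste0("  const double ", v, " = ", clit(opts$consts[[v]]), ";"), ""),
    vapply(p$diffvars, function(v)
      paste0("  double ", v, "_in = ", clit(opts$init[[v]]), ";"), ""),
    if (!is.null(tv_in)) paste0("  double ", tv_in, " = ", clit(opts$t_start), ";"),
    paste0("  const double delta = ", clit(opts$delta), ";"),
    paste0("  const long n_steps = ", n_steps, "L;"),
    paste0("  const long stride = ", opts$stride, "L;"),
    paste0("  double ", paste(scalars, collapse = ", "), ";"),
    "  long step;",
    paste0("  printf(\"t,", paste(columns, collapse = ","), "\\n\");"),
    paste0("  ", row_stmt),
    "  for (step = 1; step <= n_steps; ++step) {",
    "    /* equations */",
    vapply(p$assignments, function(a)
      paste0("    ", a$lhs, " = ", render_expr(a$rhs, "c"), ";"), ""),
    "    /* advance */",
    vapply(p$diffvars, function(v)
      paste0("    ", v, "_in = ", p$outputs[[v]], ";"), ""),
    if (!is.null(tv_in)) paste0("    ", tv_in, " = ", tv_in, " + delta;"),
    paste0("    if (step % stride == 0) ", row_stmt),
    "  }",
    "  return 0;",
    "}",
    ""
  )
  paste(src, collapse = "\n")
}

#' Equation listing of a flat program
#'
#' One numbered line per scalar assignment, in execution order, using the
#' program's stage-suffixed scalar names; a human-auditable view of the
#' stage-1 output.
#'
#' @param p A `flat_program`.
#' @return Character vector, one element per assignment.
#' @examples
#' m <- parse_cellml(fhn_cellml())
#' emit_equation_listing(expand(m, builtin_scheme("modified_euler")))
#' @export
emit_equation_listing <- function(p) {
  stopifnot(inherits(p, "flat_program"))
  vapply(seq_along(p$assignments), function(i) {
    a <- p$assignments[[i]]
    sprintf("%3d: %s = %s", i, a$lhs, render_expr(a$rhs))
  }, "")
}
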
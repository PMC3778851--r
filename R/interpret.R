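# Reference interpreter -------------------------------------------------------

#' Interpret a flat program over a time window
#'
#' Executes the assignment list repeatedly, feeding each step's output
#' bindings back into the next step's inputs and advancing time by `delta`,
#' either in IEEE double precision or in a decimal floating-point context of
#' `precision` significant digits (the arithmetic the accuracy study uses).
#' Sampled state is recorded every `stride` steps, starting with the initial
#' state.
#'
#' @param p A `flat_program` (see [expand()]).
#' @param init Named values for the state variables (numbers or decimal
#'   strings).
#' @param consts Named values for the constants.
#' @param t_start,t_end Simulation window; must span a whole number of steps.
#' @param delta Time step (> 0).
#' @param precision `"double"` (default) or integer significant digits 1-50.
#' @param stride Record every `stride`-th step.
#' @return A `simulation_result`: time grid `t`, state matrix `values` (one
#'   column per state variable), exact decimal strings `values_chr` in
#'   decimal mode, and `divergent_step` (`NA` unless the run left the finite
#'   range, in which case sampling stops there).
#' @examples
#' m <- parse_cellml(fhn_cellml())
#' p <- expand(m, builtin_scheme("rk4"))
#' b <- model_bindings(m)
#' r <- interpret(p, b$init, b$consts, t_end = 1, delta = 0.01)
#' tail(tidy(r))
#' @export
interpret <- function(p, init, consts = c(), t_start = 0, t_end, delta,
                      precision = "double", stride = 1L) {
  stopifnot(inherits(p, "flat_program"))
  stop_on_diag(check_well_formed(p), "tecgen_expand_error")
  digits <- parse_precision(precision)
  delta_s <- as_dec_string(delta)   # exact spelling for the decimal context
  delta <- as.numeric(delta)
  stopifnot(delta > 0)
  n_steps <- steps_in_window(t_start, t_end, delta)
  stride <- as.integer(stride)
  stopifnot(stride >= 1)

  missing_init <- setdiff(p$diffvars, names(init))
  if (length(missing_init) > 0)
    tecgen_stop(paste0("unbound initial value(s): ",
                       paste(missing_init, collapse = ", ")), "tecgen_run_error")
  missing_const <- setdiff(p$consts, names(consts))
  if (length(missing_const) > 0)
    tecgen_stop(paste0("unbound constant(s): ",
                       paste(missing_const, collapse = ", ")), "tecgen_run_error")

  init_s <- bindings_to_strings(init)
  const_s <- bindings_to_strings(consts)

  scalars <- vapply(p$assignments, `[[`, "", "lhs")
  slot_names <- c(p$inputs, p$delta, p$consts, scalars)
  slot_map <- stats::setNames(seq_along(slot_names) - 1L, slot_names)

  pool <- new_lit_pool()
  code_list <- lapply(p$assignments, function(a) compile_expr(a$rhs, slot_map, pool))
  lens <- vapply(code_list, nrow, 0L)
  starts <- cumsum(c(0L, utils::head(lens, -1)))
  bounds <- cbind(start = starts, end = starts + lens,
                  target = slot_map[scalars])
  code <- do.call(rbind, code_list)

  values <- stats::setNames(rep("0", length(slot_names)), slot_names)
  for (v in p$diffvars) values[[paste0(v, "_in")]] <- init_s[[v]]
  for (v in p$consts) values[[v]] <- const_s[[v]]
  values[[p$delta]] <- delta_s
  tv_in <- if (!is.na(p$time_variable)) paste0(p$time_variable, "_in") else NULL
  if (!is.null(tv_in)) values[[tv_in]] <- as_dec_string(t_start)

  feedback <- cbind(from = unname(slot_map[unname(p$outputs)]),
                    to = unname(slot_map[paste0(p$diffvars, "_in")]))
  res <- cpp_run_program(
    code, bounds, pool$values, unname(values), length(slot_names), feedback,
    if (!is.null(tv_in)) slot_map[[tv_in]] else -1L, slot_map[[p$delta]],
    as.double(n_steps), stride, unname(slot_map[paste0(p$diffvars, "_in")]),
    digits
  )
  divergent <- if (res$divergent_step >= 0) res$divergent_step else NA_real_
  rows <- res$rows
  vals <- res$values[seq_len(rows), , drop = FALSE]
  colnames(vals) <- p$diffvars
  chr <- NULL
  if (!is.null(res$values_chr)) {
    chr <- res$values_chr[seq_len(rows), , drop = FALSE]
    colnames(chr) <- p$diffvars
  }
  structure(list(
    t = res$t[seq_len(rows)], values = vals, values_chr = chr,
    t_start = t_start, delta = delta, stride = stride,
    precision = if (digits == 0) "double" else digits,
    divergent_step = divergent,
    model_name = p$model_name, scheme_name = p$scheme_name
  ), class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat("<simulation_result> ", x$model_name, " + ", x$scheme_name,
      " | delta = ", format(x$delta), ", precision = ",
      if (identical(x$precision, "double")) "double"
      else paste0(x$precision, " decimal digits"),
      "\n  samples: ", length(x$t), " x ", ncol(x$values), " variable(s)",
      if (!is.na(x$divergent_step))
        paste0("\n  DIVERGED at step ", format(x$divergent_step)),
      "\n", sep = "")
  invisible(x)
}

#' @rdname interpret
#' @param x A `simulation_result`.
#' @param ... Unused.
#' @export
tidy.simulation_result <- function(x, ...) {
  tibble::tibble(
    t = rep(x$t, times = ncol(x$values)),
    variable = rep(colnames(x$values), each = length(x$t)),
    value = as.vector(x$values)
  )
}

#' @rdname interpret
#' @param object A `simulation_result`.
#' @export
autoplot.simulation_result <- function(object, ...) {
  df <- tidy.simulation_result(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$value,
                                   colour = .data$variable)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time", y = "state",
                  title = paste(object$model_name, "+", object$scheme_name)) +
    ggplot2::theme_minimal()
}

#' Default bindings of a cell model
#'
#' Collects the declared initial values into the `init` / `consts` bindings
#' that [interpret()], [emit_source()] and [convergence_study()] take.
#'
#' @param m A [cell_model()].
#' @param map Optional [rel_map()]; defaults to [infer_roles()].
#' @return `list(init = , consts = )` of named character vectors (exact
#'   decimal strings as declared in the document).
#' @export
model_bindings <- function(m, map = infer_roles(m)) {
  val <- stats::setNames(m$variables$initial_value, m$variables$name)
  diffvars <- map_vars_with_role(map, "diffvar")
  consts <- map_vars_with_role(map, "constvar")
  missing_v <- c(diffvars, consts)[is.na(val[c(diffvars, consts)])]
  if (length(missing_v) > 0)
    tecgen_stop(paste0("no initial value declared for: ",
                       paste(missing_v, collapse = ", ")), "tecgen_run_error")
  list(init = val[diffvars], consts = val[consts])
}

#' Root-mean-square deviation between two simulation results
#'
#' Compares a candidate run against a reference run over their shared sample
#' times (the candidate grid must be a subset of the reference grid) and the
#' selected state variables:
#' \deqn{\mathrm{RMSE} = \sqrt{\mathrm{mean}\,(x_\mathrm{cand} - x_\mathrm{ref})^2}.}
#' When both runs carry decimal samples the deviations are formed in exact
#' decimal arithmetic before squaring, so error levels far below double
#' round-off remain measurable.
#'
#' @param candidate,reference `simulation_result` objects on nested grids.
#' @param vars State variables to include (default: all shared).
#' @return The root-mean-square deviation (double).
#' @export
rmse <- function(candidate, reference, vars = NULL) {
  stopifnot(inherits(candidate, "simulation_result"),
            inherits(reference, "simulation_result"))
  vars <- vars %||% intersect(colnames(candidate$values), colnames(reference$values))
  stopifnot(length(vars) > 0)
  al <- align_grids(candidate, reference)
  if (length(al$ci) == 0)
    tecgen_stop("no shared sample times", "tecgen_run_error")
  dec <- !is.null(candidate$values_chr) && !is.null(reference$values_chr)
  total <- 0
  n <- 0
  for (v in vars) {
    if (dec) {
      cv <- candidate$values_chr[al$ci, v]
      rv <- reference$values_chr[al$ri, v]
      dvals <- vapply(seq_along(cv), function(i)
        as.numeric(dec_op("sub", cv[[i]], rv[[i]], 50L)), 0)
    } else {
      dvals <- candidate$values[al$ci, v] - reference$values[al$ri, v]
    }
    total <- total + sum(dvals^2)
    n <- n + length(dvals)
  }
  sqrt(total / n)
}

# indices of shared sample times: candidate spacing must be an integer
# multiple of the reference spacing and both grids share t_start
align_grids <- function(candidate, reference) {
  dc <- candidate$delta * candidate$stride
  dr <- reference$delta * reference$stride
  ratio <- dc / dr
  if (abs(ratio - round(ratio)) > 1e-8 * max(1, ratio) ||
      abs(candidate$t_start - reference$t_start) > 1e-12)
    tecgen_stop("candidate sample grid is not nested in the reference grid",
                "tecgen_run_error")
  ratio <- round(ratio)
  nshared <- min(length(candidate$t),
                 floor((length(reference$t) - 1) / ratio) + 1)
  list(ci = seq_len(nshared), ri = 1 + (seq_len(nshared) - 1) * ratio)
}
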
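# Stage 1: symbolic expansion of a scheme over a model -----------------------
#
# The expansion replaces scheme symbols by model variable names (xi -> state
# variable, kappa -> derivative, iota -> temporal variable, tau -> time,
# constants by themselves), appends stage indices, and unfolds the model's f
# and g bodies into the deriv-eval and arith-eval statements.  The result is
# a flat, ordered, single-assignment scalar program advancing the state from
# t to t + delta; its length is the scheme/model "execution step" count.
#
# Scalar naming is deterministic and pinned so emitted code is byte-stable:
#   <v>_in / <v>_out   input and output bindings of diffvar v (and time in)
#   <v>_<j>            stage-j copy of diffvar/arithvar/time v
#   kappa<i>_<v>       i-th derivative evaluation for diffvar v
#   delta              the time step

#' Split model equations into rate and temporal classes
#'
#' Returns the differential equations `f` ordered by diffvar declaration
#' order (so derivative components stay aligned with the state vector) and
#' the algebraic equations `g` in document order.
#'
#' @param m A [cell_model()].
#' @param map A [rel_map()].
#' @return `list(f = , g = )` of equation lists.
#' @export
classify_equations <- function(m, map) {
  stopifnot(inherits(m, "cell_model"), inherits(map, "rel_map"))
  diffvars <- intersect(m$variables$name, map_vars_with_role(map, "diffvar"))
  diff_eqs <- model_diff_eqs(m)
  diff_lhs <- vapply(diff_eqs, function(e) e$lhs$var, "")
  f <- lapply(diffvars, function(v) diff_eqs[[match(v, diff_lhs)]])
  list(f = f, g = model_arith_eqs(m))
}

#' Order temporal equations by dependency
#'
#' Topologically sorts algebraic equations so every temporal variable is
#' computed before any temporal equation that reads it; ties keep document
#' order.  A dependency cycle means the model needs a simultaneous
#' (differential-algebraic) solve, which this system does not support.
#'
#' @param g List of algebraic equations (`lhs` a variable reference).
#' @return The reordered list.
#' @export
order_arith <- function(g) {
  if (length(g) <= 1) return(g)
  lhs <- vapply(g, function(e) e$lhs$name, "")
  deps <- lapply(g, function(e) intersect(free_variables(e$rhs), lhs))
  done <- character(0)
  remaining <- seq_along(g)
  out <- list()
  while (length(remaining) > 0) {
    ready <- remaining[vapply(remaining, function(i)
      all(deps[[i]] %in% done), TRUE)]
    if (length(ready) == 0)
      tecgen_stop(paste0(
        "temporal equations form a dependency cycle (",
        paste(lhs[remaining], collapse = ", "),
        "): simultaneous differential-algebraic systems are not supported"),
        "tecgen_dae_error")
    i <- ready[[1]]
    out[[length(out) + 1L]] <- g[[i]]
    done <- c(done, lhs[[i]])
    remaining <- setdiff(remaining, i)
  }
  out
}

new_flat_program <- function(x) structure(x, class = "flat_program")

#' Expand a model with a scheme into a flat program
#'
#' The stage-1 transformation: weaves the model equations into the scheme's
#' statement list, producing an ordered single-assignment scalar program.
#' Input, time and output bindings and the stage/time updates are scalarized
#' per state variable; `arith-eval` statements emit one assignment per
#' temporal equation (dependency-ordered, see [order_arith()]) with the
#' model right-hand side unfolded at the statement's stage; `deriv-eval`
#' statements likewise unfold the rate equations.  No simplification is
#' applied: the unfolded bodies appear verbatim, so assignment counts are a
#' faithful size measure of the generated simulation code.
#'
#' @param m A [cell_model()].
#' @param s A [tec_scheme()].
#' @param map A [rel_map()]; defaults to [infer_roles()] of the model.
#' @return A `flat_program` with fields `inputs`, `consts`, `delta`,
#'   `assignments` (each `list(lhs, rhs, prov)`), `outputs` (named map from
#'   diffvar to its output scalar), `diffvars`, `time_variable`.
#' @examples
#' m <- parse_cellml(fhn_cellml())
#' p <- expand(m, builtin_scheme("euler"))
#' count_steps(p)
#' @export
expand <- function(m, s, map = infer_roles(m)) {
  stopifnot(inherits(m, "cell_model"), inherits(s, "tec_scheme"),
            inherits(map, "rel_map"))
  stop_on_diag(validate_model(m), "tecgen_model_error")
  stop_on_diag(validate_scheme(s), "tecgen_scheme_error")
  stop_on_diag(validate_mapping(map, m, s), "tecgen_map_error")

  cls <- classify_equations(m, map)
  g_ordered <- order_arith(cls$g)
  diffvars <- vapply(cls$f, function(e) e$lhs$var, "")
  arithvars <- vapply(g_ordered, function(e) e$lhs$name, FUN.VALUE = "")
  consts <- map_vars_with_role(map, "constvar")
  tv <- map_vars_with_role(map, "timevar")
  tv <- if (length(tv) == 1) tv else NA_character_

  stage_name <- function(v, j) paste0(v, "_", j)
  kappa_name <- function(i, v) paste0("kappa", i, "_", v)
  in_name <- function(v) paste0(v, "_in")
  out_name <- function(v) paste0(v, "_out")

  # rename model-equation variables to their stage-j scalar names
  stage_map <- function(j) {
    nm <- c(diffvars, arithvars, if (!is.na(tv)) tv)
    stats::setNames(stage_name(nm, j), nm)
  }
  # rename scheme symbols to per-diffvar scalar names
  symbol_map <- function(v) {
    N <- s$n_stages
    map_v <- character(0)
    for (k in 0:N) map_v[paste0("xi_", k)] <- stage_name(v, k)
    for (k in seq_len(N)) map_v[paste0("kappa_", k)] <- kappa_name(k, v)
    for (k in 0:N) map_v[paste0("tau_", k)] <- stage_name(tv, k)
    map_v["delta"] <- "delta"
    map_v["t"] <- in_name(tv)
    map_v
  }
  time_map <- function() {
    N <- s$n_stages
    map_t <- character(0)
    for (k in 0:N) map_t[paste0("tau_", k)] <- stage_name(tv, k)
    map_t["delta"] <- "delta"
    map_t["t"] <- in_name(tv)
    map_t
  }

  assignments <- list()
  push <- function(lhs, rhs, prov) {
    assignments[[length(assignments) + 1L]] <<- list(lhs = lhs, rhs = rhs,
                                                     prov = prov)
  }

  for (si in seq_along(s$statements)) {
    st <- s$statements[[si]]
    prov <- function(detail) list(statement = si, kind = st$kind,
                                  stage = st$stage, detail = detail)
    switch(st$kind,
      input = for (v in diffvars)
        push(stage_name(v, 0), mx_var(in_name(v)), prov(v)),
      time_input = if (!is.na(tv))
        push(stage_name(tv, 0), mx_var(in_name(tv)), prov(tv)),
      arith = for (eq in g_ordered)
        push(stage_name(eq$lhs$name, st$stage),
             rename_vars(eq$rhs, stage_map(st$stage)),
             prov(eq$lhs$name)),
      deriv = for (v in diffvars) {
        eq <- cls$f[[match(v, diffvars)]]
        push(kappa_name(st$stage + 1L, v),
             rename_vars(eq$rhs, stage_map(st$stage)),
             prov(eq_lhs_key(eq$lhs)))
      },
      stage_update = for (v in diffvars)
        push(stage_name(v, st$stage), rename_vars(st$expr, symbol_map(v)),
             prov(v)),
      time_update = if (!is.na(tv))
        push(stage_name(tv, st$stage), rename_vars(st$expr, time_map()),
             prov(tv)),
      output = for (v in diffvars) {
        rhs <- if (is.null(st$expr)) mx_var(stage_name(v, s$n_stages))
               else rename_vars(st$expr, symbol_map(v))
        push(out_name(v), rhs, prov(v))
      }
    )
  }

  inputs <- c(in_name(diffvars), if (!is.na(tv)) in_name(tv))
  p <- new_flat_program(list(
    model_name = m$name, scheme_name = s$name,
    inputs = inputs, delta = "delta", consts = consts,
    diffvars = diffvars, arithvars = arithvars, time_variable = tv,
    assignments = assignments,
    outputs = stats::setNames(out_name(diffvars), diffvars)
  ))

  # name-collision guard: generated scalars must not collide with constants
  gen <- vapply(p$assignments, `[[`, "", "lhs")
  clash <- intersect(c(gen, inputs, "delta"), consts)
  if (length(clash) > 0)
    tecgen_stop(paste0("generated scalar name collides with constant '",
                       clash[[1]], "'; rename the model variable"),
                "tecgen_expand_error")
  stop_on_diag(check_well_formed(p), "tecgen_expand_error")
  p
}

#' Number of execution steps of a flat program
#'
#' One execution step is one scalar assignment, bindings and time updates
#' included; this is the size measure reported for generated simulation
#' codes.
#'
#' @param p A `flat_program`.
#' @return Integer assignment count.
#' @export
count_steps <- function(p) {
  stopifnot(inherits(p, "flat_program"))
  length(p$assignments)
}

#' Check flat-program well-formedness
#'
#' Empty diagnostics iff the program is single-assignment (no scalar defined
#' twice), every right-hand side only references scalars already defined
#' (inputs, constants, the time step, or earlier assignments), and every
#' state variable has an output binding.
#'
#' @param p A `flat_program`.
#' @return Diagnostics tibble (see [validate_model()]).
#' @export
check_well_formed <- function(p) {
  stopifnot(inherits(p, "flat_program"))
  d <- diag_rows()
  defined <- c(p$inputs, p$consts, p$delta)
  for (i in seq_along(p$assignments)) {
    a <- p$assignments[[i]]
    if (a$lhs %in% defined)
      diag_add(d, "error", "check_well_formed",
               paste0("assignment ", i, ": '", a$lhs, "' is defined more than once"))
    undefined <- setdiff(free_variables(a$rhs), defined)
    if (length(undefined) > 0)
      diag_add(d, "error", "check_well_formed",
               paste0("assignment ", i, ": '", undefined[[1]],
                      "' is used before it is defined"))
    defined <- c(defined, a$lhs)
  }
  for (v in names(p$outputs)) {
    if (!(p$outputs[[v]] %in% defined))
      diag_add(d, "error", "check_well_formed",
               paste0("output scalar '", p$outputs[[v]], "' is never assigned"))
  }
  diag_result(d)
}

#' Alpha-equivalence of two flat programs
#'
#' Two programs are alpha-equivalent when a single bijective renaming of
#' scalar names maps one onto the other, assignment by assignment and in
#' order (numeric literals compare by value).  Used to compare a generated
#' expansion against a hand-written reference equation set.
#'
#' @param p,q `flat_program` objects (or bare lists of
#'   `list(lhs = , rhs = )` assignments).
#' @return `TRUE` or `FALSE`, with attribute `"why"` describing the first
#'   mismatch on failure.
#' @export
alpha_equivalent <- function(p, q) {
  pa <- if (inherits(p, "flat_program")) p$assignments else p
  qa <- if (inherits(q, "flat_program")) q$assignments else q
  fail <- function(why) structure(FALSE, why = why)
  if (length(pa) != length(qa))
    return(fail(paste0("lengths differ: ", length(pa), " vs ", length(qa))))
  env <- new.env(parent = emptyenv())
  env$fwd <- character(0)
  env$bwd <- character(0)
  bind <- function(a, b) {
    if (!is.na(env$fwd[a])) return(env$fwd[[a]] == b)
    if (!is.na(env$bwd[b])) return(FALSE)
    env$fwd[a] <- b
    env$bwd[b] <- a
    TRUE
  }
  unify <- function(x, y) {
    if (x$k != y$k) return(FALSE)
    switch(x$k,
      num = dec_cmp(x$value, y$value) == 0L,
      var = bind(x$name, y$name),
      deriv = bind(x$var, y$var) && bind(x$bvar, y$bvar),
      neg = unify(x$a, y$a),
      op = , rel = x$op == y$op && unify(x$a, y$a) && unify(x$b, y$b),
      call = x$fn == y$fn && length(x$args) == length(y$args) &&
        all(mapply(unify, x$args, y$args)),
      piecewise = {
        if (length(x$pieces) != length(y$pieces)) return(FALSE)
        ok <- all(mapply(function(a, b) unify(a$cond, b$cond) && unify(a$value, b$value),
                         x$pieces, y$pieces))
        ok && (is.null(x$otherwise) == is.null(y$otherwise)) &&
          (is.null(x$otherwise) || unify(x$otherwise, y$otherwise))
      }
    )
  }
  for (i in seq_along(pa)) {
    if (!bind(pa[[i]]$lhs, qa[[i]]$lhs))
      return(fail(paste0("assignment ", i, ": left-hand sides '", pa[[i]]$lhs,
                         "' and '", qa[[i]]$lhs, "' cannot be identified")))
    if (!unify(pa[[i]]$rhs, qa[[i]]$rhs))
      return(fail(paste0("assignment ", i, ": right-hand sides differ (",
                         render_expr(pa[[i]]$rhs), " vs ",
                         render_expr(qa[[i]]$rhs), ")")))
  }
  TRUE
}

#' @export
print.flat_program <- function(x, ...) {
  cat("<flat_program> ", x$model_name, " + ", x$scheme_name, ": ",
      count_steps(x), " execution steps\n", sep = "")
  cat(emit_equation_listing(x), sep = "\n")
  invisible(x)
}
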
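# Seeded random model generator for property testing -------------------------
#
# Generates synthetic cell models drawn from the supported expression subset
# together with ground truth (roles, and the f/g bodies as independent R
# expressions built in parallel with the trees, for use as evaluation
# oracles).  Denominators of generated divisions are 1 + (subexpression)^2 so
# oracle evaluations never hit a singularity.

#' Specification for a random synthetic model
#'
#' @param seed Integer seed; equal specs generate byte-identical documents.
#' @param nx Number of state variables (>= 1).
#' @param ny Number of temporal (removable algebraic) variables.
#' @param nz Number of constants.
#' @param depth Expression depth bound (>= 1).
#' @param p_time Probability that a rate expression references time.
#' @return A `model_spec` object.
#' @export
model_spec <- function(seed, nx = 2, ny = 1, nz = 2, depth = 3, p_time = 0.2) {
  stopifnot(nx >= 1, ny >= 0, nz >= 0, depth >= 1)
  if (ny > 0 && depth < 1)
    tecgen_stop("infeasible spec: temporal equations need depth >= 1",
                "tecgen_spec_error")
  structure(list(seed = as.integer(seed), nx = nx, ny = ny, nz = nz,
                 depth = depth, p_time = p_time),
            class = "model_spec")
}

with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a random synthetic model with ground truth
#'
#' Draws a model from the supported expression subset: every state variable
#' gets a rate equation whose right-hand side references at least one state
#' variable; temporal variables form a dependency DAG (their defining
#' equations are emitted in shuffled document order, so consumers must
#' dependency-sort them); remaining variables are constants plus a time
#' variable.  The ground truth carries the generating roles and the f/g
#' bodies as plain R expression strings, built independently of the
#' expression trees' own evaluator.
#'
#' @param spec A [model_spec()].
#' @return `list(cellml = , relml = , truth = )` where `truth` has `roles`
#'   (tibble), `f` / `g` (named R expression strings), `g_topo` (temporal
#'   variable names in dependency order), `init`, `consts` (named numeric).
#' @export
random_model <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  with_local_seed(spec$seed, generate_model(spec))
}

generate_model <- function(spec) {
  xs <- paste0("x", seq_len(spec$nx))
  ws <- if (spec$ny > 0) paste0("w", seq_len(spec$ny)) else character(0)
  zs <- if (spec$nz > 0) paste0("z", seq_len(spec$nz)) else character(0)
  tv <- "time"

  rnum <- function() {
    v <- round(stats::runif(1, 0.1, 2), 2)
    format(v, nsmall = 1, trim = TRUE, scientific = FALSE)
  }
  leaf_pool <- function(avail) c(avail, zs, "LIT", "LIT")

  # returns list(mx = mathexpr, rs = independent R source string)
  gen_expr <- function(depth, avail, must = NULL) {
    if (depth <= 0 || (is.null(must) && stats::runif(1) < 0.3)) {
      pick <- sample(leaf_pool(avail), 1)
      if (!is.null(must)) pick <- must
      if (pick == "LIT") {
        s <- rnum()
        return(list(mx = mx_num(s), rs = s))
      }
      return(list(mx = mx_var(pick), rs = pick))
    }
    op <- sample(c("add", "sub", "mul", "div", "neg", "pow"), 1,
                 prob = c(0.25, 0.2, 0.25, 0.1, 0.1, 0.1))
    if (op == "neg") {
      a <- gen_expr(depth - 1, avail, must)
      return(list(mx = mx_neg(a$mx), rs = paste0("(-(", a$rs, "))")))
    }
    if (op == "pow") {
      a <- gen_expr(depth - 1, avail, must)
      k <- sample(2:3, 1)
      return(list(mx = mx_op("pow", a$mx, mx_num(as.character(k))),
                  rs = paste0("((", a$rs, ")^", k, ")")))
    }
    if (op == "div") {
      # guarded: denominator 1 + (sub)^2 never vanishes
      a <- gen_expr(depth - 1, avail, must)
      b <- gen_expr(depth - 1, avail)
      den_mx <- mx_op("add", mx_num("1"), mx_op("pow", b$mx, mx_num("2")))
      return(list(mx = mx_op("div", a$mx, den_mx),
                  rs = paste0("((", a$rs, ")/(1 + (", b$rs, ")^2))")))
    }
    side <- sample(c(1, 2), 1)
    a <- gen_expr(depth - 1, avail, if (side == 1) must)
    b <- gen_expr(depth - 1, avail, if (side == 2) must)
    sym <- c(add = "+", sub = "-", mul = "*")[[op]]
    list(mx = mx_op(op, a$mx, b$mx),
         rs = paste0("((", a$rs, ")", sym, "(", b$rs, "))"))
  }

  # temporal equations: wi may read w1..w(i-1); document order shuffled
  g_exprs <- list()
  for (i in seq_len(spec$ny)) {
    avail <- c(xs, utils::head(ws, i - 1))
    g_exprs[[ws[[i]]]] <- gen_expr(spec$depth, avail, must = sample(xs, 1))
  }
  # rate equations: must reference >= 1 state variable; may read any temporal
  f_exprs <- list()
  for (v in xs) {
    avail <- c(xs, ws, if (stats::runif(1) < spec$p_time) tv)
    f_exprs[[v]] <- gen_expr(spec$depth, avail, must = sample(xs, 1))
  }

  init <- stats::setNames(round(stats::runif(spec$nx, -0.5, 0.5), 3), xs)
  consts <- stats::setNames(round(stats::runif(max(spec$nz, 1), 0.5, 1.5), 3),
                            if (spec$nz > 0) zs else "unused")[seq_len(spec$nz)]

  variables <- tibble::tibble(
    name = c(xs, ws, zs, tv),
    initial_value = c(num_to_decimal_string_v(init),
                      rep(NA_character_, length(ws)),
                      if (spec$nz > 0) num_to_decimal_string_v(consts),
                      NA_character_),
    units = NA_character_
  )
  g_order <- sample(seq_len(spec$ny))
  equations <- c(
    lapply(g_order, function(i)
      list(lhs = mx_var(ws[[i]]), rhs = g_exprs[[ws[[i]]]]$mx)),
    lapply(xs, function(v)
      list(lhs = mx_deriv(v, tv), rhs = f_exprs[[v]]$mx))
  )
  m <- cell_model(paste0("synthetic_seed", spec$seed), variables, equations, tv)
  map <- infer_roles(m)

  truth <- list(
    roles = map$roles,
    f = stats::setNames(vapply(f_exprs, `[[`, "", "rs")[xs], xs),
    g = if (spec$ny > 0)
          stats::setNames(vapply(g_exprs, `[[`, "", "rs")[ws], ws)
        else stats::setNames(character(0), character(0)),
    g_topo = ws,       # generation order is a valid dependency order
    g_doc = ws[g_order],
    diffvars = xs, time_variable = tv,
    init = init, consts = consts
  )
  list(cellml = serialize_cellml(m), relml = serialize_relml(map), truth = truth)
}

num_to_decimal_string_v <- function(x)
  vapply(x, num_to_decimal_string, "")
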
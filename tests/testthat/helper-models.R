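# shared builders and independent oracles -------------------------------------

# compact cell-model builder: eqs as list(lhs_name_or_deriv, rhs mathexpr)
make_model <- function(name, vars, eqs, time_variable = "time") {
  cell_model(
    name,
    tibble::tibble(
      name = names(vars),
      initial_value = unname(vars),
      units = NA_character_
    ),
    eqs, time_variable
  )
}

# dx/dt = lambda * x with lambda a constant
linear_model <- function(lambda = "-1", x0 = "1") {
  make_model("linear",
    c(x = x0, lam = lambda, time = NA_character_),
    list(list(lhs = mx_deriv("x", "time"),
              rhs = mx_op("mul", mx_var("lam"), mx_var("x")))))
}

# independent tree-walk evaluator (double precision), used as the second
# route against evaluate_expr and the interpreter
oracle_eval <- function(e, env) {
  ev <- function(n) {
    switch(n$k,
      num = as.numeric(n$value),
      var = {
        if (is.null(env[[n$name]])) stop("unbound ", n$name)
        env[[n$name]]
      },
      neg = -ev(n$a),
      op = switch(n$op,
        add = ev(n$a) + ev(n$b), sub = ev(n$a) - ev(n$b),
        mul = ev(n$a) * ev(n$b), div = ev(n$a) / ev(n$b),
        pow = ev(n$a)^ev(n$b)),
      call = switch(n$fn,
        exp = exp(ev(n$args[[1]])),
        ln = log(ev(n$args[[1]])),
        log = if (length(n$args) == 1) log10(ev(n$args[[1]]))
              else log(ev(n$args[[2]]), base = ev(n$args[[1]])),
        root = if (length(n$args) == 1) sqrt(ev(n$args[[1]]))
               else ev(n$args[[2]])^(1 / ev(n$args[[1]]))),
      rel = as.numeric(switch(n$op,
        lt = ev(n$a) < ev(n$b), leq = ev(n$a) <= ev(n$b),
        gt = ev(n$a) > ev(n$b), geq = ev(n$a) >= ev(n$b),
        eq = ev(n$a) == ev(n$b), neq = ev(n$a) != ev(n$b))),
      piecewise = {
        for (p in n$pieces) if (ev(p$cond) != 0) return(ev(p$value))
        if (!is.null(n$otherwise)) ev(n$otherwise) else stop("no piece matched")
      })
  }
  ev(e)
}

# rate function from random_model ground truth: independent of the package's
# expression trees (built from the R source strings generated alongside them)
truth_rate_fn <- function(truth) {
  g_parsed <- lapply(truth$g, function(s) parse(text = s)[[1]])
  f_parsed <- lapply(truth$f, function(s) parse(text = s)[[1]])
  function(x, t) {
    env <- c(as.list(x), as.list(truth$consts), stats::setNames(list(t), truth$time_variable))
    for (w in truth$g_topo) env[[w]] <- eval(g_parsed[[w]], env)
    vapply(truth$diffvars, function(v) eval(f_parsed[[v]], env), 0)
  }
}

# hand-coded generic one-step integrators (no symbolic expansion): the
# semantic oracle for the expander + interpreter pipeline
direct_step <- function(f, x0, t0, d, scheme) {
  switch(scheme,
    euler = x0 + d * f(x0, t0),
    modified_euler = {
      k1 <- f(x0, t0)
      k2 <- f(x0 + k1 * d, t0 + d)
      x0 + 0.5 * (k1 + k2) * d
    },
    rk2 = {
      k1 <- f(x0, t0)
      k2 <- f(x0 + k1 * (0.5 * d), t0 + 0.5 * d)
      x0 + k2 * d
    },
    rk4 = {
      k1 <- f(x0, t0)
      k2 <- f(x0 + 0.5 * k1 * d, t0 + 0.5 * d)
      k3 <- f(x0 + 0.5 * k2 * d, t0 + 0.5 * d)
      k4 <- f(x0 + k3 * d, t0 + d)
      x0 + (1 / 6) * (k1 + 2 * k2 + 2 * k3 + k4) * d
    },
    stop("unknown scheme ", scheme))
}

ALL_SCHEMES <- c("euler", "modified_euler", "rk2", "rk4")

# structural model equality (round-trip oracle)
models_identical <- function(a, b) {
  if (!identical(as.data.frame(a$variables), as.data.frame(b$variables))) return(FALSE)
  if (!identical(a$time_variable, b$time_variable)) return(FALSE)
  if (length(a$equations) != length(b$equations)) return(FALSE)
  for (i in seq_along(a$equations)) {
    if (!tecgen:::expr_equal(a$equations[[i]]$lhs, b$equations[[i]]$lhs)) return(FALSE)
    if (!tecgen:::expr_equal(a$equations[[i]]$rhs, b$equations[[i]]$rhs)) return(FALSE)
  }
  TRUE
}

max_rel_diff <- function(a, b) {
  max(abs(a - b) / pmax(1e-8, abs(a), abs(b)))
}
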
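# interpreter, RMSE, convergence order ----------------------------------------

test_that("constant-rate integration is exact", {
  m <- make_model("c1", c(x = "0", time = NA),
                  list(list(lhs = mx_deriv("x", "time"), rhs = mx_num("1"))))
  p <- expand(m, builtin_scheme("euler"))
  rd <- interpret(p, c(x = "0"), t_end = 1, delta = "0.1", precision = 32,
                  stride = 10)
  expect_identical(dec_cmp(rd$values_chr[2, "x"], "1"), 0L)
  # double mode accumulates the binary representation error of 0.1 only
  r <- interpret(p, c(x = 0), t_end = 1, delta = 0.1, stride = 10)
  expect_equal(unname(r$values[2, "x"]), 1, tolerance = 1e-15)
  # with a binary-exact step the double path is exact too
  r8 <- interpret(p, c(x = 0), t_end = 1, delta = 0.125, stride = 8)
  expect_identical(unname(r8$values[2, "x"]), 1)
})

test_that("Euler decay matches (1 - delta)^n exactly in the decimal context", {
  m <- make_model("dec", c(x = "1", time = NA),
                  list(list(lhs = mx_deriv("x", "time"), rhs = mx_neg(mx_var("x")))))
  p <- expand(m, builtin_scheme("euler"))
  r <- interpret(p, c(x = "1"), t_end = 2, delta = "0.1", precision = 32)
  closed <- "1"
  for (i in 1:20) closed <- dec_op("mul", closed, "0.9", 32)
  expect_identical(dec_cmp(r$values_chr[21, "x"], closed), 0L)
})

test_that("one RK4 step reproduces the truncated exponential in 7 digits", {
  m <- make_model("dec7", c(x = "1", time = NA),
                  list(list(lhs = mx_deriv("x", "time"), rhs = mx_neg(mx_var("x")))))
  p <- expand(m, builtin_scheme("rk4"))
  r <- interpret(p, c(x = "1"), t_end = 0.1, delta = "0.1", precision = 7)
  expect_identical(unname(r$values_chr[2, "x"]), "0.9048375")
})

test_that("divergent runs are flagged with the first bad step", {
  m <- make_model("blow", c(x = "3", time = NA),
                  list(list(lhs = mx_deriv("x", "time"),
                            rhs = mx_op("pow", mx_var("x"), mx_num("2")))))
  p <- expand(m, builtin_scheme("euler"))
  r <- interpret(p, c(x = 3), t_end = 10, delta = 0.5)
  expect_false(is.na(r$divergent_step))
  rd <- interpret(p, c(x = "3"), t_end = 10, delta = "0.5", precision = 16)
  expect_false(is.na(rd$divergent_step))
})

test_that("unbound names are interpreter errors", {
  m <- parse_cellml(fhn_cellml())
  p <- expand(m, builtin_scheme("euler"))
  b <- model_bindings(m)
  expect_error(interpret(p, b$init["x"], b$consts, t_end = 1, delta = 0.1),
               class = "tecgen_run_error")
  expect_error(interpret(p, b$init, b$consts[-1], t_end = 1, delta = 0.1),
               class = "tecgen_run_error")
})

synthetic_result <- function(t, values, delta, stride = 1) {
  structure(list(t = t, values = values, values_chr = NULL, t_start = t[[1]],
                 delta = delta, stride = stride, precision = "double",
                 divergent_step = NA_real_, model_name = "synthetic",
                 scheme_name = "synthetic"),
            class = "simulation_result")
}

test_that("rmse has its defining properties", {
  v <- cbind(x = sin(0:10), y = cos(0:10))
  a <- synthetic_result(0:10, v, delta = 1)
  expect_identical(rmse(a, a), 0)
  b <- a
  b$values[, "x"] <- b$values[, "x"] + 0.25
  expect_equal(rmse(b, a, vars = "x"), 0.25)
  # mismatched grids are an error
  cc <- synthetic_result(seq(0, 10, by = 0.3), cbind(x = rep(0, 34)), delta = 0.3)
  expect_error(rmse(cc, a), class = "tecgen_run_error")
})

test_that("coarse Euler errs more than Heun which errs more than RK4", {
  m <- parse_cellml(fhn_cellml())
  b <- model_bindings(m)
  ref <- interpret(expand(m, builtin_scheme("rk4")), b$init, b$consts,
                   t_end = 5, delta = 1e-4, stride = 1000)
  errs <- vapply(c("euler", "modified_euler", "rk4"), function(s) {
    cand <- interpret(expand(m, builtin_scheme(s)), b$init, b$consts,
                      t_end = 5, delta = 1e-2, stride = 10)
    rmse(cand, ref)
  }, 0)
  expect_gt(errs[["euler"]], errs[["modified_euler"]])
  expect_gt(errs[["modified_euler"]], errs[["rk4"]])
})

test_that("estimate_order recovers exact slopes and rejects degenerate input", {
  expect_equal(estimate_order(c(0.1, 0.01), c(0.1, 0.01)), 1)
  expect_equal(estimate_order(c(0.1, 0.01), c(1e-2, 1e-4)), 2)
  expect_equal(estimate_order(data.frame(delta = c(0.2, 0.1, 0.05),
                                         rmse = c(4e-2, 1e-2, 2.5e-3))), 2,
               tolerance = 1e-10)
  expect_error(estimate_order(c(0.1), c(0.1)), class = "tecgen_run_error")
  expect_error(estimate_order(c(0.1, 0.01), c(0, 0)), class = "tecgen_run_error")
})

test_that("a linear model recovers Euler's first order to within 0.05", {
  m <- linear_model("-1", "1")
  rep <- convergence_study(
    m, schemes = "euler", deltas = c(1e-1, 1e-2, 1e-3),
    ref = list(scheme = "rk4", delta = 1e-4), horizon = 2, precision = 32)
  expect_equal(rep$orders$order[[1]], 1, tolerance = 0.05)
})

test_that("an empty scheme list yields an empty report", {
  m <- linear_model()
  rep <- convergence_study(m, schemes = character(0), deltas = c(0.1, 0.01),
                           ref = list(scheme = "rk4", delta = 1e-3),
                           horizon = 1, precision = "double")
  expect_identical(nrow(rep$entries), 0L)
  expect_identical(nrow(rep$orders), 0L)
})

test_that("the precision floor flags entries in a double-precision study", {
  # in double arithmetic RK4 reaches round-off by delta = 1e-3 on this model
  m <- linear_model("-1", "1")
  rep <- convergence_study(
    m, schemes = "rk4", deltas = c(1e-2, 1e-4),
    ref = list(scheme = "rk4", delta = 1e-5), horizon = 1,
    precision = "double")
  expect_true(any(rep$entries$flag == "floor"))
})

test_that("report accessors: tidy, glance, autoplot, writers", {
  m <- linear_model()
  rep <- convergence_study(m, schemes = c("euler", "rk2"),
                           deltas = c(0.1, 0.01),
                           ref = list(scheme = "rk4", delta = 1e-3),
                           horizon = 1, precision = 20)
  expect_identical(nrow(tidy(rep)), 4L)
  g <- glance(rep)
  expect_identical(nrow(g), 1L)
  expect_identical(g$n_entries, 4L)
  expect_s3_class(autoplot(rep), "ggplot")
  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  write_accuracy_csv(rep, csv)
  write_accuracy_json(rep, js)
  expect_identical(nrow(utils::read.csv(csv)), 4L)
  parsed <- jsonlite::read_json(js)
  expect_named(parsed$orders, c("euler", "rk2"))
  unlink(c(csv, js))
})
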
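# expression trees, MathML parsing, evaluation --------------------------------

test_that("MathML content markup parses to the expected trees", {
  doc <- xml2::read_xml(paste0(
    "<math xmlns=\"http://www.w3.org/1998/Math/MathML\">",
    "<apply><plus/>",
    "<apply><minus/>",
    "<apply><minus/><ci>x</ci><apply><divide/><ci>r</ci><cn>3.0</cn></apply></apply>",
    "<ci>y</ci></apply>",
    "<ci>a</ci></apply></math>"))
  e <- parse_mathml_expr(doc)
  expect_identical(e$k, "op")
  expect_identical(e$op, "add")
  expect_setequal(free_variables(e), c("x", "r", "y", "a"))
  expect_identical(format(e), "x - r/3.0 - y + a")

  lit <- parse_mathml_expr(xml2::read_xml("<cn>0</cn>"))
  expect_identical(lit$k, "num")
  expect_identical(lit$value, "0")

  en <- parse_mathml_expr(xml2::read_xml("<cn type=\"e-notation\">1<sep/>-5</cn>"))
  expect_identical(en$value, "1e-5")
})

test_that("unsupported MathML elements are hard errors naming the element", {
  bad <- xml2::read_xml("<apply><csymbol/><ci>x</ci></apply>")
  err <- expect_error(parse_mathml_expr(bad), class = "tecgen_unsupported_error")
  expect_match(conditionMessage(err), "csymbol")
  expect_error(parse_mathml_expr(xml2::read_xml("<apply><sin/><ci>x</ci></apply>")),
               class = "tecgen_unsupported_error")
})

test_that("serialize -> parse round-trips expression trees", {
  exprs <- list(
    mx_op("pow", mx_var("x"), mx_num("3")),
    mx_neg(mx_op("div", mx_num("1.5"), mx_op("add", mx_var("u"), mx_num("2")))),
    mx_call("exp", list(mx_var("x"))),
    mx_call("log", list(mx_num("2"), mx_var("x"))),
    mx_call("root", list(mx_num("3"), mx_var("y"))),
    mx_piecewise(
      list(list(cond = mx_rel("lt", mx_var("u"), mx_num("0")), value = mx_neg(mx_var("u"))),
           list(cond = mx_rel("geq", mx_var("u"), mx_num("1")), value = mx_num("1"))),
      otherwise = mx_var("v"))
  )
  for (e in exprs) {
    txt <- paste0("<math xmlns=\"http://www.w3.org/1998/Math/MathML\">",
                  serialize_mathml(e), "</math>")
    back <- parse_mathml_expr(xml2::read_xml(txt))
    expect_true(tecgen:::expr_equal(e, back), info = format(e))
  }
})

test_that("free_variables matches the references in the tree", {
  rhs_fhn_y <- mx_op("mul", mx_var("b"),
                     mx_op("sub", mx_op("add", mx_var("x"), mx_var("c")),
                           mx_op("mul", mx_var("d"), mx_var("y"))))
  expect_setequal(free_variables(rhs_fhn_y), c("x", "y", "b", "c", "d"))
  expect_length(free_variables(mx_num("42")), 0)
  pw <- mx_piecewise(list(list(cond = mx_rel("lt", mx_var("u"), mx_num("0")),
                               value = mx_piecewise(list(list(
                                 cond = mx_rel("gt", mx_var("v"), mx_num("1")),
                                 value = mx_var("v"))), otherwise = mx_num("0")))),
                     otherwise = mx_var("u"))
  expect_setequal(free_variables(pw), c("u", "v"))
})

test_that("evaluate_expr computes in double and decimal contexts", {
  cube <- mx_op("pow", mx_var("x"), mx_num("3"))
  expect_identical(evaluate_expr(cube, c(x = 2)), 8)
  e <- mx_op("add", mx_op("sub", mx_op("sub", mx_var("x"),
         mx_op("div", mx_op("pow", mx_var("x"), mx_num("3")), mx_num("3.0"))),
         mx_var("y")), mx_var("a"))
  expect_equal(evaluate_expr(e, c(x = 1, y = 0, a = 0)), 2 / 3)
  expect_identical(evaluate_expr(e, c(x = "1", y = "0", a = "0"), precision = 7),
                   "0.6666667")
})

test_that("evaluation errors are surfaced, never silent NaN", {
  expect_error(evaluate_expr(mx_var("x"), c()), "unbound")
  expect_error(evaluate_expr(mx_op("div", mx_num("1"), mx_var("x")), c(x = 0)),
               "division by zero")
  expect_error(evaluate_expr(mx_call("ln", list(mx_var("x"))), c(x = -1)),
               "log")
  expect_error(evaluate_expr(mx_call("root", list(mx_var("x"))), c(x = "-4"),
                             precision = 20),
               "root|negative")
})

test_that("evaluate_expr agrees with an independent tree-walk evaluator", {
  # expression/binding pairs drawn from the generator's dual representation
  n_pairs <- 0
  for (seed in 1:60) {
    rm_ <- random_model(model_spec(seed, nx = 3, ny = 2, nz = 2, depth = 4))
    m <- parse_cellml(rm_$cellml)
    set.seed(seed + 10000)
    vals <- stats::setNames(round(stats::runif(nrow(m$variables), -2, 2), 4),
                            m$variables$name)
    for (eq in m$equations) {
      got <- evaluate_expr(eq$rhs, vals)
      want <- oracle_eval(eq$rhs, as.list(vals))
      expect_lt(abs(got - want), 1e-12 * max(1, abs(want)))
      # decimal context at 20 digits agrees with the double oracle closely
      got_dec <- as.numeric(evaluate_expr(eq$rhs, vals, precision = 20))
      expect_lt(abs(got_dec - want), 1e-12 * max(1, abs(want)))
      n_pairs <- n_pairs + 1
    }
  }
  expect_gte(n_pairs, 250)
})
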
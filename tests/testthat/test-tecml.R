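# scheme representation, parsing, validation ----------------------------------

test_that("built-in schemes validate and have the pinned stage counts", {
  for (s in ALL_SCHEMES) {
    sch <- builtin_scheme(s)
    expect_identical(nrow(tecgen:::diag_errors(validate_scheme(sch))), 0L)
  }
  expect_identical(builtin_scheme("euler")$n_stages, 1L)
  expect_identical(builtin_scheme("modified_euler")$n_stages, 2L)
  expect_identical(builtin_scheme("rk2")$n_stages, 2L)
  expect_identical(builtin_scheme("rk4")$n_stages, 4L)
  expect_error(builtin_scheme("adams"), "arg")
})

test_that("the Heun scheme statements follow the predictor-corrector order", {
  s <- builtin_scheme("modified_euler")
  kinds <- vapply(s$statements, `[[`, "", "kind")
  expect_identical(kinds, c("input", "time_input", "arith", "deriv",
                            "stage_update", "time_update", "arith", "deriv",
                            "stage_update", "output"))
  # corrector: xi_2 = xi_0 + 0.5*(kappa_1 + kappa_2)*delta
  corr <- s$statements[[9]]$expr
  expect_true(tecgen:::expr_equal(corr,
    mx_op("add", mx_var("xi_0"),
          mx_op("mul", mx_op("mul", mx_num("0.5"),
                             mx_op("add", mx_var("kappa_1"), mx_var("kappa_2"))),
                mx_var("delta")))))
})

test_that("TecML serialize -> parse round-trips all builtins", {
  for (s in ALL_SCHEMES) {
    sch <- builtin_scheme(s)
    back <- parse_tecml(serialize_tecml(sch))
    expect_true(tecgen:::scheme_equal(sch, back), info = s)
    expect_identical(back$n_stages, sch$n_stages)
  }
})

test_that("use-before-definition and arity violations are scheme errors", {
  # stage update citing kappa_2 with no second deriv-eval
  st <- tecgen:::tec_statement
  bad <- tec_scheme("bad", 2L, list(
    st("input", 0L), st("time_input", 0L), st("deriv", 0L),
    st("stage_update", 1L,
       mx_op("add", mx_var("xi_0"), mx_op("mul", mx_var("kappa_2"), mx_var("delta")))),
    st("output")
  ))
  diag <- validate_scheme(bad)
  expect_true(any(grepl("kappa_2.*before", diag$message)))
  # two output bindings
  two_out <- tec_scheme("two", 1L, list(
    st("input", 0L), st("time_input", 0L), st("deriv", 0L),
    st("stage_update", 1L,
       mx_op("add", mx_var("xi_0"), mx_op("mul", mx_var("kappa_1"), mx_var("delta")))),
    st("output"), st("output")
  ))
  expect_true(any(grepl("exactly one output",
                        validate_scheme(two_out)$message)))
  # non-scheme symbol in a formula
  alien <- tec_scheme("alien", 1L, list(
    st("input", 0L), st("time_input", 0L), st("deriv", 0L),
    st("stage_update", 1L, mx_op("add", mx_var("xi_0"), mx_var("zeal"))),
    st("output")
  ))
  expect_true(any(grepl("not a scheme symbol", validate_scheme(alien)$message)))
})

test_that("shuffled statement orders are caught by definition-before-use", {
  base <- builtin_scheme("modified_euler")
  n_bad <- 0
  set.seed(7)
  for (i in 1:30) {
    perm <- sample(length(base$statements))
    if (all(perm == seq_along(perm))) next
    shuffled <- tec_scheme("p", base$n_stages, base$statements[perm])
    if (nrow(tecgen:::diag_errors(validate_scheme(shuffled))) > 0) n_bad <- n_bad + 1
  }
  expect_gt(n_bad, 20)  # almost every non-identity order breaks a dependency
  expect_identical(nrow(tecgen:::diag_errors(validate_scheme(base))), 0L)
})

test_that("parse_tecml rejects role table mismatches and unknown kinds", {
  txt <- serialize_tecml(builtin_scheme("euler"))
  bad_role <- sub("base=\"xi\" role=\"diffvar\"", "base=\"xi\" role=\"constvar\"", txt)
  expect_error(parse_tecml(bad_role), class = "tecgen_scheme_error")
  bad_kind <- sub("kind=\"input-binding\"", "kind=\"warp\"", txt)
  expect_error(parse_tecml(bad_kind), class = "tecgen_scheme_error")
})
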
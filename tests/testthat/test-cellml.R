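# cell-model parsing and validation -------------------------------------------

test_that("the FitzHugh-Nagumo document parses to the expected model", {
  m <- parse_cellml(fhn_cellml())
  expect_setequal(m$variables$name, c("x", "y", "r", "a", "b", "c", "d", "time"))
  expect_length(tecgen:::model_diff_eqs(m), 2)
  expect_length(tecgen:::model_arith_eqs(m), 1)
  expect_identical(m$time_variable, "time")
  expect_identical(nrow(tecgen:::diag_errors(validate_model(m))), 0L)
  # the algebraic equation is r = x^3
  req <- tecgen:::model_arith_eqs(m)[[1]]
  expect_identical(req$lhs$name, "r")
  expect_true(tecgen:::expr_equal(req$rhs, mx_op("pow", mx_var("x"), mx_num("3"))))
})

test_that("a constants-only model is valid but flagged not simulable", {
  doc <- paste0(
    "<model name=\"k\"><component name=\"main\">",
    "<variable name=\"c1\" initial_value=\"2\"/>",
    "</component></model>")
  m <- parse_cellml(doc)
  expect_length(m$equations, 0)
  diag <- validate_model(m)
  expect_identical(nrow(tecgen:::diag_errors(diag)), 0L)
  expect_true(any(grepl("not simulable", diag$message)))
})

test_that("serialize -> parse round-trips models structurally", {
  for (seed in c(1, 5, 11, 23)) {
    rm_ <- random_model(model_spec(seed, nx = 3, ny = 2, nz = 2, depth = 3))
    m <- parse_cellml(rm_$cellml)
    m2 <- parse_cellml(serialize_cellml(m))
    expect_true(models_identical(m, m2), info = paste("seed", seed))
  }
  m <- parse_cellml(fhn_cellml())
  expect_true(models_identical(m, parse_cellml(serialize_cellml(m))))
})

test_that("model errors are rejected: malformed XML, bad left-hand sides", {
  expect_error(parse_cellml("<model><component"), class = "tecgen_parse_error")
  # multi-term left-hand side: u + v = w
  doc <- paste0(
    "<model name=\"bad\"><component name=\"main\">",
    "<variable name=\"u\"/><variable name=\"v\"/><variable name=\"w\"/>",
    "<math><apply><eq/><apply><plus/><ci>u</ci><ci>v</ci></apply><ci>w</ci></apply></math>",
    "</component></model>")
  expect_error(parse_cellml(doc), class = "tecgen_model_error")
  expect_match(conditionMessage(tryCatch(parse_cellml(doc), error = identity)),
               "single variable|left-hand")
  # duplicate lhs
  doc2 <- paste0(
    "<model name=\"dup\"><component name=\"main\">",
    "<variable name=\"r\"/><variable name=\"x\"/>",
    "<math><apply><eq/><ci>r</ci><ci>x</ci></apply>",
    "<apply><eq/><ci>r</ci><apply><power/><ci>x</ci><cn>3</cn></apply></apply></math>",
    "</component></model>")
  err <- tryCatch(parse_cellml(doc2), error = identity)
  expect_s3_class(err, "tecgen_model_error")
  expect_match(conditionMessage(err), "more than once")
  # undeclared variable reference
  doc3 <- paste0(
    "<model name=\"und\"><component name=\"main\">",
    "<variable name=\"x\"/><variable name=\"time\"/>",
    "<math><apply><eq/>",
    "<apply><diff/><bvar><ci>time</ci></bvar><ci>x</ci></apply>",
    "<ci>ghost</ci></apply></math>",
    "</component></model>")
  expect_error(parse_cellml(doc3), class = "tecgen_model_error")
})

test_that("several derivative bound variables are rejected", {
  doc <- paste0(
    "<model name=\"tv\"><component name=\"main\">",
    "<variable name=\"x\"/><variable name=\"y\"/>",
    "<variable name=\"t1\"/><variable name=\"t2\"/>",
    "<math><apply><eq/>",
    "<apply><diff/><bvar><ci>t1</ci></bvar><ci>x</ci></apply><ci>y</ci></apply>",
    "<apply><eq/>",
    "<apply><diff/><bvar><ci>t2</ci></bvar><ci>y</ci></apply><ci>x</ci></apply>",
    "</math></component></model>")
  expect_error(parse_cellml(doc), class = "tecgen_model_error")
})

test_that("components are flattened and connections unify variables", {
  doc <- paste0(
    "<model name=\"two\">",
    "<component name=\"membrane\">",
    "<variable name=\"V\" initial_value=\"-80\"/>",
    "<variable name=\"time\"/>",
    "<math><apply><eq/>",
    "<apply><diff/><bvar><ci>time</ci></bvar><ci>V</ci></apply>",
    "<apply><minus/><ci>V</ci></apply></apply></math>",
    "</component>",
    "<component name=\"gate\">",
    "<variable name=\"V\"/>",
    "<variable name=\"g\"/>",
    "<math><apply><eq/><ci>g</ci>",
    "<apply><times/><ci>V</ci><cn>2</cn></apply></apply></math>",
    "</component>",
    "<connection><map_components component_1=\"membrane\" component_2=\"gate\"/>",
    "<map_variables variable_1=\"V\" variable_2=\"V\"/></connection>",
    "</model>")
  m <- parse_cellml(doc)
  # the two V declarations are one variable after unification
  expect_identical(sum(grepl("V", m$variables$name)), 1L)
  expect_identical(m$variables$initial_value[m$variables$name == "V"], "-80")
  expect_identical(nrow(tecgen:::diag_errors(validate_model(m))), 0L)
  # unconnected name collisions get component-qualified
  doc2 <- sub("<connection>.*</connection>", "", doc)
  m2 <- parse_cellml(doc2, check = FALSE)
  expect_setequal(grep("V", m2$variables$name, value = TRUE),
                  c("membrane__V", "gate__V"))
})

test_that("unsupported elements are skipped with a warning diagnostic", {
  doc <- paste0(
    "<model name=\"u\"><component name=\"main\">",
    "<units name=\"mv\"><unit units=\"volt\"/></units>",
    "<variable name=\"x\" initial_value=\"1\"/><variable name=\"time\"/>",
    "<math><apply><eq/>",
    "<apply><diff/><bvar><ci>time</ci></bvar><ci>x</ci></apply>",
    "<apply><minus/><ci>x</ci></apply></apply></math>",
    "</component></model>")
  m <- parse_cellml(doc)
  diag <- attr(m, "diagnostics")
  expect_true(any(diag$severity == "warning" & grepl("units", diag$message)))
})
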
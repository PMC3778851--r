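# role maps: parsing, inference, triple validation ----------------------------

test_that("the FHN role map has the published role assignments", {
  map <- parse_relml(fhn_relml())
  expect_identical(nrow(map$roles), 10L)
  role_of <- function(v) map$roles$role[map$roles$variable == v]
  expect_identical(role_of("x"), "diffvar")
  expect_identical(role_of("y"), "diffvar")
  expect_identical(role_of("dx/dtime"), "derivativevar")
  expect_identical(role_of("dy/dtime"), "derivativevar")
  expect_identical(role_of("r"), "arithvar")
  for (k in c("a", "b", "c", "d")) expect_identical(role_of(k), "constvar")
  expect_identical(role_of("time"), "timevar")
})

test_that("duplicate entries and unknown role tokens are map errors", {
  txt <- paste0("<relml><model href=\"m\"/><scheme href=\"s\"/>",
                "<var name=\"x\" type=\"diffvar\"/>",
                "<var name=\"x\" type=\"constvar\"/></relml>")
  expect_error(parse_relml(txt), class = "tecgen_map_error")
  txt2 <- paste0("<relml><var name=\"x\" type=\"statevar\"/></relml>")
  expect_error(parse_relml(txt2), class = "tecgen_map_error")
})

test_that("an incomplete map parses but fails triple validation", {
  txt <- fhn_relml()
  txt <- sub("  <var name=\"r\" type=\"arithvar\"/>\n", "", txt, fixed = TRUE)
  map <- parse_relml(txt)
  m <- parse_cellml(fhn_cellml())
  diag <- validate_mapping(map, m, builtin_scheme("modified_euler"))
  expect_true(any(grepl("'r'", diag$message)))
})

test_that("role inference reproduces the FHN fixture map", {
  m <- parse_cellml(fhn_cellml())
  inferred <- infer_roles(m)
  fixture <- parse_relml(fhn_relml())
  expect_identical(as.data.frame(inferred$roles), as.data.frame(fixture$roles))
  expect_identical(nrow(tecgen:::diag_errors(
    validate_mapping(inferred, m, builtin_scheme("modified_euler")))), 0L)
})

test_that("triple validation catches role/equation mismatches", {
  m <- parse_cellml(fhn_cellml())
  s <- builtin_scheme("modified_euler")
  base <- infer_roles(m)
  # y as constvar while dy/dt exists
  map1 <- base
  map1$roles$role[map1$roles$variable == "y"] <- "constvar"
  diag1 <- validate_mapping(map1, m, s)
  expect_true(any(grepl("differential equation", diag1$message)))
  # entry for a variable absent from the model
  map2 <- base
  map2$roles <- rbind(map2$roles,
                      tibble::tibble(variable = "ghost", role = "constvar"))
  expect_true(any(grepl("ghost", validate_mapping(map2, m, s)$message)))
  # temporal variables present but the scheme cannot evaluate them
  no_arith <- tec_scheme("na", 1L, list(
    tecgen:::tec_statement("input", 0L), tecgen:::tec_statement("time_input", 0L),
    tecgen:::tec_statement("deriv", 0L),
    tecgen:::tec_statement("stage_update", 1L,
      mx_op("add", mx_var("xi_0"), mx_op("mul", mx_var("kappa_1"), mx_var("delta")))),
    tecgen:::tec_statement("output")
  ))
  expect_true(any(grepl("arith-eval", validate_mapping(base, m, no_arith)$message)))
})

test_that("RelML serialize -> parse is the identity", {
  map <- parse_relml(fhn_relml())
  expect_true(tecgen:::relmap_equal(map, parse_relml(serialize_relml(map))))
})

test_that("inferred roles of random models always validate", {
  s <- builtin_scheme("modified_euler")
  set.seed(99)
  sizes <- data.frame(nx = sample(1:4, 40, TRUE), ny = sample(0:3, 40, TRUE),
                      nz = sample(0:2, 40, TRUE))
  for (seed in 1:40) {
    rm_ <- random_model(model_spec(seed, nx = sizes$nx[seed], ny = sizes$ny[seed],
                                   nz = sizes$nz[seed], depth = 3))
    m <- parse_cellml(rm_$cellml)
    map <- infer_roles(m)
    expect_identical(nrow(tecgen:::diag_errors(validate_mapping(map, m, s))), 0L,
                     info = paste("seed", seed))
    # inferred roles match the generator's ground truth
    ord_a <- order(map$roles$variable)
    ord_b <- order(rm_$truth$roles$variable)
    expect_identical(map$roles$variable[ord_a], rm_$truth$roles$variable[ord_b])
    expect_identical(map$roles$role[ord_a], rm_$truth$roles$role[ord_b])
  }
})
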
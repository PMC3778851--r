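# fixture documents and the random model generator ---------------------------

test_that("FHN fixture documents parse to the expected sizes", {
  m <- parse_cellml(fhn_cellml())
  map <- infer_roles(m)
  expect_length(tecgen:::map_vars_with_role(map, "diffvar"), 2)   # Nx
  expect_length(tecgen:::map_vars_with_role(map, "arithvar"), 1)  # Ny
  expect_length(tecgen:::map_vars_with_role(map, "constvar"), 4)  # Nz
  expect_identical(count_steps(expand(m, parse_tecml(scheme_tecml("euler")),
                                      parse_relml(fhn_relml()))), 11L)
})

test_that("random models are reproducible byte for byte", {
  s <- model_spec(7, nx = 3, ny = 2, nz = 2, depth = 3)
  a <- random_model(s)
  b <- random_model(s)
  expect_identical(a$cellml, b$cellml)
  expect_identical(a$relml, b$relml)
  expect_false(identical(a$cellml,
                         random_model(model_spec(8, nx = 3, ny = 2, nz = 2))$cellml))
})

test_that("generated models always validate and carry consistent ground truth", {
  set.seed(123)
  shapes <- data.frame(nx = sample(1:4, 25, TRUE), ny = sample(0:3, 25, TRUE),
                       nz = sample(0:3, 25, TRUE))
  for (i in seq_len(25)) {
    rm_ <- random_model(model_spec(i + 100, nx = shapes$nx[i], ny = shapes$ny[i],
                                   nz = shapes$nz[i], depth = 3))
    m <- parse_cellml(rm_$cellml)
    expect_identical(nrow(tecgen:::diag_errors(validate_model(m))), 0L)
    map <- parse_relml(rm_$relml)
    expect_identical(nrow(tecgen:::diag_errors(
      validate_mapping(map, m, builtin_scheme("rk2")))), 0L)
  }
})

test_that("the generator leaves the RNG stream untouched", {
  set.seed(555)
  before <- stats::runif(1)
  set.seed(555)
  invisible(random_model(model_spec(3)))
  after <- stats::runif(1)
  expect_identical(before, after)
})

test_that("FHN stays bounded over 20 time units for every scheme", {
  m <- parse_cellml(fhn_cellml())
  b <- model_bindings(m)
  for (s in ALL_SCHEMES) {
    r <- interpret(expand(m, builtin_scheme(s)), b$init, b$consts,
                   t_end = 20, delta = 0.1, stride = 10)
    expect_true(is.na(r$divergent_step), info = s)
    expect_true(all(abs(r$values) < 10), info = s)
  }
})

test_that("write_fixtures materializes a complete offline input set", {
  dir <- tempfile("fixtures")
  files <- write_fixtures(dir)
  expect_length(files, 6)
  expect_true(all(file.exists(files)))
  m <- parse_cellml(file.path(dir, "fhn.cellml"))
  s <- parse_tecml(file.path(dir, "rk4.tecml.xml"))
  map <- parse_relml(file.path(dir, "fhn.relml.xml"))
  expect_identical(count_steps(expand(m, s, map)), 26L)
  unlink(dir, recursive = TRUE)
})
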
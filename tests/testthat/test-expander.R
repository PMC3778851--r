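# symbolic expansion to flat single-assignment programs -----------------------

fhn_triple <- function(scheme) {
  m <- parse_cellml(fhn_cellml())
  list(m = m, s = builtin_scheme(scheme), map = parse_relml(fhn_relml()))
}

test_that("equation classification aligns rates with the state vector", {
  tr <- fhn_triple("euler")
  cls <- classify_equations(tr$m, tr$map)
  expect_identical(vapply(cls$f, function(e) e$lhs$var, ""), c("x", "y"))
  expect_identical(vapply(cls$g, function(e) e$lhs$name, ""), "r")
  # random models: class sizes equal the generator's
  for (seed in c(3, 9)) {
    spec <- model_spec(seed, nx = 3, ny = 2, nz = 1, depth = 2)
    rm_ <- random_model(spec)
    m <- parse_cellml(rm_$cellml)
    cls2 <- classify_equations(m, infer_roles(m))
    expect_length(cls2$f, 3)
    expect_length(cls2$g, 2)
  }
})

test_that("temporal equations are dependency-ordered, cycles rejected", {
  v <- mx_var
  g <- list(list(lhs = v("u"), rhs = mx_op("add", v("v"), mx_num("1"))),
            list(lhs = v("v"), rhs = mx_op("pow", v("x"), mx_num("2"))))
  ord <- order_arith(g)
  expect_identical(vapply(ord, function(e) e$lhs$name, ""), c("v", "u"))
  # single equation untouched
  expect_identical(order_arith(g[2]), g[2])
  cyc <- list(list(lhs = v("u"), rhs = v("v")),
              list(lhs = v("v"), rhs = v("u")))
  expect_error(order_arith(cyc), class = "tecgen_dae_error")
})

test_that("FHN expands to 11 / 16 / 26 execution steps", {
  tr <- fhn_triple("euler")
  expect_identical(count_steps(expand(tr$m, builtin_scheme("euler"), tr$map)), 11L)
  expect_identical(count_steps(expand(tr$m, builtin_scheme("modified_euler"), tr$map)), 16L)
  expect_identical(count_steps(expand(tr$m, builtin_scheme("rk4"), tr$map)), 26L)
})

test_that("the FHN Heun expansion matches the reference equations in order", {
  tr <- fhn_triple("modified_euler")
  p <- expand(tr$m, tr$s, tr$map)
  res <- alpha_equivalent(p, golden_fhn_heun())
  expect_true(res, info = attr(res, "why"))
  # sanity of the alpha check itself: a reordering must NOT be equivalent
  swapped <- golden_fhn_heun()
  swapped[c(5, 6)] <- swapped[c(6, 5)]
  expect_false(isTRUE(alpha_equivalent(p, swapped)))
})

test_that("a one-variable model under Euler yields the six textbook steps", {
  m <- make_model("one", c(x = "0", z = "2", time = NA),
                  list(list(lhs = mx_deriv("x", "time"), rhs = mx_var("z"))))
  p <- expand(m, builtin_scheme("euler"))
  expect_identical(count_steps(p), 6L)
  lhs <- vapply(p$assignments, `[[`, "", "lhs")
  expect_identical(lhs, c("x_0", "time_0", "kappa1_x", "x_1", "time_1", "x_out"))
  expect_true(tecgen:::expr_equal(p$assignments[[3]]$rhs, mx_var("z")))
  expect_true(tecgen:::expr_equal(
    p$assignments[[4]]$rhs,
    mx_op("add", mx_var("x_0"), mx_op("mul", mx_var("kappa1_x"), mx_var("delta")))))
})

test_that("RK4 kappa evaluations reference the temporal variable of their stage", {
  tr <- fhn_triple("rk4")
  p <- expand(tr$m, tr$s, tr$map)
  for (a in p$assignments) {
    mt <- regmatches(a$lhs, regexec("^kappa([0-9]+)_x$", a$lhs))[[1]]
    if (length(mt) == 2) {
      stage <- as.integer(mt[[2]]) - 1L
      rvars <- grep("^r_", free_variables(a$rhs), value = TRUE)
      expect_identical(rvars, paste0("r_", stage))
    }
  }
})

test_that("expansion output is always well formed", {
  for (seed in c(2, 8, 21)) {
    rm_ <- random_model(model_spec(seed, nx = 3, ny = 3, nz = 2, depth = 3))
    m <- parse_cellml(rm_$cellml)
    for (s in ALL_SCHEMES) {
      p <- expand(m, builtin_scheme(s))
      expect_identical(nrow(check_well_formed(p)), 0L)
      expect_identical(length(p$outputs), length(p$diffvars))
    }
  }
})

test_that("well-formedness violations are reported precisely", {
  asn <- function(lhs, rhs) list(lhs = lhs, rhs = rhs)
  base <- expand(parse_cellml(fhn_cellml()), builtin_scheme("euler"))
  used_before <- base
  used_before$assignments[[1]] <- asn("x_0", mx_var("x_1"))
  diag <- check_well_formed(used_before)
  expect_true(any(grepl("'x_1' is used before", diag$message)))
  dup <- base
  dup$assignments[[2]] <- asn("x_0", mx_var("y_in"))
  expect_true(any(grepl("'x_0' is defined more than once",
                        check_well_formed(dup)$message)))
})

test_that("step counts are invariant under model variable renaming", {
  ren <- c(x = "alpha", y = "beta", r = "rho", a = "p1", b = "p2", c = "p3",
           d = "p4", time = "tau_model")
  m <- parse_cellml(fhn_cellml())
  m2 <- m
  m2$variables$name <- unname(ren[m2$variables$name])
  m2$time_variable <- "tau_model"
  m2$equations <- lapply(m$equations, function(eq)
    list(lhs = tecgen:::rename_vars(eq$lhs, ren),
         rhs = tecgen:::rename_vars(eq$rhs, ren)))
  for (s in ALL_SCHEMES) {
    expect_identical(count_steps(expand(m2, builtin_scheme(s))),
                     count_steps(expand(m, builtin_scheme(s))), info = s)
  }
})

test_that("expansion refuses invalid triples", {
  m <- parse_cellml(fhn_cellml())
  map <- infer_roles(m)
  map$roles$role[map$roles$variable == "r"] <- "constvar"
  expect_error(expand(m, builtin_scheme("euler"), map), class = "tecgen_map_error")
})
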
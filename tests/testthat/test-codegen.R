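# source emission --------------------------------------------------------------

fhn_setup <- function(scheme = "modified_euler") {
  m <- parse_cellml(fhn_cellml())
  list(m = m, p = expand(m, builtin_scheme(scheme)), b = model_bindings(m))
}

loop_equation_lines <- function(src, target) {
  lines <- strsplit(src, "\n")[[1]]
  marker <- if (target == "c") c("/* equations */", "/* advance */")
            else c("# equations", "# advance")
  i1 <- grep(marker[[1]], lines, fixed = TRUE)
  i2 <- grep(marker[[2]], lines, fixed = TRUE)
  lines[(i1 + 1):(i2 - 1)]
}

test_that("the C source carries exactly the program's assignments in its loop", {
  fx <- fhn_setup("modified_euler")
  opts <- codegen_options("c", t_end = 1, delta = 0.01,
                          init = fx$b$init, consts = fx$b$consts)
  src <- emit_source(fx$p, opts)
  expect_length(loop_equation_lines(src, "c"), 16)
  expect_match(src, "#include <stdio.h>", fixed = TRUE)
  # assignment statement count equals count_steps on other inputs too
  for (s in c("euler", "rk4")) {
    fx2 <- fhn_setup(s)
    src2 <- emit_source(fx2$p, opts)
    expect_length(loop_equation_lines(src2, "c"), count_steps(fx2$p))
  }
})

test_that("emission is deterministic and rejects unbound or unusable inputs", {
  fx <- fhn_setup()
  opts <- codegen_options("r", t_end = 1, delta = 0.01,
                          init = fx$b$init, consts = fx$b$consts)
  expect_identical(emit_source(fx$p, opts), emit_source(fx$p, opts))
  # unbound constant is reported by name
  opts_missing <- codegen_options("r", t_end = 1, delta = 0.01,
                                  init = fx$b$init,
                                  consts = fx$b$consts[c("a", "b", "c")])
  err <- tryCatch(emit_source(fx$p, opts_missing), error = identity)
  expect_s3_class(err, "tecgen_emit_error")
  expect_match(conditionMessage(err), "\\bd\\b")
  # decimal contexts are the interpreter's job
  opts_dec <- codegen_options("r", precision = 32, t_end = 1, delta = 0.01,
                              init = fx$b$init, consts = fx$b$consts)
  expect_error(emit_source(fx$p, opts_dec), class = "tecgen_emit_error")
})

test_that("equation listings number every assignment", {
  fx <- fhn_setup()
  listing <- emit_equation_listing(fx$p)
  expect_length(listing, 16)
  expect_match(listing[[1]], "x_0 = x_in", fixed = TRUE)
  for (seed in c(4, 17)) {
    rm_ <- random_model(model_spec(seed, nx = 2, ny = 1, nz = 1, depth = 2))
    p <- expand(parse_cellml(rm_$cellml), builtin_scheme("rk2"))
    expect_length(emit_equation_listing(p), count_steps(p))
  }
})

run_emitted_r <- function(src) {
  f <- tempfile(fileext = ".R")
  writeLines(src, f)
  on.exit(unlink(f))
  out <- system2("Rscript", f, stdout = TRUE)
  utils::read.csv(text = out)
}

test_that("emitted R scripts reproduce interpreter trajectories (1000 steps)", {
  for (s in c("euler", "rk4")) {
    fx <- fhn_setup(s)
    opts <- codegen_options("r", t_end = 10, delta = 0.01, stride = 10,
                            init = fx$b$init, consts = fx$b$consts)
    tr <- run_emitted_r(emit_source(fx$p, opts))
    ref <- interpret(fx$p, fx$b$init, fx$b$consts, t_end = 10, delta = 0.01,
                     stride = 10)
    expect_identical(nrow(tr), length(ref$t))
    expect_lt(max_rel_diff(tr$x, ref$values[, "x"]), 1e-12)
    expect_lt(max_rel_diff(tr$y, ref$values[, "y"]), 1e-12)
  }
})

test_that("emitted C programs compile and reproduce interpreter trajectories", {
  cc <- Sys.which(c("cc", "gcc"))
  cc <- cc[nzchar(cc)][1]
  expect_false(is.na(cc))
  fx <- fhn_setup("modified_euler")
  opts <- codegen_options("c", t_end = 5, delta = 0.01, stride = 10,
                          init = fx$b$init, consts = fx$b$consts)
  src_f <- tempfile(fileext = ".c")
  bin_f <- tempfile()
  writeLines(emit_source(fx$p, opts), src_f)
  status <- system2(cc, c("-std=c99", "-O2", "-o", bin_f, src_f, "-lm"))
  expect_identical(status, 0L)
  tr <- utils::read.csv(text = system2(bin_f, stdout = TRUE))
  ref <- interpret(fx$p, fx$b$init, fx$b$consts, t_end = 5, delta = 0.01,
                   stride = 10)
  expect_lt(max_rel_diff(tr$x, ref$values[, "x"]), 1e-12)
  unlink(c(src_f, bin_f))
})

test_that("random models round-trip through emitted R sources", {
  set.seed(31)
  for (seed in c(6, 13, 27)) {
    rm_ <- random_model(model_spec(seed, nx = 2, ny = 2, nz = 1, depth = 3))
    m <- parse_cellml(rm_$cellml)
    b <- model_bindings(m)
    for (s in c("modified_euler", "rk4")) {
      p <- expand(m, builtin_scheme(s))
      opts <- codegen_options("r", t_end = 0.2, delta = 0.001, stride = 20,
                              init = b$init, consts = b$consts)
      tr <- run_emitted_r(emit_source(p, opts))
      ref <- interpret(p, b$init, b$consts, t_end = 0.2, delta = 0.001,
                       stride = 20)
      for (v in colnames(ref$values))
        expect_lt(max_rel_diff(tr[[v]], ref$values[, v]), 1e-12)
    }
  }
})

test_that("a program without state variables cannot be emitted", {
  fx <- fhn_setup()
  p0 <- fx$p
  p0$diffvars <- character(0)
  p0$outputs <- stats::setNames(character(0), character(0))
  opts <- codegen_options("r", t_end = 1, delta = 0.1, init = fx$b$init,
                          consts = fx$b$consts)
  expect_error(emit_source(p0, opts), class = "tecgen_emit_error")
})
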
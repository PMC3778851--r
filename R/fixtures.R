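# Shipped fixtures: the FitzHugh-Nagumo model and its role map ---------------
#
# The FHN excitable-media model in the three-equation form used throughout
# this package:
#
#   r     = x^3                    (removable temporal variable)
#   dx/dt = x - r/3.0 - y + a
#   dy/dt = b*(x + c - d*y)
#
# Parameter values and initial conditions are the package's own choice of a
# classical FitzHugh parameterization (b = 0.08, c = 0.7, d = 0.8, applied
# current a = 0.5, x(0) = -1.2, y(0) = -0.6); every structural result (step
# counts, expansion shape) is independent of these values.

fhn_model <- function() {
  v <- mx_var
  n <- mx_num
  o <- mx_op
  variables <- tibble::tibble(
    name = c("x", "y", "r", "a", "b", "c", "d", "time"),
    initial_value = c("-1.2", "-0.6", NA, "0.5", "0.08", "0.7", "0.8", NA),
    units = c("dimensionless", "dimensionless", "dimensionless",
              "dimensionless", "dimensionless", "dimensionless",
              "dimensionless", "millisecond")
  )
  equations <- list(
    list(lhs = v("r"), rhs = o("pow", v("x"), n("3"))),
    list(lhs = mx_deriv("x", "time"),
         rhs = o("add", o("sub", o("sub", v("x"), o("div", v("r"), n("3.0"))),
                          v("y")), v("a"))),
    list(lhs = mx_deriv("y", "time"),
         rhs = o("mul", v("b"), o("sub", o("add", v("x"), v("c")),
                                  o("mul", v("d"), v("y")))))
  )
  cell_model("fhn", variables, equations, "time")
}

#' FitzHugh-Nagumo fixture documents
#'
#' `fhn_cellml()` returns the CellML text of the three-equation
#' FitzHugh-Nagumo model (`r = x^3`, `dx/dt = x - r/3.0 - y + a`,
#' `dy/dt = b*(x + c - d*y)`); `fhn_relml()` the matching RelML role map
#' (`x`, `y` diffvar with paired derivatives, `r` arithvar, `a`-`d`
#' constvar, `time` timevar); `scheme_tecml()` the TecML text of a
#' [builtin_scheme()].  Together the three documents form a complete input
#' set for [expand()].
#'
#' @param scheme Scheme name (see [builtin_scheme()]).
#' @return XML text.
#' @examples
#' m <- parse_cellml(fhn_cellml())
#' count_steps(expand(m, builtin_scheme("euler"), parse_relml(fhn_relml())))
#' @export
fhn_cellml <- function() serialize_cellml(fhn_model())

#' @rdname fhn_cellml
#' @export
fhn_relml <- function(scheme = "modified_euler") {
  map <- infer_roles(fhn_model())
  map$model_ref <- "fhn.cellml"
  map$scheme_ref <- paste0(scheme, ".tecml.xml")
  serialize_relml(map)
}

#' @rdname fhn_cellml
#' @export
scheme_tecml <- function(scheme) serialize_tecml(builtin_scheme(scheme))

#' Materialize all fixture documents into a directory
#'
#' Writes `fhn.cellml`, `fhn.relml.xml` and the four scheme files
#' (`<name>.tecml.xml`); everything needed to drive the command-line
#' interface offline.
#'
#' @param dir Output directory (created if missing).
#' @return Character vector of the files written, invisibly.
#' @export
write_fixtures <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  put <- function(name, text) {
    path <- file.path(dir, name)
    writeLines(text, path, sep = "")
    files <<- c(files, path)
  }
  put("fhn.cellml", fhn_cellml())
  put("fhn.relml.xml", fhn_relml())
  for (s in c("euler", "modified_euler", "rk2", "rk4"))
    put(paste0(s, ".tecml.xml"), scheme_tecml(s))
  invisible(files)
}
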
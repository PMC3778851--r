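# Cell model representation and CellML parsing -------------------------------

#' @title Cell model objects
#' @description A `cell_model` bundles the flattened contents of a CellML
#'   document: named variables (with optional initial values and unit text),
#'   ordered equations whose left-hand side is a single variable or derivative
#'   reference, and the detected time variable.  The derivative equations make
#'   up the model's rate function f, the algebraic equations its temporal
#'   (removable) function g.
#' @param name Model name.
#' @param variables A data frame with columns `name`, `initial_value`,
#'   `units` (character; `NA` where absent).
#' @param equations List of `list(lhs = , rhs = )` pairs of `mathexpr` nodes;
#'   each `lhs` is a variable or derivative reference.
#' @param time_variable Identifier of the independent variable (`NA` if the
#'   model has no derivative equation).
#' @return A `cell_model` object.
#' @export
cell_model <- function(name, variables, equations, time_variable = NA_character_) {
  variables <- tibble::as_tibble(variables)
  stopifnot(all(c("name", "initial_value", "units") %in% names(variables)))
  m <- structure(
    list(name = name, variables = variables, equations = equations,
         time_variable = time_variable),
    class = "cell_model"
  )
  m
}

eq_lhs_key <- function(lhs) {
  if (lhs$k == "var") lhs$name
  else if (lhs$k == "deriv") paste0("d", lhs$var, "/d", lhs$bvar)
  else render_expr(lhs)
}

is_deriv_eq <- function(eq) eq$lhs$k == "deriv"

model_diff_eqs <- function(m) Filter(is_deriv_eq, m$equations)
model_arith_eqs <- function(m) Filter(function(e) !is_deriv_eq(e), m$equations)

#' @export
print.cell_model <- function(x, ...) {
  nx <- length(model_diff_eqs(x))
  ny <- length(model_arith_eqs(x))
  cat("<cell_model> ", x$name, "\n",
      "  variables: ", nrow(x$variables),
      " | differential equations: ", nx,
      " | algebraic equations: ", ny, "\n",
      "  time variable: ", x$time_variable, "\n", sep = "")
  for (eq in x$equations)
    cat("  ", eq_lhs_key(eq$lhs), " = ", render_expr(eq$rhs), "\n", sep = "")
  invisible(x)
}

# diagnostics -----------------------------------------------------------------

diag_rows <- function() {
  env <- new.env(parent = emptyenv())
  env$rows <- list()
  env
}

diag_add <- function(d, severity, where, message) {
  d$rows[[length(d$rows) + 1L]] <- list(severity = severity, where = where,
                                        message = message)
  invisible(NULL)
}

diag_result <- function(d) {
  if (length(d$rows) == 0) {
    return(tibble::tibble(severity = character(0), where = character(0),
                          message = character(0)))
  }
  tibble::tibble(
    severity = vapply(d$rows, `[[`, "", "severity"),
    where = vapply(d$rows, `[[`, "", "where"),
    message = vapply(d$rows, `[[`, "", "message")
  )
}

diag_errors <- function(diag) diag[diag$severity == "error", , drop = FALSE]

stop_on_diag <- function(diag, class) {
  errs <- diag_errors(diag)
  if (nrow(errs) > 0) {
    tecgen_stop(paste0(errs$where[[1]], ": ", errs$message[[1]],
                       if (nrow(errs) > 1) paste0(" (and ", nrow(errs) - 1, " more)")),
                class)
  }
  invisible(diag)
}

# parsing ---------------------------------------------------------------------

#' Parse a CellML document into a cell model
#'
#' Reads a CellML 1.0/1.1-style document, flattens all components into one
#' namespace (variables joined by `<connection>` maps are unified; residual
#' name collisions are qualified as `component__name`), and checks the model
#' invariants: every equation has a single variable or derivative reference
#' on its left-hand side, no left-hand side is defined twice, every
#' referenced variable is declared, and derivative equations share one bound
#' (time) variable.  Units definitions, reactions and metadata are skipped
#' and reported as warning diagnostics attached to the result.
#'
#' @param document CellML text, a file path, or an `xml2` document.
#' @param check If `TRUE` (default) stop on any validation error.
#' @return A [cell_model()].  Attribute `"diagnostics"` carries the full
#'   diagnostics table (see [validate_model()]).
#' @export
parse_cellml <- function(document, check = TRUE) {
  doc <- read_xml_input(document)
  xml2::xml_ns_strip(doc)
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "model")
    tecgen_stop("root element must be <model>", "tecgen_parse_error")
  model_name <- xml2::xml_attr(root, "name")
  if (is.na(model_name)) model_name <- "unnamed"

  d <- diag_rows()
  skipped <- character(0)

  components <- xml2::xml_find_all(root, "./component")
  if (length(components) == 0) components <- list(root)  # single implicit component

  vars <- list()     # per qualified name: list(comp, name, initial_value, units)
  eqs <- list()      # list(comp, lhs, rhs)
  for (comp in components) {
    cname <- xml2::xml_attr(comp, "name")
    if (is.na(cname)) cname <- "main"
    for (child in xml2::xml_children(comp)) {
      nm <- xml2::xml_name(child)
      if (nm == "variable") {
        vn <- xml2::xml_attr(child, "name")
        if (is.na(vn)) {
          diag_add(d, "error", "parse_cellml", "variable element without a name")
          next
        }
        qn <- paste0(cname, "\r", vn)
        if (!is.null(vars[[qn]])) {
          diag_add(d, "error", "parse_cellml",
                   paste0("duplicate variable '", vn, "' in component '", cname, "'"))
        }
        vars[[qn]] <- list(comp = cname, name = vn,
                           initial_value = xml2::xml_attr(child, "initial_value"),
                           units = xml2::xml_attr(child, "units"))
      } else if (nm == "math") {
        for (mchild in xml2::xml_children(child)) {
          eq <- tryCatch(mathml_to_expr(mchild), error = function(e) e)
          if (inherits(eq, "error")) {
            tecgen_stop(conditionMessage(eq), "tecgen_parse_error")
          }
          if (!is_mathexpr(eq) || eq$k != "rel" || eq$op != "eq")
            tecgen_stop("each <math> child must be an <apply><eq/> equation",
                        "tecgen_parse_error")
          eqs[[length(eqs) + 1L]] <- list(comp = cname, lhs = eq$a, rhs = eq$b)
        }
      } else if (nm %in% c("units", "reaction", "RDF", "documentation", "group",
                           "import")) {
        skipped <- c(skipped, nm)
      } else {
        skipped <- c(skipped, nm)
      }
    }
  }
  for (s in unique(skipped))
    diag_add(d, "warning", "parse_cellml", paste0("skipped unsupported element <", s, ">"))

  # unify connected variables (union-find over qualified names)
  parent <- stats::setNames(names(vars), names(vars))
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  for (conn in xml2::xml_find_all(root, "./connection")) {
    mc <- xml2::xml_find_first(conn, "./map_components")
    c1 <- xml2::xml_attr(mc, "component_1"); c2 <- xml2::xml_attr(mc, "component_2")
    for (mv in xml2::xml_find_all(conn, "./map_variables")) {
      v1 <- paste0(c1, "\r", xml2::xml_attr(mv, "variable_1"))
      v2 <- paste0(c2, "\r", xml2::xml_attr(mv, "variable_2"))
      if (is.null(vars[[v1]]) || is.null(vars[[v2]])) {
        diag_add(d, "error", "parse_cellml",
                 "connection references an undeclared variable")
        next
      }
      parent[[find(v2)]] <- find(v1)
    }
  }

  # final names: bare name when unambiguous, otherwise component__name
  reps <- vapply(names(vars), find, "")
  classes <- split(names(vars), reps)
  class_bare <- vapply(classes, function(members) vars[[members[[1]]]]$name, "")
  final_names <- character(length(classes))
  names(final_names) <- names(classes)
  for (i in seq_along(classes)) {
    bare <- class_bare[[i]]
    if (sum(class_bare == bare) == 1) {
      final_names[[i]] <- bare
    } else {
      rep_qn <- names(classes)[[i]]
      final_names[[i]] <- paste0(vars[[rep_qn]]$comp, "__", bare)
    }
  }
  qn_final <- stats::setNames(final_names[reps], names(vars))

  # variable table in document order of first appearance of each class
  seen <- character(0)
  rows <- list()
  for (qn in names(vars)) {
    fn <- qn_final[[qn]]
    if (fn %in% seen) {
      # merge initial values from connected duplicates
      idx <- which(vapply(rows, function(r) r$name == fn, TRUE))[[1]]
      if (is.na(rows[[idx]]$initial_value) && !is.na(vars[[qn]]$initial_value))
        rows[[idx]]$initial_value <- vars[[qn]]$initial_value
      next
    }
    seen <- c(seen, fn)
    rows[[length(rows) + 1L]] <- list(name = fn,
                                      initial_value = vars[[qn]]$initial_value,
                                      units = vars[[qn]]$units)
  }
  variables <- tibble::tibble(
    name = vapply(rows, `[[`, "", "name"),
    initial_value = vapply(rows, function(r) r$initial_value %||% NA_character_, ""),
    units = vapply(rows, function(r) r$units %||% NA_character_, "")
  )

  # rewrite equation variable references to final names
  rename_in_comp <- function(e, comp) {
    fv <- free_variables(e)
    map <- character(0)
    for (v in fv) {
      qn <- paste0(comp, "\r", v)
      if (!is.null(vars[[qn]])) map[[v]] <- qn_final[[qn]]
    }
    if (length(map) > 0) rename_vars(e, map) else e
  }
  equations <- lapply(eqs, function(eq) {
    list(lhs = rename_in_comp(eq$lhs, eq$comp),
         rhs = rename_in_comp(eq$rhs, eq$comp))
  })

  # time variable = unique bvar of derivative left-hand sides
  bvars <- unique(vapply(Filter(function(e) e$lhs$k == "deriv", equations),
                         function(e) e$lhs$bvar, ""))
  tv <- NA_character_
  if (length(bvars) > 1) {
    diag_add(d, "error", "parse_cellml",
             paste0("several independent variables in derivatives: ",
                    paste(bvars, collapse = ", ")))
  } else if (length(bvars) == 1) {
    tv <- bvars
  }

  m <- cell_model(model_name, variables, equations, tv)
  diag <- rbind(diag_result(d), validate_model(m))
  attr(m, "diagnostics") <- diag
  if (check) stop_on_diag(diag, "tecgen_model_error")
  m
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

read_xml_input <- function(document) {
  if (inherits(document, "xml_document")) return(document)
  stopifnot(is.character(document), length(document) == 1)
  tryCatch(
    xml2::read_xml(document),
    error = function(e) tecgen_stop(paste0("malformed XML: ", conditionMessage(e)),
                                    "tecgen_parse_error")
  )
}

#' Validate a cell model
#'
#' Checks the `cell_model` invariants and returns an ordered diagnostics
#' table; an empty table means the model is well formed.  A model without
#' derivative equations is well formed but flagged `not simulable` with a
#' warning row.
#'
#' @param m A [cell_model()].
#' @return A tibble with columns `severity` (`"error"`/`"warning"`),
#'   `where`, `message`.
#' @export
validate_model <- function(m) {
  stopifnot(inherits(m, "cell_model"))
  d <- diag_rows()
  declared <- m$variables$name
  if (anyDuplicated(declared))
    diag_add(d, "error", "validate_model",
             paste0("duplicate variable name '",
                    declared[duplicated(declared)][[1]], "'"))
  seen_lhs <- character(0)
  for (i in seq_along(m$equations)) {
    eq <- m$equations[[i]]
    lhs <- eq$lhs
    if (!is_mathexpr(lhs) || !(lhs$k %in% c("var", "deriv"))) {
      diag_add(d, "error", "validate_model",
               paste0("equation ", i, ": left-hand side must be a single variable ",
                      "or derivative reference (got '",
                      render_expr(lhs), "')"))
      next
    }
    key <- eq_lhs_key(lhs)
    if (key %in% seen_lhs)
      diag_add(d, "error", "validate_model",
               paste0("equation ", i, ": '", key, "' is assigned more than once"))
    seen_lhs <- c(seen_lhs, key)
    if (lhs$k == "deriv") {
      if (!(lhs$var %in% declared))
        diag_add(d, "error", "validate_model",
                 paste0("equation ", i, ": derivative of undeclared variable '",
                        lhs$var, "'"))
      if (!is.na(m$time_variable) && lhs$bvar != m$time_variable)
        diag_add(d, "error", "validate_model",
                 paste0("equation ", i, ": derivative with respect to '", lhs$bvar,
                        "' but the model time variable is '", m$time_variable, "'"))
      if (!(lhs$bvar %in% declared))
        diag_add(d, "error", "validate_model",
                 paste0("equation ", i, ": undeclared bound variable '", lhs$bvar, "'"))
    } else if (!(lhs$name %in% declared)) {
      diag_add(d, "error", "validate_model",
               paste0("equation ", i, ": undeclared variable '", lhs$name, "'"))
    }
    rhs_missing <- setdiff(free_variables(eq$rhs), declared)
    if (length(rhs_missing) > 0)
      diag_add(d, "error", "validate_model",
               paste0("equation ", i, ": undeclared variable(s) ",
                      paste0("'", rhs_missing, "'", collapse = ", ")))
    if (contains_deriv(eq$rhs))
      diag_add(d, "error", "validate_model",
               paste0("equation ", i,
                      ": derivative references may only appear as a left-hand side"))
  }
  if (length(model_diff_eqs(m)) == 0)
    diag_add(d, "warning", "validate_model",
             "model has no differential equation: not simulable")
  diag_result(d)
}

contains_deriv <- function(e) {
  found <- FALSE
  walk <- function(n) {
    if (found) return(invisible(NULL))
    switch(n$k,
      deriv = found <<- TRUE,
      neg = walk(n$a),
      op = , rel = { walk(n$a); walk(n$b) },
      call = lapply(n$args, walk),
      piecewise = {
        lapply(n$pieces, function(p) { walk(p$cond); walk(p$value) })
        if (!is.null(n$otherwise)) walk(n$otherwise)
      },
      NULL
    )
    invisible(NULL)
  }
  walk(e)
  found
}

#' Serialize a cell model back to CellML
#'
#' Writes the flattened model as a single-component CellML 1.0 document.
#' Parsing the output reproduces a structurally identical model.
#'
#' @param m A [cell_model()].
#' @return CellML text.
#' @export
serialize_cellml <- function(m) {
  stopifnot(inherits(m, "cell_model"))
  out <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    paste0("<model name=\"", xml_escape(m$name),
           "\" xmlns=\"http://www.cellml.org/cellml/1.0#\">"),
    "  <component name=\"main\">"
  )
  for (i in seq_len(nrow(m$variables))) {
    v <- m$variables[i, ]
    attrs <- paste0(" name=\"", xml_escape(v$name), "\"")
    if (!is.na(v$initial_value))
      attrs <- paste0(attrs, " initial_value=\"", xml_escape(v$initial_value), "\"")
    if (!is.na(v$units))
      attrs <- paste0(attrs, " units=\"", xml_escape(v$units), "\"")
    out <- c(out, paste0("    <variable", attrs, "/>"))
  }
  if (length(m$equations) > 0) {
    out <- c(out, "    <math xmlns=\"http://www.w3.org/1998/Math/MathML\">")
    for (eq in m$equations) {
      out <- c(out,
        "      <apply><eq/>",
        mathml_lines(eq$lhs, "        "),
        mathml_lines(eq$rhs, "        "),
        "      </apply>")
    }
    out <- c(out, "    </math>")
  }
  out <- c(out, "  </component>", "</model>", "")
  paste(out, collapse = "\n")
}
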
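# Variable-role maps (RelML) -------------------------------------------------

REL_ROLES <- c("diffvar", "derivativevar", "arithvar", "constvar", "timevar",
               "deltatimevar")

#' Construct a variable-role map
#'
#' A role map binds every cell-model variable to one scheme role: `diffvar`
#' (state variable), `derivativevar` (its time derivative, named
#' `d<var>/dt`), `arithvar` (removable temporal variable), `constvar`,
#' `timevar`.  The derivative pairing is implicit in the `d<var>/dt` naming.
#'
#' @param roles A data frame with columns `variable`, `role` (ordered).
#' @param model_ref,scheme_ref File references recorded in the RelML header
#'   (informational).
#' @return A `rel_map` object.
#' @export
rel_map <- function(roles, model_ref = NA_character_, scheme_ref = NA_character_) {
  roles <- tibble::as_tibble(roles)
  stopifnot(all(c("variable", "role") %in% names(roles)))
  bad <- setdiff(unique(roles$role), REL_ROLES)
  if (length(bad) > 0)
    tecgen_stop(paste0("unknown role token '", bad[[1]], "'"), "tecgen_map_error")
  structure(list(model_ref = model_ref, scheme_ref = scheme_ref, roles = roles),
            class = "rel_map")
}

#' @export
print.rel_map <- function(x, ...) {
  cat("<rel_map> model: ", x$model_ref, " | scheme: ", x$scheme_ref, "\n", sep = "")
  for (i in seq_len(nrow(x$roles)))
    cat("  ", format(x$roles$variable[[i]], width = 12), " ",
        x$roles$role[[i]], "\n", sep = "")
  invisible(x)
}

map_vars_with_role <- function(map, role) {
  map$roles$variable[map$roles$role == role]
}

# strip the derivative naming convention: "dx/dt" -> "x" (NA if not of form)
deriv_entry_var <- function(name) {
  m <- regmatches(name, regexec("^d(.+)/d[^/]+$", name))[[1]]
  if (length(m) == 2) m[[2]] else NA_character_
}

#' Parse a RelML role-map document
#'
#' Dialect: root `<relml>`; `<model href="..."/>` and `<scheme href="..."/>`
#' header elements; one `<var name="..." type="..."/>` entry per variable in
#' document order.  Parsing checks role tokens and duplicate entries only;
#' use [validate_mapping()] to check the map against a model and a scheme.
#'
#' @param document RelML text, a file path, or an `xml2` document.
#' @return A [rel_map()].
#' @export
parse_relml <- function(document) {
  doc <- read_xml_input(document)
  xml2::xml_ns_strip(doc)
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "relml")
    tecgen_stop("root element must be <relml>", "tecgen_parse_error")
  model_ref <- xml2::xml_attr(xml2::xml_find_first(root, "./model"), "href")
  scheme_ref <- xml2::xml_attr(xml2::xml_find_first(root, "./scheme"), "href")
  vars <- xml2::xml_find_all(root, "./var")
  nm <- vapply(vars, function(v) xml2::xml_attr(v, "name"), "")
  role <- vapply(vars, function(v) xml2::xml_attr(v, "type"), "")
  if (anyNA(nm) || anyNA(role))
    tecgen_stop("<var> entries need 'name' and 'type' attributes",
                "tecgen_map_error")
  bad <- setdiff(unique(role), REL_ROLES)
  if (length(bad) > 0)
    tecgen_stop(paste0("unknown role token '", bad[[1]], "'"), "tecgen_map_error")
  if (anyDuplicated(nm))
    tecgen_stop(paste0("duplicate variable entry '", nm[duplicated(nm)][[1]], "'"),
                "tecgen_map_error")
  rel_map(tibble::tibble(variable = nm, role = role), model_ref, scheme_ref)
}

#' Serialize a role map to RelML
#'
#' @param map A [rel_map()].
#' @return RelML text.
#' @export
serialize_relml <- function(map) {
  stopifnot(inherits(map, "rel_map"))
  hdr <- character(0)
  if (!is.na(map$model_ref))
    hdr <- c(hdr, paste0("  <model href=\"", xml_escape(map$model_ref), "\"/>"))
  if (!is.na(map$scheme_ref))
    hdr <- c(hdr, paste0("  <scheme href=\"", xml_escape(map$scheme_ref), "\"/>"))
  paste(c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    "<relml>",
    hdr,
    vapply(seq_len(nrow(map$roles)), function(i)
      paste0("  <var name=\"", xml_escape(map$roles$variable[[i]]),
             "\" type=\"", map$roles$role[[i]], "\"/>"), ""),
    "</relml>", ""
  ), collapse = "\n")
}

#' Infer variable roles from a cell model
#'
#' Derives the role map mechanically from equation shape: variables defined
#' by a derivative equation become `diffvar` (with a paired
#' `derivativevar`), variables defined by an algebraic equation `arithvar`,
#' the bound variable of the derivatives `timevar`, and everything else
#' `constvar`.
#'
#' @param m A validated [cell_model()].
#' @return A [rel_map()].
#' @export
infer_roles <- function(m) {
  stopifnot(inherits(m, "cell_model"))
  diff_lhs <- vapply(model_diff_eqs(m), function(e) e$lhs$var, "")
  arith_lhs <- vapply(model_arith_eqs(m), function(e) e$lhs$name,
                      FUN.VALUE = "")
  both <- intersect(diff_lhs, arith_lhs)
  if (length(both) > 0)
    tecgen_stop(paste0("variable '", both[[1]],
                       "' is defined by both a differential and an algebraic equation"),
                "tecgen_map_error")
  rows <- list()
  for (v in m$variables$name) {
    role <- if (v %in% diff_lhs) "diffvar"
      else if (v %in% arith_lhs) "arithvar"
      else if (!is.na(m$time_variable) && v == m$time_variable) "timevar"
      else "constvar"
    rows[[length(rows) + 1L]] <- list(variable = v, role = role)
    if (role == "diffvar")
      rows[[length(rows) + 1L]] <- list(
        variable = paste0("d", v, "/d", m$time_variable), role = "derivativevar")
  }
  rel_map(tibble::tibble(
    variable = vapply(rows, `[[`, "", "variable"),
    role = vapply(rows, `[[`, "", "role")
  ), model_ref = paste0(m$name, ".cellml"))
}

#' Validate a (model, scheme, role map) triple
#'
#' Empty diagnostics iff the correspondences the expansion relies on are well
#' defined: every model variable mapped exactly once; the `diffvar` and
#' `derivativevar` sets in bijection and matching the model's derivative
#' equations; `arithvar` entries matching the algebraic equations; exactly
#' one `timevar`, agreeing with the model's bound variable; and the scheme
#' able to serve the model (at least one state variable; an `arith-eval`
#' statement present when the model has temporal variables).
#'
#' @param map A [rel_map()].
#' @param m A [cell_model()].
#' @param s A [tec_scheme()].
#' @return Diagnostics tibble (see [validate_model()]).
#' @export
validate_mapping <- function(map, m, s) {
  stopifnot(inherits(map, "rel_map"), inherits(m, "cell_model"),
            inherits(s, "tec_scheme"))
  d <- diag_rows()
  declared <- m$variables$name
  entries <- map$roles$variable
  plain <- map$roles[map$roles$role != "derivativevar", , drop = FALSE]

  unknown <- setdiff(plain$variable, declared)
  for (v in unknown)
    diag_add(d, "error", "validate_mapping",
             paste0("map entry '", v, "' is not a model variable"))
  missing_v <- setdiff(declared, plain$variable)
  for (v in missing_v)
    diag_add(d, "error", "validate_mapping",
             paste0("model variable '", v, "' has no role entry"))
  if (anyDuplicated(entries))
    diag_add(d, "error", "validate_mapping",
             paste0("duplicate entry '", entries[duplicated(entries)][[1]], "'"))

  diffvars <- map_vars_with_role(map, "diffvar")
  derivs <- map_vars_with_role(map, "derivativevar")
  deriv_targets <- vapply(derivs, deriv_entry_var, "")
  for (i in seq_along(derivs)) {
    if (is.na(deriv_targets[[i]]))
      diag_add(d, "error", "validate_mapping",
               paste0("derivativevar entry '", derivs[[i]],
                      "' is not of the form d<var>/d<time>"))
  }
  for (v in setdiff(diffvars, deriv_targets))
    diag_add(d, "error", "validate_mapping",
             paste0("diffvar '", v, "' has no paired derivativevar entry"))
  for (v in setdiff(deriv_targets[!is.na(deriv_targets)], diffvars))
    diag_add(d, "error", "validate_mapping",
             paste0("derivativevar entry for '", v, "' but '", v,
                    "' is not marked diffvar"))

  # equation classes must match roles
  model_diff <- vapply(model_diff_eqs(m), function(e) e$lhs$var, "")
  model_arith <- vapply(model_arith_eqs(m), function(e) e$lhs$name, FUN.VALUE = "")
  for (v in setdiff(model_diff, diffvars))
    diag_add(d, "error", "validate_mapping",
             paste0("'", v, "' is defined by a differential equation but mapped as '",
                    role_of(map, v), "'"))
  for (v in setdiff(diffvars, model_diff))
    diag_add(d, "error", "validate_mapping",
             paste0("'", v, "' is mapped diffvar but the model has no d", v,
                    "/dt equation"))
  arithvars <- map_vars_with_role(map, "arithvar")
  for (v in setdiff(model_arith, arithvars))
    diag_add(d, "error", "validate_mapping",
             paste0("'", v, "' is defined by an algebraic equation but mapped as '",
                    role_of(map, v), "'"))
  for (v in setdiff(arithvars, model_arith))
    diag_add(d, "error", "validate_mapping",
             paste0("'", v, "' is mapped arithvar but has no defining equation"))

  timevars <- map_vars_with_role(map, "timevar")
  if (length(timevars) != 1) {
    diag_add(d, if (length(model_diff) > 0) "error" else "warning",
             "validate_mapping",
             paste0("expected exactly one timevar entry, found ", length(timevars)))
  } else if (!is.na(m$time_variable) && timevars != m$time_variable) {
    diag_add(d, "error", "validate_mapping",
             paste0("timevar is '", timevars, "' but the model derivatives use '",
                    m$time_variable, "'"))
  }
  for (v in intersect(map_vars_with_role(map, "constvar"),
                      c(model_diff, model_arith)))
    diag_add(d, "error", "validate_mapping",
             paste0("'", v, "' is mapped constvar but has a defining equation"))

  # scheme satisfiability
  if (length(diffvars) == 0)
    diag_add(d, "error", "validate_mapping",
             "no diffvar: the scheme's input binding cannot be satisfied")
  kinds <- vapply(s$statements, `[[`, "", "kind")
  if (length(arithvars) > 0 && !any(kinds == "arith"))
    diag_add(d, "error", "validate_mapping",
             "model has temporal variables but the scheme has no arith-eval statement")
  diag_result(d)
}

role_of <- function(map, v) {
  r <- map$roles$role[map$roles$variable == v]
  if (length(r) == 0) NA_character_ else r[[1]]
}

relmap_equal <- function(a, b) {
  identical(a$model_ref, b$model_ref) &&
    identical(a$scheme_ref, b$scheme_ref) &&
    identical(as.data.frame(a$roles), as.data.frame(b$roles))
}
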
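# Accuracy study: RMSE vs time step and empirical convergence order ----------

#' Empirical convergence order from (delta, RMSE) pairs
#'
#' Least-squares slope of \eqn{\log_{10}} RMSE against \eqn{\log_{10}\delta};
#' for a scheme of order p above the round-off floor the slope approaches p.
#'
#' @param entries A data frame with columns `delta` and `rmse` (at least two
#'   rows, all `rmse > 0`), or a numeric vector of deltas.
#' @param rmse RMSE values when `entries` is a vector.
#' @return The fitted slope (double).
#' @examples
#' estimate_order(c(0.1, 0.01), c(1e-2, 1e-4))
#' @export
estimate_order <- function(entries, rmse = NULL) {
  if (is.data.frame(entries)) {
    deltas <- entries$delta
    rmses <- entries$rmse
  } else {
    deltas <- entries
    rmses <- rmse
  }
  keep <- is.finite(deltas) & is.finite(rmses) & rmses > 0
  deltas <- deltas[keep]
  rmses <- rmses[keep]
  if (length(deltas) < 2)
    tecgen_stop("need at least two usable (delta, rmse) entries",
                "tecgen_run_error")
  fit <- stats::lsfit(log10(deltas), log10(rmses))
  unname(fit$coefficients[[2]])
}

#' Time-step accuracy study for a model
#'
#' Runs a high-accuracy reference simulation, then one candidate run per
#' (scheme, time step), computes the RMSE of each candidate against the
#' reference over the shared sample grid (all state variables, samples every
#' `sample_dt` time units), and fits each scheme's empirical convergence
#' order.  Candidate entries are excluded from the fit and flagged when they
#' diverge, or when their RMSE falls below the round-off floor of the
#' arithmetic context (`10^{1-digits}` times the root-mean-square magnitude
#' of the reference trajectory) -- the plateau a fixed-precision context
#' imposes on high-order schemes at small steps.
#'
#' @param m A [cell_model()].
#' @param map A [rel_map()]; defaults to [infer_roles()].
#' @param schemes Character vector of [builtin_scheme()] names and/or a list
#'   of `tec_scheme` objects.
#' @param deltas Candidate time steps.
#' @param ref `list(scheme = , delta = )` for the reference run;
#'   `ref$delta` must be below `min(deltas)`.
#' @param t_start,horizon Simulation window `t_start .. t_start + horizon`;
#'   `horizon` must be a whole multiple of `max(deltas)`.
#' @param precision Arithmetic context for every run (default 32 decimal
#'   digits; `"double"` is allowed but floors fourth-order schemes early).
#' @param sample_dt Sampling interval for the RMSE grid; defaults to
#'   `max(deltas)`.
#' @param init,consts Bindings; default from the model's declared initial
#'   values.
#' @return An `accuracy_report`: `entries` tibble `(scheme, delta, rmse,
#'   flag)`, `orders` tibble `(scheme, order, n_used)`, the reference spec
#'   and the floor value.  [tidy()] returns the entries, [glance()] a
#'   one-row summary, [autoplot()] the log-log error plot.
#' @export
convergence_study <- function(m, map = infer_roles(m),
                              schemes = c("euler", "modified_euler", "rk4"),
                              deltas = 10^-(1:4),
                              ref = list(scheme = "rk4", delta = 1e-5),
                              t_start = 0, horizon = 20,
                              precision = 32, sample_dt = NULL,
                              init = NULL, consts = NULL) {
  stopifnot(inherits(m, "cell_model"))
  if (is.null(init) || is.null(consts)) {
    b <- model_bindings(m, map)
    init <- init %||% b$init
    consts <- consts %||% b$consts
  }
  if (length(deltas) > 0 && ref$delta >= min(deltas))
    tecgen_stop("the reference time step must be below every candidate step",
                "tecgen_run_error")
  sample_dt <- sample_dt %||% max(deltas)
  digits <- parse_precision(precision)

  as_scheme <- function(x) if (inherits(x, "tec_scheme")) x else builtin_scheme(x)
  scheme_objs <- lapply(schemes, as_scheme)
  scheme_names <- vapply(scheme_objs, `[[`, "", "name")

  run1 <- function(scheme, delta) {
    p <- expand(m, scheme, map)
    interpret(p, init, consts, t_start = t_start, t_end = t_start + horizon,
              delta = delta, precision = precision,
              stride = as.integer(round(sample_dt / delta)))
  }
  ref_res <- run1(as_scheme(ref$scheme), ref$delta)
  if (!is.na(ref_res$divergent_step))
    tecgen_stop("reference run diverged", "tecgen_run_error")
  scale <- sqrt(mean(ref_res$values^2))
  # decimal-digit equivalent of the context; IEEE double carries DBL_DIG = 15
  eff_digits <- if (digits == 0) 15 else digits
  floor_rmse <- 10 * 10^(-eff_digits) * scale

  rows <- list()
  for (i in seq_along(scheme_objs)) {
    for (delta in deltas) {
      cand <- run1(scheme_objs[[i]], delta)
      if (!is.na(cand$divergent_step)) {
        rows[[length(rows) + 1L]] <- list(scheme = scheme_names[[i]],
                                          delta = delta, rmse = NA_real_,
                                          flag = "divergent")
        next
      }
      e <- rmse(cand, ref_res)
      flag <- if (e < floor_rmse) "floor" else "ok"
      rows[[length(rows) + 1L]] <- list(scheme = scheme_names[[i]],
                                        delta = delta, rmse = e, flag = flag)
    }
  }
  entries <- if (length(rows) == 0) {
    tibble::tibble(scheme = character(0), delta = double(0),
                   rmse = double(0), flag = character(0))
  } else {
    tibble::tibble(
      scheme = vapply(rows, `[[`, "", "scheme"),
      delta = vapply(rows, `[[`, 0, "delta"),
      rmse = vapply(rows, `[[`, 0, "rmse"),
      flag = vapply(rows, `[[`, "", "flag")
    )
  }
  orders <- lapply(unique(entries$scheme), function(sn) {
    ok <- entries[entries$scheme == sn & entries$flag == "ok", , drop = FALSE]
    ord <- if (nrow(ok) >= 2) estimate_order(ok) else NA_real_
    list(scheme = sn, order = ord, n_used = nrow(ok))
  })
  orders <- tibble::tibble(
    scheme = vapply(orders, `[[`, "", "scheme"),
    order = vapply(orders, `[[`, 0, "order"),
    n_used = vapply(orders, function(o) as.integer(o$n_used), 0L)
  )
  structure(list(
    entries = entries, orders = orders,
    ref = list(scheme = as_scheme(ref$scheme)$name, delta = ref$delta),
    precision = if (digits == 0) "double" else digits,
    horizon = horizon, sample_dt = sample_dt,
    scale = scale, floor = floor_rmse,
    model_name = m$name
  ), class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat("<accuracy_report> ", x$model_name, " | reference: ", x$ref$scheme,
      " @ delta = ", format(x$ref$delta), ", precision = ",
      if (identical(x$precision, "double")) "double"
      else paste0(x$precision, " decimal digits"), "\n", sep = "")
  print(x$entries)
  cat("fitted convergence orders:\n")
  print(x$orders)
  invisible(x)
}

#' @rdname convergence_study
#' @param x,object An `accuracy_report`.
#' @param ... Unused.
#' @export
tidy.accuracy_report <- function(x, ...) x$entries

#' @rdname convergence_study
#' @export
glance.accuracy_report <- function(x, ...) {
  tibble::tibble(
    model = x$model_name,
    ref_scheme = x$ref$scheme, ref_delta = x$ref$delta,
    precision = as.character(x$precision),
    horizon = x$horizon, floor = x$floor,
    n_entries = nrow(x$entries),
    n_floor = sum(x$entries$flag == "floor"),
    n_divergent = sum(x$entries$flag == "divergent")
  )
}

#' @rdname convergence_study
#' @export
autoplot.accuracy_report <- function(object, ...) {
  df <- object$entries[!is.na(object$entries$rmse), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta, y = .data$rmse,
                                   colour = .data$scheme,
                                   shape = .data$flag)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::geom_line(ggplot2::aes(group = .data$scheme)) +
    ggplot2::geom_hline(yintercept = object$floor, linetype = "dotted") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time step", y = "RMSE vs reference",
                  title = paste("Time step vs calculation error:",
                                object$model_name)) +
    ggplot2::theme_minimal()
}

#' Write an accuracy report to disk
#'
#' `write_accuracy_csv()` writes the entries table; `write_accuracy_json()`
#' writes a JSON summary with the per-scheme fitted orders and the study
#' configuration.
#'
#' @param report An `accuracy_report`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_accuracy_csv <- function(report, path) {
  stopifnot(inherits(report, "accuracy_report"))
  utils::write.csv(as.data.frame(report$entries), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_accuracy_csv
#' @export
write_accuracy_json <- function(report, path) {
  stopifnot(inherits(report, "accuracy_report"))
  orders <- stats::setNames(as.list(report$orders$order), report$orders$scheme)
  jsonlite::write_json(list(
    model = report$model_name,
    reference = report$ref,
    precision = report$precision,
    horizon = report$horizon,
    floor = report$floor,
    orders = orders
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
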
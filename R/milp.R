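#' Minimal MILP model container
#'
#' A mutable builder for mixed-integer linear programs in the standard
#' `row_lb <= A x <= row_ub` form, used by the inverse-inference encoder.
#' Variables are registered by name; constraints as sparse coefficient rows.
#'
#' @return an environment of class `milp_builder`.
#' @keywords internal
#' @export
milp_new <- function() {
  m <- new.env(parent = emptyenv())
  m$var_names <- character(0)
  m$lb <- numeric(0); m$ub <- numeric(0); m$type <- character(0)
  m$rows_i <- list(); m$rows_coef <- list()
  m$row_lb <- numeric(0); m$row_ub <- numeric(0); m$row_name <- character(0)
  m$index <- new.env(parent = emptyenv())
  class(m) <- "milp_builder"
  m
}

#' @rdname milp_new
#' @param m a `milp_builder`.
#' @param name unique variable name.
#' @param lb,ub bounds.
#' @param type "B" (binary), "I" (integer) or "C" (continuous).
#' @export
milp_var <- function(m, name, lb = 0, ub = 1, type = "B") {
  if (!is.null(m$index[[name]])) stop("duplicate variable: ", name)
  m$var_names <- c(m$var_names, name)
  m$lb <- c(m$lb, lb); m$ub <- c(m$ub, ub); m$type <- c(m$type, type)
  idx <- length(m$var_names)
  m$index[[name]] <- idx
  idx
}

#' @rdname milp_new
#' @param idx integer vector of variable indices (or character names).
#' @param coef numeric coefficients.
#' @export
milp_con <- function(m, idx, coef, lb = -Inf, ub = Inf, name = "") {
  if (is.character(idx)) idx <- vapply(idx, function(nm) m$index[[nm]], integer(1))
  keep <- coef != 0
  k <- length(m$row_lb) + 1L
  m$rows_i[[k]] <- as.integer(idx[keep])
  m$rows_coef[[k]] <- as.numeric(coef[keep])
  m$row_lb[k] <- lb; m$row_ub[k] <- ub; m$row_name[k] <- name
  invisible(k)
}

#' @rdname milp_new
#' @export
milp_var_id <- function(m, name) {
  v <- m$index[[name]]
  if (is.null(v)) stop("unknown variable: ", name)
  v
}

#' Linear expression helper: a named accumulation of coefficients
#' @noRd
expr_new <- function() list(idx = integer(0), coef = numeric(0))
#' @noRd
expr_add <- function(e, idx, coef) {
  list(idx = c(e$idx, as.integer(idx)), coef = c(e$coef, as.numeric(coef)))
}

#' Available linear-optimisation engines
#'
#' The solver layer runs engines external to R; `"highs"` calls the HiGHS
#' solver through the bundled python/scipy driver.
#'
#' @return character vector of engine names.
#' @export
milp_engines <- function() c("highs")

#' Solve an MILP
#'
#' Serialises the model to JSON, runs the engine driver, and reads back the
#' solution. Engine failure is reported as status `"error"`, never as
#' `"infeasible"`.
#'
#' @param m a `milp_builder`.
#' @param engine engine name (see [milp_engines()]).
#' @param time_limit seconds.
#' @param objective optional named numeric vector of objective coefficients
#'   (minimised); default feasibility (all zero).
#' @return list with `status` (`"feasible"`, `"infeasible"`, `"timeout"`,
#'   `"error"`), `x` (solution vector named by variable) and `raw_status`.
#' @export
milp_solve <- function(m, engine = "highs", time_limit = 300, objective = NULL) {
  engine <- match.arg(engine, milp_engines())
  nv <- length(m$var_names)
  obj <- numeric(nv)
  if (!is.null(objective)) {
    ii <- vapply(names(objective), function(nm) m$index[[nm]], integer(1))
    obj[ii] <- as.numeric(objective)
  }
  nr <- length(m$row_lb)
  ri <- rep.int(seq_len(nr), lengths(m$rows_i))
  payload <- list(
    n = nv,
    obj = obj,
    lb = m$lb, ub = m$ub,
    integrality = as.integer(m$type != "C"),
    a_row = ri - 1L,
    a_col = unlist(m$rows_i, use.names = FALSE) - 1L,
    a_val = unlist(m$rows_coef, use.names = FALSE),
    n_rows = nr,
    row_lb = m$row_lb, row_ub = m$row_ub,
    time_limit = time_limit
  )
  fin <- tempfile(fileext = ".json"); fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  jsonlite::write_json(payload, fin, digits = NA, auto_unbox = TRUE, null = "null")
  driver <- system.file("python", "milp_solve.py", package = "treeqsar")
  if (driver == "") driver <- file.path("inst", "python", "milp_solve.py")
  rc <- suppressWarnings(system2("python", c(driver, fin, fout),
                                 stdout = TRUE, stderr = TRUE))
  status_code <- attr(rc, "status")
  if (!file.exists(fout)) {
    return(list(status = "error", x = NULL,
                raw_status = paste(c(status_code, rc), collapse = " ")))
  }
  res <- jsonlite::fromJSON(fout)
  status <- switch(as.character(res$status),
                   "0" = "feasible", "1" = "timeout", "2" = "infeasible",
                   "3" = "error", "4" = "error", "error")
  x <- NULL
  if (!is.null(res$x) && length(res$x) == nv) x <- stats::setNames(as.numeric(res$x), m$var_names)
  if (status == "timeout" && !is.null(x) && isTRUE(res$feasible_incumbent)) status <- "feasible"
  list(status = status, x = x, raw_status = res$message)
}
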
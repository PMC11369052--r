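#' Specify an n-type birth-death-mutation process
#'
#' Defines a population of cells of `n` consecutive types.  A type-`i` cell
#' divides at rate `birth[i]`, dies at rate `death[i]`, and mutates into a
#' type-`i+1` cell at rate `mutation[i]`.  Mutations accumulate along the
#' chain `1 -> 2 -> ... -> n`; the last type cannot mutate
#' (`mutation[n]` must be 0).  The process is *critical* when every type's
#' appearance rate balances its disappearance rate, i.e.
#' `birth[i] == death[i] + mutation[i]` for every type; then extinction is
#' certain even though the mean population size keeps growing.
#'
#' With `birth = 1`, one time unit corresponds to one generation (one cell
#' division per cell on average); this interpretation is documented, not
#' enforced.
#'
#' @param birth,death,mutation numeric vectors of length `n`, non-negative
#'   per-capita rates.
#' @param initial integer vector of length `n`, the initial number of cells
#'   of each type.  Defaults to a single type-1 cell.
#' @return An object of class `bdm_process`: a list with elements `n`,
#'   `birth`, `death`, `mutation`, `initial` and the logical flag
#'   `is_critical`.
#' @seealso [simple_bdm()] for the unit-rate birth-mutation special case,
#'   [validate_bdm()] for non-throwing diagnostics.
#' @examples
#' spec <- bdm_process(birth = c(1, 1), death = c(0, 1), mutation = c(1, 0))
#' spec$is_critical
#' @export
bdm_process <- function(birth, death, mutation,
                        initial = c(1, rep(0, length(birth) - 1L))) {
  spec <- structure(
    list(n = length(birth), birth = as.numeric(birth),
         death = as.numeric(death), mutation = as.numeric(mutation),
         initial = as.numeric(initial)),
    class = "bdm_process")
  findings <- validate_bdm(spec)
  bad <- findings[vapply(findings, function(f) f$severity == "error", logical(1))]
  if (length(bad) > 0)
    stop("invalid process specification: ",
         paste(vapply(bad, `[[`, character(1), "message"), collapse = "; "),
         call. = FALSE)
  spec$is_critical <- is_critical_rates(spec)
  spec
}

#' The simple n-type critical birth-mutation process
#'
#' The unit-rate scheme: each type-`i` cell (`i < n`) divides or mutates at
#' rate one, and type-`n` cells divide or die at rate one.  All types are
#' critical, so the population eventually dies out with probability one,
#' after a transient of near-exponential growth.
#'
#' @param n integer, number of types (`n >= 1`).
#' @return A critical [bdm_process()] started from a single type-1 cell.
#' @examples
#' simple_bdm(3)
#' @export
simple_bdm <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop("`n` must be a single integer >= 1", call. = FALSE)
  n <- as.integer(n)
  bdm_process(birth = rep(1, n),
              death = c(rep(0, n - 1L), 1),
              mutation = c(rep(1, n - 1L), 0))
}

is_critical_rates <- function(spec, tol = 1e-12) {
  with(spec, all(abs(birth - (death + mutation)) < tol))
}

#' Diagnose a process specification without throwing
#'
#' Returns a list of findings rather than raising conditions, so malformed
#' or non-critical rate sets can be inspected.  Each finding has fields
#' `severity` (`"error"` or `"warning"`) and `message`.  Non-criticality is
#' a warning, not an error: the simulator runs any non-negative rates, but
#' the closed-form and asymptotic results in this package assume critical
#' rates.
#'
#' @param x a [bdm_process()] or a bare list with elements `birth`, `death`,
#'   `mutation` and optionally `initial`.
#' @return A list of findings; empty when nothing is wrong.
#' @examples
#' validate_bdm(list(birth = c(1, 1), death = c(0, 0), mutation = c(1, 1)))
#' @export
validate_bdm <- function(x) {
  findings <- list()
  note <- function(severity, message)
    findings[[length(findings) + 1L]] <<- list(severity = severity, message = message)
  n <- length(x$birth)
  if (n < 1L) note("error", "at least one type is required")
  if (length(x$death) != n || length(x$mutation) != n)
    note("error", "rate vectors have mismatched lengths")
  if (!is.null(x$initial)) {
    if (length(x$initial) != n)
      note("error", "initial composition length differs from the rate vectors")
    else if (any(x$initial < 0) || any(x$initial != round(x$initial)))
      note("error", "initial counts must be non-negative integers")
  }
  rates <- c(x$birth, x$death, x$mutation)
  if (any(!is.finite(rates)) || any(rates < 0))
    note("error", "rates must be finite and non-negative")
  if (length(findings) > 0) return(findings)
  if (x$mutation[n] != 0)
    note("error", "last type mutates: mutation rate of type n must be 0")
  crit <- abs(x$birth - (x$death + x$mutation)) < 1e-12
  for (i in which(!crit))
    note("warning", sprintf("type %d not critical (birth %g != death %g + mutation %g)",
                            i, x$birth[i], x$death[i], x$mutation[i]))
  findings
}

#' Drop the first type from a process
#'
#' For the consecutive-mutation chain the sub-process started at type 2 is
#' a shifted copy of the whole process (the decomposability, or index-shift,
#' property).  Dropping type 1 from the simple `(n+1)`-type process yields
#' exactly the simple `n`-type process.
#'
#' @param spec a [bdm_process()] with `n >= 2`.
#' @return A `bdm_process` over types `2..n`, relabelled `1..n-1`, started
#'   from a single cell of the (new) first type.
#' @export
drop_first_type <- function(spec) {
  stopifnot(inherits(spec, "bdm_process"), spec$n >= 2)
  bdm_process(birth = spec$birth[-1], death = spec$death[-1],
              mutation = spec$mutation[-1])
}

#' @export
print.bdm_process <- function(x, ...) {
  cat(sprintf("%d-type birth-death-mutation process (%s)\n", x$n,
              if (x$is_critical) "critical" else "NOT critical"))
  m <- rbind(birth = x$birth, death = x$death, mutation = x$mutation,
             initial = x$initial)
  colnames(m) <- paste0("type", seq_len(x$n))
  print(m)
  invisible(x)
}

#' @export
summary.bdm_process <- function(object, ...) {
  print(object)
  f <- validate_bdm(object)
  if (length(f) > 0)
    for (fi in f) cat(sprintf("[%s] %s\n", fi$severity, fi$message))
  invisible(object)
}

#' Read or write a process configuration file
#'
#' The configuration schema is a flat mapping with keys `n`, `birth`,
#' `death`, `mutation`, `initial` and optional run settings `t_max`, `reps`,
#' `seed`.  The format is chosen from the file extension: `.json` uses
#' JSON, `.yaml`/`.yml` uses YAML.
#'
#' @param path file path ending in `.json`, `.yaml` or `.yml`.
#' @return `read_bdm_config()` returns a list with elements `spec` (a
#'   [bdm_process()]) and any run settings present; `write_bdm_config()`
#'   returns `path` invisibly.
#' @examples
#' p <- file.path(tempdir(), "spec.json")
#' write_bdm_config(simple_bdm(2), p, t_max = 10, reps = 100, seed = 1)
#' read_bdm_config(p)$spec
#' @export
read_bdm_config <- function(path) {
  cfg <- switch(tolower(tools::file_ext(path)),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = ,
    yml  = yaml::read_yaml(path),
    stop("unsupported config format: ", path, call. = FALSE))
  spec <- bdm_process(birth = cfg$birth, death = cfg$death,
                      mutation = cfg$mutation,
                      initial = if (is.null(cfg$initial))
                        c(1, rep(0, length(cfg$birth) - 1L)) else cfg$initial)
  out <- list(spec = spec)
  for (k in c("t_max", "reps", "seed"))
    if (!is.null(cfg[[k]])) out[[k]] <- cfg[[k]]
  out
}

#' @rdname read_bdm_config
#' @param spec a [bdm_process()].
#' @param t_max,reps,seed optional run settings stored alongside the rates.
#' @export
write_bdm_config <- function(spec, path, t_max = NULL, reps = NULL, seed = NULL) {
  stopifnot(inherits(spec, "bdm_process"))
  cfg <- list(n = spec$n, birth = spec$birth, death = spec$death,
              mutation = spec$mutation, initial = spec$initial)
  if (!is.null(t_max)) cfg$t_max <- t_max
  if (!is.null(reps)) cfg$reps <- reps
  if (!is.null(seed)) cfg$seed <- seed
  switch(tolower(tools::file_ext(path)),
    json = jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA),
    yaml = ,
    yml  = yaml::write_yaml(cfg, path),
    stop("unsupported config format: ", path, call. = FALSE))
  invisible(path)
}

#' Time grids
#'
#' Convenience constructor for the evaluation grids used by the simulator
#' and the ODE solvers.  Logarithmic spacing always includes `t = 0` as the
#' first point (solutions start from their initial condition there).
#'
#' @param t_max largest time.
#' @param length.out number of points.
#' @param spacing `"linear"` or `"log"`.
#' @param t_min first positive point of a logarithmic grid.
#' @return Strictly increasing numeric vector starting at 0.
#' @export
time_grid <- function(t_max, length.out = 101L, spacing = c("linear", "log"),
                      t_min = min(1e-2, t_max / 1e4)) {
  spacing <- match.arg(spacing)
  stopifnot(t_max > 0, length.out >= 2)
  if (spacing == "linear") seq(0, t_max, length.out = length.out)
  else c(0, exp(seq(log(t_min), log(t_max), length.out = length.out - 1L)))
}
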
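#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Gas constant in kJ mol-1 K-1
#' @noRd
.RGAS <- 8.31446261815324e-3

#' RT in kJ/mol at temperature T (K)
#' @noRd
rt_kj <- function(T) .RGAS * T

stopf <- function(fmt, ..., class = "invivomca_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Derive a stage seed from a top-level seed
#'
#' Deterministic derivation so that pipeline stages can be rerun in isolation
#' with the same stream. Kept below 2^31 - 1 so the result is a valid R
#' integer seed.
#'
#' @param seed integer top-level seed
#' @param stage integer stage index (>= 1)
#' @return an integer seed
#' @export
derive_seed <- function(seed, stage) {
  s <- (as.double(seed) * 48271 + as.double(stage) * 16807) %% 2147483629
  as.integer(s)
}

#' Locate the Python interpreter used by the solver backend
#'
#' Honours `options(invivomca.python = ...)` and the `INVIVOMCA_PYTHON`
#' environment variable before falling back to `python` / `python3` on the
#' PATH.
#' @return path to a python executable
#' @export
find_python <- function() {
  cand <- getOption("invivomca.python", Sys.getenv("INVIVOMCA_PYTHON", ""))
  if (nzchar(cand)) return(cand)
  for (p in c("python", "python3")) {
    hit <- Sys.which(p)
    if (nzchar(hit)) return(unname(hit))
  }
  stopf("no python interpreter found on PATH (needed for the LP/MILP backend)")
}
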
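# Interface to the bundled HiGHS (scipy) LP/MILP backend.
#
# A problem is a list:
#   n            number of variables
#   lb, ub       variable bounds (use +-Inf freely)
#   integrality  0/1 vector (1 = integer variable)
#   con          list(i, j, x, m, cl, cu): sparse triplets (1-based here,
#                converted to 0-based on serialization) and row bounds
# Objectives are sparse: list(idx =, val =, sense = "min"|"max").

milp_problem <- function(n, lb, ub, integrality = rep(0L, n)) {
  stopifnot(length(lb) == n, length(ub) == n, length(integrality) == n)
  list(n = n, lb = lb, ub = ub, integrality = as.integer(integrality),
       con = list(i = integer(0), j = integer(0), x = numeric(0),
                  m = 0L, cl = numeric(0), cu = numeric(0)),
       objectives = list())
}

#' Append one linear constraint row: cl <= sum(x[idx] * coef) <= cu
#' @noRd
milp_add_row <- function(prob, idx, coef, cl, cu) {
  keep <- coef != 0
  idx <- idx[keep]; coef <- coef[keep]
  r <- prob$con$m + 1L
  prob$con$i <- c(prob$con$i, rep(r, length(idx)))
  prob$con$j <- c(prob$con$j, idx)
  prob$con$x <- c(prob$con$x, coef)
  prob$con$m <- r
  prob$con$cl <- c(prob$con$cl, cl)
  prob$con$cu <- c(prob$con$cu, cu)
  prob
}

milp_add_objective <- function(prob, idx, val, sense = "min") {
  keep <- val != 0
  prob$objectives <- c(prob$objectives,
                       list(list(idx = idx[keep], val = val[keep], sense = sense)))
  prob
}

backend_script <- function() {
  p <- system.file("python", "milp_backend.py", package = "invivomca")
  if (!nzchar(p)) stopf("milp_backend.py not found in installed package")
  p
}

.inf_clip <- function(v) {
  v[v == Inf] <- 1e30
  v[v == -Inf] <- -1e30
  v
}

#' Solve a batch of LP/MILP problems through the HiGHS backend
#'
#' @param problems list of problems built with `milp_problem()` /
#'   `milp_add_row()` / `milp_add_objective()`
#' @param options list, e.g. `list(mip_rel_gap = 1e-9, time_limit = 60)`
#' @return list (per problem) of lists (per objective) with elements
#'   `status`, `objective`, `x`
#' @noRd
milp_solve_batch <- function(problems, options = list(mip_rel_gap = 1e-9)) {
  payload <- list(
    problems = lapply(unname(problems), function(p) {
      list(n = p$n,
           lb = .inf_clip(p$lb), ub = .inf_clip(p$ub),
           integrality = p$integrality,
           con = list(i = p$con$i - 1L, j = p$con$j - 1L, x = p$con$x,
                      m = p$con$m,
                      cl = .inf_clip(p$con$cl), cu = .inf_clip(p$con$cu)),
           objectives = lapply(p$objectives, function(o)
             list(idx = o$idx - 1L, val = o$val, sense = o$sense)))
    }),
    options = options)
  fin <- tempfile(fileext = ".json"); fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  jsonlite::write_json(payload, fin, auto_unbox = TRUE, digits = NA,
                       null = "null")
  status <- system2(find_python(), c(backend_script(), fin, fout),
                    stdout = TRUE, stderr = TRUE)
  code <- attr(status, "status") %||% 0L
  if (code != 0 || !file.exists(fout)) {
    stopf("LP/MILP backend failed (exit %s): %s", code,
          paste(status, collapse = "\n"))
  }
  res <- jsonlite::read_json(fout, simplifyVector = FALSE)
  lapply(res$results, function(pr) lapply(pr, function(r) {
    list(status = r$status,
         objective = if (!is.null(r$objective)) as.numeric(r$objective) else NA_real_,
         x = if (!is.null(r$x)) as.numeric(unlist(r$x)) else NULL)
  }))
}

milp_solve <- function(problem, options = list(mip_rel_gap = 1e-9)) {
  milp_solve_batch(list(problem), options)[[1]]
}
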
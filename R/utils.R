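# internal validation helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_vagcst <- function(..., call. = FALSE) {
  stop(..., call. = call.)
}

#' @keywords internal
#' @noRd
check_composition <- function(ra, tol = 1e-6, what = "composition") {
  if (length(ra) == 0L) {
    stop_vagcst("empty ", what, ": at least one taxon is required")
  }
  if (is.null(names(ra)) || any(!nzchar(names(ra)))) {
    stop_vagcst(what, " must be a named numeric vector of relative abundances")
  }
  if (any(!is.finite(ra)) || any(ra < 0)) {
    stop_vagcst(what, " contains negative or non-finite relative abundances")
  }
  s <- sum(ra)
  if (abs(s - 1) > tol) {
    stop_vagcst(what, " is not normalized: values sum to ", format(s),
                " (expected 1 within ", format(tol), ")")
  }
  invisible(ra)
}

# deterministic seed handling: every stochastic entry point takes a `seed`
# argument and scopes it so the caller's RNG state is untouched
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
              add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  expr
}
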
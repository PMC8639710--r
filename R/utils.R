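#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif sd var cor pt pchisq pf qr.coef
#'   integrate aggregate quantile rgamma model.matrix lm.fit acf
#' @importFrom utils read.csv write.csv
NULL

#' Derive a stream seed from a master seed
#'
#' Every stochastic stage of the pipeline gets its own RNG stream whose
#' seed is derived deterministically from one master seed and a stream
#' index; the result stays strictly below the 32-bit integer limit so it
#' is always a valid `set.seed()` argument.
#'
#' @param master_seed integer master seed.
#' @param index integer stream index.
#' @return a single integer seed.
#' @export
derive_seed <- function(master_seed, index) {
  stopifnot(is.numeric(master_seed), is.numeric(index))
  as.integer((as.numeric(master_seed) * 48271 + index * 9973) %% 2147483587L)
}

# Run an expression with a locally-seeded RNG, restoring the caller's state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

stop_if_not_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite scalar number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  invisible(x)
}

check_same_grid <- function(a, b, what = "volumes") {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("grid mismatch between %s: %s vs %s", what,
                 paste(dim(a), collapse = "x"),
                 paste(dim(b), collapse = "x")), call. = FALSE)
  invisible(TRUE)
}
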
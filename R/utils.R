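# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Signal a classed dgmr error
#'
#' All user-facing failures carry a subclass (schema, validation, format,
#' usage, parameter, coverage, vocabulary, degenerate) under the common
#' `dgmr_error` class so callers can condition on failure kind.
#' @noRd
dgmr_abort <- function(message, class) {
  stop(errorCondition(message,
                      class = c(class, "dgmr_error", "error", "condition")))
}

#' Evaluate code under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so seeded generators do not
#' perturb an enclosing simulation.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    dgmr_abort("`seed` must be a single finite number", "dgmr_parameter_error")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic per-unit child seed, kept well below 2^31.
child_seed <- function(seed, i) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(i)
}

# Numerically stable log(sum(exp(x))).
logsumexp <- function(x) {
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Complement map for strand flips; indels never reach this point.
ALLELES <- c("A", "C", "G", "T")
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

is_palindromic <- function(a1, a2) {
  unname(COMPLEMENT[a1] == a2)
}

stopifnot_scalar_prob <- function(x, name, open_left = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (open_left) x > 0 else x >= 0) && x <= 1
  if (!ok) {
    dgmr_abort(sprintf("`%s` must be a single value in %s", name,
                       if (open_left) "(0, 1]" else "[0, 1]"),
               "dgmr_parameter_error")
  }
  invisible(x)
}
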
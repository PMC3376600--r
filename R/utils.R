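# Internal helpers shared across modules.

# Canonical class order used for pairwise models, confusion matrices and
# reports.
.BEHAVIOURS <- c("flushing", "landing", "foraging")

#' Behaviour labels recognised by the package
#'
#' The closed label set, in the canonical order used by confusion matrices
#' and the pairwise model keys: flushing, landing, foraging.
#'
#' @return character vector of length 3.
#' @export
behaviourLevels <- function() .BEHAVIOURS

.checkBehaviour <- function(label) {
  bad <- setdiff(unique(as.character(label)), .BEHAVIOURS)
  if (length(bad))
    stop("unknown behaviour label(s): ", paste(bad, collapse = ", "),
         " (expected one of ", paste(.BEHAVIOURS, collapse = ", "), ")")
  invisible(TRUE)
}

# Evaluate expr under a private RNG stream seeded with `seed`, restoring
# the caller's RNG state afterwards. All stochastic code in the package
# goes through this, so nothing depends on (or disturbs) global RNG state.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  expr
}

# Derive a reproducible child seed < 2^31 from a parent seed and a stream
# index (splits one user seed into independent-enough streams).
deriveSeed <- function(seed, stream) {
  (as.double(seed) * 48271 + 7919 * as.double(stream)) %% 2147483629 + 1
}

.assertScalarNumeric <- function(x, name, positive = TRUE) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x))
    stop(name, " must be a single finite number")
  if (positive && x <= 0) stop(name, " must be positive")
  invisible(TRUE)
}
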
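# Optimal feature-subset selection: branch and bound under a monotonic
# between-class squared-distance criterion.

# Observation matrix (rows = frames, cols = coefficients) and labels from
# either a GfccFeatureSet or a plain matrix + label vector.
.obsMatrix <- function(x, labels = NULL) {
  if (is(x, "GfccFeatureSet")) {
    list(x = t(cepstra(x)), labels = as.character(behaviour(x)))
  } else {
    if (is.null(labels)) stop("labels required for a plain matrix input")
    stopifnot(nrow(x) == length(labels))
    list(x = as.matrix(x), labels = as.character(labels))
  }
}

# Per-feature criterion contributions v_f = sum over unordered class
# pairs (i, j) of N_i * N_j * (mu_if - mu_jf)^2. The full criterion of a
# subset S is sum_{f in S} v_f (additive over dimensions, hence monotone
# under subset inclusion).
.featureContributions <- function(x, labels) {
  cls <- sort(unique(labels))
  if (length(cls) < 2L)
    stop("the separability criterion needs at least 2 classes")
  n <- vapply(cls, function(cc) sum(labels == cc), 0)
  mu <- vapply(cls, function(cc)
    colMeans(x[labels == cc, , drop = FALSE]), numeric(ncol(x)))
  mu <- matrix(mu, ncol = length(cls))     # features x classes
  v <- numeric(ncol(x))
  for (i in seq_along(cls)[-length(cls)]) {
    for (j in (i + 1L):length(cls)) {
      v <- v + n[i] * n[j] * (mu[, i] - mu[, j])^2
    }
  }
  v
}

#' Per-feature class-separability contributions
#'
#' The separability criterion is additive over feature dimensions; this
#' returns each coefficient's contribution (the class-pair-weighted
#' squared distance between class means along that coefficient), indexed
#' 0-based like the cepstral coefficients.
#'
#' @param x a [GfccFeatureSet-class], or a matrix with one observation
#'   per row.
#' @param labels class labels (taken from the feature set if omitted).
#' @return named numeric vector (`"0"`, `"1"`, ...) of contributions.
#' @seealso [separabilityCriterion()]
#' @export
separabilityContributions <- function(x, labels = NULL) {
  d <- .obsMatrix(x, labels)
  v <- .featureContributions(d$x, d$labels)
  names(v) <- as.character(seq_along(v) - 1L)
  v
}

#' Between-class separability of a coefficient subset
#'
#' Evaluates \eqn{\sum_{i<j} N_i N_j \lVert \mu_i - \mu_j \rVert^2}
#' restricted to the given coefficient subset, where \eqn{\mu_c} is the
#' class mean and \eqn{N_c} the class count. Non-negative and additive
#' over dimensions, so it is monotone under subset inclusion — the
#' property branch and bound requires for exact pruning.
#'
#' @inheritParams separabilityContributions
#' @param subset 0-based coefficient indices (into c0 ... c20).
#' @return a single non-negative number.
#' @examples
#' x <- matrix(c(0, 0, 0, 2, 2, 2), ncol = 1)
#' separabilityCriterion(x, rep(c("a", "b"), each = 3), 0)  # 3*3*2^2 = 36
#' @export
separabilityCriterion <- function(x, labels = NULL, subset) {
  d <- .obsMatrix(x, labels)
  subset <- as.integer(subset)
  if (!length(subset)) stop("subset must be non-empty")
  if (anyDuplicated(subset)) stop("subset indices must be unique")
  if (any(subset < 0L) || any(subset >= ncol(d$x)))
    stop("subset indices out of range [0, ", ncol(d$x) - 1L, "]")
  v <- .featureContributions(d$x, d$labels)
  sum(v[sort(subset) + 1L])
}

# Lexicographic comparison of sorted index vectors: TRUE if a < b.
.lexLess <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  FALSE
}

.selectionResult <- function(idx0, value, d) {
  new("SelectionResult", selectedIndices = as.integer(sort(idx0)),
      criterionValue = value, dTarget = as.integer(d))
}

#' Branch-and-bound selection of the best coefficient subset
#'
#' Finds the subset of `dTarget` coefficients maximising the separability
#' criterion, exactly. The search runs depth-first over the feature-
#' removal tree (from the full set down to `dTarget` features) and prunes
#' a branch when the criterion of its remaining set already falls below
#' the best complete subset found — valid because the criterion is
#' monotone under subset inclusion. Ties are broken toward the
#' lexicographically smallest index set.
#'
#' @inheritParams separabilityContributions
#' @param dTarget subset size (default 6).
#' @param criterion optional function taking a 0-based index vector and
#'   returning a monotone criterion value; defaults to
#'   [separabilityCriterion()] on `x`.
#' @return A [SelectionResult-class].
#' @seealso [exhaustiveSelect()] for the enumeration oracle.
#' @export
branchAndBoundSelect <- function(x, labels = NULL, dTarget = 6L,
                                 criterion = NULL) {
  d <- .obsMatrix(x, labels)
  D <- ncol(d$x)
  dTarget <- as.integer(dTarget)
  if (dTarget < 1L) stop("dTarget must be at least 1")
  if (dTarget > D)
    stop("dTarget (", dTarget, ") exceeds the feature dimension (", D, ")")
  if (is.null(criterion)) {
    v <- .featureContributions(d$x, d$labels)
    criterion <- function(idx0) sum(v[sort(idx0) + 1L])
  }

  full <- 0:(D - 1L)
  if (dTarget == D)
    return(.selectionResult(full, criterion(full), dTarget))

  # Depth-first over removal sets r1 < r2 < ... (0-based feature indices);
  # the criterion of the current kept set upper-bounds every descendant.
  nRemove <- D - dTarget
  best <- list(value = -Inf, idx = NULL)
  dfs <- function(kept, startRm, removedCount) {
    val <- criterion(kept)
    if (val < best$value) return(invisible())
    if (removedCount == nRemove) {
      if (val > best$value ||
          (val == best$value && .lexLess(kept, best$idx)))
        best <<- list(value = val, idx = kept)
      return(invisible())
    }
    maxRm <- D - 1L - (nRemove - removedCount - 1L)
    for (rm in startRm:maxRm) {
      dfs(kept[kept != rm], rm + 1L, removedCount + 1L)
    }
    invisible()
  }
  dfs(full, 0L, 0L)
  .selectionResult(best$idx, best$value, dTarget)
}

#' Exhaustive-enumeration feature selection (oracle)
#'
#' Enumerates every subset of size `dTarget` and returns the criterion
#' optimum with the same tie-break as [branchAndBoundSelect()]. Intended
#' as an independent correctness oracle; refuses instances with more than
#' 1e6 candidate subsets.
#'
#' @inheritParams branchAndBoundSelect
#' @return A [SelectionResult-class].
#' @export
exhaustiveSelect <- function(x, labels = NULL, dTarget = 6L,
                             criterion = NULL) {
  d <- .obsMatrix(x, labels)
  D <- ncol(d$x)
  dTarget <- as.integer(dTarget)
  if (dTarget < 1L) stop("dTarget must be at least 1")
  if (dTarget > D)
    stop("dTarget (", dTarget, ") exceeds the feature dimension (", D, ")")
  if (choose(D, dTarget) > 1e6)
    stop("refusing to enumerate ", choose(D, dTarget), " subsets (> 1e6)")
  if (is.null(criterion)) {
    v <- .featureContributions(d$x, d$labels)
    criterion <- function(idx0) sum(v[sort(idx0) + 1L])
  }
  combos <- combn(0:(D - 1L), dTarget)
  best <- list(value = -Inf, idx = NULL)
  for (i in seq_len(ncol(combos))) {
    idx <- combos[, i]
    val <- criterion(idx)
    if (val > best$value ||
        (val == best$value && .lexLess(idx, best$idx)))
      best <- list(value = val, idx = idx)
  }
  .selectionResult(best$idx, best$value, dTarget)
}
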
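# Equal-frequency likelihood levels and exact discrete costs.

# Continued-fraction rational approximation of a positive number.
# Level costs must be exact so that path-cost ties (which define the set
# of optimal explanations) are decidable; fractional ratios such as 1.5
# or 1.2 are therefore carried as small rationals.
.rationalize <- function(x, maxDen = 1e6, tol = 1e-9) {
  stopifnot(is.numeric(x), length(x) == 1L, is.finite(x), x > 0)
  if (abs(x - round(x)) < tol)
    return(c(num = round(x), den = 1))
  h1 <- 1; h0 <- 0; k1 <- 0; k0 <- 1; b <- x
  repeat {
    a <- floor(b)
    h2 <- a * h1 + h0; k2 <- a * k1 + k0
    if (k2 > maxDen) break
    h0 <- h1; h1 <- h2; k0 <- k1; k1 <- k2
    if (abs(h1 / k1 - x) < tol * max(1, x)) break
    frac <- b - a
    if (frac < 1e-15) break
    b <- 1 / frac
  }
  c(num = h1, den = k1)
}

#' Create a discrete cost scheme
#'
#' Defines `k` likelihood levels with level cost `r^i` for level
#' `i in 0 .. k-1`.  Level 0 holds the most likely arcs (smallest
#' p-values, plus all experimentally validated arcs); `r` is the
#' incremental cost between consecutive levels, i.e. one arc of level `i`
#' costs as much as `r` arcs of level `i - 1`.
#'
#' @param k number of likelihood levels (default 9).
#' @param r incremental cost between consecutive levels (default 10).
#'   Fractional values are represented internally as exact rationals so
#'   that path-cost comparisons are never tolerance-based.
#' @return A [CostScheme-class] object.
#' @examples
#' costScheme(k = 3, r = 3)   # level costs 1, 3, 9
#' @export
costScheme <- function(k = 9, r = 10) {
  k <- as.integer(k)
  if (!is.numeric(r) || length(r) != 1L || is.na(r) || r <= 0)
    stop("r must be a single positive number")
  rat <- .rationalize(r)
  sc <- new("CostScheme", k = k, r = as.numeric(r),
            rNum = unname(rat["num"]), rDen = unname(rat["den"]),
            boundaries = numeric(0))
  validObject(sc)
  if (max(.levelCostInt(sc, 0:(k - 1L))) > 2^48)
    warning("scaled integer level costs exceed 2^48; ",
            "path-cost sums may lose exactness for very long paths")
  sc
}

# exact scaled-integer cost of a level: rNum^i * rDen^(k-1-i)
.levelCostInt <- function(scheme, level) {
  scheme@rNum^level * scheme@rDen^(scheme@k - 1L - level)
}

# factor converting scaled-integer costs back to cost units
.costScale <- function(scheme) scheme@rDen^(scheme@k - 1L)

#' Level costs of a scheme
#'
#' @param scheme a [CostScheme-class].
#' @return Numeric vector of the `k` level costs `r^0, ..., r^(k-1)`.
#' @export
levelCosts <- function(scheme) {
  stopifnot(is(scheme, "CostScheme"))
  .levelCostInt(scheme, 0:(scheme@k - 1L)) / .costScale(scheme)
}

#' Cost of an arc at a given likelihood level
#'
#' The cost of an arc in level `i` is `r^i`, evaluated through the exact
#' rational representation of `r`.
#'
#' @param level likelihood level(s), non-negative integer(s).
#' @param r incremental cost between consecutive levels (> 0).
#' @return Numeric vector `r^level`.
#' @examples
#' arcCost(2, r = 3)    # 9
#' arcCost(0, r = 17)   # 1
#' arcCost(8, r = 10)   # 1e8
#' @export
arcCost <- function(level, r) {
  if (any(level < 0) || any(level != floor(level)))
    stop("level must be a non-negative integer")
  stopifnot(length(r) == 1L, r > 0)
  rat <- .rationalize(r)
  unname(rat["num"])^level / unname(rat["den"])^level
}

#' Assign likelihood levels by equal-frequency binning of p-values
#'
#' Sorts affinity p-values in increasing order and splits them into `k`
#' bins of (near-)equal size: level 0 receives the smallest p-values.
#' When the number of arcs is not divisible by `k`, the first
#' `n %% k` bins receive one extra arc.  Arcs with identical p-values are
#' never split across levels: all members of a tied value are pulled into
#' the lowest (most likely) level any of them would receive, because arcs
#' with similar p-values are treated as equally likely.
#'
#' @param p numeric vector of affinity p-values in (0, 1].
#' @param k number of levels.
#' @return A list with `level` (integer vector, same order as `p`) and
#'   `boundaries` (largest p-value observed in each of levels
#'   `0 .. k-2`; `NA` for levels left empty).
#' @examples
#' assignLevels(c(1e-9, 1e-7, 1e-5, 1e-3), k = 2)$level   # 0 0 1 1
#' @export
assignLevels <- function(p, k) {
  k <- as.integer(k)
  stopifnot(k >= 1L)
  n <- length(p)
  if (n == 0L)
    return(list(level = integer(0), boundaries = rep(NA_real_, max(k - 1L, 0L))))
  if (any(is.na(p) | p <= 0 | p > 1))
    stop("p-values must lie in (0, 1]")
  if (length(unique(p)) < k)
    warning(sprintf(
      "only %d distinct p-values for k = %d levels; some levels are empty",
      length(unique(p)), k))
  ord <- order(p)
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  tentative <- rep.int(0:(k - 1L), sizes)        # level by rank
  level <- integer(n)
  level[ord] <- tentative
  # tie rule: identical p-values share the lowest tentative level
  level <- stats::ave(level, match(p, p), FUN = min)
  level <- as.integer(level)
  boundaries <- if (k >= 2L) {
    vapply(0:(k - 2L), function(i) {
      sel <- level == i
      if (any(sel)) max(p[sel]) else NA_real_
    }, numeric(1))
  } else numeric(0)
  list(level = level, boundaries = boundaries)
}
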
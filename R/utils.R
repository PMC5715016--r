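#' Derive a component seed from a master seed
#'
#' Deterministically maps a master seed and a component tag to a new seed in
#' `[1, 2^31 - 2]`, so each logical source of randomness (library sizes, gene
#' effects, noise, permutations, ...) gets its own stream and adding one
#' component never perturbs another's draws.
#'
#' @param seed Master integer seed.
#' @param tag Character tag naming the component.
#' @return A single integer seed.
#' @export
deriveSeed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  h <- 0
  for (cc in utf8ToInt(tag)) h <- (h * 131 + cc) %% 2147483587
  as.integer((abs(seed) %% 2147483587 * 31 + h) %% 2147483587 + 1)
}

#' Odds ratio and Fisher exact p for a 2x2 overlap table
#'
#' Computes the sample odds ratio `(kIn/(nIn-kIn)) / (kOut/(nOut-kOut))` for
#' hits among a "top" group versus the remainder, with a Haldane 0.5
#' continuity correction applied to all four cells whenever any cell is zero,
#' and the two-sided Fisher exact test p-value of the uncorrected table.
#'
#' @param kIn Number of hits inside the top group.
#' @param nIn Size of the top group.
#' @param kOut Number of hits outside.
#' @param nOut Size of the outside group.
#' @return A list with elements `or`, `p`, and `table` (the 2x2 matrix).
#' @examples
#' overlapOddsRatio(28, 30, 100, 17000)
#' @export
overlapOddsRatio <- function(kIn, nIn, kOut, nOut) {
  stopifnot(kIn >= 0, kOut >= 0, kIn <= nIn, kOut <= nOut)
  if (nIn == 0 || nOut == 0)
    stop("both groups must be non-empty")
  tab <- matrix(c(kIn, nIn - kIn, kOut, nOut - kOut), nrow = 2,
                dimnames = list(hit = c("yes", "no"), group = c("in", "out")))
  ctab <- tab
  if (any(tab == 0)) ctab <- tab + 0.5
  or <- (ctab[1, 1] / ctab[2, 1]) / (ctab[1, 2] / ctab[2, 2])
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  list(or = unname(or), p = p, table = tab)
}

# Internal: ceiling-based "at least a fraction of n" count.
minCount <- function(frac, n) as.integer(ceiling(frac * n))

# Internal: check a numeric scalar lies in an interval.
assertScalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper)
    stop(sprintf("'%s' must be a scalar in [%s, %s]", name, lower, upper))
  invisible(x)
}
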
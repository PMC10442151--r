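#' Dip statistic (split-fit convention) and Monte-Carlo test of
#' unimodality
#'
#' The statistic is the smallest sup-norm band half-width epsilon such
#' that, for some split point of the sample, the empirical cdf left of
#' the split admits a convex nondecreasing fit within the band and the
#' part from the split onward admits a concave nondecreasing fit (a
#' jump - the mode atom - is allowed at the split). This is Hartigan's
#' dip up to the handling of the mode atom: the two branches are fitted
#' independently at the split, which makes the statistic exactly
#' computable by two incremental convex-hull scans. It is at least
#' `1/(2n)` for samples with at least two distinct values and grows
#' with the depth of any antimode.
#'
#' `dipTest()` obtains the null distribution by Monte-Carlo sampling of
#' uniform samples of the same size (the classical least-favourable
#' unimodal null) under a fixed seed, so results are reproducible;
#' because the null uses the same statistic, the test has exact level.
#'
#' @param x numeric sample.
#' @return `dipStatistic()`: the dip (numeric scalar).
#' @export
dipStatistic <- function(x) {
  x <- as.numeric(x)
  if (any(!is.finite(x))) stop("sample must be finite")
  cpp_dip(x)
}

#' @rdname dipStatistic
#' @param B number of Monte-Carlo null samples (default 199).
#' @param seed integer seed for the null sampling.
#' @return `dipTest()`: list with `dip`, `pValue`, `B`.
#' @export
dipTest <- function(x, B = 199L, seed = 1L) {
  d <- dipStatistic(x)
  n <- length(x)
  null <- withr::with_seed(seed, vapply(seq_len(B), function(b)
    cpp_dip(runif(n)), numeric(1)))
  list(dip = d, pValue = (1 + sum(null >= d)) / (B + 1), B = B)
}
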
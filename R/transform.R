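#' Add a pseudo count to every cell
#'
#' Sequencing count tables contain sampling zeros, which the log-ratio
#' machinery cannot handle; a small constant added to every cell makes all
#' entries strictly positive. 0.1 is the conventional choice for real
#' data; synthetic additive log-normal compositions are already positive
#' and need none.
#'
#' @param table an [OtuTable-class] or a numeric matrix.
#' @param pseudo positive constant, default 0.1.
#' @return numeric matrix of `counts + pseudo` (no longer integer).
#' @export
addPseudoCount <- function(table, pseudo = 0.1) {
    if (!is.numeric(pseudo) || length(pseudo) != 1L || pseudo <= 0)
        stop("pseudo count must be a positive scalar")
    m <- if (is(table, "OtuTable")) otuCounts(table) else as.matrix(table)
    m + pseudo
}

#' Close rows to compositions
#'
#' Divides each sample (row) by its total, producing relative abundances.
#' Rows must be strictly positive; use [addPseudoCount()] first on data
#' with zeros.
#'
#' @param counts strictly positive numeric matrix, samples by taxa.
#' @return row-stochastic matrix of the same shape.
#' @export
toComposition <- function(counts) {
    m <- if (is(counts, "OtuTable")) otuCounts(counts) else as.matrix(counts)
    if (any(m <= 0))
        stop("all entries must be strictly positive; ",
             "add a pseudo count to zero-containing tables first")
    m / rowSums(m)
}

#' Centered log-ratio transform
#'
#' Maps each composition row x to
#' `clr(x) = (log(x_1/g(x)), ..., log(x_p/g(x)))` with `g(x)` the geometric
#' mean of the row, computed in log space. Output rows sum to zero, and the
#' transform is invariant to per-sample rescaling (sequencing depth).
#'
#' @param x strictly positive matrix (compositions, or raw positive counts
#'   -- the closure constant cancels).
#' @return matrix of the same shape with zero-sum rows.
#' @export
clrTransform <- function(x) {
    m <- if (is(x, "OtuTable")) otuCounts(x) else as.matrix(x)
    if (any(m <= 0)) stop("clr transform requires strictly positive entries")
    lm <- log(m)
    lm - rowMeans(lm)
}

#' Empirical covariance of clr-transformed samples
#'
#' The clr covariance `C = cov(clr(x))` equals `U G U` where `G` is the
#' covariance of log absolute abundances and `U = I - J/p`; it is the
#' observable plug-in for the unobservable log-abundance covariance, and
#' the input to the penalized precision estimation. Uses the unbiased
#' (n - 1) denominator. Row sums are ~0, so the matrix is singular by
#' construction; the solver handles that with a small diagonal ridge.
#'
#' @param c matrix of clr-transformed data (samples by taxa), e.g. from
#'   [clrTransform()].
#' @return a [ClrCovariance-class].
#' @export
clrCovariance <- function(c) {
    m <- as.matrix(c)
    if (nrow(m) < 2L) stop("covariance needs at least 2 samples")
    if (max(abs(rowSums(m))) > 1e-6 * max(1, max(abs(m))))
        warning("input rows do not sum to 0; was this clr-transformed?")
    cc <- cov(m)
    new("ClrCovariance", matrix = (cc + t(cc)) / 2,
        nSamples = nrow(m))
}
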
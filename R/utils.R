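# internal helpers shared across modules

# evaluate expr under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL runs expr with the current stream.
withSeed <- function(seed, expr) {
    if (is.null(seed)) return(force(expr))
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    force(expr)
}

# number of unordered nonzero off-diagonal pairs of a precision matrix,
# under the solver's edge-calling threshold
networkEdgeCount <- function(omega, threshold = 1e-8) {
    sum(abs(omega[upper.tri(omega)]) > threshold)
}

checkSquareSymmetric <- function(m, name, tol = 1e-8) {
    if (!is.matrix(m) || nrow(m) != ncol(m))
        stop(name, " must be a square matrix", call. = FALSE)
    if (max(abs(m - t(m))) > tol)
        stop(name, " must be symmetric", call. = FALSE)
    invisible(m)
}

# pair key used wherever unordered taxa pairs index vectors/maps
pairKey <- function(a, b) {
    ifelse(a < b, paste(a, b, sep = "\r"), paste(b, a, sep = "\r"))
}

logDet <- function(m) {
    ch <- tryCatch(chol(m), error = function(e)
        stop("matrix is not positive definite", call. = FALSE))
    2 * sum(log(diag(ch)))
}

asCovMatrix <- function(cHat) {
    if (is(cHat, "ClrCovariance")) cHat@matrix else
        checkSquareSymmetric(cHat, "covariance")
}
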
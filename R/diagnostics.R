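#' Gelman-Rubin potential scale reduction factor
#'
#' Computes the between/within-chain variance-ratio diagnostic
#' \deqn{\hat R = \sqrt{\frac{(n-1)/n \, W + B/n}{W}}}
#' per monitored parameter, where `W` is the mean within-chain variance and
#' `B/n` the variance of the chain means. Values at or below 1.1 are the
#' conventional evidence of convergence for this model family.
#'
#' Parameters with zero within-chain variance are flagged rather than
#' returned as `NaN`: a parameter constant at the same value in every chain
#' gets `Rhat = 1`, one constant at different values gets `Inf`, and both
#' cases raise a warning.
#'
#' @param draws_by_chain list (one element per chain, >= 2) of numeric
#'   vectors or equal-dimension matrices (iterations x parameters).
#' @return Named numeric vector of Rhat values (one per parameter).
#' @export
gelman_rubin <- function(draws_by_chain) {
    if (length(draws_by_chain) < 2) stop("need >= 2 chains")
    mats <- lapply(draws_by_chain, function(d) {
        if (is.null(dim(d))) matrix(d, ncol = 1) else as.matrix(d)
    })
    n <- nrow(mats[[1]])
    if (n < 2) stop("need chains of length >= 2")
    if (any(vapply(mats, nrow, 0L) != n)) stop("chains must have equal length")

    chain_means <- t(vapply(mats, colMeans, numeric(ncol(mats[[1]]))))
    chain_vars <- t(vapply(mats, function(m) apply(m, 2, var),
                           numeric(ncol(mats[[1]]))))
    if (ncol(mats[[1]]) == 1) {
        chain_means <- matrix(chain_means, ncol = 1)
        chain_vars <- matrix(chain_vars, ncol = 1)
    }
    W <- colMeans(chain_vars)
    B_over_n <- apply(chain_means, 2, var)   # = B / n
    vhat <- (n - 1) / n * W + B_over_n
    rhat <- sqrt(vhat / W)

    degenerate <- W == 0
    if (any(degenerate)) {
        rhat[degenerate] <- ifelse(B_over_n[degenerate] == 0, 1, Inf)
        warning("zero within-chain variance for ",
                sum(degenerate), " parameter(s); Rhat set to 1 (identical ",
                "chains) or Inf (separated chains)")
    }
    names(rhat) <- colnames(mats[[1]])
    rhat
}
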
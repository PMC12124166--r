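#' Abundance-induced detection probability
#'
#' In the Royle-Nichols formulation the per-occasion detection probability of
#' a species at a station is induced by the latent number of individuals `Z`
#' available for detection there: each individual is detected independently
#' with probability `r`, so
#' \deqn{p = 1 - (1 - r)^Z.}
#'
#' @param r per-individual detection probability, in \[0, 1\]. Recycled
#'   against `Z`.
#' @param Z latent abundance, non-negative integer(s).
#' @return Detection probability in \[0, 1\]; exactly 0 when `Z = 0` or
#'   `r = 0`.
#' @examples
#' detection_prob(0.5, 0:3)  # 0, 0.5, 0.75, 0.875
#' @export
detection_prob <- function(r, Z) {
    if (any(r < 0 | r > 1)) stop("'r' must lie in [0, 1]")
    if (any(Z < 0) || any(Z != floor(Z))) {
        stop("'Z' must contain non-negative integers")
    }
    1 - (1 - r)^Z
}

#' Binomial log-likelihood of one detection-history cell
#'
#' Log-probability of observing `Y` detection occasions out of `V` when the
#' per-occasion detection probability is induced by latent abundance `Z`:
#' `Y ~ Binomial(V, 1 - (1 - r)^Z)`.
#'
#' Impossible configurations (e.g. `Y > 0` with `Z = 0`) return `-Inf`
#' rather than raising, so samplers and optimizers can treat them as
#' zero-probability states.
#'
#' @param Y detected occasions, `0 <= Y <= V`.
#' @param V total occasions, `>= 1`.
#' @inheritParams detection_prob
#' @return Log-probability (finite or `-Inf`).
#' @export
cell_loglik <- function(Y, V, r, Z) {
    if (any(Y < 0) || any(Y > V)) stop("'Y' must lie in [0, V]")
    dbinom(Y, V, detection_prob(r, Z), log = TRUE)
}

#' Marginal log-likelihood of a cell with latent abundance summed out
#'
#' Computes
#' \deqn{\log \sum_{z=0}^{z_{max}} Pois(z \mid \lambda)\,
#'       Binom(Y \mid V, 1 - (1 - r)^z)}
#' stably in log space. This is the exact likelihood of a detection-history
#' cell under the Royle-Nichols hierarchy, truncated at `z_max`; it is what
#' the model's Metropolis updates target, here exposed as a scalar reference
#' implementation.
#'
#' @inheritParams cell_loglik
#' @param lambda Poisson mean of the latent abundance, `> 0`.
#' @param z_max truncation bound for the enumeration (default 50). A warning
#'   is issued when the discarded Poisson tail mass `P(Z > z_max)` exceeds
#'   `1e-8`.
#' @return Scalar log-probability.
#' @export
marginal_cell_loglik <- function(Y, V, r, lambda, z_max = 50) {
    stopifnot(length(Y) == 1, length(lambda) == 1, length(r) == 1)
    if (lambda <= 0) stop("'lambda' must be > 0")
    if (z_max < 1) stop("'z_max' must be >= 1")
    tail <- ppois(z_max, lambda, lower.tail = FALSE)
    if (tail > 1e-8) {
        warning(sprintf(
            "truncated Poisson tail mass %.3g exceeds 1e-8; increase z_max",
            tail))
    }
    z <- 0:z_max
    logsumexp(dpois(z, lambda, log = TRUE) +
              cell_loglik(Y, V, r, z))
}
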
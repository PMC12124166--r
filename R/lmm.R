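#' Assemble responses for the mixed-model stage
#'
#' Selects an evenly thinned subset of posterior draws per station from the
#' derived site summaries and joins the station covariates. Using multiple
#' posterior draws per station (rather than one posterior mean) propagates
#' the abundance model's uncertainty and keeps the station-level random
#' intercept identifiable against the residual.
#'
#' @param summaries output of [derive_site_summaries()].
#' @param stations station covariate table.
#' @param response one of `"richness"`, `"abundance"`, `"biomass_kg"`.
#' @param draws_per_site number of posterior draws retained per station
#'   (default 100); capped at the number available.
#' @return data.frame with `response`, `distance_scaled`, `dogs_allowed`,
#'   `station_id`.
#' @export
prepare_lmm_data <- function(summaries, stations,
                             response = c("richness", "abundance",
                                          "biomass_kg"),
                             draws_per_site = 100) {
    response <- match.arg(response)
    key <- paste(summaries$chain, summaries$draw)
    draws <- unique(key)
    take <- draws[unique(round(seq(1, length(draws),
                                   length.out = min(draws_per_site,
                                                    length(draws)))))]
    sub <- summaries[key %in% take, ]
    idx <- match(sub$station_id, stations$station_id)
    data.frame(response = sub[[response]],
               distance_scaled = stations$distance_scaled[idx],
               dogs_allowed = stations$dogs_allowed[idx],
               station_id = sub$station_id)
}

#' Bayesian Gaussian linear mixed model by conjugate Gibbs sampling
#'
#' Fits `response ~ distance_scaled + dogs_allowed + (1 | station)` with a
#' self-contained Gibbs sampler cycling the conjugate full conditionals:
#' fixed effects (normal, flat prior), station random intercepts (normal),
#' and the residual and random-intercept variances
#' (inverse-gamma(0.001, 0.001) priors).
#'
#' @param data as returned by [prepare_lmm_data()] (columns `response`,
#'   `distance_scaled`, `dogs_allowed`, `station_id`).
#' @param mcmc an [rn_mcmc_config()]; default 3 chains x 20,000 iterations,
#'   half burn-in, thin 10 (ample for this conjugate sampler).
#' @return An object of class `rn_lmm` with per-chain draws of the fixed
#'   effects (`intercept`, `distance_scaled`, `dogs_allowed`), the
#'   random-intercept SD and residual SD.
#' @export
fit_lmm <- function(data, mcmc = rn_mcmc_config(n_chains = 3,
                                                n_iter = 20000,
                                                burn_in = 10000,
                                                thin = 10)) {
    y <- as.numeric(data$response)
    if (length(y) < 2) stop("need >= 2 responses")
    if (var(y) == 0) stop("zero-variance response; nothing to model")
    st <- factor(data$station_id)
    J <- nlevels(st)
    if (J < 2) stop("need >= 2 stations")
    strat <- tapply(data$dogs_allowed, st, function(v) v[1])
    if (length(unique(strat)) < 2 || min(table(strat)) < 2) {
        stop("need >= 2 stations per stratum")
    }
    X <- cbind(intercept = 1, distance_scaled = data$distance_scaled,
               dogs_allowed = data$dogs_allowed)
    if (qr(X)$rank < ncol(X)) stop("rank-deficient fixed-effect design")

    n <- length(y)
    sidx <- as.integer(st)
    nj <- tabulate(sidx, J)
    XtX <- crossprod(X)
    XtX_inv <- solve(XtX)
    R <- chol(XtX_inv)
    a0 <- b0 <- 0.001

    chains <- vector("list", mcmc$n_chains)
    n_keep <- (mcmc$n_iter - mcmc$burn_in) %/% mcmc$thin
    for (cc in seq_len(mcmc$n_chains)) {
        set.seed(mcmc$seed + (cc - 1L) * 1000L)
        beta <- XtX_inv %*% crossprod(X, y) + rnorm(3, 0, 0.1)
        u <- rep(0, J)
        sigma2 <- var(y) / 2
        tau2 <- var(tapply(y, st, mean)) / 2 + 1e-6
        bd <- matrix(NA_real_, n_keep, 3,
                     dimnames = list(NULL, colnames(X)))
        sdd <- matrix(NA_real_, n_keep, 2,
                      dimnames = list(NULL, c("sd_station", "sd_resid")))
        kept <- 0L
        for (t in seq_len(mcmc$n_iter)) {
            # fixed effects | u, sigma2
            ytil <- y - u[sidx]
            bhat <- XtX_inv %*% crossprod(X, ytil)
            beta <- bhat + sqrt(sigma2) * (t(R) %*% rnorm(3))
            # random intercepts | beta, variances
            res <- y - X %*% beta
            sums <- tapply(res, sidx, sum)
            prec <- nj / sigma2 + 1 / tau2
            u <- rnorm(J, (sums / sigma2) / prec, sqrt(1 / prec))
            # variances
            e <- res - u[sidx]
            sigma2 <- 1 / rgamma(1, a0 + n / 2, b0 + sum(e^2) / 2)
            tau2 <- 1 / rgamma(1, a0 + J / 2, b0 + sum(u^2) / 2)
            if (t > mcmc$burn_in && (t - mcmc$burn_in) %% mcmc$thin == 0) {
                kept <- kept + 1L
                bd[kept, ] <- beta
                sdd[kept, ] <- sqrt(c(tau2, sigma2))
            }
        }
        chains[[cc]] <- list(beta = bd, sd = sdd)
    }
    structure(list(chains = chains, mcmc = mcmc,
                   effects = colnames(X), n = n, n_stations = J),
              class = "rn_lmm")
}

#' Credible-interval support call for a coefficient
#'
#' A covariate effect is "supported" when its central credible interval
#' excludes zero.
#'
#' @param coefficient_draws numeric vector of >= 100 posterior draws.
#' @param level interval level (default 0.95).
#' @return list with `supported` (logical), `direction` (`"positive"`,
#'   `"negative"` or `"none"`), `lower`, `upper`.
#' @export
effect_support <- function(coefficient_draws, level = 0.95) {
    if (length(coefficient_draws) < 100) stop("need >= 100 draws")
    alpha <- (1 - level) / 2
    ci <- quantile(coefficient_draws, c(alpha, 1 - alpha), names = FALSE)
    supported <- ci[1] > 0 || ci[2] < 0
    list(supported = supported,
         direction = if (!supported) "none" else
             if (ci[1] > 0) "positive" else "negative",
         lower = ci[1], upper = ci[2])
}

#' Summarize a mixed-model fit
#'
#' @param object an `rn_lmm`.
#' @param ... unused.
#' @return data.frame per fixed effect: posterior mean, 95% interval, Rhat,
#'   support call.
#' @export
summary.rn_lmm <- function(object, ...) {
    mats <- lapply(object$chains, `[[`, "beta")
    pooled <- do.call(rbind, mats)
    rhat <- if (length(mats) >= 2) gelman_rubin(mats) else
        rep(NA_real_, ncol(pooled))
    rows <- lapply(seq_len(ncol(pooled)), function(k) {
        s <- effect_support(pooled[, k])
        data.frame(effect = colnames(pooled)[k],
                   mean = mean(pooled[, k]),
                   lo95 = s$lower, hi95 = s$upper,
                   rhat = as.numeric(rhat[k]),
                   supported = s$supported, direction = s$direction)
    })
    do.call(rbind, rows)
}

#' @export
print.rn_lmm <- function(x, ...) {
    cat(sprintf("Bayesian LMM (Gibbs): %d rows, %d stations, %d chains\n",
                x$n, x$n_stations, length(x$chains)))
    print(summary(x))
    invisible(x)
}
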
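#' MCMC sampler configuration
#'
#' Defaults follow the study protocol: 3 chains of 100,000 iterations,
#' burn-in 50,000, thinning 100. Proposal scales adapt toward a 25-45%
#' acceptance rate during burn-in only and are frozen afterwards, which
#' preserves detailed balance for the retained draws.
#'
#' @param n_chains number of chains (>= 2 needed for Gelman-Rubin
#'   diagnostics).
#' @param n_iter iterations per chain.
#' @param burn_in discarded initial iterations, `< n_iter`.
#' @param thin retain every `thin`-th post-burn-in iteration.
#' @param seed integer seed; chain `c` uses `seed + (c - 1) * 1000`.
#' @param adapt_interval iterations between proposal-scale adjustments
#'   during burn-in.
#' @param accept_band target acceptance-rate band for adaptation.
#' @return An object of class `rn_mcmc_config`.
#' @export
rn_mcmc_config <- function(n_chains = 3, n_iter = 100000, burn_in = 50000,
                           thin = 100, seed = 1L, adapt_interval = 50,
                           accept_band = c(0.25, 0.45)) {
    if (burn_in >= n_iter) stop("burn_in must be < n_iter")
    if (thin < 1) stop("thin must be >= 1")
    if (n_chains < 1) stop("n_chains must be >= 1")
    structure(list(n_chains = as.integer(n_chains),
                   n_iter = as.integer(n_iter),
                   burn_in = as.integer(burn_in), thin = as.integer(thin),
                   seed = as.integer(seed),
                   adapt_interval = as.integer(adapt_interval),
                   accept_band = accept_band),
              class = "rn_mcmc_config")
}

#' Model specification for the multispecies Royle-Nichols fit
#'
#' Two variants place the station covariates (scaled distance, hunting
#' stratum, their interaction) on one parameter while the other is held
#' species-constant: `"abundance"` (Model 1) models
#' `log lambda_ij = x_j' beta_i` with a species-constant logit `r_i`;
#' `"detection"` (Model 2) models `logit r_ij = x_j' alpha_i` with a
#' species-constant `log lambda_i`. Species-constant parameters are still
#' species-specific draws from the community hyperdistribution.
#'
#' @param variant `"abundance"` or `"detection"`.
#' @param n_aug number of augmented all-zero species the history must carry.
#' @param z_max truncation bound for the latent-abundance enumeration.
#' @return An object of class `rn_model_spec`.
#' @export
rn_model_spec <- function(variant = c("abundance", "detection"),
                          n_aug = 10, z_max = 50) {
    variant <- match.arg(variant)
    if (z_max < 1) stop("z_max must be >= 1")
    structure(list(variant = variant, n_aug = as.integer(n_aug),
                   z_max = as.integer(z_max)),
              class = "rn_model_spec")
}

rn_param_names <- function(variant) {
    if (variant == "abundance") {
        c("beta0", "beta_dist", "beta_dogs", "beta_dist_dogs", "logit_r")
    } else {
        c("alpha0", "alpha_dist", "alpha_dogs", "alpha_dist_dogs",
          "log_lambda")
    }
}

# Species x station link-scale matrices for the current theta (S x 5)
rn_link_matrices <- function(theta, X, variant) {
    S <- nrow(theta); J <- nrow(X)
    G <- theta[, 1:4, drop = FALSE] %*% t(X)
    if (variant == "abundance") {
        list(logLam = G, r = matrix(plogis(theta[, 5]), S, J))
    } else {
        list(logLam = matrix(theta[, 5], S, J), r = plogis(G))
    }
}

#' Fit the hierarchical multispecies Royle-Nichols model by MCMC
#'
#' Purpose-built Metropolis-within-Gibbs sampler for the augmented
#' community model
#' \deqn{Y_{ij} \sim Binom(V_j, 1 - (1 - r_{ij})^{Z_{ij}}), \quad
#'       Z_{ij} \sim Pois(\lambda_{ij}) \cdot w_i, \quad
#'       w_i \sim Bern(\omega),}
#' with species-level parameters drawn from community normal
#' hyperdistributions on the link scale. Priors: hypermeans `N(0, 10^2)`,
#' hyper-SDs `Uniform(0, 5)`, `omega ~ Uniform(0, 1)`.
#'
#' Updates: species-level coefficients by adaptive random-walk Metropolis
#' against the marginal likelihood with `Z` summed out by exact enumeration
#' over `{0..z_max}` (collapsing `Z` removes the abundance-coefficient
#' random walk's worst autocorrelation); inclusion indicators `w_i` by their
#' exact Bernoulli conditional under that marginal likelihood; `omega` by
#' its conjugate Beta full conditional; hypermeans by conjugate normal
#' updates; hyper-SDs by Metropolis on the log scale. `Z` is drawn from its
#' enumerated full conditional at every retained iteration, so derived
#' posteriors (richness, abundance, biomass) are exact per draw.
#'
#' @param history an `rn_history` (augmented per `model_spec$n_aug`).
#' @param stations station covariate table with `distance_scaled` and
#'   `dogs_allowed`.
#' @param model_spec an [rn_model_spec()].
#' @param mcmc an [rn_mcmc_config()].
#' @return An object of class `rn_fit` with per-chain retained draws of
#'   hyperparameters, species-level coefficients, inclusion indicators,
#'   `omega`, and latent `Z`.
#' @export
fit_msom <- function(history, stations, model_spec = rn_model_spec(),
                     mcmc = rn_mcmc_config()) {
    stopifnot(inherits(history, "rn_history"),
              inherits(model_spec, "rn_model_spec"),
              inherits(mcmc, "rn_mcmc_config"))
    Y <- history$Y
    if (ncol(Y) != nrow(stations)) {
        stop("history and station table dimensions disagree")
    }
    if (sum(history$augmented) != model_spec$n_aug) {
        stop(sprintf("history carries %d augmented rows but model_spec expects %d",
                     sum(history$augmented), model_spec$n_aug))
    }
    storage.mode(Y) <- "integer"
    V <- as.integer(rep(history$V, length.out = ncol(Y)))
    S <- nrow(Y); J <- ncol(Y)
    X <- rn_design(stations)
    variant <- model_spec$variant
    zmax <- model_spec$z_max
    pn <- rn_param_names(variant)
    aug <- history$augmented
    observed <- !aug

    chains <- vector("list", mcmc$n_chains)
    for (cc in seq_len(mcmc$n_chains)) {
        set.seed(mcmc$seed + (cc - 1L) * 1000L)
        chains[[cc]] <- rn_run_chain(Y, V, X, variant, zmax, aug, mcmc, pn)
    }

    structure(list(
        variant = variant, param_names = pn, species = history$species,
        augmented = aug, stations = stations, V = V, Y = Y,
        z_max = zmax, model_spec = model_spec, mcmc = mcmc,
        chains = chains
    ), class = "rn_fit")
}

# One MCMC chain; RNG state set by the caller.
rn_run_chain <- function(Y, V, X, variant, zmax, aug, mcmc, pn) {
    S <- nrow(Y); J <- ncol(Y)
    n_obs <- sum(!aug)

    # -- initial values -------------------------------------------------
    naive <- pmax(rowSums(Y) / sum(V), 0.01)
    theta <- matrix(0, S, 5)
    if (variant == "abundance") {
        theta[, 1] <- log(pmax(3 * naive, 0.05)) + rnorm(S, 0, 0.3)
        theta[, 5] <- qlogis(0.15) + rnorm(S, 0, 0.3)
    } else {
        theta[, 1] <- qlogis(pmin(pmax(naive, 0.02), 0.5)) + rnorm(S, 0, 0.3)
        theta[, 5] <- rnorm(S, 0, 0.3)
    }
    theta[, 2:4] <- rnorm(3 * S, 0, 0.1)
    mu <- colMeans(theta)
    sig <- apply(theta, 2, sd)
    sig[!is.finite(sig)] <- 0.5        # single-species edge case
    sig <- pmax(sig, 0.25)
    omega <- (n_obs + 1) / (S + 2)
    w <- rep(1L, S)

    lk <- rn_link_matrices(theta, X, variant)
    cur_ll <- rn_marg_loglik(Y, V, lk$logLam, lk$r, zmax)
    if (any(!is.finite(cur_ll))) {
        stop("non-finite marginal log-likelihood at initialization")
    }

    # -- adaptation state ----------------------------------------------
    scales <- matrix(0.5, S, 5)
    sig_scales <- rep(0.3, 5)
    resc_scales <- rep(0.3, 5)
    acc <- matrix(0, S, 5); acc_sig <- rep(0, 5); acc_resc <- rep(0, 5)

    n_keep <- (mcmc$n_iter - mcmc$burn_in) %/% mcmc$thin
    hyper_names <- c(paste0("mu_", pn), paste0("sigma_", pn), "omega")
    hyper_draws <- matrix(NA_real_, n_keep, 11,
                          dimnames = list(NULL, hyper_names))
    theta_draws <- array(NA_real_, c(n_keep, S, 5),
                         dimnames = list(NULL, rownames(Y), pn))
    w_draws <- matrix(NA_integer_, n_keep, S,
                      dimnames = list(NULL, rownames(Y)))
    Z_draws <- array(NA_integer_, c(n_keep, S, J),
                     dimnames = list(NULL, rownames(Y), colnames(Y)))
    kept <- 0L

    for (t in seq_len(mcmc$n_iter)) {
        in_burn <- t <= mcmc$burn_in
        incl <- w == 1L

        # species-level coefficients, one column at a time (RW Metropolis
        # on the marginal likelihood for included species)
        for (k in 1:5) {
            cand_theta <- theta
            cand_theta[, k] <- theta[, k] + rnorm(S) * scales[, k]
            lk_c <- rn_link_matrices(cand_theta, X, variant)
            cand_ll <- rn_marg_loglik(Y, V, lk_c$logLam, lk_c$r, zmax)
            logacc <- ifelse(incl, cand_ll - cur_ll, 0) +
                dnorm(cand_theta[, k], mu[k], sig[k], log = TRUE) -
                dnorm(theta[, k], mu[k], sig[k], log = TRUE)
            take <- log(runif(S)) < logacc
            if (any(take)) {
                theta[take, k] <- cand_theta[take, k]
                cur_ll[take] <- cand_ll[take]
                if (in_burn) acc[take, k] <- acc[take, k] + 1
            }
        }

        # excluded species: parameters are conditionally prior draws
        if (any(!incl)) {
            idx <- which(!incl)
            for (k in 1:5) {
                theta[idx, k] <- rnorm(length(idx), mu[k], sig[k])
            }
            lk <- rn_link_matrices(theta, X, variant)
            ll_all <- rn_marg_loglik(Y, V, lk$logLam, lk$r, zmax)
            cur_ll[idx] <- ll_all[idx]
        }

        # inclusion indicators for augmented species (exact conditional
        # using the marginal likelihood of their all-zero histories)
        if (any(aug)) {
            lo <- log(omega) - log1p(-omega) + cur_ll[aug]
            w[aug] <- as.integer(runif(sum(aug)) < plogis(lo))
        }

        # omega | w  ~  Beta (uniform prior)
        omega <- rbeta(1, 1 + sum(w), 1 + sum(1L - w))

        # hypermeans: conjugate normal update, prior N(0, 10^2)
        for (k in 1:5) {
            prec <- nrow(theta) / sig[k]^2 + 1 / 100
            mhat <- (sum(theta[, k]) / sig[k]^2) / prec
            mu[k] <- rnorm(1, mhat, sqrt(1 / prec))
        }

        # hyper-SDs: Metropolis on the log scale, prior Uniform(0, 5)
        for (k in 1:5) {
            cand <- sig[k] * exp(rnorm(1) * sig_scales[k])
            if (cand < 5) {
                la <- sum(dnorm(theta[, k], mu[k], cand, log = TRUE)) -
                    sum(dnorm(theta[, k], mu[k], sig[k], log = TRUE)) +
                    log(cand) - log(sig[k])
                if (log(runif(1)) < la) {
                    sig[k] <- cand
                    if (in_burn) acc_sig[k] <- acc_sig[k] + 1
                }
            }
        }

        # joint scale move: rescale a column's species deviations together
        # with its hyper-SD. Hyper-SDs and their species effects are
        # strongly coupled (funnel geometry); this move traverses the
        # funnel directly. Prior terms cancel against the Jacobian, leaving
        # log-acceptance = likelihood change + eps.
        for (k in 1:5) {
            eps <- rnorm(1) * resc_scales[k]
            cfac <- exp(eps)
            if (sig[k] * cfac >= 5) next
            cand_theta <- theta
            cand_theta[, k] <- mu[k] + cfac * (theta[, k] - mu[k])
            lk_c <- rn_link_matrices(cand_theta, X, variant)
            cand_ll <- rn_marg_loglik(Y, V, lk_c$logLam, lk_c$r, zmax)
            la <- sum((cand_ll - cur_ll)[incl]) + eps
            if (is.finite(la) && log(runif(1)) < la) {
                theta <- cand_theta
                sig[k] <- sig[k] * cfac
                cur_ll <- cand_ll
                if (in_burn) acc_resc[k] <- acc_resc[k] + 1
            }
        }

        # proposal-scale adaptation, burn-in only
        if (in_burn && t %% mcmc$adapt_interval == 0) {
            rate <- acc / mcmc$adapt_interval
            scales <- scales * exp(0.12 * (rate > mcmc$accept_band[2]) -
                                   0.12 * (rate < mcmc$accept_band[1]))
            rate_s <- acc_sig / mcmc$adapt_interval
            sig_scales <- sig_scales *
                exp(0.12 * (rate_s > mcmc$accept_band[2]) -
                    0.12 * (rate_s < mcmc$accept_band[1]))
            rate_r <- acc_resc / mcmc$adapt_interval
            resc_scales <- resc_scales *
                exp(0.12 * (rate_r > mcmc$accept_band[2]) -
                    0.12 * (rate_r < mcmc$accept_band[1]))
            acc[] <- 0; acc_sig[] <- 0; acc_resc[] <- 0
        }

        # retention
        if (!in_burn && (t - mcmc$burn_in) %% mcmc$thin == 0) {
            kept <- kept + 1L
            hyper_draws[kept, ] <- c(mu, sig, omega)
            theta_draws[kept, , ] <- theta
            w_draws[kept, ] <- w
            lk <- rn_link_matrices(theta, X, variant)
            Z_draws[kept, , ] <- rn_draw_z(Y, V, lk$logLam, lk$r, w, zmax)
        }
    }

    list(hyper = hyper_draws, theta = theta_draws, w = w_draws,
         Z = Z_draws, scales = scales)
}

#' @export
print.rn_fit <- function(x, ...) {
    nk <- nrow(x$chains[[1]]$hyper)
    cat(sprintf(
        "Multispecies Royle-Nichols fit (%s covariates): %d species (%d augmented) x %d stations\n",
        x$variant, length(x$species), sum(x$augmented), ncol(x$Y)))
    cat(sprintf("%d chain(s) x %d retained draws (n_iter %d, burn-in %d, thin %d)\n",
                length(x$chains), nk, x$mcmc$n_iter, x$mcmc$burn_in,
                x$mcmc$thin))
    invisible(x)
}

# Stack monitored draws (hyperparameters + all species-level coefficients)
# as one matrix per chain.
rn_monitored <- function(fit, include_species = TRUE) {
    lapply(fit$chains, function(ch) {
        out <- ch$hyper
        if (include_species) {
            S <- dim(ch$theta)[2]
            sp_mat <- matrix(ch$theta, nrow = dim(ch$theta)[1])
            colnames(sp_mat) <- as.vector(outer(
                dimnames(ch$theta)[[2]], dimnames(ch$theta)[[3]],
                function(s, p) paste0(p, "[", s, "]")))
            out <- cbind(out, sp_mat)
        }
        out
    })
}

#' Summarize a multispecies Royle-Nichols fit
#'
#' @param object an `rn_fit`.
#' @param include_species include per-species coefficients (default TRUE)
#'   in addition to community hyperparameters.
#' @param ... unused.
#' @return data.frame with posterior mean, SD, 2.5/50/97.5% quantiles and
#'   Rhat (NA with a single chain) per monitored parameter.
#' @export
summary.rn_fit <- function(object, include_species = TRUE, ...) {
    mats <- rn_monitored(object, include_species)
    pooled <- do.call(rbind, mats)
    qs <- t(apply(pooled, 2, quantile, probs = c(0.025, 0.5, 0.975),
                  names = FALSE))
    rhat <- if (length(mats) >= 2) gelman_rubin(mats) else
        rep(NA_real_, ncol(pooled))
    data.frame(parameter = colnames(pooled),
               mean = colMeans(pooled),
               sd = apply(pooled, 2, sd),
               q2.5 = qs[, 1], q50 = qs[, 2], q97.5 = qs[, 3],
               rhat = as.numeric(rhat),
               row.names = NULL)
}
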
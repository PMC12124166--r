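# Small helper: simulate + augment a community and fit Model 1 briefly.
fit_small <- function(seed, n_species = 10, n_per_stratum = 4, n_aug = 4,
                      variant = "abundance",
                      mcmc = rn_mcmc_config(n_chains = 2, n_iter = 800,
                                            burn_in = 400, thin = 4,
                                            seed = seed)) {
    sc <- simulation_scenario(seed = seed, n_species = n_species,
                              n_stations_per_stratum = n_per_stratum)
    sim <- simulate_community(sc, n_aug = n_aug)
    fit <- fit_msom(sim$history, sim$stations,
                    rn_model_spec(variant, n_aug = n_aug), mcmc)
    list(sim = sim, fit = fit)
}

test_that("latent-abundance draws match the enumerated full conditional", {
    # tiny instance: fixed parameters, compare empirical draw frequencies
    # of Z against the exhaustive discretized posterior
    Y <- matrix(c(2L, 0L, 4L, 1L, 5L, 0L), nrow = 2)
    V <- c(5L, 5L, 5L)
    logLam <- matrix(log(c(1.2, 0.4, 2, 0.8, 1.5, 0.3)), nrow = 2)
    r <- matrix(c(0.4, 0.2, 0.3, 0.5, 0.25, 0.6), nrow = 2)
    zmax <- 4L
    w <- c(1L, 1L)
    n_draw <- 30000
    counts <- array(0, c(2, 3, zmax + 1))
    set.seed(123)
    for (d in seq_len(n_draw)) {
        Z <- rnmsom:::rn_draw_z(Y, V, logLam, r, w, zmax)
        for (i in 1:2) for (j in 1:3) {
            counts[i, j, Z[i, j] + 1] <- counts[i, j, Z[i, j] + 1] + 1
        }
    }
    for (i in 1:2) for (j in 1:3) {
        # oracle: enumerate Pois(z) * Binom(Y | V, p(z)) directly
        pz <- dpois(0:zmax, exp(logLam[i, j])) *
            dbinom(Y[i, j], V[j], 1 - (1 - r[i, j])^(0:zmax))
        pz <- pz / sum(pz)
        emp <- counts[i, j, ] / n_draw
        se <- sqrt(pz * (1 - pz) / n_draw)
        expect_true(all(abs(emp - pz) <= 3.5 * se + 1e-12))
    }
    # excluded species are pinned at zero
    Z0 <- rnmsom:::rn_draw_z(Y, V, logLam, r, c(0L, 1L), zmax)
    expect_true(all(Z0[1, ] == 0))
})

test_that("single-species posterior concentrates at the marginal MLE", {
    # strong data: 40 stations, 50 occasions, no covariate structure
    set.seed(10)
    J <- 40
    st <- data.frame(station_id = sprintf("CT%02d", 1:J),
                     dogs_allowed = 0L, distance_km = 1, distance_scaled = 0)
    lam_true <- 2; r_true <- 0.3
    Z <- rpois(J, lam_true)
    Yv <- rbinom(J, 50, 1 - (1 - r_true)^Z)
    h <- structure(list(
        Y = matrix(as.integer(Yv), 1, J,
                   dimnames = list("SP1", st$station_id)),
        V = setNames(rep(50L, J), st$station_id),
        occasions = build_occasions(0, 250, 5),
        species = "SP1", augmented = FALSE), class = "rn_history")
    fit <- fit_msom(h, st, rn_model_spec("abundance", n_aug = 0, z_max = 40),
                    rn_mcmc_config(n_chains = 2, n_iter = 3000,
                                   burn_in = 1000, thin = 4, seed = 2))
    th <- do.call(rbind, lapply(fit$chains, function(ch) ch$theta[, 1, ]))
    # independent oracle: maximize the marginal likelihood numerically
    nll <- function(p) {
        -sum(vapply(seq_len(J), function(j) {
            marginal_cell_loglik(Yv[j], 50, plogis(p[2]), exp(p[1]),
                                 z_max = 40)
        }, 0))
    }
    opt <- optim(c(0, 0), nll)
    expect_lt(abs(mean(th[, 1]) - opt$par[1]), 3 * sd(th[, 1]))
    expect_lt(abs(mean(th[, 5]) - opt$par[2]), 3 * sd(th[, 5]))
})

test_that("fits are reproducible and correctly shaped", {
    a <- fit_small(21)
    b <- fit_small(21)
    expect_identical(a$fit$chains[[1]]$hyper, b$fit$chains[[1]]$hyper)
    expect_identical(a$fit$chains[[2]]$Z, b$fit$chains[[2]]$Z)
    fit <- a$fit
    expect_equal(dim(fit$chains[[1]]$hyper), c(100, 11))
    expect_equal(dim(fit$chains[[1]]$theta), c(100, 14, 5))
    expect_equal(dim(fit$chains[[1]]$Z), c(100, 14, 8))
    expect_true(all(fit$chains[[1]]$Z >= 0))
    expect_true(all(fit$chains[[1]]$w %in% 0:1))
    # observed species always included
    expect_true(all(fit$chains[[1]]$w[, !fit$augmented] == 1L))
    s <- summary(fit, include_species = FALSE)
    expect_equal(nrow(s), 11)
    expect_true(all(is.finite(s$mean)))
})

test_that("all-zero augmented histories push inclusion below omega", {
    res <- fit_small(31, n_species = 12, n_per_stratum = 5, n_aug = 6)
    ch <- res$fit$chains[[1]]
    w_aug <- mean(ch$w[, res$fit$augmented])
    omega_mean <- mean(ch$hyper[, "omega"])
    expect_lt(w_aug, omega_mean)
})

test_that("the detection-covariate variant fits and is well formed", {
    res <- fit_small(41, variant = "detection")
    s <- summary(res$fit, include_species = FALSE)
    expect_true(all(grepl("alpha|log_lambda|omega", s$parameter)))
    expect_true(all(is.finite(s$mean)))
})

test_that("invalid configurations are rejected before compute", {
    expect_error(rn_mcmc_config(n_iter = 100, burn_in = 100), "burn_in")
    expect_error(rn_mcmc_config(thin = 0), "thin")
    expect_error(rn_model_spec(z_max = 0), "z_max")
    sim <- simulate_community(simulation_scenario(
        seed = 1, n_species = 5, n_stations_per_stratum = 2), n_aug = 2)
    expect_error(fit_msom(sim$history, sim$stations,
                          rn_model_spec("abundance", n_aug = 5),
                          rn_mcmc_config(n_chains = 1, n_iter = 20,
                                         burn_in = 10, thin = 1)),
                 "augmented")
    expect_error(fit_msom(sim$history, sim$stations[1:2, ],
                          rn_model_spec("abundance", n_aug = 2),
                          rn_mcmc_config(n_chains = 1, n_iter = 20,
                                         burn_in = 10, thin = 1)),
                 "dimensions")
})
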
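test_that("station simulation reproduces the study layout", {
    sc <- simulation_scenario(seed = 1)
    st <- simulate_stations(sc)
    expect_equal(nrow(st), 20)
    expect_equal(sum(st$dogs_allowed == 1), 10)
    expect_true(all(st$distance_km >= 0.54 & st$distance_km <= 5.1))
    expect_equal(mean(st$distance_scaled), 0, tolerance = 1e-9)
    expect_equal(sd(st$distance_scaled), 1, tolerance = 1e-9)
    # determinism under a fixed seed
    expect_identical(st, simulate_stations(sc))
    # degenerate range still yields one station per stratum
    st2 <- simulate_stations(simulation_scenario(
        n_stations_per_stratum = 1, distance_range_km = c(1, 1.0001)))
    expect_equal(nrow(st2), 2)
    expect_lt(diff(range(st2$distance_km)), 1e-3)
    expect_error(simulation_scenario(distance_range_km = c(2, 1)),
                 "invalid distance range")
})

test_that("species parameters are community hyperdistribution draws", {
    hp <- community_hyperparams()
    sp <- draw_species_params(hp, 29, seed = 3)
    expect_equal(nrow(sp), 29)
    # zero-variance limit collapses every species onto the community mean
    hp0 <- community_hyperparams(sigma_beta = rep(0, 4), sigma_detect = 0)
    sp0 <- draw_species_params(hp0, 5, seed = 1)
    expect_true(all(sp0$beta0 == hp0$mu_beta[1]))
    expect_true(all(sp0$beta_dogs == hp0$mu_beta[3]))
    expect_true(all(sp0$logit_r == hp0$mu_detect))
    # Monte-Carlo check of the stated normal for the intercept
    big <- draw_species_params(hp, 10000, seed = 9)
    se <- hp$sigma_beta[1] / sqrt(10000)
    expect_lt(abs(mean(big$beta0) - hp$mu_beta[1]), 3 * se)
    expect_error(community_hyperparams(sigma_beta = c(1, 1, -1, 1)),
                 ">= 0")
})

test_that("latent abundance follows the log-linear Poisson model", {
    st <- simulate_stations(simulation_scenario(seed = 2))
    # all coefficients zero: lambda = 1 everywhere
    sp <- data.frame(code = sprintf("S%02d", 1:200), beta0 = 0,
                     beta_dist = 0, beta_dogs = 0, beta_dist_dogs = 0,
                     logit_r = 0)
    Z <- simulate_abundance(sp, st, seed = 4)
    expect_true(all(Z >= 0) && all(Z == floor(Z)))
    expect_equal(mean(Z), 1, tolerance = 3 / sqrt(length(Z)))
    # Poisson property: variance ~ mean across replicate draws
    expect_equal(var(as.vector(Z)), mean(Z), tolerance = 0.05)
    # strongly negative distance effect empties distant sites
    spneg <- transform(sp[1:50, ], beta_dist = -8)
    far <- which.max(st$distance_scaled)
    Zn <- simulate_abundance(spneg, st, seed = 5)
    expect_true(all(Zn[, far] == 0))
})

test_that("detection histories are binomial in the induced probability", {
    sp1 <- data.frame(code = "A", beta0 = 0, beta_dist = 0, beta_dogs = 0,
                      beta_dist_dogs = 0, logit_r = Inf)   # r = 1
    Z <- matrix(3L, 1, 5, dimnames = list("A", paste0("CT", 1:5)))
    Y <- simulate_histories(Z, sp1, V = 10, seed = 1)
    expect_true(all(Y == 10))
    # Z = 0 never produces detections
    Z0 <- matrix(0L, 1, 5, dimnames = dimnames(Z))
    expect_true(all(simulate_histories(Z0, sp1, V = 10, seed = 1) == 0))
    # r = 0.5, Z = 1, V = 10: mean detections ~ 5
    sp5 <- transform(sp1, logit_r = qlogis(0.5))
    Zr <- matrix(1L, 1, 2000, dimnames = list("A", sprintf("S%04d", 1:2000)))
    Yr <- simulate_histories(Zr, sp5, V = 10, seed = 2)
    se <- sqrt(10 * 0.25 / 2000)
    expect_lt(abs(mean(Yr) - 5), 3 * se)
    expect_error(simulate_histories(Z, sp1, V = 0), "V")
})

test_that("records round-trip through the detection-history builder", {
    cal <- build_occasions(0, 49, 5)
    for (seed in 1:5) {
        sc <- simulation_scenario(seed = seed, n_species = 12,
                                  n_stations_per_stratum = 4)
        st <- simulate_stations(sc)
        sp <- draw_species_params(sc$hyperparams, sc$n_species, seed = seed)
        Z <- simulate_abundance(sp, st, seed = seed + 100)
        rec <- simulate_records(Z, sp, st, cal, seed = seed + 200)
        h <- build_history(rec, st, sp$code, cal, partial_policy = "keep")
        expect_identical(h$Y, attr(rec, "Y"))
        expect_true(all(h$Y[Z == 0] == 0))
    }
    # empty community produces an empty record table
    spE <- draw_species_params(community_hyperparams(), 2, seed = 1)
    stE <- simulate_stations(simulation_scenario(n_stations_per_stratum = 2))
    recE <- simulate_records(matrix(0L, 2, 4,
                                    dimnames = list(spE$code,
                                                    stE$station_id)),
                             spE, stE, cal, seed = 1)
    expect_equal(nrow(recE), 0)
})

test_that("records for Y detected occasions span exactly Y windows", {
    cal <- build_occasions(0, 50, 5)
    sp <- data.frame(code = "A", beta0 = 2, beta_dist = 0, beta_dogs = 0,
                     beta_dist_dogs = 0, logit_r = qlogis(0.4))
    st <- data.frame(station_id = "CT01", dogs_allowed = 0L,
                     distance_km = 1, distance_scaled = 0)
    Z <- matrix(5L, 1, 1, dimnames = list("A", "CT01"))
    rec <- simulate_records(Z, sp, st, cal, seed = 3)
    Y <- attr(rec, "Y")[1, 1]
    day <- as.numeric(difftime(rec$datetime, rnmsom:::rn_epoch(),
                               units = "days"))
    expect_equal(length(unique(findInterval(day, cal$start_day))), Y)
})

test_that("fixed seed fixes every downstream table bit-for-bit", {
    sc <- simulation_scenario(seed = 99, n_species = 8,
                              n_stations_per_stratum = 3)
    a <- simulate_community(sc, n_aug = 4)
    b <- simulate_community(sc, n_aug = 4)
    expect_identical(a$stations, b$stations)
    expect_identical(a$Z, b$Z)
    expect_identical(a$records, b$records)
    expect_identical(a$history$Y, b$history$Y)
})
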
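#' Community hyperparameters for a simulated assemblage
#'
#' Species-level parameters in the hierarchical Royle-Nichols model are
#' draws from community-level normal distributions on the link scale (log
#' for expected abundance, logit for per-individual detection). This
#' constructor bundles those hyperparameters.
#'
#' Defaults describe a tropical-forest camera-trap community: median
#' expected abundance near `exp(-0.5) ~ 0.6` individuals per station at the
#' covariate origin with a long right tail across species (`sigma = 1` on
#' the log scale), a mild positive distance effect and a negative effect of
#' the hunting-with-dogs stratum on abundance, per-individual detection
#' around `plogis(-1.8) ~ 0.14` per 5-day occasion, and inclusion
#' probability 0.75 (roughly 29 observed of 39 candidate species).
#'
#' @param mu_beta community means of the species-level abundance
#'   coefficients (intercept, scaled distance, dogs stratum, interaction) on
#'   the log scale.
#' @param sigma_beta matching community SDs, `>= 0` (0 gives the degenerate
#'   all-species-identical limit).
#' @param mu_detect,sigma_detect community mean/SD of the species baseline
#'   per-individual detection parameter on the logit scale.
#' @param omega inclusion probability in \[0, 1\] for augmented species.
#' @return An object of class `rn_hyperparams`.
#' @export
community_hyperparams <- function(mu_beta = c(-0.5, 0.3, -0.4, 0),
                                  sigma_beta = c(1, 0.5, 0.5, 0.25),
                                  mu_detect = -1.8,
                                  sigma_detect = 0.5,
                                  omega = 0.75) {
    stopifnot(length(mu_beta) == 4, length(sigma_beta) == 4)
    if (any(sigma_beta < 0) || sigma_detect < 0) {
        stop("community SDs must be >= 0")
    }
    if (omega < 0 || omega > 1) stop("'omega' must lie in [0, 1]")
    structure(list(mu_beta = mu_beta, sigma_beta = sigma_beta,
                   mu_detect = mu_detect, sigma_detect = sigma_detect,
                   omega = omega),
              class = "rn_hyperparams")
}

#' Simulation scenario mirroring the study's sampling design
#'
#' Default scenario: 2 river-bank strata x 10 stations, distances uniform on
#' 0.54-5.1 km, 29 species, 49 continuous sampling days binned into 5-day
#' occasions.
#'
#' @param n_stations_per_stratum stations per hunting stratum, `>= 1`.
#' @param distance_range_km `(min, max)` with `0 < min < max`.
#' @param n_species number of (observed) species simulated.
#' @param n_days continuous deployment length in days.
#' @param occasion_length_days occasion window length in days.
#' @param seed integer seed; fixes every downstream table bit-for-bit.
#' @param hyperparams an [community_hyperparams()] object.
#' @return An object of class `rn_scenario`.
#' @export
simulation_scenario <- function(n_stations_per_stratum = 10,
                                distance_range_km = c(0.54, 5.1),
                                n_species = 29,
                                n_days = 49,
                                occasion_length_days = 5,
                                seed = 1L,
                                hyperparams = community_hyperparams()) {
    if (n_stations_per_stratum < 1) stop("need >= 1 station per stratum")
    if (distance_range_km[1] <= 0) stop("minimum distance must be > 0")
    if (distance_range_km[1] >= distance_range_km[2]) {
        stop("invalid distance range (min >= max)")
    }
    if (n_days < occasion_length_days) stop("n_days < occasion_length_days")
    structure(list(n_stations_per_stratum = n_stations_per_stratum,
                   distance_range_km = distance_range_km,
                   n_species = n_species, n_days = n_days,
                   occasion_length_days = occasion_length_days,
                   seed = as.integer(seed), hyperparams = hyperparams),
              class = "rn_scenario")
}

#' Simulate camera-trap stations on two hunting strata
#'
#' Draws station distances uniformly on the scenario's range and assigns
#' exactly half of the stations to each stratum (`dogs_allowed` 1/0).
#'
#' @param scenario an [simulation_scenario()] object.
#' @return data.frame with `station_id`, `dogs_allowed`, `distance_km`,
#'   `distance_scaled`.
#' @export
simulate_stations <- function(scenario) {
    stopifnot(inherits(scenario, "rn_scenario"))
    set.seed(scenario$seed)
    n <- 2L * scenario$n_stations_per_stratum
    d <- runif(n, scenario$distance_range_km[1], scenario$distance_range_km[2])
    data.frame(
        station_id = sprintf("CT%02d", seq_len(n)),
        dogs_allowed = rep(c(0L, 1L), each = scenario$n_stations_per_stratum),
        distance_km = d,
        distance_scaled = scale_distances(d)
    )
}

#' Draw species-level parameters from the community hyperdistributions
#'
#' Each species' abundance coefficient vector is drawn componentwise from
#' `Normal(mu_beta, sigma_beta)` and its baseline per-individual detection
#' parameter from `Normal(mu_detect, sigma_detect)`, all on the link scale.
#'
#' @param hyperparams an [community_hyperparams()] object.
#' @param n_species number of species, `>= 1`.
#' @param seed optional integer seed.
#' @return data.frame with `code`, `beta0`, `beta_dist`, `beta_dogs`,
#'   `beta_dist_dogs`, `logit_r`.
#' @export
draw_species_params <- function(hyperparams, n_species, seed = NULL) {
    stopifnot(inherits(hyperparams, "rn_hyperparams"), n_species >= 1)
    if (!is.null(seed)) set.seed(seed)
    B <- sapply(1:4, function(k) {
        rnorm(n_species, hyperparams$mu_beta[k], hyperparams$sigma_beta[k])
    })
    if (n_species == 1) B <- matrix(B, nrow = 1)
    data.frame(
        code = sprintf("SP%02d", seq_len(n_species)),
        beta0 = B[, 1], beta_dist = B[, 2], beta_dogs = B[, 3],
        beta_dist_dogs = B[, 4],
        logit_r = rnorm(n_species, hyperparams$mu_detect,
                        hyperparams$sigma_detect)
    )
}

# Station design matrix (intercept, scaled distance, stratum, interaction)
rn_design <- function(stations) {
    cbind(1, stations$distance_scaled, stations$dogs_allowed,
          stations$distance_scaled * stations$dogs_allowed)
}

# Species x station log-abundance under the abundance-covariate structure
rn_log_lambda <- function(species_params, stations) {
    B <- as.matrix(species_params[, c("beta0", "beta_dist", "beta_dogs",
                                      "beta_dist_dogs")])
    X <- rn_design(stations)
    L <- B %*% t(X)
    dimnames(L) <- list(species_params$code, stations$station_id)
    L
}

#' Simulate latent abundance
#'
#' Draws the latent abundance matrix `Z[i, j] ~ Poisson(lambda[i, j])` with
#' `log lambda[i, j] = beta0_i + beta_dist_i * dist_j + beta_dogs_i * dogs_j
#' + beta_dist_dogs_i * dist_j * dogs_j`.
#'
#' @param species_params as returned by [draw_species_params()].
#' @param stations as returned by [simulate_stations()] (must carry
#'   `distance_scaled`).
#' @param seed optional integer seed.
#' @return Species x station integer matrix.
#' @export
simulate_abundance <- function(species_params, stations, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    lam <- exp(rn_log_lambda(species_params, stations))
    Z <- matrix(rpois(length(lam), lam), nrow = nrow(lam),
                dimnames = dimnames(lam))
    storage.mode(Z) <- "integer"
    Z
}

#' Simulate occasion-count detection histories
#'
#' Given latent abundances, draws `Y[i, j] ~ Binomial(V_j, 1 - (1 -
#' r_i)^Z[i, j])`; cells with `Z = 0` are always 0.
#'
#' @param Z latent abundance matrix from [simulate_abundance()].
#' @param species_params species table carrying `logit_r`.
#' @param V occasions per station; scalar or per-station vector.
#' @param seed optional integer seed.
#' @return Species x station integer matrix of detection-occasion counts.
#' @export
simulate_histories <- function(Z, species_params, V, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    r <- plogis(species_params$logit_r)
    if (any(r < 0 | r > 1)) stop("'r' must lie in [0, 1]")
    if (any(V < 1)) stop("'V' must be >= 1")
    Vj <- rep(V, length.out = ncol(Z))
    p <- 1 - (1 - r)^Z                    # recycles r down columns
    Y <- matrix(rbinom(length(Z), rep(Vj, each = nrow(Z)), p),
                nrow = nrow(Z), dimnames = dimnames(Z))
    storage.mode(Y) <- "integer"
    Y
}

#' Simulate timestamped camera-trap records
#'
#' Simulates occasion-level detection from the latent abundances (each
#' occasion of station `j` detects species `i` with probability
#' `1 - (1 - r_i)^Z[i, j]`), then emits 1-3 timestamped records uniformly
#' inside each detected occasion window. Collapsing the records by occasion
#' therefore reproduces the occasion-count matrix exactly; that matrix is
#' attached as `attr(, "Y")` for round-trip checks.
#'
#' @inheritParams simulate_histories
#' @param stations station table (for ids).
#' @param occasion_calendar from [build_occasions()].
#' @param seed optional integer seed.
#' @return data.frame with `station_id`, `species_code`, `datetime`
#'   (POSIXct, UTC), carrying the generating `Y` matrix as an attribute.
#' @export
simulate_records <- function(Z, species_params, stations, occasion_calendar,
                             seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    r <- plogis(species_params$logit_r)
    nocc <- nrow(occasion_calendar)
    S <- nrow(Z); J <- ncol(Z)
    Y <- matrix(0L, S, J,
                dimnames = list(species_params$code, stations$station_id))
    rows <- vector("list", S * J)
    k <- 0
    for (i in seq_len(S)) {
        for (j in seq_len(J)) {
            p <- 1 - (1 - r[i])^Z[i, j]
            det <- which(runif(nocc) < p)
            Y[i, j] <- length(det)
            if (length(det) == 0) next
            n_per <- sample(1:3, length(det), replace = TRUE)
            occ <- rep(det, n_per)
            day <- occasion_calendar$start_day[occ] +
                runif(length(occ)) *
                (occasion_calendar$end_day[occ] -
                 occasion_calendar$start_day[occ])
            k <- k + 1
            rows[[k]] <- data.frame(
                station_id = stations$station_id[j],
                species_code = species_params$code[i],
                datetime = rn_epoch() + day * 86400
            )
        }
    }
    recs <- if (k == 0) {
        data.frame(station_id = character(), species_code = character(),
                   datetime = as.POSIXct(character(), tz = "UTC"))
    } else {
        do.call(rbind, rows[seq_len(k)])
    }
    recs <- recs[order(recs$datetime, recs$station_id, recs$species_code), ,
                 drop = FALSE]
    rownames(recs) <- NULL
    attr(recs, "Y") <- Y
    recs
}

#' Simulate a complete synthetic camera-trap study
#'
#' One-call wrapper running the full generative chain of the default study
#' design: stations, species-level parameters, latent abundances,
#' timestamped records, occasion-binned (and optionally augmented)
#' detection histories.
#'
#' @param scenario an [simulation_scenario()].
#' @param n_aug all-zero augmented species appended to the history
#'   (default 10).
#' @return list with `stations`, `species_params`, `Z`, `records`,
#'   `history` (augmented `rn_history`), `occasions`, and `truth` (the
#'   generating hyperparameters).
#' @export
simulate_community <- function(scenario = simulation_scenario(),
                               n_aug = 10) {
    stations <- simulate_stations(scenario)
    set.seed(scenario$seed + 1L)
    sp <- draw_species_params(scenario$hyperparams, scenario$n_species)
    Z <- simulate_abundance(sp, stations)
    cal <- build_occasions(0, scenario$n_days, scenario$occasion_length_days)
    records <- simulate_records(Z, sp, stations, cal)
    history <- build_history(records, stations, sp$code, cal,
                             partial_policy = "keep")
    stopifnot(identical(history$Y, attr(records, "Y")))
    history <- augment_history(history, n_aug)
    list(stations = stations, species_params = sp, Z = Z,
         records = records, history = history, occasions = cal,
         truth = scenario$hyperparams)
}
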
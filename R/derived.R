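#' Per-site species richness from one posterior draw
#'
#' Counts, at each station, the species that are both included in the
#' community (`w = 1`) and locally present (`Z >= 1`).
#'
#' @param Z species x station latent abundance matrix (one posterior draw).
#' @param w inclusion indicators (0/1), one per species row.
#' @return Named integer vector, one richness count per station.
#' @export
site_richness <- function(Z, w) {
    stopifnot(nrow(Z) == length(w), all(w %in% c(0, 1)))
    colSums((Z >= 1) & (w == 1))
}

#' Per-site aggregated relative abundance from one posterior draw
#'
#' Sums latent abundance over included species at each station:
#' `sum_i w_i * Z_ij`.
#'
#' @inheritParams site_richness
#' @return Named numeric vector per station.
#' @export
site_abundance <- function(Z, w) {
    stopifnot(nrow(Z) == length(w))
    colSums(Z * w)
}

#' Per-site aggregated biomass from one posterior draw
#'
#' Mass-weighted abundance `sum_i w_i * Z_ij * mass_i` over observed
#' species. Augmented (never-observed) species have no body mass and
#' contribute zero; an observed species missing from the trait table is an
#' error.
#'
#' @inheritParams site_richness
#' @param traits trait table with columns `code` and `mass_kg`.
#' @param augmented logical per species row; augmented rows contribute 0.
#' @return Named numeric vector of kg per station.
#' @export
site_biomass <- function(Z, w, traits, augmented = rep(FALSE, nrow(Z))) {
    stopifnot(nrow(Z) == length(w), nrow(Z) == length(augmented))
    mass <- traits$mass_kg[match(rownames(Z), traits$code)]
    missing_mass <- !augmented & is.na(mass)
    if (any(missing_mass)) {
        stop("observed species missing body mass: ",
             paste(rownames(Z)[missing_mass], collapse = ", "))
    }
    mass[augmented] <- 0
    colSums(Z * w * mass)
}

#' Derived per-draw, per-site posterior summaries
#'
#' Computes species richness, aggregated relative abundance and aggregated
#' biomass at every station for every retained posterior draw of an
#' abundance-covariate fit. These per-draw values are the responses of the
#' downstream linear mixed models.
#'
#' @param fit an `rn_fit` from [fit_msom()].
#' @param traits trait table with `code` and `mass_kg` for every observed
#'   species.
#' @return data.frame with `chain`, `draw`, `station_id`, `richness`,
#'   `abundance`, `biomass_kg` (long format, deterministic given the fit).
#' @export
derive_site_summaries <- function(fit, traits) {
    stopifnot(inherits(fit, "rn_fit"))
    out <- vector("list", length(fit$chains))
    for (cc in seq_along(fit$chains)) {
        ch <- fit$chains[[cc]]
        nk <- dim(ch$Z)[1]
        J <- dim(ch$Z)[3]
        res <- vector("list", nk)
        for (d in seq_len(nk)) {
            Zd <- matrix(ch$Z[d, , ], nrow = dim(ch$Z)[2],
                         dimnames = dimnames(ch$Z)[2:3])
            wd <- ch$w[d, ]
            res[[d]] <- data.frame(
                chain = cc, draw = d,
                station_id = colnames(Zd),
                richness = as.integer(site_richness(Zd, wd)),
                abundance = site_abundance(Zd, wd),
                biomass_kg = site_biomass(Zd, wd, traits, fit$augmented),
                row.names = NULL)
        }
        out[[cc]] <- do.call(rbind, res)
    }
    do.call(rbind, out)
}
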
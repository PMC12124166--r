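#' Standardize distances to mean 0, SD 1
#'
#' Covariates enter the models on a standardized scale to aid MCMC
#' convergence and make effect sizes comparable. Uses the sample SD
#' (`n - 1` divisor) so results are bit-reproducible.
#'
#' @param distances numeric vector with at least 2 distinct values.
#' @return Numeric vector with sample mean 0 and sample SD 1.
#' @examples
#' scale_distances(c(1, 3))  # -0.707..., +0.707...
#' @export
scale_distances <- function(distances) {
    if (length(distances) < 2) stop("need at least 2 values")
    s <- sd(distances)
    if (s == 0) stop("distances are constant; cannot standardize (zero SD)")
    (distances - mean(distances)) / s
}

#' Build an occasion calendar of fixed-length day windows
#'
#' Splits a continuous deployment of `n_days` days into consecutive
#' `[start, end)` windows of `occasion_length` days. A trailing remainder
#' shorter than `occasion_length` is emitted as a final window flagged
#' `partial`; downstream code decides whether to keep or drop it.
#'
#' @param start_day first day of deployment (numeric day offset, default 0).
#' @param n_days total deployment length in days, `>= occasion_length`.
#' @param occasion_length window length in days, `>= 1`.
#' @return data.frame with columns `occasion`, `start_day`, `end_day`
#'   (exclusive), `partial`.
#' @examples
#' build_occasions(0, 49, 5)  # 10 windows, last spans 4 days, partial
#' @export
build_occasions <- function(start_day = 0, n_days, occasion_length = 5) {
    if (occasion_length < 1 || n_days < occasion_length) {
        stop("need n_days >= occasion_length >= 1")
    }
    starts <- seq(start_day, start_day + n_days - 1e-9, by = occasion_length)
    ends <- pmin(starts + occasion_length, start_day + n_days)
    data.frame(
        occasion = seq_along(starts),
        start_day = starts,
        end_day = ends,
        partial = (ends - starts) < occasion_length
    )
}

#' Reference start of the sampling window used for timestamp arithmetic
#' @keywords internal
rn_epoch <- function() as.POSIXct("2018-07-01 00:00:00", tz = "UTC")

#' Build occasion-binned detection histories from timestamped records
#'
#' Collapses raw camera-trap records (one row per photograph/event) into the
#' species x station matrix of occasion-level detections the model consumes:
#' `Y[i, j]` counts occasions with at least one record of species `i` at
#' station `j` (multiple records within one occasion count once), and `V[j]`
#' is the number of retained occasions at station `j`.
#'
#' @param records data.frame with columns `station_id`, `species_code`,
#'   `datetime` (POSIXct or ISO-8601 string, UTC).
#' @param stations data.frame with column `station_id` (one row per station).
#' @param species character vector of species codes, or a data.frame with a
#'   `code` column; species without records appear as all-zero rows.
#' @param occasion_calendar as returned by [build_occasions()].
#' @param partial_policy `"keep"` (default) retains a trailing partial
#'   occasion; `"drop"` discards it (and any records falling in it).
#' @param start POSIXct origin that day offsets in the calendar are measured
#'   from.
#' @return An object of class `rn_history`: list with `Y` (species x station
#'   integer matrix), `V` (per-station occasion totals), `occasions` (the
#'   retained calendar), `species` (codes), `augmented` (logical per row).
#' @export
build_history <- function(records, stations, species, occasion_calendar,
                          partial_policy = c("keep", "drop"),
                          start = rn_epoch()) {
    partial_policy <- match.arg(partial_policy)
    if (is.data.frame(species)) species <- species$code
    species <- as.character(species)
    station_ids <- as.character(stations$station_id)

    cal <- occasion_calendar
    if (partial_policy == "drop") cal <- cal[!cal$partial, , drop = FALSE]

    Y <- matrix(0L, nrow = length(species), ncol = length(station_ids),
                dimnames = list(species, station_ids))

    if (nrow(records) > 0) {
        bad_st <- !(as.character(records$station_id) %in% station_ids)
        bad_sp <- !(as.character(records$species_code) %in% species)
        if (any(bad_st)) {
            stop("records reference unknown stations (rows ",
                 paste(which(bad_st), collapse = ", "), ")")
        }
        if (any(bad_sp)) {
            stop("records reference unknown species (rows ",
                 paste(which(bad_sp), collapse = ", "), ")")
        }
        dt <- records$datetime
        if (!inherits(dt, "POSIXct")) dt <- as.POSIXct(dt, tz = "UTC")
        day <- as.numeric(difftime(dt, start, units = "days"))
        out_of_window <- day < min(occasion_calendar$start_day) |
            day >= max(occasion_calendar$end_day)
        if (any(out_of_window)) {
            stop("records fall outside the sampling window (rows ",
                 paste(which(out_of_window), collapse = ", "), ")")
        }
        occ <- findInterval(day, cal$start_day)
        keep <- occ >= 1 & day < cal$end_day[pmax(occ, 1)]
        if (any(keep)) {
            hits <- unique(data.frame(
                i = match(as.character(records$species_code)[keep], species),
                j = match(as.character(records$station_id)[keep], station_ids),
                occ = occ[keep]))
            cnt <- aggregate(occ ~ i + j, data = hits, FUN = length)
            Y[cbind(cnt$i, cnt$j)] <- as.integer(cnt$occ)
        }
    }

    structure(list(
        Y = Y,
        V = setNames(rep(nrow(cal), length(station_ids)), station_ids),
        occasions = cal,
        species = species,
        augmented = rep(FALSE, length(species))
    ), class = "rn_history")
}

#' Append all-zero detection histories for potentially undetected species
#'
#' Data augmentation for community richness estimation: `n_aug` hypothetical
#' species with all-zero histories are appended, each carrying a Bernoulli
#' inclusion indicator in the model, so estimated richness can exceed the
#' observed species count.
#'
#' @param history an `rn_history`.
#' @param n_aug number of augmented all-zero rows, `>= 0`.
#' @return The augmented `rn_history`; new rows flagged in `$augmented`.
#' @export
augment_history <- function(history, n_aug) {
    stopifnot(inherits(history, "rn_history"), n_aug >= 0)
    if (n_aug == 0) return(history)
    aug_codes <- sprintf("AUG%02d", seq_len(n_aug))
    Za <- matrix(0L, nrow = n_aug, ncol = ncol(history$Y),
                 dimnames = list(aug_codes, colnames(history$Y)))
    history$Y <- rbind(history$Y, Za)
    history$species <- c(history$species, aug_codes)
    history$augmented <- c(history$augmented, rep(TRUE, n_aug))
    history
}

#' @export
print.rn_history <- function(x, ...) {
    cat(sprintf(
        "Detection history: %d species (%d augmented) x %d stations, V = %s occasions\n",
        nrow(x$Y), sum(x$augmented), ncol(x$Y),
        paste(unique(x$V), collapse = "/")))
    cat(sprintf("Total detections: %d; species with >= 1 detection: %d\n",
                sum(x$Y), sum(rowSums(x$Y) > 0)))
    invisible(x)
}

#' Focal species trait table
#'
#' Loads the shipped trait table of the 29 focal terrestrial and
#' semiterrestrial vertebrates (species code, English name, game status,
#' mean body mass in kg, whether the species was recorded by camera trap).
#'
#' @return data.frame with columns `code`, `scientific_name`,
#'   `english_name`, `game`, `mass_kg`, `recorded`.
#' @export
focal_species <- function() {
    path <- system.file("extdata", "species_traits.csv", package = "rnmsom")
    tr <- read.csv(path, stringsAsFactors = FALSE)
    tr$game <- as.logical(tr$game)
    tr$recorded <- as.logical(tr$recorded)
    tr
}
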
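#' Survey count container for repeated point counts
#'
#' Holds a ragged site x replicate x species array of nonnegative integer
#' counts together with a replicate mask. The mask distinguishes a survey
#' that took place and recorded zero birds (a real observation entering the
#' likelihood) from a replicate slot that was never surveyed (ignored by all
#' likelihoods). Sites may have anywhere from one to `dim(counts)[2]` active
#' replicates.
#'
#' @param counts nonnegative integer array, `site x replicate x species`.
#' @param replicate_mask logical matrix, `site x replicate`; `TRUE` where a
#'   survey occurred.
#' @param site_ids,species_names character labels for the first and third
#'   array dimensions.
#' @return An object of class `survey_counts`.
#' @export
survey_counts <- function(counts, replicate_mask, site_ids = NULL,
                          species_names = NULL) {
  counts <- as.array(counts)
  if (length(dim(counts)) != 3L)
    stop("`counts` must be a 3-d array (site x replicate x species)")
  if (is.null(site_ids)) site_ids <- paste0("site", seq_len(dim(counts)[1]))
  if (is.null(species_names))
    species_names <- paste0("sp", seq_len(dim(counts)[3]))
  replicate_mask <- as.matrix(replicate_mask)
  storage.mode(replicate_mask) <- "logical"
  x <- structure(
    list(counts = counts, replicate_mask = replicate_mask,
         site_ids = as.character(site_ids),
         species_names = as.character(species_names)),
    class = "survey_counts")
  validate_survey_counts(x)
  x
}

validate_survey_counts <- function(x) {
  d <- dim(x$counts)
  if (!all(dim(x$replicate_mask) == d[1:2]))
    stop("replicate_mask must be site x replicate, matching counts")
  if (length(x$site_ids) != d[1] || length(x$species_names) != d[3])
    stop("label lengths do not match count dimensions")
  if (anyDuplicated(x$species_names))
    stop("species_names must be unique")
  if (anyDuplicated(x$site_ids))
    stop("site_ids must be unique")
  active <- x$counts[rep(x$replicate_mask, times = d[3])]
  active <- active[!is.na(active)]
  if (any(active < 0)) stop("counts must be nonnegative")
  if (any(active != round(active))) stop("counts must be integers")
  if (any(rowSums(x$replicate_mask) < 1L))
    stop("every site needs at least one surveyed replicate")
  invisible(x)
}

#' @export
print.survey_counts <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf(
    "survey_counts: %d sites, up to %d replicates, %d species\n",
    d[1], d[2], d[3]))
  cat(sprintf("  surveys: %d total (%d-%d per site), %d birds counted\n",
              sum(x$replicate_mask), min(rowSums(x$replicate_mask)),
              max(rowSums(x$replicate_mask)), total_count(x)))
  invisible(x)
}

total_count <- function(x) {
  s <- 0
  for (k in seq_along(x$species_names))
    s <- s + sum(x$counts[, , k][x$replicate_mask])
  s
}

#' Number of surveyed replicates per site
#' @param x a `survey_counts` or `detection_history`.
#' @return integer vector over sites.
#' @export
n_surveys <- function(x) rowSums(x$replicate_mask)

#' Read repeated point-count data from a long-format CSV
#'
#' Expects columns `site`, `replicate`, `species`, `count` (extra columns are
#' ignored; names can be remapped through `schema`). The replicate mask is
#' `TRUE` exactly for the (site, replicate) pairs present in the file;
#' species absent from a surveyed replicate are zero-filled.
#'
#' @param path CSV file path.
#' @param schema named character vector mapping the canonical names
#'   (`site`, `replicate`, `species`, `count`) to the file's column names.
#' @return A [survey_counts] object.
#' @export
read_counts_csv <- function(path,
                            schema = c(site = "site", replicate = "replicate",
                                       species = "species", count = "count")) {
  if (!file.exists(path)) stop("counts file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("site", "replicate", "species", "count")
  missing_cols <- need[!schema[need] %in% names(df)]
  if (length(missing_cols))
    stop("counts CSV schema error: missing column(s) ",
         paste(schema[missing_cols], collapse = ", "))
  df <- df[, schema[need]]
  names(df) <- need
  if (any(is.na(df$count)) || any(df$count < 0))
    stop("counts validation error: counts must be nonnegative")
  if (any(df$count != round(df$count)))
    stop("counts validation error: counts must be integers")
  if (anyDuplicated(df[, c("site", "replicate", "species")]))
    stop("counts validation error: duplicate (site, replicate, species) row")
  site_ids <- unique(as.character(df$site))
  species <- unique(as.character(df$species))
  reps <- sort(unique(as.integer(df$replicate)))
  jmax <- max(reps)
  S <- length(site_ids); K <- length(species)
  counts <- array(0L, dim = c(S, jmax, K))
  mask <- matrix(FALSE, S, jmax)
  i <- match(as.character(df$site), site_ids)
  j <- as.integer(df$replicate)
  k <- match(as.character(df$species), species)
  mask[cbind(i, j)] <- TRUE
  counts[cbind(i, j, k)] <- as.integer(df$count)
  survey_counts(counts, mask, site_ids, species)
}

#' Write survey counts to the long CSV format `read_counts_csv` reads
#'
#' One row per surveyed (site, replicate, species) triple, zeros included,
#' so that reading the file back reproduces the object exactly.
#'
#' @param x a [survey_counts] object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_counts_csv <- function(x, path) {
  d <- dim(x$counts)
  ij <- which(x$replicate_mask, arr.ind = TRUE)
  rows <- do.call(rbind, lapply(seq_len(d[3]), function(k) {
    data.frame(site = x$site_ids[ij[, 1]], replicate = ij[, 2],
               species = x$species_names[k],
               count = x$counts[cbind(ij[, 1], ij[, 2], k)])
  }))
  rows <- rows[order(match(rows$site, x$site_ids), rows$replicate,
                     match(rows$species, x$species_names)), ]
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Site covariate table: distances to five classes of human construction
#'
#' Raw per-site distances in km to the nearest primary road, secondary road,
#' fence, human settlement, and city.
#'
#' @param df data.frame with columns `site`, `d_primary_km`,
#'   `d_secondary_km`, `d_fence_km`, `d_settlement_km`, `d_city_km`.
#' @return An object of class `site_covariates`.
#' @export
site_covariates <- function(df) {
  need <- c("site", covariate_csv_columns())
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("covariate table missing column(s): ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[, need]
  if (anyDuplicated(df$site)) stop("duplicate site ids in covariate table")
  raw <- as.matrix(df[, covariate_csv_columns()])
  if (any(!is.finite(raw))) stop("distances must be finite")
  if (any(raw < 0)) stop("distances must be nonnegative")
  structure(df, class = c("site_covariates", "data.frame"))
}

#' Read the companion covariate CSV
#' @param path CSV with columns `site`, `d_primary_km`, `d_secondary_km`,
#'   `d_fence_km`, `d_settlement_km`, `d_city_km`.
#' @return A [site_covariates] object.
#' @export
read_covariates_csv <- function(path) {
  if (!file.exists(path)) stop("covariates file not found: ", path)
  site_covariates(read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_covariates_csv
#' @param x a [site_covariates] object.
#' @export
write_covariates_csv <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Standardize the distance covariates to mean 0, sample SD 1
#'
#' Centers and scales each distance column (divisor n - 1), storing the
#' constants so raw and standardized scales round-trip exactly. Standardized
#' distances make the five coefficients directly comparable, and give the
#' sign convention used throughout: a negative coefficient means the
#' response increases with proximity to that feature class.
#'
#' @param cov a [site_covariates] object with at least 2 sites.
#' @return An object of class `site_covariates_std`: the raw table plus a
#'   standardized design matrix `X` (columns named after
#'   `covariate_classes()`) and the `center`/`scale` constants.
#' @export
standardize_covariates <- function(cov) {
  stopifnot(inherits(cov, "site_covariates"))
  if (nrow(cov) < 2) stop("need at least 2 sites to standardize")
  raw <- as.matrix(as.data.frame(cov)[, covariate_csv_columns()])
  colnames(raw) <- covariate_classes()
  ctr <- colMeans(raw)
  scl <- apply(raw, 2, sd)          # divisor n - 1
  degenerate <- scl == 0
  if (any(degenerate))
    stop("degenerate covariate (constant column): ",
         paste(covariate_classes()[degenerate], collapse = ", "))
  X <- sweep(sweep(raw, 2, ctr), 2, scl, "/")
  structure(
    list(site = as.character(cov$site), raw = raw, X = X,
         center = ctr, scale = scl),
    class = "site_covariates_std")
}

#' Map standardized covariates back to raw distances in km
#' @param std a `site_covariates_std` object.
#' @return matrix of raw distances.
#' @export
unstandardize_covariates <- function(std) {
  stopifnot(inherits(std, "site_covariates_std"))
  sweep(sweep(std$X, 2, std$scale, "*"), 2, std$center, "+")
}

#' Reduce counts to detection/non-detection histories
#'
#' The multi-species occupancy model uses only whether a species was
#' recorded on a survey, not how many individuals: `detections = 1`
#' wherever `counts > 0`. The replicate mask is preserved.
#'
#' @param x a [survey_counts] object.
#' @return An object of class `detection_history` with a binary
#'   `detections` array and the same mask and labels.
#' @export
binarize <- function(x) {
  stopifnot(inherits(x, "survey_counts") || inherits(x, "detection_history"))
  det <- array(as.integer(x[[1]] > 0), dim = dim(x[[1]]))
  structure(
    list(detections = det, replicate_mask = x$replicate_mask,
         site_ids = x$site_ids, species_names = x$species_names),
    class = "detection_history")
}

#' @export
print.detection_history <- function(x, ...) {
  d <- dim(x$detections)
  cat(sprintf(
    "detection_history: %d sites, up to %d replicates, %d species\n",
    d[1], d[2], d[3]))
  invisible(x)
}

# Detections per site x species, counting surveyed replicates only.
detection_totals <- function(dh) {
  d <- dim(dh$detections)
  out <- matrix(0L, d[1], d[3], dimnames = list(dh$site_ids, dh$species_names))
  for (k in seq_len(d[3]))
    out[, k] <- rowSums(matrix(dh$detections[, , k], d[1], d[2]) *
                          dh$replicate_mask)
  out
}

#' Select one species (or the cross-species total) as single-species counts
#'
#' For the N-mixture models: either slices one species' counts, or sums all
#' species' counts within each (site, replicate) for the total-abundance
#' model.
#'
#' @param x a [survey_counts] object.
#' @param species a species name present in `x$species_names`, or `"total"`.
#' @return A [survey_counts] with one species dimension.
#' @export
select_species <- function(x, species) {
  stopifnot(inherits(x, "survey_counts"))
  d <- dim(x$counts)
  if (identical(species, "total")) {
    m <- apply(x$counts, c(1, 2), sum)
    return(survey_counts(array(m, dim = c(d[1], d[2], 1)),
                         x$replicate_mask, x$site_ids, "total"))
  }
  k <- match(species, x$species_names)
  if (is.na(k)) stop("unknown species: ", species)
  survey_counts(x$counts[, , k, drop = FALSE], x$replicate_mask,
                x$site_ids, species)
}
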
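#' Read and validate a site-by-species community matrix
#'
#' The first CSV column is the site ID; remaining columns are species
#' abundances (non-negative numbers). Species columns whose total abundance
#' is zero carry no information for any structure metric and are dropped
#' with a warning. A site with no individuals at all is an error: such a
#' "community" has no defined structure.
#'
#' @param path Path to a CSV file (header row, UTF-8).
#' @return A numeric matrix, sites in rows, species in columns.
#' @export
read_community <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("community table needs at least one species column",
                          call. = FALSE)
  sites <- as.character(raw[[1]])
  m <- as.matrix(raw[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(raw[-1], is.numeric, TRUE))
    stop("non-numeric abundance column(s): ",
         paste(names(raw)[-1][bad], collapse = ", "), call. = FALSE)
  }
  rownames(m) <- sites
  as_community_matrix(m)
}

#' Validate a community matrix held in memory
#'
#' @param m Numeric matrix, sites in rows (rownames), species in columns
#'   (colnames), non-negative abundances.
#' @return The validated matrix, with all-zero species columns dropped.
#' @export
as_community_matrix <- function(m) {
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("community matrix needs site rownames and species colnames",
         call. = FALSE)
  if (anyDuplicated(rownames(m))) stop("duplicate site IDs", call. = FALSE)
  if (anyDuplicated(colnames(m))) stop("duplicate species names", call. = FALSE)
  if (any(!is.finite(m))) stop("non-finite abundances", call. = FALSE)
  neg <- which(m < 0, arr.ind = TRUE)
  if (nrow(neg))
    stop("negative abundance at site '", rownames(m)[neg[1, 1]],
         "', species '", colnames(m)[neg[1, 2]], "'", call. = FALSE)
  empty <- rowSums(m) == 0
  if (any(empty))
    stop("site(s) with no individuals: ",
         paste(rownames(m)[empty], collapse = ", "), call. = FALSE)
  zero_sp <- colSums(m) == 0
  if (any(zero_sp)) {
    warning("dropping all-zero species column(s): ",
            paste(colnames(m)[zero_sp], collapse = ", "))
    m <- m[, !zero_sp, drop = FALSE]
  }
  m
}

#' Read a species trait table
#'
#' Expects columns `species`, `wing_mm`, `beak_mm`, `tarsus_mm`, `mass_g`
#' (further numeric trait columns are accepted). All values must be finite
#' and positive; missing values are rejected rather than pairwise-deleted,
#' since with a handful of traits silent deletion would distort Gower
#' distances.
#'
#' @param path CSV path.
#' @param log_mass Log10-transform the `mass_g` column (off by default).
#' @return Numeric matrix, species in rows, traits in columns.
#' @export
read_traits <- function(path, log_mass = FALSE) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"species" %in% names(raw)) stop("trait table needs a 'species' column",
                                       call. = FALSE)
  m <- as.matrix(raw[, setdiff(names(raw), "species"), drop = FALSE])
  rownames(m) <- raw$species
  if (anyDuplicated(rownames(m))) stop("duplicate species in trait table",
                                       call. = FALSE)
  if (!is.numeric(m) || any(!is.finite(m)))
    stop("trait table has missing or non-numeric values", call. = FALSE)
  if (any(m <= 0)) stop("trait values must be positive", call. = FALSE)
  if (log_mass && "mass_g" %in% colnames(m))
    m[, "mass_g"] <- log10(m[, "mass_g"])
  m
}

#' Assign sites to biogeographic regions by longitude
#'
#' Sites are binned into the three realms of the study gradient by
#' decimal-degree longitude, using half-open bins: west `[111, 113)`,
#' center `[113, 115)`, east `[115, 117)`.
#'
#' @param longitudes Named numeric vector of decimal degrees E per site.
#' @return Named character vector of region labels (`west`/`center`/`east`).
#' @export
assign_regions <- function(longitudes) {
  if (is.null(names(longitudes))) stop("longitudes must be named by site",
                                       call. = FALSE)
  out_of_range <- longitudes < 111 | longitudes >= 117
  if (any(out_of_range))
    stop("longitude outside [111, 117) for site(s): ",
         paste(names(longitudes)[out_of_range], collapse = ", "), call. = FALSE)
  breaks <- c(111, 113, 115, 117)
  labs <- c("west", "center", "east")
  setNames(labs[findInterval(longitudes, breaks)], names(longitudes))
}

#' Gower dissimilarity matrix on continuous traits
#'
#' `d(i, j)` is the mean over traits of the absolute difference scaled by
#' the observed trait range, so every entry lies in `[0, 1]` and every
#' trait contributes with equal weight. A trait with zero observed range
#' carries no information and is an error.
#'
#' @param traits Numeric matrix, species in rows, traits in columns.
#' @return Symmetric species-by-species dissimilarity matrix in `[0, 1]`.
#' @export
gower_matrix <- function(traits) {
  if (!is.matrix(traits)) traits <- as.matrix(traits)
  if (nrow(traits) < 2) stop("need at least 2 species", call. = FALSE)
  if (is.null(rownames(traits))) stop("traits must have species rownames",
                                      call. = FALSE)
  if (any(!is.finite(traits))) stop("non-finite trait values", call. = FALSE)
  rng <- apply(traits, 2, function(x) diff(range(x)))
  if (any(rng == 0))
    stop("zero-range trait(s): ",
         paste(colnames(traits)[rng == 0], collapse = ", "), call. = FALSE)
  scaled <- sweep(traits, 2, rng, "/")
  d <- matrix(0, nrow(traits), nrow(traits),
              dimnames = list(rownames(traits), rownames(traits)))
  for (k in seq_len(ncol(scaled)))
    d <- d + abs(outer(scaled[, k], scaled[, k], "-"))
  d / ncol(scaled)
}

#' Read site metadata (site, longitude)
#' @param path CSV path with columns `site` and `longitude`.
#' @return Named numeric vector of longitudes.
#' @export
read_sites <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("site", "longitude") %in% names(raw)))
    stop("site table needs 'site' and 'longitude' columns", call. = FALSE)
  setNames(as.numeric(raw$longitude), as.character(raw$site))
}

#' Read a site-by-month climate table
#' @param path CSV with columns `site`, `m01`..`m12` (monthly mean temperature, degrees C).
#' @return Numeric matrix, sites in rows, 12 month columns.
#' @export
read_climate <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  months <- sprintf("m%02d", 1:12)
  if (!all(c("site", months) %in% names(raw)))
    stop("climate table needs 'site' and 'm01'..'m12' columns", call. = FALSE)
  m <- as.matrix(raw[, months])
  rownames(m) <- raw$site
  if (any(!is.finite(m))) stop("non-finite temperatures", call. = FALSE)
  m
}
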
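#' Equal-volume zone boundaries in normalized distance
#'
#' The nucleus is modeled as a sphere of radius R; spots are scored by
#' `d = distance-to-periphery / R`. Cutting the ball into `n` concentric
#' shells of equal volume puts the k-th boundary at
#' `d_k = 1 - ((n - k)/n)^(1/3)`, k = 1..n-1. For n = 3 the cutoffs are
#' `1 - (2/3)^(1/3)` and `1 - (1/3)^(1/3)`.
#'
#' @param n_zones number of zones (>= 1); zone 1 is the most peripheral.
#' @return numeric vector of `n_zones - 1` cutoffs in normalized distance.
#' @export
zone_boundaries <- function(n_zones) {
  if (!is.numeric(n_zones) || length(n_zones) != 1 || n_zones < 1 ||
      n_zones != round(n_zones)) {
    stop("n_zones must be a single integer >= 1")
  }
  k <- seq_len(n_zones - 1)
  1 - ((n_zones - k) / n_zones)^(1 / 3)
}

#' Assign spots to equal-volume zones
#'
#' `d = distance / radius`; the zone is the smallest k with `d <= cutoff_k`,
#' else zone `n_zones`. Boundary values belong to the more peripheral
#' (lower-index) zone.
#'
#' @param distance spot-to-periphery distance(s), same units as `radius`.
#' @param radius nuclear radius (scalar or per-spot vector); > 0.
#' @param n_zones number of zones (default 3).
#' @return integer zone indices, 1 (peripheral) to `n_zones` (central).
#' @export
assign_zone <- function(distance, radius, n_zones = 3) {
  if (any(radius <= 0)) stop("nuclear radius must be > 0")
  d <- distance / radius
  if (any(d < 0)) stop("negative spot-to-periphery distance")
  if (any(d > 1 + 1e-9)) {
    stop("normalized distance > 1: spot beyond the nuclear center (check ",
         "that distances are to the periphery and radii match)")
  }
  d <- pmin(d, 1)
  cuts <- zone_boundaries(n_zones)
  if (length(cuts) == 0) return(rep(1L, length(d)))
  as.integer(rowSums(outer(d, cuts, ">")) + 1L)
}

#' Read a spot-measurement table
#'
#' TSV with columns `cell_id`, `strain`, `radius_um`, `distance_um`
#' (distance from spot center to the nuclear periphery, radius of the same
#' nucleus; distances are normalized by the radius downstream).
#'
#' @param path TSV path.
#' @return validated data.frame.
#' @export
read_spots <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  validate_spots(tab)
}

validate_spots <- function(tab) {
  need <- c("cell_id", "strain", "radius_um", "distance_um")
  if (!all(need %in% names(tab))) {
    stop("spot table needs columns ", paste(need, collapse = ", "))
  }
  if (any(tab$radius_um <= 0)) stop("nuclear radius must be > 0")
  if (any(tab$distance_um < 0) || any(tab$distance_um > tab$radius_um)) {
    stop("spot distances must satisfy 0 <= distance <= radius")
  }
  tab
}

#' Zone count table per strain
#'
#' @param spots spot-measurement data.frame (see [read_spots()]).
#' @param n_zones number of equal-volume zones (default 3).
#' @return integer matrix, strains x zones, with zone columns
#'   `zone1..zoneN` (1 = peripheral); attribute `n_zones`.
#' @export
zone_table <- function(spots, n_zones = 3) {
  spots <- validate_spots(spots)
  zone <- assign_zone(spots$distance_um, spots$radius_um, n_zones)
  tab <- table(factor(spots$strain, levels = unique(spots$strain)),
               factor(zone, levels = seq_len(n_zones)))
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = list(rownames(tab), paste0("zone", seq_len(n_zones))))
  attr(m, "n_zones") <- n_zones
  m
}

#' Zone percentages per strain
#'
#' @param table zone count matrix from [zone_table()].
#' @return matrix of row percentages (each row sums to 100).
#' @export
zone_percentages <- function(table) {
  100 * sweep(table, 1, rowSums(table), "/")
}

#' Two-sided chi-square comparison of two strains' zone distributions
#'
#' Pearson chi-square on the 2 x n_zones contingency table, no continuity
#' correction, `df = n_zones - 1`.
#'
#' @param table zone count matrix from [zone_table()].
#' @param strain_a,strain_b row names of the two strains to compare.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
chi_square_test <- function(table, strain_a, strain_b) {
  for (s in c(strain_a, strain_b)) {
    if (!s %in% rownames(table)) {
      stop("strain '", s, "' not in table; available: ",
           paste(rownames(table), collapse = ", "))
    }
  }
  m <- table[c(strain_a, strain_b), , drop = FALSE]
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected == 0)) {
    stop("zero expected count; pool adjacent zones before testing")
  }
  ht <- stats::chisq.test(m, correct = FALSE)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value))
}
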
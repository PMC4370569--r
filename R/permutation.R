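#' Mean-difference statistic between member and non-member probes
#'
#' `mean(values[mask]) - mean(values[!mask])`, the effect size the circular
#' permutation null is computed for.
#'
#' @param values numeric per-probe signal values.
#' @param mask logical membership mask of the same length.
#' @return the mean difference, in signal units.
#' @export
mean_diff_statistic <- function(values, mask) {
  if (length(values) != length(mask)) stop("values and mask lengths differ")
  if (!any(mask) || all(mask)) {
    stop("degenerate mask: need at least one member and one non-member")
  }
  mean(values[mask]) - mean(values[!mask])
}

# Split probe indices by chromosome, preserving input order within each.
split_by_chrom <- function(n, chrom) {
  if (is.null(chrom)) return(list(all = seq_len(n)))
  chrom <- as.character(chrom)
  if (length(chrom) != n) stop("chrom labels must match probe count")
  split(seq_len(n), factor(chrom, levels = unique(chrom)))
}

#' Circularly shift a membership mask
#'
#' Within each chromosome, member labels are rotated forward by that
#' chromosome's offset over the probe index; values stay fixed. Membership
#' cardinality is conserved per chromosome.
#'
#' @param mask logical membership mask.
#' @param offsets integer offsets, one per chromosome (in chromosome order
#'   of appearance), each in `[0, n_probes_on_chromosome)`.
#' @param chrom per-probe chromosome labels; `NULL` treats the whole mask as
#'   one chromosome.
#' @return the rotated mask.
#' @export
circular_shift <- function(mask, offsets, chrom = NULL) {
  idx <- split_by_chrom(length(mask), chrom)
  if (length(offsets) != length(idx)) {
    stop("need one offset per chromosome (", length(idx), "), got ",
         length(offsets))
  }
  out <- mask
  for (j in seq_along(idx)) {
    ii <- idx[[j]]
    n <- length(ii)
    o <- offsets[j]
    if (o < 0 || o >= n) {
      if (o == n) o <- 0L  # full cycle is the identity
      else stop("offset ", o, " out of range [0, ", n, ") for chromosome ",
                names(idx)[j])
    }
    out[ii] <- mask[ii][((seq_len(n) - 1 - o) %% n) + 1]
  }
  out
}

# Shared machinery: per-chromosome member positions and values, plus the
# constants needed to turn member sums into mean-difference statistics.
perm_setup <- function(values, mask, chrom, mode) {
  if (length(values) != length(mask)) stop("values and mask lengths differ")
  if (!any(mask) || all(mask)) {
    stop("degenerate mask: need at least one member and one non-member")
  }
  if (mode == "joint") chrom <- NULL
  idx <- split_by_chrom(length(values), chrom)
  list(
    idx = idx,
    values = lapply(idx, function(ii) values[ii]),
    pos = lapply(idx, function(ii) which(mask[ii])),
    n = vapply(idx, length, integer(1)),
    k_total = sum(mask),
    s_total = sum(values),
    n_total = length(values)
  )
}

stat_from_member_sum <- function(m, setup) {
  k <- setup$k_total
  m / k - (setup$s_total - m) / (setup$n_total - k)
}

# Member sum on one chromosome for a vector of offsets, chunked to bound
# memory at ~2e6 matrix cells.
member_sums_for_offsets <- function(vals, pos, n, offsets) {
  k <- length(pos)
  if (k == 0) return(numeric(length(offsets)))
  out <- numeric(length(offsets))
  chunk <- max(1L, as.integer(2e6 / k))
  for (from in seq(1, length(offsets), by = chunk)) {
    to <- min(from + chunk - 1L, length(offsets))
    idx <- (outer(pos - 1L, offsets[from:to], "+") %% n) + 1L
    m <- vals[idx]
    dim(m) <- dim(idx)
    out[from:to] <- colSums(m)
  }
  out
}

count_extreme <- function(null_stats, observed, alternative) {
  tol <- 1e-12 * max(1, abs(observed))
  switch(alternative,
    greater = sum(null_stats >= observed - tol),
    less = sum(null_stats <= observed + tol),
    two_sided = sum(abs(null_stats) >= abs(observed) - tol),
    stop("unknown alternative: ", alternative)
  )
}

perm_result <- function(observed, null_stats, n_perm, p, alternative, seed,
                        mode, exhaustive) {
  structure(
    list(observed_stat = observed, null_stats = null_stats,
         n_permutations = n_perm, p_value = p, alternative = alternative,
         seed = seed, mode = mode, exhaustive = exhaustive),
    class = "nucorg_permtest"
  )
}

#' @export
print.nucorg_permtest <- function(x, ...) {
  cat(if (x$exhaustive) "Exhaustive" else "Sampled",
      "circular permutation test\n")
  cat("  observed mean difference:", format(x$observed_stat, digits = 4), "\n")
  cat("  permutations:", x$n_permutations,
      if (!x$exhaustive) paste0("(seed ", x$seed, ")") else "", "\n")
  cat("  alternative:", x$alternative, "  p =",
      format(x$p_value, digits = 4), "\n")
  invisible(x)
}

#' Circular permutation test for class enrichment
#'
#' Tests whether member probes (e.g. probes over subtelomeres or tRNA genes)
#' carry higher signal than the rest of the genome, against a positional
#' null that rotates the membership labels circularly along each chromosome.
#' Rotation preserves the signal's spatial autocorrelation while breaking
#' the feature-signal alignment. One independent uniform offset is drawn per
#' chromosome per permutation;
#' `p = (1 + #extreme null stats) / (n_permutations + 1)`.
#'
#' @param values numeric per-probe signal values (typically log2 ratios
#'   after uniqueness filtering).
#' @param mask logical membership mask.
#' @param chrom per-probe chromosome labels; `NULL` = single chromosome.
#' @param n_permutations number of sampled rotations (default 1000).
#' @param alternative `"two_sided"` (on the absolute statistic), `"greater"`
#'   or `"less"`.
#' @param seed integer seed for reproducibility; the global RNG state is
#'   restored on exit.
#' @param mode `"per_chromosome"` rotates each chromosome independently;
#'   `"joint"` applies a single offset to the concatenated genome.
#' @return object of class `nucorg_permtest`.
#' @seealso [exhaustive_test()] for the exact enumeration used as oracle.
#' @export
permutation_test <- function(values, mask, chrom = NULL,
                             n_permutations = 1000,
                             alternative = c("two_sided", "greater", "less"),
                             seed = NULL,
                             mode = c("per_chromosome", "joint")) {
  alternative <- match.arg(alternative)
  mode <- match.arg(mode)
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  setup <- perm_setup(values, mask, chrom, mode)
  observed <- mean_diff_statistic(values, mask)
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  msum <- numeric(n_permutations)
  for (j in seq_along(setup$idx)) {
    offs <- sample.int(setup$n[j], n_permutations, replace = TRUE) - 1L
    msum <- msum + member_sums_for_offsets(setup$values[[j]], setup$pos[[j]],
                                           setup$n[j], offs)
  }
  null_stats <- stat_from_member_sum(msum, setup)
  b <- count_extreme(null_stats, observed, alternative)
  perm_result(observed, null_stats, n_permutations,
              (1 + b) / (n_permutations + 1), alternative, seed, mode,
              exhaustive = FALSE)
}

#' Exhaustive circular permutation test
#'
#' Enumerates every combination of per-chromosome offsets exactly once
#' (including the identity, which always counts itself as extreme, so
#' `p >= 1/total`). Serves as the exact oracle for [permutation_test()].
#'
#' @inheritParams permutation_test
#' @param max_combinations refuse to enumerate more than this many offset
#'   combinations (default 1e6).
#' @return object of class `nucorg_permtest` with `n_permutations` equal to
#'   the number of enumerated combinations.
#' @export
exhaustive_test <- function(values, mask, chrom = NULL,
                            alternative = c("two_sided", "greater", "less"),
                            max_combinations = 1e6,
                            mode = c("per_chromosome", "joint")) {
  alternative <- match.arg(alternative)
  mode <- match.arg(mode)
  setup <- perm_setup(values, mask, chrom, mode)
  total <- prod(setup$n)
  if (total > max_combinations) {
    stop("exhaustive enumeration needs ", format(total, big.mark = ","),
         " combinations (> ", format(max_combinations, big.mark = ","),
         "); use permutation_test() instead")
  }
  observed <- mean_diff_statistic(values, mask)
  msum <- 0
  for (j in seq_along(setup$idx)) {
    per_chrom <- member_sums_for_offsets(setup$values[[j]], setup$pos[[j]],
                                         setup$n[j], seq_len(setup$n[j]) - 1L)
    msum <- as.vector(outer(msum, per_chrom, "+"))
  }
  null_stats <- stat_from_member_sum(msum, setup)
  b <- count_extreme(null_stats, observed, alternative)
  perm_result(observed, null_stats, as.integer(total), b / total,
              alternative, seed = NULL, mode, exhaustive = TRUE)
}

#' Circular permutation test on a probe track
#'
#' Convenience wrapper: extracts values and chromosome labels from a probe
#' track and runs [permutation_test()].
#'
#' @param track probe track (run [filter_unique()] first for inference).
#' @param mask logical membership mask aligned with the track.
#' @param ... passed to [permutation_test()].
#' @export
permutation_test_track <- function(track, mask, ...) {
  permutation_test(track$score, mask,
                   chrom = as.character(GenomeInfoDb::seqnames(track)), ...)
}
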
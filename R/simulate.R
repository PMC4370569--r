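# Run code with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  force(code)
}

#' Default synthetic feature plan
#'
#' Counts and lengths chosen to mirror the scale of the real annotation
#' classes the pipeline summarizes (tRNA genes ~80 bp, LTR elements a few
#' hundred bp, 5S rRNA genes ~120 bp) on a toy genome.
#'
#' @return data.frame with columns `class`, `n`, `length`, `placement`
#'   (`"uniform"` or `"subtelomere_border"`).
#' @export
default_feature_plan <- function() {
  data.frame(
    class = c("tRNA", "LTR", "5S_rRNA"),
    n = c(20L, 15L, 5L),
    length = c(80L, 350L, 120L),
    placement = c("uniform", "uniform", "uniform"),
    stringsAsFactors = FALSE
  )
}

#' Simulate an annotated toy genome
#'
#' Builds a genome layout, places subtelomeric domains at both ends of each
#' chromosome, and places the planned feature classes without overlap
#' (uniformly at random, or abutting the inner subtelomere borders for
#' `placement = "subtelomere_border"`, mirroring the association of LTR
#' elements with subtelomeric boundaries). Deterministic under `seed`.
#'
#' @param chromosomes named numeric vector of chromosome lengths (bp).
#' @param feature_plan data.frame as in [default_feature_plan()].
#' @param subtelomere_length bp of subtelomeric domain per chromosome end
#'   (0 disables them).
#' @param seed integer seed.
#' @param out_dir if non-`NULL`, writes `annotation.gff3`,
#'   `subtelomeres.bed` and `features.tsv` there.
#' @return list with `layout` (Seqinfo), `features` (feature `GRanges`,
#'   subtelomeres included) and `files` (paths written, or `NULL`).
#' @export
make_genome_and_features <- function(chromosomes = c(chrA = 100000,
                                                     chrB = 100000),
                                     feature_plan = default_feature_plan(),
                                     subtelomere_length = 10000,
                                     seed = 1, out_dir = NULL) {
  layout <- genome_layout(chromosomes)
  chr <- GenomeInfoDb::seqnames(layout)
  len <- GenomeInfoDb::seqlengths(layout)
  subtel <- NULL
  if (subtelomere_length > 0) {
    if (any(len < 2 * subtelomere_length)) {
      stop("chromosomes shorter than two subtelomeric domains")
    }
    subtel <- GenomicRanges::GRanges(
      seqnames = rep(chr, each = 2),
      ranges = IRanges::IRanges(
        start = as.vector(rbind(1, len - subtelomere_length + 1)),
        width = subtelomere_length
      )
    )
  }
  occupied <- lapply(stats::setNames(as.list(chr), chr), function(cn) {
    if (is.null(subtel)) IRanges::IRanges() else
      IRanges::ranges(subtel[GenomeInfoDb::seqnames(subtel) == cn])
  })
  feats <- with_seed(seed, {
    rows <- list()
    for (pi in seq_len(nrow(feature_plan))) {
      cls <- feature_plan$class[pi]
      flen <- feature_plan$length[pi]
      placement <- feature_plan$placement[pi]
      for (fi in seq_len(feature_plan$n[pi])) {
        placed <- FALSE
        for (attempt in 1:200) {
          cn <- sample(chr, 1, prob = len)
          if (placement == "subtelomere_border" && !is.null(subtel)) {
            # within 2 kb inside of a subtelomere's inner border
            side <- sample(1:2, 1)
            start <- if (side == 1) subtelomere_length + sample.int(2000, 1)
              else len[cn] - subtelomere_length - flen + 1L - sample.int(2000, 1)
          } else {
            start <- sample.int(len[cn] - flen + 1L, 1)
          }
          cand <- IRanges::IRanges(start = start, width = flen)
          if (BiocGenerics::end(cand) > len[cn]) next
          if (sum(IRanges::countOverlaps(cand, occupied[[cn]])) == 0) {
            occupied[[cn]] <- c(occupied[[cn]], cand)
            rows[[length(rows) + 1]] <- data.frame(
              chrom = cn, start = start, end = start + flen - 1L,
              class = cls, stringsAsFactors = FALSE)
            placed <- TRUE
            break
          }
        }
        if (!placed) {
          frac <- vapply(occupied, function(r) sum(BiocGenerics::width(r)),
                         numeric(1)) / len
          stop("could not place ", cls, " feature without overlap; ",
               "occupied fraction per chromosome: ",
               paste(sprintf("%s=%.2f", names(frac), frac), collapse = ", "))
        }
      }
    }
    do.call(rbind, rows)
  })
  fs_list <- list()
  if (!is.null(subtel)) {
    sg <- subtel
    sg$feature_class <- rep("subtelomere", length(sg))
    sg$id <- paste0("subtel_", seq_along(sg))
    fs_list$subtel <- sg
  }
  if (!is.null(feats)) {
    fg <- GenomicRanges::GRanges(
      seqnames = feats$chrom,
      ranges = IRanges::IRanges(start = feats$start, end = feats$end)
    )
    fg$feature_class <- feats$class
    fg$id <- paste0(feats$class, "_", stats::ave(seq_len(nrow(feats)),
                                                 feats$class, FUN = seq_along))
    fs_list$feats <- fg
  }
  fs <- if (length(fs_list) > 0) suppressWarnings(do.call(c, unname(fs_list)))
        else GenomicRanges::GRanges()
  fs <- BiocGenerics::sort(check_against_layout(fs, layout, "feature"),
                           ignore.strand = TRUE)
  fs <- validate_features(fs)
  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    gff <- file.path(out_dir, "annotation.gff3")
    write_gff3(fs, gff)
    bed <- file.path(out_dir, "subtelomeres.bed")
    sub_fs <- fs[fs$feature_class == "subtelomere"]
    rtracklayer::export(GenomicRanges::granges(sub_fs), bed, format = "BED")
    tsv <- file.path(out_dir, "features.tsv")
    write_features_tsv(fs, tsv)
    files <- c(gff3 = gff, bed = bed, tsv = tsv)
  }
  list(layout = layout, features = fs, files = files)
}

#' Write a feature set as GFF3
#'
#' @param fs feature set.
#' @param path output path.
#' @export
write_gff3 <- function(fs, path) {
  out <- GenomicRanges::granges(fs)
  out$source <- rep("nucorg", length(fs))
  out$type <- fs$feature_class
  out$ID <- fs$id
  rtracklayer::export(out, path, format = "gff3")
  invisible(path)
}

# Stationary AR(1) series: marginal sd `sd`, lag-1 autocorrelation `rho`.
ar1_series <- function(n, sd, rho) {
  x0 <- stats::rnorm(1, 0, sd)
  e <- stats::rnorm(n, 0, sd * sqrt(1 - rho^2))
  as.numeric(stats::filter(e, rho, method = "recursive", init = x0))
}

#' Simulate paired probe tracks with a class effect
#'
#' Tiles each chromosome with fixed-step probes and simulates a control
#' track, a condition track and their log2 ratio. Per chromosome the ratio
#' follows a stationary lag-1 autoregressive process (marginal sd `sd`,
#' autocorrelation `rho`) — the minimal model of tiling-probe spatial
#' autocorrelation — with an additive effect `effect` (log2 units) on probes
#' overlapping the target classes. The condition track is
#' `control * 2^ratio`, so [log2_ratio()] recovers the simulated ratio
#' exactly.
#'
#' @param layout genome layout.
#' @param fs feature set (used for the target mask).
#' @param target_classes classes receiving the effect; `NULL` or `effect =
#'   0` gives a pure null track.
#' @param effect additive class effect on the log2 ratio.
#' @param probe_step probe spacing and width, bp (default 60).
#' @param baseline log2 baseline of the control track.
#' @param sd marginal standard deviation of the AR(1) noise.
#' @param rho lag-1 autocorrelation in `[0, 1)`.
#' @param seed integer seed.
#' @return list with probe tracks `condition`, `control`, `ratio`, and the
#'   logical `mask` of target-class probes.
#' @export
simulate_probe_signal <- function(layout, fs, target_classes = NULL,
                                  effect = 0, probe_step = 60, baseline = 8,
                                  sd = 0.5, rho = 0.7, seed = 1) {
  stopifnot(probe_step >= 1, sd > 0, rho >= 0, rho < 1)
  chr <- GenomeInfoDb::seqnames(layout)
  len <- GenomeInfoDb::seqlengths(layout)
  grl <- lapply(chr, function(cn) {
    starts <- seq(1L, len[cn] - probe_step + 1L, by = probe_step)
    GenomicRanges::GRanges(cn, IRanges::IRanges(start = starts,
                                                width = probe_step))
  })
  grid <- suppressWarnings(do.call(c, grl))
  grid <- check_against_layout(grid, layout, "probe")
  n_per <- vapply(grl, length, integer(1))
  sig <- with_seed(seed, {
    ratio_noise <- unlist(lapply(n_per, ar1_series, sd = sd, rho = rho))
    control_log <- baseline + unlist(lapply(n_per, ar1_series, sd = sd,
                                            rho = rho))
    list(ratio_noise = ratio_noise, control_log = control_log)
  })
  mask <- if (!is.null(target_classes) && length(fs) > 0) {
    probes_overlapping(fs, grid, target_classes)
  } else rep(FALSE, length(grid))
  ratio_val <- sig$ratio_noise + effect * mask
  mk <- function(score) {
    tr <- grid
    tr$score <- score
    tr$unique <- rep(TRUE, length(tr))
    tr
  }
  list(condition = mk(2^(sig$control_log + ratio_val)),
       control = mk(2^sig$control_log),
       ratio = mk(ratio_val),
       mask = mask)
}

#' Simulate a paired occupancy table
#'
#' Condition A counts are negative binomial with mean `mu` and dispersion
#' `size = dispersion`; condition B uses mean `fold * mu`. `dispersion =
#' Inf` gives the Poisson limit.
#'
#' @param fs feature set whose ids/classes label the rows, or `NULL` to
#'   generate `n_features` anonymous features.
#' @param class_label restrict `fs` to one class / label generated rows.
#' @param n_features number of rows when `fs` is `NULL`.
#' @param mu mean occupancy in condition A (> 0).
#' @param dispersion negative-binomial size parameter (default 10).
#' @param fold mean ratio B/A (> 0); 1 is the paired null.
#' @param seed integer seed.
#' @return occupancy table data.frame (`id`, `class`, `occ_a`, `occ_b`).
#' @export
simulate_occupancy <- function(fs = NULL, class_label = "LTR",
                               n_features = 100, mu = 100, dispersion = 10,
                               fold = 1, seed = 1) {
  stopifnot(mu > 0, fold > 0, dispersion > 0)
  if (!is.null(fs)) {
    if (!is.null(class_label)) fs <- fs[fs$feature_class %in% class_label]
    ids <- fs$id
    cls <- fs$feature_class
  } else {
    ids <- paste0(class_label, "_", seq_len(n_features))
    cls <- rep(class_label, n_features)
  }
  n <- length(ids)
  if (n == 0) stop("no features to simulate occupancy for")
  draw <- function(m) {
    if (is.finite(dispersion)) stats::rnbinom(n, size = dispersion, mu = m)
    else stats::rpois(n, m)
  }
  with_seed(seed, {
    tab <- data.frame(id = ids, class = cls,
                      occ_a = as.numeric(draw(mu)),
                      occ_b = as.numeric(draw(fold * mu)),
                      stringsAsFactors = FALSE)
    validate_occupancy_table(tab)
  })
}

#' Simulate nuclear spot measurements
#'
#' Draws each spot's zone from the given zone probabilities, then its
#' normalized distance-to-periphery uniformly over that zone's
#' volume-weighted radial density (inverse CDF of the r^2 density), so
#' `zone_probs = "uniform"` is exactly uniform in the ball. Nuclear radii
#' are uniform over `radius_range`.
#'
#' @param n_cells number of spots.
#' @param strain strain label.
#' @param zone_probs numeric vector of length `n_zones` summing to 1, or
#'   `"uniform"`. The wild-type telomere preset is `c(0.75, 0.15, 0.10)`.
#' @param n_zones number of equal-volume zones (default 3).
#' @param radius_range min/max nuclear radius, micrometres.
#' @param seed integer seed.
#' @return spot data.frame (`cell_id`, `strain`, `radius_um`,
#'   `distance_um`, `zone`), `zone` being the [assign_zone()] label.
#' @export
simulate_spots <- function(n_cells, strain = "wt",
                           zone_probs = c(0.75, 0.15, 0.10), n_zones = 3,
                           radius_range = c(0.9, 1.3), seed = 1) {
  uniform <- identical(zone_probs, "uniform")
  if (!uniform) {
    if (length(zone_probs) != n_zones) {
      stop("need one zone probability per zone")
    }
    if (abs(sum(zone_probs) - 1) > 1e-8 || any(zone_probs < 0)) {
      stop("zone probabilities must be non-negative and sum to 1")
    }
  }
  with_seed(seed, {
    if (uniform) {
      u <- stats::runif(n_cells)
    } else {
      zone <- sample.int(n_zones, n_cells, replace = TRUE, prob = zone_probs)
      # zone k occupies u = r^3 in [(n-k)/n, (n-k+1)/n]; uniform there is
      # volume-uniform within the shell
      u <- stats::runif(n_cells, (n_zones - zone) / n_zones,
                        (n_zones - zone + 1) / n_zones)
    }
    d <- 1 - u^(1 / 3)
    radius <- stats::runif(n_cells, radius_range[1], radius_range[2])
    tab <- data.frame(
      cell_id = paste0(strain, "_", seq_len(n_cells)),
      strain = strain,
      radius_um = radius,
      distance_um = d * radius,
      stringsAsFactors = FALSE
    )
    tab$zone <- assign_zone(tab$distance_um, tab$radius_um, n_zones)
    tab
  })
}
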
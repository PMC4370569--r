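#' Build a probe track
#'
#' A probe track is a `GRanges` of probe intervals with a numeric `score`
#' (signal units or a log2 ratio) and a logical `unique` flag (whether the
#' probe has a single genomic match). Probes are sorted by chromosome order
#' of the layout, then start coordinate.
#'
#' @param gr `GRanges` with a numeric `score` column, or a data.frame with
#'   columns chrom, start, end, score (1-based inclusive coordinates).
#' @param layout genome layout.
#' @param unique logical vector of per-probe uniqueness flags; recycled;
#'   default all `TRUE`.
#' @return a sorted probe track `GRanges`.
#' @export
probe_track <- function(gr, layout, unique = TRUE) {
  if (is.data.frame(gr)) {
    gr2 <- GenomicRanges::GRanges(
      seqnames = gr$chrom,
      ranges = IRanges::IRanges(start = gr$start, end = gr$end)
    )
    gr2$score <- as.numeric(gr$score)
    gr <- gr2
  }
  if (is.null(gr$score)) stop("probe track needs a numeric 'score' column")
  if (is.null(gr$unique)) gr$unique <- rep_len(as.logical(unique), length(gr))
  gr <- check_against_layout(gr, layout, what = "probe")
  was_sorted <- !BiocGenerics::is.unsorted(gr, ignore.strand = TRUE)
  if (!was_sorted) {
    message("probe track was not position-sorted; sorting")
    gr <- BiocGenerics::sort(gr, ignore.strand = TRUE)
  }
  gr
}

#' Read a bedGraph file as a probe track
#'
#' @param path four-column bedGraph (chrom, start, end, value).
#' @param layout genome layout.
#' @return probe track; `unique` defaults to `TRUE` for every probe.
#' @export
read_bedgraph <- function(path, layout) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  probe_track(gr, layout)
}

#' Write a probe track as bedGraph
#'
#' Only interval and score are representable in bedGraph; the `unique` flag
#' is not serialized.
#'
#' @param track probe track.
#' @param path output path.
#' @export
write_bedgraph <- function(track, path) {
  out <- GenomicRanges::granges(track)
  out$score <- track$score
  rtracklayer::export(out, path, format = "bedGraph")
  invisible(path)
}

#' Per-probe log2 ratio of two tracks
#'
#' `value_i = log2((num_i + pseudocount) / (den_i + pseudocount))`. The two
#' tracks must share an identical probe grid; the result's `unique` flag is
#' the AND of the inputs'.
#'
#' @param numerator,denominator probe tracks on the same grid.
#' @param pseudocount added to both before the ratio; default 0 (tracks are
#'   assumed already positive/normalized).
#' @return probe track of log2 ratios.
#' @export
log2_ratio <- function(numerator, denominator, pseudocount = 0) {
  same <- length(numerator) == length(denominator) &&
    all(as.character(GenomeInfoDb::seqnames(numerator)) ==
          as.character(GenomeInfoDb::seqnames(denominator))) &&
    all(BiocGenerics::start(numerator) == BiocGenerics::start(denominator)) &&
    all(BiocGenerics::end(numerator) == BiocGenerics::end(denominator))
  if (!same) {
    if (length(numerator) != length(denominator)) {
      stop("probe grids differ: ", length(numerator), " vs ",
           length(denominator), " probes")
    }
    i <- which(as.character(GenomeInfoDb::seqnames(numerator)) !=
                 as.character(GenomeInfoDb::seqnames(denominator)) |
                 BiocGenerics::start(numerator) != BiocGenerics::start(denominator) |
                 BiocGenerics::end(numerator) != BiocGenerics::end(denominator))[1]
    stop("probe grids differ at probe ", i, " (",
         GenomeInfoDb::seqnames(numerator)[i], ":",
         BiocGenerics::start(numerator)[i], " vs ",
         GenomeInfoDb::seqnames(denominator)[i], ":",
         BiocGenerics::start(denominator)[i], ")")
  }
  out <- GenomicRanges::granges(numerator)
  out$score <- log2((numerator$score + pseudocount) /
                      (denominator$score + pseudocount))
  out$unique <- numerator$unique & denominator$unique
  out
}

#' Keep only probes with a single genomic match
#'
#' Statistics and significance tests run on unique probes only; the full
#' track is kept separately for visualization.
#'
#' @param track probe track.
#' @return the track restricted to `unique == TRUE` probes.
#' @export
filter_unique <- function(track) {
  out <- track[track$unique]
  if (length(out) == 0) {
    stop("no probes left after uniqueness filtering; ",
         "check the 'unique' flags assigned at load time")
  }
  out
}

#' Threshold a log2-ratio track into targets
#'
#' A probe is a target iff its log2 ratio exceeds `log2(fold)` strictly
#' ("more than" `fold`-fold enrichment).
#'
#' @param track probe track of log2 ratios.
#' @param fold fold-enrichment threshold (> 0); e.g. `fold = 2` selects
#'   probes with more than two-fold enrichment.
#' @return logical target mask, one element per probe.
#' @export
threshold_targets <- function(track, fold) {
  if (!is.numeric(fold) || length(fold) != 1 || fold <= 0) {
    stop("'fold' must be a single positive number")
  }
  track$score > log2(fold)
}

# Tukey boxplot statistics of a numeric vector: type-7 quartiles, whiskers
# at 1.5 IQR clamped to the most extreme data point inside the fence.
box_stats <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  list(
    n_probes = length(x),
    mean = mean(x),
    q1 = q[1], median = q[2], q3 = q[3],
    whisker_low = min(x[x >= q[1] - 1.5 * iqr]),
    whisker_high = max(x[x <= q[3] + 1.5 * iqr])
  )
}

#' Boxplot summaries for members and non-members
#'
#' Computes Tukey boxplot statistics (type-7 quartiles, whiskers at 1.5 IQR
#' clamped to the data) for the probes inside a membership mask and for the
#' rest of the track.
#'
#' @param track probe track.
#' @param mask logical membership mask (e.g. from [probes_overlapping()] or
#'   [threshold_targets()]).
#' @return data.frame with rows `member` and `non_member` and columns
#'   `group, n_probes, mean, q1, median, q3, whisker_low, whisker_high`.
#' @export
class_summary <- function(track, mask) {
  if (length(mask) != length(track)) {
    stop("mask length (", length(mask), ") != probe count (",
         length(track), ")")
  }
  if (!any(mask) || all(mask)) {
    stop("need at least one member and one non-member probe")
  }
  rows <- lapply(list(member = track$score[mask],
                      non_member = track$score[!mask]),
                 function(x) as.data.frame(box_stats(x)))
  out <- do.call(rbind, rows)
  data.frame(group = rownames(out), out, row.names = NULL,
             stringsAsFactors = FALSE)
}
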
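# Independent oracles and small fixture builders used across test files.

# Brute-force all-pairs interval overlap: probe i is a member iff it shares
# >= 1 bp with any selected feature (1-based closed intervals).
bf_overlap_mask <- function(track, fs, classes) {
  sel <- fs[fs$feature_class %in% classes]
  p_chr <- as.character(GenomeInfoDb::seqnames(track))
  p_s <- BiocGenerics::start(track); p_e <- BiocGenerics::end(track)
  f_chr <- as.character(GenomeInfoDb::seqnames(sel))
  f_s <- BiocGenerics::start(sel); f_e <- BiocGenerics::end(sel)
  vapply(seq_along(track), function(i) {
    any(f_chr == p_chr[i] & f_s <= p_e[i] & f_e >= p_s[i])
  }, logical(1))
}

# Full 2^n sign-pattern enumeration of the signed-rank two-sided p-value
# (midranks, ties with the observed statistic count as extreme).
enum_signed_rank_p <- function(a, b) {
  d <- b - a
  d <- d[d != 0]
  n <- length(d)
  ranks <- rank(abs(d))
  w_obs <- sum(ranks[d > 0])
  mu <- sum(ranks) / 2
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% ranks)
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# Quick GRanges builders on a small two-chromosome layout.
toy_layout <- function() genome_layout(c(chr1 = 10000, chr2 = 8000))

toy_features <- function(chrom, start, end, class,
                         id = paste0("f", seq_along(start)),
                         layout = toy_layout()) {
  fs <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start = start, end = end))
  fs$feature_class <- class
  fs$id <- id
  GenomeInfoDb::seqlevels(fs) <- GenomeInfoDb::seqnames(layout)
  GenomeInfoDb::seqinfo(fs) <- layout
  fs
}

toy_track <- function(chrom, start, end, score, layout = toy_layout(),
                      unique = TRUE) {
  probe_track(data.frame(chrom = chrom, start = start, end = end,
                         score = score),
              layout, unique = unique)
}

# Evenly tiled track on one or more chromosomes.
tiled_track <- function(score, step = 60, layout = toy_layout()) {
  len <- GenomeInfoDb::seqlengths(layout)
  chrom <- character(0); starts <- integer(0)
  for (cn in GenomeInfoDb::seqnames(layout)) {
    s <- seq(1L, len[cn] - step + 1L, by = step)
    chrom <- c(chrom, rep(cn, length(s)))
    starts <- c(starts, s)
  }
  toy_track(chrom, starts, starts + step - 1L, score, layout)
}
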
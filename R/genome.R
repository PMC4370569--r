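#' Construct a genome layout
#'
#' A genome layout is the coordinate frame every other object in the package
#' is validated against: an ordered set of chromosome names and lengths,
#' represented as a [GenomeInfoDb::Seqinfo] object. Chromosome order is fixed
#' at construction and determines probe order in tracks.
#'
#' @param chromosomes named numeric vector of chromosome lengths in bp
#'   (names are chromosome names), or a data.frame with columns `name` and
#'   `length`.
#' @return a `Seqinfo` object.
#' @examples
#' genome_layout(c(chr1 = 100000, chr2 = 80000))
#' @export
genome_layout <- function(chromosomes) {
  if (is.data.frame(chromosomes)) {
    nm <- as.character(chromosomes$name)
    len <- as.numeric(chromosomes$length)
  } else {
    nm <- names(chromosomes)
    len <- as.numeric(chromosomes)
  }
  if (is.null(nm) || anyNA(nm) || any(nm == "")) {
    stop("every chromosome must be named")
  }
  if (anyDuplicated(nm)) {
    stop("duplicate chromosome names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  if (anyNA(len) || any(len < 1)) {
    stop("chromosome lengths must be >= 1 bp")
  }
  GenomeInfoDb::Seqinfo(seqnames = nm, seqlengths = as.integer(len))
}

#' Genome layout of the three S. pombe chromosomes
#'
#' Chromosome I and II lengths coincide with the distal endpoints of the
#' packaged subtelomeric domains (the subtelomeres run to the chromosome
#' ends); chromosome III is included for completeness.
#'
#' @return a `Seqinfo` with chromosomes I, II, III.
#' @seealso [subtelomere_regions_pombe()]
#' @export
spombe_layout <- function() {
  genome_layout(c(I = 5579133, II = 4539804, III = 2452883))
}

# Coerce x to a Seqinfo, accepting a layout or anything with seqinfo().
as_layout <- function(x) {
  if (methods::is(x, "Seqinfo")) return(x)
  GenomeInfoDb::seqinfo(x)
}

# Validate a GRanges against a layout: chromosomes known, coordinates within
# bounds. `what` names the offending records in error messages.
check_against_layout <- function(gr, layout, what = "record") {
  layout <- as_layout(layout)
  bad_chr <- setdiff(as.character(unique(GenomeInfoDb::seqnames(gr))),
                     GenomeInfoDb::seqnames(layout))
  if (length(bad_chr) > 0) {
    stop("chromosome(s) not in layout: ", paste(bad_chr, collapse = ", "))
  }
  lens <- GenomeInfoDb::seqlengths(layout)[as.character(GenomeInfoDb::seqnames(gr))]
  too_far <- which(BiocGenerics::end(gr) > lens | BiocGenerics::start(gr) < 1)
  if (length(too_far) > 0) {
    lab <- if (!is.null(gr$id)) gr$id[too_far[1]] else too_far[1]
    stop(what, " ", lab, " extends outside its chromosome (",
         GenomeInfoDb::seqnames(gr)[too_far[1]], ":",
         BiocGenerics::start(gr)[too_far[1]], "-",
         BiocGenerics::end(gr)[too_far[1]], ")")
  }
  gr2 <- gr
  GenomeInfoDb::seqlevels(gr2) <- GenomeInfoDb::seqnames(layout)
  GenomeInfoDb::seqinfo(gr2) <- layout
  gr2
}

#' Read a GFF3 annotation into a classified feature set
#'
#' Features are returned as a [GenomicRanges::GRanges] whose `feature_class`
#' column is the GFF type (column 3) and whose `id` column is the GFF `ID`
#' attribute (falling back to `Name`, then to a positional id). All other
#' attributes are retained as metadata columns so that
#' [reclassify_features()] can match on them.
#'
#' @param path path to a GFF3 file.
#' @param layout genome layout the coordinates must be valid under.
#' @return `GRanges` with metadata columns `feature_class`, `id`, plus the
#'   GFF attributes.
#' @export
read_gff3 <- function(path, layout) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "gff3"),
    error = function(e) stop("failed to parse GFF3 '", path, "': ",
                             conditionMessage(e))
  )
  fs <- GenomicRanges::GRanges(
    seqnames = GenomeInfoDb::seqnames(gr),
    ranges = IRanges::ranges(gr),
    strand = BiocGenerics::strand(gr)
  )
  mc <- S4Vectors::mcols(gr)
  fs$feature_class <- as.character(mc$type)
  id <- if ("ID" %in% names(mc)) as.character(mc$ID) else rep(NA_character_, length(gr))
  if ("Name" %in% names(mc)) {
    id <- ifelse(is.na(id), as.character(mc$Name), id)
  }
  id <- ifelse(is.na(id), paste0("feature_", seq_along(gr)), id)
  fs$id <- id
  keep <- setdiff(names(mc), c("type", "score", "phase"))
  for (col in keep) {
    v <- mc[[col]]
    if (methods::is(v, "List")) v <- vapply(v, paste, character(1), collapse = ",")
    S4Vectors::mcols(fs)[[col]] <- as.character(v)
  }
  fs <- check_against_layout(fs, layout, what = "GFF record")
  validate_features(fs)
}

# Internal feature-set validator: classes non-empty, ids unique.
validate_features <- function(fs) {
  if (length(fs) == 0) return(fs)
  if (is.null(fs$feature_class) || any(is.na(fs$feature_class)) ||
      any(fs$feature_class == "")) {
    stop("every feature needs a non-empty feature_class")
  }
  if (is.null(fs$id)) stop("every feature needs an id")
  if (anyDuplicated(fs$id)) {
    stop("feature ids are not unique: ",
         paste(utils::head(unique(fs$id[duplicated(fs$id)]), 3), collapse = ", "))
  }
  fs
}

#' Default feature reclassification rules
#'
#' Four rules, applied in order: annotations matching "LTRTF2" become class
#' `LTR`; protein-coding features matching "Tf2" become class `Tf2`;
#' annotations matching "origin_of_replication" become class `origin`; and
#' features whose `external_name` attribute matches "intron" become class
#' `intron`. Matching is by fixed substring over the feature's class, id and
#' retained annotation attributes (or over one named field).
#'
#' @return list of rules, each a list with elements `pattern`, `new_class`,
#'   and optionally `field` (restrict matching to one metadata column) and
#'   `require_class` (rule only fires for features currently of that class).
#' @export
default_reclass_rules <- function() {
  list(
    list(pattern = "LTRTF2", new_class = "LTR"),
    list(pattern = "Tf2", new_class = "Tf2",
         require_class = "protein_coding_gene"),
    list(pattern = "origin_of_replication", new_class = "origin"),
    list(pattern = "intron", new_class = "intron", field = "external_name")
  )
}

#' Reclassify features by annotation-matching rules
#'
#' Applies substring-matching rules (see [default_reclass_rules()]) to the
#' feature set, in order, and returns a copy with updated `feature_class`
#' labels. Rules that match nothing are silently inert; the operation is
#' idempotent.
#'
#' @param fs feature set (`GRanges` from [read_gff3()]).
#' @param rules list of rules; defaults to [default_reclass_rules()].
#' @return the reclassified feature set.
#' @export
reclassify_features <- function(fs, rules = default_reclass_rules()) {
  if (length(fs) == 0) return(fs)
  mc <- S4Vectors::mcols(fs)
  chr_cols <- names(mc)[vapply(mc, is.character, logical(1))]
  for (rule in rules) {
    if (!is.null(rule$field)) {
      if (!rule$field %in% names(mc)) next
      hay <- as.character(mc[[rule$field]])
      hit <- !is.na(hay) & grepl(rule$pattern, hay, fixed = TRUE)
    } else {
      hit <- rep(FALSE, length(fs))
      for (col in chr_cols) {
        hay <- as.character(mc[[col]])
        hit <- hit | (!is.na(hay) & grepl(rule$pattern, hay, fixed = TRUE))
      }
    }
    if (!is.null(rule$require_class)) {
      hit <- hit & fs$feature_class == rule$require_class
    }
    fs$feature_class[hit] <- rule$new_class
    mc <- S4Vectors::mcols(fs)
  }
  fs
}

#' Packaged S. pombe subtelomeric domains
#'
#' The four subtelomeric regions of chromosomes I and II (both chromosome
#' ends), shipped as 1-based inclusive coordinates in
#' `inst/extdata/subtelomeres_pombe.tsv` and returned as a `GRanges`.
#'
#' @param layout layout to validate against; defaults to [spombe_layout()].
#' @return `GRanges` of the four regions.
#' @export
subtelomere_regions_pombe <- function(layout = spombe_layout()) {
  path <- system.file("extdata", "subtelomeres_pombe.tsv", package = "nucorg",
                      mustWork = TRUE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  gr <- GenomicRanges::GRanges(
    seqnames = tab$chrom,
    ranges = IRanges::IRanges(start = tab$start, end = tab$end)
  )
  check_against_layout(gr, layout, what = "subtelomere region")
}

#' Define subtelomere features from region coordinates
#'
#' @param layout genome layout.
#' @param regions `GRanges` of subtelomeric regions (1-based inclusive, the
#'   native `GRanges` convention); defaults to the packaged S. pombe domains.
#' @return feature set of class `subtelomere`, ids `subtel_1..n`.
#' @export
define_subtelomeres <- function(layout,
                                regions = subtelomere_regions_pombe(layout)) {
  if (length(regions) == 0) {
    fs <- GenomicRanges::GRanges(seqinfo = as_layout(layout))
    fs$feature_class <- character(0)
    fs$id <- character(0)
    return(fs)
  }
  regions <- check_against_layout(regions, layout, what = "subtelomere region")
  if (sum(IRanges::countOverlaps(regions, regions) > 1) > 0) {
    stop("subtelomere regions overlap one another")
  }
  fs <- GenomicRanges::granges(regions)
  fs$feature_class <- rep("subtelomere", length(fs))
  fs$id <- paste0("subtel_", seq_along(fs))
  validate_features(fs)
}

#' Probe membership in feature classes
#'
#' A probe is a member iff its interval shares at least one bp with any
#' feature of one of the requested classes. Strand is ignored (tiling probes
#' are unstranded).
#'
#' @param fs feature set.
#' @param track probe track (`GRanges` with `score`).
#' @param classes character vector of feature classes.
#' @return logical mask, one element per probe.
#' @export
probes_overlapping <- function(fs, track, classes) {
  avail <- unique(fs$feature_class)
  unknown <- setdiff(classes, avail)
  if (length(unknown) > 0) {
    stop("unknown feature class(es): ", paste(unknown, collapse = ", "),
         "; available: ", paste(sort(avail), collapse = ", "))
  }
  sel <- fs[fs$feature_class %in% classes]
  IRanges::overlapsAny(track, sel, minoverlap = 1L, ignore.strand = TRUE)
}

#' Write a feature set as TSV
#'
#' Columns: chrom, start, end (1-based inclusive), strand, feature_class, id.
#'
#' @param fs feature set.
#' @param path output path.
#' @export
write_features_tsv <- function(fs, path) {
  tab <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(fs)),
    start = BiocGenerics::start(fs),
    end = BiocGenerics::end(fs),
    strand = as.character(BiocGenerics::strand(fs)),
    feature_class = fs$feature_class,
    id = fs$id,
    stringsAsFactors = FALSE
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature set from TSV
#'
#' @param path TSV written by [write_features_tsv()].
#' @param layout genome layout.
#' @return feature set `GRanges`.
#' @export
read_features_tsv <- function(path, layout) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  fs <- GenomicRanges::GRanges(
    seqnames = tab$chrom,
    ranges = IRanges::IRanges(start = tab$start, end = tab$end),
    strand = tab$strand
  )
  fs$feature_class <- as.character(tab$feature_class)
  fs$id <- as.character(tab$id)
  validate_features(check_against_layout(fs, layout, what = "feature"))
}
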
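# ---- small shared helpers -------------------------------------------------

log_line <- function(...) message("[nucorg] ", ...)

write_tsv <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# md5 of an R object via its JSON serialization (stable across sessions).
hash_config <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(jsonlite::toJSON(x, auto_unbox = TRUE,
                                           digits = NA, force = TRUE)), tmp)
  unname(tools::md5sum(tmp))
}

input_checksums <- function(paths) {
  paths <- paths[vapply(paths, function(p) is.character(p) && file.exists(p),
                        logical(1))]
  if (length(paths) == 0) return(list())
  as.list(tools::md5sum(unlist(paths)))
}

resolve_track <- function(x, layout) {
  if (is.character(x)) read_bedgraph(x, layout) else x
}

resolve_features <- function(x, layout) {
  if (!is.character(x)) return(x)
  if (grepl("\\.gff3?$", x)) read_gff3(x, layout) else read_features_tsv(x, layout)
}

# ---- enrichment stage -----------------------------------------------------

#' Run the class-enrichment analysis
#'
#' For each (track, class) pair: uniqueness-filter the track, compute the
#' member/non-member boxplot summaries and the circular permutation test of
#' the mean-difference statistic, and report raw p-values alongside
#' Benjamini-Hochberg adjusted ones (raw permutation p-values are primary;
#' the adjustment is informational when several classes are tested).
#'
#' @param tracks named list of log2-ratio probe tracks (or bedGraph paths).
#' @param features feature set (or GFF3/TSV path).
#' @param classes character vector of feature classes to test.
#' @param layout genome layout (needed when inputs are paths).
#' @param n_permutations,alternative,mode passed to [permutation_test()].
#' @param seed integer seed, recorded in the report; each (track, class)
#'   pair derives its own sub-seed deterministically.
#' @param out_dir if non-`NULL`, writes `enrichment.tsv` and
#'   `enrichment.json` there.
#' @return list with `results` (data.frame), `summaries` (per-pair
#'   [class_summary()] tables), `tests` (per-pair `nucorg_permtest`), and
#'   `report` (what the JSON contains).
#' @export
run_enrichment <- function(tracks, features, classes, layout = NULL,
                           n_permutations = 1000,
                           alternative = "two_sided",
                           mode = "per_chromosome",
                           seed = 1, out_dir = NULL) {
  paths <- Filter(is.character, c(as.list(tracks), list(features)))
  fs <- resolve_features(features, layout)
  if (is.null(names(tracks))) names(tracks) <- paste0("track", seq_along(tracks))
  rows <- list()
  summaries <- list()
  tests <- list()
  i <- 0
  for (tn in names(tracks)) {
    track <- resolve_track(tracks[[tn]], layout)
    stat_track <- filter_unique(track)
    for (cl in classes) {
      i <- i + 1
      sub_seed <- (seed * 1000L + i) %% .Machine$integer.max
      row <- data.frame(track = tn, class = cl, n_member = NA_integer_,
                        n_non_member = NA_integer_,
                        member_median = NA_real_, non_member_median = NA_real_,
                        observed_stat = NA_real_, p_value = NA_real_,
                        error = NA_character_, stringsAsFactors = FALSE)
      res <- tryCatch({
        mask <- probes_overlapping(fs, stat_track, cl)
        cs <- class_summary(stat_track, mask)
        pt <- permutation_test_track(stat_track, mask,
                                     n_permutations = n_permutations,
                                     alternative = alternative,
                                     seed = sub_seed, mode = mode)
        summaries[[paste(tn, cl, sep = ".")]] <- cs
        tests[[paste(tn, cl, sep = ".")]] <- pt
        row$n_member <- cs$n_probes[cs$group == "member"]
        row$n_non_member <- cs$n_probes[cs$group == "non_member"]
        row$member_median <- cs$median[cs$group == "member"]
        row$non_member_median <- cs$median[cs$group == "non_member"]
        row$observed_stat <- pt$observed_stat
        row$p_value <- pt$p_value
        row
      }, error = function(e) {
        log_line("enrichment ", tn, "/", cl, " failed: ", conditionMessage(e))
        row$error <- conditionMessage(e)
        row
      })
      rows[[i]] <- res
    }
    log_line("enrichment: track ", tn, ", ", length(stat_track),
             " unique probes, ", length(classes), " classes")
  }
  results <- do.call(rbind, rows)
  results$p_adj_bh <- stats::p.adjust(results$p_value, method = "BH")
  report <- list(
    stage = "enrichment", seed = seed, n_permutations = n_permutations,
    alternative = alternative, mode = mode, classes = classes,
    config_hash = hash_config(list(classes = classes,
                                   n_permutations = n_permutations,
                                   alternative = alternative, mode = mode,
                                   seed = seed)),
    input_md5 = input_checksums(paths),
    results = results
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(results, file.path(out_dir, "enrichment.tsv"))
    write_json_report(report, file.path(out_dir, "enrichment.json"))
  }
  list(results = results, summaries = summaries, tests = tests,
       report = report)
}

# ---- occupancy stage ------------------------------------------------------

#' Run the paired occupancy analysis
#'
#' Builds (or accepts) a paired per-feature occupancy table for one feature
#' class, runs the paired two-sided rank test and the fold-change summary.
#'
#' @param cov_a,cov_b coverage tracks or bedGraph paths (condition A = e.g.
#'   wild type, B = mutant); ignored when `table` is given.
#' @param features feature set or path; ignored when `table` is given.
#' @param class_label feature class to analyze.
#' @param table optional prebuilt occupancy table.
#' @param layout genome layout (for path inputs).
#' @param mode,length_normalize passed to [occupancy_table()].
#' @param exact_threshold passed to [paired_rank_test()].
#' @param pseudocount passed to [fold_change_summary()].
#' @param seed recorded in the report (the stage itself is deterministic).
#' @param out_dir if non-`NULL`, writes `occupancy.tsv` and
#'   `occupancy.json`.
#' @return list with `table`, `test` (`nucorg_ranktest`), `fold_summary`
#'   and `report`.
#' @export
run_occupancy <- function(cov_a = NULL, cov_b = NULL, features = NULL,
                          class_label = "LTR", table = NULL, layout = NULL,
                          mode = "per_base", length_normalize = FALSE,
                          exact_threshold = 25, pseudocount = 0,
                          seed = 1, out_dir = NULL) {
  paths <- Filter(is.character, list(cov_a, cov_b, features))
  if (is.null(table)) {
    fs <- resolve_features(features, layout)
    table <- occupancy_table(resolve_track(cov_a, layout),
                             resolve_track(cov_b, layout),
                             fs, class_label, mode, length_normalize)
  } else {
    table <- validate_occupancy_table(table)
    if (!is.null(class_label)) table <- table[table$class %in% class_label, ]
  }
  if (nrow(table) == 0) stop("no features of class ", class_label)
  test <- paired_rank_test(table, exact_threshold = exact_threshold)
  folds <- fold_change_summary(table, pseudocount = pseudocount)
  log_line("occupancy: class ", paste(class_label, collapse = ","), ", ",
           nrow(table), " features, p = ", format(test$p_value, digits = 3))
  report <- list(
    stage = "occupancy", seed = seed, class = class_label, mode = mode,
    config_hash = hash_config(list(class = class_label, mode = mode,
                                   exact_threshold = exact_threshold,
                                   pseudocount = pseudocount, seed = seed)),
    input_md5 = input_checksums(paths),
    test = list(statistic = test$statistic, n_pairs = test$n_pairs,
                p_value = test$p_value, method = test$method),
    fold_summary = folds
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(table, file.path(out_dir, "occupancy.tsv"))
    write_json_report(report, file.path(out_dir, "occupancy.json"))
  }
  list(table = table, test = test, fold_summary = folds, report = report)
}

# ---- zone stage -----------------------------------------------------------

#' Run the nuclear zone analysis
#'
#' Scores spots into equal-volume zones, tabulates counts and percentages
#' per strain, and compares strain pairs with the two-sided chi-square test.
#'
#' @param spots spot data.frame or TSV path (see [read_spots()]).
#' @param n_zones number of equal-volume zones (default 3).
#' @param comparisons list of 2-element character vectors of strain names;
#'   `NULL` compares all pairs. With a single strain the table is reported
#'   and no test is run (with a warning).
#' @param seed recorded in the report (the stage itself is deterministic).
#' @param out_dir if non-`NULL`, writes `zones.tsv` and `zones.json`.
#' @return list with `counts`, `percentages`, `tests` (named list of
#'   chi-square results) and `report`.
#' @export
run_zones <- function(spots, n_zones = 3, comparisons = NULL, seed = 1,
                      out_dir = NULL) {
  paths <- Filter(is.character, list(spots))
  if (is.character(spots)) spots <- read_spots(spots)
  counts <- zone_table(spots, n_zones)
  pct <- zone_percentages(counts)
  strains <- rownames(counts)
  tests <- list()
  if (length(strains) < 2) {
    warning("single strain: zone table reported, no comparison run")
    log_line("zones: single strain ", strains, ", no test")
  } else {
    if (is.null(comparisons)) {
      comparisons <- utils::combn(strains, 2, simplify = FALSE)
    }
    for (cmp in comparisons) {
      key <- paste(cmp, collapse = "_vs_")
      tests[[key]] <- chi_square_test(counts, cmp[1], cmp[2])
    }
    log_line("zones: ", nrow(spots), " spots, ", length(strains),
             " strains, ", length(tests), " comparisons")
  }
  count_df <- data.frame(strain = strains, as.data.frame(unclass(counts)),
                         row.names = NULL, stringsAsFactors = FALSE)
  report <- list(
    stage = "zones", seed = seed, n_zones = n_zones,
    config_hash = hash_config(list(n_zones = n_zones, seed = seed)),
    input_md5 = input_checksums(paths),
    counts = count_df,
    percentages = data.frame(strain = strains,
                             as.data.frame(unclass(pct)), row.names = NULL),
    tests = tests
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(count_df, file.path(out_dir, "zones.tsv"))
    write_json_report(report, file.path(out_dir, "zones.json"))
  }
  list(counts = counts, percentages = pct, tests = tests, report = report)
}
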
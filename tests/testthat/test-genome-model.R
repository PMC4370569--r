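test_that("genome_layout enforces unique names and positive lengths", {
  lay <- genome_layout(c(chr1 = 100, chr2 = 50))
  expect_s4_class(lay, "Seqinfo")
  expect_identical(GenomeInfoDb::seqnames(lay), c("chr1", "chr2"))
  expect_error(genome_layout(c(chr1 = 100, chr1 = 50)), "duplicate")
  expect_error(genome_layout(c(chr1 = 0)), ">= 1")
  expect_error(genome_layout(stats::setNames(100, "")), "named")
})

test_that("read_gff3 parses records with classes from the type column", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\ttRNA\t101\t180\t.\t+\t.\tID=t1",
    "chr1\tsrc\tgene\t500\t900\t.\t-\t.\tID=g1;Name=abc1",
    "chr2\tsrc\tLTR\t200\t550\t.\t+\t.\tID=l1"
  ), gff)
  fs <- read_gff3(gff, toy_layout())
  expect_length(fs, 3)
  expect_identical(fs$feature_class, c("tRNA", "gene", "LTR"))
  expect_identical(fs$id, c("t1", "g1", "l1"))
  # native 1-based closed coordinates preserved
  expect_equal(BiocGenerics::start(fs), c(101, 500, 200))
  expect_equal(BiocGenerics::end(fs), c(180, 900, 550))
  expect_identical(as.character(BiocGenerics::strand(fs)), c("+", "-", "+"))
})

test_that("read_gff3 handles empty files and rejects invalid coordinates", {
  gff <- tempfile(fileext = ".gff3")
  writeLines("##gff-version 3", gff)
  expect_length(read_gff3(gff, toy_layout()), 0)

  writeLines(c("##gff-version 3",
               "chr1\tsrc\ttRNA\t9990\t10050\t.\t+\t.\tID=t1"), gff)
  expect_error(read_gff3(gff, toy_layout()), "outside")
  writeLines(c("##gff-version 3",
               "chr9\tsrc\ttRNA\t1\t50\t.\t+\t.\tID=t1"), gff)
  expect_error(read_gff3(gff, toy_layout()), "not in layout")
})

test_that("GFF3 round trip is coordinate-identical", {
  fs <- toy_features(c("chr1", "chr1", "chr2"), c(101, 500, 200),
                     c(180, 900, 550), c("tRNA", "gene", "LTR"))
  path <- tempfile(fileext = ".gff3")
  write_gff3(fs, path)
  back <- read_gff3(path, toy_layout())
  expect_equal(BiocGenerics::start(back), BiocGenerics::start(fs))
  expect_equal(BiocGenerics::end(back), BiocGenerics::end(fs))
  expect_identical(back$feature_class, fs$feature_class)
  expect_identical(back$id, fs$id)
})

test_that("reclassification applies the four rules in order and is idempotent", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\trepeat_region\t100\t400\t.\t+\t.\tID=r1;Name=LTRTF2-1",
    "chr1\tsrc\tprotein_coding_gene\t1000\t4000\t.\t+\t.\tID=g1;Name=Tf2-7",
    "chr1\tsrc\tgene\t5000\t5400\t.\t+\t.\tID=g2;Name=Tf2-like",
    "chr2\tsrc\tsite\t100\t300\t.\t+\t.\tID=o1;Name=origin_of_replication_x",
    "chr2\tsrc\tregion\t500\t560\t.\t+\t.\tID=i1;external_name=intron",
    "chr2\tsrc\ttRNA\t1000\t1080\t.\t+\t.\tID=t1"
  ), gff)
  fs <- read_gff3(gff, toy_layout())
  rc <- reclassify_features(fs)
  expect_identical(rc$feature_class[rc$id == "r1"], "LTR")
  expect_identical(rc$feature_class[rc$id == "g1"], "Tf2")
  # "Tf2" only fires together with the protein-coding class
  expect_identical(rc$feature_class[rc$id == "g2"], "gene")
  expect_identical(rc$feature_class[rc$id == "o1"], "origin")
  expect_identical(rc$feature_class[rc$id == "i1"], "intron")
  # no matching rule: class unchanged
  expect_identical(rc$feature_class[rc$id == "t1"], "tRNA")
  # idempotent
  expect_identical(reclassify_features(rc)$feature_class, rc$feature_class)
})

test_that("packaged subtelomeric domains match the published coordinates", {
  reg <- subtelomere_regions_pombe()
  expect_length(reg, 4)
  expect_identical(as.character(GenomeInfoDb::seqnames(reg)),
                   c("I", "I", "II", "II"))
  expect_equal(BiocGenerics::start(reg), c(1, 5496300, 1, 4437300))
  expect_equal(BiocGenerics::end(reg), c(98950, 5579133, 96400, 4539804))
  # total span under 1-based inclusive reading
  expect_equal(sum(BiocGenerics::width(reg)),
               98950 + (5579133 - 5496300 + 1) +
                 96400 + (4539804 - 4437300 + 1))
  fs <- define_subtelomeres(spombe_layout())
  expect_identical(unique(fs$feature_class), "subtelomere")
  expect_length(fs, 4)
})

test_that("define_subtelomeres validates regions", {
  lay <- toy_layout()
  reg <- GenomicRanges::GRanges("chr1",
                                IRanges::IRanges(c(1, 50), c(100, 200)))
  expect_error(define_subtelomeres(lay, reg), "overlap")
  reg2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(9000, 12000))
  expect_error(define_subtelomeres(lay, reg2), "outside")
  empty <- GenomicRanges::GRanges()
  expect_length(define_subtelomeres(lay, empty), 0)
})

test_that("probe membership follows 1-bp overlap with closed intervals", {
  fs <- toy_features("chr1", 100, 180, "tRNA")
  # contained probe is a member
  tr <- toy_track("chr1", 150, 170, 1)
  expect_true(probes_overlapping(fs, tr, "tRNA"))
  # adjacent probe starting one bp past the feature end is not
  tr2 <- toy_track("chr1", 181, 200, 1)
  expect_false(probes_overlapping(fs, tr2, "tRNA"))
  # single shared bp is enough
  tr3 <- toy_track("chr1", 180, 200, 1)
  expect_true(probes_overlapping(fs, tr3, "tRNA"))
  expect_error(probes_overlapping(fs, tr, "nosuch"), "available")
})

test_that("membership mask equals the brute-force all-pairs oracle", {
  set.seed(42)
  for (rep in 1:20) {
    n_p <- sample(50:200, 1)
    n_f <- sample(5:50, 1)
    chrom_p <- sample(c("chr1", "chr2"), n_p, replace = TRUE)
    s_p <- ifelse(chrom_p == "chr1", sample(9900, n_p, TRUE),
                  sample(7900, n_p, TRUE))
    df <- data.frame(chrom = chrom_p, start = s_p,
                     end = s_p + sample(20:80, n_p, TRUE),
                     score = rnorm(n_p))
    tr <- probe_track(df, toy_layout())
    chrom_f <- sample(c("chr1", "chr2"), n_f, replace = TRUE)
    s_f <- ifelse(chrom_f == "chr1", sample(9800, n_f, TRUE),
                  sample(7800, n_f, TRUE))
    cls_f <- c("tRNA", "LTR", sample(c("tRNA", "LTR"), n_f - 2, TRUE))
    fs <- toy_features(chrom_f, s_f, s_f + sample(30:150, n_f, TRUE), cls_f)
    for (cls in list("tRNA", "LTR", c("tRNA", "LTR"))) {
      expect_identical(probes_overlapping(fs, tr, cls),
                       bf_overlap_mask(tr, fs, cls))
    }
    # cardinality monotone in the class set
    expect_gte(sum(probes_overlapping(fs, tr, c("tRNA", "LTR"))),
               max(sum(probes_overlapping(fs, tr, "tRNA")),
                   sum(probes_overlapping(fs, tr, "LTR"))))
  }
})

test_that("feature TSV round trip preserves the set", {
  fs <- toy_features(c("chr1", "chr2"), c(10, 20), c(50, 90),
                     c("tRNA", "LTR"))
  path <- tempfile(fileext = ".tsv")
  write_features_tsv(fs, path)
  back <- read_features_tsv(path, toy_layout())
  expect_equal(BiocGenerics::start(back), BiocGenerics::start(fs))
  expect_identical(back$feature_class, fs$feature_class)
})
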
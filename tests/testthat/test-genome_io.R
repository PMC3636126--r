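# GenBank and CSV-dialect parsing, feature extraction, FASTA export.

write_tmp <- function(lines) {
  tf <- tempfile()
  writeLines(lines, tf)
  tf
}

test_that("GenBank round trip preserves all eleven feature classes exactly", {
  rec <- record_with_all_classes()
  tf <- write_tmp(strsplit(write_genbank(rec), "\n")[[1]])
  back <- parse_genbank(tf)
  expect_identical(back$accession, rec$accession)
  expect_identical(back$organism, rec$organism)
  expect_identical(back$sequence, rec$sequence)
  expect_identical(back$topology, "circular")
  expect_equal(back$features, rec$features)
  expect_setequal(back$features$feature_class, FEATURE_CLASSES)
})

test_that("GenBank parser handles empty feature tables and complement locations", {
  rec0 <- genome_record("EMPTY1", "x", strrep("ACGT", 50), "linear")
  back0 <- parse_genbank(write_tmp(strsplit(write_genbank(rec0), "\n")[[1]]))
  expect_equal(nrow(back0$features), 0L)
  expect_identical(back0$topology, "linear")

  gb <- c("LOCUS       T1  1000 bp    DNA     circular PLN",
          "ACCESSION   T1",
          "FEATURES             Location/Qualifiers",
          "     gene            complement(100..250)",
          "                     /gene=\"rbcL\"",
          "ORIGIN",
          sprintf("%9d %s", 1, tolower(strrep("acgtacgtag ", 5))),
          "//")
  # build a real 1000 bp origin
  set.seed(3)
  seq <- random_seq(1000)
  chunks <- vapply(seq(1, 1000, 60), function(p) {
    s <- seq(p, min(p + 59, 1000), 10)
    sprintf("%9d %s", p, tolower(paste(substring(seq, s, pmin(s + 9, 1000)), collapse = " ")))
  }, character(1))
  gb <- c(gb[1:5], "ORIGIN", chunks, "//")
  rec <- parse_genbank(write_tmp(gb))
  expect_equal(nrow(rec$features), 1L)
  expect_identical(rec$features$name, "rbcL")
  expect_equal(rec$features$start, 100L)
  expect_equal(rec$features$end, 250L)
  expect_identical(rec$features$strand, "-")
})

test_that("join locations decompose into part segments and malformed ones are skipped", {
  set.seed(4)
  seq <- random_seq(600)
  chunks <- vapply(seq(1, 600, 60), function(p) {
    s <- seq(p, min(p + 59, 600), 10)
    sprintf("%9d %s", p, tolower(paste(substring(seq, s, pmin(s + 9, 600)), collapse = " ")))
  }, character(1))
  gb <- c("LOCUS       J1  600 bp    DNA     circular PLN",
          "ACCESSION   J1",
          "FEATURES             Location/Qualifiers",
          "     CDS             join(10..90,200..280)",
          "                     /gene=\"ycf3\"",
          "     gene            550..9999",
          "                     /gene=\"broken\"",
          "ORIGIN", chunks, "//")
  expect_warning(rec <- parse_genbank(write_tmp(gb)), "out-of-bounds")
  expect_equal(nrow(rec$features), 2L)
  expect_equal(rec$features$part_index, c(1L, 2L))
  expect_equal(rec$features$start, c(10L, 200L))
  expect_true(all(rec$features$name == "ycf3"))
})

test_that("feature name falls back through gene > product > note > synthesized", {
  set.seed(5)
  seq <- random_seq(300)
  chunks <- vapply(seq(1, 300, 60), function(p) {
    s <- seq(p, min(p + 59, 300), 10)
    sprintf("%9d %s", p, tolower(paste(substring(seq, s, pmin(s + 9, 300)), collapse = " ")))
  }, character(1))
  gb <- c("LOCUS       Q1  300 bp    DNA     linear PLN",
          "FEATURES             Location/Qualifiers",
          "     tRNA            10..85",
          "                     /product=\"trnH-GUG\"",
          "     rRNA            100..160",
          "                     /note=\"some rRNA\"",
          "     exon            200..250",
          "ORIGIN", chunks, "//")
  rec <- parse_genbank(write_tmp(gb))
  expect_identical(rec$features$name,
                   c("trnH-GUG", "some rRNA", "Exon_200_250"))
})

test_that("write_feature_fasta extracts, reverse-complements and validates classes", {
  set.seed(6)
  seq <- random_seq(100)
  substr(seq, 10, 21) <- "ATGGCAGGTAAA"
  feats <- data.frame(feature_class = c("Gene", "Gene"),
                      name = c("rbcL", "rbcLrc"),
                      start = c(10L, 10L), end = c(21L, 21L),
                      strand = c("+", "-"), part_index = 1L,
                      stringsAsFactors = FALSE)
  rec <- genome_record("F1", "", seq, "linear", feats)
  fa <- write_feature_fasta(rec, "Gene")
  lines <- strsplit(fa, "\n")[[1]]
  expect_equal(lines[1], ">F1|Gene|rbcL|10..21|+")
  expect_equal(lines[2], "ATGGCAGGTAAA")
  expect_equal(lines[4], "TTTACCTGCCAT")
  expect_identical(write_feature_fasta(rec, "tRNA"), "")
  expect_error(write_feature_fasta(rec, "Plasmid"), "Minus35Signal")
})

test_that("FASTA export lengths equal end - start + 1 summed over parts", {
  rec <- record_with_all_classes()
  for (cls in unique(rec$features$feature_class)) {
    fa <- write_feature_fasta(rec, cls)
    if (!nzchar(fa)) next
    lines <- strsplit(fa, "\n")[[1]]
    seqs <- lines[!startsWith(lines, ">")]
    rows <- rec$features[rec$features$feature_class == cls, ]
    expect_equal(nchar(seqs), rows$end - rows$start + 1L)
  }
})

test_that("user annotation files parse with validation", {
  set.seed(7)
  seq <- random_seq(2000)
  f <- write_tmp(c("Gene,rbcL,100,1544",
                   "tRNA,trnH-GUG,1600,1675",
                   ">myGenome draft",
                   substr(seq, 1, 1000), substr(seq, 1001, 2000)))
  rec <- parse_user_annotation_file(f)
  expect_identical(rec$accession, "myGenome")
  expect_equal(genome_length(rec), 2000L)
  expect_equal(rec$features$feature_class, c("Gene", "tRNA"))
  expect_equal(rec$features$start, c(100L, 1600L))
  expect_equal(rec$features$end, c(1544L, 1675L))
  expect_true(all(rec$features$strand == "+"))

  # zero items is fine
  rec0 <- parse_user_annotation_file(write_tmp(c(">g", "ACGTACGT")))
  expect_equal(nrow(rec0$features), 0L)

  # start > end is fatal with the line number
  expect_error(parse_user_annotation_file(
    write_tmp(c("CDS,matK,900,300", ">g", seq))), "line 1")
  # bad class token is fatal and names the token
  expect_error(parse_user_annotation_file(
    write_tmp(c("Plasmidd,x,1,10", ">g", seq))), "Plasmidd")
  # end beyond sequence length is fatal with the line number
  expect_error(parse_user_annotation_file(
    write_tmp(c("Gene,x,1,99999", ">g", seq))), "line 1")
})

test_that("modified items parse and apply", {
  items <- parse_modified_items_file(write_tmp(c("rbcL,120,1600", "matK,10,50")))
  expect_equal(items$feature_name, c("rbcL", "matK"))
  expect_equal(items$start, c(120L, 10L))
  expect_equal(items$end, c(1600L, 50L))
  expect_equal(nrow(parse_modified_items_file(write_tmp(character(0)))), 0L)
  expect_error(parse_modified_items_file(write_tmp("rbcL,120")), "line 1")

  rec <- make_record("M1", c("rbcL", "matK"), c(100L, 2000L), c(1544L, 3500L))
  mod <- apply_modifications(rec, items[1, , drop = FALSE])
  expect_equal(mod$features$start, c(120L, 2000L))
  expect_equal(mod$features$end, c(1600L, 3500L))
  # original untouched; empty item list is identity
  expect_equal(rec$features$start, c(100L, 2000L))
  expect_equal(apply_modifications(rec, items[0, , drop = FALSE]), rec)
  expect_error(apply_modifications(rec, data.frame(
    feature_name = "xyz9", start = 1L, end = 2L)), "xyz9")
})

test_that("comparison list files parse in both published and user forms", {
  req <- parse_comparison_list_file(write_tmp("NC_003119.6,NC_008641.1"))
  expect_equal(req$names, c("NC_003119.6", "NC_008641.1"))
  expect_null(req$user_genome_length)
  expect_null(req$user_features)

  req2 <- parse_comparison_list_file(write_tmp(
    c("myGenome,NC_003119.6", "154000", "rbcL,100,1544")))
  expect_equal(req2$user_genome_length, 154000L)
  expect_equal(nrow(req2$user_features), 1L)
  expect_equal(req2$user_features$name, "rbcL")

  expect_error(parse_comparison_list_file(write_tmp(character(0))), "no names line")
  expect_error(parse_comparison_list_file(write_tmp(
    c("a,b", "notanumber", "rbcL,1,10"))), "integer")
})

test_that("parsers reject out-of-range coordinates deterministically", {
  expect_error(genome_record("X", "", "ACGT", "linear",
                             data.frame(feature_class = "Gene", name = "g",
                                        start = 2L, end = 9L, strand = "+",
                                        part_index = 1L)),
               "beyond sequence length")
  expect_error(genome_record("X", "", "ACGT", "linear",
                             data.frame(feature_class = "Gene", name = "g",
                                        start = 3L, end = 2L, strand = "+",
                                        part_index = 1L)),
               "start > end")
})
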
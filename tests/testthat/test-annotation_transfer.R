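# Feature library construction, seeded local alignment and annotation
# transfer onto draft genomes.

library_fixture <- function(seed = 9) {
  p <- plastome_params(lsc_len = 3000, ssc_len = 800, ir_len = 600,
                       n_features_per_region = 2, seed = seed)
  rec <- simulate_plastome(p)
  list(record = rec, library = build_feature_library(rec))
}

test_that("feature libraries keep IR duplicates as separate coding-orientation entries", {
  fx <- library_fixture()
  lib <- fx$library
  rec <- fx$record
  expect_equal(nrow(lib$entries), nrow(rec$features))  # all single-part here
  dup <- table(lib$entries$normalized_name)
  expect_true(any(dup == 2))                           # the IR pair
  ir_name <- names(dup)[dup == 2][1]
  pair <- lib$entries[lib$entries$normalized_name == ir_name, ]
  expect_equal(length(unique(pair$location_id)), 2L)
  # both copies stored in coding orientation: identical sequences
  expect_identical(pair$sequence[1], pair$sequence[2])

  # minus-strand entries really are reverse-complemented
  minus <- rec$features[rec$features$strand == "-", ][1, ]
  ent <- lib$entries[lib$entries$location_id ==
                       sprintf("%s:%d..%d(-)", rec$accession, minus$start, minus$end), ]
  expect_identical(ent$sequence,
                   revcomp(substr(rec$sequence, minus$start, minus$end)))

  expect_error(build_feature_library(list()), "no reference records")
  bare <- genome_record("B1", "", strrep("ACGT", 100), "circular")
  expect_error(build_feature_library(bare), "no features")
})

test_that("local_align finds exact library copies with full score and identity 1", {
  fx <- library_fixture()
  entry <- fx$library$entries[1, ]
  hits <- local_align(entry$sequence, fx$library)
  expect_gt(nrow(hits), 0L)
  top <- hits[1, ]
  expect_equal(top$location_id, entry$location_id)
  expect_equal(top$identity, 1)
  expect_equal(top$score, nchar(entry$sequence))  # match reward 1 per base
  expect_equal(top$q_start, 1L)
  expect_equal(top$q_end, nchar(entry$sequence))

  # no shared 11-mer -> no hits
  expect_equal(nrow(local_align(strrep("AC", 40), fx$library)), 0L)
})

test_that("local_align tolerates point mutations and still ranks the right entry first", {
  fx <- library_fixture(seed = 12)
  lib <- fx$library
  long_i <- which.max(nchar(lib$entries$sequence))
  entry <- lib$entries[long_i, ]
  set.seed(77)
  x <- strsplit(entry$sequence, "")[[1]]
  nmut <- max(1L, round(0.05 * length(x)))
  pos <- sample(length(x), nmut)
  x[pos] <- vapply(x[pos], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                   character(1))
  hits <- local_align(paste(x, collapse = ""), lib)
  top <- hits[1, ]
  expect_equal(top$normalized_name, entry$normalized_name)
  expect_gte(top$identity, 0.90)
  expect_lt(top$identity, 1)
})

test_that("annotate_genome recovers planted features exactly at zero mutation", {
  fx <- library_fixture(seed = 15)
  rec <- fx$record
  ann <- annotate_genome(rec, fx$library)
  planted <- rec$features
  expect_equal(nrow(ann), nrow(planted))
  key <- function(n, s, e) paste(n, s, e)
  got <- key(ann$normalized_feature_name, ann$start, ann$end)
  want <- key(vapply(planted$name, normalize_feature_name, character(1)),
              planted$start, planted$end)
  expect_setequal(got, want)
  expect_true(all(ann$identity == 1))
  expect_true(all(ann$expectation <= 1e-6))
  # strands recovered too (IRb copies are minus-strand hits)
  expect_setequal(paste(got, ann$strand), paste(want, planted$strand))
  # literal |End-Start|/L ratio: one less than the inclusive span
  lenp <- planted$end - planted$start + 1L
  expect_equal(sort(ann$length_ratio), sort((lenp - 1) / lenp))
})

test_that("annotation is non-redundant: best-scoring entry wins per name and locus", {
  fx <- library_fixture(seed = 18)
  rec <- fx$record
  # query = the genome itself; IR names appear at two disjoint loci and must
  # both survive, while duplicate library entries for the same locus collapse
  ann <- annotate_genome(rec, fx$library)
  for (nm in unique(ann$normalized_feature_name)) {
    rows <- ann[ann$normalized_feature_name == nm, ]
    if (nrow(rows) < 2) next
    for (i in seq_len(nrow(rows) - 1L)) {
      ov <- min(rows$end[i], rows$end[i + 1L]) - max(rows$start[i], rows$start[i + 1L]) + 1L
      shorter <- min(rows$end[i] - rows$start[i], rows$end[i + 1L] - rows$start[i + 1L]) + 1L
      expect_lte(ov, 0.5 * shorter)
    }
  }
  # empty result for a query with no similarity
  none <- annotate_genome(strrep("ACAC", 500), fx$library)
  expect_equal(nrow(none), 0L)
})

test_that("recall degrades gracefully with mutation rate", {
  recalls <- vapply(c(0, 0.05, 0.15), function(rate) {
    vals <- vapply(1:3, function(rep) {
      fx <- library_fixture(seed = 20 + rep)
      mut <- mutate_genome(fx$record, rate, 0, seed = 500 + rep)
      ann <- annotate_genome(mut, fx$library)
      planted <- vapply(mut$features$name, normalize_feature_name, character(1))
      mean(planted %in% ann$normalized_feature_name)
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_true(all(diff(recalls) <= 0))
  expect_equal(recalls[1], 1)
})

test_that("the 8-column table and GenBank outputs serialise and round-trip", {
  fx <- library_fixture(seed = 25)
  ann <- annotate_genome(fx$record, fx$library)
  tsv <- write_annotation_table(ann)
  lines <- strsplit(tsv, "\n")[[1]]
  expect_equal(strsplit(lines[1], "\t")[[1]],
               c("NormalizedFeatureName", "Start", "End", "FeatureNameOrLocation",
                 "LengthRatio", "Identity", "Score", "Expectation"))
  expect_equal(length(lines), nrow(ann) + 1L)
  expect_true(all(lengths(strsplit(lines[-1], "\t")) == 8L))
  # empty list -> header only
  empty <- annotate_genome(strrep("ACAC", 500), fx$library)
  expect_equal(strsplit(write_annotation_table(empty), "\n")[[1]], lines[1])

  tf <- tempfile()
  write_annotation_genbank(fx$record, ann, tf)
  back <- parse_genbank(tf)
  expect_equal(nrow(back$features), nrow(ann))
  expect_equal(back$features$start, ann$start)
  expect_equal(back$features$end, ann$end)
})
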
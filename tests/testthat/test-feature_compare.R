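# Feature-content comparison: name normalisation, shared/unique sets,
# region filtering and the link-table export.

test_that("feature names normalise by case and whitespace, keeping anticodons distinct", {
  expect_identical(normalize_feature_name(" rbcL "), "rbcL")
  expect_identical(normalize_feature_name("RBCL"), normalize_feature_name("rbcL"))
  expect_identical(normalize_feature_name("RBCL"), "rbcL")
  expect_identical(normalize_feature_name("some  Note\ttext"), "some note text")
  expect_false(normalize_feature_name("trnH-GUG") == normalize_feature_name("trnH-CAC"))
  expect_error(normalize_feature_name("   "), "empty")
})

test_that("compare_pair partitions names into shared and unique sets", {
  a <- make_record("A", c("rbcL", "matK", "psbA"), c(100L, 900L, 1800L),
                   c(700L, 1500L, 2400L), seed = 11)
  b <- make_record("B", c("RBCL", "ndhF"), c(50L, 1000L), c(600L, 2200L), seed = 12)
  res <- compare_pair(a, b)
  expect_equal(res$shared, "Gene:rbcL")
  expect_setequal(res$unique_ref, c("Gene:matK", "Gene:psbA"))
  expect_equal(res$unique_other, "Gene:ndhF")
  # partition property on both sides
  expect_equal(length(res$shared) + length(res$unique_ref), 3L)
  expect_equal(length(res$shared) + length(res$unique_other), 2L)
  # disjointness
  expect_length(intersect(res$shared, res$unique_ref), 0L)
  expect_length(intersect(res$shared, res$unique_other), 0L)

  # self comparison: all shared, nothing unique
  self <- compare_pair(a, a)
  expect_length(self$unique_ref, 0L)
  expect_length(self$unique_other, 0L)
  expect_setequal(self$shared, c("Gene:rbcL", "Gene:matK", "Gene:psbA"))

  expect_error(compare_pair(a, b, feature_classes = character(0)), "non-empty")
})

test_that("symmetry: swapping arguments swaps the unique sets", {
  a <- make_record("A", c("rbcL", "matK"), c(100L, 900L), c(700L, 1500L), seed = 13)
  b <- make_record("B", c("rbcL", "ndhF"), c(100L, 900L), c(700L, 1500L), seed = 14)
  ab <- compare_pair(a, b)
  ba <- compare_pair(b, a)
  expect_equal(ab$shared, ba$shared)
  expect_equal(ab$unique_ref, ba$unique_other)
  expect_equal(ab$unique_other, ba$unique_ref)
})

test_that("region filtering keeps overlapping reference features only, monotonically", {
  a <- make_record("A", c("rbcL", "matK", "psbA"), c(100L, 900L, 1800L),
                   c(700L, 1500L, 2400L), seed = 15)
  b <- make_record("B", "rbcL", 100L, 700L, seed = 16)
  res <- compare_pair(a, b, region = c(2000L, 3000L))
  expect_length(res$shared, 0L)                # rbcL excluded by the window
  expect_equal(res$unique_ref, "Gene:psbA")    # psbA overlaps 1800..2400
  # any-overlap rule: window touching a single base keeps the feature
  res2 <- compare_pair(a, b, region = c(700L, 700L))
  expect_equal(res2$shared, "Gene:rbcL")
  # shrinking the region never grows the reference-side name set
  full <- compare_pair(a, b)
  for (win in list(c(1L, 5000L), c(500L, 2000L), c(500L, 900L), c(880L, 890L))) {
    sub <- compare_pair(a, b, region = win)
    expect_true(all(c(sub$shared, sub$unique_ref) %in% c(full$shared, full$unique_ref)))
  }
  expect_error(compare_pair(a, b, region = c(3000L, 2000L)), "start > end")
})

test_that("duplicate IR copies collapse to one name key but keep both coordinate instances", {
  a <- make_record("A", c("rps12", "rps12"), c(100L, 4000L), c(400L, 4300L),
                   strands = c("+", "-"), seed = 17)
  b <- make_record("B", "rps12", 90L, 390L, seed = 18)
  res <- compare_pair(a, b)
  expect_equal(res$shared, "Gene:rps12")
  tsv <- export_links(list(res))
  lines <- strsplit(tsv, "\n")[[1]]
  expect_equal(length(lines), 2L)  # header + one shared row
  row <- strsplit(lines[2], "\t")[[1]]
  expect_equal(row[5], "100..400(+);4000..4300(-)")
  expect_equal(row[6], "90..390(+)")
})

test_that("compare_one_to_many resolves names and builds user genomes", {
  a <- make_record("A", "rbcL", 100L, 700L, seed = 19)
  b <- make_record("B", "rbcL", 100L, 700L, seed = 20)
  c_ <- make_record("C", "ndhF", 100L, 700L, seed = 21)
  resolver <- list(A = a, B = b, C = c_)

  req <- structure(list(names = c("A", "B", "C"), user_genome_length = NULL,
                        user_features = NULL, region = NULL),
                   class = "comparison_request")
  out <- compare_one_to_many(req, resolver)
  expect_length(out, 2L)
  expect_true(all(vapply(out, function(r) r$ref_label == "A", logical(1))))

  solo <- structure(list(names = "A", user_genome_length = NULL,
                         user_features = NULL, region = NULL),
                    class = "comparison_request")
  expect_length(compare_one_to_many(solo, resolver), 0L)

  # user-genome form built from a parsed list file
  tf <- tempfile()
  writeLines(c("myG,B,C", "9000", "rbcL,100,700", "matK,900,1500", "psbA,2000,2600"), tf)
  ureq <- parse_comparison_list_file(tf)
  ures <- compare_one_to_many(ureq, resolver)
  expect_length(ures, 2L)
  expect_equal(length(ures[[1]]$shared) + length(ures[[1]]$unique_ref), 3L)

  bad <- structure(list(names = c("A", "ZZZ"), user_genome_length = NULL,
                        user_features = NULL, region = NULL),
                   class = "comparison_request")
  expect_error(compare_one_to_many(bad, resolver), "ZZZ")
})

test_that("export_links is deterministic and complete", {
  a <- make_record("A", c("rbcL", "matK"), c(100L, 900L), c(700L, 1500L), seed = 22)
  b <- make_record("B", c("rbcL", "ndhF"), c(100L, 900L), c(700L, 1500L), seed = 23)
  res <- compare_pair(a, b)
  t1 <- export_links(list(res))
  t2 <- export_links(list(compare_pair(a, b)))
  expect_identical(t1, t2)
  lines <- strsplit(t1, "\n")[[1]]
  expect_equal(length(lines), 4L)  # header + shared + unique_other + unique_ref
  expect_equal(strsplit(lines[1], "\t")[[1]],
               c("ref_label", "other_label", "status", "name",
                 "ref_coords", "other_coords"))
  expect_error(export_links(list()), "non-empty")
})
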
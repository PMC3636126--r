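#' Normalise a feature name
#'
#' Trims surrounding whitespace, collapses internal whitespace runs and
#' case-folds the name so that `"RBCL"`, `" rbcL "` and `"rbcl"` compare
#' equal. Names on the bundled canonical plastid gene list
#' ([PLASTID_GENES]) are reported in their conventional capitalisation.
#' tRNA anticodon suffixes are retained as distinguishing (trnH-GUG and
#' trnH-CAC stay distinct keys).
#'
#' @param name feature name (non-empty).
#' @return normalised name.
#' @export
normalize_feature_name <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  key <- tolower(gsub("\\s+", " ", trimws(name)))
  if (!nzchar(key)) stop("empty feature name")
  hit <- match(key, tolower(PLASTID_GENES))
  if (!is.na(hit)) PLASTID_GENES[hit] else key
}

# Name keys used by the comparison logic: feature content is compared by
# normalised name WITHIN feature class, so a Gene rbcL and a CDS rbcL are
# tracked separately.
feature_keys <- function(features) {
  if (nrow(features) == 0L) return(character(0))
  paste0(features$feature_class, ":",
         vapply(features$name, normalize_feature_name, character(1)))
}

#' Compare the feature content of two genomes
#'
#' Computes the shared and unique feature names between a reference genome
#' and another genome. Comparison is by normalised feature name within
#' feature class; duplicated instances (e.g. inverted-repeat gene copies)
#' collapse to one name key, but every coordinate instance is retained for
#' export. When `region` is given, the reference side is restricted to
#' features overlapping the window (any overlap).
#'
#' @param ref,other [genome_record()] objects.
#' @param feature_classes non-empty subset of [FEATURE_CLASSES].
#' @param region optional `c(start, end)` window on the reference genome.
#' @return object of class `comparison_result` with elements `ref_label`,
#'   `other_label`, `shared`, `unique_ref`, `unique_other` (character
#'   vectors of `class:name` keys), `coords` (data frame of all instances)
#'   and `region`.
#' @export
compare_pair <- function(ref, other, feature_classes = FEATURE_CLASSES,
                         region = NULL) {
  stopifnot(inherits(ref, "genome_record"), inherits(other, "genome_record"))
  if (!length(feature_classes)) stop("feature_classes must be non-empty")
  bad <- setdiff(feature_classes, FEATURE_CLASSES)
  if (length(bad)) stop("unknown feature class(es): ", paste(bad, collapse = ", "))
  if (!is.null(region)) {
    stopifnot(length(region) == 2L)
    if (region[1] > region[2]) stop("region start > end")
    if (region[1] < 1L || region[2] > genome_length(ref))
      stop("region outside reference genome bounds")
  }

  rf <- ref$features[ref$features$feature_class %in% feature_classes, , drop = FALSE]
  of <- other$features[other$features$feature_class %in% feature_classes, , drop = FALSE]
  if (!is.null(region) && nrow(rf))
    rf <- rf[rf$start <= region[2] & rf$end >= region[1], , drop = FALSE]

  rkeys <- feature_keys(rf)
  okeys <- feature_keys(of)
  shared <- sort(intersect(unique(rkeys), unique(okeys)))
  unique_ref <- sort(setdiff(unique(rkeys), shared))
  unique_other <- sort(setdiff(unique(okeys), shared))

  coords <- rbind(
    if (nrow(rf)) data.frame(side = "ref", key = rkeys, rf, stringsAsFactors = FALSE),
    if (nrow(of)) data.frame(side = "other", key = okeys, of, stringsAsFactors = FALSE)
  )
  if (is.null(coords)) coords <- data.frame(side = character(0), key = character(0))
  rownames(coords) <- NULL

  structure(list(
    ref_label = ref$accession, other_label = other$accession,
    shared = shared, unique_ref = unique_ref, unique_other = unique_other,
    coords = coords, region = region
  ), class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s vs %s: %d shared, %d unique to %s, %d unique to %s\n",
              x$ref_label, x$other_label, length(x$shared),
              length(x$unique_ref), x$ref_label,
              length(x$unique_other), x$other_label))
  invisible(x)
}

#' One-by-more feature content comparison
#'
#' Resolves each name of a [parse_comparison_list_file()] request to a
#' genome record and compares the first (reference) genome against every
#' other. When the request carries user-genome lines, the reference is a
#' synthetic record built from the stated length (sequence of `N`s) and the
#' focused features (class `Gene`, plus strand, as the dialect carries
#' neither class nor strand).
#'
#' @param request a `comparison_request`.
#' @param resolver named list mapping names/accessions to
#'   [genome_record()] objects.
#' @param feature_classes,region forwarded to [compare_pair()].
#' @return list of `comparison_result`, one per non-reference name.
#' @export
compare_one_to_many <- function(request, resolver,
                                feature_classes = FEATURE_CLASSES,
                                region = NULL) {
  stopifnot(inherits(request, "comparison_request"))
  nms <- request$names
  if (!is.null(request$user_features)) {
    uf <- request$user_features
    feats <- if (nrow(uf)) data.frame(
      feature_class = "Gene", name = uf$name, start = uf$start, end = uf$end,
      strand = "+", part_index = 1L, stringsAsFactors = FALSE
    ) else empty_features()
    ref <- genome_record(nms[1], "", strrep("N", request$user_genome_length),
                         "circular", feats)
    others <- nms[-1]
  } else {
    missing <- setdiff(nms, names(resolver))
    if (length(missing))
      stop("unresolvable genome name(s): ", paste(missing, collapse = ", "))
    ref <- resolver[[nms[1]]]
    others <- nms[-1]
  }
  missing <- setdiff(others, names(resolver))
  if (length(missing))
    stop("unresolvable genome name(s): ", paste(missing, collapse = ", "))
  lapply(others, function(nm)
    compare_pair(ref, resolver[[nm]], feature_classes, region))
}

#' Export comparison results as a link table
#'
#' Flattens comparison results into a deterministic TSV with columns
#' `ref_label`, `other_label`, `status` (`shared`, `unique_other` or
#' `unique_ref`), `name`, `ref_coords`, `other_coords`. All coordinate
#' instances of a name are exported, joined by `;` as
#' `start..end(strand)`. Rows are ordered by other_label, then status
#' (alphabetical), then name, so identical inputs give byte-identical
#' output.
#'
#' @param results non-empty list of `comparison_result`.
#' @param path optional output file.
#' @return TSV text (invisibly when `path` is given).
#' @export
export_links <- function(results, path = NULL) {
  if (inherits(results, "comparison_result")) results <- list(results)
  if (!length(results)) stop("results must be non-empty")
  rows <- list()
  for (res in results) {
    coord_str <- function(side, key) {
      cc <- res$coords[res$coords$side == side & res$coords$key == key, , drop = FALSE]
      if (!nrow(cc)) return("")
      cc <- cc[order(cc$start, cc$end), , drop = FALSE]
      paste(sprintf("%d..%d(%s)", cc$start, cc$end, cc$strand), collapse = ";")
    }
    add <- function(status, keys) {
      for (k in keys) rows[[length(rows) + 1L]] <<- data.frame(
        ref_label = res$ref_label, other_label = res$other_label,
        status = status, name = k,
        ref_coords = coord_str("ref", k), other_coords = coord_str("other", k),
        stringsAsFactors = FALSE)
    }
    add("shared", res$shared)
    add("unique_ref", res$unique_ref)
    add("unique_other", res$unique_other)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(ref_label = character(0), other_label = character(0),
               status = character(0), name = character(0),
               ref_coords = character(0), other_coords = character(0))
  tab <- tab[order(tab$other_label, tab$status, tab$name), , drop = FALSE]
  lines <- c(paste(names(tab), collapse = "\t"),
             if (nrow(tab)) do.call(paste, c(tab, sep = "\t")))
  text <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(lines, path)
    invisible(text)
  } else text
}
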
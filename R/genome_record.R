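#' Construct a genome record
#'
#' A `genome_record` bundles one (chloroplast) genome: an accession, an
#' organism name, the nucleotide sequence, the molecule topology and an
#' ordered feature table. Coordinates are 1-based and inclusive throughout;
#' origin-spanning features on circular molecules are represented as two or
#' more part-segments sharing a name and carrying increasing `part_index`,
#' so that `start <= end` holds for every row.
#'
#' @param accession text identifier.
#' @param organism organism name.
#' @param sequence IUPAC DNA string (upper-cased on ingest), length >= 1.
#' @param topology `"circular"` or `"linear"`.
#' @param features data frame with columns `feature_class`, `name`, `start`,
#'   `end`, `strand` and optionally `part_index` (defaults to 1).
#' @return object of class `genome_record`.
#' @export
genome_record <- function(accession, organism = "", sequence,
                          topology = c("circular", "linear"),
                          features = empty_features()) {
  topology <- match.arg(topology)
  stopifnot(is.character(accession), length(accession) == 1L, nzchar(accession))
  sequence <- toupper(as_sequence(sequence))
  L <- nchar(sequence)
  if (L < 1L) stop("sequence must have length >= 1")
  if (grepl("[^ACGTRYSWKMBDHVN]", sequence))
    stop("sequence contains non-IUPAC nucleotide codes")
  features <- as_feature_table(features, L)
  structure(
    list(accession = accession, organism = organism, sequence = sequence,
         topology = topology, features = features),
    class = "genome_record"
  )
}

#' @rdname genome_record
#' @export
empty_features <- function() {
  data.frame(feature_class = character(0), name = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             part_index = integer(0), stringsAsFactors = FALSE)
}

as_feature_table <- function(features, L = NULL) {
  stopifnot(is.data.frame(features))
  if (nrow(features) == 0L) return(empty_features())
  need <- c("feature_class", "name", "start", "end", "strand")
  miss <- setdiff(need, names(features))
  if (length(miss)) stop("feature table missing columns: ", paste(miss, collapse = ", "))
  if (is.null(features$part_index)) features$part_index <- 1L
  features <- features[, c(need, "part_index")]
  features$feature_class <- as.character(features$feature_class)
  features$name <- as.character(features$name)
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  features$strand <- as.character(features$strand)
  features$part_index <- as.integer(features$part_index)
  bad <- setdiff(unique(features$feature_class), FEATURE_CLASSES)
  if (length(bad))
    stop("unknown feature class(es): ", paste(bad, collapse = ", "),
         "; valid classes are: ", paste(FEATURE_CLASSES, collapse = ", "))
  if (!all(features$strand %in% c("+", "-")))
    stop("feature strand must be '+' or '-'")
  if (any(features$start > features$end))
    stop("feature with start > end")
  if (any(features$start < 1L))
    stop("feature with start < 1")
  if (!is.null(L) && any(features$end > L))
    stop("feature with end beyond sequence length ", L)
  rownames(features) <- NULL
  features
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s (%s), %d bp %s, %d feature segment(s)\n",
              x$accession,
              if (nzchar(x$organism)) x$organism else "unknown organism",
              nchar(x$sequence), x$topology, nrow(x$features)))
  if (nrow(x$features)) {
    tab <- table(x$features$feature_class)
    cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Length of a genome record
#' @param x a `genome_record`.
#' @return integer sequence length in bp.
#' @export
genome_length <- function(x) {
  stopifnot(inherits(x, "genome_record"))
  nchar(x$sequence)
}

# Group the rows of a feature table into whole (possibly multi-part)
# features: a new feature starts wherever part_index does not continue the
# previous row's series for the same (class, name, strand).
group_feature_rows <- function(features) {
  n <- nrow(features)
  if (n == 0L) return(integer(0))
  id <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    new <- i == 1L ||
      features$part_index[i] <= features$part_index[i - 1L] ||
      features$name[i] != features$name[i - 1L] ||
      features$feature_class[i] != features$feature_class[i - 1L] ||
      features$strand[i] != features$strand[i - 1L]
    if (new) cur <- cur + 1L
    id[i] <- cur
  }
  id
}

# Extract the (coding-orientation) sequence of one grouped feature:
# parts concatenated in part_index order, each reverse-complemented when on
# the minus strand.
feature_sequence <- function(record, rows) {
  rows <- rows[order(rows$part_index), , drop = FALSE]
  parts <- substring(record$sequence, rows$start, rows$end)
  if (rows$strand[1] == "-") parts <- vapply(parts, revcomp, character(1))
  paste(parts, collapse = "")
}
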
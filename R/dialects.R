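#' Export all features of one class as FASTA
#'
#' Writes one FASTA entry per (possibly multi-part) feature of the requested
#' class. Headers have the form `accession|class|name|start..end|strand`
#' (multi-part ranges joined by `+`). Minus-strand features are
#' reverse-complemented to coding orientation; multi-part features are
#' concatenated in `part_index` order.
#'
#' @param record a [genome_record()].
#' @param feature_class one of the eleven [FEATURE_CLASSES].
#' @param path optional output file; when `NULL` the FASTA text is returned.
#' @return FASTA text (empty string when the record has no such features).
#' @export
write_feature_fasta <- function(record, feature_class, path = NULL) {
  stopifnot(inherits(record, "genome_record"))
  if (!feature_class %in% FEATURE_CLASSES)
    stop("unknown feature class '", feature_class, "'; valid classes are: ",
         paste(FEATURE_CLASSES, collapse = ", "))
  f <- record$features
  keep <- f$feature_class == feature_class
  entries <- character(0)
  if (any(keep)) {
    gid <- group_feature_rows(f)
    for (g in unique(gid[keep])) {
      rows <- f[gid == g, , drop = FALSE]
      if (rows$feature_class[1] != feature_class) next
      rows <- rows[order(rows$part_index), , drop = FALSE]
      range_txt <- paste(sprintf("%d..%d", rows$start, rows$end), collapse = "+")
      header <- sprintf(">%s|%s|%s|%s|%s", record$accession, feature_class,
                        rows$name[1], range_txt, rows$strand[1])
      entries <- c(entries, header, feature_sequence(record, rows))
    }
  }
  text <- if (length(entries)) paste0(paste(entries, collapse = "\n"), "\n") else ""
  if (!is.null(path)) {
    writeLines(entries, path)
    invisible(text)
  } else text
}

# Accept CSV feature-type tokens: canonical class names plus the GenBank
# spellings of the signal boxes (leading "-" is hostile to CSV tooling, so
# "Minus10Signal"/"Minus35Signal" are the canonical tokens).
normalize_class_token <- function(token) {
  t <- trimws(token)
  alias <- c("-10 Signal" = "Minus10Signal", "-35 Signal" = "Minus35Signal",
             "-10_signal" = "Minus10Signal", "-35_signal" = "Minus35Signal")
  if (t %in% names(alias)) t <- alias[[t]]
  if (!t %in% FEATURE_CLASSES) return(NA_character_)
  t
}

#' Parse a two-part user annotation file
#'
#' The dialect has two parts: first, annotation items, one per line, with
#' four comma-separated fields `FeatureType,FeatureName,Start,End`
#' (1-based inclusive coordinates); second, the complete genome sequence as
#' a single FASTA record. Items carry no strand field; all user features are
#' taken to lie on the plus strand.
#'
#' @param path path to the annotation file.
#' @return a [genome_record()] (topology `"circular"`, the plastome default)
#'   whose accession is the first token of the FASTA header.
#' @export
parse_user_annotation_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  fasta_i <- which(startsWith(lines, ">"))[1]
  if (is.na(fasta_i)) stop("no FASTA part (line starting with '>') in ", path)
  header <- sub("^>", "", lines[fasta_i])
  accession <- strsplit(trimws(header), "\\s+")[[1]][1]
  sequence <- toupper(gsub("\\s", "", paste(lines[-seq_len(fasta_i)], collapse = "")))
  if (!nzchar(sequence)) stop("FASTA part contains no sequence in ", path)
  L <- nchar(sequence)

  item_lines <- lines[seq_len(fasta_i - 1L)]
  keep <- nzchar(trimws(item_lines))
  feats <- empty_features()
  for (i in which(keep)) {
    fields <- trimws(strsplit(item_lines[i], ",")[[1]])
    if (length(fields) != 4L)
      stop(sprintf("line %d: expected 4 comma-separated fields (FeatureType,FeatureName,Start,End), got %d",
                   i, length(fields)))
    cls <- normalize_class_token(fields[1])
    if (is.na(cls))
      stop(sprintf("line %d: unknown FeatureType '%s'", i, fields[1]))
    se <- suppressWarnings(as.integer(fields[3:4]))
    if (any(is.na(se)))
      stop(sprintf("line %d: non-integer coordinates", i))
    if (se[1] > se[2])
      stop(sprintf("line %d: start %d > end %d", i, se[1], se[2]))
    if (se[1] < 1L || se[2] > L)
      stop(sprintf("line %d: coordinates %d..%d outside [1, %d]", i, se[1], se[2], L))
    feats <- rbind(feats, data.frame(
      feature_class = cls, name = fields[2], start = se[1], end = se[2],
      strand = "+", part_index = 1L, stringsAsFactors = FALSE))
  }
  genome_record(accession, "", sequence, "circular", feats)
}

#' Parse a modified-items file
#'
#' Each line holds one modified item with three comma-separated fields:
#' `FeatureName,Start,End` (1-based inclusive).
#'
#' @param path path to the file.
#' @return data frame with columns `feature_name`, `start`, `end` (possibly
#'   zero rows for an empty file).
#' @export
parse_modified_items_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- data.frame(feature_name = character(0), start = integer(0),
                    end = integer(0), stringsAsFactors = FALSE)
  for (i in seq_along(lines)) {
    if (!nzchar(trimws(lines[i]))) next
    fields <- trimws(strsplit(lines[i], ",")[[1]])
    if (length(fields) != 3L)
      stop(sprintf("line %d: expected 3 comma-separated fields (FeatureName,Start,End), got %d",
                   i, length(fields)))
    se <- suppressWarnings(as.integer(fields[2:3]))
    if (any(is.na(se))) stop(sprintf("line %d: non-integer coordinates", i))
    if (se[1] > se[2]) stop(sprintf("line %d: start %d > end %d", i, se[1], se[2]))
    out <- rbind(out, data.frame(feature_name = fields[1], start = se[1],
                                 end = se[2], stringsAsFactors = FALSE))
  }
  out
}

#' Apply modified items to a genome record
#'
#' Every feature whose normalised name (see [normalize_feature_name()])
#' matches an item's name receives the item's coordinates; all other
#' features are untouched and the input record is not mutated.
#'
#' @param record a [genome_record()].
#' @param items data frame as returned by [parse_modified_items_file()].
#' @return a new [genome_record()].
#' @export
apply_modifications <- function(record, items) {
  stopifnot(inherits(record, "genome_record"))
  if (nrow(items) == 0L) return(record)
  f <- record$features
  keys <- vapply(f$name, normalize_feature_name, character(1))
  unmatched <- character(0)
  for (i in seq_len(nrow(items))) {
    key <- normalize_feature_name(items$feature_name[i])
    hit <- which(keys == key)
    if (!length(hit)) {
      unmatched <- c(unmatched, items$feature_name[i])
      next
    }
    f$start[hit] <- items$start[i]
    f$end[hit] <- items$end[i]
    f$part_index[hit] <- 1L
  }
  if (length(unmatched))
    stop("no feature matches modified item name(s): ",
         paste(unique(unmatched), collapse = ", "))
  genome_record(record$accession, record$organism, record$sequence,
                record$topology, f)
}

#' Parse a comparison list file
#'
#' First line: comma-separated organism names or accessions (the first name
#' is the reference; when user-genome lines follow it denotes the user's
#' unpublished genome). Optional second line: the length of the user genome.
#' Optional following lines: one focused feature per line as
#' `FeatureName,Start,End`.
#'
#' @param path path to the list file.
#' @return object of class `comparison_request`: a list with `names`,
#'   `user_genome_length` (or `NULL`), `user_features` (data frame or
#'   `NULL`) and `region` (`NULL`; set downstream for regional comparison).
#' @export
parse_comparison_list_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("no names line in ", path)
  nms <- trimws(strsplit(lines[1], ",")[[1]])
  nms <- nms[nzchar(nms)]
  if (!length(nms)) stop("no names line in ", path)
  req <- structure(list(names = nms, user_genome_length = NULL,
                        user_features = NULL, region = NULL),
                   class = "comparison_request")
  if (length(lines) >= 2L) {
    len <- suppressWarnings(as.integer(trimws(lines[2])))
    if (is.na(len) || len < 1L)
      stop("line 2: expected a positive integer user genome length, got '",
           trimws(lines[2]), "'")
    req$user_genome_length <- len
    feats <- data.frame(name = character(0), start = integer(0),
                        end = integer(0), stringsAsFactors = FALSE)
    for (i in seq_along(lines)[-(1:2)]) {
      fields <- trimws(strsplit(lines[i], ",")[[1]])
      if (length(fields) != 3L)
        stop(sprintf("line %d: expected 3 fields (FeatureName,Start,End)", i))
      se <- suppressWarnings(as.integer(fields[2:3]))
      if (any(is.na(se))) stop(sprintf("line %d: non-integer coordinates", i))
      if (se[1] > se[2]) stop(sprintf("line %d: start > end", i))
      if (se[2] > len)
        stop(sprintf("line %d: feature end %d beyond user genome length %d", i, se[2], len))
      feats <- rbind(feats, data.frame(name = fields[1], start = se[1],
                                       end = se[2], stringsAsFactors = FALSE))
    }
    req$user_features <- feats
  }
  req
}

#' @export
print.comparison_request <- function(x, ...) {
  cat(sprintf("<comparison_request> reference %s vs %d other genome(s)\n",
              x$names[1], length(x$names) - 1L))
  if (!is.null(x$user_genome_length))
    cat(sprintf("  user genome: %d bp, %d focused feature(s)\n",
                x$user_genome_length,
                if (is.null(x$user_features)) 0L else nrow(x$user_features)))
  invisible(x)
}
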
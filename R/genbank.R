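#' Parse a GenBank flat file into a genome record
#'
#' Reads one GenBank record (LOCUS/ACCESSION/ORGANISM/FEATURES/ORIGIN) and
#' extracts every feature of the eleven recognised classes (see
#' [FEATURE_CLASSES]); all other feature keys (e.g. `source`, `misc_feature`)
#' are ignored. `join(...)` and `complement(...)` locations are decomposed
#' into part-segments with increasing `part_index`, in the order the parts
#' appear in the location string, so every stored segment satisfies
#' `1 <= start <= end <= L`. The feature name is taken from the first of the
#' `/gene`, `/product`, `/note` qualifiers that is present, else synthesised
#' as `class_start_end`.
#'
#' Malformed or out-of-bounds locations produce a per-feature warning and the
#' feature is skipped; a missing ORIGIN sequence block is a fatal error.
#'
#' @param path path to a GenBank flat file.
#' @return a [genome_record()].
#' @seealso [write_genbank()] for the inverse operation.
#' @export
parse_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty GenBank file: ", path)

  locus_i <- grep("^LOCUS", lines)[1]
  if (is.na(locus_i)) stop("no LOCUS line in ", path)
  locus <- strsplit(trimws(sub("^LOCUS", "", lines[locus_i])), "\\s+")[[1]]
  locus_name <- locus[1]
  topology <- if (any(grepl("circular", locus, ignore.case = TRUE))) "circular" else "linear"

  acc_i <- grep("^ACCESSION", lines)
  accession <- if (length(acc_i)) {
    toks <- strsplit(trimws(sub("^ACCESSION", "", lines[acc_i[1]])), "\\s+")[[1]]
    if (length(toks) && nzchar(toks[1])) toks[1] else locus_name
  } else locus_name

  org_i <- grep("^ {2,}ORGANISM", lines)
  organism <- if (length(org_i)) trimws(sub("^ +ORGANISM", "", lines[org_i[1]])) else ""

  origin_i <- grep("^ORIGIN", lines)
  if (!length(origin_i)) stop("no ORIGIN sequence block in ", path)
  end_i <- grep("^//", lines)
  end_i <- if (length(end_i)) end_i[end_i > origin_i[1]][1] else length(lines) + 1L
  if (is.na(end_i)) end_i <- length(lines) + 1L
  seq_lines <- lines[seq(origin_i[1] + 1L, end_i - 1L)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!nzchar(sequence)) stop("ORIGIN block contains no sequence in ", path)
  L <- nchar(sequence)

  feat_i <- grep("^FEATURES", lines)
  features <- empty_features()
  if (length(feat_i) && feat_i[1] < origin_i[1]) {
    block <- lines[seq(feat_i[1] + 1L, origin_i[1] - 1L)]
    features <- parse_feature_block(block, L)
  }
  genome_record(accession, organism, sequence, topology, features)
}

# Split a FEATURES block into (key, location, qualifiers) units and convert
# the recognised keys into feature-table rows.
parse_feature_block <- function(block, L) {
  starts <- grep("^ {5}\\S", block)
  out <- vector("list", length(starts))
  key_of <- setNames(names(.genbank_keys), .genbank_keys)
  for (k in seq_along(starts)) {
    from <- starts[k]
    to <- if (k < length(starts)) starts[k + 1L] - 1L else length(block)
    unit <- block[from:to]
    key <- sub("^ {5}(\\S+).*$", "\\1", unit[1])
    if (!key %in% names(key_of)) next
    cls <- key_of[[key]]
    # location may continue onto lines that do not begin a qualifier
    body <- trimws(unit)
    body[1] <- trimws(sub("^ {5}\\S+", "", unit[1]))
    qual_start <- which(startsWith(body, "/"))[1]
    loc_end <- if (is.na(qual_start)) length(body) else qual_start - 1L
    loc <- paste(body[seq_len(loc_end)], collapse = "")
    parts <- tryCatch(parse_genbank_location(loc),
                      error = function(e) NULL)
    if (is.null(parts) || any(parts$end > L) || any(parts$start < 1L)) {
      warning(sprintf("skipping %s feature with malformed or out-of-bounds location '%s'",
                      cls, loc), call. = FALSE)
      next
    }
    quals <- parse_qualifiers(if (is.na(qual_start)) character(0)
                              else body[qual_start:length(body)])
    name <- quals[["gene"]] %||% quals[["product"]] %||% quals[["note"]] %||%
      sprintf("%s_%d_%d", cls, parts$start[1], parts$end[nrow(parts)])
    out[[k]] <- data.frame(
      feature_class = cls, name = name,
      start = parts$start, end = parts$end, strand = parts$strand,
      part_index = seq_len(nrow(parts)), stringsAsFactors = FALSE
    )
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty_features())
  do.call(rbind, out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Parse a GenBank location string into a data frame of parts
# (start, end, strand). Supports n, n..m, complement(), join(), order()
# and partial-end markers (< and >), which are stripped.
parse_genbank_location <- function(loc, strand = "+") {
  loc <- gsub("[<> ]", "", loc)
  if (grepl("^complement\\(.*\\)$", loc)) {
    inner <- sub("^complement\\((.*)\\)$", "\\1", loc)
    p <- parse_genbank_location(inner, strand)
    p$strand <- ifelse(p$strand == "+", "-", "+")
    return(p)
  }
  if (grepl("^(join|order)\\(.*\\)$", loc)) {
    inner <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
    segs <- split_top_level(inner)
    return(do.call(rbind, lapply(segs, parse_genbank_location, strand = strand)))
  }
  if (grepl("^[0-9]+\\.\\.[0-9]+$", loc)) {
    se <- as.integer(strsplit(loc, "\\.\\.")[[1]])
    if (se[1] > se[2]) stop("start > end in location")
    return(data.frame(start = se[1], end = se[2], strand = strand,
                      stringsAsFactors = FALSE))
  }
  if (grepl("^[0-9]+$", loc)) {
    v <- as.integer(loc)
    return(data.frame(start = v, end = v, strand = strand,
                      stringsAsFactors = FALSE))
  }
  stop("unsupported location: ", loc)
}

# Split on commas not nested inside parentheses.
split_top_level <- function(x) {
  chars <- strsplit(x, "")[[1]]
  depth <- cumsum((chars == "(") - (chars == ")"))
  cuts <- which(chars == "," & depth == 0L)
  bounds <- c(0L, cuts, length(chars) + 1L)
  vapply(seq_len(length(bounds) - 1L), function(i)
    paste(chars[seq(bounds[i] + 1L, bounds[i + 1L] - 1L)], collapse = ""),
    character(1))
}

parse_qualifiers <- function(lines) {
  if (!length(lines)) return(list())
  # re-join continuation lines (those not starting a new qualifier)
  joined <- character(0)
  for (ln in lines) {
    if (startsWith(ln, "/")) joined <- c(joined, ln)
    else if (length(joined)) joined[length(joined)] <- paste(joined[length(joined)], ln)
  }
  out <- list()
  for (q in joined) {
    m <- regmatches(q, regexec('^/([A-Za-z0-9_]+)=?"?([^"]*)"?$', q))[[1]]
    if (length(m) == 3L && !m[2] %in% names(out)) out[[m[2]]] <- m[3]
  }
  out
}

#' Write a genome record as a GenBank flat file
#'
#' Emits a minimal but standard-conforming GenBank record: a LOCUS line with
#' length and topology, a FEATURES table using the conventional key for each
#' of the eleven feature classes (`gene`, `CDS`, ..., `-10_signal`,
#' `-35_signal`), and a 60-column ORIGIN block. Multi-part features (rows
#' sharing name/class/strand with increasing `part_index`) are emitted as
#' `join(...)` locations; minus-strand features as `complement(...)`. The
#' output round-trips exactly through [parse_genbank()].
#'
#' @param record a [genome_record()].
#' @param path optional file path; when `NULL` the text is returned.
#' @return invisibly (or visibly when `path` is `NULL`) the GenBank text.
#' @export
write_genbank <- function(record, path = NULL) {
  stopifnot(inherits(record, "genome_record"))
  L <- genome_length(record)
  out <- c(
    sprintf("LOCUS       %-16s %d bp    DNA     %s PLN 01-JAN-2013",
            record$accession, L, record$topology),
    sprintf("DEFINITION  %s chloroplast genome.",
            if (nzchar(record$organism)) record$organism else record$accession),
    sprintf("ACCESSION   %s", record$accession),
    sprintf("SOURCE      %s", record$organism),
    sprintf("  ORGANISM  %s", record$organism),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", L)
  )
  f <- record$features
  if (nrow(f)) {
    gid <- group_feature_rows(f)
    for (g in unique(gid)) {
      rows <- f[gid == g, , drop = FALSE]
      rows <- rows[order(rows$part_index), , drop = FALSE]
      segs <- sprintf("%d..%d", rows$start, rows$end)
      loc <- if (length(segs) > 1L) sprintf("join(%s)", paste(segs, collapse = ",")) else segs
      if (rows$strand[1] == "-") loc <- sprintf("complement(%s)", loc)
      key <- .genbank_keys[[rows$feature_class[1]]]
      out <- c(out,
               sprintf("     %-16s%s", key, loc),
               sprintf("                     /gene=\"%s\"", rows$name[1]))
    }
  }
  out <- c(out, "ORIGIN")
  seq <- record$sequence
  pos <- seq(1L, L, by = 60L)
  for (p in pos) {
    starts <- seq(p, min(p + 59L, L), by = 10L)
    chunk <- substring(seq, starts, pmin(starts + 9L, L))
    out <- c(out, sprintf("%9d %s", p, tolower(paste(chunk, collapse = " "))))
  }
  out <- c(out, "//")
  text <- paste0(paste(out, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(out, path)
    invisible(text)
  } else text
}
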
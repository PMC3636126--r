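#' Build a feature library from annotated reference genomes
#'
#' Collects one library entry per feature instance of the requested classes
#' (inverted-repeat duplicates are kept as separate entries; their
#' `location_id` distinguishes them). Minus-strand features are stored
#' reverse-complemented, i.e. in coding orientation. Entry names are
#' normalised with [normalize_feature_name()].
#'
#' @param records list of [genome_record()] (>= 1, with >= 1 feature of the
#'   chosen classes).
#' @param feature_classes subset of [FEATURE_CLASSES].
#' @return object of class `feature_library` wrapping a data frame with
#'   columns `normalized_name`, `feature_class`, `source_accession`,
#'   `location_id`, `sequence`.
#' @export
build_feature_library <- function(records, feature_classes = FEATURE_CLASSES) {
  if (inherits(records, "genome_record")) records <- list(records)
  if (!length(records)) stop("no reference records supplied")
  bad <- setdiff(feature_classes, FEATURE_CLASSES)
  if (length(bad)) stop("unknown feature class(es): ", paste(bad, collapse = ", "))
  entries <- list()
  for (rec in records) {
    f <- rec$features
    if (!nrow(f)) next
    gid <- group_feature_rows(f)
    for (g in unique(gid)) {
      rows <- f[gid == g, , drop = FALSE]
      if (!rows$feature_class[1] %in% feature_classes) next
      rows <- rows[order(rows$part_index), , drop = FALSE]
      loc <- sprintf("%s:%s(%s)", rec$accession,
                     paste(sprintf("%d..%d", rows$start, rows$end), collapse = "+"),
                     rows$strand[1])
      entries[[length(entries) + 1L]] <- data.frame(
        normalized_name = normalize_feature_name(rows$name[1]),
        feature_class = rows$feature_class[1],
        source_accession = rec$accession,
        location_id = loc,
        sequence = feature_sequence(rec, rows),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(entries))
    stop("no features of the requested class(es) in the reference records")
  structure(list(entries = do.call(rbind, entries)), class = "feature_library")
}

#' @export
print.feature_library <- function(x, ...) {
  cat(sprintf("<feature_library> %d entries from %d genome(s)\n",
              nrow(x$entries), length(unique(x$entries$source_accession))))
  invisible(x)
}

#' Default scoring parameters for the seeded local aligner
#'
#' Exact seed word of 11 nt; match +1, mismatch -2; a gap of length k costs
#' `gap_open + k * gap_extend` (5 + 2k). The E-value of a hit with score S
#' is `K * m * n * exp(-lambda * S)` with the ungapped Karlin-Altschul
#' parameters for the +1/-2 scheme (lambda = 1.33, K = 0.621), used as a
#' documented approximation for the gapped scheme; m is the query length
#' and n the total library length.
#'
#' @param word_size exact seed length.
#' @param match,mismatch substitution scores.
#' @param gap_open,gap_extend positive gap costs.
#' @param lambda,K Karlin-Altschul parameters.
#' @return named list of scoring parameters.
#' @export
align_scoring <- function(word_size = 11L, match = 1, mismatch = -2,
                          gap_open = 5, gap_extend = 2,
                          lambda = 1.33, K = 0.621) {
  list(word_size = as.integer(word_size), match = match, mismatch = mismatch,
       gap_open = gap_open, gap_extend = gap_extend, lambda = lambda, K = K)
}

# Substitution matrix over A/C/G/T/N: ambiguity (mapped to N) never matches.
substitution_matrix <- function(scoring) {
  letters <- c("A", "C", "G", "T", "N")
  mat <- matrix(scoring$mismatch, 5, 5, dimnames = list(letters, letters))
  diag(mat)[1:4] <- scoring$match
  mat["N", "N"] <- scoring$mismatch
  mat
}

sanitize_dna <- function(x) gsub("[^ACGT]", "N", toupper(x))

#' Seeded local alignment of a query against a feature library
#'
#' Seed-and-extend local alignment replacing an external BLAST dependency:
#' exact `word_size`-mer seeds shared between the query and a library entry
#' are grouped into diagonal clusters; each cluster defines a query window
#' in which the optimal local alignment of the full entry is computed by
#' Smith-Waterman (via Biostrings) under the given scoring scheme.
#' Duplicate alignments from split clusters are collapsed. Hits are
#' returned sorted by score descending.
#'
#' @param query_segment DNA string (forward strand; callers handle strand).
#' @param library a [build_feature_library()] object.
#' @param scoring see [align_scoring()].
#' @return data frame with one row per hit: `library_index`,
#'   `normalized_name`, `feature_class`, `location_id`, `q_start`, `q_end`,
#'   `lib_start`, `lib_end`, `n_match`, `aln_len`, `identity`, `score`,
#'   `evalue`.
#' @export
local_align <- function(query_segment, library, scoring = align_scoring()) {
  stopifnot(inherits(library, "feature_library"))
  q <- sanitize_dna(as_sequence(query_segment))
  if (!nzchar(q)) stop("query must be non-empty")
  w <- scoring$word_size
  lq <- nchar(q)
  lib <- library$entries
  lib_total <- sum(nchar(lib$sequence))
  submat <- substitution_matrix(scoring)
  empty <- data.frame(library_index = integer(0), normalized_name = character(0),
                      feature_class = character(0), location_id = character(0),
                      q_start = integer(0), q_end = integer(0),
                      lib_start = integer(0), lib_end = integer(0),
                      n_match = integer(0), aln_len = integer(0),
                      identity = numeric(0), score = numeric(0),
                      evalue = numeric(0), stringsAsFactors = FALSE)
  if (lq < w) return(empty)

  qk <- substring(q, seq_len(lq - w + 1L), seq_len(lq - w + 1L) + w - 1L)
  ok_q <- !grepl("N", qk, fixed = TRUE)
  q_pos <- split(which(ok_q), qk[ok_q])

  hits <- list()
  for (e in seq_len(nrow(lib))) {
    es <- sanitize_dna(lib$sequence[e])
    le <- nchar(es)
    if (le < w) next
    ek <- substring(es, seq_len(le - w + 1L), seq_len(le - w + 1L) + w - 1L)
    ok_e <- !grepl("N", ek, fixed = TRUE)
    ie <- which(ok_e)
    qhit <- q_pos[ek[ie]]
    nh <- lengths(qhit)
    keep <- nh > 0L & !is.na(names(qhit))
    if (!any(keep)) next
    epos <- rep(ie[keep], nh[keep])
    qpos <- unlist(qhit[keep], use.names = FALSE)
    d <- qpos - epos
    o <- order(d, qpos)
    d <- d[o]; qpos <- qpos[o]
    band <- max(30L, ceiling(0.2 * le))
    cluster <- cumsum(c(TRUE, diff(d) > band))
    for (cl in unique(cluster)) {
      qs <- qpos[cluster == cl]
      win_s <- max(1L, min(qs) - le)
      win_e <- min(lq, max(qs) + w - 1L + le)
      window <- substr(q, win_s, win_e)
      aln <- Biostrings::pairwiseAlignment(
        pattern = Biostrings::DNAString(es),
        subject = Biostrings::DNAString(window),
        type = "local", substitutionMatrix = submat,
        gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
      sc <- aln@score
      if (sc <= 0) next
      ap <- as.character(Biostrings::alignedPattern(aln))
      as_ <- as.character(Biostrings::alignedSubject(aln))
      pa <- strsplit(ap, "")[[1]]
      sa <- strsplit(as_, "")[[1]]
      n_match <- sum(pa == sa & pa != "-")
      aln_len <- length(pa)
      sub_rng <- Biostrings::subject(aln)
      pat_rng <- Biostrings::pattern(aln)
      hits[[length(hits) + 1L]] <- data.frame(
        library_index = e,
        normalized_name = lib$normalized_name[e],
        feature_class = lib$feature_class[e],
        location_id = lib$location_id[e],
        q_start = win_s + as.integer(Biostrings::start(sub_rng)) - 1L,
        q_end = win_s + as.integer(Biostrings::end(sub_rng)) - 1L,
        lib_start = as.integer(Biostrings::start(pat_rng)),
        lib_end = as.integer(Biostrings::end(pat_rng)),
        n_match = n_match, aln_len = aln_len,
        identity = n_match / aln_len,
        score = sc,
        evalue = scoring$K * lq * lib_total * exp(-scoring$lambda * sc),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) return(empty)
  out <- do.call(rbind, hits)
  out <- out[!duplicated(out[, c("library_index", "q_start", "q_end", "score")]), ,
             drop = FALSE]
  out <- out[order(-out$score, out$evalue, out$q_start, out$location_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Default annotation-transfer thresholds
#'
#' @param min_identity minimum alignment identity fraction.
#' @param max_expectation maximum E-value.
#' @param min_length_ratio minimum `(End - Start)/L` ratio.
#' @param max_overlap maximum fraction (of the shorter interval) by which
#'   two surviving entries with the same normalised name may overlap.
#' @return named list of thresholds.
#' @export
annotation_thresholds <- function(min_identity = 0.7, max_expectation = 1e-6,
                                  min_length_ratio = 0.2, max_overlap = 0.5) {
  list(min_identity = min_identity, max_expectation = max_expectation,
       min_length_ratio = min_length_ratio, max_overlap = max_overlap)
}

#' Annotate a draft genome by similarity to a feature library
#'
#' Runs the seeded local aligner on both strands of the query, filters hits
#' by identity, E-value and length ratio, and reduces them to a
#' non-redundant entry list: among overlapping hits carrying the same
#' normalised name, only the highest-scoring one survives (biological
#' information is attached from the most similar library feature). Entries
#' are sorted by start position.
#'
#' Each entry carries the 8 canonical fields: NormalizedFeatureName, Start,
#' End, FeatureName/Location, LengthRatio (`(End - Start)/L` with L the
#' matched library feature length — the literal published formula, one
#' less than the inclusive span; see the methods vignette), Identity
#' (matched bases over alignment columns, in \[0, 1\]), Score and
#' Expectation — plus two carrier columns (`strand`, `feature_class`) used
#' only by [write_annotation_genbank()] and never emitted by the tabular
#' serialiser.
#'
#' @param query a [genome_record()] or DNA string.
#' @param library a [build_feature_library()] object.
#' @param thresholds see [annotation_thresholds()].
#' @param scoring see [align_scoring()].
#' @return data frame of class `annotation_entries` (possibly empty).
#' @export
annotate_genome <- function(query, library,
                            thresholds = annotation_thresholds(),
                            scoring = align_scoring()) {
  qseq <- as_sequence(query)
  lq <- nchar(qseq)
  if (lq < scoring$word_size) stop("query shorter than the seed word size")
  fwd <- local_align(qseq, library, scoring)
  if (nrow(fwd)) fwd$strand <- "+"
  rev <- local_align(revcomp(qseq), library, scoring)
  if (nrow(rev)) {
    tmp <- lq - rev$q_end + 1L
    rev$q_end <- lq - rev$q_start + 1L
    rev$q_start <- tmp
    rev$strand <- "-"
  }
  hits <- rbind(if (nrow(fwd)) fwd else NULL, if (nrow(rev)) rev else NULL)
  empty <- structure(
    data.frame(normalized_feature_name = character(0), start = integer(0),
               end = integer(0), feature_name_or_location = character(0),
               length_ratio = numeric(0), identity = numeric(0),
               score = numeric(0), expectation = numeric(0),
               strand = character(0), feature_class = character(0),
               stringsAsFactors = FALSE),
    class = c("annotation_entries", "data.frame"))
  if (is.null(hits) || !nrow(hits)) return(empty)

  lib_len <- nchar(library$entries$sequence)[hits$library_index]
  hits$length_ratio <- (hits$q_end - hits$q_start) / lib_len
  hits <- hits[hits$identity >= thresholds$min_identity &
                 hits$evalue <= thresholds$max_expectation &
                 hits$length_ratio >= thresholds$min_length_ratio, , drop = FALSE]
  if (!nrow(hits)) return(empty)

  hits <- hits[order(-hits$score, hits$evalue, hits$q_start, hits$location_id), ,
               drop = FALSE]
  kept <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    same <- which(kept & hits$normalized_name == hits$normalized_name[i])
    redundant <- FALSE
    for (j in same) {
      ov <- min(hits$q_end[i], hits$q_end[j]) - max(hits$q_start[i], hits$q_start[j]) + 1L
      shorter <- min(hits$q_end[i] - hits$q_start[i], hits$q_end[j] - hits$q_start[j]) + 1L
      if (ov > thresholds$max_overlap * shorter) { redundant <- TRUE; break }
    }
    kept[i] <- !redundant
  }
  hits <- hits[kept, , drop = FALSE]
  hits <- hits[order(hits$q_start, hits$q_end, hits$normalized_name), , drop = FALSE]
  structure(
    data.frame(normalized_feature_name = hits$normalized_name,
               start = hits$q_start, end = hits$q_end,
               feature_name_or_location = hits$location_id,
               length_ratio = hits$length_ratio, identity = hits$identity,
               score = hits$score, expectation = hits$evalue,
               strand = hits$strand, feature_class = hits$feature_class,
               stringsAsFactors = FALSE, row.names = NULL),
    class = c("annotation_entries", "data.frame"))
}

#' Serialise annotation entries as the 8-column table
#'
#' Writes a TSV with exactly the eight canonical columns in order:
#' NormalizedFeatureName, Start, End, FeatureNameOrLocation, LengthRatio,
#' Identity, Score, Expectation.
#'
#' @param entries an `annotation_entries` data frame.
#' @param path optional output file.
#' @return TSV text.
#' @export
write_annotation_table <- function(entries, path = NULL) {
  header <- paste(c("NormalizedFeatureName", "Start", "End",
                    "FeatureNameOrLocation", "LengthRatio", "Identity",
                    "Score", "Expectation"), collapse = "\t")
  rows <- if (nrow(entries)) sprintf(
    "%s\t%d\t%d\t%s\t%.4f\t%.4f\t%s\t%.3e",
    entries$normalized_feature_name, entries$start, entries$end,
    entries$feature_name_or_location, entries$length_ratio,
    entries$identity, format_num(entries$score), entries$expectation)
  lines <- c(header, rows)
  text <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(lines, path)
    invisible(text)
  } else text
}

#' Write transferred annotations as a GenBank flat file
#'
#' Builds a genome record from the query sequence and the transferred
#' entries and serialises it with [write_genbank()], so the result can be
#' re-used by [parse_genbank()].
#'
#' @param query the annotated [genome_record()] (or DNA string; then a
#'   generic accession is used).
#' @param entries an `annotation_entries` data frame.
#' @param path optional output file.
#' @return GenBank text.
#' @export
write_annotation_genbank <- function(query, entries, path = NULL) {
  if (!inherits(query, "genome_record"))
    query <- genome_record("query", "", as_sequence(query), "circular")
  feats <- if (nrow(entries)) data.frame(
    feature_class = if (!is.null(entries$feature_class)) entries$feature_class else "Gene",
    name = entries$normalized_feature_name,
    start = entries$start, end = entries$end,
    strand = if (!is.null(entries$strand)) entries$strand else "+",
    part_index = 1L, stringsAsFactors = FALSE
  ) else empty_features()
  rec <- genome_record(query$accession, query$organism, query$sequence,
                       query$topology, feats)
  write_genbank(rec, path)
}
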
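#' Maximal exact matches between two sequences
#'
#' Finds every maximal exact match (MEM) of length >= `min_len` between
#' genome A and genome B, on both strands of B. A MEM cannot be extended by
#' a single base on either side without breaking the match. Positions
#' carrying ambiguity codes never match. Matches are located by hashing all
#' `min_len`-mers of B and merging runs of consecutive seed hits along each
#' diagonal, which yields exactly the maximal matches.
#'
#' @param seq_a,seq_b DNA strings or [genome_record()] objects.
#' @param min_len minimum reported match length (>= 2); default 20, the
#'   conventional minimum unique-match length of whole-genome aligners.
#' @return data frame with columns `start_a`, `start_b`, `length`,
#'   `strand_b`, sorted by (start_a, start_b, strand_b). `start_b` is
#'   always a forward-strand coordinate on B; for `strand_b == "-"` the
#'   matched text of A equals the reverse complement of
#'   B[start_b..start_b+length-1].
#' @export
maximal_exact_matches <- function(seq_a, seq_b, min_len = 20) {
  a <- as_sequence(seq_a)
  b <- as_sequence(seq_b)
  min_len <- as.integer(min_len)
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  if (min_len < 2L) stop("min_len must be >= 2")
  lb <- nchar(b)
  fwd <- mem_one_strand(a, b, min_len)
  if (nrow(fwd)) fwd$strand_b <- "+"
  rev <- mem_one_strand(a, revcomp(b), min_len)
  if (nrow(rev)) {
    rev$start_b <- lb - (rev$start_b + rev$length - 1L) + 1L
    rev$strand_b <- "-"
  }
  out <- rbind(
    if (nrow(fwd)) fwd else NULL,
    if (nrow(rev)) rev else NULL
  )
  if (is.null(out) || !nrow(out))
    return(data.frame(start_a = integer(0), start_b = integer(0),
                      length = integer(0), strand_b = character(0),
                      stringsAsFactors = FALSE))
  out <- out[order(out$start_a, out$start_b, out$strand_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# MEMs of a against the forward strand of b via seed-run merging: a maximal
# run of consecutive matching k-mers (k = min_len) along one diagonal is a
# maximal match of length (run span + k - 1), and every match >= k contains
# such a run.
mem_one_strand <- function(a, b, k) {
  la <- nchar(a)
  lb <- nchar(b)
  empty <- data.frame(start_a = integer(0), start_b = integer(0),
                      length = integer(0), stringsAsFactors = FALSE)
  if (la < k || lb < k) return(empty)
  ka <- substring(a, seq_len(la - k + 1L), seq_len(la - k + 1L) + k - 1L)
  kb <- substring(b, seq_len(lb - k + 1L), seq_len(lb - k + 1L) + k - 1L)
  ok_a <- !grepl("[^ACGT]", ka)
  ok_b <- !grepl("[^ACGT]", kb)
  pos_b <- split(which(ok_b), kb[ok_b])
  ia <- which(ok_a)
  hits_b <- pos_b[ka[ia]]
  nh <- lengths(hits_b)
  keep <- nh > 0L & !is.na(names(hits_b))
  # unname/flatten: pairs (i in a, j in b) sharing a k-mer
  i <- rep(ia[keep], nh[keep])
  j <- unlist(hits_b[keep], use.names = FALSE)
  if (!length(i)) return(empty)
  d <- i - j
  o <- order(d, i)
  i <- i[o]; j <- j[o]; d <- d[o]
  newrun <- c(TRUE, d[-1] != d[-length(d)] | i[-1] != i[-length(i)] + 1L)
  run <- cumsum(newrun)
  start_i <- tapply(i, run, min)
  end_i <- tapply(i, run, max)
  start_j <- tapply(j, run, min)
  data.frame(start_a = as.integer(start_i), start_b = as.integer(start_j),
             length = as.integer(end_i - start_i + k),
             stringsAsFactors = FALSE)
}

#' Matched nucleotide count between two genomes
#'
#' N_mat is the number of positions of A covered by at least one maximal
#' exact match (either strand), averaged with the covered position count of
#' B and rounded half up. Averaging keeps N_mat symmetric in its two
#' genomes even when their lengths differ; overlapping matches count each
#' position once.
#'
#' @inheritParams maximal_exact_matches
#' @return integer N_mat (0 when there is no match at all).
#' @export
matched_nucleotides <- function(seq_a, seq_b, min_len = 20) {
  a <- as_sequence(seq_a)
  b <- as_sequence(seq_b)
  mems <- maximal_exact_matches(a, b, min_len)
  if (!nrow(mems)) return(0L)
  cov_a <- logical(nchar(a))
  cov_b <- logical(nchar(b))
  for (r in seq_len(nrow(mems))) {
    cov_a[mems$start_a[r]:(mems$start_a[r] + mems$length[r] - 1L)] <- TRUE
    cov_b[mems$start_b[r]:(mems$start_b[r] + mems$length[r] - 1L)] <- TRUE
  }
  as.integer(floor((sum(cov_a) + sum(cov_b)) / 2 + 0.5))
}

#' Alignment-based genome distance
#'
#' The whole-genome alignment distance D_AB = -log2(N_mat / L_max), where
#' N_mat is the matched nucleotide count between genomes A and B and L_max
#' the maximum genome length in the analysed set. N_mat is clamped into
#' \[1, L_max\] so the distance stays finite (an empty match set gives
#' D = log2(L_max)).
#'
#' @param n_mat matched nucleotide count.
#' @param l_max maximum genome length in the set (>= 1).
#' @return non-negative real; 0 iff `n_mat == l_max`.
#' @export
alignment_distance <- function(n_mat, l_max) {
  if (l_max < 1) stop("l_max must be >= 1")
  n_mat <- min(max(as.numeric(n_mat), 1), as.numeric(l_max))
  -log2(n_mat / l_max)
}

#' Alignment-based distance matrix over a set of genomes
#'
#' L_max is computed once over the whole input set; every off-diagonal
#' entry is `alignment_distance(matched_nucleotides(A, B, min_len), L_max)`
#' and the diagonal is 0 by definition. Note that the printed formula would
#' give a nonzero self-distance to any genome shorter than L_max; the
#' diagonal is defined as 0 instead (see the methods vignette).
#'
#' @param genomes list of [genome_record()] with distinct accessions
#'   (>= 2).
#' @param min_len minimum exact-match length.
#' @return a [distance_matrix()].
#' @export
alignment_distance_matrix <- function(genomes, min_len = 20) {
  stopifnot(length(genomes) >= 2L)
  labels <- vapply(genomes, function(g) g$accession, character(1))
  if (anyDuplicated(labels)) stop("duplicate genome labels")
  l_max <- max(vapply(genomes, genome_length, integer(1)))
  n <- length(genomes)
  m <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n)) {
    n_mat <- matched_nucleotides(genomes[[i]], genomes[[j]], min_len)
    m[i, j] <- m[j, i] <- alignment_distance(n_mat, l_max)
  }
  distance_matrix(m, labels)
}
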
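#' Base-base correlation (BBC) feature vector
#'
#' Computes the 16-component alignment-free BBC vector of a genome. For
#' each ordered base pair (i, j) over \{A, C, G, T\} the component is
#' \deqn{\sum_{l=1}^{K} P_{ij}(l) \log_2 \frac{P_{ij}(l)}{P_i P_j}}
#' where \eqn{P_i} is the frequency of base i among unambiguous positions
#' and \eqn{P_{ij}(l)} the frequency of observing base i at position t and
#' base j at position t+l over all windows t = 1..L-l with both positions
#' unambiguous. Zero-probability terms contribute 0. Positions carrying
#' IUPAC ambiguity codes are excluded from both marginal and joint counts.
#' The sequence is treated as linear (no wrap-around windows) even for
#' circular genomes; the effect is O(K/L), negligible at plastome scale.
#'
#' @param sequence DNA string or [genome_record()].
#' @param K maximum gap depth (default 10); must satisfy `K < L`.
#' @param label genome label (defaults to the record accession).
#' @return object of class `bbc_vector`: list with `components` (named
#'   numeric of length 16, order AA, AC, ..., TT), `K` and `genome_label`.
#' @export
bbc_vector <- function(sequence, K = 10, label = NULL) {
  if (inherits(sequence, "genome_record") && is.null(label))
    label <- sequence$accession
  seq <- as_sequence(sequence)
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1")
  L <- nchar(seq)
  if (K >= L) stop("K must be smaller than the sequence length")
  bases <- c("A", "C", "G", "T")
  ints <- match(strsplit(seq, "")[[1]], bases)  # NA for ambiguity codes
  n_ok <- sum(!is.na(ints))
  if (n_ok < 2L) stop("sequence has fewer than 2 unambiguous bases")
  p <- tabulate(ints, 4L) / n_ok
  p_indep <- rep(p, each = 4L) * rep(p, times = 4L)  # index (i-1)*4 + j
  comp <- numeric(16L)
  for (l in seq_len(K)) {
    x <- ints[seq_len(L - l)]
    y <- ints[seq_len(L - l) + l]
    ok <- !is.na(x) & !is.na(y)
    if (!any(ok)) next
    pij <- tabulate((x[ok] - 1L) * 4L + y[ok], 16L) / sum(ok)
    term <- ifelse(pij > 0 & p_indep > 0, pij * log2(pij / p_indep), 0)
    comp <- comp + term
  }
  names(comp) <- paste0(rep(bases, each = 4L), rep(bases, times = 4L))
  structure(list(components = comp, K = K,
                 genome_label = if (is.null(label)) "" else label),
            class = "bbc_vector")
}

#' @export
print.bbc_vector <- function(x, ...) {
  cat(sprintf("<bbc_vector> %s (K = %d)\n",
              if (nzchar(x$genome_label)) x$genome_label else "unlabelled", x$K))
  print(round(x$components, 6))
  invisible(x)
}

#' The ten vector distance measures
#' @format Character vector of length 10.
#' @export
BBC_DISTANCE_METHODS <- c(
  "euclidean", "sqeuclidean", "manhattan", "chebyshev", "minkowski",
  "canberra", "braycurtis", "cosine", "pearson", "spearman"
)

#' Distance between two feature vectors
#'
#' All ten measures are symmetric, non-negative and zero for identical
#' vectors. `minkowski` uses order `p` (default 3); `braycurtis` operates
#' on absolute values (BBC components may be negative); `cosine`,
#' `pearson` (1 - r) and `spearman` (1 - rank r) define the distance of
#' two degenerate (zero-norm / constant) vectors as 0 when both are
#' degenerate and 1 when only one is, removing undefined divisions.
#'
#' @param u,v `bbc_vector` objects (with equal `K`) or plain numeric
#'   vectors of equal length.
#' @param method one of [BBC_DISTANCE_METHODS].
#' @param p Minkowski order.
#' @return non-negative real.
#' @export
vector_distance <- function(u, v, method = "euclidean", p = 3) {
  if (inherits(u, "bbc_vector") && inherits(v, "bbc_vector") && u$K != v$K)
    stop("BBC vectors have mismatched K (", u$K, " vs ", v$K, ")")
  if (inherits(u, "bbc_vector")) u <- u$components
  if (inherits(v, "bbc_vector")) v <- v$components
  stopifnot(is.numeric(u), is.numeric(v), length(u) == length(v))
  if (!method %in% BBC_DISTANCE_METHODS)
    stop("unknown method '", method, "'; the ten methods are: ",
         paste(BBC_DISTANCE_METHODS, collapse = ", "))
  d <- u - v
  corr_dist <- function(a, b) {
    ca <- stats::sd(a) == 0
    cb <- stats::sd(b) == 0
    if (ca && cb) return(0)
    if (ca || cb) return(1)
    max(0, 1 - cor(a, b))
  }
  switch(method,
    euclidean  = sqrt(sum(d^2)),
    sqeuclidean = sum(d^2),
    manhattan  = sum(abs(d)),
    chebyshev  = max(abs(d)),
    minkowski  = sum(abs(d)^p)^(1 / p),
    canberra   = {
      den <- abs(u) + abs(v)
      sum(ifelse(den > 0, abs(d) / den, 0))
    },
    braycurtis = {
      den <- sum(abs(u) + abs(v))
      if (den > 0) sum(abs(d)) / den else 0
    },
    cosine     = {
      nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
      if (nu == 0 && nv == 0) 0
      else if (nu == 0 || nv == 0) 1
      else max(0, 1 - sum(u * v) / (nu * nv))
    },
    pearson    = corr_dist(u, v),
    spearman   = corr_dist(rank(u), rank(v))
  )
}

#' Labelled distance matrix
#'
#' Wraps a symmetric non-negative matrix with zero diagonal; the container
#' used by both distance pipelines and by [nj_tree()].
#'
#' @param values square numeric matrix.
#' @param labels genome labels (defaults to rownames of `values`).
#' @return matrix of class `distance_matrix` with dimnames set to labels.
#' @export
distance_matrix <- function(values, labels = rownames(values)) {
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  if (is.null(labels)) stop("labels required")
  labels <- as.character(labels)
  if (anyDuplicated(labels)) stop("duplicate genome labels")
  if (length(labels) != nrow(values)) stop("label/matrix size mismatch")
  if (any(!is.finite(values))) stop("distance matrix entries must be finite")
  if (any(values < 0)) stop("distance matrix entries must be non-negative")
  if (max(abs(values - t(values))) > 1e-8) stop("distance matrix must be symmetric")
  if (any(diag(values) != 0)) stop("distance matrix diagonal must be zero")
  values <- (values + t(values)) / 2
  dimnames(values) <- list(labels, labels)
  class(values) <- c("distance_matrix", class(values))
  values
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("<distance_matrix> %d genomes\n", nrow(x)))
  print(round(unclass(x), 6))
  invisible(x)
}

#' BBC distance matrix over a set of genomes
#'
#' Computes one BBC vector per genome and all pairwise distances under the
#' chosen measure.
#'
#' @param genomes list of [genome_record()] with distinct accessions.
#' @param method one of [BBC_DISTANCE_METHODS].
#' @param K maximum gap depth.
#' @param p Minkowski order.
#' @return a [distance_matrix()] over the genome labels in input order.
#' @export
bbc_distance_matrix <- function(genomes, method = "euclidean", K = 10, p = 3) {
  stopifnot(length(genomes) >= 2L)
  labels <- vapply(genomes, function(g) g$accession, character(1))
  if (anyDuplicated(labels)) stop("duplicate genome labels")
  vecs <- lapply(genomes, bbc_vector, K = K)
  n <- length(genomes)
  m <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n)) {
    m[i, j] <- m[j, i] <- vector_distance(vecs[[i]], vecs[[j]], method, p)
  }
  distance_matrix(m, labels)
}
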
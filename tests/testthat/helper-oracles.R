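# Independent oracles used to validate the fast implementations, plus small
# fixture builders. Each oracle is a deliberately naive re-derivation from
# first principles and shares no code with the package internals.

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Exhaustive BBC: explicit double loop over positions for every lag.
bbc_oracle <- function(seq, K) {
  bases <- c("A", "C", "G", "T")
  idx <- match(strsplit(toupper(seq), "")[[1]], bases)
  L <- length(idx)
  p <- numeric(4)
  for (b in 1:4) p[b] <- sum(!is.na(idx) & idx == b)
  p <- p / sum(!is.na(idx))
  comp <- matrix(0, 4, 4)
  for (l in 1:K) {
    cnt <- matrix(0, 4, 4)
    tot <- 0
    for (t in 1:(L - l)) {
      i <- idx[t]; j <- idx[t + l]
      if (!is.na(i) && !is.na(j)) {
        cnt[i, j] <- cnt[i, j] + 1
        tot <- tot + 1
      }
    }
    if (tot == 0) next
    for (i in 1:4) for (j in 1:4) {
      pij <- cnt[i, j] / tot
      if (pij > 0 && p[i] > 0 && p[j] > 0)
        comp[i, j] <- comp[i, j] + pij * log2(pij / (p[i] * p[j]))
    }
  }
  out <- as.vector(t(comp))
  names(out) <- paste0(rep(bases, each = 4), rep(bases, times = 4))
  out
}

# Exhaustive MEM finder: test every start pair (i, j) for left-maximality,
# then extend right as far as the match goes. O(n^2 * len).
mem_oracle_strand <- function(av, bv, k) {
  la <- length(av); lb <- length(bv)
  is_base <- function(x) x %in% c("A", "C", "G", "T")
  res <- list()
  for (i in seq_len(la)) for (j in seq_len(lb)) {
    if (i > 1 && j > 1 && is_base(av[i - 1]) && av[i - 1] == bv[j - 1]) next
    len <- 0L
    while (i + len <= la && j + len <= lb &&
           is_base(av[i + len]) && av[i + len] == bv[j + len]) len <- len + 1L
    if (len >= k) res[[length(res) + 1L]] <- c(i, j, len)
  }
  res
}

mem_oracle <- function(a, b, min_len) {
  av <- strsplit(toupper(a), "")[[1]]
  bv <- strsplit(toupper(b), "")[[1]]
  lb <- length(bv)
  rb <- rev(chartr("ACGT", "TGCA", bv))
  fwd <- mem_oracle_strand(av, bv, min_len)
  rev_ <- mem_oracle_strand(av, rb, min_len)
  rows <- list()
  for (h in fwd)
    rows[[length(rows) + 1L]] <- data.frame(start_a = h[1], start_b = h[2],
                                            length = h[3], strand_b = "+")
  for (h in rev_)
    rows[[length(rows) + 1L]] <- data.frame(start_a = h[1],
                                            start_b = lb - (h[2] + h[3] - 1L) + 1L,
                                            length = h[3], strand_b = "-")
  if (!length(rows))
    return(data.frame(start_a = integer(0), start_b = integer(0),
                      length = integer(0), strand_b = character(0)))
  out <- do.call(rbind, rows)
  out <- out[order(out$start_a, out$start_b, out$strand_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# A small record carrying one feature of each of the eleven classes.
record_with_all_classes <- function() {
  set.seed(99)
  seq <- random_seq(1200)
  feats <- data.frame(
    feature_class = FEATURE_CLASSES,
    name = paste0("f_", FEATURE_CLASSES),
    start = seq(10, by = 100, length.out = 11),
    end = seq(59, by = 100, length.out = 11),
    strand = rep(c("+", "-"), length.out = 11),
    part_index = 1L, stringsAsFactors = FALSE)
  genome_record("ALLCLS1", "test organism", seq, "circular", feats)
}

make_record <- function(accession, names, starts, ends,
                        classes = "Gene", strands = "+", L = 5000, seed = 1) {
  set.seed(seed)
  feats <- data.frame(feature_class = classes, name = names, start = starts,
                      end = ends, strand = strands, part_index = 1L,
                      stringsAsFactors = FALSE)
  genome_record(accession, "", random_seq(L), "circular", feats)
}
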
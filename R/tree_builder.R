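#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining: iteratively join the pair (i, j) minimising
#' Q(i, j) = (n - 2) d(i, j) - sum_k d(i, k) - sum_k d(j, k), with branch
#' lengths from the standard two-point formulas and, for the final three
#' nodes, the three-point formulas. Ties in Q are broken deterministically
#' on the lexicographically lowest label pair, where every active node is
#' identified by the smallest leaf label it contains, so the tree is
#' bit-reproducible. Negative branch-length estimates are clamped to 0
#' with the deficit added to the sibling edge.
#'
#' @param matrix a [distance_matrix()] (or labelled symmetric numeric
#'   matrix) over n >= 3 taxa.
#' @return an unrooted tree of class `phylo` (ape) whose tip set equals the
#'   matrix labels.
#' @export
nj_tree <- function(matrix) {
  m <- unclass(matrix)
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("need a square matrix")
  n <- nrow(m)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa")
  labels <- rownames(m)
  if (is.null(labels)) stop("matrix must carry taxon labels")
  if (max(abs(m - t(m))) > 1e-8) stop("matrix must be symmetric")
  mode(m) <- "double"

  nodes <- lapply(labels, function(l) list(leaf = l, min_label = l))
  active <- seq_len(n)

  while (length(active) > 3L) {
    na <- length(active)
    D <- m[active, active, drop = FALSE]
    r <- rowSums(D)
    Q <- (na - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    pair_labels <- t(apply(cand, 1, function(ij) {
      sort(c(nodes[[active[ij[1]]]]$min_label, nodes[[active[ij[2]]]]$min_label))
    }))
    best <- order(pair_labels[, 1], pair_labels[, 2])[1]
    i <- cand[best, 1]; j <- cand[best, 2]

    dij <- D[i, j]
    li <- dij / 2 + (r[i] - r[j]) / (2 * (na - 2))
    lj <- dij - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }

    ai <- active[i]; aj <- active[j]
    new_node <- list(
      children = list(list(node = nodes[[ai]], len = li),
                      list(node = nodes[[aj]], len = lj)),
      min_label = min(nodes[[ai]]$min_label, nodes[[aj]]$min_label)
    )
    d_new <- pmax(0, (m[ai, active] + m[aj, active] - dij) / 2)
    m <- rbind(cbind(m, 0), 0)
    idx <- nrow(m)
    m[idx, active] <- d_new
    m[active, idx] <- d_new
    m[idx, idx] <- 0
    nodes[[idx]] <- new_node
    active <- c(setdiff(active, c(ai, aj)), idx)
  }

  x <- active[1]; y <- active[2]; z <- active[3]
  dxy <- m[x, y]; dxz <- m[x, z]; dyz <- m[y, z]
  lx <- max(0, (dxy + dxz - dyz) / 2)
  ly <- max(0, (dxy + dyz - dxz) / 2)
  lz <- max(0, (dxz + dyz - dxy) / 2)
  root <- list(
    children = list(list(node = nodes[[x]], len = lx),
                    list(node = nodes[[y]], len = ly),
                    list(node = nodes[[z]], len = lz)),
    min_label = min(nodes[[x]]$min_label, nodes[[y]]$min_label,
                    nodes[[z]]$min_label)
  )
  ape::read.tree(text = newick_from_node(root))
}

# Serialize the internal node structure as Newick, children ordered by the
# smallest contained leaf label.
newick_from_node <- function(node) {
  rec <- function(nd) {
    if (!is.null(nd$leaf)) return(nd$leaf)
    ord <- order(vapply(nd$children, function(ch) ch$node$min_label, character(1)))
    inner <- vapply(nd$children[ord], function(ch)
      sprintf("%s:%s", rec(ch$node), format_num(ch$len)), character(1))
    sprintf("(%s)", paste(inner, collapse = ","))
  }
  paste0(rec(node), ";")
}

#' Write a phylogenetic tree as Newick or Nexus
#'
#' The Newick serialisation is deterministic: at every internal node the
#' children are ordered by the smallest leaf label they contain, and branch
#' lengths use the shortest decimal representation that parses back to the
#' same double, so write -> parse -> write is byte-identical. The Nexus
#' output wraps the same Newick string in a TREES block with a TRANSLATE
#' table (taxa numbered in alphabetical order).
#'
#' @param tree an object of class `phylo`.
#' @param format `"newick"` or `"nexus"`.
#' @param path optional output file.
#' @return the serialised text.
#' @export
write_tree <- function(tree, format = c("newick", "nexus"), path = NULL) {
  format <- match.arg(format)
  stopifnot(inherits(tree, "phylo"))
  nwk <- newick_from_phylo(tree)
  text <- if (format == "newick") {
    paste0(nwk, "\n")
  } else {
    taxa <- sort(tree$tip.label)
    translate <- sprintf("        %d %s%s", seq_along(taxa), taxa,
                         ifelse(seq_along(taxa) < length(taxa), ",", ""))
    body <- nwk
    # replace labels by their TRANSLATE numbers (longest first, delimiters
    # guarantee no partial replacement)
    for (k in order(nchar(taxa), decreasing = TRUE)) {
      body <- gsub(paste0("([(,])", escape_regex(taxa[k]), ":"),
                   sprintf("\\1%d:", k), body)
    }
    paste0(paste(c(
      "#NEXUS",
      "BEGIN TREES;",
      "    TRANSLATE",
      translate,
      "        ;",
      sprintf("    TREE tree1 = [&U] %s", body),
      "END;"
    ), collapse = "\n"), "\n")
  }
  if (!is.null(path)) {
    cat(text, file = path)
    invisible(text)
  } else text
}

escape_regex <- function(x) gsub("([][(){}.|^$*+?\\\\])", "\\\\\\1", x)

# Deterministic Newick serialisation of an ape phylo object.
newick_from_phylo <- function(tree) {
  ntip <- length(tree$tip.label)
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  min_label <- character(ntip + tree$Nnode)
  lens <- if (is.null(tree$edge.length)) rep(NA_real_, nrow(tree$edge)) else tree$edge.length
  rec <- function(node) {
    if (node <= ntip) {
      min_label[node] <<- tree$tip.label[node]
      return(tree$tip.label[node])
    }
    edges <- children[[as.character(node)]]
    kids <- tree$edge[edges, 2]
    txt <- vapply(seq_along(kids), function(q) rec(kids[q]), character(1))
    ord <- order(min_label[kids])
    min_label[node] <<- min(min_label[kids])
    parts <- vapply(seq_along(kids)[ord], function(q) {
      if (is.na(lens[edges[q]])) txt[q]
      else sprintf("%s:%s", txt[q], format_num(lens[edges[q]]))
    }, character(1))
    sprintf("(%s)", paste(parts, collapse = ","))
  }
  root <- ntip + 1L
  paste0(rec(root), ";")
}

#' Read a tree from Newick text or file
#'
#' Thin wrapper over [ape::read.tree()].
#'
#' @param path file path, or `text` given directly.
#' @param text Newick string.
#' @return a `phylo` object.
#' @export
read_tree <- function(path = NULL, text = NULL) {
  ape::read.tree(file = path, text = text)
}

#' Write a distance matrix in PHYLIP, MEGA or Nexus format
#'
#' `phylip`: first line the taxon count, then one row per taxon with the
#' name padded or truncated to 10 characters (truncation collisions get a
#' `~k` uniqueness suffix) followed by the full square matrix at 6
#' decimals. `mega`: classic `#mega` dialect with a Title line and the
#' lower-left triangle. `nexus`: TAXA and DISTANCES blocks with
#' `TRIANGLE=LOWER`. All outputs are deterministic byte-for-byte.
#'
#' @param matrix a [distance_matrix()].
#' @param format `"phylip"`, `"mega"` or `"nexus"`.
#' @param path optional output file.
#' @return the serialised text.
#' @export
write_matrix <- function(matrix, format = c("phylip", "mega", "nexus"),
                         path = NULL) {
  format <- match.arg(format)
  m <- unclass(matrix)
  labels <- rownames(m)
  n <- nrow(m)
  lines <- switch(format,
    phylip = {
      nm <- phylip_names(labels)
      c(sprintf("%5d", n),
        vapply(seq_len(n), function(i)
          paste0(nm[i], paste(sprintf("%.6f", m[i, ]), collapse = " ")),
          character(1)))
    },
    mega = {
      tri <- vapply(seq_len(n), function(i) {
        if (i == 1L) sprintf("[%d]", i)
        else paste0(sprintf("[%d]", i), " ",
                    paste(sprintf("%.6f", m[i, seq_len(i - 1L)]), collapse = "  "))
      }, character(1))
      c("#mega",
        "!Title: Genome distance matrix;",
        sprintf("!Format DataType=Distance DataFormat=LowerLeft NTaxa=%d;", n),
        "",
        sprintf("[%d] #%s", seq_len(n), gsub("\\s+", "_", labels)),
        "",
        tri)
    },
    nexus = {
      safe <- gsub("\\s+", "_", labels)
      wid <- max(nchar(safe))
      rows <- vapply(seq_len(n), function(i)
        paste0("        ", formatC(safe[i], width = -wid), " ",
               paste(sprintf("%.6f", m[i, seq_len(i)]), collapse = " ")),
        character(1))
      c("#NEXUS",
        "BEGIN TAXA;",
        sprintf("    DIMENSIONS NTAX=%d;", n),
        sprintf("    TAXLABELS %s;", paste(safe, collapse = " ")),
        "END;",
        "BEGIN DISTANCES;",
        "    FORMAT TRIANGLE=LOWER DIAGONAL;",
        "    MATRIX",
        rows,
        "    ;",
        "END;")
    })
  text <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(lines, path)
    invisible(text)
  } else text
}

# 10-character PHYLIP name field with uniqueness suffixes on truncation
# collisions.
phylip_names <- function(labels) {
  nm <- gsub("\\s+", "_", labels)
  trunc <- substr(nm, 1L, 10L)
  dup <- duplicated(trunc) | duplicated(trunc, fromLast = TRUE)
  if (any(dup & nchar(nm) > 10L)) {
    for (key in unique(trunc[dup])) {
      idx <- which(trunc == key)
      for (q in seq_along(idx)) {
        suf <- sprintf("~%d", q)
        trunc[idx[q]] <- paste0(substr(key, 1L, 10L - nchar(suf)), suf)
      }
    }
  }
  sprintf("%-10s", trunc)
}

#' Read a PHYLIP square distance matrix
#'
#' Inverse of `write_matrix(..., format = "phylip")`.
#'
#' @param path file path, or `text` given directly.
#' @param text PHYLIP matrix text.
#' @return a [distance_matrix()].
#' @export
read_matrix_phylip <- function(path = NULL, text = NULL) {
  lines <- if (!is.null(text)) strsplit(text, "\n")[[1]] else readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  n <- as.integer(trimws(lines[1]))
  if (is.na(n) || n < 2L) stop("invalid PHYLIP header")
  if (length(lines) < n + 1L) stop("truncated PHYLIP matrix")
  labels <- character(n)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    row <- lines[i + 1L]
    labels[i] <- trimws(substr(row, 1L, 10L))
    vals <- as.numeric(strsplit(trimws(substr(row, 11L, nchar(row))), "\\s+")[[1]])
    if (length(vals) != n) stop("row ", i, " has ", length(vals), " values, expected ", n)
    m[i, ] <- vals
  }
  diag(m) <- 0
  distance_matrix((m + t(m)) / 2, labels)
}

#' ASCII rendering of a tree
#'
#' Simple text overview of the phylogeny (stands in for a graphical tree
#' map); delegates to [ape::print.phylo()] structure with a cladogram
#' drawing.
#'
#' @param tree a `phylo` object.
#' @return invisibly, the lines printed.
#' @export
ascii_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  out <- utils::capture.output(str_tree_rec(tree))
  cat(out, sep = "\n")
  invisible(out)
}

str_tree_rec <- function(tree) {
  ntip <- length(tree$tip.label)
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  rec <- function(node, prefix, head) {
    if (node <= ntip) {
      cat(prefix, head, tree$tip.label[node], "\n", sep = "")
      return(invisible())
    }
    cat(prefix, head, "+\n", sep = "")
    edges <- children[[as.character(node)]]
    kids <- tree$edge[edges, 2]
    for (q in seq_along(kids)) {
      last <- q == length(kids)
      rec(kids[q],
          paste0(prefix, if (nzchar(head)) (if (grepl("\\\\", head)) "    " else "|   ") else ""),
          if (last) "\\-- " else "|-- ")
    }
  }
  rec(length(tree$tip.label) + 1L, "", "")
}
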
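#' Parameters for a synthetic quadripartite plastome
#'
#' The simulated molecule follows the canonical plastome architecture
#' LSC + IRa + SSC + IRb, with IRb the exact reverse complement of IRa.
#' Real plastomes are 110-200 kb with IRs of 6-76 kb; the defaults here are
#' deliberately scaled down (LSC 8 kb, SSC 2 kb, IR 1.5 kb) for desk-scale
#' test runtimes, while real-scale values remain legal.
#'
#' @param lsc_len,ssc_len,ir_len region lengths in bp (ir_len >= 100).
#' @param n_features_per_region features planted in each of LSC, SSC and
#'   IRa (IRa features are duplicated into IRb).
#' @param gc_content GC fraction in (0, 1); default 0.37, typical of
#'   plastomes.
#' @param seed RNG seed making the genome reproducible.
#' @return object of class `plastome_params`.
#' @export
plastome_params <- function(lsc_len = 8000, ssc_len = 2000, ir_len = 1500,
                            n_features_per_region = 3, gc_content = 0.37,
                            seed = 1) {
  stopifnot(lsc_len >= 1, ssc_len >= 1, ir_len >= 100,
            n_features_per_region >= 0,
            gc_content > 0, gc_content < 1)
  structure(list(lsc_len = as.integer(lsc_len), ssc_len = as.integer(ssc_len),
                 ir_len = as.integer(ir_len),
                 n_features_per_region = as.integer(n_features_per_region),
                 gc_content = gc_content, seed = as.integer(seed)),
            class = "plastome_params")
}

random_dna <- function(n, gc) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Simulate a synthetic plastome
#'
#' Generates a circular genome LSC + IRa + SSC + IRb (IRb = exact reverse
#' complement of IRa) and plants non-overlapping named features in the LSC,
#' SSC and IRa regions; IRa features are mirrored into IRb (minus strand,
#' same name), reproducing the characteristic duplicated IR gene content.
#' Feature names are drawn without replacement from [PLASTID_GENES]
#' (tRNA-named features become class `tRNA`, `rrn*` names class `rRNA`,
#' everything else class `Gene`). Deterministic given `params$seed`.
#'
#' @param params a [plastome_params()].
#' @param accession accession for the record (default derived from seed).
#' @return a [genome_record()].
#' @export
simulate_plastome <- function(params, accession = NULL) {
  stopifnot(inherits(params, "plastome_params"))
  if (is.null(accession))
    accession <- sprintf("SYNP%04d", params$seed %% 10000L)
  with_seed(params$seed, {
    lsc <- random_dna(params$lsc_len, params$gc_content)
    ira <- random_dna(params$ir_len, params$gc_content)
    ssc <- random_dna(params$ssc_len, params$gc_content)
    sequence <- paste0(lsc, ira, ssc, revcomp(ira))

    nper <- params$n_features_per_region
    regions <- list(
      LSC = c(1L, params$lsc_len),
      IRa = c(params$lsc_len + 1L, params$lsc_len + params$ir_len),
      SSC = c(params$lsc_len + params$ir_len + 1L,
              params$lsc_len + params$ir_len + params$ssc_len)
    )
    n_names <- 3L * nper
    if (n_names > length(PLASTID_GENES))
      stop("features requested exceed the bundled gene-name pool")
    pool <- sample(PLASTID_GENES, n_names)
    feats <- empty_features()
    used <- 0L
    for (rn in names(regions)) {
      rg <- regions[[rn]]
      rlen <- rg[2] - rg[1] + 1L
      if (nper == 0L) next
      slot <- rlen %/% nper
      if (slot < 60L)
        stop("features requested exceed region capacity in ", rn)
      for (k in seq_len(nper)) {
        used <- used + 1L
        name <- pool[used]
        slot_s <- rg[1] + (k - 1L) * slot
        flen <- sample(seq(50L, max(50L, min(800L, slot - 10L))), 1L)
        fstart <- slot_s + sample.int(slot - flen - 1L, 1L) - 1L
        fend <- fstart + flen - 1L
        cls <- if (startsWith(name, "trn")) "tRNA"
               else if (startsWith(name, "rrn")) "rRNA"
               else "Gene"
        strand <- sample(c("+", "-"), 1L)
        feats <- rbind(feats, data.frame(
          feature_class = cls, name = name, start = fstart, end = fend,
          strand = strand, part_index = 1L, stringsAsFactors = FALSE))
        if (rn == "IRa") {
          # mirror into IRb: IRb = revcomp(IRa), so offset u..v in IRa maps
          # to the reflected interval on the opposite strand
          irb_s <- params$lsc_len + params$ir_len + params$ssc_len
          u <- fstart - regions$IRa[1]
          v <- fend - regions$IRa[1]
          feats <- rbind(feats, data.frame(
            feature_class = cls, name = name,
            start = irb_s + (params$ir_len - 1L - v) + 1L,
            end = irb_s + (params$ir_len - 1L - u) + 1L,
            strand = if (strand == "+") "-" else "+",
            part_index = 1L, stringsAsFactors = FALSE))
        }
      }
    }
    feats <- feats[order(feats$start, feats$end), , drop = FALSE]
    genome_record(accession, "synthetic plastome", sequence, "circular", feats)
  })
}

#' Mutate a genome along one branch
#'
#' Applies per-site substitutions (probability `sub_rate`, uniform over the
#' three alternative bases, Jukes-Cantor-like) and insertion/deletion
#' events (per-site rate `indel_rate`, insertion or deletion with equal
#' probability, lengths geometric with mean 3). Feature coordinates are
#' lifted over through the indels; a feature entirely erased by a deletion
#' is dropped. Deterministic given `seed`; the input record is not
#' modified.
#'
#' @param record a [genome_record()].
#' @param sub_rate,indel_rate per-site rates in \[0, 0.5\].
#' @param seed RNG seed.
#' @param accession optional new accession for the mutated record.
#' @return a new [genome_record()].
#' @export
mutate_genome <- function(record, sub_rate, indel_rate = 0, seed = 1,
                          accession = NULL) {
  stopifnot(inherits(record, "genome_record"),
            sub_rate >= 0, sub_rate <= 0.5,
            indel_rate >= 0, indel_rate <= 0.5)
  if (is.null(accession)) accession <- record$accession
  with_seed(seed, {
    x <- strsplit(record$sequence, "")[[1]]
    L <- length(x)
    bases <- c("A", "C", "G", "T")
    if (sub_rate > 0) {
      hit <- which(runif(L) < sub_rate & x %in% bases)
      if (length(hit)) {
        cur <- match(x[hit], bases)
        shift <- sample.int(3L, length(hit), replace = TRUE)
        x[hit] <- bases[((cur - 1L + shift) %% 4L) + 1L]
      }
    }
    feats <- record$features
    if (indel_rate > 0) {
      ev_pos <- which(runif(L) < indel_rate)
      if (length(ev_pos)) {
        ev_ins <- runif(length(ev_pos)) < 0.5
        ev_len <- 1L + rgeom(length(ev_pos), 1 / 3)
        # apply right-to-left so earlier positions stay valid
        ord <- order(ev_pos, decreasing = TRUE)
        for (q in ord) {
          p <- ev_pos[q]; k <- ev_len[q]
          if (ev_ins[q]) {
            ins <- sample(bases, k, replace = TRUE)
            x <- append(x, ins, after = p)
            if (nrow(feats)) {
              # any coordinate beyond the insertion point shifts right by k;
              # a feature spanning p simply grows
              feats$start <- ifelse(feats$start > p, feats$start + k, feats$start)
              feats$end <- ifelse(feats$end > p, feats$end + k, feats$end)
            }
          } else {
            k <- min(k, length(x) - p + 1L)
            x <- x[-(p:(p + k - 1L))]
            if (nrow(feats)) {
              shift_s <- function(v) ifelse(v < p, v,
                                            ifelse(v <= p + k - 1L, p, v - k))
              shift_e <- function(v) ifelse(v < p, v,
                                            ifelse(v <= p + k - 1L, p - 1L, v - k))
              feats$start <- shift_s(feats$start)
              feats$end <- shift_e(feats$end)
              feats <- feats[feats$end >= feats$start & feats$start >= 1L, ,
                             drop = FALSE]
            }
          }
        }
      }
    }
    newseq <- paste(x, collapse = "")
    if (nrow(feats)) feats <- feats[feats$end <= nchar(newseq), , drop = FALSE]
    genome_record(accession, record$organism, newseq, record$topology, feats)
  })
}

#' Specification of a simulated clade
#'
#' @param newick_topology Newick string with branch lengths.
#' @param substitution_rate_per_unit expected substitutions per site per
#'   unit branch length.
#' @param indel_rate_per_unit expected indel events per site per unit
#'   branch length.
#' @param seed RNG seed.
#' @return object of class `clade_spec`.
#' @export
clade_spec <- function(newick_topology, substitution_rate_per_unit,
                       indel_rate_per_unit = 0, seed = 1) {
  tree <- ape::read.tree(text = newick_topology)
  if (is.null(tree)) stop("newick_topology does not parse as a tree")
  if (is.null(tree$edge.length)) stop("newick_topology must carry branch lengths")
  stopifnot(is.finite(substitution_rate_per_unit), substitution_rate_per_unit >= 0,
            is.finite(indel_rate_per_unit), indel_rate_per_unit >= 0)
  structure(list(newick_topology = newick_topology, tree = tree,
                 substitution_rate_per_unit = substitution_rate_per_unit,
                 indel_rate_per_unit = indel_rate_per_unit,
                 seed = as.integer(seed)),
            class = "clade_spec")
}

#' Bundled 6-taxon clade preset
#'
#' The package's standard end-to-end fixture: three well-separated species
#' pairs, `((A:0.5,B:0.5):2,(C:0.5,D:0.5):2,(E:0.5,F:0.5):2)`, evolved at
#' 0.02 substitutions per site per unit branch length (sister taxa ~2%
#' diverged, cross-clade pairs ~9-10%) with a small indel rate, on
#' ~19.6 kb genomes. These divergences sit in the regime where both the
#' alignment-free BBC pipeline and the exact-match alignment pipeline
#' recover the generating topology.
#'
#' @param seed RNG seed controlling both the root genome and the mutations.
#' @return list with `root_params` (a [plastome_params()]) and `spec`
#'   (a [clade_spec()]), ready for [simulate_clade()].
#' @export
clade6_preset <- function(seed = 1) {
  list(
    root_params = plastome_params(lsc_len = 12000, ssc_len = 2600,
                                  ir_len = 2500, n_features_per_region = 3,
                                  seed = seed),
    spec = clade_spec("((A:0.5,B:0.5):2,(C:0.5,D:0.5):2,(E:0.5,F:0.5):2);",
                      substitution_rate_per_unit = 0.02,
                      indel_rate_per_unit = 1e-4, seed = seed)
  )
}

#' Simulate a clade of plastomes along a known tree
#'
#' Simulates the root plastome, then evolves it independently along every
#' branch of the given topology; the expected divergence on a branch is
#' proportional to its length (per-branch substitution probability =
#' rate-per-unit x branch length, clamped at 0.5). Returns the leaf
#' genomes (accessions = tip labels) together with the generating tree for
#' topology-recovery tests.
#'
#' @param root_params a [plastome_params()].
#' @param spec a [clade_spec()].
#' @return list with `genomes` (named list of [genome_record()] in tip
#'   order) and `tree` (the generating `phylo`).
#' @export
simulate_clade <- function(root_params, spec) {
  stopifnot(inherits(root_params, "plastome_params"), inherits(spec, "clade_spec"))
  tree <- spec$tree
  ntip <- length(tree$tip.label)
  root_rec <- simulate_plastome(root_params)
  recs <- vector("list", ntip + tree$Nnode)
  recs[[ntip + 1L]] <- root_rec
  # cladewise edge order guarantees parents are visited before children
  tr <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(tr$edge))) {
    parent <- tr$edge[e, 1]
    child <- tr$edge[e, 2]
    len <- tr$edge.length[e]
    sub <- min(0.5, spec$substitution_rate_per_unit * len)
    ind <- min(0.5, spec$indel_rate_per_unit * len)
    seed_e <- (abs(spec$seed) * 1009L + e * 7919L) %% 2000000000L
    acc <- if (child <= ntip) tree$tip.label[child] else recs[[parent]]$accession
    recs[[child]] <- mutate_genome(recs[[parent]], sub, ind, seed = seed_e,
                                   accession = acc)
  }
  genomes <- recs[seq_len(ntip)]
  names(genomes) <- tree$tip.label
  list(genomes = genomes, tree = tree)
}
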
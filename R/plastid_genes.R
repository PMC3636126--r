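#' Canonical plastid gene names
#'
#' A bundled list of widely conserved chloroplast gene names with their
#' conventional capitalisation (photosystem, ATP synthase, NADH
#' dehydrogenase, ribosomal protein, rRNA and tRNA genes, among others).
#' Used as the canonical-case exception list by
#' [normalize_feature_name()] and as the name pool for
#' [simulate_plastome()]. tRNA names carry their anticodon suffix, which is
#' preserved as distinguishing (trnH-GUG is not trnH-CAC).
#'
#' @format Character vector.
#' @export
PLASTID_GENES <- c(
  "rbcL", "matK", "psbA", "psbB", "psbC", "psbD", "psbE", "psbF", "psbH",
  "psbI", "psbJ", "psbK", "psbL", "psbM", "psbN", "psbT", "psbZ",
  "psaA", "psaB", "psaC", "psaI", "psaJ",
  "atpA", "atpB", "atpE", "atpF", "atpH", "atpI",
  "ndhA", "ndhB", "ndhC", "ndhD", "ndhE", "ndhF", "ndhG", "ndhH", "ndhI",
  "ndhJ", "ndhK",
  "petA", "petB", "petD", "petG", "petL", "petN",
  "rpoA", "rpoB", "rpoC1", "rpoC2",
  "rps2", "rps3", "rps4", "rps7", "rps8", "rps11", "rps12", "rps14",
  "rps15", "rps16", "rps18", "rps19",
  "rpl2", "rpl14", "rpl16", "rpl20", "rpl22", "rpl23", "rpl32", "rpl33",
  "rpl36",
  "clpP", "accD", "ccsA", "cemA", "infA", "ycf1", "ycf2", "ycf3", "ycf4",
  "rrn4.5", "rrn5", "rrn16", "rrn23",
  "trnH-GUG", "trnK-UUU", "trnQ-UUG", "trnS-GCU", "trnG-UCC", "trnR-UCU",
  "trnC-GCA", "trnD-GUC", "trnY-GUA", "trnE-UUC", "trnT-GGU", "trnS-UGA",
  "trnF-GAA", "trnV-UAC", "trnM-CAU", "trnW-CCA", "trnP-UGG", "trnI-CAU",
  "trnL-CAA", "trnV-GAC", "trnI-GAU", "trnA-UGC", "trnR-ACG", "trnN-GUU",
  "trnL-UAG"
)
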
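# Fixed gene vocabulary for the synthetic cohort generator. The symbols are
# real core prokaryotic genes so that generated annotations look like (and
# normalize like) annotator output; products are plausible but synthetic.

synthetic_cds_symbols <- function() {
  c(
    # ribosomal proteins
    paste0("rpl", LETTERS[1:24]),
    paste0("rps", LETTERS[2:20]),
    # aminoacyl-tRNA ligases
    "alaS", "argS", "asnS", "aspS", "cysS", "glnS", "gltX", "glyS", "hisS",
    "ileS", "leuS", "lysS", "metG", "pheS", "proS", "serS", "thrS", "trpS",
    "tyrS", "valS",
    # replication, repair, transcription
    "dnaA", "dnaB", "dnaE", "dnaG", "dnaN", "dnaX", "gyrA", "gyrB", "parC",
    "parE", "topA", "polA", "ligA", "ssb", "holA", "holB", "rpoA", "rpoB",
    "rpoC", "rpoD", "rpoE", "nusA", "nusB", "nusG", "greA",
    # translation factors and processing
    "infA", "infB", "infC", "tsf", "tuf", "fusA", "frr", "prfA", "prfB",
    "lepA", "efp", "map", "fmt", "def",
    # protein folding, degradation, secretion
    "secA", "secY", "secE", "secG", "ftsH", "ftsY", "ffh", "lepB", "groL",
    "groS", "dnaK", "dnaJ", "grpE", "hslU", "hslV", "lon", "clpB", "clpP",
    "clpX", "tig",
    # central and nucleotide metabolism
    "eno", "pgk", "gapA", "pfkA", "fbaA", "tpiA", "pgi", "pyk", "ldh",
    "ackA", "pta", "ppa", "adk", "cmk", "gmk", "pyrG", "pyrH", "tmk", "ndk",
    "thyA", "dut", "hisB", "prs", "upp", "apt", "hpt", "deoD", "rpiA", "nox",
    # ATP synthase
    paste0("atp", LETTERS[1:8])
  )
}

synthetic_cds_products <- function(symbols) {
  special <- c(
    eno = "Enolase", pgk = "Phosphoglycerate kinase",
    ftsH = "ATP-dependent zinc metalloprotease FtsH",
    parC = "DNA topoisomerase 4 subunit A",
    parE = "DNA topoisomerase 4 subunit B",
    hisB = "Histidine biosynthesis bifunctional protein HisB",
    dnaA = "Chromosomal replication initiator protein DnaA",
    secA = "Protein translocase subunit SecA",
    secY = "Protein translocase subunit SecY"
  )
  out <- paste0(toupper(substring(symbols, 1, 1)), substring(symbols, 2),
                " family protein")
  hit <- symbols %in% names(special)
  out[hit] <- special[symbols[hit]]
  out
}

synthetic_trna_products <- function() {
  anticodons <- c(Ala = "ggc", Arg = "acg", Asn = "gtt", Asp = "gtc",
                  Cys = "gca", Gln = "ttg", Glu = "ttc", Gly = "gcc",
                  His = "gtg", Ile = "gat", Leu = "cag", Lys = "ttt",
                  Met = "cat", Phe = "gaa", Pro = "tgg", Ser = "gga",
                  Thr = "tgt", Trp = "cca", Tyr = "gta", Val = "tac")
  paste0("tRNA-", names(anticodons), "(", anticodons, ")")
}

#' Synthetic core-minimal-function reference set
#'
#' A fixed, deterministic CMF-shaped reference table used by the cohort
#' generator: 159 CDS core genes (replication, transcription, translation,
#' protein fate, central metabolism, ATP synthase), 20 tRNA isotypes,
#' the three rRNA subunits and tmRNA — 183 keys by default, mirroring the
#' size of a minimal-genome-derived core set. Keys are produced by the
#' package's own normalization, so generated annotations round-trip.
#'
#' @param cmf_size Number of entries (default and maximum 183; smaller
#'   values keep the first `cmf_size` keys in sorted order).
#' @return A CMF tibble (see [build_cmf()] for the columns).
#' @export
synthetic_cmf <- function(cmf_size = 183L) {
  cds <- synthetic_cds_symbols()
  parts <- tibble(
    feature_type = c(rep("CDS", length(cds)), rep("tRNA", 20L),
                     rep("rRNA", 3L), "tmRNA"),
    gene_symbol = c(cds, rep(NA_character_, 24L)),
    product = c(synthetic_cds_products(cds), synthetic_trna_products(),
                paste0(c("16S", "23S", "5S"), " ribosomal RNA"),
                "transfer-messenger RNA, SsrA")
  )
  parts$key <- gene_key_chr(parts$feature_type, parts$gene_symbol, parts$product)
  stopifnot(!anyDuplicated(parts$key))
  out <- parts[order(parts$key, method = "radix"),
               c("key", "gene_symbol", "product", "feature_type")]
  out$category <- NA_character_
  out$source_genomes <- "synthetic"
  if (cmf_size < 1L || cmf_size > nrow(out)) {
    abort(paste0("`cmf_size` must be in [1, ", nrow(out), "]."))
  }
  as_tibble(out[seq_len(cmf_size), ])
}

# Decoy (contamination) gene pool: products disjoint from the core set by
# construction; a fixed fraction is "hypothetical protein" to exercise the
# certainty filter downstream.
synthetic_decoy_pool <- function(pool_size = 200L, hypothetical_fraction = 0.1) {
  templates <- c("ABC transporter permease", "MFS transporter",
                 "Glycosyl hydrolase family protein", "Two-component sensor kinase",
                 "Transcriptional regulator TetR family", "Acyltransferase domain protein",
                 "Cell wall hydrolase", "Phage integrase", "Transposase",
                 "Restriction endonuclease", "Sugar kinase", "Aminotransferase class V",
                 "Oxidoreductase FAD-binding", "Peptidase M23 family",
                 "Lipoprotein signal peptidase accessory")
  n_hyp <- round(pool_size * hypothetical_fraction)
  n_named <- pool_size - n_hyp
  prod <- paste0(rep_len(templates, n_named), " D",
                 sprintf("%03d", seq_len(n_named)))
  tibble(
    feature_type = "CDS",
    gene_symbol = NA_character_,
    product = c(prod, rep("hypothetical protein", n_hyp))
  )
}
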
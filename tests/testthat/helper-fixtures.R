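# In-code fixtures shared across test files.

gene_rows <- function(genome_id, products, symbols = NA_character_,
                      types = "CDS", group = "OTHER") {
  n <- length(products)
  tibble::tibble(
    genome_id = genome_id,
    source_group = group,
    locus_id = sprintf("%s_%03d", genome_id, seq_len(n)),
    feature_type = rep_len(types, n),
    gene_symbol = rep_len(symbols, n),
    product = products
  )
}

# annotation built from CDS gene symbols only
symbol_annotation <- function(genome_id, symbols, group = "OTHER") {
  gene_rows(genome_id, paste(symbols, "protein"), symbols, group = group)
}

tiny_cmf <- function(symbols = c("dnaA", "gyrA", "rpoB", "secY")) {
  build_cmf(dplyr::bind_rows(
    symbol_annotation("ref1", symbols),
    symbol_annotation("ref2", symbols)
  ))
}

# presence matrix straight from 0/1 rows
manual_matrix <- function(cells, groups = rep("A", nrow(cells)),
                          ids = paste0("g", seq_len(nrow(cells)))) {
  keys <- paste0("k", seq_len(ncol(cells)))
  colnames(cells) <- keys
  dplyr::bind_cols(
    tibble::tibble(genome_id = ids, source_group = groups),
    tibble::as_tibble(cells)
  )
}

write_gff3_fixture <- function(lines, path = tempfile(fileext = ".gff")) {
  writeLines(lines, path)
  path
}
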
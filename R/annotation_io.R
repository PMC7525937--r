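#' Read a prokaryotic genome annotation
#'
#' Reads gene-level features from either a GFF3 file (the dialect emitted by
#' standard prokaryotic annotators such as Prokka with gene records added) or
#' a tab-separated feature table (columns `locus_tag`, `ftype`, `length_bp`,
#' `gene`, `EC_number`, `COG`, `product`). The format is auto-detected from
#' the first line. Only gene-level feature types are retained (`CDS`, `tRNA`,
#' `rRNA`, `tmRNA`); parent `gene` records, `repeat_region` and other types
#' are skipped because the downstream core-function screen operates on gene
#' functions only. Coordinates are not retained.
#'
#' Features lacking a `product` attribute are assigned
#' `"hypothetical protein"`, matching the annotator's own convention (such
#' records are later removed by the certainty filter during reference-set
#' construction, but still count as evidence when screening genomes).
#'
#' @param path Path to a GFF3 file or a tab-separated feature table.
#' @param genome_id Identifier for the genome; stored in every row.
#' @param source_group One of `"NCBI"`, `"UMGS"`, `"SYNTHETIC"`, `"OTHER"`:
#'   which genome set the genome belongs to.
#' @return A tibble with one row per retained feature and columns
#'   `genome_id`, `source_group`, `locus_id`, `feature_type`, `gene_symbol`
#'   (`NA` when absent) and `product`. Zero retained features yields an
#'   empty tibble with a warning (degenerate genomes are allowed).
#' @examples
#' gff <- tempfile(fileext = ".gff")
#' writeLines(c(
#'   "##gff-version 3",
#'   paste0("c1\tprokka\tCDS\t1\t900\t.\t+\t0\t",
#'          "ID=L_00001;gene=dnaA;product=Chromosomal replication initiator protein DnaA")
#' ), gff)
#' read_annotation(gff, "g1", "NCBI")
#' @export
read_annotation <- function(path, genome_id,
                            source_group = c("OTHER", "NCBI", "UMGS", "SYNTHETIC")) {
  source_group <- match.arg(toupper(source_group[1]),
                            c("OTHER", "NCBI", "UMGS", "SYNTHETIC"))
  if (!is.character(genome_id) || length(genome_id) != 1L || !nzchar(genome_id)) {
    abort("`genome_id` must be a single non-empty string.")
  }
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  lines <- readr::read_lines(path)
  first <- lines[nzchar(trimws(lines))][1]
  genes <- if (is.na(first)) {
    empty_gene_table()
  } else if (startsWith(first, "##gff-version") || startsWith(first, "#") ||
             length(strsplit(first, "\t", fixed = TRUE)[[1]]) == 9L) {
    parse_gff3_lines(lines, path)
  } else {
    parse_feature_table(path)
  }
  if (nrow(genes) == 0L) {
    warn(paste0("No gene-level features found in ", path,
                "; returning an empty annotation."))
  }
  if (anyDuplicated(genes$locus_id)) {
    abort(paste0("Duplicated locus identifiers in ", path, ": ",
                 paste(unique(genes$locus_id[duplicated(genes$locus_id)]),
                       collapse = ", ")))
  }
  tibble(genome_id = rep(genome_id, nrow(genes)),
         source_group = rep(source_group, nrow(genes)),
         genes)
}

empty_gene_table <- function() {
  tibble(locus_id = character(), feature_type = character(),
         gene_symbol = character(), product = character())
}

retained_feature_types <- c("CDS", "tRNA", "rRNA", "tmRNA")

parse_gff3_lines <- function(lines, path) {
  fasta_at <- which(lines == "##FASTA")
  if (length(fasta_at)) lines <- lines[seq_len(fasta_at[1] - 1L)]
  keep <- nzchar(lines) & !startsWith(lines, "#")
  idx <- which(keep)
  if (!length(idx)) return(empty_gene_table())
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L)) {
    bad <- idx[which(nf != 9L)[1]]
    abort(paste0("Unparseable GFF3 line ", bad, " in ", path,
                 ": expected 9 tab-separated fields, found ", nf[which(nf != 9L)[1]], "."))
  }
  type <- vapply(fields, `[[`, character(1), 3L)
  sel <- type %in% retained_feature_types
  if (!any(sel)) return(empty_gene_table())
  fields <- fields[sel]
  type <- type[sel]
  line_no <- idx[sel]
  attrs <- lapply(fields, function(f) parse_gff3_attributes(f[[9L]]))
  get_attr <- function(key) {
    vapply(attrs, function(a) if (!is.null(a[[key]])) a[[key]] else NA_character_,
           character(1))
  }
  locus <- get_attr("locus_tag")
  ids <- get_attr("ID")
  locus <- ifelse(is.na(locus), ids, locus)
  locus <- ifelse(is.na(locus), paste0("feature_line", line_no), locus)
  product <- get_attr("product")
  product <- ifelse(is.na(product) | !nzchar(product), "hypothetical protein", product)
  gene <- get_attr("gene")
  gene <- ifelse(!is.na(gene) & !nzchar(gene), NA_character_, gene)
  tibble(locus_id = locus, feature_type = type, gene_symbol = gene,
         product = product)
}

# Semicolon-separated key=value pairs, percent-decoded (RFC 3986 escapes for
# ';', '=', '%', ',' inside attribute values).
parse_gff3_attributes <- function(s) {
  pairs <- strsplit(s, ";", fixed = TRUE)[[1]]
  pairs <- pairs[nzchar(pairs)]
  out <- list()
  for (p in pairs) {
    eq <- regexpr("=", p, fixed = TRUE)
    if (eq < 0L) next
    key <- substr(p, 1L, eq - 1L)
    val <- substr(p, eq + 1L, nchar(p))
    if (grepl("%", val, fixed = TRUE)) val <- URLdecode(val)
    out[[key]] <- val
  }
  out
}

parse_feature_table <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = c("", "NA", "-", "—"), progress = FALSE)
  names(tab) <- tolower(names(tab))
  needed <- c("locus_tag", "ftype", "product")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols)) {
    abort(paste0("Feature table ", path, " lacks required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  tab <- tab[tab$ftype %in% retained_feature_types, , drop = FALSE]
  if (nrow(tab) == 0L) return(empty_gene_table())
  gene <- if ("gene" %in% names(tab)) tab$gene else rep(NA_character_, nrow(tab))
  product <- tab$product
  product <- ifelse(is.na(product) | !nzchar(product), "hypothetical protein", product)
  tibble(locus_id = tab$locus_tag, feature_type = tab$ftype,
         gene_symbol = gene, product = product)
}

#' Read a completeness/contamination quality table
#'
#' Reads a CheckM-style tab-separated table with columns `genome_id`,
#' `completeness` (percent, 0-100) and `contamination` (percent, >= 0).
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `genome_id`, `completeness`,
#'   `contamination`, one row per genome.
#' @export
read_quality_table <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing_cols <- setdiff(c("genome_id", "completeness", "contamination"), names(tab))
  if (length(missing_cols)) {
    abort(paste0("Quality table lacks required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  tab <- as_tibble(tab[c("genome_id", "completeness", "contamination")])
  tab$completeness <- as.numeric(tab$completeness)
  tab$contamination <- as.numeric(tab$contamination)
  if (nrow(tab) == 0L) {
    warn("Quality table is empty.")
    return(tab)
  }
  if (anyDuplicated(tab$genome_id)) {
    abort(paste0("Duplicated genome_id in quality table: ",
                 paste(unique(tab$genome_id[duplicated(tab$genome_id)]), collapse = ", ")))
  }
  if (any(is.na(tab$completeness)) ||
      any(tab$completeness < 0 | tab$completeness > 100)) {
    abort("Completeness values must lie in [0, 100].")
  }
  if (any(is.na(tab$contamination)) || any(tab$contamination < 0)) {
    abort("Contamination values must be >= 0.")
  }
  tab
}

#' Write and read a binary presence/absence matrix
#'
#' The presence matrix is a wide tibble: `genome_id`, `source_group`, then
#' one 0/1 column per core-function key, in reference order. The on-disk
#' format is TSV with cells written exactly as `0`/`1`; a write-then-read
#' round trip reproduces the matrix bit-exactly.
#'
#' @param matrix A presence matrix tibble as built by
#'   [build_presence_matrix()].
#' @param path Output (or input) TSV path.
#' @return `write_presence_matrix()` returns `path` invisibly;
#'   `read_presence_matrix()` returns the presence matrix tibble.
#' @export
write_presence_matrix <- function(matrix, path) {
  check_presence_matrix(matrix)
  if (nrow(matrix) == 0L) abort("Refusing to write an empty presence matrix.")
  readr::write_tsv(matrix, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_presence_matrix
#' @export
read_presence_matrix <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!all(c("genome_id", "source_group") %in% names(tab)[1:2])) {
    abort("Presence matrix file must start with columns genome_id, source_group.")
  }
  keys <- setdiff(names(tab), c("genome_id", "source_group"))
  if (nrow(tab) == 0L) {
    warn("Presence matrix file has a header but no rows.")
  }
  for (k in keys) {
    v <- tab[[k]]
    bad <- which(!(v %in% c("0", "1")))
    if (length(bad)) {
      abort(paste0("Non-binary cell in presence matrix: row ", bad[1],
                   ", column '", k, "' has value '", v[bad[1]], "'."))
    }
    tab[[k]] <- as.integer(v)
  }
  as_tibble(tab)
}

check_presence_matrix <- function(matrix) {
  if (!is.data.frame(matrix) ||
      !all(c("genome_id", "source_group") %in% names(matrix))) {
    abort("A presence matrix needs columns genome_id and source_group.")
  }
  keys <- presence_keys(matrix)
  if (anyDuplicated(matrix$genome_id)) abort("Duplicated genome_id in presence matrix.")
  cells <- as.matrix(matrix[keys])
  if (length(cells) && !all(cells %in% c(0L, 1L))) {
    abort("Presence matrix cells must all be 0 or 1.")
  }
  invisible(matrix)
}

presence_keys <- function(matrix) setdiff(names(matrix), c("genome_id", "source_group"))

#' Write and read a core-function reference table
#'
#' Serializes a core minimal-function set (as built by [build_cmf()]) to TSV
#' with columns `key`, `gene_symbol`, `product`, `feature_type`, `category`,
#' `source_genomes` (comma-joined). Round trip is the identity.
#'
#' @param cmf A CMF tibble.
#' @param path TSV path.
#' @return `write_cmf()` returns `path` invisibly; `read_cmf()` the tibble.
#' @export
write_cmf <- function(cmf, path) {
  check_cmf(cmf)
  out <- cmf
  readr::write_tsv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' @rdname write_cmf
#' @export
read_cmf <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = "", progress = FALSE)
  check_cmf(tab)
  as_tibble(tab)
}

check_cmf <- function(cmf) {
  needed <- c("key", "gene_symbol", "product", "feature_type", "category",
              "source_genomes")
  if (!is.data.frame(cmf) || !all(needed %in% names(cmf))) {
    abort(paste0("A CMF table needs columns: ", paste(needed, collapse = ", ")))
  }
  if (any(is.na(cmf$key) | !nzchar(cmf$key))) abort("CMF keys must be non-empty.")
  if (anyDuplicated(cmf$key)) abort("CMF keys must be unique.")
  invisible(cmf)
}
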
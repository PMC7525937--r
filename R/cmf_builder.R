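#' Normalize gene records to canonical function keys
#'
#' Adds a `key` column giving each feature a canonical, annotator-stable
#' identity used for all matching between genomes and the core minimal
#' function (CMF) set:
#'
#' * `CDS`: the lowercased gene symbol with any trailing `_<digits>`
#'   multi-copy suffix removed (`dnaA_2` -> `dnaa`); when no symbol was
#'   assigned, the lowercased product string with whitespace collapsed and
#'   punctuation (except hyphens) stripped.
#' * `tRNA`: `trna-` plus the lowercased three-letter isotype parsed from
#'   the product (`tRNA-Ala(ggc)` -> `trna-ala`); the anticodon is
#'   discarded, so isoacceptor variants of one isotype share a key.
#' * `rRNA`: `rrna-` plus the subunit token (`16s`/`23s`/`5s`).
#' * `tmRNA`: the constant `tmrna`.
#'
#' A tRNA or rRNA product that cannot be parsed falls back to the
#' normalized product string with a warning. The mapping is deterministic
#' and locale-independent.
#'
#' @param genes A gene tibble with columns `feature_type`, `gene_symbol`,
#'   `product` (e.g. from [read_annotation()]).
#' @return The input with a `key` column appended (replaced if present).
#' @examples
#' normalize_key(tibble::tibble(
#'   feature_type = c("CDS", "tRNA", "rRNA"),
#'   gene_symbol = c("dnaA_2", NA, NA),
#'   product = c("replication initiator", "tRNA-Ala(ggc)", "16S ribosomal RNA")
#' ))$key
#' @export
normalize_key <- function(genes) {
  stopifnot(is.data.frame(genes),
            all(c("feature_type", "gene_symbol", "product") %in% names(genes)))
  if (any(is.na(genes$product) | !nzchar(genes$product))) {
    abort("Every record must carry a non-empty product string.")
  }
  genes$key <- gene_key_chr(genes$feature_type, genes$gene_symbol, genes$product)
  as_tibble(genes)
}

gene_key_chr <- function(feature_type, gene_symbol, product) {
  n <- length(feature_type)
  key <- character(n)

  is_cds <- feature_type == "CDS"
  has_sym <- is_cds & !is.na(gene_symbol) & nzchar(gene_symbol)
  key[has_sym] <- sub("_[0-9]+$", "", tolower(gene_symbol[has_sym]))
  key[is_cds & !has_sym] <- normalize_product(product[is_cds & !has_sym])

  is_trna <- feature_type == "tRNA"
  if (any(is_trna)) {
    iso <- stringr::str_match(product[is_trna], stringr::regex("tRNA-([A-Za-z]{3})\\b"))[, 2]
    ok <- !is.na(iso)
    key[is_trna][ok] <- paste0("trna-", tolower(iso[ok]))
    if (any(!ok)) {
      warn(paste0("Could not parse tRNA isotype from product(s): ",
                  paste(unique(product[is_trna][!ok]), collapse = "; "),
                  "; using normalized product string."))
      key[is_trna][!ok] <- normalize_product(product[is_trna][!ok])
    }
  }

  is_rrna <- feature_type == "rRNA"
  if (any(is_rrna)) {
    sub_tok <- stringr::str_match(tolower(product[is_rrna]), "(16s|23s|5s)")[, 2]
    ok <- !is.na(sub_tok)
    key[is_rrna][ok] <- paste0("rrna-", sub_tok[ok])
    if (any(!ok)) {
      warn(paste0("Could not parse rRNA subunit from product(s): ",
                  paste(unique(product[is_rrna][!ok]), collapse = "; "),
                  "; using normalized product string."))
      key[is_rrna][!ok] <- normalize_product(product[is_rrna][!ok])
    }
  }

  key[feature_type == "tmRNA"] <- "tmrna"

  other <- !(feature_type %in% retained_feature_types)
  key[other] <- normalize_product(product[other])
  key
}

# lowercase, strip punctuation except hyphen, collapse whitespace
normalize_product <- function(x) {
  x <- tolower(x)
  x <- gsub("[^a-z0-9 -]+", "", x)
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

#' Certainty filter for reference-genome annotations
#'
#' Removes gene calls whose product is flagged as uncertain (case-insensitive
#' substring match against `uncertainty_markers`, by default "hypothetical"
#' and "putative") and any record whose normalized key appears on a
#' user-maintained exclusion list (a reproducible stand-in for manual
#' curation). Applied only when constructing the reference set; screened
#' genomes are never filtered. Idempotent; row order preserved.
#'
#' @param genes A gene tibble (from [read_annotation()]).
#' @param uncertainty_markers Non-empty character vector of product
#'   substrings flagging uncertain calls.
#' @param exclusion_list Character vector of normalized keys to drop.
#' @return The filtered tibble.
#' @export
filter_certain_genes <- function(genes,
                                 uncertainty_markers = c("hypothetical", "putative"),
                                 exclusion_list = character()) {
  stopifnot(is.data.frame(genes))
  if (length(uncertainty_markers) == 0L) {
    abort("`uncertainty_markers` must be non-empty.")
  }
  if (nrow(genes) == 0L) return(as_tibble(genes))
  flagged <- Reduce(`|`, lapply(uncertainty_markers, function(m) {
    stringr::str_detect(genes$product, stringr::fixed(m, ignore_case = TRUE))
  }))
  keep <- !flagged
  if (length(exclusion_list)) {
    keys <- gene_key_chr(genes$feature_type, genes$gene_symbol, genes$product)
    keep <- keep & !(keys %in% exclusion_list)
  }
  as_tibble(genes[keep, , drop = FALSE])
}

#' Build a core set of minimal functions (CMF)
#'
#' Derives the reference set of core minimal functions from two or more
#' annotated minimal genomes: each genome is passed through the certainty
#' filter, records are mapped to canonical keys ([normalize_key()]),
#' multi-copy keys within a genome collapse to one, and (with
#' `require_all = TRUE`, the default) only keys present in every reference
#' genome are retained. Each retained key carries the gene symbol, product
#' and feature type of its first occurrence in the first contributing
#' genome, plus the set of reference genomes it was found in. Entries are
#' sorted lexicographically by key (C locale), so the set is deterministic
#' and symmetric in the order of input genomes.
#'
#' @param annotations A gene tibble covering the reference genomes (rows
#'   from [read_annotation()] for >= 2 genomes, bound together), with a
#'   `genome_id` column.
#' @param require_all Keep only keys present in every reference genome
#'   (set intersection). With `FALSE`, the union is kept.
#' @param uncertainty_markers,exclusion_list Passed to
#'   [filter_certain_genes()].
#' @return A CMF tibble with columns `key`, `gene_symbol`, `product`,
#'   `feature_type`, `category` (`NA` until
#'   [assign_functional_categories()] is applied) and `source_genomes`
#'   (comma-joined genome ids). Provenance (reference genomes and filter
#'   parameters) is attached as the `"provenance"` attribute.
#' @export
build_cmf <- function(annotations, require_all = TRUE,
                      uncertainty_markers = c("hypothetical", "putative"),
                      exclusion_list = character()) {
  stopifnot(is.data.frame(annotations), "genome_id" %in% names(annotations))
  genome_ids <- unique(annotations$genome_id)
  if (require_all && length(genome_ids) < 2L) {
    abort("Building a CMF with `require_all = TRUE` needs >= 2 reference genomes.")
  }
  certain <- filter_certain_genes(annotations, uncertainty_markers, exclusion_list)
  certain <- normalize_key(certain)
  # one record per (genome, key): multi-copy genes collapse
  per_genome <- dplyr::distinct(certain, .data$genome_id, .data$key, .keep_all = TRUE)
  key_presence <- dplyr::summarise(
    dplyr::group_by(per_genome, .data$key),
    n_genomes = dplyr::n_distinct(.data$genome_id),
    source_genomes = paste(sort(unique(.data$genome_id)), collapse = ","),
    .groups = "drop"
  )
  kept <- if (require_all) {
    key_presence$key[key_presence$n_genomes == length(genome_ids)]
  } else {
    key_presence$key
  }
  if (length(kept) == 0L) {
    warn("The certainty-filtered reference genomes share no function keys; the CMF is empty.")
  }
  first_rec <- dplyr::distinct(per_genome, .data$key, .keep_all = TRUE)
  out <- tibble(key = sort(kept, method = "radix")) |>
    left_join(select(first_rec, "key", "gene_symbol", "product", "feature_type"),
              by = "key") |>
    mutate(category = NA_character_) |>
    left_join(select(key_presence, "key", "source_genomes"), by = "key") |>
    select("key", "gene_symbol", "product", "feature_type", "category",
           "source_genomes")
  attr(out, "provenance") <- list(
    reference_genomes = genome_ids,
    require_all = require_all,
    uncertainty_markers = uncertainty_markers,
    exclusion_list = exclusion_list
  )
  out
}

#' CMF coverage of a genome
#'
#' Fraction (as a percent) of a genome's distinct function keys that belong
#' to the CMF: `100 * |CMF keys found in the genome| / |distinct keys of all
#' annotated features|`. The denominator deliberately counts every annotated
#' feature, certain or not, so coverage answers "how much of this genome's
#' annotated gene content is core".
#'
#' @param cmf A CMF tibble.
#' @param annotation A single genome's gene tibble; must be non-empty.
#' @return Coverage percent, rounded to one decimal.
#' @export
genome_cmf_coverage <- function(cmf, annotation) {
  check_cmf(cmf)
  if (!is.data.frame(annotation) || nrow(annotation) == 0L) {
    abort("Coverage of an empty annotation is undefined.")
  }
  keys <- unique(normalize_key(annotation)$key)
  round(100 * sum(keys %in% cmf$key) / length(keys), 1)
}

#' Attach functional categories to a CMF
#'
#' Joins a user-supplied key-to-category mapping table (e.g. derived from
#' KEGG orthology) onto the CMF. A key may map to several categories; they
#' are comma-joined in the `category` column. Unmapped entries receive
#' `"unassigned"`; mapping rows whose key matches no CMF entry are ignored
#' with a warning.
#'
#' @param cmf A CMF tibble.
#' @param mapping A tibble with columns `key` (or `gene_symbol`) and
#'   `category`.
#' @return The CMF with its `category` column filled.
#' @export
assign_functional_categories <- function(cmf, mapping) {
  check_cmf(cmf)
  stopifnot(is.data.frame(mapping), "category" %in% names(mapping))
  join_col <- if ("key" %in% names(mapping)) "key" else "gene_symbol"
  if (!join_col %in% names(mapping)) {
    abort("The category mapping needs a `key` or `gene_symbol` column.")
  }
  ref <- if (join_col == "key") cmf$key else cmf$gene_symbol
  unknown <- setdiff(unique(mapping[[join_col]]), ref)
  if (length(unknown)) {
    warn(paste0("Category mapping entries match no CMF entry and are ignored: ",
                paste(unknown, collapse = ", ")))
  }
  agg <- dplyr::summarise(
    dplyr::group_by(mapping, .data[[join_col]]),
    category = paste(unique(.data$category), collapse = ","),
    .groups = "drop"
  )
  idx <- match(ref, agg[[join_col]])
  cmf$category <- ifelse(is.na(idx), "unassigned", agg$category[idx])
  cmf
}

#' Count CMF entries per functional category
#'
#' @param cmf A CMF tibble with categories assigned; entries carrying
#'   several comma-joined categories count once in each.
#' @return A tibble `category`, `n`, sorted by decreasing count.
#' @export
count_categories <- function(cmf) {
  check_cmf(cmf)
  tidyr::separate_rows(cmf, "category", sep = ",") |>
    count(.data$category, sort = TRUE)
}
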
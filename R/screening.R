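#' Screen one genome against the CMF
#'
#' Returns the binary presence profile of a genome over the CMF keys:
#' position j is 1 iff any annotated feature of the genome normalizes to
#' the j-th key. No certainty filtering is applied here — a confidently
#' called gene in a draft genome counts as present even if its product
#' string would fail the reference-set filter. Duplicated records do not
#' change the profile.
#'
#' @param cmf A non-empty CMF tibble.
#' @param annotation A single genome's gene tibble (may be empty: the
#'   profile is then all zeros).
#' @return A named integer 0/1 vector over the CMF keys, in CMF order.
#' @export
screen_genome <- function(cmf, annotation) {
  check_cmf(cmf)
  if (nrow(cmf) == 0L) abort("Cannot screen against an empty CMF.")
  keys <- if (is.data.frame(annotation) && nrow(annotation) > 0L) {
    unique(normalize_key(annotation)$key)
  } else {
    character()
  }
  setNames(as.integer(cmf$key %in% keys), cmf$key)
}

#' Adherence of a presence profile
#'
#' The per-genome adherence statistic: the percentage of CMF genes
#' detected, `100 * sum(profile) / length(profile)`, reported to one
#' decimal.
#'
#' @param profile A binary vector over the CMF keys.
#' @return Adherence percent in \[0, 100\].
#' @export
adherence <- function(profile) {
  if (length(profile) == 0L) abort("Adherence of a zero-length profile is undefined.")
  if (!all(profile %in% c(0L, 1L))) abort("Profile entries must be 0 or 1.")
  round(100 * sum(profile) / length(profile), 1)
}

#' Build the genomes-by-CMF presence/absence matrix
#'
#' Applies [screen_genome()] to every genome in the input annotation table
#' and assembles the binary matrix, one row per genome in input order, one
#' 0/1 column per CMF key in CMF order.
#'
#' @param cmf A non-empty CMF tibble.
#' @param annotations A gene tibble covering one or more genomes, with
#'   `genome_id` and `source_group` columns.
#' @return A presence matrix tibble: `genome_id`, `source_group`, then the
#'   CMF key columns.
#' @export
build_presence_matrix <- function(cmf, annotations) {
  check_cmf(cmf)
  if (nrow(cmf) == 0L) abort("Cannot screen against an empty CMF.")
  stopifnot(is.data.frame(annotations),
            all(c("genome_id", "source_group") %in% names(annotations)))
  if (nrow(annotations) == 0L) abort("`annotations` contains no genomes.")
  ids <- unique(annotations$genome_id)
  if (length(rle(annotations$genome_id)$values) != length(ids)) {
    abort("Duplicated genome_id: each genome's records must form one contiguous block.")
  }
  grp <- annotations$source_group[match(ids, annotations$genome_id)]
  keyed <- normalize_key(annotations)
  hits <- dplyr::distinct(keyed[keyed$key %in% cmf$key, c("genome_id", "key")])
  cells <- matrix(0L, nrow = length(ids), ncol = nrow(cmf),
                  dimnames = list(NULL, cmf$key))
  cells[cbind(match(hits$genome_id, ids), match(hits$key, cmf$key))] <- 1L
  dplyr::bind_cols(tibble(genome_id = ids, source_group = grp),
                   as_tibble(cells))
}

#' Per-gene missingness profile of a genome group
#'
#' For each CMF key, the percentage of genomes in a group whose profile
#' lacks the key. The companion [count_missing_above()] counts keys whose
#' missingness exceeds a threshold (e.g. genes lacking in more than 50% of
#' genomes).
#'
#' @param matrix A presence matrix tibble.
#' @param group Optional source-group name; `NULL` profiles all genomes.
#' @return A tibble `key`, `n_missing`, `pct_missing` in CMF column order.
#' @export
missing_profile <- function(matrix, group = NULL) {
  check_presence_matrix(matrix)
  rows <- if (is.null(group)) matrix else matrix[matrix$source_group == group, ]
  if (nrow(rows) == 0L) {
    abort(paste0("No genomes in group '", group %||% "<all>", "'."))
  }
  keys <- presence_keys(matrix)
  cells <- as.matrix(rows[keys])
  n_missing <- colSums(cells == 0L)
  tibble(key = keys, n_missing = as.integer(n_missing),
         pct_missing = 100 * n_missing / nrow(rows))
}

#' @rdname missing_profile
#' @param profile A missingness profile from [missing_profile()].
#' @param threshold Missingness percentage; keys strictly above it count.
#' @export
count_missing_above <- function(profile, threshold) {
  stopifnot(is.data.frame(profile), "pct_missing" %in% names(profile))
  sum(profile$pct_missing > threshold)
}

#' Per-genome adherence report
#'
#' One row per genome: adherence percent, number of missing CMF genes, and
#' (when a quality table is supplied) the completeness estimate. Genomes
#' absent from the quality table keep `NA` completeness with a warning.
#'
#' @param matrix A presence matrix tibble.
#' @param quality Optional quality tibble (from [read_quality_table()] or
#'   the synthetic generator) with `genome_id` and `completeness` columns.
#' @return A tibble `genome_id`, `source_group`, `n_missing`,
#'   `adherence_percent`, `completeness`.
#' @export
adherence_report <- function(matrix, quality = NULL) {
  check_presence_matrix(matrix)
  if (nrow(matrix) == 0L) abort("The presence matrix is empty.")
  keys <- presence_keys(matrix)
  cells <- as.matrix(matrix[keys])
  n_present <- rowSums(cells)
  out <- tibble(
    genome_id = matrix$genome_id,
    source_group = matrix$source_group,
    n_missing = as.integer(length(keys) - n_present),
    adherence_percent = round(100 * n_present / length(keys), 1)
  )
  if (!is.null(quality)) {
    stopifnot(is.data.frame(quality),
              all(c("genome_id", "completeness") %in% names(quality)))
    idx <- match(out$genome_id, quality$genome_id)
    if (anyNA(idx)) {
      warn(paste0(sum(is.na(idx)),
                  " genome(s) missing from the quality table; completeness left NA."))
    }
    out$completeness <- quality$completeness[idx]
  } else {
    out$completeness <- NA_real_
  }
  out
}

#' Group-level adherence summary
#'
#' Mean and sample (n-1) standard deviation of adherence per group. With
#' `stratify_quality = TRUE` genomes are additionally split at the
#' completeness threshold (ties go to high quality: "equal or greater").
#'
#' @param report An adherence report tibble.
#' @param stratify_quality Also split each group into high/low quality?
#' @param quality_threshold Completeness percent defining high quality.
#' @return A tibble with `source_group` (and `quality_stratum` when
#'   stratifying), `n`, `mean_adherence`, `sd_adherence`.
#' @export
adherence_summary <- function(report, stratify_quality = FALSE,
                              quality_threshold = 90) {
  stopifnot(is.data.frame(report),
            all(c("source_group", "adherence_percent") %in% names(report)))
  grp <- if (stratify_quality) {
    report$quality_stratum <- ifelse(
      is.na(report$completeness), NA_character_,
      ifelse(report$completeness >= quality_threshold, "high", "low"))
    dplyr::group_by(report, .data$source_group, .data$quality_stratum)
  } else {
    dplyr::group_by(report, .data$source_group)
  }
  dplyr::summarise(grp,
                   n = dplyr::n(),
                   mean_adherence = mean(.data$adherence_percent),
                   sd_adherence = sd(.data$adherence_percent),
                   .groups = "drop")
}
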
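#' Run the full screening analysis
#'
#' Orchestrates the whole pipeline from annotated genomes to statistics:
#' presence/absence screening against a reference set, per-genome adherence
#' and per-gene missingness, group comparisons (Kruskal-Wallis and the
#' two-group rank-sum test on adherence — both are reported), Ward
#' clustering on Jaccard distances with a Fisher's exact test of cluster
#' vs. source at k = 2, PCA on the binary matrix (optionally logistic PCA),
#' PERMANOVA on binary-Euclidean distances, and Kendall correlations of
#' adherence and ordination axes with completeness. With a single source
#' group the comparative stages are skipped with a warning; screening
#' outputs are still produced.
#'
#' Every stochastic step uses `seed`, so the same inputs and parameters
#' reproduce the same summary bit for bit.
#'
#' @param annotations A long gene tibble (`genome_id`, `source_group`,
#'   `locus_id`, `feature_type`, `gene_symbol`, `product`) or a
#'   `cmf_cohort` from [generate_cohort()].
#' @param cmf The reference set tibble; defaults to the cohort's own set
#'   when `annotations` is a cohort.
#' @param quality Optional quality table (`genome_id`, `completeness`).
#' @param n_permutations,seed PERMANOVA permutations and master seed.
#' @param quality_threshold Completeness percent splitting high/low quality.
#' @param missingness_threshold Percent for [count_missing_above()].
#' @param n_axes Ordination axes to keep.
#' @param run_logistic_pca Also fit a rank-`n_axes` logistic PCA?
#' @param output_dir Optional directory; when given, the reference set,
#'   presence matrix, adherence report, ordination scores and a JSON
#'   summary are written there.
#' @return A `cmf_analysis` object; see [glance.cmf_analysis()] and
#'   [tidy.cmf_analysis()] for tabular views, and `$summary` for the
#'   JSON-serializable summary.
#' @export
run_cmf_analysis <- function(annotations, cmf = NULL, quality = NULL,
                             n_permutations = 999L, seed,
                             quality_threshold = 90,
                             missingness_threshold = 50,
                             n_axes = 2L, run_logistic_pca = FALSE,
                             output_dir = NULL) {
  if (missing(seed)) abort("`seed` is required: every stochastic stage uses it.")
  if (inherits(annotations, "cmf_cohort")) {
    cohort <- annotations
    annotations <- cohort$annotations
    cmf <- cmf %||% cohort$cmf
    quality <- quality %||% cohort$quality
  }
  if (is.null(cmf)) abort("Supply `cmf` (or pass a cohort that carries one).")

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("Stage '", name, "' failed: ", conditionMessage(e)))
    })
  }
  log_step <- function(...) message("[cmfscan] ", ...)

  log_step("screening ", dplyr::n_distinct(annotations$genome_id),
           " genomes against ", nrow(cmf), " core functions")
  mat <- stage("screening", build_presence_matrix(cmf, annotations))
  report <- stage("screening", adherence_report(mat, quality))
  groups <- unique(mat$source_group)
  summary_groups <- adherence_summary(report)
  strata <- if (!all(is.na(report$completeness))) {
    adherence_summary(report, stratify_quality = TRUE, quality_threshold)
  } else NULL
  missing_by_group <- lapply(setNames(groups, groups),
                             function(g) missing_profile(mat, g))
  count_above <- vapply(missing_by_group, count_missing_above,
                        numeric(1), threshold = missingness_threshold)

  tests <- list()
  cluster <- contingency <- perm <- NULL
  if (length(groups) >= 2L) {
    log_step("group statistics on adherence (", length(groups), " groups)")
    tests$kruskal_wallis <- stage("group_stats",
      kruskal_wallis(report, .data$adherence_percent, .data$source_group))
    if (length(groups) == 2L) {
      tests$rank_sum <- stage("group_stats",
        rank_sum_test(report, .data$adherence_percent, .data$source_group))
    }
    log_step("Ward clustering (Jaccard) and cluster-source contingency")
    dj <- stage("ordination", distance_matrix(mat, "jaccard_binary"))
    cluster <- stage("ordination", ward_cluster(dj, k = 2L))
    if (length(groups) == 2L) {
      contingency <- tryCatch(
        cluster_source_table(cluster$labels, mat$source_group),
        error = function(e) {
          warn(paste0("Cluster-source table degenerate: ", conditionMessage(e)))
          NULL
        })
      if (!is.null(contingency)) {
        tests$fisher_cluster_source <- stage("group_stats",
                                             fisher_exact_2x2(contingency))
      }
    }
    log_step("PERMANOVA on binary-Euclidean distances, ",
             n_permutations, " permutations, seed ", seed)
    de <- stage("ordination", distance_matrix(mat, "euclidean_binary"))
    perm <- stage("permanova",
                  permanova(de, mat$source_group, n_permutations, seed = seed))
  } else {
    warn("Only one source group: group comparisons, clustering and PERMANOVA skipped.")
  }

  log_step("PCA of the centered binary matrix")
  ord <- stage("ordination", pca_binary(mat, n_axes = n_axes))
  logistic <- NULL
  if (run_logistic_pca) {
    log_step("logistic PCA, rank ", n_axes)
    logistic <- stage("ordination", logistic_pca(mat, rank = n_axes))
  }

  if (!all(is.na(report$completeness))) {
    with_q <- filter(report, !is.na(.data$completeness))
    tests$kendall_adherence_completeness <- stage("group_stats",
      kendall_tau_b(with_q, .data$adherence_percent, .data$completeness))
    for (g in groups) {
      sub <- filter(with_q, .data$source_group == g)
      if (nrow(sub) >= 3L && length(unique(sub$adherence_percent)) > 1L &&
          length(unique(sub$completeness)) > 1L) {
        tests[[paste0("kendall_adherence_completeness_", g)]] <-
          stage("group_stats",
                kendall_tau_b(sub, .data$adherence_percent, .data$completeness))
      }
    }
    for (ax in seq_len(min(2L, ncol(ord$scores)))) {
      tests[[paste0("kendall_pc", ax, "_completeness")]] <- stage("group_stats",
        axis_quality_correlation(ord, ax, report))
    }
  }

  summary <- list(
    cmf_size = nrow(cmf),
    n_genomes = nrow(mat),
    adherence_by_group = as.list_rows(summary_groups),
    quality_strata = if (!is.null(strata)) as.list_rows(strata) else NULL,
    missing_count_above = as.list(count_above),
    missingness_threshold = missingness_threshold,
    tests = lapply(tests, function(t) {
      list(test_name = t$test_name, statistic = t$statistic,
           p_value = t$p_value, n_per_group = t$n_per_group,
           method_details = t$method_details)
    }),
    permanova = if (!is.null(perm)) {
      list(pseudo_F = perm$pseudo_F, p_value = perm$p_value,
           n_permutations = perm$n_permutations, seed = perm$seed)
    } else NULL,
    pca_explained_variance = ord$explained_variance,
    logistic_pca_explained_variance = if (!is.null(logistic))
      logistic$explained_variance else NULL,
    provenance = list(
      package = "cmfscan",
      seed = seed, n_permutations = n_permutations,
      quality_threshold = quality_threshold,
      missingness_threshold = missingness_threshold,
      n_axes = n_axes, run_logistic_pca = run_logistic_pca
    )
  )

  out <- structure(list(
    cmf = cmf, matrix = mat, report = report,
    group_summary = summary_groups, quality_strata = strata,
    missing_by_group = missing_by_group, tests = tests, cluster = cluster,
    contingency = contingency, ordination = ord, logistic_pca = logistic,
    permanova = perm, summary = summary
  ), class = "cmf_analysis")

  if (!is.null(output_dir)) {
    log_step("writing artifacts to ", output_dir)
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_cmf(cmf, file.path(output_dir, "cmf.tsv"))
    write_presence_matrix(mat, file.path(output_dir, "matrix.tsv"))
    readr::write_tsv(report, file.path(output_dir, "report.tsv"), progress = FALSE)
    readr::write_tsv(tidy(ord), file.path(output_dir, "scores.tsv"), progress = FALSE)
    jsonlite::write_json(summary, file.path(output_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  }
  out
}

as.list_rows <- function(df) lapply(seq_len(nrow(df)), function(i) as.list(df[i, ]))

#' @export
print.cmf_analysis <- function(x, ...) {
  cat("CMF screening analysis:", nrow(x$matrix), "genomes x",
      nrow(x$cmf), "core functions\n\n")
  print(x$group_summary)
  if (length(x$tests)) {
    cat("\nTests:\n")
    print(tidy(x))
  }
  if (!is.null(x$permanova)) print(x$permanova)
  invisible(x)
}
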
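#' Tidy a hypothesis-test result
#'
#' @param x A [cmf_test] object.
#' @param ... Unused.
#' @return A one-row tibble: `test_name`, `statistic`, `p.value`,
#'   `n_total`, `method`.
#' @export
tidy.cmf_test <- function(x, ...) {
  tibble(test_name = x$test_name, statistic = x$statistic,
         p.value = x$p_value, n_total = sum(x$n_per_group),
         method = x$method_details)
}

#' @rdname tidy.cmf_test
#' @export
glance.cmf_test <- function(x, ...) tidy(x)

#' Tidy an ordination
#'
#' @param x A `cmf_ordination` object.
#' @param ... Unused.
#' @return A tibble with `genome_id` and one column per axis score.
#' @export
tidy.cmf_ordination <- function(x, ...) {
  dplyr::bind_cols(tibble(genome_id = x$ids), as_tibble(x$scores))
}

#' @rdname tidy.cmf_ordination
#' @return For `glance()`: one row with the per-axis explained-variance
#'   fractions and the method.
#' @export
glance.cmf_ordination <- function(x, ...) {
  ev <- setNames(as.list(x$explained_variance),
                 paste0("var_frac_pc", seq_along(x$explained_variance)))
  dplyr::bind_cols(tibble(method = x$method, n = length(x$ids)),
                   as_tibble(ev))
}

#' Tidy a PERMANOVA result
#'
#' @param x A `cmf_permanova` object.
#' @param ... Unused.
#' @return A one-row tibble with the pseudo-F partition and p-value.
#' @export
tidy.cmf_permanova <- function(x, ...) {
  tibble(pseudo_F = x$pseudo_F, p.value = x$p_value,
         df_between = x$df[1], df_within = x$df[2],
         ss_between = x$ss_between, ss_within = x$ss_within,
         n_permutations = x$n_permutations, seed = x$seed)
}

#' @rdname tidy.cmf_permanova
#' @export
glance.cmf_permanova <- function(x, ...) tidy(x)

#' Tidy views of a full analysis
#'
#' `tidy()` stacks all hypothesis tests; `glance()` gives the one-row
#' headline summary (group adherence means, key p-values, PERMANOVA).
#'
#' @param x A `cmf_analysis` object from [run_cmf_analysis()].
#' @param ... Unused.
#' @export
tidy.cmf_analysis <- function(x, ...) {
  if (!length(x$tests)) return(tidy_test_empty())
  dplyr::bind_cols(tibble(test = names(x$tests)),
                   dplyr::bind_rows(lapply(x$tests, tidy)))
}

tidy_test_empty <- function() {
  tibble(test = character(), test_name = character(), statistic = numeric(),
         p.value = numeric(), n_total = integer(), method = character())
}

#' @rdname tidy.cmf_analysis
#' @export
glance.cmf_analysis <- function(x, ...) {
  gs <- x$group_summary
  means <- setNames(as.list(gs$mean_adherence),
                    paste0("mean_adherence_", gs$source_group))
  out <- dplyr::bind_cols(
    tibble(n_genomes = nrow(x$matrix), cmf_size = nrow(x$cmf)),
    as_tibble(means)
  )
  if (!is.null(x$tests$kruskal_wallis)) {
    out$kruskal_p <- x$tests$kruskal_wallis$p_value
  }
  if (!is.null(x$tests$fisher_cluster_source)) {
    out$fisher_cluster_p <- x$tests$fisher_cluster_source$p_value
  }
  if (!is.null(x$permanova)) {
    out$permanova_F <- x$permanova$pseudo_F
    out$permanova_p <- x$permanova$p_value
  }
  if (!is.null(x$tests$kendall_adherence_completeness)) {
    out$kendall_tau <- x$tests$kendall_adherence_completeness$statistic
  }
  out
}
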
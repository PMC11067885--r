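#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a segmentation
#'
#' @param x A `segmentation`.
#' @param ... Unused.
#' @return A plain tibble of segments with a `width` column.
#' @export
tidy.segmentation <- function(x, ...) {
  d <- as_tibble(x)
  d$width <- d$end - d$start
  d
}

#' One-row summary of a segmentation
#'
#' @param x A `segmentation`.
#' @param ... Unused.
#' @return A one-row tibble: `n_chromosomes`, `n_blocks`, `n_chains`,
#'   `n_breakpoints`, `n_breakpoints_zero_width`, `aligned_fraction`.
#' @export
glance.segmentation <- function(x, ...) {
  cov <- class_coverage(x)
  genome_len <- sum(chrom_lengths(segmentation_layout(x)))
  aligned <- sum(cov$total_bases[cov$class %in% c("collinear_alignment",
                                                  "isolated_alignment")])
  chains <- segmentation_chains(x)
  tibble(
    n_chromosomes = length(unique(as_tibble(x)$chrom)),
    n_blocks = attr(x, "n_aligned_blocks"),
    n_chains = if (is.null(chains)) NA_integer_ else nrow(chains),
    n_breakpoints = cov$n[cov$class == "breakpoint"],
    n_breakpoints_zero_width = cov$n_zero_width[cov$class == "breakpoint"],
    aligned_fraction = aligned / genome_len
  )
}

#' Tidy a scrambling report
#'
#' @param x A `scrambling_report`.
#' @param ... Unused.
#' @return The per-unit tibble (`unit`, `chrom`, `arm_class`, `L_same`,
#'   `L_opposite`, `index`, `weight`).
#' @export
tidy.scrambling_report <- function(x, ...) as_tibble(x)

#' One-row summary of a scrambling report
#'
#' @param x A `scrambling_report`.
#' @param ... Unused.
#' @return A one-row tibble: `grouping`, `n_units`, `n_units_aligned`,
#'   `weighted_index`.
#' @export
glance.scrambling_report <- function(x, ...) {
  d <- as_tibble(x)
  tibble(
    grouping = attr(x, "grouping"),
    n_units = nrow(d),
    n_units_aligned = sum(!is.na(d$index)),
    weighted_index = weighted_scrambling_index(x)
  )
}

#' Tidy the operonic-status association test
#'
#' @param x An `operon_assoc_test`.
#' @param ... Unused.
#' @return A tibble with one row per cell: `category`, `observed`,
#'   `expected`.
#' @export
tidy.operon_assoc_test <- function(x, ...) {
  tibble(
    category = names(x$observed),
    observed = unname(x$observed),
    expected = unname(x$expected)
  )
}

#' One-row summary of the operonic-status association test
#'
#' @param x An `operon_assoc_test`.
#' @param ... Unused.
#' @return A one-row tibble: `n_pairs`, `statistic`, `df_quoted`,
#'   `p_quoted`, `df_independence`, `p_independence`.
#' @export
glance.operon_assoc_test <- function(x, ...) {
  tibble(
    n_pairs = x$n,
    statistic = x$statistic_gof,
    df_quoted = x$df_gof, p_quoted = x$p_gof,
    df_independence = x$df_indep, p_independence = x$p_indep
  )
}

#' Tidy the arm-class breakpoint rate test
#'
#' @param x An `arm_rate_test`.
#' @param ... Unused.
#' @return The per-arm-class count table.
#' @export
tidy.arm_rate_test <- function(x, ...) as_tibble(x$table)

#' One-row summary of the arm-class breakpoint rate test
#'
#' @param x An `arm_rate_test`.
#' @param ... Unused.
#' @return A one-row tibble: `statistic`, `df`, `p_value` (`NA` when the
#'   test was degenerate and not run).
#' @export
glance.arm_rate_test <- function(x, ...) {
  if (is.null(x$test)) {
    tibble(statistic = NA_real_, df = NA_real_, p_value = NA_real_)
  } else {
    tibble(statistic = unname(x$test$statistic),
           df = unname(x$test$parameter),
           p_value = x$test$p.value)
  }
}

#' Tidy the operon-size-by-breakpoint comparison
#'
#' @param x An `operon_size_test`.
#' @param ... Unused.
#' @return The per-operon tibble (`operon_id`, `n_genes`,
#'   `overlaps_breakpoint`).
#' @export
tidy.operon_size_test <- function(x, ...) x$sizes

#' One-row summary of the operon-size-by-breakpoint comparison
#'
#' @param x An `operon_size_test`.
#' @param ... Unused.
#' @return A one-row tibble: group sizes and medians, `statistic`,
#'   `p_value` (`NA` when the test was not run).
#' @export
glance.operon_size_test <- function(x, ...) {
  g <- x$groups
  pick <- function(flag, col) {
    v <- g[[col]][g$overlaps_breakpoint == flag]
    if (length(v)) v else NA
  }
  tibble(
    n_overlapping = pick(TRUE, "n"),
    n_not = pick(FALSE, "n"),
    median_overlapping = pick(TRUE, "median_size"),
    median_not = pick(FALSE, "median_size"),
    statistic = if (is.null(x$test)) NA_real_ else unname(x$test$statistic),
    p_value = if (is.null(x$test)) NA_real_ else x$test$p.value
  )
}

#' Tidy synteny blocks
#'
#' @param x A `synteny_blocks` object.
#' @param ... Unused.
#' @return The pair-level tibble with rank and block assignment.
#' @export
tidy.synteny_blocks <- function(x, ...) as_tibble(x)

#' One-row summary of synteny blocks
#'
#' @param x A `synteny_blocks` object.
#' @param ... Unused.
#' @return A one-row tibble: `n_pairs`, `n_blocks`, `max_size`,
#'   `mean_size`, `fraction_singletons`.
#' @export
glance.synteny_blocks <- function(x, ...) {
  sizes <- synteny_block_sizes(x)
  n_blocks <- sum(sizes$n_blocks)
  tibble(
    n_pairs = nrow(as_tibble(x)),
    n_blocks = n_blocks,
    max_size = if (n_blocks) max(sizes$size) else NA_integer_,
    mean_size = if (n_blocks) {
      sum(sizes$size * sizes$n_blocks) / n_blocks
    } else {
      NA_real_
    },
    fraction_singletons = if (n_blocks) {
      sum(sizes$n_blocks[sizes$size == 1]) / n_blocks
    } else {
      NA_real_
    }
  )
}
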
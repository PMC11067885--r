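#' Call operons from gene order
#'
#' An operon is a maximal run of two or more same-strand genes that follow
#' each other along a chromosome with intergenic distances of at most
#' `max_gap` bases (default 500, the distance that reproduces the operon
#' length distributions reported for compact tunicate genomes).  The
#' intergenic distance is `next gene start - previous gene end` on gene
#' spans; overlapping genes (negative gap) are treated as gap 0 and merged
#' when on the same strand.  A gene of the opposite strand between two
#' candidates breaks the run.  Singleton genes are not operons.
#'
#' @param genes A tibble of gene models: `gene_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @param max_gap Maximum intergenic distance in bases.
#' @return An `operon_set` tibble: `operon_id`, `chrom`, `strand`, `start`,
#'   `end`, `n_genes` and list-column `gene_ids` (members in genomic order).
#' @export
call_operons <- function(genes, max_gap = 500) {
  g <- arrange(as_tibble(genes), .data$chrom, .data$start)
  n <- nrow(g)
  if (n == 0) return(empty_operon_set())
  new_run <- c(TRUE,
               g$chrom[-1] != g$chrom[-n] |
                 g$strand[-1] != g$strand[-n] |
                 (g$start[-1] - g$end[-n]) > max_gap)
  run <- cumsum(new_run)
  ops <- g |>
    mutate(run = run) |>
    group_by(.data$run) |>
    summarise(
      chrom = .data$chrom[[1]], strand = .data$strand[[1]],
      start = min(.data$start), end = max(.data$end),
      n_genes = n(), gene_ids = list(.data$gene_id),
      .groups = "drop"
    ) |>
    filter(.data$n_genes >= 2L)
  ops <- arrange(ops, .data$chrom, .data$start)
  ops$operon_id <- paste0("op", seq_len(nrow(ops)))
  ops <- ops[, c("operon_id", "chrom", "strand", "start", "end", "n_genes",
                 "gene_ids")]
  structure(ops, class = c("operon_set", class(tibble())))
}

empty_operon_set <- function() {
  structure(
    tibble(operon_id = character(), chrom = character(), strand = character(),
           start = numeric(), end = numeric(), n_genes = integer(),
           gene_ids = list()),
    class = c("operon_set", class(tibble()))
  )
}

#' Long-format operon membership table
#'
#' @param operons An `operon_set`.
#' @return A tibble `operon_id`, `gene_id` (one row per member gene).
#' @export
operon_members <- function(operons) {
  tidyr::unnest(as_tibble(operons)[, c("operon_id", "gene_ids")],
                "gene_ids") |>
    rename(gene_id = "gene_ids")
}

# Map gene ids to orthogroup ids at the chosen granularity.  Genes lacking an
# assignment never match any gene: they are replaced by unique sentinels.
gene_groups <- function(gene_ids, map, genome,
                        gene_equivalence = c("hog", "og")) {
  gene_equivalence <- match.arg(gene_equivalence)
  col <- paste0(gene_equivalence, "_id")
  m <- filter(as_tibble(map), .data$genome_id == genome)
  grp <- m[[col]][match(gene_ids, m$gene_id)]
  miss <- is.na(grp)
  grp[miss] <- paste0(".unassigned:", genome, ":", gene_ids[miss])
  grp
}

#' Cross-genome operon equivalence
#'
#' Two operons are `exact`-equivalent when the multisets of orthogroup ids of
#' their member genes are equal; `inexact` equivalence additionally accepts
#' equal-size operons of three or more genes whose multisets differ by a
#' single substituted element (an operon ABC matches ABC, XBC, AXC or ABX).
#' Order and strand are ignored; genes without an orthogroup assignment
#' match nothing.
#'
#' @param genes1,genes2 Character vectors of member gene ids.
#' @param map An `ortholog_map`.
#' @param genome1,genome2 Genome ids of the two operons in `map`.
#' @param gene_equivalence `"hog"` or `"og"`.
#' @param operon_equivalence `"exact"` or `"inexact"`.
#' @return Logical scalar.
#' @export
operon_equivalent <- function(genes1, genes2, map, genome1, genome2,
                              gene_equivalence = c("hog", "og"),
                              operon_equivalence = c("exact", "inexact")) {
  operon_equivalence <- match.arg(operon_equivalence)
  g1 <- gene_groups(genes1, map, genome1, gene_equivalence)
  g2 <- gene_groups(genes2, map, genome2, gene_equivalence)
  groups_equivalent(g1, g2, operon_equivalence)
}

groups_equivalent <- function(g1, g2, operon_equivalence) {
  if (length(g1) != length(g2)) return(FALSE)
  n_diff <- multiset_difference(g1, g2)
  if (n_diff == 0L) return(TRUE)
  operon_equivalence == "inexact" && length(g1) >= 3L && n_diff == 1L
}

# Number of substitutions separating two equal-length multisets: size minus
# the multiset intersection.
multiset_difference <- function(g1, g2) {
  t1 <- table(g1)
  t2 <- table(g2)
  common <- intersect(names(t1), names(t2))
  length(g1) - sum(pmin(t1[common], t2[common]))
}

#' Operon sharing across genomes
#'
#' Counts, for every subset of the non-reference genomes, the operons of the
#' reference genome that have an equivalent operon in exactly the genomes of
#' that subset (and in no other).  The counts over all subsets (including the
#' empty one, reference-only operons) sum to the reference genome's operon
#' count.
#'
#' @param operon_sets Named list of `operon_set` objects, one per genome;
#'   names are genome ids as used in `map`.
#' @param map An `ortholog_map`.
#' @param reference Genome id of the reference; defaults to the first set.
#' @param gene_equivalence,operon_equivalence Equivalence criteria, as in
#'   [operon_equivalent()].
#' @return A tibble `shared_with` (`+`-separated genome ids, `""` for
#'   reference-only), `n_genomes`, `n_operons`.
#' @export
shared_operons <- function(operon_sets, map,
                           reference = names(operon_sets)[[1]],
                           gene_equivalence = c("hog", "og"),
                           operon_equivalence = c("exact", "inexact")) {
  gene_equivalence <- match.arg(gene_equivalence)
  operon_equivalence <- match.arg(operon_equivalence)
  if (is.null(names(operon_sets)) || !reference %in% names(operon_sets)) {
    stop_config("operon_sets must be named by genome id, including the reference")
  }
  others <- setdiff(names(operon_sets), reference)
  ref_ops <- as_tibble(operon_sets[[reference]])
  ref_groups <- lapply(ref_ops$gene_ids, gene_groups, map = map,
                       genome = reference, gene_equivalence = gene_equivalence)
  membership <- matrix(FALSE, nrow = nrow(ref_ops), ncol = length(others),
                       dimnames = list(NULL, others))
  for (g in others) {
    g_ops <- as_tibble(operon_sets[[g]])
    g_groups <- lapply(g_ops$gene_ids, gene_groups, map = map, genome = g,
                       gene_equivalence = gene_equivalence)
    for (i in seq_along(ref_groups)) {
      membership[i, g] <- any(vapply(
        g_groups, groups_equivalent, logical(1),
        g1 = ref_groups[[i]], operon_equivalence = operon_equivalence
      ))
    }
  }
  subset_key <- apply(membership, 1L, function(r) {
    paste(others[r], collapse = "+")
  })
  out <- tibble(shared_with = subset_key) |>
    group_by(.data$shared_with) |>
    summarise(n_operons = n(), .groups = "drop") |>
    mutate(n_genomes = ifelse(.data$shared_with == "", 0L,
                              lengths(strsplit(.data$shared_with, "+",
                                               fixed = TRUE)))) |>
    arrange(dplyr::desc(.data$n_genomes), .data$shared_with)
  out[, c("shared_with", "n_genomes", "n_operons")]
}

#' Proportion of elements overlapping a breakpoint region
#'
#' An element overlaps when it intersects at least one breakpoint region of
#' the segmentation.  A zero-width breakpoint at position `p` overlaps an
#' element `[s, e)` only when the point lies strictly inside it
#' (`s < p < e`); an element abutting the point at its own boundary is not
#' counted.
#'
#' @param elements A named list of element tables (each with `chrom`,
#'   `start`, `end`; e.g. operon spans, genes, exons), or a single such
#'   table.
#' @param seg A `segmentation` on the same genome.
#' @return A tibble `element_class`, `n_total`, `n_overlapping`,
#'   `proportion`.
#' @export
breakpoint_overlap <- function(elements, seg) {
  if (is.data.frame(elements)) {
    elements <- list(elements = elements)
  }
  bp <- breakpoint_regions(seg)
  seg_chroms <- unique(as_tibble(seg)$chrom)
  rows <- lapply(names(elements), function(nm) {
    el <- as_tibble(elements[[nm]])
    unknown <- setdiff(unique(el$chrom), seg_chroms)
    if (length(unknown)) {
      stop_validation(paste0(
        "elements of '", nm, "' on chromosome(s) absent from segmentation: ",
        paste(unknown, collapse = ", ")
      ))
    }
    hit <- overlaps_breakpoints(el, bp)
    tibble(element_class = nm, n_total = nrow(el),
           n_overlapping = sum(hit),
           proportion = ifelse(nrow(el) > 0, sum(hit) / nrow(el), NA_real_))
  })
  bind_rows(rows)
}

# Logical vector: does each element intersect >= 1 breakpoint region?
overlaps_breakpoints <- function(el, bp) {
  hit <- rep(FALSE, nrow(el))
  if (nrow(el) == 0 || nrow(bp) == 0) return(hit)
  pos <- filter(bp, .data$end > .data$start)
  zero <- filter(bp, .data$end == .data$start)
  for (chrom in unique(el$chrom)) {
    sel <- which(el$chrom == chrom)
    p <- filter(pos, .data$chrom == !!chrom)
    if (nrow(p) > 0) {
      ov <- IRanges::findOverlaps(
        IRanges::IRanges(el$start[sel] + 1L, el$end[sel]),
        IRanges::IRanges(p$start + 1L, p$end)
      )
      hit[sel[unique(S4Vectors::queryHits(ov))]] <- TRUE
    }
    z <- filter(zero, .data$chrom == !!chrom)
    if (nrow(z) > 0) {
      pts <- sort(z$start)
      inside <- points_strictly_inside(el$start[sel], el$end[sel], pts) > 0
      hit[sel[inside]] <- TRUE
    }
  }
  hit
}

#' Association of operonic status across a genome pair
#'
#' Classifies each single-copy ortholog pair as operonic in both genomes, in
#' one only, or in neither.  Reports (a) a chi-squared statistic of the four
#' observed counts against expected counts derived from independent marginal
#' operonic rates, quoted with 3 degrees of freedom, and (b) the standard
#' 2x2 independence test (1 degree of freedom, no continuity correction) as
#' a calibrated cross-check.  The two statistics are numerically identical;
#' they differ only in the reference distribution used for the p-value.
#'
#' @param pair_status A tibble with logical columns `operonic_a`,
#'   `operonic_b`, one row per single-copy ortholog pair.
#' @return An `operon_assoc_test` object (see `tidy()` / `glance()`),
#'   containing the 4-cell table, both statistics, degrees of freedom and
#'   p-values.
#' @export
operonic_status_test <- function(pair_status) {
  d <- as_tibble(pair_status)
  if (!all(c("operonic_a", "operonic_b") %in% names(d))) {
    stop_validation("pair_status needs logical columns operonic_a, operonic_b")
  }
  n <- nrow(d)
  counts <- c(
    both = sum(d$operonic_a & d$operonic_b),
    a_only = sum(d$operonic_a & !d$operonic_b),
    b_only = sum(!d$operonic_a & d$operonic_b),
    neither = sum(!d$operonic_a & !d$operonic_b)
  )
  if (sum(counts > 0) < 2) {
    stop_domain("fewer than two occupied categories: association undefined")
  }
  p_a <- (counts[["both"]] + counts[["a_only"]]) / n
  p_b <- (counts[["both"]] + counts[["b_only"]]) / n
  expected <- n * c(
    both = p_a * p_b, a_only = p_a * (1 - p_b),
    b_only = (1 - p_a) * p_b, neither = (1 - p_a) * (1 - p_b)
  )
  if (any(expected == 0)) {
    stop_domain("degenerate test: an expected count is zero")
  }
  chi2 <- sum((counts - expected)^2 / expected)
  structure(
    list(
      observed = counts, expected = expected, n = n,
      marginal_rate_a = p_a, marginal_rate_b = p_b,
      statistic_gof = chi2, df_gof = 3L,
      p_gof = pchisq(chi2, df = 3L, lower.tail = FALSE),
      statistic_indep = chi2, df_indep = 1L,
      p_indep = pchisq(chi2, df = 1L, lower.tail = FALSE)
    ),
    class = "operon_assoc_test"
  )
}

#' @export
print.operon_assoc_test <- function(x, ...) {
  cat("Operonic-status association across a genome pair\n")
  cat("  counts:", paste(names(x$observed), x$observed, sep = "=",
                         collapse = "  "), "\n")
  cat(sprintf("  chi-squared = %.4g (4-category vs independence, df = %d, p = %.3g)\n",
              x$statistic_gof, x$df_gof, x$p_gof))
  cat(sprintf("  2x2 independence cross-check: df = %d, p = %.3g\n",
              x$df_indep, x$p_indep))
  invisible(x)
}

#' Operon sizes split by breakpoint overlap, with rank-sum test
#'
#' Splits operon sizes (gene counts) by whether the operon span overlaps a
#' breakpoint region, and compares the two distributions with a two-sided
#' Wilcoxon rank-sum test.  When either group is empty the comparison is
#' reported as missing, with a notice, and no test is run.
#'
#' @param operons An `operon_set`.
#' @param seg A `segmentation` on the same genome.
#' @return An `operon_size_test` list: `sizes` tibble (`operon_id`,
#'   `n_genes`, `overlaps_breakpoint`), `groups` summary, and `test` (an
#'   `htest` or `NULL`).
#' @export
operon_size_by_breakpoint <- function(operons, seg) {
  ops <- as_tibble(operons)
  hit <- overlaps_breakpoints(ops, breakpoint_regions(seg))
  sizes <- tibble(operon_id = ops$operon_id, n_genes = ops$n_genes,
                  overlaps_breakpoint = hit)
  groups <- sizes |>
    group_by(.data$overlaps_breakpoint) |>
    summarise(n = n(), median_size = stats::median(.data$n_genes),
              .groups = "drop")
  test <- NULL
  if (length(unique(sizes$overlaps_breakpoint)) == 2) {
    test <- suppressWarnings(stats::wilcox.test(
      n_genes ~ overlaps_breakpoint, data = sizes, exact = FALSE
    ))
  } else {
    notify("one overlap group is empty: rank-sum test not run")
  }
  structure(list(sizes = sizes, groups = groups, test = test),
            class = "operon_size_test")
}
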
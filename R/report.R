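#' Full pairwise comparison of two genomes
#'
#' Runs the complete analysis pipeline on a pair of genomes: collinearity
#' segmentation of both genomes, class coverage, the scrambling index,
#' breakpoint accumulation rates (when a divergence time is given), operon
#' calling and breakpoint overlap (when gene annotations are given), and
#' ortholog-based statistics -- macrosynteny blocks, the dot-plot table and
#' the operonic-status association test -- when an ortholog map is given.
#' Components whose inputs are missing are skipped and reported as `NULL`.
#'
#' @param aln An `alignment_set` (genome A as target, genome B as query).
#' @param annotation_a,annotation_b Optional annotation lists for the two
#'   genomes, each with at least a `genes` table (`gene_id`, `chrom`,
#'   `start`, `end`, `strand`) and optionally `exons`; the structure
#'   returned by [read_gff3()] or [sim_annotation()].
#' @param orthologs Optional `ortholog_map` covering both genomes.
#' @param genome_ids Genome ids of target and query as used in `orthologs`
#'   (default `c("A", "B")`).
#' @param divergence_time Optional divergence time in million years.
#' @param max_gap Operon-calling intergenic distance (default 500).
#' @return A `comparison_report` list: `genome_ids`, `n_blocks`,
#'   `segmentation` (target/query), `coverage` (target/query), `scrambling`
#'   (per-chromosome `scrambling_report`), `scrambling_arm` (per-arm, or
#'   `NULL` without arm annotation), `breakpoint_rate` (target/query, or
#'   `NULL`), `operons`, `breakpoint_overlap`, `operon_sizes`,
#'   `shared_operons` (exact and inexact), `synteny`, `synteny_sizes`,
#'   `dotplot`, `operon_assoc`.
#' @export
compare_genomes <- function(aln, annotation_a = NULL, annotation_b = NULL,
                            orthologs = NULL, genome_ids = c("A", "B"),
                            divergence_time = NULL, max_gap = 500) {
  if (length(genome_ids) != 2 || anyDuplicated(genome_ids)) {
    stop_config("genome_ids must be two distinct genome ids")
  }
  segs <- segment_both_directions(aln)
  coverage <- lapply(segs, class_coverage)
  scram <- scrambling_index(aln, by = "chromosome")
  scram_arm <- if (!is.null(layout_arms(target_layout(aln)))) {
    scrambling_index(aln, by = "arm")
  }

  rate <- NULL
  if (!is.null(divergence_time)) {
    rate <- lapply(segs, breakpoint_rate, divergence_time = divergence_time)
  }

  ann <- setNames(list(annotation_a, annotation_b), genome_ids)
  have_ann <- !vapply(ann, is.null, logical(1))
  operons <- overlap <- op_sizes <- NULL
  if (any(have_ann)) {
    operons <- lapply(ann[have_ann], function(a) {
      call_operons(a$genes, max_gap = max_gap)
    })
    seg_of <- setNames(list(segs$target, segs$query), genome_ids)
    overlap <- lapply(names(operons), function(g) {
      el <- list(operons = as_tibble(operons[[g]])[, c("chrom", "start", "end")],
                 genes = ann[[g]]$genes)
      if (!is.null(ann[[g]]$exons)) el$exons <- ann[[g]]$exons
      breakpoint_overlap(el, seg_of[[g]])
    })
    names(overlap) <- names(operons)
    op_sizes <- lapply(names(operons), function(g) {
      operon_size_by_breakpoint(operons[[g]], seg_of[[g]])
    })
    names(op_sizes) <- names(operons)
  }

  synteny <- sizes <- dotplot <- assoc <- shared <- NULL
  if (!is.null(orthologs) && all(have_ann)) {
    pairs <- ortholog_pair_table(orthologs, genome_ids[[1]], genome_ids[[2]],
                                 annotation_a$genes, annotation_b$genes)
    if (nrow(pairs) > 0) {
      synteny <- synteny_blocks(pairs)
      sizes <- synteny_block_sizes(synteny)
      dotplot <- dotplot_table(pairs)
      in_op_a <- pairs$gene_a %in% operon_members(
        operons[[genome_ids[[1]]]])$gene_id
      in_op_b <- pairs$gene_b %in% operon_members(
        operons[[genome_ids[[2]]]])$gene_id
      status <- tibble(operonic_a = in_op_a, operonic_b = in_op_b)
      assoc <- tryCatch(operonic_status_test(status),
                        scramblr_domain_error = function(e) {
                          notify(conditionMessage(e))
                          NULL
                        })
      shared <- list(
        exact = shared_operons(operons, orthologs,
                               reference = genome_ids[[1]],
                               operon_equivalence = "exact"),
        inexact = shared_operons(operons, orthologs,
                                 reference = genome_ids[[1]],
                                 operon_equivalence = "inexact")
      )
    }
  }

  structure(
    list(
      genome_ids = genome_ids,
      n_blocks = nrow(as_tibble(aln)),
      segmentation = segs,
      coverage = coverage,
      scrambling = scram,
      scrambling_arm = scram_arm,
      breakpoint_rate = rate,
      operons = operons,
      breakpoint_overlap = overlap,
      operon_sizes = op_sizes,
      shared_operons = shared,
      synteny = synteny,
      synteny_sizes = sizes,
      dotplot = dotplot,
      operon_assoc = assoc
    ),
    class = "comparison_report"
  )
}

# Single-copy ortholog pairs with gene coordinates on both genomes, ready
# for synteny_blocks() / dotplot_table().  Pairs whose genes are missing
# from either gene table are dropped.
ortholog_pair_table <- function(map, genome_a, genome_b, genes_a, genes_b) {
  p <- single_copy_pairs(map, genome_a, genome_b)
  ga <- as_tibble(genes_a)
  gb <- as_tibble(genes_b)
  ia <- match(p$gene_a, ga$gene_id)
  ib <- match(p$gene_b, gb$gene_id)
  keep <- !is.na(ia) & !is.na(ib)
  p <- p[keep, ]; ia <- ia[keep]; ib <- ib[keep]
  tibble(
    pair_id = p$group_id, gene_a = p$gene_a, gene_b = p$gene_b,
    t_chrom = ga$chrom[ia], t_start = ga$start[ia], t_end = ga$end[ia],
    q_chrom = gb$chrom[ib], q_start = gb$start[ib], q_end = gb$end[ib]
  )
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Pairwise genome comparison:", x$genome_ids[[1]], "vs",
      x$genome_ids[[2]], "\n")
  cat("  alignment blocks:", x$n_blocks, "\n")
  covt <- x$coverage$target
  frac <- covt$fraction_of_genome[covt$class == "collinear_alignment"] +
    covt$fraction_of_genome[covt$class == "isolated_alignment"]
  cat(sprintf("  target aligned fraction: %.3f\n", frac))
  cat(sprintf("  weighted scrambling index: %.4f\n",
              weighted_scrambling_index(x$scrambling)))
  nb <- covt$n[covt$class == "breakpoint"]
  cat("  target breakpoint regions:", nb, "\n")
  if (!is.null(x$breakpoint_rate)) {
    cat(sprintf("  breakpoint rate (target): %.3f / Mbp / My\n",
                x$breakpoint_rate$target$rate))
  }
  if (!is.null(x$operons)) {
    for (g in names(x$operons)) {
      cat("  operons in", g, ":", nrow(x$operons[[g]]), "\n")
    }
  }
  if (!is.null(x$operon_assoc)) {
    cat(sprintf("  operonic-status association: chi-squared = %.4g\n",
                x$operon_assoc$statistic_gof))
  }
  invisible(x)
}

#' Write a comparison report to disk
#'
#' Emits a machine-readable JSON summary (`summary.json`) and tabular
#' artifacts: segmentation BEDs for both genomes, per-chromosome scrambling
#' TSV, collinear chain table, and -- when present -- operon TSVs, the
#' synteny block table and the dot-plot table.
#'
#' @param report A `comparison_report`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_comparison_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- report$genome_ids
  paths <- c(summary = file.path(dir, "summary.json"))

  p <- file.path(dir, paste0("segmentation_", ids, ".bed"))
  write_bed(report$segmentation$target, p[[1]])
  write_bed(report$segmentation$query, p[[2]])
  paths <- c(paths, setNames(p, paste0("segmentation_", ids)))

  p <- file.path(dir, "scrambling.tsv")
  readr::write_tsv(as_tibble(report$scrambling), p)
  paths <- c(paths, scrambling = p)

  p <- file.path(dir, "chains.tsv")
  write_chain_table(segmentation_chains(report$segmentation$target), p)
  paths <- c(paths, chains = p)

  for (g in names(report$operons %||% list())) {
    p <- file.path(dir, paste0("operons_", g, ".tsv"))
    ops <- as_tibble(report$operons[[g]])
    ops$gene_ids <- vapply(ops$gene_ids, paste, character(1), collapse = ",")
    readr::write_tsv(ops, p)
    paths <- c(paths, setNames(p, paste0("operons_", g)))
  }
  if (!is.null(report$synteny)) {
    p <- file.path(dir, "synteny_blocks.tsv")
    readr::write_tsv(as_tibble(report$synteny), p)
    paths <- c(paths, synteny = p)
    p <- file.path(dir, "dotplot.tsv")
    readr::write_tsv(report$dotplot, p)
    paths <- c(paths, dotplot = p)
  }

  jsonlite::write_json(report_summary(report), paths[["summary"]],
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

# Plain-list summary of a comparison report with numbers rounded to six
# significant digits, suitable for JSON serialisation.
report_summary <- function(report) {
  ids <- report$genome_ids
  sig <- function(x) if (is.numeric(x)) signif(x, 6) else x
  cov_list <- lapply(report$coverage, function(cv) {
    cv$class <- as.character(cv$class)
    lapply(as.list(cv), sig)
  })
  names(cov_list) <- ids
  out <- list(
    genome_ids = ids,
    n_blocks = report$n_blocks,
    coverage = cov_list,
    weighted_scrambling_index =
      sig(weighted_scrambling_index(report$scrambling)),
    scrambling_by_chromosome = lapply(
      as.list(as_tibble(report$scrambling)[
        , c("unit", "L_same", "L_opposite", "index")]), sig)
  )
  if (!is.null(report$breakpoint_rate)) {
    br <- lapply(report$breakpoint_rate, function(r) lapply(as.list(r), sig))
    names(br) <- ids
    out$breakpoint_rate <- br
  }
  if (!is.null(report$operons)) {
    out$n_operons <- lapply(report$operons, nrow)
    out$breakpoint_overlap <- lapply(report$breakpoint_overlap,
                                     function(t) lapply(as.list(t), sig))
  }
  if (!is.null(report$shared_operons)) {
    out$shared_operons <- lapply(report$shared_operons, function(t) {
      lapply(as.list(t), sig)
    })
  }
  if (!is.null(report$synteny)) {
    out$synteny <- list(
      n_pairs = nrow(as_tibble(report$synteny)),
      n_blocks = sum(report$synteny_sizes$n_blocks),
      max_block_size = max(report$synteny_sizes$size)
    )
  }
  if (!is.null(report$operon_assoc)) {
    a <- report$operon_assoc
    out$operon_assoc <- list(
      observed = as.list(a$observed),
      statistic = sig(a$statistic_gof),
      df_quoted = a$df_gof, p_quoted = sig(a$p_gof),
      df_independence = a$df_indep, p_independence = sig(a$p_indep)
    )
  }
  out
}

#' Run the simulator and write all artifacts (CLI backend)
#'
#' Simulates an aligned genome pair and writes, under `dir`: per-genome
#' annotation files, the alignment as PAF, and the ground-truth JSON.
#'
#' @param out Output directory.
#' @param seed Integer seed.
#' @param n_genes,n_events Optional overrides of the simulation defaults.
#' @return The `sim_pair`, invisibly.
#' @export
run_simulate <- function(out, seed = 1L, n_genes = NULL, n_events = NULL) {
  cfg <- sim_config(seed = as.integer(seed))
  if (!is.null(n_genes)) cfg$n_genes <- as.integer(n_genes)
  if (!is.null(n_events)) cfg$n_events <- as.integer(n_events)
  pair <- simulate_genome_pair(cfg)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  for (g in names(pair$genomes)) {
    emit_annotations(pair$genomes[[g]], out, prefix = g)
  }
  write_paf(pair$alignment, file.path(out, "alignment.paf"))
  write_truth(pair, file.path(out, "truth.json"))
  invisible(pair)
}

#' Run the comparison pipeline from files (CLI backend)
#'
#' @param alignment Path to a PAF (or MAF, by `.maf` extension) alignment.
#' @param out Output directory for [write_comparison_report()].
#' @param gff_a,gff_b Optional GFF3 annotation paths.
#' @param orthologs Optional ortholog table path.
#' @param layout_a,layout_b Optional layout TSV paths (target, query).
#' @param genome_ids Two genome ids (default `c("A", "B")`).
#' @param divergence_time Optional divergence time in million years.
#' @return The `comparison_report`, invisibly.
#' @export
run_compare <- function(alignment, out, gff_a = NULL, gff_b = NULL,
                        orthologs = NULL, layout_a = NULL, layout_b = NULL,
                        genome_ids = c("A", "B"), divergence_time = NULL) {
  t_layout <- if (!is.null(layout_a)) read_layout(layout_a)
  q_layout <- if (!is.null(layout_b)) read_layout(layout_b)
  reader <- if (grepl("\\.maf$", alignment)) read_maf else read_paf
  aln <- reader(alignment, target_layout = t_layout, query_layout = q_layout)
  ann_a <- if (!is.null(gff_a)) read_gff3(gff_a)
  ann_b <- if (!is.null(gff_b)) read_gff3(gff_b)
  map <- if (!is.null(orthologs)) read_ortholog_table(orthologs)
  report <- compare_genomes(aln, annotation_a = ann_a, annotation_b = ann_b,
                            orthologs = map, genome_ids = genome_ids,
                            divergence_time = divergence_time)
  write_comparison_report(report, out)
  invisible(report)
}

#' Breakpoint rate from an alignment file (CLI backend)
#'
#' @param alignment Path to a PAF (or `.maf`) alignment.
#' @param divergence_time Divergence time in million years.
#' @return A one-row tibble, as [breakpoint_rate()].
#' @export
run_rate <- function(alignment, divergence_time) {
  reader <- if (grepl("\\.maf$", alignment)) read_maf else read_paf
  aln <- reader(alignment)
  breakpoint_rate(classify_segments(aln),
                  divergence_time = as.numeric(divergence_time))
}
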
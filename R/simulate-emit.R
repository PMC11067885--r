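#' In-memory annotation of a simulated genome
#'
#' Projects genes, exons and repeats into the genome's current coordinates
#' and attaches per-gene dN/dS values (ancestral base value plus the
#' configured short-arm shift, applied according to the arm on which the
#' gene currently sits).
#'
#' @param state A `sim_genome`.
#' @return A list: `genes`, `exons`, `repeats`, `dnds`, `layout`.
#' @export
sim_annotation <- function(state) {
  genes <- genome_genes(state)
  exons <- genome_exons(state)
  layout <- state_layout(state)
  cfg <- state$config
  base <- setNames(state$dnds$dnds, state$dnds$gene_id)
  dnds <- tibble(
    gene_id = genes$gene_id,
    dnds = unname(base[genes$ancestral_id])
  )
  shift <- cfg$dnds_short_arm_shift
  if (!is.null(shift) && shift != 0) {
    arms <- layout_arms(layout)
    short <- filter(arms, .data$arm_class == "short")
    mid <- (genes$start + genes$end) / 2
    on_short <- rep(FALSE, nrow(genes))
    for (i in seq_len(nrow(short))) {
      on_short <- on_short | (genes$chrom == short$chrom[[i]] &
                                mid >= short$arm_start[[i]] &
                                mid < short$arm_end[[i]])
    }
    dnds$dnds <- dnds$dnds + shift * on_short
  }
  list(
    genes = genes[, c("gene_id", "chrom", "start", "end", "strand")],
    exons = exons,
    repeats = project_split_intervals(state, state$repeats),
    dnds = dnds,
    layout = layout
  )
}

#' Ortholog map of one or more simulated genomes
#'
#' Each current gene is assigned a hierarchical orthogroup derived from its
#' ancestral gene; duplicated copies receive a distinct HOG but share the
#' ancestral gene's OG, mirroring how orthology inference groups recent
#' paralogs at the family level.
#'
#' @param states A named list of `sim_genome` objects (names become
#'   `genome_id`s; defaults to each state's `branch_id`).
#' @return An `ortholog_map`.
#' @export
sim_ortholog_map <- function(states) {
  if (is.null(names(states))) {
    names(states) <- vapply(states, function(s) s$branch_id, character(1))
  }
  rows <- lapply(names(states), function(nm) {
    g <- genome_genes(states[[nm]])
    tibble(
      genome_id = nm,
      gene_id = g$gene_id,
      hog_id = ifelse(g$copy_id == 0L,
                      paste0("hog_", g$ancestral_id),
                      paste0("hog_", g$ancestral_id, "_c", g$copy_id)),
      og_id = paste0("og_", g$ancestral_id)
    )
  })
  as_ortholog_map(bind_rows(rows))
}

#' Write a simulated genome's annotation files
#'
#' Emits GFF3 gene models, a layout TSV, a repeat BED, a per-gene dN/dS TSV
#' and this genome's rows of the ortholog TSV; files parse back through the
#' package readers into the in-memory objects.
#'
#' @param state A `sim_genome`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix (defaults to the branch id).
#' @return Named character vector of file paths, invisibly.
#' @export
emit_annotations <- function(state, dir, prefix = state$branch_id) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ann <- sim_annotation(state)
  paths <- c(
    gff3 = file.path(dir, paste0(prefix, ".gff3")),
    layout = file.path(dir, paste0(prefix, ".layout.tsv")),
    repeats = file.path(dir, paste0(prefix, ".repeats.bed")),
    dnds = file.path(dir, paste0(prefix, ".dnds.tsv")),
    orthologs = file.path(dir, paste0(prefix, ".orthologs.tsv"))
  )
  write_gff3(list(genes = ann$genes, exons = ann$exons), paths[["gff3"]])
  write_layout(ann$layout, paths[["layout"]])
  write_bed(feature_track("repeat", ann$repeats), paths[["repeats"]])
  readr::write_tsv(ann$dnds, paths[["dnds"]])
  write_ortholog_table(sim_ortholog_map(setNames(list(state),
                                                 state$branch_id)),
                       paths[["orthologs"]])
  invisible(paths)
}

#' Simulate an aligned pair of descendant genomes
#'
#' Runs the full simulation: an annotated ancestor, two descendant branches
#' evolved independently under the configured event process, and the true
#' one-to-one alignment between the descendants.
#'
#' @param cfg A `sim_config`.
#' @param branches Two branch labels (default `"A"`, `"B"`).
#' @param branch_lengths Optional numeric vector of branch lengths in
#'   million years (rate mode).
#' @return A `sim_pair` list: `ancestor`, `genomes` (named list of two
#'   `sim_genome`s), `alignment` (an `alignment_set`, first branch as
#'   target), `config`.
#' @export
simulate_genome_pair <- function(cfg, branches = c("A", "B"),
                                 branch_lengths = NULL) {
  ancestor <- make_ancestral_genome(cfg)
  genomes <- lapply(seq_along(branches), function(i) {
    evolve(ancestor, cfg, branches[[i]],
           branch_length = branch_lengths[i] %||% NULL)
  })
  names(genomes) <- branches
  structure(
    list(
      ancestor = ancestor, genomes = genomes,
      alignment = emit_alignments(genomes[[1]], genomes[[2]]),
      config = cfg
    ),
    class = "sim_pair"
  )
}

#' Ground-truth JSON for a simulated pair
#'
#' Records the event logs of both branches, the planted ancestral operons
#' and the closed-form breakpoint bounds implied by the event counts (each
#' event creates at most two breakpoint junctions).
#'
#' @param pair A `sim_pair`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(pair, path) {
  planted <- pair$ancestor$planted_operons
  n_events <- vapply(pair$genomes,
                     function(g) sum(!g$event_log$flank), numeric(1))
  truth <- list(
    seed = pair$config$seed,
    event_log = lapply(pair$genomes, function(g) as_tibble(g$event_log)),
    planted_operons = tibble(
      chrom = planted$chrom, strand = planted$strand,
      start = planted$start, end = planted$end, n_genes = planted$n_genes,
      gene_ids = vapply(planted$gene_ids, paste, character(1),
                        collapse = ",")
    ),
    expected_breakpoints = list(
      lower = 0, upper = 2 * sum(n_events)
    )
  )
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Plant well-separated inversions on one chromosome
#'
#' Partitions a region into `k` equal slots and inverts the central half of
#' each slot (cut points snapped to intergenic space), guaranteeing that
#' inversions are mutually distant and distant from the region edges.  With
#' flank loss at 0, segmentation of the descendant against the ancestor
#' reports exactly `2k` breakpoint regions (all zero-width) and `2k` strand
#' transitions.
#'
#' @param ancestor A `sim_genome`.
#' @param k Number of inversions.
#' @param chrom Chromosome to invert on (default: the first).
#' @param region Optional `(start, end)` region; default whole chromosome.
#' @return The descendant `sim_genome` with the inversions applied and
#'   logged.
#' @export
plant_separated_inversions <- function(ancestor, k,
                                       chrom = names(ancestor$segs)[[1]],
                                       region = NULL) {
  state <- ancestor
  state$branch_id <- "planted"
  state$event_log <- empty_event_log()
  len <- chrom_length_of(state, chrom)
  region <- region %||% c(0, len)
  sw <- (region[[2]] - region[[1]]) / k
  gene_iv <- current_gene_intervals(state, chrom)
  for (i in seq_len(k)) {
    s0 <- region[[1]] + (i - 1) * sw + sw / 4
    e0 <- region[[1]] + (i - 1) * sw + 3 * sw / 4
    s <- snap_intergenic(round(s0), gene_iv, region)
    e <- snap_intergenic(round(e0), gene_iv, region)
    if (is.null(s) || is.null(e) || e <= s) {
      stop_config("could not place separated inversions: slots too narrow")
    }
    ev <- tibble(
      branch = "planted", event_id = i, type = "inversion",
      chrom = chrom, start = s, end = e,
      dest_chrom = NA_character_, dest_pos = NA_real_,
      scope = "intra_arm", resamples = 0L, flank = FALSE
    )
    state <- apply_event(state, ev)
  }
  state
}

#' Quick random one-to-one alignment sets
#'
#' Generates a random valid alignment set directly (without evolving a
#' genome): target chromosomes are tiled with blocks and gaps, and the
#' blocks are permuted onto query chromosomes with random strands.  Useful
#' for property tests over many replicates.
#'
#' @param n_blocks Number of blocks.
#' @param n_target_chroms,n_query_chroms Chromosome counts.
#' @param chrom_length Length of every chromosome (bases).
#' @param aligned_fraction Fraction of each genome covered by blocks.
#' @param seed Optional integer seed (deterministic output when given).
#' @return An `alignment_set`.
#' @export
simulate_alignment_set <- function(n_blocks = 20, n_target_chroms = 2,
                                   n_query_chroms = 2, chrom_length = 1e5,
                                   aligned_fraction = 0.6, seed = NULL) {
  run <- function() {
    t_chrom <- sort(sample(paste0("t", seq_len(n_target_chroms)), n_blocks,
                           replace = TRUE))
    t_pos <- tile_chromosomes(t_chrom, chrom_length, aligned_fraction)
    perm <- sample(n_blocks)
    q_chrom_lab <- sort(sample(paste0("q", seq_len(n_query_chroms)),
                               n_blocks, replace = TRUE))
    # query widths are tiled independently: reusing the target widths can
    # overflow a query chromosome when the permutation concentrates blocks
    q_pos <- tile_chromosomes(q_chrom_lab, chrom_length, aligned_fraction)
    blocks <- tibble(
      t_chrom = t_chrom[perm], t_start = t_pos$start[perm],
      t_end = t_pos$end[perm],
      q_chrom = q_chrom_lab, q_start = q_pos$start, q_end = q_pos$end,
      strand = sample(c("+", "-"), n_blocks, replace = TRUE)
    )
    t_layout <- layout_from_lengths(setNames(
      rep(chrom_length, n_target_chroms),
      paste0("t", seq_len(n_target_chroms))
    ))
    q_layout <- layout_from_lengths(setNames(
      rep(chrom_length, n_query_chroms),
      paste0("q", seq_len(n_query_chroms))
    ))
    alignment_set(blocks, t_layout, q_layout)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# Non-overlapping (start, end) pairs per chromosome: sampled block widths
# interleaved with random gaps, scaled to the chromosome.
tile_chromosomes <- function(chrom, len, aligned_fraction) {
  start <- numeric(length(chrom))
  end <- numeric(length(chrom))
  for (c in unique(chrom)) {
    sel <- which(chrom == c)
    m <- length(sel)
    v <- stats::rexp(m) + 0.1
    w <- pmax(round(v / sum(v) * aligned_fraction * len), 1)
    gtot <- len - sum(w)
    g <- stats::rexp(m + 1) + 0.1
    g <- floor(g / sum(g) * gtot)
    pos <- cumsum(g[seq_len(m)] + c(0, w[-m]))
    start[sel] <- pos
    end[sel] <- pos + w
  }
  tibble(start = start, end = end)
}
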
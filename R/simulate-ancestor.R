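#' Simulation configuration
#'
#' Defines the study conditions emulated by the simulator: a compact genome
#' with three arm-structured chromosomes (two autosomes with short and long
#' arms, one sex chromosome with a pseudoautosomal region and an X-specific
#' region), dense head-to-tail operons with short intergenic gaps, sparse
#' repeats, and rearrangement events that are overwhelmingly
#' intra-chromosomal (94%) and, within a chromosome, intra-arm (99%).
#'
#' The default genome is a desk-scale model (~6.6 Mb, 1500 genes) preserving
#' the densities of the emulated genomes (a gene every ~4 kb, about half of
#' all genes in operons of mean size ~3).
#'
#' @param seed Integer seed; all simulator output is deterministic given the
#'   config.
#' @param layout A `genome_layout` with arm annotation.
#' @param n_genes Total gene count, distributed across chromosomes
#'   proportionally to length.
#' @param operon_gene_fraction Fraction of genes placed in operon-compatible
#'   runs (same strand, intergenic gaps <= 500 bases).
#' @param operon_size_prob Geometric continuation probability for operon
#'   sizes (sizes 2-9).
#' @param gene_length_meanlog,gene_length_sdlog Log-normal gene length
#'   parameters (bases).
#' @param exon_rate Poisson rate for extra exons per gene (exon count =
#'   1 + Poisson).
#' @param within_operon_gap,between_run_gap Integer ranges (min, max) for
#'   intergenic gaps inside operon runs (must stay <= 500) and between runs
#'   (must exceed 500 so planted operons are exactly recoverable).
#' @param repeat_fraction Target fraction of the genome covered by repeat
#'   intervals (placed in intergenic space).
#' @param dnds_meanlog,dnds_sdlog Log-normal parameters of per-gene dN/dS.
#' @param dnds_short_arm_shift Additive dN/dS shift applied to genes on
#'   short arms at annotation-emission time (plantable effect; default 0).
#' @param n_events Rearrangement events per branch in count mode.
#' @param event_rate Events per million years in rate mode (used when
#'   `n_events` is `NULL`; each branch receives Poisson(rate x branch
#'   length) events).
#' @param event_mix Probabilities of event types `inversion`,
#'   `translocation`, `deletion`, `duplication`.
#' @param p_intra_chrom Probability that an event stays within one
#'   chromosome.
#' @param p_intra_arm Probability, conditional on intra-chromosomal, that an
#'   event stays within one arm.
#' @param event_len_frac Range (min, max) of event length as a fraction of
#'   the containing region's length.
#' @param flank_loss Bases deleted at each event junction (0-500) to emulate
#'   unalignable breakpoint material.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       layout = default_sim_layout(),
                       n_genes = 1500L,
                       operon_gene_fraction = 0.5,
                       operon_size_prob = 0.45,
                       gene_length_meanlog = log(1100),
                       gene_length_sdlog = 0.45,
                       exon_rate = 2,
                       within_operon_gap = c(25L, 500L),
                       between_run_gap = c(600L, 2200L),
                       repeat_fraction = 0.10,
                       dnds_meanlog = log(0.10),
                       dnds_sdlog = 0.4,
                       dnds_short_arm_shift = 0,
                       n_events = 40L,
                       event_rate = NULL,
                       event_mix = c(inversion = 0.70, translocation = 0.25,
                                     deletion = 0.025, duplication = 0.025),
                       p_intra_chrom = 0.94,
                       p_intra_arm = 0.99,
                       event_len_frac = c(0.01, 0.10),
                       flank_loss = 0L) {
  if (max(within_operon_gap) > 500) {
    stop_config("within_operon_gap must stay <= 500 bases")
  }
  if (min(between_run_gap) <= 500) {
    stop_config("between_run_gap must exceed 500 bases")
  }
  probs <- c(operon_gene_fraction, repeat_fraction, p_intra_chrom,
             p_intra_arm, event_mix)
  if (any(probs < 0 | probs > 1)) {
    stop_config("probabilities and fractions must lie in [0, 1]")
  }
  if (abs(sum(event_mix) - 1) > 1e-9) {
    stop_config("event_mix must sum to 1")
  }
  if (flank_loss < 0 || flank_loss > 500) {
    stop_config("flank_loss must lie in [0, 500] bases")
  }
  structure(
    list(
      seed = as.integer(seed), layout = as_genome_layout(layout),
      n_genes = as.integer(n_genes),
      operon_gene_fraction = operon_gene_fraction,
      operon_size_prob = operon_size_prob,
      gene_length_meanlog = gene_length_meanlog,
      gene_length_sdlog = gene_length_sdlog,
      exon_rate = exon_rate,
      within_operon_gap = as.integer(within_operon_gap),
      between_run_gap = as.integer(between_run_gap),
      repeat_fraction = repeat_fraction,
      dnds_meanlog = dnds_meanlog, dnds_sdlog = dnds_sdlog,
      dnds_short_arm_shift = dnds_short_arm_shift,
      n_events = if (is.null(n_events)) NULL else as.integer(n_events),
      event_rate = event_rate,
      event_mix = event_mix,
      p_intra_chrom = p_intra_chrom, p_intra_arm = p_intra_arm,
      event_len_frac = event_len_frac,
      flank_loss = as.integer(flank_loss)
    ),
    class = "sim_config"
  )
}

#' Default simulated genome layout
#'
#' Three chromosomes emulating a compact arm-structured karyotype: two
#' autosomes with a short and a long arm separated by the centromere, and a
#' sex chromosome with a pseudoautosomal region and an X-specific region.
#'
#' @return A `genome_layout`.
#' @export
default_sim_layout <- function() {
  genome_layout(
    chrom = c("chr1", "chr1", "chr2", "chr2", "chrX", "chrX"),
    length = c(2.4e6, 2.4e6, 2.0e6, 2.0e6, 2.2e6, 2.2e6),
    centromere = c(6e5, 6e5, 5e5, 5e5, 1.4e6, 1.4e6),
    arm_name = c("1S", "1L", "2S", "2L", "PAR", "XSR"),
    arm_start = c(0, 6e5, 0, 5e5, 0, 1.4e6),
    arm_end = c(6e5, 2.4e6, 5e5, 2.0e6, 1.4e6, 2.2e6),
    arm_class = c("short", "long", "short", "long", "PAR", "XSR")
  )
}

#' Generate an annotated ancestral genome
#'
#' Places genes chromosome by chromosome in runs: operonic runs (two or more
#' same-strand genes, consecutive gaps drawn within the operon gap range) and
#' singletons, separated by gaps wide enough that operon calling recovers
#' the planted operons exactly.  Repeats are placed in intergenic space up
#' to the configured genome fraction; per-gene dN/dS values are drawn
#' log-normally.  Output is deterministic given the config seed.
#'
#' @param cfg A `sim_config`.
#' @return A `sim_genome` (the ancestor): carries the layout, gene, exon,
#'   repeat and dN/dS tables, the planted operon truth, identity segments
#'   and an empty event log.
#' @export
make_ancestral_genome <- function(cfg) {
  withr::with_seed(cfg$seed, make_ancestor_impl(cfg))
}

make_ancestor_impl <- function(cfg) {
  layout <- cfg$layout
  lens <- chrom_lengths(layout)
  quota <- round(cfg$n_genes * lens / sum(lens))

  genes <- list(); exons <- list(); planted <- list()
  offset <- 0L
  for (chrom in names(lens)) {
    placed <- place_genes_on_chrom(chrom, lens[[chrom]], quota[[chrom]], cfg)
    placed$exons$gene_idx <- placed$exons$gene_idx + offset
    placed$operons$gene_idx <- lapply(placed$operons$gene_idx,
                                      function(i) i + offset)
    genes[[chrom]] <- placed$genes
    exons[[chrom]] <- placed$exons
    planted[[chrom]] <- placed$operons
    offset <- offset + nrow(placed$genes)
  }
  genes <- bind_rows(genes)
  exons <- bind_rows(exons)
  planted <- bind_rows(planted)
  if (nrow(genes) > 0) {
    genes$gene_id <- sprintf("g%05d", seq_len(nrow(genes)))
    exons$gene_id <- genes$gene_id[exons$gene_idx]
    exons$gene_idx <- NULL
    planted$gene_ids <- lapply(planted$gene_idx, function(i) genes$gene_id[i])
    # operon spans must agree with the (rounded) gene coordinates exactly
    planted$start <- vapply(planted$gene_idx,
                            function(i) min(genes$start[i]), numeric(1))
    planted$end <- vapply(planted$gene_idx,
                          function(i) max(genes$end[i]), numeric(1))
    planted$gene_idx <- NULL
  } else {
    genes$gene_id <- character(0)
    exons <- tibble(gene_id = character(), chrom = character(),
                    start = numeric(), end = numeric())
    planted <- tibble(chrom = character(), strand = character(),
                      start = numeric(), end = numeric(),
                      n_genes = integer(), gene_ids = list())
  }

  repeats <- place_repeats(genes, lens, cfg)
  dnds <- tibble(
    gene_id = genes$gene_id,
    dnds = stats::rlnorm(nrow(genes), cfg$dnds_meanlog, cfg$dnds_sdlog)
  )

  segs <- lapply(names(lens), function(chrom) {
    tibble(anc_chrom = chrom, anc_start = 0, anc_end = lens[[chrom]],
           strand = "+", copy_id = 0L)
  })
  names(segs) <- names(lens)

  arms <- layout_arms(layout)
  arms <- if (is.null(arms)) {
    tibble(chrom = names(lens), arm_name = names(lens),
           arm_class = "unassigned", start = 0, end = unname(lens))
  } else {
    tibble(chrom = arms$chrom, arm_name = arms$arm_name,
           arm_class = arms$arm_class, start = arms$arm_start,
           end = arms$arm_end)
  }
  centromeres <- distinct(as_tibble(layout), .data$chrom, .data$centromere)

  structure(
    list(
      branch_id = "ancestor",
      segs = segs, arms = arms, centromeres = centromeres,
      genes = genes[, c("gene_id", "chrom", "start", "end", "strand")],
      exons = exons[, c("gene_id", "chrom", "start", "end")],
      planted_operons = planted,
      repeats = repeats, dnds = dnds,
      next_copy = 1L,
      event_log = empty_event_log(),
      config = cfg
    ),
    class = "sim_genome"
  )
}

# Gene runs for one chromosome: operonic runs (size >= 2) and singletons in
# shuffled order, with gap classes guaranteeing exact operon recovery.
place_genes_on_chrom <- function(chrom, len, n, cfg) {
  empty <- list(
    genes = tibble(chrom = character(), start = numeric(), end = numeric(),
                   strand = character()),
    exons = tibble(gene_idx = integer(), chrom = character(),
                   start = numeric(), end = numeric()),
    operons = tibble(chrom = character(), strand = character(),
                     start = numeric(), end = numeric(), n_genes = integer(),
                     gene_idx = list())
  )
  if (n == 0) return(empty)
  n_operonic <- round(cfg$operon_gene_fraction * n)
  run_sizes <- integer(0)
  remaining <- n_operonic
  while (remaining >= 2) {
    s <- 2L + stats::rgeom(1, cfg$operon_size_prob)
    s <- min(s, 9L, remaining)
    if (s < 2L) s <- 2L
    run_sizes <- c(run_sizes, s)
    remaining <- remaining - s
  }
  n_single <- n - sum(run_sizes)
  runs <- sample(c(run_sizes, rep(1L, n_single)))

  g_start <- numeric(0); g_end <- numeric(0); g_strand <- character(0)
  op_rows <- list()
  pos <- runif(1, cfg$between_run_gap[[1]], cfg$between_run_gap[[2]])
  for (r in runs) {
    strand <- sample(c("+", "-"), 1)
    first_idx <- length(g_start) + 1L
    for (k in seq_len(r)) {
      glen <- pmin(pmax(round(stats::rlnorm(1, cfg$gene_length_meanlog,
                                            cfg$gene_length_sdlog)), 200),
                   20000)
      g_start <- c(g_start, pos)
      g_end <- c(g_end, pos + glen)
      g_strand <- c(g_strand, strand)
      pos <- pos + glen
      if (k < r) {
        pos <- pos + sample(cfg$within_operon_gap[[1]]:
                              cfg$within_operon_gap[[2]], 1)
      }
    }
    if (r >= 2) {
      op_rows[[length(op_rows) + 1L]] <- tibble(
        chrom = chrom, strand = strand,
        start = g_start[[first_idx]], end = g_end[[length(g_end)]],
        n_genes = r, gene_idx = list(first_idx:length(g_end))
      )
    }
    pos <- pos + sample(cfg$between_run_gap[[1]]:cfg$between_run_gap[[2]], 1)
  }
  if (max(g_end) > len - 500) {
    stop_config(paste0(
      "infeasible packing on ", chrom, ": ", n,
      " genes exceed the chromosome length"
    ))
  }
  genes <- tibble(chrom = chrom, start = round(g_start), end = round(g_end),
                  strand = g_strand)
  exons <- make_exons(genes, cfg)
  ops <- if (length(op_rows)) bind_rows(op_rows) else empty$operons
  # local indices are offset by the caller across chromosomes
  list(genes = genes, exons = exons, operons = ops)
}

make_exons <- function(genes, cfg) {
  rows <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    w <- genes$end[[i]] - genes$start[[i]]
    k <- 1L + stats::rpois(1, cfg$exon_rate)
    while (k > 1L && w < k * 60 + (k - 1L) * 40) k <- k - 1L
    if (k == 1L) {
      rows[[i]] <- tibble(gene_idx = i, chrom = genes$chrom[[i]],
                          start = genes$start[[i]], end = genes$end[[i]])
      next
    }
    # random internal boundaries: alternate exon (>=50) / intron (>=40)
    slack <- w - k * 50 - (k - 1L) * 40
    parts <- as.vector(stats::rmultinom(1, slack, rep(1, 2L * k - 1L)))
    widths <- parts + rep(c(50, 40), length.out = 2L * k - 1L)
    bounds <- genes$start[[i]] + cumsum(c(0, widths))
    ex <- seq(1, 2L * k - 1L, by = 2)
    rows[[i]] <- tibble(gene_idx = i, chrom = genes$chrom[[i]],
                        start = bounds[ex], end = bounds[ex + 1L])
  }
  bind_rows(rows)
}

place_repeats <- function(genes, lens, cfg) {
  out <- tibble(chrom = character(), start = numeric(), end = numeric())
  target <- cfg$repeat_fraction * sum(lens)
  if (target <= 0) return(out)
  gaps <- list()
  for (chrom in names(lens)) {
    g <- genes[genes$chrom == chrom, ]
    g <- g[order(g$start), ]
    bounds_s <- c(0, g$end)
    bounds_e <- c(g$start, lens[[chrom]])
    keep <- bounds_e - bounds_s >= 150
    gaps[[chrom]] <- tibble(chrom = chrom, start = bounds_s[keep],
                            end = bounds_e[keep])
  }
  gaps <- bind_rows(gaps)
  gaps <- gaps[sample(nrow(gaps)), ]
  placed <- 0
  rows <- list()
  for (i in seq_len(nrow(gaps))) {
    if (placed >= target) break
    gw <- gaps$end[[i]] - gaps$start[[i]]
    rl <- min(round(runif(1, 100, 1000)), floor(0.8 * gw),
              ceiling(target - placed))
    if (rl < 50) next
    s <- gaps$start[[i]] + floor((gw - rl) / 2)
    rows[[length(rows) + 1L]] <- tibble(chrom = gaps$chrom[[i]], start = s,
                                        end = s + rl)
    placed <- placed + rl
  }
  if (length(rows)) arrange(bind_rows(rows), .data$chrom, .data$start) else out
}
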
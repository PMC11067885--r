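small_cfg <- function(seed = 11L, n_genes = 60L, ...) {
  sim_config(seed = seed, n_genes = n_genes, ...)
}

test_that("the simulator is deterministic under its seed", {
  a1 <- make_ancestral_genome(small_cfg())
  a2 <- make_ancestral_genome(small_cfg())
  expect_identical(a1$genes, a2$genes)
  expect_identical(a1$exons, a2$exons)
  expect_identical(a1$repeats, a2$repeats)

  p1 <- simulate_genome_pair(small_cfg(n_genes = 40L))
  p2 <- simulate_genome_pair(small_cfg(n_genes = 40L))
  expect_identical(tibble::as_tibble(p1$alignment),
                   tibble::as_tibble(p2$alignment))
  expect_identical(p1$genomes$A$event_log, p2$genomes$A$event_log)
})

test_that("ancestral gene spans do not overlap and operons close the loop", {
  anc <- make_ancestral_genome(small_cfg())
  g <- anc$genes
  for (c in unique(g$chrom)) {
    x <- g[g$chrom == c, ]
    x <- x[order(x$start), ]
    expect_true(all(x$start[-1] >= x$end[-nrow(x)]))
  }
  called <- call_operons(anc$genes)
  planted <- anc$planted_operons[order(anc$planted_operons$chrom,
                                       anc$planted_operons$start), ]
  expect_equal(tibble::as_tibble(called)[, c("chrom", "strand", "start",
                                             "end", "n_genes")],
               planted[, c("chrom", "strand", "start", "end", "n_genes")],
               ignore_attr = TRUE)
  expect_equal(called$gene_ids, planted$gene_ids, ignore_attr = TRUE)
})

test_that("zero repeat fraction gives an empty repeat track", {
  anc <- make_ancestral_genome(small_cfg(repeat_fraction = 0))
  expect_equal(nrow(anc$repeats), 0L)
})

test_that("infeasible packing raises a configuration error", {
  expect_error(make_ancestral_genome(sim_config(n_genes = 100000L)),
               "infeasible", class = "scramblr_config_error")
})

test_that("zero events leaves the descendant identical to the ancestor", {
  anc <- make_ancestral_genome(small_cfg())
  desc <- evolve(anc, small_cfg(n_events = 0L), "A")
  expect_identical(desc$segs, anc$segs)
  expect_equal(nrow(desc$event_log), 0L)

  aln <- emit_alignments(anc, desc)
  b <- tibble::as_tibble(aln)
  expect_equal(nrow(b), length(anc$segs))
  expect_true(all(b$strand == "+"))
  expect_equal(weighted_scrambling_index(scrambling_index(aln)), 1)
  seg <- classify_segments(aln)
  cov <- class_coverage(seg)
  expect_equal(cov$n[cov$class == "breakpoint"], 0L)
})

test_that("a clean inversion flips and reverses its genes", {
  anc <- make_ancestral_genome(small_cfg())
  g0 <- anc$genes[anc$genes$chrom == "chr1", ]
  g0 <- g0[order(g0$start), ]
  # invert an intergenic-bounded window holding at least two genes
  k <- min(4, nrow(g0) - 1)
  s <- g0$start[[1]] - 10
  e <- g0$end[[k]] + 10
  ev <- tibble::tibble(
    branch = "m", event_id = 1L, type = "inversion", chrom = "chr1",
    start = s, end = e, dest_chrom = NA_character_, dest_pos = NA_real_,
    scope = "intra_arm", resamples = 0L, flank = FALSE
  )
  desc <- apply_event(anc, ev)
  g1 <- genome_genes(desc)
  expect_equal(nrow(g1), nrow(anc$genes))
  inside0 <- g0[g0$start >= s & g0$end <= e, ]
  g1c <- g1[g1$chrom == "chr1", ]
  g1c <- g1c[order(g1c$start), ]
  inside1 <- g1c[g1c$start >= s & g1c$end <= e, ]
  # order reversed, strands flipped, gene set identical
  expect_equal(inside1$ancestral_id, rev(inside0$gene_id))
  flip <- function(x) ifelse(x == "+", "-", "+")
  expect_equal(inside1$strand,
               flip(rev(inside0$strand)))

  # target-side alignment shows the +,-,+ sandwich on chr1
  aln <- emit_alignments(desc, anc)
  b <- tibble::as_tibble(aln)
  b <- b[b$t_chrom == "chr1", ]
  b <- b[order(b$t_start), ]
  expect_equal(b$strand, c("+", "-", "+"))
  seg <- classify_segments(aln)
  d <- tibble::as_tibble(seg)
  zw <- d[d$class == "breakpoint" & d$start == d$end, ]
  expect_equal(nrow(zw), 2L)
  expect_equal(sort(zw$start), c(s, e))
})

test_that("replaying the event log reproduces the descendant exactly", {
  anc <- make_ancestral_genome(small_cfg(n_genes = 80L))
  desc <- evolve(anc, small_cfg(n_genes = 80L, n_events = 15L), "B")
  replayed <- replay_events(anc, desc$event_log)
  expect_identical(replayed$segs, desc$segs)
  expect_identical(genome_genes(replayed), genome_genes(desc))
})

test_that("events larger than their region are resampled and reported", {
  anc <- make_ancestral_genome(small_cfg())
  cfg <- small_cfg(n_events = 5L, event_len_frac = c(0.5, 0.95),
                   p_intra_arm = 1)
  desc <- evolve(anc, cfg, "A")
  expect_equal(nrow(desc$event_log), 5L)
  expect_true(all(desc$event_log$resamples >= 0))
})

test_that("conservation: without deletions or duplications, everything aligns", {
  cfg <- small_cfg(
    n_events = 12L,
    event_mix = c(inversion = 0.7, translocation = 0.3, deletion = 0,
                  duplication = 0)
  )
  pair <- simulate_genome_pair(cfg)
  b <- tibble::as_tibble(pair$alignment)
  genome_len <- sum(chrom_lengths(target_layout(pair$alignment)))
  expect_equal(sum(b$t_end - b$t_start), genome_len)
  expect_equal(sum(b$q_end - b$q_start), genome_len)
})

test_that("deletions remove sequence and duplications create new copies", {
  anc <- make_ancestral_genome(small_cfg())
  len0 <- sum(chrom_lengths(state_layout(anc)))
  n0 <- nrow(genome_genes(anc))

  cfg_del <- small_cfg(n_events = 3L,
                       event_mix = c(inversion = 0, translocation = 0,
                                     deletion = 1, duplication = 0))
  del <- evolve(anc, cfg_del, "D")
  expect_lt(sum(chrom_lengths(state_layout(del))), len0)

  cfg_dup <- small_cfg(n_events = 3L,
                       event_mix = c(inversion = 0, translocation = 0,
                                     deletion = 0, duplication = 1))
  dup <- evolve(anc, cfg_dup, "P")
  expect_gt(sum(chrom_lengths(state_layout(dup))), len0)
  gd <- genome_genes(dup)
  copies <- gd[gd$copy_id > 0, ]
  if (nrow(copies) > 0) {
    map <- sim_ortholog_map(list(G = dup))
    m0 <- map[map$gene_id %in% copies$gene_id[[1]], ]
    anc_id <- copies$ancestral_id[[1]]
    orig <- map[map$gene_id == anc_id, ]
    # same OG as the original copy, distinct HOG
    expect_equal(m0$og_id, orig$og_id)
    expect_false(m0$hog_id == orig$hog_id)
  }
})

test_that("annotations round-trip through the emitted files", {
  anc <- make_ancestral_genome(small_cfg(n_genes = 50L))
  desc <- evolve(anc, small_cfg(n_genes = 50L, n_events = 5L), "A")
  dir <- withr::local_tempdir()
  paths <- emit_annotations(desc, dir)
  ann <- sim_annotation(desc)

  back <- read_gff3(paths[["gff3"]])
  expect_equal(back$genes[order(back$genes$gene_id), ],
               ann$genes[order(ann$genes$gene_id), ],
               ignore_attr = TRUE)
  expect_equal(
    dplyr::arrange(back$exons, .data$gene_id, .data$start),
    dplyr::arrange(ann$exons[, c("gene_id", "chrom", "start", "end")],
                   .data$gene_id, .data$start),
    ignore_attr = TRUE
  )
  expect_equal(tibble::as_tibble(read_layout(paths[["layout"]])),
               tibble::as_tibble(ann$layout))
  dnds <- read_dnds_table(paths[["dnds"]])
  expect_equal(dnds, ann$dnds)
  map <- read_ortholog_table(paths[["orthologs"]])
  expect_equal(nrow(map), nrow(ann$genes))
})

test_that("the emitted alignment set reconstructs gene orthology positions", {
  pair <- simulate_genome_pair(small_cfg(n_genes = 40L, n_events = 6L))
  aln <- pair$alignment
  expect_s3_class(aln, "alignment_set")
  # validation already enforces one-to-one; also check layouts match states
  expect_equal(chrom_lengths(target_layout(aln)),
               chrom_lengths(state_layout(pair$genomes$A)))
  expect_equal(chrom_lengths(query_layout(aln)),
               chrom_lengths(state_layout(pair$genomes$B)))
})

test_that("branch seeds are deterministic, distinct and below 2^31", {
  s1 <- scramblr:::branch_seed(1L, "A")
  s2 <- scramblr:::branch_seed(1L, "B")
  expect_identical(s1, scramblr:::branch_seed(1L, "A"))
  expect_false(s1 == s2)
  for (seed in c(1L, 1000L, 2147483L)) {
    for (b in c("A", "B", "planted", "rep19")) {
      v <- scramblr:::branch_seed(seed, b)
      expect_true(v >= 0 && v < 2^31)
    }
  }
})

test_that("rate mode draws Poisson event counts per branch length", {
  anc <- make_ancestral_genome(small_cfg())
  cfg <- small_cfg(n_events = NULL, event_rate = 2)
  desc <- evolve(anc, cfg, "A", branch_length = 3)
  expect_true(nrow(desc$event_log) >= 0)
  expect_error(evolve(anc, cfg, "A"), class = "scramblr_config_error")
})

test_that("the truth JSON is written and parses", {
  pair <- simulate_genome_pair(small_cfg(n_genes = 40L, n_events = 4L))
  path <- withr::local_tempfile(fileext = ".json")
  write_truth(pair, path)
  truth <- jsonlite::read_json(path)
  expect_equal(truth$seed, 11)
  expect_equal(length(truth$event_log$A), 4L)
  expect_equal(truth$expected_breakpoints$upper, 2 * 8)
})
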
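profile_fixture <- function() {
  # two isolated blocks, surrounded by breakpoints
  aln <- toy_aln(
    t_chrom = "t1", t_start = c(2000, 6000), t_end = c(3000, 7000),
    q_chrom = "q1", q_start = c(5000, 0), q_end = c(6000, 1000),
    strand = c("+", "-"),
    t_len = c(t1 = 10000), q_len = c(q1 = 10000)
  )
  classify_segments(aln)
}

test_that("a track covering the whole genome gives fraction 1 everywhere", {
  seg <- profile_fixture()
  track <- tibble::tibble(chrom = "t1", start = 0, end = 10000)
  prof <- boundary_enrichment(seg, list(all = track), window = 100,
                              step = 50)
  d <- tibble::as_tibble(prof)
  occupied <- d[d$n_boundaries > 0, ]
  expect_true(all(occupied$fraction == 1, na.rm = TRUE))
})

test_that("no features gives fraction 0; empty classes give NA", {
  seg <- profile_fixture()
  track <- tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric())
  prof <- boundary_enrichment(seg, list(none = track), window = 100,
                              step = 50)
  d <- tibble::as_tibble(prof)
  occupied <- d[d$n_boundaries > 0, ]
  expect_true(all(occupied$fraction == 0, na.rm = TRUE))
  # no collinear alignments in the fixture: NA profile
  coll <- d[d$class == "collinear_alignment", ]
  expect_true(all(is.na(coll$fraction)))
  expect_true(all(coll$n_boundaries == 0))
})

test_that("features planted at isolated-alignment starts peak at offset 0", {
  seg <- profile_fixture()
  starts <- tibble::as_tibble(seg)
  starts <- starts[starts$class == "isolated_alignment", ]
  track <- tibble::tibble(chrom = starts$chrom, start = starts$start,
                          end = starts$start + 10)
  prof <- boundary_enrichment(seg, list(planted = track), window = 1000,
                              step = 10)
  d <- tibble::as_tibble(prof)
  iso <- d[d$class == "isolated_alignment" & d$side == "start", ]
  expect_equal(iso$fraction[iso$offset == 0], 1)
  expect_lt(iso$fraction[iso$offset == -1000], 1)
})

test_that("offsets outside the chromosome are excluded from denominators", {
  # one block starting at 0: the chromosome-start breakpoint is at 0 width 0
  aln <- toy_aln("t1", 500, 700, "q1", 0, 200, "+",
                 c(t1 = 1000), c(q1 = 1000))
  seg <- classify_segments(aln)
  track <- tibble::tibble(chrom = "t1", start = 0, end = 1000)
  prof <- boundary_enrichment(seg, list(all = track), window = 600,
                              step = 600)
  d <- tibble::as_tibble(prof)
  bp <- d[d$class == "breakpoint" & d$side == "start", ]
  # offset -600: the [0,500) breakpoint's start lies at 0, so -600 is off
  # the chromosome for it, but on-chromosome for the [700,1000) breakpoint
  expect_equal(bp$fraction[bp$offset == -600], 1)
  expect_equal(bp$n_boundaries[[1]], 2L)
})

test_that("binned_profile averages per bin with the floor rule", {
  layout <- layout_from_lengths(c(c1 = 1000))
  q <- tibble::tibble(chrom = "c1", pos = c(0, 10, 510, 999),
                      value = c(1, 3, 10, 20))
  prof <- binned_profile(q, layout, bins = 2)
  d <- tibble::as_tibble(prof)
  expect_equal(d$mean_value, c(2, 15))
  expect_equal(d$n_elements, c(2L, 2L))
  # element exactly at the end maps to the last bin (floor rule capped)
  expect_equal(d$bin, c(0, 1))
})

test_that("empty bins are reported as missing", {
  layout <- layout_from_lengths(c(c1 = 1000))
  q <- tibble::tibble(chrom = "c1", pos = c(100, 200), value = c(1, 2))
  d <- tibble::as_tibble(binned_profile(q, layout, bins = 4))
  expect_true(all(is.na(d$mean_value[d$bin >= 1])))
  expect_equal(d$n_elements[d$bin >= 1], rep(0L, 3))
})

test_that("multi-genome profiles average bin means, not pooled elements", {
  layout <- layout_from_lengths(c(c1 = 100))
  q <- tibble::tibble(
    chrom = "c1", pos = c(10, 10, 10, 10),
    value = c(0, 0, 0, 4),
    genome_id = c("A", "A", "A", "B")
  )
  d <- tibble::as_tibble(binned_profile(q, layout, bins = 1))
  # pooled mean would be 1; the mean of per-genome means is (0 + 4)/2 = 2
  expect_equal(d$mean_value, 2)
})

test_that("binned_profile is equivariant under chromosome mirror", {
  layout <- layout_from_lengths(c(c1 = 1000))
  q <- tibble::tibble(chrom = "c1", pos = c(50, 250, 450, 650, 850),
                      value = c(1, 2, 3, 4, 5))
  fwd <- tibble::as_tibble(binned_profile(q, layout, bins = 5))
  mirrored <- q
  mirrored$pos <- 1000 - q$pos
  rev_prof <- tibble::as_tibble(binned_profile(mirrored, layout, bins = 5))
  expect_equal(rev_prof$mean_value, rev(fwd$mean_value))
})

test_that("elements beyond the chromosome end are a validation error", {
  layout <- layout_from_lengths(c(c1 = 1000))
  q <- tibble::tibble(chrom = "c1", pos = 1001, value = 1)
  expect_error(binned_profile(q, layout),
               class = "scramblr_validation_error")
  q2 <- tibble::tibble(chrom = "nope", pos = 10, value = 1)
  expect_error(binned_profile(q2, layout),
               class = "scramblr_validation_error")
})

test_that("disjoint arm-class supports give the minimal exact rank-sum p", {
  values <- tibble::tibble(
    arm_class = rep(c("short", "long"), each = 10),
    value = c(1:10, 101:110)
  )
  d <- arm_class_compare(values)
  expect_equal(nrow(d), 1L)
  expect_equal(d$p_value, 2 / choose(20, 10))
  expect_equal(d$median_a, 5.5)
  expect_equal(d$median_b, 105.5)
})

test_that("sparse arm classes are skipped with a notice", {
  values <- tibble::tibble(
    arm_class = c(rep("short", 10), rep("long", 10), "XSR"),
    value = c(1:10, 11:20, 5)
  )
  expect_condition(d <- arm_class_compare(values),
                   class = "scramblr_notice")
  expect_equal(nrow(d), 3L)
  expect_true(all(d$skipped[d$class_b == "XSR" | d$class_a == "XSR"]))
  expect_false(d$skipped[d$class_a == "short" & d$class_b == "long"])

  expect_error(
    arm_class_compare(tibble::tibble(arm_class = "short", value = 1)),
    class = "scramblr_domain_error"
  )
})

test_that("gene_breakpoint_rate_by_arm builds the 3x2 table with df 2", {
  chrom_len <- c(S = 100000, L = 100000, X = 100000)
  layout <- one_arm_layout(chrom_len, c("short", "long", "XSR"))
  genes <- tibble::tibble(
    gene_id = paste0("g", 1:30),
    chrom = rep(names(chrom_len), each = 10),
    start = rep(seq(0, 90000, by = 10000), 3),
    end = rep(seq(0, 90000, by = 10000), 3) + 500
  )
  # cut half the genes of S, none of L, two of X
  cuts <- list(
    S = genes$start[1:5] + 250,
    L = numeric(0),
    X = genes$start[21:22] + 250
  )
  aln <- aln_with_breakpoints_at(cuts, chrom_len)
  seg <- classify_segments(aln)
  res <- gene_breakpoint_rate_by_arm(genes, seg, layout)
  tab <- res$table[order(res$table$arm_class), ]
  expect_equal(tab$arm_class, c("XSR", "long", "short"))
  expect_equal(tab$n_overlapping, c(2L, 0L, 5L))
  expect_equal(tab$rate, c(0.2, 0, 0.5))
  expect_equal(unname(res$test$parameter), 2)

  expect_error(
    gene_breakpoint_rate_by_arm(genes, seg, layout_from_lengths(chrom_len)),
    class = "scramblr_config_error"
  )
})

test_that("degenerate arm tables skip the chi-squared test with a notice", {
  chrom_len <- c(S = 10000, L = 10000)
  layout <- one_arm_layout(chrom_len, c("short", "long"))
  genes <- tibble::tibble(
    gene_id = c("g1", "g2"), chrom = c("S", "L"),
    start = c(100, 100), end = c(600, 600)
  )
  # no breakpoints anywhere -> the n_overlapping column is all zero
  aln <- aln_with_breakpoints_at(list(S = numeric(0), L = numeric(0)),
                                 chrom_len)
  seg <- classify_segments(aln)
  expect_condition(res <- gene_breakpoint_rate_by_arm(genes, seg, layout),
                   class = "scramblr_notice")
  expect_null(res$test)
})
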
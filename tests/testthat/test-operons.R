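genes_tbl <- function(start, end, strand, chrom = "c1") {
  tibble::tibble(
    gene_id = paste0("g", seq_along(start)), chrom = chrom,
    start = start, end = end, strand = strand
  )
}

test_that("call_operons applies the 500-base threshold exactly", {
  # gaps: 500 (joins), 501 (breaks)
  g <- genes_tbl(
    start = c(0, 1500, 3001), end = c(1000, 2500, 4000),
    strand = "+"
  )
  ops <- call_operons(g)
  expect_equal(nrow(ops), 1L)
  expect_equal(ops$n_genes, 2L)
  expect_equal(ops$gene_ids[[1]], c("g1", "g2"))
  expect_equal(ops$start, 0)
  expect_equal(ops$end, 2500)
})

test_that("overlapping same-strand genes merge (negative gap is zero)", {
  g <- genes_tbl(start = c(0, 900), end = c(1000, 1900), strand = "+")
  ops <- call_operons(g)
  expect_equal(nrow(ops), 1L)
  expect_equal(ops$n_genes, 2L)
})

test_that("strand changes and chromosome changes break runs", {
  g <- genes_tbl(start = c(0, 1100, 2200), end = c(1000, 2100, 3200),
                 strand = c("+", "-", "+"))
  expect_equal(nrow(call_operons(g)), 0L)

  g2 <- genes_tbl(start = c(0, 1100), end = c(1000, 2100), strand = "+",
                  chrom = c("c1", "c2"))
  expect_equal(nrow(call_operons(g2)), 0L)
})

test_that("singletons are not operons and empty input yields empty set", {
  g <- genes_tbl(start = 0, end = 1000, strand = "+")
  expect_equal(nrow(call_operons(g)), 0L)
  expect_equal(nrow(call_operons(g[0, ])), 0L)
})

toy_map <- function() {
  as_ortholog_map(tibble::tibble(
    genome_id = rep(c("G1", "G2"), each = 4),
    gene_id = c("a", "b", "c", "d", "w", "x", "y", "z"),
    hog_id = c("hA", "hB", "hC", "hD", "hA", "hB", "hC", "hX"),
    og_id = c("oA", "oB", "oC", "oD", "oA", "oB", "oC", "oX")
  ))
}

test_that("exact equivalence is multiset equality of orthogroups", {
  map <- toy_map()
  expect_true(operon_equivalent(c("a", "b", "c"), c("w", "x", "y"),
                                map, "G1", "G2"))
  # order does not matter
  expect_true(operon_equivalent(c("c", "a", "b"), c("w", "x", "y"),
                                map, "G1", "G2"))
  expect_false(operon_equivalent(c("a", "b", "c"), c("w", "x", "z"),
                                 map, "G1", "G2",
                                 operon_equivalence = "exact"))
  # different sizes never match
  expect_false(operon_equivalent(c("a", "b"), c("w", "x", "y"),
                                 map, "G1", "G2",
                                 operon_equivalence = "inexact"))
})

test_that("inexact equivalence accepts exactly one substitution at size 3+", {
  map <- toy_map()
  abc <- c("a", "b", "c")   # groups hA hB hC
  # ABC matches ABC, XBC, AXC, ABX (the four accepted patterns)
  expect_true(operon_equivalent(abc, c("w", "x", "y"), map, "G1", "G2",
                                operon_equivalence = "inexact"))
  expect_true(operon_equivalent(abc, c("z", "x", "y"), map, "G1", "G2",
                                operon_equivalence = "inexact"))
  expect_true(operon_equivalent(abc, c("w", "z", "y"), map, "G1", "G2",
                                operon_equivalence = "inexact"))
  expect_true(operon_equivalent(abc, c("w", "x", "z"), map, "G1", "G2",
                                operon_equivalence = "inexact"))
  # size-2 operons: identical still matches, one substitution does not
  expect_true(operon_equivalent(c("a", "b"), c("w", "x"), map, "G1", "G2",
                                operon_equivalence = "inexact"))
  expect_false(operon_equivalent(c("a", "b"), c("w", "z"), map, "G1", "G2",
                                 operon_equivalence = "inexact"))
})

test_that("genes without orthogroup assignment never match", {
  map <- as_ortholog_map(tibble::tibble(
    genome_id = c("G1", "G1", "G2", "G2"),
    gene_id = c("a", "b", "w", "x"),
    hog_id = c("hA", NA, "hA", NA),
    og_id = c("oA", NA, "oA", NA)
  ))
  # b and x are both unassigned: sentinels are unique, so no match
  expect_false(operon_equivalent(c("a", "b"), c("w", "x"), map, "G1", "G2"))
})

test_that("shared_operons counts partition the reference operon set", {
  map <- toy_map()
  ops1 <- call_operons(genes_tbl(
    start = c(0, 1100, 5000, 6100), end = c(1000, 2100, 6000, 7100),
    strand = "+"
  ))
  # relabel members to ortholog-mapped gene ids
  ops1$gene_ids <- list(c("a", "b"), c("c", "d"))
  ops2 <- ops1
  ops2$gene_ids <- list(c("w", "x"), c("y", "z"))
  shared <- shared_operons(list(G1 = ops1, G2 = ops2), map,
                           reference = "G1")
  expect_equal(sum(shared$n_operons), nrow(ops1))
  # (a,b) ~ (w,x) exactly; (c,d) has no counterpart (hD vs hX)
  expect_equal(shared$n_operons[shared$shared_with == "G2"], 1L)
  expect_equal(shared$n_operons[shared$shared_with == ""], 1L)
})

test_that("breakpoint overlap uses half-open intersection and strict points", {
  aln <- toy_aln(
    t_chrom = "t1", t_start = c(0, 100), t_end = c(100, 200),
    q_chrom = "q1", q_start = c(300, 0), q_end = c(400, 100),
    strand = c("+", "-"),
    t_len = c(t1 = 300), q_len = c(q1 = 500)
  )
  seg <- classify_segments(aln)
  # breakpoints: zero-width at 100, positive [200, 300)
  el <- tibble::tibble(
    chrom = "t1",
    start = c(50, 100, 90, 250, 195),
    end = c(100, 150, 110, 260, 200)
  )
  hits <- scramblr:::overlaps_breakpoints(
    el, scramblr:::breakpoint_regions(seg)
  )
  # [50,100) abuts the point at its end -> no
  # [100,150) abuts at its start -> no
  # [90,110) strictly contains 100 -> yes
  # [250,260) intersects [200,300) -> yes
  # [195,200) abuts [200,300) half-open -> no
  expect_equal(hits, c(FALSE, FALSE, TRUE, TRUE, FALSE))

  prop <- breakpoint_overlap(list(things = el), seg)
  expect_equal(prop$n_total, 5L)
  expect_equal(prop$n_overlapping, 2L)
  expect_equal(prop$proportion, 0.4)

  bad <- tibble::tibble(chrom = "zz", start = 0, end = 10)
  expect_error(breakpoint_overlap(list(b = bad), seg), "zz",
               class = "scramblr_validation_error")
})

test_that("operonic_status_test reproduces a frozen chi-squared value", {
  status <- tibble::tibble(
    operonic_a = rep(c(TRUE, TRUE, FALSE, FALSE),
                     times = c(2500, 500, 500, 6500)),
    operonic_b = rep(c(TRUE, FALSE, TRUE, FALSE),
                     times = c(2500, 500, 500, 6500))
  )
  res <- operonic_status_test(status)
  expect_equal(unname(res$observed), c(2500, 500, 500, 6500))
  expect_equal(unname(res$expected), c(900, 2100, 2100, 4900))
  expect_equal(res$statistic_gof, 5804.9887, tolerance = 1e-6)
  # the quoted and cross-check statistics are numerically identical
  expect_identical(res$statistic_gof, res$statistic_indep)
  expect_equal(res$df_gof, 3L)
  expect_equal(res$df_indep, 1L)
  expect_true(res$p_gof < 1e-100)
  # matches the standard 2x2 chi-squared without continuity correction
  m <- matrix(c(2500, 500, 500, 6500), 2, byrow = TRUE)
  expect_equal(res$statistic_indep,
               unname(stats::chisq.test(m, correct = FALSE)$statistic))
})

test_that("degenerate operonic status tables raise domain errors", {
  all_both <- tibble::tibble(operonic_a = rep(TRUE, 10),
                             operonic_b = rep(TRUE, 10))
  expect_error(operonic_status_test(all_both),
               class = "scramblr_domain_error")
  # two occupied cells but a zero expected count
  degen <- tibble::tibble(operonic_a = rep(TRUE, 10),
                          operonic_b = rep(c(TRUE, FALSE), 5))
  expect_error(operonic_status_test(degen),
               class = "scramblr_domain_error")
})

test_that("operon size comparison degrades gracefully", {
  aln <- toy_aln("t1", 0, 1000, "q1", 0, 1000, "+",
                 c(t1 = 1000), c(q1 = 1000))
  seg <- classify_segments(aln)   # no breakpoints at all
  ops <- call_operons(genes_tbl(
    start = c(0, 150, 600, 750), end = c(100, 250, 700, 850), strand = "+"
  ))
  expect_condition(
    res <- operon_size_by_breakpoint(ops, seg),
    class = "scramblr_notice"
  )
  expect_null(res$test)
  expect_false(any(res$sizes$overlaps_breakpoint))
})
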
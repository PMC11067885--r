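test_that("scrambling index hits its extremes and frozen hand values", {
  all_same <- toy_aln(
    t_chrom = "t1", t_start = c(0, 200), t_end = c(100, 300),
    q_chrom = "q1", q_start = c(0, 200), q_end = c(100, 300),
    strand = "+", t_len = c(t1 = 400), q_len = c(q1 = 400)
  )
  expect_equal(weighted_scrambling_index(scrambling_index(all_same)), 1)

  balanced <- toy_aln(
    t_chrom = "t1", t_start = c(0, 200), t_end = c(100, 300),
    q_chrom = "q1", q_start = c(0, 200), q_end = c(100, 300),
    strand = c("+", "-"), t_len = c(t1 = 400), q_len = c(q1 = 400)
  )
  expect_equal(weighted_scrambling_index(scrambling_index(balanced)), 0)

  # 300 same vs 100 opposite -> |300-100|/400 = 0.5
  skewed <- toy_aln(
    t_chrom = "t1", t_start = c(0, 400), t_end = c(300, 500),
    q_chrom = "q1", q_start = c(0, 400), q_end = c(300, 500),
    strand = c("+", "-"), t_len = c(t1 = 600), q_len = c(q1 = 600)
  )
  expect_equal(weighted_scrambling_index(scrambling_index(skewed)), 0.5)
})

test_that("the weighted mean uses full unit lengths including unaligned", {
  # chromosome A (len 1000): fully oriented, index 1
  # chromosome B (len 3000): 300 same vs 100 opposite, index 0.5
  # weighted mean: (1000*1 + 3000*0.5) / 4000 = 0.625
  aln <- toy_aln(
    t_chrom = c("A", "B", "B"), t_start = c(0, 0, 400),
    t_end = c(100, 300, 500),
    q_chrom = "q1", q_start = c(0, 200, 600), q_end = c(100, 500, 700),
    strand = c("+", "+", "-"),
    t_len = c(A = 1000, B = 3000), q_len = c(q1 = 1000)
  )
  rep <- scrambling_index(aln)
  expect_equal(weighted_scrambling_index(rep), 0.625)
})

test_that("units without alignment are excluded, not counted as zero", {
  aln <- toy_aln(
    t_chrom = "A", t_start = 0, t_end = 100,
    q_chrom = "q1", q_start = 0, q_end = 100, strand = "+",
    t_len = c(A = 1000, EMPTY = 5000), q_len = c(q1 = 200)
  )
  rep <- scrambling_index(aln)
  d <- tibble::as_tibble(rep)
  expect_true(is.na(d$index[d$unit == "EMPTY"]))
  expect_equal(weighted_scrambling_index(rep), 1)
})

test_that("arm grouping attributes block length by overlap", {
  layout <- genome_layout(
    chrom = c("A", "A"), length = 1000, centromere = 400,
    arm_name = c("S", "L"), arm_start = c(0, 400), arm_end = c(400, 1000),
    arm_class = c("short", "long")
  )
  # one + block straddling the arm boundary: 300 bases short, 100 long;
  # one - block of 100 on the long arm
  aln <- alignment_set(
    tibble::tibble(
      t_chrom = "A", t_start = c(100, 600), t_end = c(500, 700),
      q_chrom = "q1", q_start = c(0, 600), q_end = c(400, 700),
      strand = c("+", "-")
    ),
    layout, layout_from_lengths(c(q1 = 1000))
  )
  d <- strand_randomisation_index(aln, by = "arm")
  short <- d[d$unit == "A:S", ]
  long <- d[d$unit == "A:L", ]
  expect_equal(short$L_same, 300)
  expect_equal(short$L_opposite, 0)
  expect_equal(short$index, 1)
  expect_equal(long$L_same, 100)
  expect_equal(long$L_opposite, 100)
  expect_equal(long$index, 0)
  expect_equal(long$weight, 600)

  bare <- toy_aln("A", 0, 10, "q1", 0, 10, "+", c(A = 100), c(q1 = 100))
  expect_error(strand_randomisation_index(bare, by = "arm"),
               class = "scramblr_config_error")
})

test_that("genome grouping collapses to a single unit", {
  aln <- toy_aln(
    t_chrom = c("A", "B"), t_start = 0, t_end = c(100, 300),
    q_chrom = "q1", q_start = c(0, 200), q_end = c(100, 500),
    strand = c("+", "-"),
    t_len = c(A = 500, B = 500), q_len = c(q1 = 600)
  )
  d <- strand_randomisation_index(aln, by = "genome")
  expect_equal(nrow(d), 1L)
  expect_equal(d$index, abs(100 - 300) / 400)
})

test_that("breakpoint_rate reproduces hand arithmetic and validates input", {
  aln <- toy_aln(
    t_chrom = "t1", t_start = c(0, 200), t_end = c(100, 300),
    q_chrom = "q1", q_start = c(0, 400), q_end = c(100, 500),
    strand = c("+", "-"),
    t_len = c(t1 = 400), q_len = c(q1 = 600)
  )
  seg <- classify_segments(aln)
  # 2 breakpoint regions ([100,200) and [300,400)), 200 aligned bases
  r <- breakpoint_rate(seg, divergence_time = 4)
  expect_equal(r$n_breakpoints, 2L)
  expect_equal(r$aligned_bases, 200)
  expect_equal(r$rate, 2 / (200 / 1e6) / 4)

  expect_error(breakpoint_rate(seg, divergence_time = 0),
               class = "scramblr_domain_error")
  expect_error(breakpoint_rate(seg, divergence_time = -1),
               class = "scramblr_domain_error")

  none <- classify_segments(
    toy_aln(character(0), numeric(0), numeric(0), character(0),
            numeric(0), numeric(0), character(0),
            t_len = c(t1 = 100), q_len = c(q1 = 100))
  )
  expect_error(breakpoint_rate(none, 1), class = "scramblr_domain_error")
})

test_that("synteny blocks follow the worked rank example", {
  # query ranks 1,3,2,4 against target ranks 1,2,3,4 -> block sizes 1,2,1
  pairs <- tibble::tibble(
    pair_id = paste0("p", 1:4),
    t_chrom = "tc", t_start = c(10, 20, 30, 40), t_end = c(15, 25, 35, 45),
    q_chrom = "qc", q_start = c(10, 30, 20, 40), q_end = c(15, 35, 25, 45)
  )
  blocks <- synteny_blocks(pairs)
  sizes <- synteny_block_sizes(blocks)
  expect_equal(sizes$size, c(1L, 2L))
  expect_equal(sizes$n_blocks, c(2L, 1L))
  expect_equal(sum(sizes$size * sizes$n_blocks), 4L)
})

test_that("synteny blocks allow descending runs but never span chromosomes", {
  desc <- tibble::tibble(
    pair_id = paste0("p", 1:3),
    t_chrom = "tc", t_start = c(10, 20, 30), t_end = c(15, 25, 35),
    q_chrom = "qc", q_start = c(30, 20, 10), q_end = c(35, 25, 15)
  )
  expect_equal(synteny_block_sizes(synteny_blocks(desc))$size, 3L)

  split_chrom <- tibble::tibble(
    pair_id = paste0("p", 1:4),
    t_chrom = c("tc", "tc", "td", "td"),
    t_start = c(10, 20, 10, 20), t_end = c(15, 25, 15, 25),
    q_chrom = "qc", q_start = c(10, 20, 30, 40), q_end = c(15, 25, 35, 45)
  )
  sizes <- synteny_block_sizes(synteny_blocks(split_chrom))
  expect_equal(sizes$size, 2L)
  expect_equal(sizes$n_blocks, 2L)
})

test_that("intervening non-ortholog genes do not break synteny runs", {
  # ranks are computed among the single-copy orthologs only, so the pair
  # coordinates can be arbitrarily far apart
  pairs <- tibble::tibble(
    pair_id = c("p1", "p2"),
    t_chrom = "tc", t_start = c(10, 50000), t_end = c(15, 50005),
    q_chrom = "qc", q_start = c(10, 99000), q_end = c(15, 99005)
  )
  expect_equal(synteny_block_sizes(synteny_blocks(pairs))$size, 2L)
})

test_that("synteny input validation rejects duplicates", {
  base <- tibble::tibble(
    pair_id = c("p1", "p1"),
    t_chrom = "tc", t_start = c(10, 20), t_end = c(15, 25),
    q_chrom = "qc", q_start = c(10, 20), q_end = c(15, 25)
  )
  expect_error(synteny_blocks(base), "pair_id",
               class = "scramblr_validation_error")

  dup_coord <- tibble::tibble(
    pair_id = c("p1", "p2"),
    t_chrom = "tc", t_start = c(10, 10), t_end = c(15, 15),
    q_chrom = "qc", q_start = c(10, 20), q_end = c(15, 25)
  )
  expect_error(synteny_blocks(dup_coord), "coordinates",
               class = "scramblr_validation_error")
})

test_that("dotplot_table reports midpoints in deterministic order", {
  pairs <- tibble::tibble(
    pair_id = c("p2", "p1"),
    t_chrom = "tc", t_start = c(100, 10), t_end = c(200, 20),
    q_chrom = "qc", q_start = c(100, 10), q_end = c(200, 20)
  )
  d <- dotplot_table(pairs)
  expect_equal(d$pair_id, c("p1", "p2"))
  expect_equal(d$t_pos, c(15, 150))
})
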
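# Shared fixtures and brute-force oracles used across the test files.

# Compact alignment-set builder: one row per block, explicit coordinates.
toy_aln <- function(t_chrom, t_start, t_end, q_chrom, q_start, q_end, strand,
                    t_len = NULL, q_len = NULL) {
  blocks <- tibble::tibble(
    t_chrom = t_chrom, t_start = t_start, t_end = t_end,
    q_chrom = q_chrom, q_start = q_start, q_end = q_end, strand = strand
  )
  t_layout <- if (!is.null(t_len)) layout_from_lengths(t_len)
  q_layout <- if (!is.null(q_len)) layout_from_lengths(q_len)
  alignment_set(blocks, t_layout, q_layout)
}

# Brute-force chain successor written directly from the collinearity
# definition (O(n^2), no shared code with the package implementation):
# block j follows block i iff j is i's target-order successor on i's target
# chromosome, both lie on the same query chromosome with the same strand,
# and j is i's query-order successor (strand +) or predecessor (strand -).
oracle_next <- function(t_chrom, t_start, q_chrom, q_start, strand) {
  n <- length(t_start)
  res <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    cand <- which(t_chrom == t_chrom[i] & t_start > t_start[i])
    if (!length(cand)) next
    j <- cand[which.min(t_start[cand])]
    if (q_chrom[i] != q_chrom[j] || strand[i] != strand[j]) next
    if (strand[i] == "+") {
      qc <- which(q_chrom == q_chrom[i] & q_start > q_start[i])
      if (length(qc) && qc[which.min(q_start[qc])] == j) res[i] <- j
    } else {
      qc <- which(q_chrom == q_chrom[i] & q_start < q_start[i])
      if (length(qc) && qc[which.max(q_start[qc])] == j) res[i] <- j
    }
  }
  res
}

# The package-internal successor function under test (not exported).
chain_next_impl <- function(t_chrom, t_start, q_chrom, q_start, strand) {
  scramblr:::chain_next(t_chrom, t_start, q_chrom, q_start, strand)
}

# All permutations of 1..n as a list of integer vectors (n <= 5).
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (k in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, as.integer(n), after = k)
    }
  }
  out
}

# Does a segmentation tile every chromosome of its layout exactly?
tiles_exactly <- function(seg) {
  d <- tibble::as_tibble(seg)
  lens <- chrom_lengths(segmentation_layout(seg))
  for (c in names(lens)) {
    x <- d[d$chrom == c, ]
    x <- x[order(x$start, x$end), ]
    if (nrow(x) == 0) return(FALSE)
    if (x$start[1] != 0 || x$end[nrow(x)] != lens[[c]]) return(FALSE)
    if (nrow(x) > 1 && any(x$start[-1] != x$end[-nrow(x)])) return(FALSE)
  }
  TRUE
}

# Alignment set with breakpoints planted at chosen positions: each
# chromosome is tiled by blocks cut exactly at its planted positions, with
# alternating strands so that no two neighbours ever chain.  Every internal
# boundary therefore becomes a zero-width breakpoint, and there are no other
# breakpoint regions.
aln_with_breakpoints_at <- function(cuts_by_chrom, chrom_len) {
  rows <- list()
  q_off <- 0
  for (c in names(chrom_len)) {
    cuts <- sort(unique(cuts_by_chrom[[c]]))
    bounds <- c(0, cuts, chrom_len[[c]])
    s <- bounds[-length(bounds)]
    e <- bounds[-1]
    m <- length(s)
    rows[[c]] <- tibble::tibble(
      t_chrom = c, t_start = s, t_end = e,
      q_chrom = "q1", q_start = q_off + s, q_end = q_off + e,
      strand = rep_len(c("+", "-"), m)
    )
    q_off <- q_off + chrom_len[[c]]
  }
  blocks <- dplyr::bind_rows(rows)
  alignment_set(blocks, layout_from_lengths(chrom_len),
                layout_from_lengths(c(q1 = q_off)))
}

# Layout with one whole-chromosome arm per chromosome.
one_arm_layout <- function(chrom_len, classes) {
  genome_layout(
    chrom = names(chrom_len), length = unname(chrom_len),
    arm_name = paste0(names(chrom_len), "_arm"),
    arm_start = 0, arm_end = unname(chrom_len),
    arm_class = classes
  )
}
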
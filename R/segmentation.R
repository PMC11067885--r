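#' Chain alignments under the strictest collinearity definition
#'
#' Two blocks are linked if and only if they are adjacent in the
#' target-sorted order of their target chromosome, adjacent in the
#' query-sorted order of their query chromosome, share the same strand, and
#' their query adjacency direction matches the strand (ascending query order
#' for `+`, descending for `-`).  Collinearity is thus interrupted by
#' inversions (strand changes) and translocations (one extra aligned region
#' in one genome only) of any length, while the unaligned gap between chain
#' members is unbounded.  Chains are the maximal unions of such links and
#' have at least two members.
#'
#' @param aln An `alignment_set`.
#' @return A tibble with one row per chain: `chain_id`, `n_blocks`,
#'   `orientation`, target and query spans, and list-columns `block_ids` and
#'   `bridges` (the unaligned target gaps between consecutive members).
#' @export
chain_collinear <- function(aln) {
  b <- as_tibble(aln)
  nxt <- chain_next(b$t_chrom, b$t_start, b$q_chrom, b$q_start, b$strand)
  chains_from_links(b, nxt)
}

# For each block (row order of the input), the row index of its chain
# successor, or NA.  Pure integer/base-R path: this is called half a million
# times by exhaustive oracle checks.
chain_next <- function(t_chrom, t_start, q_chrom, q_start, strand) {
  n <- length(t_start)
  if (n < 2L) return(rep(NA_integer_, n))
  nxt_on <- function(chrom, start) {
    # successor of each block in (chrom, start) order within its chromosome
    o <- order(chrom, start)
    succ <- rep(NA_integer_, n)
    same <- chrom[o][-n] == chrom[o][-1L]
    succ[o[-n][same]] <- o[-1L][same]
    succ
  }
  t_next <- nxt_on(t_chrom, t_start)
  q_next <- nxt_on(q_chrom, q_start)
  q_prev <- rep(NA_integer_, n)
  q_prev[q_next[!is.na(q_next)]] <- which(!is.na(q_next))

  j <- t_next
  ok <- !is.na(j)
  idx <- which(ok)
  jj <- j[idx]
  good <- strand[idx] == strand[jj] & q_chrom[idx] == q_chrom[jj] &
    ifelse(strand[idx] == "+",
           !is.na(q_next[idx]) & q_next[idx] == jj,
           !is.na(q_prev[idx]) & q_prev[idx] == jj)
  j[idx[!good]] <- NA_integer_
  j
}

# Assemble maximal chains from successor links.
chains_from_links <- function(b, nxt) {
  n <- nrow(b)
  has_pred <- rep(FALSE, n)
  has_pred[nxt[!is.na(nxt)]] <- TRUE
  heads <- which(!has_pred & !is.na(nxt))
  rows <- vector("list", length(heads))
  for (k in seq_along(heads)) {
    members <- heads[[k]]
    i <- nxt[[heads[[k]]]]
    while (!is.na(i)) {
      members <- c(members, i)
      i <- nxt[[i]]
    }
    m <- b[members, ]
    gaps_s <- m$t_end[-length(members)]
    gaps_e <- m$t_start[-1]
    rows[[k]] <- tibble(
      chain_id = k,
      n_blocks = length(members),
      orientation = m$strand[[1]],
      t_chrom = m$t_chrom[[1]],
      t_start = min(m$t_start), t_end = max(m$t_end),
      q_chrom = m$q_chrom[[1]],
      q_start = min(m$q_start), q_end = max(m$q_end),
      block_ids = list(m$block_id),
      bridges = list(tibble(start = gaps_s, end = gaps_e))
    )
  }
  if (length(rows) == 0) {
    return(tibble(
      chain_id = integer(), n_blocks = integer(), orientation = character(),
      t_chrom = character(), t_start = numeric(), t_end = numeric(),
      q_chrom = character(), q_start = numeric(), q_end = numeric(),
      block_ids = list(), bridges = list()
    ))
  }
  bind_rows(rows)
}

#' Partition the target genome into the four region classes
#'
#' Every target chromosome is tiled exactly by labelled intervals: aligned
#' blocks that belong to a chain are `collinear_alignment`, aligned blocks in
#' no chain are `isolated_alignment`, unaligned gaps between consecutive
#' members of one chain are `bridge`, and all remaining unaligned sequence is
#' `breakpoint`.  Two abutting blocks that are not chain-linked produce a
#' zero-width breakpoint at their shared boundary: breakpoint *counts* must
#' not depend on breakpoint width.  Unaligned sequence before the first and
#' after the last aligned block of a chromosome is breakpoint, never bridge.
#'
#' @param aln An `alignment_set`.
#' @param chains Chains produced by [chain_collinear()] on the same set; when
#'   `NULL` they are computed.
#' @return A `segmentation`: tibble with columns `chrom`, `start`, `end`,
#'   `class` (zero-width breakpoints have `start == end`), carrying the chain
#'   table, the alignment block count and the target layout as attributes.
#' @export
classify_segments <- function(aln, chains = NULL) {
  b <- as_tibble(aln)
  if (is.null(chains)) {
    chains <- chain_collinear(aln)
  } else {
    unknown <- setdiff(unlist(chains$block_ids), b$block_id)
    if (length(unknown)) {
      stop_validation(paste0(
        "chain references unknown block id(s): ",
        paste(unknown, collapse = ", ")
      ))
    }
  }
  nxt <- chain_next(b$t_chrom, b$t_start, b$q_chrom, b$q_start, b$strand)
  in_chain <- rep(FALSE, nrow(b))
  in_chain[unlist(chains$block_ids) |> match(b$block_id)] <- TRUE

  lens <- chrom_lengths(target_layout(aln))
  out <- vector("list", length(lens))
  for (ci in seq_along(lens)) {
    chrom <- names(lens)[[ci]]
    len <- lens[[ci]]
    idx <- which(b$t_chrom == chrom)
    idx <- idx[order(b$t_start[idx])]
    if (length(idx) == 0) {
      out[[ci]] <- tibble(chrom = chrom, start = 0, end = len,
                          class = "breakpoint")
      next
    }
    m <- length(idx)
    aligned <- tibble(
      chrom = chrom, start = b$t_start[idx], end = b$t_end[idx],
      class = ifelse(in_chain[idx], "collinear_alignment",
                     "isolated_alignment")
    )
    gaps <- NULL
    if (m > 1) {
      gs <- b$t_end[idx][-m]
      ge <- b$t_start[idx][-1]
      linked <- !is.na(nxt[idx][-m]) & nxt[idx][-m] == idx[-1]
      cls <- ifelse(linked, "bridge", "breakpoint")
      keep <- cls == "breakpoint" | ge > gs   # drop only zero-width bridges
      gaps <- tibble(chrom = chrom, start = gs[keep], end = ge[keep],
                     class = cls[keep])
    }
    end_s <- c(if (b$t_start[idx][1] > 0) 0,
               if (b$t_end[idx][m] < len) b$t_end[idx][m])
    end_e <- c(if (b$t_start[idx][1] > 0) b$t_start[idx][1],
               if (b$t_end[idx][m] < len) len)
    ends <- if (length(end_s)) {
      tibble(chrom = chrom, start = end_s, end = end_e,
             class = "breakpoint")
    }
    out[[ci]] <- bind_rows(aligned, gaps, ends)
  }
  seg <- arrange(bind_rows(out), .data$chrom, .data$start, .data$end)
  seg$class <- factor(seg$class, levels = segment_classes)
  structure(
    seg,
    chains = chains,
    n_aligned_blocks = nrow(b),
    target_layout = target_layout(aln),
    class = c("segmentation", class(tibble()))
  )
}

segment_classes <- c("collinear_alignment", "bridge", "breakpoint",
                     "isolated_alignment")

#' @export
segmentation_chains <- function(seg) attr(seg, "chains")

#' @export
segmentation_layout <- function(seg) attr(seg, "target_layout")

#' Segment both genomes of an alignment pair
#'
#' Runs [classify_segments()] on the alignment set and on its
#' strand-preserving target/query swap, giving the region classes of both
#' genomes.
#'
#' @param aln An `alignment_set`.
#' @return A list with elements `target` and `query`, each a `segmentation`.
#' @export
segment_both_directions <- function(aln) {
  list(
    target = classify_segments(aln),
    query = classify_segments(swap_alignment(aln))
  )
}

#' Per-class coverage and breakpoint statistics of a segmentation
#'
#' @param seg A `segmentation`.
#' @return A tibble with one row per class: `class`, `n` (interval count,
#'   zero-width breakpoints included), `total_bases`, `fraction_of_genome`
#'   (fractions sum to 1), and for breakpoints the mean and standard
#'   deviation of region widths (zero-width regions included) plus the count
#'   of zero-width regions.
#' @export
class_coverage <- function(seg) {
  genome_len <- sum(chrom_lengths(segmentation_layout(seg)))
  d <- as_tibble(seg)
  d$width <- d$end - d$start
  out <- d |>
    group_by(class = .data$class) |>
    summarise(
      n = n(),
      total_bases = sum(.data$width),
      mean_width = mean(.data$width),
      sd_width = sd(.data$width),
      n_zero_width = sum(.data$width == 0),
      .groups = "drop"
    )
  out <- left_join(tibble(class = factor(segment_classes,
                                         levels = segment_classes)),
                   out, by = "class")
  out$n[is.na(out$n)] <- 0L
  out$total_bases[is.na(out$total_bases)] <- 0
  out$n_zero_width[is.na(out$n_zero_width)] <- 0L
  out$fraction_of_genome <- out$total_bases / genome_len
  out[, c("class", "n", "total_bases", "fraction_of_genome", "mean_width",
          "sd_width", "n_zero_width")]
}

# Breakpoint regions of a segmentation (optionally excluding zero-width).
breakpoint_regions <- function(seg, count_zero_width = TRUE) {
  d <- filter(as_tibble(seg), .data$class == "breakpoint")
  if (!count_zero_width) d <- filter(d, .data$end > .data$start)
  d
}

#' Number of strand transitions along the target genome
#'
#' Counts, over target chromosomes, adjacent pairs of aligned blocks (in
#' target order) whose strands differ.  Each clean internal inversion
#' contributes two transitions.
#'
#' @param aln An `alignment_set`.
#' @return Integer count.
#' @export
strand_transitions <- function(aln) {
  b <- arrange(as_tibble(aln), .data$t_chrom, .data$t_start)
  if (nrow(b) < 2) return(0L)
  i <- seq_len(nrow(b) - 1L)
  sum(b$t_chrom[i] == b$t_chrom[i + 1L] &
        b$strand[i] != b$strand[i + 1L])
}

#' Export the chain table as TSV
#'
#' @param chains Result of [chain_collinear()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chain_table <- function(chains, path) {
  d <- mutate(
    chains,
    block_ids = vapply(.data$block_ids, paste, character(1), collapse = ","),
    bridges = vapply(.data$bridges, function(x) {
      paste(paste0(fmt_int(x$start), "-", fmt_int(x$end)), collapse = ",")
    }, character(1))
  )
  readr::write_tsv(d, path)
  invisible(path)
}
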
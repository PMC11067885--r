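#' Strand-randomisation (scrambling) index per grouping unit
#'
#' For each unit (target chromosome, target arm, or the whole genome) the
#' index is the absolute difference between the total length of same-strand
#' and opposite-strand alignments divided by the total aligned length, all
#' measured on the target genome within the unit:
#' `|L_same - L_opposite| / (L_same + L_opposite)`.
#' A value of one indicates that all alignments have the same orientation; a
#' value of zero indicates that, overall, orientations appear random.  Units
#' with no aligned base get `NA` and are excluded from averaging.
#'
#' @param aln An `alignment_set`.
#' @param by `"chromosome"` (default), `"arm"` (requires arm annotation in
#'   the target layout) or `"genome"` (a single unit).
#' @return A tibble with one row per unit: `unit`, `chrom`, `L_same`,
#'   `L_opposite`, `index`, `weight` (the unit's full sequence length).
#' @export
strand_randomisation_index <- function(aln,
                                       by = c("chromosome", "arm", "genome")) {
  by <- match.arg(by)
  b <- as_tibble(aln)
  layout <- target_layout(aln)
  lens <- chrom_lengths(layout)

  if (by == "arm") {
    arms <- layout_arms(layout)
    if (is.null(arms)) {
      stop_config("arm grouping requires arm annotations in the target layout")
    }
    units <- tibble(
      unit = paste0(arms$chrom, ":", arms$arm_name),
      chrom = arms$chrom, u_start = arms$arm_start, u_end = arms$arm_end,
      weight = arms$arm_end - arms$arm_start,
      arm_class = arms$arm_class
    )
  } else if (by == "chromosome") {
    units <- tibble(
      unit = names(lens), chrom = names(lens),
      u_start = 0, u_end = unname(lens), weight = unname(lens),
      arm_class = NA_character_
    )
  } else {
    units <- tibble(
      unit = "genome", chrom = NA_character_, u_start = NA_real_,
      u_end = NA_real_, weight = sum(lens), arm_class = NA_character_
    )
  }

  same_opp <- function(u) {
    if (is.na(u$chrom)) {
      sel <- b
      ov <- sel$t_end - sel$t_start
    } else {
      sel <- filter(b, .data$t_chrom == u$chrom)
      ov <- pmin(sel$t_end, u$u_end) - pmax(sel$t_start, u$u_start)
      keep <- ov > 0
      sel <- sel[keep, ]; ov <- ov[keep]
    }
    c(same = sum(ov[sel$strand == "+"]), opp = sum(ov[sel$strand == "-"]))
  }
  so <- t(vapply(seq_len(nrow(units)),
                 function(i) same_opp(units[i, ]), numeric(2)))
  units$L_same <- unname(so[, "same"])
  units$L_opposite <- unname(so[, "opp"])
  tot <- units$L_same + units$L_opposite
  units$index <- ifelse(tot > 0,
                        abs(units$L_same - units$L_opposite) / tot, NA_real_)
  units[, c("unit", "chrom", "arm_class", "L_same", "L_opposite", "index",
            "weight")]
}

#' Scrambling index report with length-weighted mean
#'
#' Computes the per-unit strand-randomisation indices and their mean weighted
#' by the unit's full sequence length (chromosome or arm length including
#' unaligned sequence, not aligned length).  Units with no aligned base are
#' excluded from both the numerator and the weight sum.
#'
#' @param aln An `alignment_set`.
#' @param by Grouping unit, as in [strand_randomisation_index()].
#' @return A `scrambling_report`: the per-unit tibble with the weighted mean
#'   attached as attribute `weighted_mean` (also available via `glance()`).
#' @export
scrambling_index <- function(aln, by = c("chromosome", "arm", "genome")) {
  units <- strand_randomisation_index(aln, by = by)
  ok <- !is.na(units$index)
  wm <- if (any(ok)) {
    sum(units$index[ok] * units$weight[ok]) / sum(units$weight[ok])
  } else {
    NA_real_
  }
  structure(units, weighted_mean = wm, grouping = match.arg(by),
            class = c("scrambling_report", class(tibble())))
}

#' @export
weighted_scrambling_index <- function(report) attr(report, "weighted_mean")

#' Breakpoint accumulation rate
#'
#' The number of breakpoint regions per megabase of aligned target sequence
#' per million years of divergence.  Divergence time is the time since the
#' split of the two genomes (in million years) and enters the rate once.
#' Aligned length is the total of collinear and isolated alignment bases on
#' the target.
#'
#' @param seg A `segmentation`.
#' @param divergence_time Divergence time in million years (> 0).
#' @param count_zero_width Count zero-width breakpoint regions (default
#'   `TRUE`); both counts are reported either way.
#' @return A one-row tibble: `n_breakpoints`, `n_breakpoints_zero_width`,
#'   `aligned_bases`, `divergence_my`, `rate` (breakpoints / Mbp aligned /
#'   My).
#' @export
breakpoint_rate <- function(seg, divergence_time, count_zero_width = TRUE) {
  if (!is.numeric(divergence_time) || divergence_time <= 0) {
    stop_domain("divergence_time must be a positive number of million years")
  }
  cov <- class_coverage(seg)
  aligned <- sum(cov$total_bases[cov$class %in%
                                   c("collinear_alignment",
                                     "isolated_alignment")])
  if (aligned <= 0) {
    stop_domain("no aligned sequence: breakpoint rate is undefined")
  }
  bp <- breakpoint_regions(seg, count_zero_width = TRUE)
  n_zero <- sum(bp$end == bp$start)
  n_all <- nrow(bp)
  n <- if (count_zero_width) n_all else n_all - n_zero
  tibble(
    n_breakpoints = n,
    n_breakpoints_zero_width = n_zero,
    aligned_bases = aligned,
    divergence_my = divergence_time,
    rate = n / (aligned / 1e6) / divergence_time
  )
}

#' Macrosynteny blocks from single-copy ortholog pairs
#'
#' Genes are ranked along each genome by (chromosome, start) among the
#' single-copy orthologs only, so intervening non-ortholog genes never break
#' a run.  Blocks are maximal runs of pairs whose ranks are consecutive in
#' both genomes, allowing ascending or descending query rank
#' (strand-independent), and never span a chromosome change on either
#' genome.  Every pair belongs to exactly one block (size >= 1).
#'
#' @param pairs A tibble of single-copy ortholog pairs with gene coordinates
#'   in both genomes: columns `pair_id`, `t_chrom`, `t_start`, `t_end`,
#'   `q_chrom`, `q_start`, `q_end`.  Each gene must appear in exactly one
#'   pair.
#' @return A `synteny_blocks` object: the input pairs with `t_rank`,
#'   `q_rank` and `block_id` columns, ordered by target rank.  Use
#'   [synteny_block_sizes()] for the size histogram.
#' @export
synteny_blocks <- function(pairs) {
  p <- as_tibble(pairs)
  needed <- c("pair_id", "t_chrom", "t_start", "q_chrom", "q_start")
  if (!all(needed %in% names(p))) {
    stop_validation(paste0(
      "pairs need columns: ", paste(needed, collapse = ", ")
    ))
  }
  if (anyDuplicated(p$pair_id)) {
    stop_validation("duplicated pair_id in single-copy pairs")
  }
  if (anyDuplicated(p[, c("t_chrom", "t_start")]) ||
        anyDuplicated(p[, c("q_chrom", "q_start")])) {
    stop_validation("duplicated gene coordinates in single-copy pairs")
  }
  p$t_rank <- order(order(p$t_chrom, p$t_start))
  p$q_rank <- order(order(p$q_chrom, p$q_start))
  p <- arrange(p, .data$t_rank)
  n <- nrow(p)
  block_id <- integer(n)
  if (n > 0) {
    bid <- 1L
    block_id[[1]] <- bid
    dir <- 0L
    if (n > 1) {
      for (i in 2:n) {
        dq <- p$q_rank[[i]] - p$q_rank[[i - 1L]]
        same_chrom <- p$t_chrom[[i]] == p$t_chrom[[i - 1L]] &&
          p$q_chrom[[i]] == p$q_chrom[[i - 1L]]
        extend <- same_chrom && abs(dq) == 1L && (dir == 0L || dq == dir)
        if (extend) {
          dir <- dq
        } else {
          bid <- bid + 1L
          dir <- 0L
        }
        block_id[[i]] <- bid
      }
    }
  }
  p$block_id <- block_id
  structure(p, class = c("synteny_blocks", class(tibble())))
}

#' Synteny block size histogram
#'
#' @param blocks A `synteny_blocks` object.
#' @return A tibble `size`, `n_blocks`; block sizes sum to the number of
#'   pairs.
#' @export
synteny_block_sizes <- function(blocks) {
  sizes <- as_tibble(blocks) |>
    group_by(.data$block_id) |>
    summarise(size = n(), .groups = "drop")
  sizes |>
    group_by(.data$size) |>
    summarise(n_blocks = n(), .groups = "drop") |>
    arrange(.data$size)
}

#' Dot-plot table of ortholog positions
#'
#' One row per single-copy ortholog pair with gene midpoints as positions,
#' for strand-independent macrosynteny dot plots.
#'
#' @param pairs As in [synteny_blocks()]; `t_end`/`q_end` required for
#'   midpoints.
#' @return A tibble `pair_id`, `t_chrom`, `t_pos`, `q_chrom`, `q_pos` in
#'   deterministic (target chromosome, position) order.
#' @export
dotplot_table <- function(pairs) {
  p <- as_tibble(pairs)
  out <- tibble(
    pair_id = p$pair_id,
    t_chrom = p$t_chrom, t_pos = (p$t_start + p$t_end) / 2,
    q_chrom = p$q_chrom, q_pos = (p$q_start + p$q_end) / 2
  )
  arrange(out, .data$t_chrom, .data$t_pos)
}
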
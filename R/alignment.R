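#' One-to-one pairwise alignment sets
#'
#' An alignment set is the unit consumed by every downstream analysis: a
#' tibble of aligned blocks linking intervals of a target genome to intervals
#' of a query genome, with a relative strand per block.  Coordinates are
#' 0-based half-open on the forward strand of both genomes; the strand is a
#' property of the block, not of the interval.
#'
#' The defining invariant is the one-to-one property: blocks are pairwise
#' non-overlapping on the target *and* on the query, so every base of either
#' genome participates in at most one alignment.
#'
#' @param blocks A data frame with columns `t_chrom`, `t_start`, `t_end`,
#'   `q_chrom`, `q_start`, `q_end`, `strand` (`"+"` or `"-"`); an integer
#'   `block_id` column is added when absent.
#' @param target_layout,query_layout `genome_layout` objects.  When `NULL`,
#'   minimal layouts are inferred from the extent of the blocks.
#' @return An `alignment_set`: a tibble of blocks carrying the two layouts as
#'   attributes (`target_layout`, `query_layout`).
#' @examples
#' aln <- alignment_set(
#'   tibble::tibble(
#'     t_chrom = "chr1", t_start = c(0, 200), t_end = c(100, 300),
#'     q_chrom = "chrA", q_start = c(0, 200), q_end = c(100, 300),
#'     strand = "+"
#'   ),
#'   layout_from_lengths(c(chr1 = 400)),
#'   layout_from_lengths(c(chrA = 400))
#' )
#' @export
alignment_set <- function(blocks, target_layout = NULL, query_layout = NULL) {
  blocks <- as_tibble(blocks)
  needed <- c("t_chrom", "t_start", "t_end", "q_chrom", "q_start", "q_end",
              "strand")
  missing <- setdiff(needed, names(blocks))
  if (length(missing)) {
    stop_validation(paste0(
      "blocks lack column(s): ", paste(missing, collapse = ", ")
    ))
  }
  if (!"block_id" %in% names(blocks)) {
    blocks$block_id <- seq_len(nrow(blocks))
  }
  blocks <- blocks[, c("block_id", needed)]
  blocks$block_id <- as.integer(blocks$block_id)
  blocks$t_chrom <- as.character(blocks$t_chrom)
  blocks$q_chrom <- as.character(blocks$q_chrom)
  for (col in c("t_start", "t_end", "q_start", "q_end")) {
    blocks[[col]] <- as.numeric(blocks[[col]])
  }

  if (is.null(target_layout)) {
    target_layout <- infer_layout(blocks$t_chrom, blocks$t_end)
  }
  if (is.null(query_layout)) {
    query_layout <- infer_layout(blocks$q_chrom, blocks$q_end)
  }

  x <- structure(
    blocks,
    target_layout = target_layout,
    query_layout = query_layout,
    class = c("alignment_set", class(tibble()))
  )
  validate_alignment_set(x)
  x
}

infer_layout <- function(chrom, end) {
  if (length(chrom) == 0) {
    return(layout_from_lengths(c(placeholder = 1))[0, ])
  }
  lens <- tapply(end, chrom, max)
  layout_from_lengths(setNames(as.numeric(lens), names(lens)))
}

#' @export
target_layout <- function(aln) attr(aln, "target_layout")

#' @export
query_layout <- function(aln) attr(aln, "query_layout")

#' Validate an alignment set
#'
#' Checks coordinate sanity (positive widths on both genomes, intervals within
#' their chromosomes) and the one-to-one property (no two blocks overlap on
#' either genome).  Overlaps are reported with the first offending block pair.
#'
#' @param x An `alignment_set`.
#' @return `x`, invisibly.
#' @export
validate_alignment_set <- function(x) {
  if (nrow(x) == 0) return(invisible(x))
  if (anyDuplicated(x$block_id)) {
    stop_validation("duplicated block_id in alignment set")
  }
  bad_strand <- setdiff(unique(x$strand), c("+", "-"))
  if (length(bad_strand)) {
    stop_validation("strand must be '+' or '-'")
  }
  if (any(x$t_end - x$t_start < 1) || any(x$q_end - x$q_start < 1)) {
    stop_validation(
      "alignment blocks of width 0 on either genome are not allowed"
    )
  }
  check_bounds(x$t_chrom, x$t_start, x$t_end, target_layout(x), "target")
  check_bounds(x$q_chrom, x$q_start, x$q_end, query_layout(x), "query")
  check_one_to_one(x$block_id, x$t_chrom, x$t_start, x$t_end, "target")
  check_one_to_one(x$block_id, x$q_chrom, x$q_start, x$q_end, "query")
  invisible(x)
}

check_bounds <- function(chrom, start, end, layout, genome) {
  lens <- chrom_lengths(layout)
  unknown <- setdiff(unique(chrom), names(lens))
  if (length(unknown)) {
    stop_validation(paste0(
      "blocks on ", genome, " chromosome(s) absent from layout: ",
      paste(unknown, collapse = ", ")
    ))
  }
  if (any(start < 0) || any(end > lens[chrom])) {
    stop_validation(paste0(
      "block coordinates outside [0, length) on the ", genome, " genome"
    ))
  }
}

check_one_to_one <- function(block_id, chrom, start, end, genome) {
  o <- order(chrom, start, end)
  chrom <- chrom[o]; start <- start[o]; end <- end[o]; block_id <- block_id[o]
  if (length(start) < 2) return(invisible(NULL))
  i <- seq_len(length(start) - 1L)
  same <- chrom[i] == chrom[i + 1L]
  if (any(same & start[i] == start[i + 1L])) {
    k <- which(same & start[i] == start[i + 1L])[[1]]
    stop_validation(paste0(
      "blocks ", block_id[k], " and ", block_id[k + 1L],
      " start at the same ", genome, " position"
    ))
  }
  clash <- same & end[i] > start[i + 1L]
  if (any(clash)) {
    k <- which(clash)[[1]]
    stop_validation(paste0(
      "one-to-one violation on the ", genome, " genome: blocks ",
      block_id[k], " and ", block_id[k + 1L], " overlap on ", chrom[k]
    ))
  }
  invisible(NULL)
}

#' Swap the target and query genomes of an alignment set
#'
#' Exchanges the two genomes of every block while preserving the relative
#' strand, giving the query-centric view of the same alignment.
#'
#' @param aln An `alignment_set`.
#' @return An `alignment_set` with target and query exchanged.
#' @export
swap_alignment <- function(aln) {
  blocks <- as_tibble(aln)
  swapped <- tibble(
    block_id = blocks$block_id,
    t_chrom = blocks$q_chrom, t_start = blocks$q_start, t_end = blocks$q_end,
    q_chrom = blocks$t_chrom, q_start = blocks$t_start, q_end = blocks$t_end,
    strand = blocks$strand
  )
  alignment_set(swapped, target_layout = query_layout(aln),
                query_layout = target_layout(aln))
}

# Cross-check a user-supplied layout against lengths inferred from an
# alignment file; silent length mismatch corrupts downstream weighting, so a
# mismatch is an error.
reconcile_layout <- function(inferred, supplied, genome) {
  if (is.null(supplied)) return(inferred)
  supplied <- as_genome_layout(supplied)
  inf_len <- chrom_lengths(inferred)
  sup_len <- chrom_lengths(supplied)
  common <- intersect(names(inf_len), names(sup_len))
  if (length(setdiff(names(inf_len), names(sup_len)))) {
    stop_validation(paste0(
      "supplied ", genome, " layout lacks chromosome(s): ",
      paste(setdiff(names(inf_len), names(sup_len)), collapse = ", ")
    ))
  }
  off <- common[inf_len[common] != sup_len[common]]
  if (length(off)) {
    stop_validation(paste0(
      genome, " chromosome length mismatch between alignment file and ",
      "layout: ", paste(off, collapse = ", ")
    ))
  }
  supplied
}
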
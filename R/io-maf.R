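#' Read a two-species MAF alignment into an alignment set
#'
#' Reads the pairwise MAF dialect emitted by whole-genome aligners: each `a`
#' block is followed by exactly two `s` lines, the first for the target
#' genome and the second for the query.  MAF counts minus-strand coordinates
#' from the end of the sequence; these are converted to forward-strand
#' 0-based half-open offsets, so the resulting alignment set is identical to
#' the PAF representation of the same alignment.
#'
#' @param path Path to a MAF file.
#' @param target_layout,query_layout Optional layouts cross-checked against
#'   the `srcSize` fields.
#' @return An `alignment_set`.
#' @export
read_maf <- function(path, target_layout = NULL, query_layout = NULL) {
  lines <- readr::read_lines(path)
  lines <- lines[!startsWith(lines, "#")]
  is_a <- startsWith(lines, "a")
  is_s <- startsWith(lines, "s")
  block_of <- cumsum(is_a)
  if (any(is_s & block_of == 0)) {
    stop_parse("MAF 's' line before any 'a' block header")
  }
  s_per_block <- tabulate(block_of[is_s], nbins = max(c(0L, block_of)))
  if (any(s_per_block != 2L)) {
    bad <- which(s_per_block != 2L)[[1]]
    stop_parse(paste0(
      "unsupported MAF input: block ", bad, " has ", s_per_block[[bad]],
      " sequence rows (exactly 2 are required)"
    ))
  }
  s_lines <- strsplit(lines[is_s], "[ \t]+")
  parse_s <- function(f, i) {
    if (length(f) < 6) {
      stop_parse(paste0("malformed MAF 's' line in block ", i))
    }
    list(
      src = f[[2]], start = as.numeric(f[[3]]), size = as.numeric(f[[4]]),
      strand = f[[5]], src_size = as.numeric(f[[6]])
    )
  }
  n_blocks <- length(s_lines) %/% 2L
  rows <- vector("list", n_blocks)
  t_lens <- q_lens <- list()
  for (i in seq_len(n_blocks)) {
    t <- parse_s(s_lines[[2L * i - 1L]], i)
    q <- parse_s(s_lines[[2L * i]], i)
    if (t$strand != "+") {
      stop_parse(paste0(
        "MAF block ", i, ": target sequence on '-' strand is unsupported"
      ))
    }
    # Minus-strand MAF coordinates count from the sequence end.
    if (q$strand == "-") {
      q_start <- q$src_size - (q$start + q$size)
    } else {
      q_start <- q$start
    }
    rows[[i]] <- tibble(
      block_id = i,
      t_chrom = t$src, t_start = t$start, t_end = t$start + t$size,
      q_chrom = q$src, q_start = q_start, q_end = q_start + q$size,
      strand = q$strand
    )
    t_lens[[t$src]] <- t$src_size
    q_lens[[q$src]] <- q$src_size
  }
  if (n_blocks == 0) {
    aln <- alignment_set(empty_blocks())
  } else {
    aln <- alignment_set(
      bind_rows(rows),
      layout_from_lengths(unlist(t_lens)),
      layout_from_lengths(unlist(q_lens))
    )
  }
  set_layouts(
    aln,
    reconcile_layout(target_layout(aln), target_layout, "target"),
    reconcile_layout(query_layout(aln), query_layout, "query")
  )
}
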
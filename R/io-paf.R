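#' Read a PAF alignment file into an alignment set
#'
#' PAF is the primary alignment dialect of the package: minimal, line
#' oriented, already 0-based half-open.  Columns 1-4 describe the query
#' interval, 5 the relative strand, 6-9 the target interval; chromosome
#' lengths are taken from columns 2 and 7 and cross-checked against supplied
#' layouts when given (a mismatch is an error).
#'
#' @param path Path to a PAF file (12 or more tab-separated columns).
#' @param target_layout,query_layout Optional `genome_layout` objects used to
#'   cross-check (and extend, e.g. with arm classes) the inferred layouts.
#' @return An `alignment_set`.
#' @export
read_paf <- function(path, target_layout = NULL, query_layout = NULL) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    aln <- alignment_set(empty_blocks())
  } else {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 12L)) {
      bad <- which(nf < 12L)[[1]]
      stop_parse(paste0(
        "malformed PAF line ", bad, ": expected >= 12 columns, found ",
        nf[[bad]]
      ))
    }
    m <- matrix(unlist(lapply(fields, `[`, 1:12)), ncol = 12, byrow = TRUE)
    num <- function(j) {
      v <- suppressWarnings(as.numeric(m[, j]))
      if (anyNA(v)) {
        stop_parse(paste0(
          "malformed PAF line ", which(is.na(v))[[1]],
          ": non-numeric value in column ", j
        ))
      }
      v
    }
    blocks <- tibble(
      block_id = seq_along(lines),
      t_chrom = m[, 6], t_start = num(8), t_end = num(9),
      q_chrom = m[, 1], q_start = num(3), q_end = num(4),
      strand = m[, 5]
    )
    t_layout <- layout_from_first(m[, 6], num(7))
    q_layout <- layout_from_first(m[, 1], num(2))
    aln <- alignment_set(blocks, t_layout, q_layout)
  }
  aln <- set_layouts(
    aln,
    reconcile_layout(target_layout(aln), target_layout, "target"),
    reconcile_layout(query_layout(aln), query_layout, "query")
  )
  aln
}

empty_blocks <- function() {
  tibble(
    block_id = integer(), t_chrom = character(), t_start = numeric(),
    t_end = numeric(), q_chrom = character(), q_start = numeric(),
    q_end = numeric(), strand = character()
  )
}

# Per-chromosome lengths from repeated (name, length) columns; inconsistent
# lengths across lines are a parse error.
layout_from_first <- function(chrom, len) {
  tab <- distinct(tibble(chrom = chrom, length = len))
  if (anyDuplicated(tab$chrom)) {
    dup <- tab$chrom[duplicated(tab$chrom)][[1]]
    stop_parse(paste0(
      "inconsistent chromosome length for ", dup, " across PAF lines"
    ))
  }
  layout_from_lengths(setNames(tab$length, tab$chrom))
}

set_layouts <- function(aln, t_layout, q_layout) {
  attr(aln, "target_layout") <- t_layout
  attr(aln, "query_layout") <- q_layout
  aln
}

#' Write an alignment set as PAF
#'
#' Blocks are written in deterministic (target chromosome, start) order.  The
#' residue-match and block-length columns are reconstructed from the interval
#' widths (the internal representation does not retain per-base identity).
#'
#' @param aln An `alignment_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_paf <- function(aln, path) {
  b <- arrange(as_tibble(aln), .data$t_chrom, .data$t_start)
  t_len <- chrom_lengths(target_layout(aln))
  q_len <- chrom_lengths(query_layout(aln))
  tw <- b$t_end - b$t_start
  qw <- b$q_end - b$q_start
  lines <- paste(
    b$q_chrom, fmt_int(q_len[b$q_chrom]), fmt_int(b$q_start),
    fmt_int(b$q_end), b$strand,
    b$t_chrom, fmt_int(t_len[b$t_chrom]), fmt_int(b$t_start),
    fmt_int(b$t_end),
    fmt_int(pmin(tw, qw)), fmt_int(pmax(tw, qw)), "255",
    sep = "\t"
  )
  readr::write_lines(lines, path)
  invisible(path)
}
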
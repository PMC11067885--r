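#' Read gene models from a GFF3 annotation
#'
#' Parses `gene`/`mRNA`/`exon` records (exons may be children of genes
#' directly or via an mRNA) and converts the 1-based inclusive GFF3
#' convention to the package's 0-based half-open convention.  Introns are
#' derived as the gaps between consecutive exons of a gene.
#'
#' @param path Path to a GFF3 file.
#' @return A `gene_annotation` list with tibbles `genes` (`gene_id`, `chrom`,
#'   `start`, `end`, `strand`), `exons` and `introns` (`gene_id`, `chrom`,
#'   `start`, `end`).
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  d <- as.data.frame(gr, stringsAsFactors = FALSE)
  d <- as_tibble(d)
  d$seqnames <- as.character(d$seqnames)
  d$strand <- as.character(d$strand)
  d$type <- as.character(d$type)
  d$ID <- if ("ID" %in% names(d)) as.character(d$ID) else NA_character_
  d$Parent <- if ("Parent" %in% names(d)) {
    vapply(d$Parent, function(p) {
      if (length(p) == 0) NA_character_ else as.character(p[[1]])
    }, character(1))
  } else {
    NA_character_
  }
  # Back to 0-based half-open: GFF3 columns 4-5 are 1-based inclusive.
  d$start0 <- d$start - 1
  d$end0 <- d$end

  genes <- filter(d, .data$type == "gene")
  if (nrow(genes) == 0) {
    stop_parse("no gene records found in GFF3")
  }
  gene_tbl <- tibble(
    gene_id = genes$ID, chrom = genes$seqnames,
    start = genes$start0, end = genes$end0, strand = genes$strand
  )
  if (anyNA(gene_tbl$gene_id)) {
    stop_parse("gene record without an ID attribute")
  }

  mrna <- filter(d, .data$type == "mRNA")
  mrna_gene <- setNames(mrna$Parent, mrna$ID)

  exons <- filter(d, .data$type == "exon")
  exon_gene <- exons$Parent
  via_mrna <- exon_gene %in% names(mrna_gene)
  exon_gene[via_mrna] <- mrna_gene[exon_gene[via_mrna]]
  exon_tbl <- tibble(
    gene_id = exon_gene, chrom = exons$seqnames,
    start = exons$start0, end = exons$end0
  )
  orphan <- setdiff(unique(exon_tbl$gene_id), gene_tbl$gene_id)
  if (length(orphan)) {
    stop_validation(paste0(
      "exons with unknown parent gene: ", paste(orphan, collapse = ", ")
    ))
  }
  exon_tbl <- arrange(exon_tbl, .data$gene_id, .data$start)

  gene_span <- gene_tbl
  ex_check <- left_join(exon_tbl,
                        rename(gene_span, g_start = "start", g_end = "end"),
                        by = c("gene_id", "chrom"))
  if (anyNA(ex_check$g_start)) {
    stop_validation("exon on a different chromosome than its parent gene")
  }
  if (any(ex_check$start < ex_check$g_start | ex_check$end > ex_check$g_end)) {
    bad <- ex_check$gene_id[
      which(ex_check$start < ex_check$g_start |
              ex_check$end > ex_check$g_end)[[1]]
    ]
    stop_validation(paste0("exon outside the span of its parent gene ", bad))
  }

  introns <- derive_introns(exon_tbl)
  structure(
    list(genes = gene_tbl, exons = exon_tbl, introns = introns),
    class = "gene_annotation"
  )
}

# Gaps between consecutive exons of each gene, in genome-forward order.
derive_introns <- function(exon_tbl) {
  exon_tbl <- arrange(exon_tbl, .data$gene_id, .data$start)
  g <- group_by(exon_tbl, .data$gene_id, .data$chrom)
  out <- dplyr::reframe(
    g,
    intron_start = .data$end[-dplyr::n()],
    intron_end = .data$start[-1]
  )
  out <- filter(out, .data$intron_end > .data$intron_start)
  tibble(gene_id = out$gene_id, chrom = out$chrom,
         start = out$intron_start, end = out$intron_end)
}

#' Write gene models as GFF3
#'
#' Emits `gene`, `mRNA` and `exon` records (one mRNA per gene) in 1-based
#' inclusive GFF3 coordinates, ordered by (chromosome, start).
#'
#' @param annotation A `gene_annotation`, or a list with `genes` and `exons`
#'   tibbles in package coordinates.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(annotation, path) {
  genes <- arrange(annotation$genes, .data$chrom, .data$start)
  exons <- arrange(annotation$exons, .data$gene_id, .data$start)
  ex_split <- split(exons, exons$gene_id)
  gene_line <- function(g) {
    paste(g$chrom, "scramblr", "gene", fmt_int(g$start + 1), fmt_int(g$end),
          ".", g$strand, ".", paste0("ID=", g$gene_id), sep = "\t")
  }
  lines <- character(0)
  out <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    mrna_id <- paste0(g$gene_id, ".t1")
    ex <- ex_split[[g$gene_id]]
    ex_lines <- if (is.null(ex)) character(0) else {
      paste(ex$chrom, "scramblr", "exon", fmt_int(ex$start + 1),
            fmt_int(ex$end), ".", g$strand, ".",
            paste0("ID=", mrna_id, ".exon", seq_len(nrow(ex)),
                   ";Parent=", mrna_id),
            sep = "\t")
    }
    out[[i]] <- c(
      gene_line(g),
      paste(g$chrom, "scramblr", "mRNA", fmt_int(g$start + 1),
            fmt_int(g$end), ".", g$strand, ".",
            paste0("ID=", mrna_id, ";Parent=", g$gene_id), sep = "\t"),
      ex_lines
    )
  }
  readr::write_lines(c("##gff-version 3", unlist(out)), path)
  invisible(path)
}

#' Feature tracks: named interval sets
#'
#' A feature track is a named tibble of genomic intervals (repeats, conserved
#' noncoding elements, exons, introns, operon spans, ...) used by the overlap
#' and boundary-enrichment analyses.
#'
#' @param name Track name.
#' @param intervals Data frame with columns `chrom`, `start`, `end`.
#' @param layout Optional `genome_layout` used to validate the intervals.
#' @return A `feature_track` tibble with columns `chrom`, `start`, `end` and
#'   a `track_name` attribute.
#' @export
feature_track <- function(name, intervals, layout = NULL) {
  x <- as_tibble(intervals)[, c("chrom", "start", "end")]
  x$chrom <- as.character(x$chrom)
  if (any(x$end < x$start)) {
    stop_validation("feature intervals must have end >= start")
  }
  if (!is.null(layout)) {
    lens <- chrom_lengths(layout)
    unknown <- setdiff(unique(x$chrom), names(lens))
    if (length(unknown)) {
      stop_validation(paste0(
        "features on chromosome(s) absent from layout: ",
        paste(unknown, collapse = ", ")
      ))
    }
    if (any(x$start < 0 | x$end > lens[x$chrom])) {
      stop_validation("feature interval outside its chromosome")
    }
  }
  x <- arrange(x, .data$chrom, .data$start, .data$end)
  structure(x, track_name = name,
            class = c("feature_track", class(tibble())))
}

track_name <- function(x) attr(x, "track_name") %||% "track"

#' Write a feature track or segmentation as BED4
#'
#' Intervals are written 0-based half-open in deterministic (chromosome,
#' start) order.  For a segmentation, the name column holds the region class
#' and zero-width breakpoints are written as zero-length features.  An empty
#' track produces a file holding only a header comment.
#'
#' @param x A `feature_track` or `segmentation`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  if (inherits(x, "segmentation")) {
    d <- as_tibble(x)[, c("chrom", "start", "end", "class")]
    names(d)[4] <- "name"
    header <- "# scramblr segmentation: BED4, 0-based half-open"
  } else {
    d <- as_tibble(x)[, c("chrom", "start", "end")]
    d$name <- track_name(x)
    header <- paste0("# scramblr track '", track_name(x),
                     "': BED4, 0-based half-open")
  }
  d <- arrange(d, .data$chrom, .data$start, .data$end)
  lines <- paste(d$chrom, fmt_int(d$start), fmt_int(d$end), d$name,
                 sep = "\t")
  readr::write_lines(c(header, lines), path)
  invisible(path)
}
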
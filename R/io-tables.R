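#' Read a gene-to-orthogroup assignment table
#'
#' The ortholog map records, for every gene of every genome, its hierarchical
#' orthogroup (HOG, fine-grained, near one-to-one) and its orthogroup (OG,
#' gene-family level) as produced by orthology inference.  Either assignment
#' may be missing (empty field).
#'
#' @param path TSV with header `genome_id  gene_id  hog_id  og_id`.
#' @return An `ortholog_map` tibble.
#' @export
read_ortholog_table <- function(path) {
  x <- readr::read_tsv(
    path, show_col_types = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  as_ortholog_map(x)
}

#' @rdname read_ortholog_table
#' @param x A data frame with columns `genome_id`, `gene_id`, `hog_id`,
#'   `og_id`.
#' @export
as_ortholog_map <- function(x) {
  x <- as_tibble(x)
  needed <- c("genome_id", "gene_id", "hog_id", "og_id")
  if (!all(needed %in% names(x))) {
    stop_validation("ortholog table needs columns genome_id, gene_id, hog_id, og_id")
  }
  x <- x[, needed]
  if (anyDuplicated(x[, c("genome_id", "gene_id")])) {
    dup <- x[duplicated(x[, c("genome_id", "gene_id")]), ]
    stop_validation(paste0(
      "duplicated (genome, gene) row in ortholog table: ",
      dup$genome_id[[1]], "/", dup$gene_id[[1]]
    ))
  }
  structure(x, class = c("ortholog_map", class(tibble())))
}

#' Write an ortholog map as TSV
#' @param map An `ortholog_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ortholog_table <- function(map, path) {
  readr::write_tsv(as_tibble(map), path)
  invisible(path)
}

#' Extract single-copy ortholog pairs between two genomes
#'
#' A single-copy pair comes from an orthogroup (at the chosen granularity)
#' containing exactly one gene in each of the two genomes; each gene of
#' either genome therefore appears in at most one pair.
#'
#' @param map An `ortholog_map`.
#' @param genome_a,genome_b Genome identifiers as used in the map.
#' @param granularity `"hog"` (default) or `"og"`.
#' @return A tibble with columns `group_id`, `gene_a`, `gene_b`.
#' @export
single_copy_pairs <- function(map, genome_a, genome_b,
                              granularity = c("hog", "og")) {
  granularity <- match.arg(granularity)
  col <- paste0(granularity, "_id")
  d <- filter(as_tibble(map), .data$genome_id %in% c(genome_a, genome_b),
              !is.na(.data[[col]]))
  d$group_id <- d[[col]]
  counts <- d |>
    group_by(.data$group_id) |>
    summarise(
      n_a = sum(.data$genome_id == genome_a),
      n_b = sum(.data$genome_id == genome_b),
      .groups = "drop"
    ) |>
    filter(.data$n_a == 1L, .data$n_b == 1L)
  d <- filter(d, .data$group_id %in% counts$group_id)
  a <- filter(d, .data$genome_id == genome_a)[, c("group_id", "gene_id")]
  b <- filter(d, .data$genome_id == genome_b)[, c("group_id", "gene_id")]
  out <- left_join(rename(a, gene_a = "gene_id"),
                   rename(b, gene_b = "gene_id"), by = "group_id")
  arrange(out, .data$group_id)
}

#' Read a per-gene dN/dS table
#'
#' dN/dS values (ratio of nonsynonymous to synonymous substitution rates, a
#' proxy for selective constraint) are consumed as an input table; the
#' package performs no codon-model estimation.
#'
#' @param path TSV with header `gene_id  dnds`.
#' @return A tibble with columns `gene_id`, `dnds`.
#' @export
read_dnds_table <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         gene_id = readr::col_character(),
                         dnds = readr::col_double()
                       ))
  if (!all(c("gene_id", "dnds") %in% names(x))) {
    stop_validation("dN/dS table needs columns gene_id and dnds")
  }
  as_tibble(x)
}
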
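#' Genome layout: chromosome lengths, centromeres and arm classes
#'
#' A genome layout is a tibble with one row per chromosome arm (or one row per
#' chromosome when no arm annotation is available) describing the coordinate
#' system of one genome.  All coordinates are 0-based half-open base offsets.
#'
#' Arm classes follow the conventions used for compact tunicate genomes with
#' few, arm-structured chromosomes: `short` and `long` autosomal arms, the
#' pseudoautosomal region `PAR`, the sex-specific regions `XSR`/`YSR`, and
#' `unassigned`.
#'
#' @param chrom Character vector of chromosome names.
#' @param length Integer-ish vector of chromosome lengths in bases (repeated
#'   across the rows of one chromosome).
#' @param centromere Optional centromere midpoint offset per row (`NA` if
#'   unknown).
#' @param arm_name,arm_start,arm_end,arm_class Optional arm annotation
#'   columns; `NA` when the chromosome carries no arm annotation.
#'
#' @return A `genome_layout` tibble with columns `chrom`, `length`,
#'   `centromere`, `arm_name`, `arm_start`, `arm_end`, `arm_class`.
#' @examples
#' genome_layout(
#'   chrom = c("chr1", "chr1"), length = 2e6,
#'   centromere = 6e5,
#'   arm_name = c("1S", "1L"),
#'   arm_start = c(0, 6e5), arm_end = c(6e5, 2e6),
#'   arm_class = c("short", "long")
#' )
#' @export
genome_layout <- function(chrom, length, centromere = NA_real_,
                          arm_name = NA_character_, arm_start = NA_real_,
                          arm_end = NA_real_, arm_class = NA_character_) {
  x <- tibble(
    chrom = as.character(chrom),
    length = as.numeric(length),
    centromere = as.numeric(centromere),
    arm_name = as.character(arm_name),
    arm_start = as.numeric(arm_start),
    arm_end = as.numeric(arm_end),
    arm_class = as.character(arm_class)
  )
  as_genome_layout(x)
}

arm_classes <- c("short", "long", "PAR", "XSR", "YSR", "unassigned")

#' Coerce a data frame to a genome layout, validating its invariants
#'
#' @param x A data frame with at least columns `chrom` and `length`; optional
#'   columns `centromere`, `arm_name`, `arm_start`, `arm_end`, `arm_class`.
#' @return A validated `genome_layout` tibble.
#' @export
as_genome_layout <- function(x) {
  x <- as_tibble(x)
  if (!all(c("chrom", "length") %in% names(x))) {
    stop_validation("a genome layout needs `chrom` and `length` columns")
  }
  for (col in c("centromere", "arm_start", "arm_end")) {
    if (!col %in% names(x)) x[[col]] <- NA_real_
  }
  for (col in c("arm_name", "arm_class")) {
    if (!col %in% names(x)) x[[col]] <- NA_character_
  }
  x <- x[, c("chrom", "length", "centromere", "arm_name", "arm_start",
             "arm_end", "arm_class")]
  x$chrom <- as.character(x$chrom)
  validate_genome_layout(x)
  x <- arrange(x, .data$chrom, .data$arm_start)
  structure(x, class = c("genome_layout", class(tibble())))
}

validate_genome_layout <- function(x) {
  len <- distinct(x, .data$chrom, .data$length)
  if (anyDuplicated(len$chrom)) {
    stop_validation("inconsistent lengths for a chromosome in layout")
  }
  if (any(len$length <= 0)) {
    stop_validation("chromosome lengths must be positive")
  }
  ann <- filter(x, !is.na(.data$arm_name))
  if (nrow(ann) > 0) {
    if (anyDuplicated(ann[, c("chrom", "arm_name")])) {
      stop_validation("duplicated (chrom, arm_name) in layout")
    }
    bad_class <- setdiff(unique(ann$arm_class), arm_classes)
    if (length(bad_class)) {
      stop_validation(paste0(
        "unknown arm_class: ", paste(bad_class, collapse = ", ")
      ))
    }
    if (any(is.na(ann$arm_start) | is.na(ann$arm_end))) {
      stop_validation("annotated arms must have arm_start and arm_end")
    }
    if (any(ann$arm_start < 0 | ann$arm_end > ann$length |
              ann$arm_start >= ann$arm_end)) {
      stop_validation("arm intervals must satisfy 0 <= start < end <= length")
    }
    split_arms <- split(ann, ann$chrom)
    for (a in split_arms) {
      a <- a[order(a$arm_start), ]
      if (nrow(a) > 1 && any(a$arm_end[-nrow(a)] > a$arm_start[-1])) {
        stop_validation(paste0("overlapping arms on ", a$chrom[[1]]))
      }
    }
  }
  invisible(x)
}

#' Build a minimal layout from named chromosome lengths
#'
#' @param lengths Named numeric vector of chromosome lengths.
#' @return A `genome_layout` with no centromere or arm annotation.
#' @export
layout_from_lengths <- function(lengths) {
  if (is.null(names(lengths)) || any(names(lengths) == "")) {
    stop_validation("`lengths` must be a fully named vector")
  }
  genome_layout(chrom = names(lengths), length = unname(lengths))
}

#' Named vector of chromosome lengths in a layout
#'
#' @param layout A `genome_layout`.
#' @return Named numeric vector.
#' @export
chrom_lengths <- function(layout) {
  len <- distinct(layout, .data$chrom, .data$length)
  setNames(len$length, len$chrom)
}

# Arm annotation rows only, or NULL when the layout has none.
layout_arms <- function(layout) {
  ann <- filter(layout, !is.na(.data$arm_name))
  if (nrow(ann) == 0) NULL else ann
}

#' Read / write a genome layout TSV
#'
#' The layout file is a TSV with header
#' `chrom  length  centromere  arm_name  arm_start  arm_end  arm_class`;
#' empty fields denote missing annotation.
#'
#' @param path File path.
#' @return `read_layout()` returns a `genome_layout`; `write_layout()`
#'   invisibly returns `path`.
#' @export
read_layout <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         chrom = readr::col_character(),
                         length = readr::col_double(),
                         centromere = readr::col_double(),
                         arm_name = readr::col_character(),
                         arm_start = readr::col_double(),
                         arm_end = readr::col_double(),
                         arm_class = readr::col_character()
                       ))
  as_genome_layout(x)
}

#' @rdname read_layout
#' @param layout A `genome_layout`.
#' @export
write_layout <- function(layout, path) {
  readr::write_tsv(as_tibble(layout), path)
  invisible(path)
}
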
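#' Feature enrichment at segment-class boundaries
#'
#' For every segment class and boundary side, computes at each relative
#' offset in `[-window, +window]` the fraction of boundaries whose position
#' plus offset lies inside a feature of each track.  Position 0 is the
#' boundary base; the orientation is genome-forward (strand-agnostic).  The
#' `start` side anchors at interval left edges, the `stop` side at right
#' edges; a zero-width breakpoint contributes its single position once (to
#' the `start` side).  Offsets falling outside the chromosome are excluded
#' from a boundary's denominator.
#'
#' @param seg A `segmentation`.
#' @param tracks A named list of `feature_track`s (or plain interval tables).
#' @param window Half-window in bases (default 1000).
#' @param step Offset step in bases (default 10).
#' @return An `enrichment_profile` tibble: `class`, `side`, `track`,
#'   `offset`, `fraction`, `n_boundaries`.  Classes without boundaries yield
#'   `NA` fractions.
#' @export
boundary_enrichment <- function(seg, tracks, window = 1000, step = 10) {
  if (window < 1) stop_config("window must be >= 1 base")
  d <- as_tibble(seg)
  lens <- chrom_lengths(segmentation_layout(seg))
  offsets <- seq(-window, window, by = step)
  zero <- d$end == d$start

  anchors <- bind_rows(
    tibble(class = d$class, side = "start", chrom = d$chrom, pos = d$start),
    tibble(class = d$class[!zero], side = "stop", chrom = d$chrom[!zero],
           pos = d$end[!zero])
  )

  if (is.data.frame(tracks)) tracks <- list(track = tracks)
  track_iv <- lapply(tracks, function(tr) {
    tr <- as_tibble(tr)
    merged <- merge_intervals(tr)
    split(merged, merged$chrom)
  })

  grid <- expand.grid(class = segment_classes,
                      side = c("start", "stop"),
                      track = names(tracks),
                      stringsAsFactors = FALSE)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    a <- filter(anchors, as.character(.data$class) == grid$class[[i]],
                .data$side == grid$side[[i]])
    if (nrow(a) == 0) {
      rows[[i]] <- tibble(class = grid$class[[i]], side = grid$side[[i]],
                          track = grid$track[[i]], offset = offsets,
                          fraction = NA_real_, n_boundaries = 0L)
      next
    }
    iv <- track_iv[[grid$track[[i]]]]
    covered <- matrix(FALSE, nrow = nrow(a), ncol = length(offsets))
    valid <- matrix(TRUE, nrow = nrow(a), ncol = length(offsets))
    for (chrom in unique(a$chrom)) {
      sel <- which(a$chrom == chrom)
      pos <- outer(a$pos[sel], offsets, `+`)
      valid[sel, ] <- pos >= 0 & pos < lens[[chrom]]
      ch_iv <- iv[[chrom]]
      if (!is.null(ch_iv) && nrow(ch_iv) > 0) {
        covered[sel, ] <- point_in_intervals(as.vector(pos), ch_iv$start,
                                             ch_iv$end)
      }
    }
    frac <- colSums(covered & valid) / pmax(colSums(valid), 1L)
    frac[colSums(valid) == 0] <- NA_real_
    rows[[i]] <- tibble(class = grid$class[[i]], side = grid$side[[i]],
                        track = grid$track[[i]], offset = offsets,
                        fraction = frac, n_boundaries = nrow(a))
  }
  out <- bind_rows(rows)
  out$class <- factor(out$class, levels = segment_classes)
  structure(out, window = window, step = step,
            class = c("enrichment_profile", class(tibble())))
}

# Union of possibly-overlapping intervals, per chromosome.
merge_intervals <- function(x) {
  x <- arrange(as_tibble(x)[, c("chrom", "start", "end")],
               .data$chrom, .data$start, .data$end)
  if (nrow(x) < 2) return(x)
  out <- x[1, ]
  for (i in 2:nrow(x)) {
    last <- nrow(out)
    if (x$chrom[[i]] == out$chrom[[last]] &&
          x$start[[i]] <= out$end[[last]]) {
      out$end[[last]] <- max(out$end[[last]], x$end[[i]])
    } else {
      out <- bind_rows(out, x[i, ])
    }
  }
  out
}

# TRUE for each point p covered by a sorted set of disjoint half-open
# intervals (s <= p < e).
point_in_intervals <- function(p, start_sorted, end_sorted) {
  idx <- findInterval(p, start_sorted)
  idx > 0 & p < end_sorted[pmax(idx, 1L)]
}

#' Percent-of-chromosome-length binned profile
#'
#' Assigns each element to one of `bins` equal bins of its chromosome's
#' relative length (bin `floor(bins * midpoint / length)`) and averages a
#' named quantity per bin.  With a `genome_id` column, per-genome bin means
#' are computed first and then averaged across genomes (bins are never
#' pooled across genomes).
#'
#' @param quantity A tibble with columns `chrom`, `pos` (element midpoint in
#'   bases), `value`, and optionally `genome_id`.
#' @param layout A `genome_layout` covering every chromosome used (for the
#'   multi-genome case, chromosome lengths per genome must be resolvable;
#'   pass a layout with the union of chromosomes or a `genome_id` column).
#' @param bins Number of bins tiling 0-100% (default 50).
#' @return A `binned_profile` tibble: `bin`, `pct_mid` (bin midpoint in
#'   percent), `mean_value`, `n_elements`.  Empty bins are reported with
#'   `NA` mean.
#' @export
binned_profile <- function(quantity, layout, bins = 50) {
  q <- as_tibble(quantity)
  lens <- chrom_lengths(layout)
  unknown <- setdiff(unique(q$chrom), names(lens))
  if (length(unknown)) {
    stop_validation(paste0(
      "elements on chromosome(s) absent from layout: ",
      paste(unknown, collapse = ", ")
    ))
  }
  if (any(q$pos < 0 | q$pos > lens[q$chrom])) {
    stop_validation("element midpoint beyond chromosome end")
  }
  q$bin <- pmin(floor(bins * q$pos / lens[q$chrom]), bins - 1)
  if (!"genome_id" %in% names(q)) q$genome_id <- "genome"
  per_genome <- q |>
    group_by(.data$genome_id, .data$bin) |>
    summarise(mean_value = mean(.data$value), n_elements = n(),
              .groups = "drop")
  out <- per_genome |>
    group_by(.data$bin) |>
    summarise(mean_value = mean(.data$mean_value),
              n_elements = sum(.data$n_elements), .groups = "drop")
  full <- left_join(tibble(bin = 0:(bins - 1)), out, by = "bin")
  full$n_elements[is.na(full$n_elements)] <- 0L
  full$pct_mid <- (full$bin + 0.5) * 100 / bins
  full <- full[, c("bin", "pct_mid", "mean_value", "n_elements")]
  structure(full, bins = bins,
            class = c("binned_profile", class(tibble())))
}

#' Pairwise arm-class comparisons of a per-element quantity
#'
#' Two-sided Wilcoxon rank-sum tests between every pair of occupied arm
#' classes (short vs long, short vs XSR, long vs XSR, ...).  Classes with
#' fewer than two elements are skipped with a notice.
#'
#' @param values A tibble with columns `arm_class`, `value`.
#' @param classes Arm classes to compare (default `short`, `long`, `XSR`).
#' @return An `arm_compare` tibble: `class_a`, `class_b`, `n_a`, `n_b`,
#'   `median_a`, `median_b`, `statistic`, `p_value`, `skipped`.
#' @export
arm_class_compare <- function(values, classes = c("short", "long", "XSR")) {
  v <- filter(as_tibble(values), .data$arm_class %in% classes)
  present <- intersect(classes, unique(v$arm_class))
  if (length(present) < 2) {
    stop_domain("fewer than two occupied arm classes: nothing to compare")
  }
  pairs <- utils::combn(present, 2)
  rows <- vector("list", ncol(pairs))
  for (i in seq_len(ncol(pairs))) {
    a <- v$value[v$arm_class == pairs[1, i]]
    b <- v$value[v$arm_class == pairs[2, i]]
    skipped <- length(a) < 2 || length(b) < 2
    if (skipped) {
      notify(paste0("arm class with < 2 elements: skipping ",
                    pairs[1, i], " vs ", pairs[2, i]))
      stat <- p <- NA_real_
    } else {
      wt <- stats::wilcox.test(a, b, alternative = "two.sided")
      stat <- unname(wt$statistic)
      p <- wt$p.value
    }
    rows[[i]] <- tibble(
      class_a = pairs[1, i], class_b = pairs[2, i],
      n_a = length(a), n_b = length(b),
      median_a = ifelse(length(a), stats::median(a), NA_real_),
      median_b = ifelse(length(b), stats::median(b), NA_real_),
      statistic = stat, p_value = p, skipped = skipped
    )
  }
  structure(bind_rows(rows), class = c("arm_compare", class(tibble())))
}

#' Gene-breakpoint overlap rates by arm class
#'
#' Counts genes overlapping / not overlapping breakpoint regions per arm
#' class and tests independence of overlap status and arm class with a
#' chi-squared test on the resulting table (df = occupied classes - 1).
#' Genes are assigned to arms by their midpoint; genes outside any annotated
#' arm are dropped.
#'
#' @param genes Gene table (`gene_id`, `chrom`, `start`, `end`).
#' @param seg A `segmentation` on the same genome.
#' @param layout A `genome_layout` with arm annotation.
#' @param classes Arm classes to include (default `short`, `long`, `XSR`).
#' @return An `arm_rate_test` list: `table` tibble (`arm_class`,
#'   `n_overlapping`, `n_not`, `rate`), `test` (an `htest`, or `NULL` with a
#'   notice when degenerate).
#' @export
gene_breakpoint_rate_by_arm <- function(genes, seg, layout,
                                        classes = c("short", "long", "XSR")) {
  arms <- layout_arms(layout)
  if (is.null(arms)) {
    stop_config("gene_breakpoint_rate_by_arm requires arm annotations")
  }
  g <- as_tibble(genes)
  g$mid <- (g$start + g$end) / 2
  arms <- filter(arms, .data$arm_class %in% classes)
  g$arm_class <- NA_character_
  for (i in seq_len(nrow(arms))) {
    sel <- g$chrom == arms$chrom[[i]] & g$mid >= arms$arm_start[[i]] &
      g$mid < arms$arm_end[[i]]
    g$arm_class[sel] <- arms$arm_class[[i]]
  }
  g <- filter(g, !is.na(.data$arm_class))
  if (nrow(g) == 0) stop_domain("no genes fall inside the requested arms")
  g$hit <- overlaps_breakpoints(g, breakpoint_regions(seg))
  tab <- g |>
    group_by(arm_class = .data$arm_class) |>
    summarise(n_overlapping = sum(.data$hit), n_not = sum(!.data$hit),
              .groups = "drop") |>
    mutate(rate = .data$n_overlapping /
             (.data$n_overlapping + .data$n_not))
  test <- NULL
  m <- as.matrix(tab[, c("n_overlapping", "n_not")])
  occupied <- rowSums(m) > 0
  m <- m[occupied, , drop = FALSE]
  if (nrow(m) >= 2 && all(colSums(m) > 0)) {
    test <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  } else {
    notify("degenerate table: chi-squared test not run")
  }
  structure(list(table = tab, test = test),
            class = "arm_rate_test")
}
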
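# Genome state machinery: a sim_genome represents each chromosome as an
# ordered run of ancestral segments (anc_chrom, anc_start, anc_end, strand,
# copy_id).  Rearrangements splice this run; genes, exons and repeats are
# projected through it on demand.  Event cut points are sampled in intergenic
# space, so genes are never split and ortholog bookkeeping stays exact.

empty_event_log <- function() {
  tibble(
    branch = character(), event_id = integer(), type = character(),
    chrom = character(), start = numeric(), end = numeric(),
    dest_chrom = character(), dest_pos = numeric(), scope = character(),
    resamples = integer(), flank = logical()
  )
}

seg_widths <- function(segtab) segtab$anc_end - segtab$anc_start

seg_cur_starts <- function(segtab) {
  w <- seg_widths(segtab)
  cumsum(c(0, w))[seq_along(w)]
}

chrom_length_of <- function(state, chrom) sum(seg_widths(state$segs[[chrom]]))

#' Current chromosome lengths, arms and centromeres of a simulated genome
#'
#' @param state A `sim_genome`.
#' @return A `genome_layout` in the genome's current coordinates.
#' @export
state_layout <- function(state) {
  lens <- vapply(state$segs, function(s) sum(seg_widths(s)), numeric(1))
  arms <- state$arms
  cen <- setNames(state$centromeres$centromere, state$centromeres$chrom)
  genome_layout(
    chrom = arms$chrom, length = unname(lens[arms$chrom]),
    centromere = unname(cen[arms$chrom]),
    arm_name = arms$arm_name, arm_start = arms$start, arm_end = arms$end,
    arm_class = arms$arm_class
  )
}

# Split the segment run of a chromosome so that a boundary exists at pos.
split_chrom_at <- function(segtab, pos) {
  starts <- seg_cur_starts(segtab)
  w <- seg_widths(segtab)
  i <- findInterval(pos, starts)
  if (i == 0 || pos == starts[[i]] || pos >= starts[[i]] + w[[i]]) {
    return(segtab)   # boundary already present (or at chromosome end)
  }
  off <- pos - starts[[i]]
  row <- segtab[i, ]
  if (row$strand == "+") {
    left <- mutate(row, anc_end = row$anc_start + off)
    right <- mutate(row, anc_start = row$anc_start + off)
  } else {
    left <- mutate(row, anc_start = row$anc_end - off)
    right <- mutate(row, anc_end = row$anc_end - off)
  }
  bind_rows(segtab[seq_len(i - 1L), ], left, right,
            segtab[seq_len(nrow(segtab))[-seq_len(i)], ])
}

# Row indices of segments lying within [s, e) after boundaries exist there.
rows_in_span <- function(segtab, s, e) {
  starts <- seg_cur_starts(segtab)
  ends <- starts + seg_widths(segtab)
  which(starts >= s & ends <= e)
}

# Anchor (single position) transforms for each operation, used to keep arm
# boundaries and centromeres in the current coordinate system.
anchor_invert <- function(pos, s, e) {
  inside <- pos > s & pos < e
  pos[inside] <- s + e - pos[inside]
  pos
}

anchor_delete <- function(pos, s, e) {
  pos[pos > s & pos < e] <- s
  pos[pos >= e] <- pos[pos >= e] - (e - s)
  pos
}

anchor_insert <- function(pos, p, w) {
  pos[pos > p] <- pos[pos > p] + w
  pos
}

apply_anchor <- function(.state, .chrom, .f, ...) {
  # formals are dotted so that anchor arguments passed by name (s, e, p, w)
  # can never partially match them
  sel <- .state$arms$chrom == .chrom
  .state$arms$start[sel] <- .f(.state$arms$start[sel], ...)
  .state$arms$end[sel] <- .f(.state$arms$end[sel], ...)
  cs <- .state$centromeres$chrom == .chrom &
    !is.na(.state$centromeres$centromere)
  .state$centromeres$centromere[cs] <-
    .f(.state$centromeres$centromere[cs], ...)
  .state
}

#' Apply one recorded rearrangement event to a simulated genome
#'
#' Deterministic: used both by [evolve()] (after sampling the event) and by
#' [replay_events()].  Coordinates are in the genome's pre-event coordinate
#' system.  Inversions flip strand and reverse the order of contained
#' segments; translocations cut and paste; duplications copy with a fresh
#' copy identifier; deletions remove sequence.
#'
#' @param state A `sim_genome`.
#' @param ev One-row tibble with columns as in the event log.
#' @return The updated `sim_genome`.
#' @export
apply_event <- function(state, ev) {
  chrom <- ev$chrom
  s <- ev$start; e <- ev$end
  segtab <- split_chrom_at(split_chrom_at(state$segs[[chrom]], s), e)
  idx <- rows_in_span(segtab, s, e)

  if (ev$type == "inversion") {
    inv <- segtab[rev(idx), ]
    inv$strand <- ifelse(inv$strand == "+", "-", "+")
    segtab[idx, ] <- inv
    state$segs[[chrom]] <- segtab
    state <- apply_anchor(state, chrom, anchor_invert, s = s, e = e)
  } else if (ev$type == "deletion") {
    state$segs[[chrom]] <- segtab[-idx, ]
    state <- apply_anchor(state, chrom, anchor_delete, s = s, e = e)
  } else if (ev$type == "translocation") {
    moved <- segtab[idx, ]
    state$segs[[chrom]] <- segtab[-idx, ]
    state <- apply_anchor(state, chrom, anchor_delete, s = s, e = e)
    p <- ev$dest_pos
    if (ev$dest_chrom == chrom) p <- anchor_delete(p, s, e)
    state <- insert_segments(state, ev$dest_chrom, p, moved)
  } else if (ev$type == "duplication") {
    copy <- segtab[idx, ]
    copy$copy_id <- state$next_copy
    state$next_copy <- state$next_copy + 1L
    state$segs[[chrom]] <- segtab
    state <- insert_segments(state, ev$dest_chrom, ev$dest_pos, copy)
  } else {
    stop_config(paste0("unknown event type: ", ev$type))
  }
  state$event_log <- bind_rows(state$event_log, ev)
  state
}

insert_segments <- function(state, chrom, p, rows) {
  segtab <- split_chrom_at(state$segs[[chrom]], p)
  starts <- seg_cur_starts(segtab)
  at <- sum(starts < p)   # number of rows entirely left of p
  n <- nrow(segtab)
  state$segs[[chrom]] <- bind_rows(
    segtab[seq_len(at), ], rows,
    if (at < n) segtab[(at + 1L):n, ]
  )
  apply_anchor(state, chrom, anchor_insert, p = p,
               w = sum(seg_widths(rows)))
}

#' Project gene models into a simulated genome's current coordinates
#'
#' Every ancestral gene wholly contained in a segment maps into that
#' segment's current interval; minus-strand segments flip gene strand and
#' reverse gene order.  Genes on duplicated segments receive suffixed ids
#' (`_c<copy>`).  Genes in deleted material are absent.
#'
#' @param state A `sim_genome`.
#' @return A tibble `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `ancestral_id`, `copy_id`.
#' @export
genome_genes <- function(state) {
  project_intervals(state, state$genes, id_col = "gene_id",
                    with_strand = TRUE)
}

#' @export
genome_exons <- function(state) {
  ex <- state$exons
  ex$strand <- "+"
  out <- project_intervals(state, mutate(ex, row_id = paste0(
    .data$gene_id, "#", seq_len(nrow(ex))
  )), id_col = "row_id", with_strand = FALSE)
  out$gene_id <- sub("#.*$", "", out$ancestral_id)
  key <- out$copy_id > 0L
  out$gene_id[key] <- paste0(out$gene_id[key], "_c", out$copy_id[key])
  out[, c("gene_id", "chrom", "start", "end")]
}

# Whole-interval projection (no splitting): intervals must never straddle a
# segment boundary (guaranteed for genes/exons by intergenic cut sampling).
project_intervals <- function(state, iv, id_col, with_strand) {
  rows <- list()
  for (chrom in names(state$segs)) {
    segtab <- state$segs[[chrom]]
    if (nrow(segtab) == 0) next
    starts <- seg_cur_starts(segtab)
    for (i in seq_len(nrow(segtab))) {
      seg <- segtab[i, ]
      sel <- iv$chrom == seg$anc_chrom & iv$start >= seg$anc_start &
        iv$end <= seg$anc_end
      if (!any(sel)) next
      g <- iv[sel, ]
      if (seg$strand == "+") {
        g_start <- starts[[i]] + (g$start - seg$anc_start)
        g_end <- starts[[i]] + (g$end - seg$anc_start)
        g_strand <- if (with_strand) g$strand else NULL
      } else {
        g_start <- starts[[i]] + (seg$anc_end - g$end)
        g_end <- starts[[i]] + (seg$anc_end - g$start)
        g_strand <- if (with_strand) ifelse(g$strand == "+", "-", "+") else NULL
      }
      ids <- g[[id_col]]
      new_ids <- if (seg$copy_id > 0L) {
        paste0(ids, "_c", seg$copy_id)
      } else {
        ids
      }
      row <- tibble(chrom = chrom, start = g_start, end = g_end,
                    ancestral_id = ids, copy_id = seg$copy_id)
      row[[id_col]] <- new_ids
      if (with_strand) row$strand <- g_strand
      rows[[length(rows) + 1L]] <- row
    }
  }
  if (length(rows) == 0) {
    out <- tibble(chrom = character(), start = numeric(), end = numeric(),
                  ancestral_id = character(), copy_id = integer())
    out[[id_col]] <- character(0)
    if (with_strand) out$strand <- character(0)
  } else {
    out <- bind_rows(rows)
  }
  cols <- c(id_col, "chrom", "start", "end",
            if (with_strand) "strand", "ancestral_id", "copy_id")
  arrange(out[, cols], .data$chrom, .data$start)
}

# Split-allowed projection for repeats.
project_split_intervals <- function(state, iv) {
  rows <- list()
  for (chrom in names(state$segs)) {
    segtab <- state$segs[[chrom]]
    if (nrow(segtab) == 0) next
    starts <- seg_cur_starts(segtab)
    for (i in seq_len(nrow(segtab))) {
      seg <- segtab[i, ]
      sel <- iv$chrom == seg$anc_chrom & iv$start < seg$anc_end &
        iv$end > seg$anc_start
      if (!any(sel)) next
      g <- iv[sel, ]
      cs <- pmax(g$start, seg$anc_start)
      ce <- pmin(g$end, seg$anc_end)
      if (seg$strand == "+") {
        rows[[length(rows) + 1L]] <- tibble(
          chrom = chrom, start = starts[[i]] + (cs - seg$anc_start),
          end = starts[[i]] + (ce - seg$anc_start)
        )
      } else {
        rows[[length(rows) + 1L]] <- tibble(
          chrom = chrom, start = starts[[i]] + (seg$anc_end - ce),
          end = starts[[i]] + (seg$anc_end - cs)
        )
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  arrange(bind_rows(rows), .data$chrom, .data$start)
}

#' Evolve a descendant genome by sampled rearrangement events
#'
#' Applies `n` rearrangement events drawn from the configured event mix and
#' scope probabilities (94% intra-chromosomal; of those, 99% intra-arm by
#' default).  Event intervals are a configurable fraction of the containing
#' region's length with cut points snapped to intergenic space; events that
#' cannot be placed (e.g. longer than their arm) are resampled, and the
#' resample count is recorded in the event log.  In rate mode
#' (`cfg$n_events` is `NULL`), `n` is drawn as Poisson(`event_rate` x
#' `branch_length`).
#'
#' @param ancestor A `sim_genome` (from [make_ancestral_genome()]).
#' @param cfg The `sim_config`.
#' @param branch_id Character label of the branch (seeds the branch RNG
#'   deterministically together with `cfg$seed`).
#' @param branch_length Branch length in million years (rate mode only).
#' @return The descendant `sim_genome`, with the complete `event_log`.
#' @export
evolve <- function(ancestor, cfg, branch_id, branch_length = NULL) {
  seed <- branch_seed(cfg$seed, branch_id)
  withr::with_seed(seed, evolve_impl(ancestor, cfg, branch_id, branch_length))
}

branch_seed <- function(seed, branch_id) {
  h <- sum(utf8ToInt(branch_id) * seq_along(utf8ToInt(branch_id)))
  as.integer((seed + 104729 * (h %% 10007)) %% 2147483647L)
}

evolve_impl <- function(ancestor, cfg, branch_id, branch_length) {
  state <- ancestor
  state$branch_id <- branch_id
  state$event_log <- empty_event_log()
  n <- cfg$n_events
  if (is.null(n)) {
    if (is.null(cfg$event_rate) || is.null(branch_length)) {
      stop_config("rate mode needs event_rate and branch_length")
    }
    n <- stats::rpois(1, cfg$event_rate * branch_length)
  }
  for (i in seq_len(n)) {
    ev <- sample_event(state, cfg, branch_id, i)
    state <- apply_event(state, ev$event)
    if (cfg$flank_loss > 0) {
      state <- apply_flank_loss(state, cfg, branch_id, i, ev$junctions)
    }
  }
  state
}

sample_event <- function(state, cfg, branch_id, event_id) {
  type <- sample(names(cfg$event_mix), 1, prob = cfg$event_mix)
  lens <- vapply(state$segs, function(s) sum(seg_widths(s)), numeric(1))
  max_resample <- 100L
  for (attempt in 0:max_resample) {
    intra_chrom <- type == "inversion" || runif(1) < cfg$p_intra_chrom
    intra_arm <- runif(1) < cfg$p_intra_arm
    chrom <- sample(names(lens), 1, prob = lens)
    arms_c <- filter(state$arms, .data$chrom == !!chrom)
    if (intra_arm && nrow(arms_c) > 0) {
      a <- arms_c[sample(nrow(arms_c), 1, prob = arms_c$end - arms_c$start), ]
      region <- c(a$start, a$end)
      scope <- "intra_arm"
    } else {
      region <- c(0, lens[[chrom]])
      scope <- "inter_arm"
    }
    gene_iv <- current_gene_intervals(state, chrom)
    span <- try_sample_span(region, gene_iv, cfg$event_len_frac)
    if (is.null(span)) next
    dest_chrom <- NA_character_; dest_pos <- NA_real_
    if (type %in% c("translocation", "duplication")) {
      if (!intra_chrom && length(lens) > 1) {
        dest_chrom <- sample(setdiff(names(lens), chrom), 1)
        scope <- "inter_chrom"
      } else {
        dest_chrom <- chrom
      }
      if (type == "duplication" && runif(1) < 0.5 && dest_chrom == chrom) {
        dest_pos <- span[[2]]   # tandem
      } else {
        dest_iv <- current_gene_intervals(state, dest_chrom)
        dest_region <- if (dest_chrom == chrom && scope == "intra_arm") {
          region
        } else {
          c(0, lens[[dest_chrom]])
        }
        dest_pos <- try_sample_point(dest_region, dest_iv,
                                     forbid = if (dest_chrom == chrom) span)
        if (is.null(dest_pos)) next
      }
    }
    return(list(
      event = tibble(
        branch = branch_id, event_id = event_id, type = type,
        chrom = chrom, start = span[[1]], end = span[[2]],
        dest_chrom = dest_chrom, dest_pos = dest_pos, scope = scope,
        resamples = attempt, flank = FALSE
      ),
      junctions = tibble(
        chrom = c(chrom, chrom), pos = c(span[[1]], span[[2]])
      )
    ))
  }
  stop_config(paste0(
    "could not place a ", type, " event after ", max_resample, " resamples"
  ))
}

current_gene_intervals <- function(state, chrom) {
  g <- genome_genes(state)
  g <- g[g$chrom == chrom, ]
  g[order(g$start), c("start", "end")]
}

# Sample an event interval inside region, snapping both cut points to
# intergenic space; NULL when placement fails.
try_sample_span <- function(region, gene_iv, len_frac) {
  rw <- region[[2]] - region[[1]]
  if (rw < 10) return(NULL)
  len <- round(runif(1, len_frac[[1]], len_frac[[2]]) * rw)
  if (len < 2 || len >= rw) return(NULL)
  s0 <- round(runif(1, region[[1]], region[[2]] - len))
  s <- snap_intergenic(s0, gene_iv, region)
  e <- snap_intergenic(s0 + len, gene_iv, region)
  if (is.null(s) || is.null(e) || e <= s) return(NULL)
  c(s, e)
}

try_sample_point <- function(region, gene_iv, forbid = NULL) {
  for (k in 1:20) {
    p <- snap_intergenic(round(runif(1, region[[1]], region[[2]])), gene_iv,
                         region)
    if (is.null(p)) next
    if (!is.null(forbid) && p > forbid[[1]] && p < forbid[[2]]) next
    return(p)
  }
  NULL
}

# Move a position out of any gene body to the nearest gene edge inside the
# region; NULL when impossible.
snap_intergenic <- function(pos, gene_iv, region) {
  if (nrow(gene_iv) == 0) {
    return(if (pos >= region[[1]] && pos <= region[[2]]) pos else NULL)
  }
  i <- findInterval(pos, gene_iv$start)
  if (i > 0 && pos < gene_iv$end[[i]] && pos > gene_iv$start[[i]]) {
    left <- gene_iv$start[[i]]
    right <- gene_iv$end[[i]]
    pos <- if (pos - left <= right - pos) left else right
  }
  if (pos < region[[1]] || pos > region[[2]]) return(NULL)
  # the snapped point may coincide with an adjacent gene's boundary; gaps are
  # always positive in simulated genomes, so a gene edge is intergenic
  pos
}

apply_flank_loss <- function(state, cfg, branch_id, event_id, junctions) {
  f <- cfg$flank_loss
  for (j in seq_len(nrow(junctions))) {
    chrom <- junctions$chrom[[j]]
    pos <- junctions$pos[[j]]
    gene_iv <- current_gene_intervals(state, chrom)
    len <- chrom_length_of(state, chrom)
    lo <- max(0, pos - f)
    hi <- min(len, pos + f)
    if (nrow(gene_iv) > 0) {
      prev_end <- suppressWarnings(max(gene_iv$end[gene_iv$end <= pos], 0))
      next_start <- suppressWarnings(
        min(gene_iv$start[gene_iv$start >= pos], len)
      )
      lo <- max(lo, prev_end)
      hi <- min(hi, next_start)
    }
    if (hi > lo) {
      ev <- tibble(
        branch = branch_id, event_id = event_id, type = "deletion",
        chrom = chrom, start = lo, end = hi,
        dest_chrom = NA_character_, dest_pos = NA_real_,
        scope = "flank", resamples = 0L, flank = TRUE
      )
      state <- apply_event(state, ev)
    }
  }
  state
}

#' Replay a recorded event log from the ancestor
#'
#' Re-applies every logged event deterministically; the result reproduces
#' the descendant's segment coordinates exactly.
#'
#' @param ancestor The ancestral `sim_genome`.
#' @param log An event-log tibble (see [evolve()]).
#' @return A `sim_genome`.
#' @export
replay_events <- function(ancestor, log) {
  state <- ancestor
  state$event_log <- empty_event_log()
  if (nrow(log) > 0) state$branch_id <- log$branch[[1]]
  for (i in seq_len(nrow(log))) {
    state <- apply_event(state, log[i, ])
  }
  state
}

#' Emit the true one-to-one alignment between two descendants
#'
#' Alignment blocks are the maximal intervals with unbroken common ancestry
#' and consistent relative strand between the two genomes (the first genome
#' is the target).  Deleted material is unaligned; duplicated material
#' aligns only through its designated orthologous copy (the original), so
#' the one-to-one property holds by construction.
#'
#' @param a,b `sim_genome` objects derived from the same ancestor.  Pass the
#'   ancestor itself for an identity comparison.
#' @return An `alignment_set` (target = `a`, query = `b`).
#' @export
emit_alignments <- function(a, b) {
  pa <- anc_pieces(a)
  pb <- anc_pieces(b)
  rows <- list()
  for (ac in intersect(unique(pa$anc_chrom), unique(pb$anc_chrom))) {
    xa <- pa[pa$anc_chrom == ac, ]
    xb <- pb[pb$anc_chrom == ac, ]
    cuts <- sort(unique(c(xa$anc_start, xa$anc_end, xb$anc_start,
                          xb$anc_end)))
    if (length(cuts) < 2) next
    piece_s <- cuts[-length(cuts)]
    piece_e <- cuts[-1]
    ia <- interval_hit(piece_s, piece_e, xa)
    ib <- interval_hit(piece_s, piece_e, xb)
    ok <- !is.na(ia) & !is.na(ib)
    if (!any(ok)) next
    map_piece <- function(x, i, s, e) {
      if (x$strand[[i]] == "+") {
        st <- x$cur_start[[i]] + (s - x$anc_start[[i]])
      } else {
        st <- x$cur_start[[i]] + (x$anc_end[[i]] - e)
      }
      c(st, st + (e - s))
    }
    ma <- t(mapply(function(i, s, e) map_piece(xa, i, s, e),
                   ia[ok], piece_s[ok], piece_e[ok]))
    mb <- t(mapply(function(i, s, e) map_piece(xb, i, s, e),
                   ib[ok], piece_s[ok], piece_e[ok]))
    rows[[length(rows) + 1L]] <- tibble(
      t_chrom = xa$chrom[ia[ok]], t_start = ma[, 1], t_end = ma[, 2],
      q_chrom = xb$chrom[ib[ok]], q_start = mb[, 1], q_end = mb[, 2],
      strand = ifelse(xa$strand[ia[ok]] == xb$strand[ib[ok]], "+", "-")
    )
  }
  blocks <- if (length(rows)) bind_rows(rows) else
    empty_blocks()[, -1]
  blocks <- merge_alignment_blocks(blocks)
  blocks$block_id <- seq_len(nrow(blocks))
  alignment_set(blocks, state_layout(a), state_layout(b))
}

# Which piece row (if any) contains each elementary ancestral interval.
interval_hit <- function(piece_s, piece_e, x) {
  idx <- rep(NA_integer_, length(piece_s))
  o <- order(x$anc_start)
  i <- findInterval(piece_s, x$anc_start[o])
  valid <- i > 0
  valid[valid] <- piece_e[valid] <= x$anc_end[o][i[valid]]
  idx[valid] <- o[i[valid]]
  idx
}

anc_pieces <- function(state) {
  rows <- list()
  for (chrom in names(state$segs)) {
    segtab <- state$segs[[chrom]]
    segtab <- mutate(segtab, chrom = chrom, cur_start = seg_cur_starts(segtab))
    rows[[length(rows) + 1L]] <- filter(segtab, .data$copy_id == 0L)
  }
  bind_rows(rows)
}

# Merge adjacent blocks that are contiguous on both genomes with the same
# relative strand: the result is the set of maximal consistent intervals.
merge_alignment_blocks <- function(blocks) {
  if (nrow(blocks) < 2) return(blocks)
  b <- arrange(blocks, .data$t_chrom, .data$t_start)
  out <- list()
  cur <- b[1, ]
  for (i in 2:nrow(b)) {
    nxt <- b[i, ]
    joinable <- nxt$t_chrom == cur$t_chrom && nxt$t_start == cur$t_end &&
      nxt$q_chrom == cur$q_chrom && nxt$strand == cur$strand &&
      ((cur$strand == "+" && nxt$q_start == cur$q_end) ||
         (cur$strand == "-" && nxt$q_end == cur$q_start))
    if (joinable) {
      cur$t_end <- nxt$t_end
      cur$q_start <- min(cur$q_start, nxt$q_start)
      cur$q_end <- max(cur$q_end, nxt$q_end)
    } else {
      out[[length(out) + 1L]] <- cur
      cur <- nxt
    }
  }
  out[[length(out) + 1L]] <- cur
  bind_rows(out)
}
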
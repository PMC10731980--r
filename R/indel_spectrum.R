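## Affected reference interval of an anchor-base InDel plus the
## inserted/deleted sequence. For a deletion REF=anchor+deleted the interval
## is [pos+1, pos+len(deleted)]; for an insertion the interval is the
## zero-length boundary between pos and pos+1.
.indel_interval <- function(pos, ref, alt) {
  lr <- nchar(ref); la <- nchar(alt)
  if (lr == la) stop("SNV input: adjacency is defined for InDels only")
  if (la > lr) list(start = pos + 1, end = pos, seq = substring(alt, 2))
  else list(start = pos + 1, end = pos + lr - 1, seq = substring(ref, 2))
}

## Length of the maximal single-base run ending at position p (inclusive,
## extending leftward) / starting at p (extending rightward).
.run_left <- function(seq, p) {
  if (p < 1 || p > nchar(seq)) return(0L)
  b <- substring(seq, p, p)
  i <- p
  while (i > 1 && substring(seq, i - 1, i - 1) == b) i <- i - 1
  p - i + 1L
}
.run_right <- function(seq, p) {
  len <- nchar(seq)
  if (p < 1 || p > len) return(0L)
  b <- substring(seq, p, p)
  i <- p
  while (i < len && substring(seq, i + 1, i + 1) == b) i <- i + 1
  i - p + 1L
}

#' Is an InDel adjacent to a homopolymer run?
#'
#' TRUE iff the reference carries a single-base run of length >= `min_run`
#' starting at either boundary of the affected interval, or the inserted /
#' deleted sequence is itself a homopolymer that, together with the matching
#' adjacent run (possibly of length zero), reaches `min_run`.
#'
#' @param genome A `reference_genome`.
#' @param contig,pos,ref,alt Anchor-base InDel record fields.
#' @param min_run Minimum run length (default 4).
#' @return Logical scalar.
#' @export
homopolymer_adjacent <- function(genome, contig, pos, ref, alt, min_run = 4) {
  stopifnot(inherits(genome, "reference_genome"))
  iv <- .indel_interval(pos, ref, alt)
  seq <- genome$contigs[[contig]]
  if (is.null(seq)) stop("unknown contig: ", contig)
  lb <- iv$start - 1L
  rb <- iv$end + 1L
  rl <- .run_left(seq, lb)
  rr <- .run_right(seq, rb)
  if (rl >= min_run || rr >= min_run) return(TRUE)
  # homopolymer InDel sequence extending an adjacent run
  sbases <- unique(strsplit(iv$seq, "")[[1]])
  if (length(sbases) == 1) {
    b <- sbases
    m <- nchar(iv$seq)
    ext_l <- m + if (lb >= 1 && substring(seq, lb, lb) == b) rl else 0L
    ext_r <- m + if (rb <= nchar(seq) && substring(seq, rb, rb) == b) rr else 0L
    if (ext_l >= min_run || ext_r >= min_run) return(TRUE)
  }
  FALSE
}

## Count consecutive exact copies of `unit` ending at position p (leftward) /
## starting at position p (rightward) in `seq`.
.copies_left <- function(seq, p, unit) {
  u <- nchar(unit)
  n <- 0L
  while (p - u + 1 >= 1 && substring(seq, p - u + 1, p) == unit) {
    n <- n + 1L
    p <- p - u
  }
  n
}
.copies_right <- function(seq, p, unit) {
  u <- nchar(unit)
  len <- nchar(seq)
  n <- 0L
  while (p + u - 1 <= len && substring(seq, p, p + u - 1) == unit) {
    n <- n + 1L
    p <- p + u
  }
  n
}

## Is s an integer number of copies of some unit of length u? Returns the
## unit or NULL.
.as_unit_copies <- function(s, u) {
  if (nchar(s) %% u != 0 || nchar(s) < u) return(NULL)
  unit <- substring(s, 1, u)
  if (paste(rep(unit, nchar(s) / u), collapse = "") == s) unit else NULL
}

#' Is an InDel adjacent to a polynucleotide tandem repeat?
#'
#' TRUE iff a tandem repeat (unit length in `unit_sizes`, at least
#' `min_copies` exact copies) abuts the affected interval on either side, or
#' the InDel sequence is an integer number of copies of the abutting unit
#' and flank plus InDel together reach `min_copies` copies.
#'
#' @inheritParams homopolymer_adjacent
#' @param unit_sizes Tandem-repeat unit lengths to consider (default 2:3).
#' @param min_copies Minimum exact copy number (default 3).
#' @return Logical scalar.
#' @export
repeat_adjacent <- function(genome, contig, pos, ref, alt,
                            unit_sizes = 2:3, min_copies = 3) {
  stopifnot(inherits(genome, "reference_genome"))
  iv <- .indel_interval(pos, ref, alt)
  seq <- genome$contigs[[contig]]
  if (is.null(seq)) stop("unknown contig: ", contig)
  lb <- iv$start - 1L
  rb <- iv$end + 1L
  for (u in unit_sizes) {
    if (lb - u + 1 >= 1) {
      unit_l <- substring(seq, lb - u + 1, lb)
      cl <- .copies_left(seq, lb, unit_l)
      if (cl >= min_copies) return(TRUE)
      w <- .as_unit_copies(iv$seq, u)
      if (!is.null(w) && w == unit_l && cl + nchar(iv$seq) / u >= min_copies)
        return(TRUE)
    }
    if (rb + u - 1 <= nchar(seq)) {
      unit_r <- substring(seq, rb, rb + u - 1)
      cr <- .copies_right(seq, rb, unit_r)
      if (cr >= min_copies) return(TRUE)
      w <- .as_unit_copies(iv$seq, u)
      if (!is.null(w) && w == unit_r && cr + nchar(iv$seq) / u >= min_copies)
        return(TRUE)
    }
  }
  FALSE
}

#' Classify the slippage context of an InDel
#'
#' Single-valued adjacency with precedence homopolymer >
#' polynucleotide_repeat (a homopolymer is a unit-1 repeat; precedence
#' avoids double counting).
#'
#' @inheritParams repeat_adjacent
#' @param min_run Minimum homopolymer run length.
#' @return One of `"homopolymer"`, `"polynucleotide_repeat"`, `"none"`.
#' @export
indel_adjacency <- function(genome, contig, pos, ref, alt, min_run = 4,
                            unit_sizes = 2:3, min_copies = 3) {
  if (homopolymer_adjacent(genome, contig, pos, ref, alt, min_run))
    return("homopolymer")
  if (repeat_adjacent(genome, contig, pos, ref, alt, unit_sizes, min_copies))
    return("polynucleotide_repeat")
  "none"
}

#' Insertion/deletion counts and ratio per group
#'
#' @param s A `singleton_set`.
#' @return data.frame `group`, `n_ins`, `n_del`, `ratio` (insertions /
#'   deletions, rounded to 2 decimals; NA with `ratio_defined = FALSE` when
#'   a group has no deletions), including an `"overall"` row.
#' @export
ins_del_ratio <- function(s) {
  stopifnot(inherits(s, "singleton_set"))
  lg <- attr(s, "line_groups")
  df <- as.data.frame(s)
  groups <- c(sort(unique(unname(lg))), "overall")
  rows <- lapply(groups, function(g) {
    d <- if (g == "overall") df else df[df$group == g, , drop = FALSE]
    ni <- sum(d$vtype == "INS"); nd <- sum(d$vtype == "DEL")
    data.frame(group = g, n_ins = ni, n_del = nd,
               ratio = if (nd == 0) NA_real_ else round(ni / nd, 2),
               ratio_defined = nd > 0)
  })
  do.call(rbind, rows)
}

#' Short/long InDel size classes per group
#'
#' `short` is size <= `threshold`, `long` is size > `threshold` (exhaustive
#' and exclusive). Per-line means include zero-count lines.
#'
#' @param s A `singleton_set`.
#' @param threshold Size threshold in bp (default 3).
#' @return data.frame per group (plus `"overall"`): counts, percentages of
#'   all InDels, and per-line means.
#' @export
size_class_counts <- function(s, threshold = 3) {
  stopifnot(inherits(s, "singleton_set"), threshold >= 1)
  lg <- attr(s, "line_groups")
  df <- as.data.frame(s)[s$vtype %in% c("INS", "DEL"), , drop = FALSE]
  groups <- c(sort(unique(unname(lg))), "overall")
  rows <- lapply(groups, function(g) {
    d <- if (g == "overall") df else df[df$group == g, , drop = FALSE]
    L <- if (g == "overall") length(lg) else sum(unname(lg) == g)
    ns <- sum(d$size <= threshold); nl <- sum(d$size > threshold)
    n <- ns + nl
    data.frame(group = g, n_lines = L, n_indel = n,
               n_short = ns, n_long = nl,
               pct_short = if (n == 0) NA_real_ else round(100 * ns / n, 2),
               pct_long = if (n == 0) NA_real_ else round(100 * nl / n, 2),
               per_line_short = round(ns / L, 2),
               per_line_long = round(nl / L, 2))
  })
  do.call(rbind, rows)
}

#' Per-group InDel report
#'
#' Assembles counts, insertion/deletion ratio, size classes, slippage-
#' context adjacency percentages, and (when >= 2 groups with variation) a
#' one-way ANOVA on per-line InDel counts. Classifier thresholds are
#' recorded in the `parameters` attribute.
#'
#' @param s A `singleton_set`.
#' @param genome A `reference_genome`.
#' @param threshold Short/long size threshold.
#' @param min_run,unit_sizes,min_copies Adjacency-classifier thresholds.
#' @return List of class `indel_report`: `by_group` (data.frame), `records`
#'   (per-InDel adjacency calls), `anova` (`group_comparison` or NULL).
#' @export
indel_report <- function(s, genome, threshold = 3, min_run = 4,
                         unit_sizes = 2:3, min_copies = 3) {
  stopifnot(inherits(s, "singleton_set"), inherits(genome, "reference_genome"))
  lg <- attr(s, "line_groups")
  df <- as.data.frame(s)[s$vtype %in% c("INS", "DEL"), , drop = FALSE]
  adj <- character(nrow(df))
  for (i in seq_len(nrow(df)))
    adj[i] <- indel_adjacency(genome, df$contig[i], df$pos[i], df$ref[i],
                              df$alt[i], min_run, unit_sizes, min_copies)
  df$adjacency <- adj
  sizes <- size_class_counts(s, threshold)
  ratios <- ins_del_ratio(s)
  groups <- c(sort(unique(unname(lg))), "overall")
  rows <- lapply(groups, function(g) {
    d <- if (g == "overall") df else df[df$group == g, , drop = FALSE]
    L <- if (g == "overall") length(lg) else sum(unname(lg) == g)
    n <- nrow(d)
    n_adj <- sum(d$adjacency != "none")
    data.frame(group = g,
               n_indel = n,
               per_line_indel = round(n / L, 2),
               n_homopolymer = sum(d$adjacency == "homopolymer"),
               n_repeat = sum(d$adjacency == "polynucleotide_repeat"),
               pct_adjacent = if (n == 0) NA_real_ else
                 round(100 * n_adj / n, 2))
  })
  by_group <- merge(merge(do.call(rbind, rows), ratios, by = "group"),
                    sizes[, c("group", "n_short", "n_long", "pct_short",
                              "pct_long", "per_line_short", "per_line_long")],
                    by = "group")
  by_group <- by_group[match(groups, by_group$group), ]
  rownames(by_group) <- NULL
  counts <- per_line_counts(s, vtype = "InDel")$per_line
  glab <- unname(lg[names(counts)])
  v_within <- vapply(split(counts, glab), stats::var, numeric(1))
  an <- if (length(unique(glab)) >= 2 && any(v_within > 0))
    group_anova_tukey(counts, glab) else NULL
  structure(list(by_group = by_group, records = df, anova = an),
            parameters = list(threshold = threshold, min_run = min_run,
                              unit_sizes = unit_sizes,
                              min_copies = min_copies),
            class = "indel_report")
}

#' @export
print.indel_report <- function(x, ...) {
  p <- attr(x, "parameters")
  cat(sprintf(
    "indel_report (size threshold %d bp, homopolymer run >= %d, unit %s x >= %d)\n",
    p$threshold, p$min_run, paste(range(p$unit_sizes), collapse = "-"),
    p$min_copies))
  print(x$by_group)
  invisible(x)
}
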
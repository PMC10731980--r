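#' The 12 directed substitution classes, reference-strand, uncollapsed
#' @format Character vector `"A>C" ... "T>G"`.
#' @export
SUBSTITUTION_CLASSES <- c("A>C", "A>G", "A>T",
                          "C>A", "C>G", "C>T",
                          "G>A", "G>C", "G>T",
                          "T>A", "T>C", "T>G")

#' Label a substitution
#'
#' Directed, reference-strand labeling with no strand collapsing (C>T and
#' G>A are distinct classes). A transition is a purine-to-purine (A<->G) or
#' pyrimidine-to-pyrimidine (C<->T) change; every purine<->pyrimidine
#' interchange is a transversion.
#'
#' @param ref,alt Single bases in A/C/G/T (vectorized, `ref != alt`).
#' @return data.frame with columns `class`, `ti_tv` (`"transition"` /
#'   `"transversion"`) and `category` (`"pur_pur"`, `"pyr_pyr"`, `"cross"`).
#' @export
substitution_class <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (any(!ref %in% c("A", "C", "G", "T")) ||
      any(!alt %in% c("A", "C", "G", "T")))
    stop("substitution bases must be A/C/G/T")
  if (any(ref == alt)) stop("ref and alt must differ")
  purine <- c("A", "G")
  rp <- ref %in% purine; ap <- alt %in% purine
  category <- ifelse(rp & ap, "pur_pur", ifelse(!rp & !ap, "pyr_pyr", "cross"))
  data.frame(class = paste0(ref, ">", alt),
             ti_tv = ifelse(category == "cross", "transversion", "transition"),
             category = category)
}

#' Substitution-spectrum table for singleton SNVs
#'
#' Counts and percentages over the 12 directed classes, with transition /
#' transversion and purine-purine / pyrimidine-pyrimidine subtotals, per
#' group and overall.
#'
#' @param s A `singleton_set` (only SNV records are used).
#' @param collapse6 Also report the 6-class strand-collapsed view
#'   (C>T pooled with G>A, etc.).
#' @return List of class `spectrum_summary` with `classes` (data.frame
#'   `group`, `class`, `count`, `pct`), `summary` (per-group totals) and
#'   optionally `classes6`.
#' @export
spectrum_table <- function(s, collapse6 = FALSE) {
  stopifnot(inherits(s, "singleton_set"))
  lg <- attr(s, "line_groups")
  snv <- as.data.frame(s)[s$vtype == "SNV", , drop = FALSE]
  lab <- if (nrow(snv)) substitution_class(snv$ref, snv$alt) else
    data.frame(class = character(), ti_tv = character(),
               category = character())
  snv <- cbind(snv, lab)
  groups <- c(sort(unique(unname(lg))), "overall")
  one <- function(df, gname) {
    n <- nrow(df)
    counts <- table(factor(df$class, levels = SUBSTITUTION_CLASSES))
    cls <- data.frame(group = gname, class = SUBSTITUTION_CLASSES,
                      count = as.integer(counts),
                      pct = if (n == 0) NA_real_ else
                        round(100 * as.integer(counts) / n, 2))
    smry <- data.frame(group = gname, n_snv = n,
                       n_transition = sum(df$ti_tv == "transition"),
                       n_transversion = sum(df$ti_tv == "transversion"),
                       pct_transition = if (n == 0) NA_real_ else
                         round(100 * sum(df$ti_tv == "transition") / n, 2),
                       n_pur_pur = sum(df$category == "pur_pur"),
                       n_pyr_pyr = sum(df$category == "pyr_pyr"))
    list(cls = cls, smry = smry)
  }
  parts <- lapply(groups, function(g) {
    df <- if (g == "overall") snv else snv[snv$group == g, , drop = FALSE]
    one(df, g)
  })
  out <- list(classes = do.call(rbind, lapply(parts, `[[`, "cls")),
              summary = do.call(rbind, lapply(parts, `[[`, "smry")))
  if (collapse6) {
    pair <- c("A>C" = "T>G", "A>G" = "T>C", "A>T" = "T>A",
              "C>A" = "G>T", "C>G" = "G>C", "C>T" = "G>A")
    canon <- names(pair)
    coll <- out$classes
    coll$class6 <- ifelse(coll$class %in% canon, coll$class,
                          canon[match(coll$class, pair)])
    agg <- stats::aggregate(count ~ group + class6, data = coll, FUN = sum)
    out$classes6 <- agg[order(agg$group, agg$class6), ]
  }
  structure(out, class = c("spectrum_summary", "list"))
}

#' Per-line transition fraction
#'
#' Fraction of a line's singleton SNVs that are transitions. Lines with zero
#' SNVs have an undefined fraction and are excluded (reported in the
#' `excluded_lines` attribute), which matters for downstream fraction-based
#' tests.
#'
#' @param s A `singleton_set`.
#' @return data.frame `line`, `group`, `n_snv`, `n_transition`, `fraction`;
#'   attribute `excluded_lines`.
#' @export
transition_fraction_per_line <- function(s) {
  stopifnot(inherits(s, "singleton_set"))
  lg <- attr(s, "line_groups")
  snv <- as.data.frame(s)[s$vtype == "SNV", , drop = FALSE]
  lab <- if (nrow(snv)) substitution_class(snv$ref, snv$alt)$ti_tv
         else character(0)
  n_snv <- setNames(integer(length(lg)), names(lg))
  n_ti <- n_snv
  if (nrow(snv)) {
    t1 <- table(snv$line)
    n_snv[names(t1)] <- as.integer(t1)
    ti <- snv$line[lab == "transition"]
    if (length(ti)) {
      t2 <- table(ti)
      n_ti[names(t2)] <- as.integer(t2)
    }
  }
  keep <- n_snv > 0
  out <- data.frame(line = names(lg)[keep],
                    group = unname(lg)[keep],
                    n_snv = unname(n_snv[keep]),
                    n_transition = unname(n_ti[keep]),
                    fraction = unname(n_ti[keep] / n_snv[keep]))
  attr(out, "excluded_lines") <- names(lg)[!keep]
  out
}

#' Extract the reference k-flank around a site
#'
#' Returns the `2k+1`-mer centered on `pos` from the reference (+) strand.
#' Sites closer than `k` to a contig end return `NA` (callers exclude them
#' from context matrices and tally them as edge-excluded).
#'
#' @param genome A `reference_genome`.
#' @param contig Contig name.
#' @param pos 1-based position(s) on the contig.
#' @param k Flank width (default 5).
#' @return Character vector of `2k+1`-mers (NA for edge sites).
#' @export
extract_flanks <- function(genome, contig, pos, k = 5) {
  stopifnot(inherits(genome, "reference_genome"))
  seq <- genome$contigs[[contig]]
  if (is.null(seq)) stop("unknown contig: ", contig)
  len <- nchar(seq)
  if (any(pos < 1 | pos > len)) stop("position off contig ", contig)
  out <- rep(NA_character_, length(pos))
  ok <- pos - k >= 1 & pos + k <= len
  if (any(ok)) out[ok] <- substring(seq, pos[ok] - k, pos[ok] + k)
  out
}

#' Flanking-context frequency matrix around singleton SNVs
#'
#' Builds the position (-k..+k) by base (A,C,G,T) relative-frequency matrix
#' of the reference context around mutated sites, optionally restricted to a
#' mutated reference base and/or a treatment group, together with the
#' per-position consensus (argmax base; ties broken lexicographically and
#' flagged). Edge sites (closer than `k` to a contig end) are excluded and
#' tallied.
#'
#' @param s A `singleton_set`.
#' @param genome A `reference_genome`.
#' @param base Optional mutated reference base filter (e.g. `"C"`).
#' @param group Optional group filter.
#' @param k Flank width.
#' @return Object of class `context_matrix`: `matrix` (4 x 2k+1, columns
#'   `-k..k`, each column summing to 1), `n_sites`, `n_edge_excluded`,
#'   `consensus` (named base per non-focal position), `max_freq`, `tie`
#'   (logical per position), `subset`.
#' @export
context_frequency_matrix <- function(s, genome, base = NULL, group = NULL,
                                     k = 5) {
  stopifnot(inherits(s, "singleton_set"), inherits(genome, "reference_genome"))
  df <- as.data.frame(s)[s$vtype == "SNV", , drop = FALSE]
  if (!is.null(base)) df <- df[df$ref == base, , drop = FALSE]
  if (!is.null(group)) df <- df[df$group == group, , drop = FALSE]
  if (nrow(df) == 0) stop("empty subset: no usable SNV sites")
  flanks <- unlist(lapply(split(df, df$contig), function(d)
    extract_flanks(genome, d$contig[1], d$pos, k = k)), use.names = FALSE)
  n_edge <- sum(is.na(flanks))
  flanks <- flanks[!is.na(flanks)]
  if (length(flanks) == 0) stop("empty subset: all sites edge-excluded")
  cm <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(flanks))
  bases <- c("A", "C", "G", "T")
  m <- matrix(0, 4, 2 * k + 1, dimnames = list(bases, as.character(-k:k)))
  for (b in bases) if (b %in% rownames(cm)) m[b, ] <- cm[b, ]
  m <- sweep(m, 2, colSums(m), "/")
  pos_lab <- as.character(-k:k)
  focal <- as.character(0)
  cons_pos <- setdiff(pos_lab, focal)
  top <- apply(m[, cons_pos, drop = FALSE], 2, function(col) {
    mx <- max(col)
    hits <- bases[col == mx]
    c(base = hits[1], freq = mx, tie = length(hits) > 1)
  })
  structure(list(matrix = m,
                 n_sites = length(flanks),
                 n_edge_excluded = n_edge,
                 consensus = setNames(unname(top["base", ]), cons_pos),
                 max_freq = setNames(as.numeric(top["freq", ]), cons_pos),
                 tie = setNames(as.logical(top["tie", ]), cons_pos),
                 subset = list(base = base, group = group, k = k)),
            class = "context_matrix")
}

#' @export
print.context_matrix <- function(x, ...) {
  cat("context_matrix:", x$n_sites, "sites (",
      x$n_edge_excluded, "edge-excluded ), subset:",
      x$subset$base %||% "any base", "/", x$subset$group %||% "all groups",
      "\n")
  print(round(x$matrix, 3))
  cat("consensus:", paste(x$consensus, collapse = ""),
      if (any(x$tie)) " [ties flagged]" else "", "\n")
  invisible(x)
}

#' Consensus string over a span of flank positions
#' @param cm A `context_matrix`.
#' @param from,to Position labels (integers, e.g. -3 and -1).
#' @return Character string of the consensus bases at those positions.
#' @export
consensus_string <- function(cm, from, to) {
  stopifnot(inherits(cm, "context_matrix"))
  paste(cm$consensus[as.character(seq(from, to))], collapse = "")
}

#' Per-contig distribution of singletons across groups
#'
#' Per-line mean counts per contig and group (contigs with zero variants
#' report 0), plus a one-way ANOVA across groups for each contig.
#'
#' @param s A `singleton_set`.
#' @param genome A `reference_genome` (fixes the contig roster).
#' @return List with `means` (data.frame `contig`, `group`, `mean`) and
#'   `anova` (data.frame `contig`, `f`, `p`).
#' @export
chromosome_distribution <- function(s, genome) {
  stopifnot(inherits(s, "singleton_set"), inherits(genome, "reference_genome"))
  lg <- attr(s, "line_groups")
  contigs <- names(genome$contigs)
  df <- as.data.frame(s)
  means <- list(); pvals <- list()
  for (ct in contigs) {
    counts <- setNames(integer(length(lg)), names(lg))
    sub <- df[df$contig == ct, , drop = FALSE]
    if (nrow(sub)) {
      tab <- table(sub$line)
      counts[names(tab)] <- as.integer(tab)
    }
    gm <- vapply(split(counts, unname(lg)), mean, numeric(1))
    means[[ct]] <- data.frame(contig = ct, group = names(gm),
                              mean = unname(gm))
    v_within <- vapply(split(counts, unname(lg)), stats::var, numeric(1))
    if (length(gm) >= 2 && any(v_within > 0)) {
      cmp <- group_anova_tukey(counts, unname(lg))
      pvals[[ct]] <- data.frame(contig = ct, f = cmp$f, p = cmp$p)
    } else {
      pvals[[ct]] <- data.frame(contig = ct, f = NA_real_, p = NA_real_)
    }
  }
  list(means = do.call(rbind, c(means, list(make.row.names = FALSE))),
       anova = do.call(rbind, c(pvals, list(make.row.names = FALSE))))
}
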
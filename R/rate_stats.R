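#' Per-line singleton counts and group means
#'
#' Every line in the cohort roster is counted, including lines with zero
#' singletons.
#'
#' @param s A `singleton_set`.
#' @param vtype `"all"`, `"SNV"`, `"InDel"`, or a predicate function taking
#'   the record data.frame and returning a logical vector.
#' @return List with `per_line` (named integer vector over all lines) and
#'   `group_means` (data.frame `group`, `n_lines`, `mean`).
#' @export
per_line_counts <- function(s, vtype = c("all", "SNV", "InDel")) {
  stopifnot(inherits(s, "singleton_set"))
  lg <- attr(s, "line_groups")
  df <- as.data.frame(s)
  if (is.function(vtype)) {
    df <- df[vtype(df), , drop = FALSE]
  } else {
    vtype <- match.arg(vtype)
    if (vtype == "SNV") df <- df[df$vtype == "SNV", , drop = FALSE]
    if (vtype == "InDel") df <- df[df$vtype %in% c("INS", "DEL"), , drop = FALSE]
  }
  if (any(!df$line %in% names(lg))) stop("unknown line label in records")
  counts <- setNames(integer(length(lg)), names(lg))
  if (nrow(df)) {
    tab <- table(df$line)
    counts[names(tab)] <- as.integer(tab)
  }
  gm <- vapply(split(counts, unname(lg[names(counts)])), mean, numeric(1))
  list(per_line = counts,
       group_means = data.frame(group = names(gm),
                                n_lines = as.integer(table(unname(lg))[names(gm)]),
                                mean = unname(gm)))
}

#' Zygosity-weighted effective mutation count
#'
#' A heterozygous de novo mutation in a selfing line is transmitted to
#' homozygosity with probability 1/2, so the effective heritable count is
#' `E = N_hom + 0.5 * N_het`.
#'
#' @param s A `singleton_set`.
#' @param group Optional group label to subset to.
#' @param vtype `"all"`, `"SNV"` or `"InDel"`.
#' @return Numeric effective count.
#' @export
effective_mutation_count <- function(s, group = NULL,
                                     vtype = c("all", "SNV", "InDel")) {
  stopifnot(inherits(s, "singleton_set"))
  vtype <- match.arg(vtype)
  df <- as.data.frame(s)
  if (!is.null(group)) df <- df[df$group == group, , drop = FALSE]
  if (vtype == "SNV") df <- df[df$vtype == "SNV", , drop = FALSE]
  if (vtype == "InDel") df <- df[df$vtype %in% c("INS", "DEL"), , drop = FALSE]
  sum(df$zygosity == "homozygous") + 0.5 * sum(df$zygosity == "heterozygous")
}

#' Mutation rate per site per line per generation
#'
#' `rate = E / (D * S * L * g)` where `E` is the zygosity-weighted effective
#' count, `S` the per-haplotype site count (reference non-N length by
#' default), `L` the number of lines, `g` the number of generations and `D`
#' the diploid site factor (2 when both homologous copies are mutational
#' targets).
#'
#' @param E Effective mutation count.
#' @param S Sites (bp).
#' @param L Number of lines.
#' @param g Generations.
#' @param D Diploid site factor.
#' @return Numeric rate.
#' @export
mutation_rate <- function(E, S, L, g = 1, D = 2) {
  if (any(c(S, L, g, D) <= 0)) stop("S, L, g and D must be positive")
  E / (D * S * L * g)
}

#' Per-group mutation-rate estimates
#'
#' @param s A `singleton_set`.
#' @param sites Per-haplotype site count; pass a `reference_genome` to use
#'   its non-N length, or a number.
#' @param g Generations.
#' @param D Diploid site factor.
#' @param vtype `"all"`, `"SNV"` or `"InDel"`.
#' @return data.frame with one row per group: `group`, `n_lines`,
#'   `effective_count`, `sites`, `generations`, `diploid_factor`, `rate`.
#' @export
estimate_group_rates <- function(s, sites, g = 1, D = 2,
                                 vtype = c("all", "SNV", "InDel")) {
  stopifnot(inherits(s, "singleton_set"))
  vtype <- match.arg(vtype)
  if (inherits(sites, "reference_genome")) sites <- sites$non_n_length
  lg <- attr(s, "line_groups")
  groups <- sort(unique(unname(lg)))
  rows <- lapply(groups, function(gr) {
    L <- sum(unname(lg) == gr)
    E <- effective_mutation_count(s, group = gr, vtype = vtype)
    data.frame(group = gr, n_lines = L, effective_count = E, sites = sites,
               generations = g, diploid_factor = D,
               rate = mutation_rate(E, sites, L, g, D))
  })
  do.call(rbind, rows)
}

#' Compact letter display from a non-significance relation
#'
#' Letters are assigned to the maximal cliques of the graph whose edges join
#' pairs of groups that are not significantly different, so two groups share
#' a letter iff they are not significantly different. Cliques are ordered by
#' the descending best group mean among their members (ties broken by group
#' name) before letters are allocated, making the display deterministic.
#'
#' @param nonsig Symmetric logical matrix (group x group); `TRUE` off the
#'   diagonal means "not significantly different".
#' @param means Named numeric vector of group means.
#' @return Named character vector of letter strings per group.
#' @export
compact_letter_display <- function(nonsig, means) {
  groups <- rownames(nonsig)
  stopifnot(!is.null(groups), all(groups %in% names(means)))
  if (length(groups) == 1) return(setNames("a", groups))
  adj <- nonsig
  diag(adj) <- FALSE
  gph <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  cliques <- igraph::max_cliques(gph)
  members <- lapply(cliques, function(cl) sort(groups[as.integer(cl)]))
  best <- vapply(members, function(m) max(means[m]), numeric(1))
  first <- vapply(members, `[`, character(1), 1)
  o <- order(-best, first)
  members <- members[o]
  lab <- rep(letters, length.out = length(members))
  out <- setNames(rep("", length(groups)), groups)
  for (i in seq_along(members))
    for (g in members[[i]])
      out[g] <- paste0(out[g], lab[i])
  out
}

#' One-way ANOVA with Tukey HSD and letter grouping
#'
#' Standard one-way ANOVA F test followed by Tukey's honestly-significant-
#' difference pairwise comparisons, summarized as a compact letter display
#' at level `alpha`.
#'
#' @param values Numeric vector of per-line values.
#' @param groups Group label per value (>= 2 groups, >= 2 values each).
#' @param alpha Significance level for the letter display.
#' @return List of class `group_comparison`: `f`, `p`, `df_between`,
#'   `df_within`, `group_means`, `tukey` (data.frame `pair`, `diff`, `lwr`,
#'   `upr`, `p_adj`), `letters`, `alpha`.
#' @export
group_anova_tukey <- function(values, groups, alpha = 0.05) {
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  tab <- table(groups)
  if (length(tab) < 2) stop("need at least two groups")
  if (any(tab < 2)) stop("need at least two values per group")
  v_within <- vapply(split(values, groups), stats::var, numeric(1))
  if (all(v_within == 0))
    stop("degenerate input: zero within-group variance in every group")
  d <- data.frame(y = values, g = factor(groups))
  fit <- aov(y ~ g, data = d)
  ss <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$g
  pairs <- rownames(tk)
  tukey <- data.frame(pair = pairs, diff = tk[, "diff"], lwr = tk[, "lwr"],
                      upr = tk[, "upr"], p_adj = tk[, "p adj"],
                      row.names = NULL)
  gm <- vapply(split(values, groups), mean, numeric(1))
  k <- length(gm)
  nonsig <- matrix(TRUE, k, k, dimnames = list(names(gm), names(gm)))
  halves <- strsplit(pairs, "-", fixed = TRUE)
  for (i in seq_along(halves)) {
    a <- halves[[i]][1]; b <- halves[[i]][2]
    ns <- tukey$p_adj[i] >= alpha
    nonsig[a, b] <- ns; nonsig[b, a] <- ns
  }
  structure(list(f = ss[1, "F value"], p = ss[1, "Pr(>F)"],
                 df_between = ss[1, "Df"], df_within = ss[2, "Df"],
                 group_means = gm, tukey = tukey,
                 letters = compact_letter_display(nonsig, gm),
                 alpha = alpha),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$f, x$p))
  cat("group means (letters at alpha =", x$alpha, "):\n")
  for (g in names(sort(x$group_means, decreasing = TRUE)))
    cat(sprintf("  %-12s %.4g  %s\n", g, x$group_means[g], x$letters[g]))
  invisible(x)
}

#' Pairwise t-tests of per-line fractions against a reference group
#'
#' Two-sample two-sided t-tests (Welch by default) of each treatment group
#' against the reference group.
#'
#' @param values Numeric vector (e.g. per-line transition fractions).
#' @param groups Group label per value.
#' @param reference Reference group label.
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @return data.frame: `group`, `n`, `mean`, `reference_mean`, `t`, `df`,
#'   `p`.
#' @export
proportion_t_test <- function(values, groups, reference, var_equal = FALSE) {
  groups <- as.character(groups)
  ok <- !is.na(values)
  values <- values[ok]; groups <- groups[ok]
  if (!reference %in% groups) stop("reference group absent: ", reference)
  ref <- values[groups == reference]
  if (length(ref) < 2) stop("fewer than 2 usable values in reference group")
  others <- setdiff(sort(unique(groups)), reference)
  rows <- lapply(others, function(g) {
    x <- values[groups == g]
    if (length(x) < 2) stop("fewer than 2 usable values in group ", g)
    tt <- t.test(x, ref, var.equal = var_equal)
    data.frame(group = g, n = length(x), mean = mean(x),
               reference_mean = mean(ref),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value)
  })
  do.call(rbind, rows)
}

#' Generic group comparison for a value table
#'
#' A convenience wrapper for tables such as per-pot germination counts:
#' one-way ANOVA + Tukey letter grouping on a two-column table.
#'
#' @param table data.frame with a group column and a value column.
#' @param group_col,value_col Column names.
#' @param alpha Significance level.
#' @return A `group_comparison` (see [group_anova_tukey()]).
#' @export
compare_groups <- function(table, group_col = "group", value_col = "value",
                           alpha = 0.05) {
  stopifnot(all(c(group_col, value_col) %in% names(table)))
  group_anova_tukey(table[[value_col]], table[[group_col]], alpha = alpha)
}
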
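#' Locus-level filter configuration
#'
#' Quality thresholds applied per locus before singleton selection. A locus
#' is dropped when its missing-call fraction exceeds `max_missing_fraction`
#' or its heterozygous-call fraction exceeds `max_het_fraction` (both
#' comparisons strict). The missing fraction is computed over all lines; the
#' het fraction over non-missing calls by default (`het_denominator =
#' "all"` divides by all lines instead).
#'
#' @param max_missing_fraction Maximum tolerated missing-call fraction.
#' @param max_het_fraction Maximum tolerated heterozygous-call fraction.
#' @param het_denominator `"non_missing"` (default) or `"all"`.
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(max_missing_fraction = 0.20,
                          max_het_fraction = 0.20,
                          het_denominator = c("non_missing", "all")) {
  stopifnot(max_missing_fraction >= 0, max_missing_fraction <= 1,
            max_het_fraction >= 0, max_het_fraction <= 1)
  structure(list(max_missing_fraction = max_missing_fraction,
                 max_het_fraction = max_het_fraction,
                 het_denominator = match.arg(het_denominator)),
            class = "filter_config")
}

#' Apply locus-level quality filters
#'
#' Drops every locus whose missing-call fraction or heterozygous-call
#' fraction exceeds (strictly) the configured thresholds; the order of the
#' surviving loci is preserved. An empty result is allowed.
#'
#' @param table A [cohort_table()].
#' @param cfg A [filter_config()].
#' @return The filtered `cohort_table`.
#' @export
apply_locus_filters <- function(table, cfg = filter_config()) {
  stopifnot(inherits(table, "cohort_table"), inherits(cfg, "filter_config"))
  gt <- table$genotypes
  n <- ncol(gt)
  n_missing <- rowSums(gt == "missing")
  n_het <- rowSums(gt == "het")
  missing_frac <- n_missing / n
  het_denom <- if (cfg$het_denominator == "non_missing") n - n_missing
               else rep(n, nrow(gt))
  het_frac <- ifelse(het_denom == 0, 0, n_het / het_denom)
  keep <- !(missing_frac > cfg$max_missing_fraction |
              het_frac > cfg$max_het_fraction)
  cohort_table(table$loci[keep, , drop = FALSE],
               gt[keep, , drop = FALSE],
               table$line_groups)
}

#' Classify a variant from its VCF anchor-base alleles
#'
#' `len(ref) == len(alt) == 1` is an SNV (size 0); a longer alt is an
#' insertion, a longer ref a deletion, with size the absolute length
#' difference. Equal-length multi-base alleles (MNPs) and symbolic alleles
#' are rejected.
#'
#' @param ref,alt Character vectors of reference and alternate alleles.
#' @return data.frame with columns `vtype` (`"SNV"`, `"INS"`, `"DEL"`) and
#'   `size` (integer bp, 0 for SNV).
#' @export
classify_variant_type <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (any(grepl("[^ACGT]", c(ref, alt))))
    stop("unsupported variant: alleles must be strings over A/C/G/T")
  if (any(ref == alt)) stop("ref and alt alleles must differ")
  lr <- nchar(ref); la <- nchar(alt)
  if (any(lr == la & lr > 1))
    stop("unsupported variant: equal-length multi-base alleles (MNP)")
  vtype <- ifelse(lr == la, "SNV", ifelse(la > lr, "INS", "DEL"))
  data.frame(vtype = vtype, size = abs(la - lr))
}

#' Construct a singleton set from a plain data.frame
#'
#' @param records data.frame with columns `contig`, `pos`, `ref`, `alt`,
#'   `vtype`, `size`, `line`, `group`, `zygosity`.
#' @param line_groups Named character vector giving the full line roster and
#'   its groups (lines with zero singletons included).
#' @return An object of class `singleton_set` (a data.frame).
#' @export
as_singleton_set <- function(records, line_groups) {
  need <- c("contig", "pos", "ref", "alt", "vtype", "size",
            "line", "group", "zygosity")
  stopifnot(all(need %in% names(records)))
  if (!all(records$zygosity %in% c("homozygous", "heterozygous")))
    stop("zygosity must be homozygous/heterozygous")
  if (!all(records$line %in% names(line_groups)))
    stop("singleton record for a line absent from line_groups")
  records <- records[order(records$contig, records$pos, records$line),
                     need, drop = FALSE]
  rownames(records) <- NULL
  structure(records, line_groups = line_groups,
            class = c("singleton_set", "data.frame"))
}

#' @export
print.singleton_set <- function(x, ...) {
  lg <- attr(x, "line_groups")
  cat("singleton_set:", nrow(x), "records across", length(lg), "lines (",
      length(unique(lg)), "groups )\n")
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 6))
  invisible(x)
}

#' Select singleton (unique-site) variants
#'
#' A locus is a singleton iff exactly one line in the whole cohort carries a
#' non-reference, non-missing genotype there. Uniqueness is positional by
#' default: two different alt alleles at the same (contig, pos) carried by
#' two different lines disqualify both. The owning line's genotype sets
#' zygosity (`hom_alt` -> homozygous, `het` -> heterozygous).
#'
#' @param table A filtered [cohort_table()].
#' @param allele_aware If `TRUE`, uniqueness is judged per
#'   (contig, pos, ref, alt) instead of per position.
#' @return A `singleton_set`.
#' @export
select_singletons <- function(table, allele_aware = FALSE) {
  stopifnot(inherits(table, "cohort_table"))
  gt <- table$genotypes
  lines <- colnames(gt)
  carrier <- gt == "het" | gt == "hom_alt"
  key <- if (allele_aware)
    paste(table$loci$contig, table$loci$pos, table$loci$ref, table$loci$alt)
  else paste(table$loci$contig, table$loci$pos)

  # distinct carrier lines per position key
  idx <- which(carrier, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    empty <- data.frame(contig = character(), pos = integer(),
                        ref = character(), alt = character(),
                        vtype = character(), size = integer(),
                        line = character(), group = character(),
                        zygosity = character())
    return(as_singleton_set(empty, table$line_groups))
  }
  pair_key <- key[idx[, "row"]]
  pair_line <- lines[idx[, "col"]]
  n_lines_per_key <- tapply(pair_line, pair_key,
                            function(x) length(unique(x)))
  singleton_keys <- names(n_lines_per_key)[n_lines_per_key == 1]
  take <- pair_key %in% singleton_keys
  rows <- idx[take, "row"]
  cols <- idx[take, "col"]
  cls <- classify_variant_type(table$loci$ref[rows], table$loci$alt[rows])
  rec <- data.frame(contig = table$loci$contig[rows],
                    pos = table$loci$pos[rows],
                    ref = table$loci$ref[rows],
                    alt = table$loci$alt[rows],
                    vtype = cls$vtype, size = cls$size,
                    line = lines[cols],
                    group = unname(table$line_groups[lines[cols]]),
                    zygosity = ifelse(gt[cbind(rows, cols)] == "hom_alt",
                                      "homozygous", "heterozygous"))
  as_singleton_set(rec, table$line_groups)
}

#' Summarize a singleton set by variant type and zygosity
#'
#' Percentages are 100 x class count / total singletons, rounded to two
#' decimals; the variant-type percentages partition 100%. Groups (and the
#' `"overall"` row) with zero singletons report NA percentages.
#'
#' @param s A `singleton_set`.
#' @return data.frame, one row per group plus an `"overall"` row, with
#'   counts `n_total`, `n_snv`, `n_ins`, `n_del`, `n_hom`, `n_het` and the
#'   corresponding percentages.
#' @export
summarize_singletons <- function(s) {
  stopifnot(inherits(s, "singleton_set"))
  lg <- attr(s, "line_groups")
  groups <- sort(unique(unname(lg)))
  one <- function(df) {
    n <- nrow(df)
    pct <- function(k) if (n == 0) NA_real_ else round(100 * k / n, 2)
    data.frame(n_total = n,
               n_snv = sum(df$vtype == "SNV"),
               n_ins = sum(df$vtype == "INS"),
               n_del = sum(df$vtype == "DEL"),
               n_hom = sum(df$zygosity == "homozygous"),
               n_het = sum(df$zygosity == "heterozygous"),
               pct_snv = pct(sum(df$vtype == "SNV")),
               pct_ins = pct(sum(df$vtype == "INS")),
               pct_del = pct(sum(df$vtype == "DEL")),
               pct_hom = pct(sum(df$zygosity == "homozygous")),
               pct_het = pct(sum(df$zygosity == "heterozygous")))
  }
  rows <- lapply(groups, function(g) one(s[s$group == g, , drop = FALSE]))
  out <- cbind(data.frame(group = c(groups, "overall")),
               rbind(do.call(rbind, rows), one(s)))
  rownames(out) <- NULL
  out
}
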
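#' Classify the genomic region of variants
#'
#' One region call per variant with explicit precedence: CDS overlap ->
#' `exon` (coding); UTR feature -> `UTR`; exon feature without CDS/UTR ->
#' `exon` (non-coding); inside a gene but no exon -> `intron`; outside all
#' genes -> `intergenic`. InDels are classified by any overlap of their
#' affected reference interval, resolved by the same precedence. Variants
#' overlapping conflicting features of several transcripts receive the most
#' severe (highest-precedence) call.
#'
#' @param index A `gff_index` from [read_gff()].
#' @param variants data.frame with `contig`, `pos`, `ref`, `alt` columns
#'   (e.g. a `singleton_set`).
#' @return data.frame with columns `region` (`intergenic`, `UTR`, `exon`,
#'   `intron`), `coding` (logical; `TRUE` implies `region == "exon"`) and
#'   `gene_id` (first overlapping gene, NA outside genes).
#' @export
classify_region <- function(index, variants) {
  stopifnot(inherits(index, "gff_index"))
  df <- as.data.frame(variants)
  n <- nrow(df)
  lr <- nchar(df$ref)
  start <- df$pos
  end <- df$pos + pmax(lr - 1, 0)
  q <- GenomicRanges::GRanges(df$contig, IRanges::IRanges(start, end))
  ov <- function(type) {
    g <- index$by_type[[type]]
    hits <- GenomicRanges::findOverlaps(q, g)
    list(any = seq_len(n) %in% S4Vectors::queryHits(hits), hits = hits)
  }
  in_cds <- ov("CDS")$any
  in_utr <- ov("five_prime_UTR")$any | ov("three_prime_UTR")$any
  in_exon <- ov("exon")$any
  gene_hits <- ov("gene")
  in_gene <- gene_hits$any
  region <- ifelse(in_cds, "exon",
            ifelse(in_utr, "UTR",
            ifelse(in_exon, "exon",
            ifelse(in_gene, "intron", "intergenic"))))
  gene_id <- rep(NA_character_, n)
  if (length(gene_hits$hits)) {
    g <- index$by_type[["gene"]]
    ids <- if (!is.null(g$ID)) as.character(g$ID) else
      as.character(seq_along(g))
    qh <- S4Vectors::queryHits(gene_hits$hits)
    sh <- S4Vectors::subjectHits(gene_hits$hits)
    first <- tapply(ids[sh], qh, function(x) sort(x)[1])
    gene_id[as.integer(names(first))] <- unname(first)
  }
  data.frame(region = region, coding = in_cds, gene_id = gene_id)
}

#' Read a SIFT score table
#'
#' External SIFT scores keyed by (contig, pos, alt); scores are 0-1
#' tolerance scores where values below 0.05 are conventionally deleterious.
#'
#' @param path TSV with columns `contig`, `pos`, `alt`, `score`.
#' @return data.frame of class `sift_table`.
#' @export
read_sift <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   colClasses = c(contig = "character", pos = "integer",
                                  alt = "character", score = "numeric"))
  if (any(df$score < 0 | df$score > 1, na.rm = TRUE))
    stop("SIFT scores must lie in [0, 1]")
  structure(df, class = c("sift_table", "data.frame"))
}

#' Intolerance (deleteriousness) calls
#'
#' A variant is intolerant iff it is an SNV with a supplied SIFT score
#' strictly below 0.05, or an InDel overlapping a coding sequence. Variants
#' without a score are not intolerant on the SIFT basis.
#'
#' @param variants data.frame with `contig`, `pos`, `alt`, `vtype`.
#' @param regions Region calls from [classify_region()] (same row order).
#' @param sift Optional `sift_table`.
#' @param threshold SIFT deleteriousness threshold (strict less-than).
#' @return data.frame with `intolerant` (logical), `basis` (`"sift_score"`,
#'   `"coding_indel"`, `"none"`) and `sift_score`.
#' @export
intolerance <- function(variants, regions, sift = NULL, threshold = 0.05) {
  df <- as.data.frame(variants)
  stopifnot(nrow(df) == nrow(regions))
  score <- rep(NA_real_, nrow(df))
  if (!is.null(sift)) {
    key <- paste(df$contig, df$pos, df$alt)
    skey <- paste(sift$contig, sift$pos, sift$alt)
    score <- sift$score[match(key, skey)]
  }
  if (any(score < 0 | score > 1, na.rm = TRUE))
    stop("SIFT scores must lie in [0, 1]")
  by_sift <- df$vtype == "SNV" & !is.na(score) & score < threshold
  by_indel <- df$vtype %in% c("INS", "DEL") & regions$coding
  data.frame(intolerant = by_sift | by_indel,
             basis = ifelse(by_sift, "sift_score",
                            ifelse(by_indel, "coding_indel", "none")),
             sift_score = score)
}

#' Per-group region composition
#'
#' @param s A `singleton_set`.
#' @param regions Region calls from [classify_region()] (same row order).
#' @return data.frame per group (plus `"overall"`): counts and percentages
#'   per region; percentages partition 100 (up to rounding).
#' @export
region_summary <- function(s, regions) {
  stopifnot(inherits(s, "singleton_set"))
  lg <- attr(s, "line_groups")
  df <- cbind(as.data.frame(s), region = regions$region)
  lv <- c("intergenic", "UTR", "exon", "intron")
  groups <- c(sort(unique(unname(lg))), "overall")
  rows <- lapply(groups, function(g) {
    d <- if (g == "overall") df else df[df$group == g, , drop = FALSE]
    n <- nrow(d)
    cnt <- table(factor(d$region, levels = lv))
    out <- data.frame(group = g, n = n)
    for (r in lv) {
      out[[paste0("n_", r)]] <- as.integer(cnt[r])
      out[[paste0("pct_", r)]] <- if (n == 0) NA_real_ else
        round(100 * as.integer(cnt[r]) / n, 2)
    }
    out
  })
  do.call(rbind, rows)
}
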
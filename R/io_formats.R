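#' Cohort genotype table
#'
#' The central container for a genotyped MA cohort: a loci-by-lines matrix of
#' genotype cells plus per-line treatment labels.
#'
#' @param loci data.frame with columns `contig`, `pos`, `ref`, `alt`
#'   (1-based VCF anchor coordinates, one row per biallelic locus).
#' @param genotypes Character matrix, `nrow(loci)` x n_lines, cells drawn
#'   from [GT_CODES]; column names are line identifiers.
#' @param line_groups Named character vector mapping every line to its
#'   treatment label.
#' @return An object of class `cohort_table`.
#' @export
cohort_table <- function(loci, genotypes, line_groups) {
  stopifnot(is.data.frame(loci),
            all(c("contig", "pos", "ref", "alt") %in% names(loci)))
  genotypes <- as.matrix(genotypes)
  if (nrow(genotypes) != nrow(loci))
    stop("genotype matrix rows (", nrow(genotypes),
         ") do not match loci (", nrow(loci), ")")
  if (is.null(colnames(genotypes))) stop("genotype matrix must have line names")
  if (!all(genotypes %in% GT_CODES))
    stop("genotype cells must be one of: ", paste(GT_CODES, collapse = ", "))
  missing_grp <- setdiff(colnames(genotypes), names(line_groups))
  if (length(missing_grp))
    stop("line(s) without a group label: ", paste(missing_grp, collapse = ", "))
  line_groups <- line_groups[colnames(genotypes)]
  key <- paste(loci$contig, loci$pos, loci$ref, loci$alt)
  if (anyDuplicated(key)) stop("duplicate locus (contig,pos,ref,alt)")
  rownames(genotypes) <- NULL
  loci <- loci[, c("contig", "pos", "ref", "alt")]
  loci$pos <- as.integer(loci$pos)
  rownames(loci) <- NULL
  structure(list(loci = loci, genotypes = genotypes,
                 line_groups = line_groups),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("cohort_table:", nrow(x$loci), "loci x", ncol(x$genotypes), "lines,",
      length(unique(x$line_groups)), "group(s)\n")
  invisible(x)
}

#' @export
dim.cohort_table <- function(x) dim(x$genotypes)

## Map VCF GT strings to genotype cells for alt-allele index k (vectorized,
## k recycled per element). het = exactly one chromosome carries allele k;
## hom_alt = both do.
.gt_to_cell <- function(gt, k) {
  gt <- sub(":.*$", "", gt)                 # GT is the first colon-field
  alleles <- strsplit(gt, "[/|]")
  k <- rep_len(as.character(k), length(gt))
  out <- character(length(gt))
  for (i in seq_along(out)) {
    a <- alleles[[i]]
    if (length(a) == 0 || anyNA(a) || any(a == ".")) {
      out[i] <- "missing"
    } else if (!all(grepl("^[0-9]+$", a))) {
      stop("malformed GT field: ", gt[i])
    } else {
      n <- sum(a == k[i])
      out[i] <- if (length(a) == 1) {
        if (n == 1) "hom_alt" else "hom_ref"  # haploid call
      } else c("hom_ref", "het", "hom_alt")[n + 1L]
    }
  }
  out
}

## Read one VCF into a long per-allele table:
## contig, pos, ref, alt, one genotype column per sample.
.read_vcf_alleles <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  samples <- colnames(v@gt)[-1]
  if (n == 0) {
    out <- data.frame(contig = character(), pos = integer(),
                      ref = character(), alt = character(),
                      stringsAsFactors = FALSE)
    gt <- matrix(character(), 0, length(samples),
                 dimnames = list(NULL, samples))
    return(list(loci = out, cells = gt, samples = samples))
  }
  gt_raw <- v@gt[, -1, drop = FALSE]
  if (is.null(dim(gt_raw))) gt_raw <- matrix(gt_raw, nrow = n,
                                             dimnames = list(NULL, samples))
  alts <- strsplit(as.character(fix[, "ALT"]), ",", fixed = TRUE)
  rows <- rep(seq_len(n), lengths(alts))
  allele_k <- unlist(lapply(lengths(alts), seq_len), use.names = FALSE)
  loci <- data.frame(contig = as.character(fix[rows, "CHROM"]),
                     pos = as.integer(fix[rows, "POS"]),
                     ref = toupper(as.character(fix[rows, "REF"])),
                     alt = toupper(unlist(alts, use.names = FALSE)),
                     stringsAsFactors = FALSE)
  cells <- matrix("missing", nrow(loci), length(samples),
                  dimnames = list(NULL, samples))
  for (s in samples)
    cells[, s] <- .gt_to_cell(as.character(gt_raw[, s])[rows], allele_k)
  list(loci = loci, cells = cells, samples = samples)
}

#' Read a genotyped cohort from VCF
#'
#' Accepts either one joint multi-sample VCF or a set of per-line
#' single-sample VCFs. Genotype cells are mapped `0/0 -> hom_ref`,
#' `0/1` or `1/0 -> het`, `1/1 -> hom_alt`, `./. -> missing`; multi-allelic
#' records are split into one biallelic locus per alt allele, with the cell
#' determined by the count of that allele in the call. In the per-line
#' dialect a locus absent from a line's VCF defaults to `hom_ref` (set
#' `absent_means = "missing"` for callers that omit no-coverage sites).
#'
#' @param paths One path (joint VCF) or a named character vector of paths,
#'   names being line identifiers (per-line dialect).
#' @param groups Named character vector mapping line identifier to treatment
#'   label; every sample in the VCF(s) must be present.
#' @param dialect `"joint"` (one multi-sample VCF), `"per_line"` (one VCF
#'   per line, named by line), or `"auto"`: a single path is joint, several
#'   are per-line.
#' @param absent_means Cell value for loci absent from a per-line VCF.
#' @return A [cohort_table()].
#' @export
read_cohort_vcf <- function(paths, groups,
                            dialect = c("auto", "joint", "per_line"),
                            absent_means = c("hom_ref", "missing")) {
  absent_means <- match.arg(absent_means)
  dialect <- match.arg(dialect)
  if (dialect == "auto") dialect <- if (length(paths) == 1) "joint"
                                    else "per_line"
  if (dialect == "joint") {
    if (length(paths) != 1) stop("joint dialect expects exactly one VCF")
    parsed <- .read_vcf_alleles(paths)
    unknown <- setdiff(parsed$samples, names(groups))
    if (length(unknown))
      stop("sample(s) in VCF without group label: ",
           paste(unknown, collapse = ", "))
    tab <- cohort_table(parsed$loci, parsed$cells, groups)
  } else {
    if (is.null(names(paths)) || any(names(paths) == ""))
      stop("per-line VCF paths must be named by line identifier")
    unknown <- setdiff(names(paths), names(groups))
    if (length(unknown))
      stop("sample(s) in VCF without group label: ",
           paste(unknown, collapse = ", "))
    per <- lapply(paths, .read_vcf_alleles)
    all_loci <- unique(do.call(rbind, lapply(per, `[[`, "loci")))
    key <- function(df) paste(df$contig, df$pos, df$ref, df$alt)
    all_key <- key(all_loci)
    cells <- matrix(absent_means, nrow(all_loci), length(paths),
                    dimnames = list(NULL, names(paths)))
    for (ln in names(paths)) {
      p <- per[[ln]]
      if (nrow(p$loci) == 0) next
      idx <- match(key(p$loci), all_key)
      # a single-sample VCF has exactly one genotype column
      cells[idx, ln] <- p$cells[, 1]
    }
    tab <- cohort_table(all_loci, cells, groups)
  }
  sort_cohort(tab)
}

#' Sort a cohort table by (contig, pos, ref, alt)
#' @param table A `cohort_table`.
#' @return The sorted `cohort_table`.
#' @export
sort_cohort <- function(table) {
  o <- order(table$loci$contig, table$loci$pos, table$loci$ref, table$loci$alt)
  cohort_table(table$loci[o, , drop = FALSE],
               table$genotypes[o, , drop = FALSE],
               table$line_groups)
}

#' Write a cohort table as a joint multi-sample VCF 4.2 file
#'
#' @param table A `cohort_table`.
#' @param path Output path (plain text).
#' @param reference_name Optional reference tag for the header.
#' @return `path`, invisibly.
#' @export
write_cohort_vcf <- function(table, path, reference_name = NULL) {
  stopifnot(inherits(table, "cohort_table"))
  lines <- colnames(table$genotypes)
  hdr <- c("##fileformat=VCFv4.2",
           if (!is.null(reference_name)) paste0("##reference=", reference_name),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", lines), collapse = "\t"))
  gt_map <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1", missing = "./.")
  body <- character(nrow(table$loci))
  if (nrow(table$loci) > 0) {
    gt <- matrix(gt_map[table$genotypes], nrow = nrow(table$genotypes))
    body <- paste(table$loci$contig, table$loci$pos, ".", table$loci$ref,
                  table$loci$alt, ".", "PASS", ".", "GT",
                  apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a GFF3 annotation into an interval index
#'
#' Keeps the feature types used for region classification (`gene`, `exon`,
#' `CDS`, `five_prime_UTR`, `three_prime_UTR`) and supports point/interval
#' overlap queries.
#'
#' @param path Path to a GFF3 file.
#' @param keep_types Feature types to retain.
#' @return An object of class `gff_index` wrapping a `GRanges` per type.
#' @export
read_gff <- function(path,
                     keep_types = c("gene", "exon", "CDS",
                                    "five_prime_UTR", "three_prime_UTR")) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (any(GenomicRanges::end(gr) < GenomicRanges::start(gr)))
    stop("GFF feature with end < start")
  gr <- gr[as.character(gr$type) %in% keep_types]
  by_type <- lapply(setNames(keep_types, keep_types), function(tp) {
    gr[as.character(gr$type) == tp]
  })
  structure(list(by_type = by_type, types = keep_types), class = "gff_index")
}

#' @export
print.gff_index <- function(x, ...) {
  cat("gff_index:",
      paste(sprintf("%s=%d", x$types,
                    vapply(x$by_type, length, integer(1))), collapse = ", "),
      "\n")
  invisible(x)
}

#' Query feature types overlapping a position or interval
#'
#' @param index A `gff_index`.
#' @param contig Contig name.
#' @param start,end 1-based inclusive interval (point query when equal).
#' @return Character vector of overlapping feature types (possibly empty).
#' @export
query_features <- function(index, contig, start, end = start) {
  stopifnot(inherits(index, "gff_index"))
  known <- unique(unlist(lapply(index$by_type, function(g)
    as.character(GenomicRanges::seqnames(g)))))
  if (!contig %in% known)
    stop("contig not present in annotation: ", contig)
  q <- GenomicRanges::GRanges(contig, IRanges::IRanges(start, end))
  hit <- vapply(index$by_type, function(g) {
    length(GenomicRanges::findOverlaps(q, g)) > 0
  }, logical(1))
  names(hit)[hit]
}

## Fixed-precision numeric formatting for report files: deterministic and
## re-parseable.
.fmt_col <- function(x, digits = 6) {
  if (is.double(x)) ifelse(is.na(x), "NA", formatC(x, digits = digits,
                                                   format = "g"))
  else x
}

#' Write report tables as TSV files
#'
#' Writes each data.frame in `results` to `<out_dir>/<name>.tsv` with a fixed
#' column order, stable row order as given, and fixed float precision, so a
#' repeated run yields byte-identical files.
#'
#' @param results Named list of data.frames.
#' @param out_dir Output directory (created if absent).
#' @param digits Significant digits for floating-point columns.
#' @return Character vector of written paths, invisibly.
#' @export
write_report_tables <- function(results, out_dir, digits = 6) {
  stopifnot(is.list(results), !is.null(names(results)))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(results)) {
    df <- as.data.frame(results[[nm]])
    df[] <- lapply(df, .fmt_col, digits = digits)
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = TRUE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read a singleton table written by [write_report_tables()]
#' @param path Path to a singletons TSV.
#' @param line_groups Named character vector of line -> group (restores the
#'   full line roster, including zero-singleton lines).
#' @return A `singleton_set`.
#' @export
read_singletons_tsv <- function(path, line_groups) {
  df <- read.table(path, sep = "\t", header = TRUE, colClasses = c(
    contig = "character", pos = "integer", ref = "character",
    alt = "character", vtype = "character", size = "integer",
    line = "character", group = "character", zygosity = "character"))
  as_singleton_set(df, line_groups)
}
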
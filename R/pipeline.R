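#' Read a two-column line-to-group table
#' @param path TSV with columns `line`, `group`.
#' @return Named character vector line -> group.
#' @export
read_groups <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   colClasses = c(line = "character", group = "character"))
  setNames(df$group, df$line)
}

#' Run the full post-calling analysis pipeline
#'
#' Reads a cohort VCF, applies locus filters, selects singletons, and
#' produces composition summaries, zygosity-weighted rate estimates, the
#' substitution spectrum with per-line transition fractions and t-tests
#' against the reference group, flanking-context matrices for mutated C and
#' G sites, the chromosome distribution, the InDel report, and (when a GFF
#' / SIFT table is supplied) region and intolerance annotation. All tables
#' are written to `out_dir` together with a JSON manifest (parameters,
#' seed, package version, input digests) sufficient to reproduce the run.
#'
#' @param vcf Path to a joint VCF, or named vector of per-line VCFs.
#' @param reference Path to the reference FASTA.
#' @param groups Path to a line/group TSV, or a named character vector.
#' @param out_dir Output directory.
#' @param gff Optional GFF3 path (region stage skipped when NULL).
#' @param sift Optional SIFT TSV path.
#' @param cfg A [filter_config()].
#' @param reference_group Group used as the comparison baseline (default
#'   `"CK"` when present, else the alphabetically first group).
#' @param D,g Diploid site factor and generations for rate estimation.
#' @param k Flank width for context matrices.
#' @param seed Seed recorded in the manifest (the pipeline itself is
#'   deterministic given its inputs).
#' @return Invisibly, a list with every stage's in-memory result.
#' @export
run_pipeline <- function(vcf, reference, groups, out_dir, gff = NULL,
                         sift = NULL, cfg = filter_config(),
                         reference_group = NULL, D = 2, g = 1, k = 5,
                         seed = NULL) {
  inputs <- c(vcf = unname(vcf)[1], reference = reference,
              gff = gff, sift = sift)
  if (is.character(groups) && length(groups) == 1 && file.exists(groups)) {
    inputs["groups"] <- groups
    groups <- read_groups(groups)
  }
  genome <- read_reference(reference)
  cohort <- read_cohort_vcf(vcf, groups)
  filtered <- apply_locus_filters(cohort, cfg)
  s <- select_singletons(filtered)
  notes <- character(0)

  grp_levels <- sort(unique(unname(groups)))
  if (is.null(reference_group))
    reference_group <- if ("CK" %in% grp_levels) "CK" else grp_levels[1]

  res <- list(singletons = as.data.frame(s),
              composition = summarize_singletons(s))
  res$rates <- do.call(rbind, lapply(c("all", "SNV", "InDel"), function(v)
    cbind(vtype = v, estimate_group_rates(s, genome, g = g, D = D,
                                          vtype = v))))
  counts <- per_line_counts(s)
  res$per_line_counts <- data.frame(line = names(counts$per_line),
                                    group = unname(groups[names(counts$per_line)]),
                                    count = unname(counts$per_line))
  res$group_means <- counts$group_means

  spec <- spectrum_table(s)
  res$spectrum_classes <- spec$classes
  res$spectrum_summary <- spec$summary
  tf <- transition_fraction_per_line(s)
  res$transition_fractions <- tf
  usable <- table(tf$group)
  if (length(usable) >= 2 && reference_group %in% names(usable) &&
      all(usable >= 2)) {
    res$transition_t_tests <- proportion_t_test(tf$fraction, tf$group,
                                                reference_group)
  } else notes <- c(notes, "transition t-tests skipped: too few usable lines")

  ctx <- list()
  for (b in c("C", "G")) for (gr in c(list(NULL), as.list(grp_levels))) {
    lab <- paste0("ctx_", b, "_", gr %||% "all")
    cm <- tryCatch(context_frequency_matrix(s, genome, base = b, group = gr,
                                            k = k),
                   error = function(e) NULL)
    if (!is.null(cm)) ctx[[lab]] <- cm
  }
  res$context_matrices <- ctx
  res$chromosome_distribution <- chromosome_distribution(s, genome)
  res$indels <- indel_report(s, genome)

  if (!is.null(gff)) {
    idx <- read_gff(gff)
    regions <- classify_region(idx, s)
    sift_tab <- if (!is.null(sift)) read_sift(sift) else NULL
    res$regions <- cbind(as.data.frame(s)[, c("contig", "pos", "ref", "alt",
                                              "vtype", "line", "group")],
                         regions,
                         intolerance(s, regions, sift_tab))
    res$region_summary <- region_summary(s, regions)
    if (is.null(sift))
      notes <- c(notes, "no SIFT table: intolerance calls use coding InDels only")
  } else {
    notes <- c(notes, "no GFF supplied: region/intolerance stage skipped")
  }

  tables <- list(singletons = res$singletons,
                 composition = res$composition,
                 rates = res$rates,
                 per_line_counts = res$per_line_counts,
                 spectrum_classes = res$spectrum_classes,
                 spectrum_summary = res$spectrum_summary,
                 transition_fractions = res$transition_fractions,
                 chromosome_means = res$chromosome_distribution$means,
                 chromosome_anova = res$chromosome_distribution$anova,
                 indel_by_group = res$indels$by_group)
  if (!is.null(res$transition_t_tests))
    tables$transition_t_tests <- res$transition_t_tests
  if (!is.null(res$regions)) {
    tables$regions <- res$regions
    tables$region_summary <- res$region_summary
  }
  for (nm in names(ctx)) {
    m <- ctx[[nm]]$matrix
    tables[[nm]] <- cbind(data.frame(base = rownames(m)), as.data.frame(m))
  }
  write_report_tables(tables, out_dir)

  manifest <- list(
    package = "mamutspec",
    version = as.character(packageVersion("mamutspec")),
    seed = seed,
    parameters = list(max_missing_fraction = cfg$max_missing_fraction,
                      max_het_fraction = cfg$max_het_fraction,
                      het_denominator = cfg$het_denominator,
                      reference_group = reference_group,
                      diploid_factor = D, generations = g, flank_k = k,
                      sites = genome$non_n_length),
    inputs = as.list(tools::md5sum(inputs[!is.na(inputs)])),
    notes = notes)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(res)
}
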
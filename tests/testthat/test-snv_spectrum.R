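test_that("all 12 directed substitution classes are labeled correctly", {
  purines <- c("A", "G"); pyrimidines <- c("C", "T")
  for (r in c(purines, pyrimidines)) for (a in c(purines, pyrimidines)) {
    if (r == a) next
    got <- substitution_class(r, a)
    expect_equal(got$class, paste0(r, ">", a))
    both_pur <- r %in% purines && a %in% purines
    both_pyr <- r %in% pyrimidines && a %in% pyrimidines
    expect_equal(got$ti_tv,
                 if (both_pur || both_pyr) "transition" else "transversion")
    expect_equal(got$category,
                 if (both_pur) "pur_pur" else if (both_pyr) "pyr_pyr"
                 else "cross")
  }
  expect_equal(substitution_class("C", "T")$ti_tv, "transition")
  expect_equal(substitution_class("A", "C")$ti_tv, "transversion")
  expect_error(substitution_class("N", "A"), "A/C/G/T")
})

test_that("spectrum table satisfies the class-count identities", {
  set.seed(42)
  n <- 400
  lines <- paste0("L", 1:10)
  lg <- setNames(rep(c("CK", "TX"), each = 5), lines)
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- vapply(ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1), character(1))
  df <- data.frame(contig = "chr1", pos = seq_len(n) * 10L, ref = ref,
                   alt = alt, vtype = "SNV", size = 0L,
                   line = sample(lines, n, replace = TRUE),
                   zygosity = "heterozygous")
  df$group <- unname(lg[df$line])
  s <- as_singleton_set(df, lg)
  spec <- spectrum_table(s, collapse6 = TRUE)
  for (g in unique(spec$summary$group)) {
    cls <- spec$classes[spec$classes$group == g, ]
    sm <- spec$summary[spec$summary$group == g, ]
    expect_equal(sum(cls$count), sm$n_snv)
    expect_equal(sm$n_transition + sm$n_transversion, sm$n_snv)
    expect_equal(sm$n_pyr_pyr,
                 sum(cls$count[cls$class %in% c("C>T", "T>C")]))
    expect_equal(sm$n_pur_pur,
                 sum(cls$count[cls$class %in% c("A>G", "G>A")]))
    cls6 <- spec$classes6[spec$classes6$group == g, ]
    expect_equal(sum(cls6$count), sm$n_snv)
  }
  single <- make_singletons(1)  # one C>T
  expect_equal(spectrum_table(single)$summary$pct_transition[3], 100)
})

test_that("per-line transition fractions match a pooled recount", {
  lg <- c(A = "CK", B = "CK", C = "TX")
  df <- data.frame(contig = "chr1", pos = (1:6) * 10L,
                   ref = c("C", "C", "A", "A", "G", "G"),
                   alt = c("T", "G", "G", "T", "A", "A"),
                   vtype = "SNV", size = 0L,
                   line = c("A", "A", "A", "A", "B", "B"),
                   zygosity = "heterozygous")
  df$group <- unname(lg[df$line])
  s <- as_singleton_set(df, lg)
  tf <- transition_fraction_per_line(s)
  expect_equal(tf$fraction[tf$line == "A"], 0.5)  # 2 ti of 4
  expect_equal(tf$fraction[tf$line == "B"], 1.0)
  expect_equal(attr(tf, "excluded_lines"), "C")
  # group mean equals direct pooled recomputation per line
  expect_equal(mean(tf$fraction[tf$group == "CK"]), mean(c(0.5, 1.0)))
})

test_that("flank extraction slices the reference and excludes edges", {
  g <- reference_genome(c(c1 = "AAACGTAAAAA"))
  expect_equal(extract_flanks(g, "c1", 6, k = 2), "CGTAA")
  expect_true(is.na(extract_flanks(g, "c1", 2, k = 5)))
  expect_error(extract_flanks(g, "c1", 50), "off contig")
  set.seed(8)
  big <- random_genome(500)
  seq <- big$contigs[[1]]
  for (pos in sample(6:495, 50))
    expect_equal(extract_flanks(big, "chr1", pos, k = 5),
                 substring(seq, pos - 5, pos + 5))
})

test_that("context matrices are column-normalized with consistent focus", {
  set.seed(13)
  g <- random_genome(4000)
  seq <- g$contigs[[1]]
  pos <- sample(10:3990, 120)
  ref <- vapply(pos, function(p) substring(seq, p, p), character(1))
  alt <- vapply(ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1), character(1))
  lg <- c(L1 = "CK")
  s <- as_singleton_set(
    data.frame(contig = "chr1", pos = pos, ref = ref, alt = alt,
               vtype = "SNV", size = 0L, line = "L1", group = "CK",
               zygosity = "heterozygous"), lg)
  cm <- context_frequency_matrix(s, g, base = "C")
  expect_equal(unname(colSums(cm$matrix)), rep(1, 11), tolerance = 1e-9)
  # position 0 equals the subset's mutated-base composition
  expect_equal(unname(cm$matrix["C", "0"]), 1)
  expect_equal(cm$n_sites + cm$n_edge_excluded, sum(ref == "C"))

  # single site -> 0/1 indicator columns
  s1 <- as_singleton_set(
    data.frame(contig = "chr1", pos = 100L,
               ref = substring(seq, 100, 100),
               alt = setdiff(c("A", "C", "G", "T"),
                             substring(seq, 100, 100))[1],
               vtype = "SNV", size = 0L, line = "L1", group = "CK",
               zygosity = "heterozygous"), lg)
  cm1 <- context_frequency_matrix(s1, g)
  expect_true(all(cm1$matrix %in% c(0, 1)))
  expect_false(any(cm1$tie))

  # lexicographic tie-breaking is flagged
  g2 <- reference_genome(c(c1 = "ATCGATCGATCGATCG"))
  s2 <- as_singleton_set(
    data.frame(contig = "c1", pos = c(7L, 10L), ref = c("C", "A"),
               alt = c("T", "G"), vtype = "SNV", size = 0L, line = "L1",
               group = "CK", zygosity = "heterozygous"), lg)
  cm2 <- context_frequency_matrix(s2, g2, k = 2)
  expect_true(any(cm2$tie))  # every column is an even two-base split
  expect_error(context_frequency_matrix(s, g, base = "C", group = "TX"),
               "empty subset")
})

test_that("chromosome distribution conserves totals and reports zeros", {
  cfg <- sim_config(genome_length = 1e5, n_contigs = 4,
                    germline_variant_count = 0, snv_rate = 8e-6,
                    indel_rate = 0, n_lines_per_group = 5,
                    groups = c("CK", "TX"), seed = 17)
  sim <- simulate_cohort(cfg)
  s <- select_singletons(apply_locus_filters(sim$cohort))
  cd <- chromosome_distribution(s, sim$genome)
  L <- 5
  total_from_means <- sum(cd$means$mean * L)
  expect_equal(total_from_means, nrow(s))
  expect_setequal(unique(cd$means$contig), names(sim$genome$contigs))

  # all variants on one contig -> zero means elsewhere
  one <- as.data.frame(s)
  one$contig <- names(sim$genome$contigs)[1]
  one$pos <- seq_len(nrow(one)) * 3L
  s_one <- as_singleton_set(one, attr(s, "line_groups"))
  cd1 <- chromosome_distribution(s_one, sim$genome)
  off <- cd1$means[cd1$means$contig != names(sim$genome$contigs)[1], ]
  expect_true(all(off$mean == 0))
})
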
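test_that("simulated reference honors GC content, seeding and salting", {
  cfg0 <- sim_config(genome_length = 2e4, n_contigs = 2, gc_fraction = 0,
                     germline_variant_count = 0, seed = 1)
  g <- simulate_reference(cfg0)
  expect_false(grepl("[CG]", paste(g$contigs, collapse = "")))

  cfg <- sim_config(genome_length = 5e4, n_contigs = 2,
                    germline_variant_count = 400, seed = 9)
  g1 <- simulate_reference(cfg)
  g2 <- simulate_reference(cfg)
  expect_identical(g1$contigs, g2$contigs)

  # observed GC within 3 sd of binomial expectation at gc = 0.36
  chars <- table(strsplit(paste(g1$contigs, collapse = ""), "")[[1]])
  gc_obs <- sum(chars[c("C", "G")]) / sum(chars)
  expect_lt(abs(gc_obs - 0.36), 3 * sqrt(0.36 * 0.64 / 5e4) + 0.01)

  tr <- attr(g1, "repeat_tracts")
  expect_gt(nrow(tr), 0)
  # planted tracts really sit in the sequence
  for (i in sample(nrow(tr), min(10, nrow(tr)))) {
    str <- get_seq(g1, tr$contig[i], tr$start[i], tr$end[i])
    expect_identical(str, strrep(tr$unit[i],
                                 (tr$end[i] - tr$start[i] + 1) /
                                   nchar(tr$unit[i])))
  }
})

test_that("germline planting respects counts and multi-line sharing", {
  cfg <- sim_config(genome_length = 5e4, germline_variant_count = 0,
                    n_lines_per_group = 3, groups = c("CK", "TX"), seed = 2)
  g <- simulate_reference(cfg)
  empty <- plant_germline_variants(g, cfg)
  expect_equal(nrow(empty$variants), 0)

  cfg <- sim_config(genome_length = 5e4, germline_variant_count = 100,
                    n_lines_per_group = 3, groups = c("CK", "TX"), seed = 2)
  g <- simulate_reference(cfg)
  germ <- plant_germline_variants(g, cfg)
  expect_equal(nrow(germ$variants), 100)
  carriers_per <- table(germ$carriers$variant_id)
  expect_true(all(carriers_per >= 2))
  # each planted ref allele matches the genome
  for (i in sample.int(100, 20))
    expect_identical(get_seq(g, germ$variants$contig[i],
                             germ$variants$pos[i]),
                     germ$variants$ref[i])
})

test_that("de novo planting follows configured rates, classes and zygosity", {
  cfg0 <- sim_config(genome_length = 5e4, germline_variant_count = 0,
                     snv_rate = 0, indel_rate = 0, n_lines_per_group = 2,
                     groups = "CK", seed = 3)
  sim <- simulate_cohort(cfg0)
  expect_equal(nrow(sim$truth$denovo), 0)

  cfg1 <- sim_config(genome_length = 1e5, germline_variant_count = 0,
                     transition_fraction = 1, snv_rate = 2e-5,
                     indel_rate = 0, n_lines_per_group = 5, groups = "CK",
                     seed = 4)
  sim <- simulate_cohort(cfg1)
  dn <- sim$truth$denovo
  expect_gt(nrow(dn), 0)
  expect_true(all(dn$class %in% c("A>G", "G>A", "C>T", "T>C")))

  # per-line planted SNVs consistent with the Poisson expectation on the
  # observed scale (D = 2, heritable-rate to observed-count factor)
  mu <- 2e-5 * 2 * sim$genome$non_n_length * 2 / 1.17
  counts <- numeric(0)
  for (sd in 1:5) {
    cfg <- sim_config(genome_length = 1e5, germline_variant_count = 0,
                      snv_rate = 2e-5, indel_rate = 0,
                      n_lines_per_group = 5, groups = "CK", seed = sd)
    counts <- c(counts, table(factor(simulate_cohort(cfg)$truth$denovo$line,
                                     levels = names(sim_line_groups(cfg)))))
  }
  expect_lt(abs(mean(counts) - mu), 3 * sqrt(mu / length(counts)))
})

test_that("planted variants anchor on the reference and recover exactly", {
  cfg <- sim_config(genome_length = 2e5, germline_variant_count = 200,
                    n_lines_per_group = 8, groups = c("CK", "TX"),
                    snv_rate = 5e-6, indel_rate = 1e-6, seed = 5)
  sim <- simulate_cohort(cfg)
  # every emitted allele matches the reference at its anchor
  loci <- sim$cohort$loci
  for (i in seq_len(nrow(loci)))
    expect_identical(get_seq(sim$genome, loci$contig[i], loci$pos[i],
                             loci$pos[i] + nchar(loci$ref[i]) - 1),
                     loci$ref[i])
  # de novo variants are singletons by construction; germline never
  s <- select_singletons(apply_locus_filters(sim$cohort))
  dn <- sim$truth$denovo
  expect_equal(nrow(s), nrow(dn))
  expect_setequal(paste(s$contig, s$pos, s$line),
                  paste(dn$contig, dn$pos, dn$line))
  expect_length(intersect(paste(s$contig, s$pos),
                          paste(sim$truth$germline$contig,
                                sim$truth$germline$pos)), 0)
})

test_that("cohort emission is deterministic and round-trips through the readers", {
  cfg <- sim_config(genome_length = 5e4, germline_variant_count = 50,
                    n_lines_per_group = 4, groups = c("CK", "TX"),
                    snv_rate = 5e-6, indel_rate = 1e-6, seed = 6)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- emit_cohort(simulate_cohort(cfg), d1)
  p2 <- emit_cohort(simulate_cohort(cfg), d2)
  for (nm in names(p1))
    expect_identical(readLines(p1[[nm]]), readLines(p2[[nm]]))

  sim <- simulate_cohort(cfg)
  back <- read_cohort_vcf(unname(p1["vcf"]), read_groups(p1[["groups"]]))
  expect_identical(back$loci, sim$cohort$loci)
  expect_identical(back$genotypes, sim$cohort$genotypes)
  g <- read_reference(p1[["reference"]])
  expect_identical(g$contigs, sim$genome$contigs)

  # empty truth still yields a valid, readable VCF
  cfg0 <- sim_config(genome_length = 2e4, germline_variant_count = 0,
                     snv_rate = 0, indel_rate = 0, n_lines_per_group = 2,
                     groups = "CK", seed = 1)
  p0 <- emit_cohort(simulate_cohort(cfg0), withr::local_tempdir())
  back0 <- read_cohort_vcf(unname(p0["vcf"]), read_groups(p0[["groups"]]))
  expect_equal(nrow(back0$loci), 0)
})
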
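test_that("insertion/deletion counts, ratio and undefined flag", {
  s <- make_singletons(946, 47, 62, n_hom = 178)
  r <- ins_del_ratio(s)
  ov <- r[r$group == "overall", ]
  expect_equal(ov$n_ins, 47); expect_equal(ov$n_del, 62)
  expect_equal(ov$ratio, 0.76)

  s2 <- make_singletons(0, 0, 5)
  expect_equal(ins_del_ratio(s2)[3, "ratio"], 0)
  s3 <- make_singletons(0, 5, 0)
  ov3 <- ins_del_ratio(s3)
  expect_true(is.na(ov3$ratio[ov3$group == "overall"]))
  expect_false(ov3$ratio_defined[ov3$group == "overall"])
})

test_that("size classes partition at the threshold and per-line means", {
  lg <- setNames(rep("CK", 40), paste0("L", sprintf("%02d", 1:40)))
  df <- data.frame(contig = "chr1", pos = (1:4) * 50L,
                   ref = c("A", "A", "A", "A"),
                   alt = c("AT", "ATT", "ATTT", "ATTTT"),
                   vtype = "INS", size = 1:4,
                   line = names(lg)[1:4], group = "CK",
                   zygosity = "heterozygous")
  s <- as_singleton_set(df, lg)
  sc <- size_class_counts(s)
  ov <- sc[sc$group == "overall", ]
  expect_equal(ov$n_short, 3)  # sizes 1,2,3 at the <=3 boundary
  expect_equal(ov$n_long, 1)
  expect_equal(ov$n_short + ov$n_long, ov$n_indel)
  expect_equal(ov$per_line_long, round(1 / 40, 2))
  # 4 long InDels over 40 lines -> 0.10 per line
  df4 <- df; df4$size <- rep(4L, 4); df4$alt <- "ATTTT"
  expect_equal(size_class_counts(as_singleton_set(df4, lg))[2, "per_line_long"],
               0.10)
  # partition is exhaustive/exclusive at any threshold
  for (th in c(1, 2, 5)) {
    sct <- size_class_counts(s, threshold = th)
    expect_true(all(sct$n_short + sct$n_long == sct$n_indel))
  }
})

test_that("homopolymer adjacency follows the boundary-run rule", {
  #          123456789
  g <- reference_genome(c(c1 = "CAAAAGTACGTACCCCACGT"))
  # deletion of one A with remaining run AAA >= 4 counting the deleted base
  expect_true(homopolymer_adjacent(g, "c1", 1, "CA", "C"))
  # deletion of T in mixed context
  expect_false(homopolymer_adjacent(g, "c1", 6, "GT", "G"))
  # insertion of C next to CCCC run
  expect_true(homopolymer_adjacent(g, "c1", 16, "C", "CC"))
  # insertion of a 4-base homopolymer creates a run on its own
  expect_true(homopolymer_adjacent(g, "c1", 7, "T", "TGGGG"))
  expect_false(homopolymer_adjacent(g, "c1", 7, "T", "TGGG"))
  expect_error(homopolymer_adjacent(g, "c1", 7, "T", "A"), "SNV")
})

test_that("tandem-repeat adjacency detects abutting units", {
  g <- reference_genome(c(c1 = "GGTATATATCCGCAAAATTTGCATCATCATGG"))
  # insertion of AT next to (AT)x3 at 3..8
  expect_true(repeat_adjacent(g, "c1", 9, "T", "TAT"))
  # insertion of GC next to AAAA: no tandem (homopolymer only)
  expect_false(repeat_adjacent(g, "c1", 17, "A", "AGC"))
  expect_true(homopolymer_adjacent(g, "c1", 17, "A", "AGC"))
  expect_true(homopolymer_adjacent(g, "c1", 13, "C", "CA"))
  # deletion of the last CAT unit from (CAT)x3 at 22..30
  expect_true(repeat_adjacent(g, "c1", 27, "TCAT", "T"))
  # a middle-unit deletion leaves <3 copies on each side: not adjacent
  expect_false(repeat_adjacent(g, "c1", 24, "TCAT", "T"))
  # precedence: homopolymer wins when both would match
  expect_equal(indel_adjacency(g, "c1", 17, "A", "AA"), "homopolymer")
})

test_that("adjacency classifiers equal brute-force oracles on random InDels", {
  set.seed(77)
  g <- random_genome(5000)
  seq <- g$contigs[[1]]
  n_checked <- 0
  for (i in 1:800) {
    pos <- sample(30:4950, 1)
    size <- sample(1:6, 1)
    if (runif(1) < 0.5) {
      ins <- paste(sample(c("A", "C", "G", "T"), size, replace = TRUE),
                   collapse = "")
      ref <- substring(seq, pos, pos)
      alt <- paste0(ref, ins)
    } else {
      ref <- substring(seq, pos, pos + size)
      alt <- substring(seq, pos, pos)
    }
    expect_identical(homopolymer_adjacent(g, "chr1", pos, ref, alt),
                     naive_hp_adjacent(seq, pos, ref, alt))
    expect_identical(repeat_adjacent(g, "chr1", pos, ref, alt),
                     naive_rep_adjacent(seq, pos, ref, alt))
    n_checked <- n_checked + 1
  }
  expect_equal(n_checked, 800)
})

test_that("indel report aggregates counts, adjacency and conservation", {
  cfg <- sim_config(genome_length = 2e5, germline_variant_count = 0,
                    snv_rate = 0, indel_rate = 6e-6, n_lines_per_group = 8,
                    groups = c("CK", "TX"), seed = 23)
  sim <- simulate_cohort(cfg)
  s <- select_singletons(apply_locus_filters(sim$cohort))
  rep <- indel_report(s, sim$genome)
  bg <- rep$by_group
  ov <- bg[bg$group == "overall", ]
  expect_equal(ov$n_ins + ov$n_del, ov$n_indel)
  expect_equal(ov$n_short + ov$n_long, ov$n_indel)
  expect_equal(nrow(rep$records), ov$n_indel)
  # planted repeat-adjacent InDels are called adjacent
  dn <- sim$truth$denovo
  planted <- paste(dn$contig[dn$planted_adjacent], dn$pos[dn$planted_adjacent])
  called <- paste(rep$records$contig, rep$records$pos)
  adj_called <- called[rep$records$adjacency != "none"]
  expect_true(all(planted %in% adj_called))

  # empty group yields a zeroed row
  lg0 <- c(L1 = "CK", L2 = "CK", L3 = "EMPTY", L4 = "EMPTY")
  df <- data.frame(contig = "chr1", pos = c(50L, 90L), ref = "AT",
                   alt = "A", vtype = "DEL", size = 1L,
                   line = c("L1", "L2"), group = "CK",
                   zygosity = "heterozygous")
  g0 <- random_genome(200)
  s0 <- as_singleton_set(df, lg0)
  r0 <- indel_report(s0, g0)
  row_empty <- r0$by_group[r0$by_group$group == "EMPTY", ]
  expect_equal(row_empty$n_indel, 0)
  expect_true(is.na(row_empty$pct_adjacent))
})
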
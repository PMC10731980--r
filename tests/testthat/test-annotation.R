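make_gff <- function() {
  f <- withr::local_tempfile(fileext = ".gff3", .local_envir = parent.frame())
  writeLines(c(
    "##gff-version 3",
    "chr1\tt\tgene\t100\t1000\t.\t+\t.\tID=g1",
    "chr1\tt\tfive_prime_UTR\t100\t149\t.\t+\t.\tParent=g1.1",
    "chr1\tt\texon\t100\t400\t.\t+\t.\tParent=g1.1",
    "chr1\tt\tCDS\t150\t400\t.\t+\t0\tParent=g1.1",
    "chr1\tt\texon\t600\t800\t.\t+\t.\tParent=g1.1",
    "chr1\tt\tCDS\t600\t700\t.\t+\t0\tParent=g1.1",
    "chr1\tt\tthree_prime_UTR\t701\t800\t.\t+\t.\tParent=g1.1",
    "chr1\tt\tgene\t2000\t2500\t.\t-\t.\tID=g2",
    "chr1\tt\texon\t2000\t2500\t.\t-\t.\tParent=g2.1"), f)
  f
}

test_that("region classification follows the stated precedence", {
  idx <- read_gff(make_gff())
  v <- data.frame(contig = "chr1",
                  pos = c(200L, 500L, 120L, 750L, 2100L, 5000L),
                  ref = "A", alt = "T")
  rc <- classify_region(idx, v)
  expect_equal(rc$region,
               c("exon", "intron", "UTR", "UTR", "exon", "intergenic"))
  expect_equal(rc$coding, c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
  expect_true(all(rc$coding == (rc$coding & rc$region == "exon")))
  expect_equal(rc$gene_id[1], "g1")
  expect_true(is.na(rc$gene_id[6]))

  # an InDel spanning into a CDS is classified by any overlap
  del <- data.frame(contig = "chr1", pos = 145L,
                    ref = paste(rep("A", 10), collapse = ""), alt = "A")
  expect_equal(classify_region(idx, del)$region, "exon")
  expect_true(classify_region(idx, del)$coding)
})

test_that("random positions agree with a naive feature scan", {
  idx <- read_gff(make_gff())
  feats <- data.frame(
    contig = "chr1",
    type = c("gene", "five_prime_UTR", "exon", "CDS", "exon", "CDS",
             "three_prime_UTR", "gene", "exon"),
    start = c(100, 100, 100, 150, 600, 600, 701, 2000, 2000),
    end = c(1000, 149, 400, 400, 800, 700, 800, 2500, 2500))
  naive_region <- function(pos) {
    tps <- naive_feature_scan(feats, "chr1", pos)
    if ("CDS" %in% tps) "exon"
    else if (any(c("five_prime_UTR", "three_prime_UTR") %in% tps)) "UTR"
    else if ("exon" %in% tps) "exon"
    else if ("gene" %in% tps) "intron"
    else "intergenic"
  }
  set.seed(31)
  pos <- sample.int(6000, 400)
  rc <- classify_region(idx, data.frame(contig = "chr1", pos = pos,
                                        ref = "A", alt = "T"))
  expect_equal(rc$region, vapply(pos, naive_region, character(1)))
})

test_that("intolerance calls follow the SIFT/coding-InDel rule", {
  regions <- data.frame(region = c("exon", "exon", "exon", "intergenic"),
                        coding = c(TRUE, TRUE, TRUE, FALSE),
                        gene_id = c("g1", "g1", "g1", NA))
  v <- data.frame(contig = "chr1", pos = c(200L, 210L, 220L, 5000L),
                  alt = c("T", "G", "A", "C"),
                  vtype = c("SNV", "SNV", "DEL", "SNV"))
  sift <- structure(data.frame(contig = "chr1", pos = c(200L, 210L),
                               alt = c("T", "G"), score = c(0.04, 0.05)),
                    class = c("sift_table", "data.frame"))
  ic <- intolerance(v, regions, sift)
  expect_equal(ic$intolerant, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(ic$basis, c("sift_score", "none", "coding_indel", "none"))
  # no score and non-coding -> never intolerant for SNVs
  ic2 <- intolerance(v, regions, sift = NULL)
  expect_equal(ic2$intolerant, c(FALSE, FALSE, TRUE, FALSE))
  bad <- sift; bad$score[1] <- 1.2
  expect_error(intolerance(v, regions, bad), "\\[0, 1\\]")
})

test_that("region percentages per group partition 100", {
  set.seed(3)
  idx <- read_gff(make_gff())
  lg <- c(L1 = "CK", L2 = "TX")
  n <- 60
  df <- data.frame(contig = "chr1", pos = sample.int(6000, n), ref = "A",
                   alt = "T", vtype = "SNV", size = 0L,
                   line = sample(names(lg), n, replace = TRUE),
                   zygosity = "heterozygous")
  df$group <- unname(lg[df$line])
  s <- as_singleton_set(df, lg)
  rc <- classify_region(idx, s)
  rs <- region_summary(s, rc)
  pct <- rs$pct_intergenic + rs$pct_UTR + rs$pct_exon + rs$pct_intron
  expect_true(all(abs(pct - 100) <= 0.02))
})

test_that("pipeline runs are deterministic and degrade without a GFF", {
  cfg <- sim_config(genome_length = 5e4, germline_variant_count = 60,
                    n_lines_per_group = 5, groups = c("CK", "TX"),
                    snv_rate = 1e-5, indel_rate = 2e-6, seed = 12)
  sim <- simulate_cohort(cfg)
  src <- withr::local_tempdir()
  paths <- emit_cohort(sim, src)
  gff <- make_gff()

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  res1 <- run_pipeline(unname(paths["vcf"]), paths[["reference"]],
                       paths[["groups"]], d1, gff = gff, seed = 1)
  res2 <- run_pipeline(unname(paths["vcf"]), paths[["reference"]],
                       paths[["groups"]], d2, gff = gff, seed = 1)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  expect_true(file.exists(file.path(d1, "manifest.json")))
  expect_true("region_summary" %in%
                sub("\\.tsv$", "", list.files(d1, pattern = "tsv$")))

  d3 <- withr::local_tempdir()
  res3 <- run_pipeline(unname(paths["vcf"]), paths[["reference"]],
                       paths[["groups"]], d3, gff = NULL, seed = 1)
  man <- jsonlite::read_json(file.path(d3, "manifest.json"))
  expect_true(any(grepl("region", unlist(man$notes))))
  expect_false(file.exists(file.path(d3, "region_summary.tsv")))
})
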
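test_that("packaged counts table parses to the published genotype and allele counts", {
  pairs <- fixture_pairs()
  expect_length(pairs, 3L)
  ids <- vapply(pairs, function(p) p$snp$snp_id, character(1))
  expect_identical(ids, c("rs2071287", "rs204993", "rs2070673"))

  expected <- list(
    rs2071287 = list(cases = c(81L, 96L, 33L), controls = c(83L, 100L, 27L),
                     case_alleles = c(ref = 258L, alt = 162L),
                     ctrl_alleles = c(ref = 266L, alt = 154L)),
    rs204993 = list(cases = c(60L, 102L, 48L), controls = c(89L, 100L, 21L),
                    case_alleles = c(ref = 222L, alt = 198L),
                    ctrl_alleles = c(ref = 278L, alt = 142L)),
    rs2070673 = list(cases = c(46L, 115L, 49L), controls = c(31L, 94L, 85L),
                     case_alleles = c(ref = 207L, alt = 213L),
                     ctrl_alleles = c(ref = 156L, alt = 264L))
  )
  for (p in pairs) {
    e <- expected[[p$snp$snp_id]]
    expect_identical(c(p$cases$n_ref_hom, p$cases$n_het, p$cases$n_alt_hom),
                     e$cases)
    expect_identical(c(p$controls$n_ref_hom, p$controls$n_het,
                       p$controls$n_alt_hom), e$controls)
    expect_identical(p$cases$n, 210L)
    expect_identical(p$controls$n, 210L)
    expect_identical(allele_counts(p$cases), e$case_alleles)
    expect_identical(allele_counts(p$controls), e$ctrl_alleles)
  }
})

test_that("allele-count conservation holds: ref + alt = 2n", {
  for (p in fixture_pairs()) {
    for (cohort in c("cases", "controls")) {
      ac <- allele_counts(p[[cohort]])
      expect_identical(unname(sum(ac)), 2L * p[[cohort]]$n)
    }
  }
  gc <- genotype_counts(10, 5, 3)
  expect_identical(unname(allele_counts(gc)), c(25L, 11L))
})

test_that("count-table parsing enforces format and validity", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  hdr <- paste(c("snp_id", "gene", "ref_allele", "alt_allele",
                 "case_ref_hom", "case_het", "case_alt_hom",
                 "ctrl_ref_hom", "ctrl_het", "ctrl_alt_hom"),
               collapse = "\t")
  writeLines(c(hdr, "rs1\tG1\tG\tA\t10\t5\t3\t7\t6\t2"), tmp)
  pair <- read_counts_table(tmp)[[1]]
  expect_identical(unname(allele_counts(pair$cases)[["alt"]]), 11L)

  # missing column named in the error
  writeLines(c(sub("\tctrl_alt_hom", "", hdr),
               "rs1\tG1\tG\tA\t10\t5\t3\t7\t6"), tmp)
  expect_error(read_counts_table(tmp), "ctrl_alt_hom")

  # negative / non-integer counts named by SNP and cell
  writeLines(c(hdr, "rs1\tG1\tG\tA\t10\t-5\t3\t7\t6\t2"), tmp)
  expect_error(read_counts_table(tmp), "case_het.*rs1|rs1.*case_het")
  writeLines(c(hdr, "rs1\tG1\tG\tA\t10\t5.5\t3\t7\t6\t2"), tmp)
  expect_error(read_counts_table(tmp), "case_het")

  # duplicate snp_id
  writeLines(c(hdr, "rs1\tG1\tG\tA\t10\t5\t3\t7\t6\t2",
               "rs1\tG1\tG\tA\t1\t2\t3\t4\t5\t6"), tmp)
  expect_error(read_counts_table(tmp), "duplicate")

  # all-zero cohort is a degenerate input
  writeLines(c(hdr, "rs1\tG1\tG\tA\t0\t0\t0\t7\t6\t2"), tmp)
  expect_error(read_counts_table(tmp), "positive")

  expect_error(read_counts_table(file.path(tempdir(), "nope.tsv")),
               "not found")
})

test_that("type constructors validate their invariants", {
  expect_error(genotype_counts(-1, 2, 3), "non-negative")
  expect_error(genotype_counts(1.5, 2, 3), "non-negative integers")
  expect_error(snp_info("rs1", ref_allele = "G", alt_allele = "G"),
               "differ")
  expect_error(snp_info("rs1", ref_allele = "G", alt_allele = "X"),
               "A, C, G, T")
  expect_error(snp_info("", ref_allele = "G", alt_allele = "A"),
               "non-empty")
  # lowercase alleles are normalised
  s <- snp_info("rs1", ref_allele = "g", alt_allele = "a")
  expect_identical(s$ref_allele, "G")
})

test_that("aggregate_subjects tallies records and flags bad ones", {
  snp <- snp_info("rs1", gene = "G1", ref_allele = "G", alt_allele = "A")
  recs <- data.frame(
    subject_id = c("s1", "s2", "s3", "c1"),
    phenotype = c("case", "case", "case", "control"),
    snp_id = "rs1",
    genotype = c("G/G", "A/G", "A/G", "G/A"),
    stringsAsFactors = FALSE
  )
  pair <- aggregate_subjects(recs, snp)[[1]]
  expect_identical(c(pair$cases$n_ref_hom, pair$cases$n_het,
                     pair$cases$n_alt_hom), c(1L, 2L, 0L))
  # unordered genotypes: G/A counted as heterozygote
  expect_identical(pair$controls$n_het, 1L)

  bad <- recs
  bad$genotype[2] <- "T/C"
  expect_error(aggregate_subjects(bad, snp), "s2")

  unk <- recs
  unk$snp_id[1] <- "rs_other"
  expect_error(aggregate_subjects(unk, snp), "rs_other")

  miss <- recs
  miss$genotype[3] <- NA
  expect_message(out <- aggregate_subjects(miss, snp), "1 subject")
  expect_identical(out[[1]]$cases$n, 2L)
})

test_that("record expansion and aggregation round-trips the published counts", {
  pair <- fixture_pair("rs2070673")
  recs <- expand_to_records(pair)
  expect_identical(nrow(recs), 420L)
  back <- aggregate_subjects(recs, pair$snp)[[1]]
  expect_identical(unclass(back$cases)[1:4], unclass(pair$cases)[1:4])
  expect_identical(unclass(back$controls)[1:4], unclass(pair$controls)[1:4])
})

test_that("counts TSV write/read round trip is the identity", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  pairs <- fixture_pairs()
  write_counts_table(pairs, tmp)
  back <- read_counts_table(tmp)
  for (i in seq_along(pairs)) {
    expect_identical(unclass(back[[i]]$cases)[1:4],
                     unclass(pairs[[i]]$cases)[1:4])
    expect_identical(unclass(back[[i]]$controls)[1:4],
                     unclass(pairs[[i]]$controls)[1:4])
    expect_identical(back[[i]]$snp$snp_id, pairs[[i]]$snp$snp_id)
  }
})

test_that("subject files read with extension-driven separators", {
  recs <- expand_to_records(fixture_pair("rs204993"))
  csv <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(recs, csv, row.names = FALSE, quote = FALSE)
  got <- read_subjects(csv)
  expect_identical(nrow(got), 420L)
  expect_identical(sort(unique(got$phenotype)), c("case", "control"))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(recs, tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_identical(read_subjects(tsv)$genotype, got$genotype)
})
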
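tt <- dmd_transcript()

test_that("HGVS c. parsing resolves exon-level events", {
  m <- parse_hgvs_lite("c.7543_7660del", tt)
  expect_equal(m$mclass, "deletion")
  expect_equal(c(m$first_exon, m$last_exon), c(52L, 52L))

  # multi-exon boundary-aligned deletion and duplication
  m2 <- parse_hgvs_lite("c.6913_7309del", tt)  # exons 48-50
  expect_equal(c(m2$first_exon, m2$last_exon), c(48L, 50L))
  m3 <- parse_hgvs_lite("c.32_93dup", tt)      # exon 2
  expect_equal(m3$mclass, "duplication")
  expect_equal(c(m3$first_exon, m3$last_exon), c(2L, 2L))

  # splice-site offsets anchor at exon boundaries
  don <- parse_hgvs_lite("c.7660+1G>A", tt)
  expect_equal(don$mclass, "small_lesion")
  expect_equal(don$lesion_exon, 52L)
  expect_equal(don$lesion_site, "donor")
  acc <- parse_hgvs_lite("c.7543-2A>G", tt)
  expect_equal(acc$lesion_exon, 52L)
  expect_equal(acc$lesion_site, "acceptor")
  # a typographic unicode minus sign is normalized
  acc2 <- parse_hgvs_lite("c.7543−2A>G", tt)
  expect_equal(acc2$lesion_site, "acceptor")

  # intra-exonic small variants land in the containing exon
  expect_equal(parse_hgvs_lite("c.7600C>T", tt)$lesion_exon, 52L)
  expect_equal(parse_hgvs_lite("c.7600del", tt)$lesion_site, "intra")
  expect_equal(parse_hgvs_lite("c.7595_7600delinsAA", tt)$lesion_exon, 52L)
})

test_that("unsupported HGVS strings error rather than reinterpret", {
  expect_error(parse_hgvs_lite("c.7500_7700del", tt), "not exon-boundary")
  expect_error(parse_hgvs_lite("c.20000C>T", tt), "outside CDS")
  expect_error(parse_hgvs_lite("c.7601+1G>A", tt), "last coding base")
  expect_error(parse_hgvs_lite("c.7601-1G>A", tt), "first coding base")
  expect_error(parse_hgvs_lite("g.12345del", tt), "c\\. prefix")
  expect_error(parse_hgvs_lite("c.100_90del", tt), "start after end")
  expect_error(parse_hgvs_lite("c.7543+1_7660del", tt), "offsets on a range")
})

test_that("boundary-aligned records round-trip through HGVS", {
  set.seed(99)
  for (i in 1:50) {
    f <- sample(1:79, 1); l <- min(79L, f + sample.int(7L, 1) - 1L)
    mc <- sample(c("deletion", "duplication"), 1)
    m <- mutation("r", mc, f, l, t = tt)
    m2 <- parse_hgvs_lite(to_hgvs(m, tt), tt, id = "r")
    expect_equal(m2$mclass, mc)
    expect_equal(c(m2$first_exon, m2$last_exon), c(f, l))
  }
})

test_that("mutation table IO validates rows and routes HGVS cells", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c(
    "id\tmclass\tfirst_exon\tlast_exon\tlesion_site\tphenotype\thgvs",
    "m1\tdeletion\t48\t50\t\tDMD\t",
    "m2\tsmall_lesion\t70\t\tintra\tDMD\t",
    "m3\t\t\t\t\tBMD\tc.7543_7660del",
    "m4\tDuplication\t2\t2\t\tdmd\t"), f)
  ms <- read_mutation_table(f, tt)
  expect_equal(nrow(ms), 4L)
  expect_equal(ms$mclass, c("deletion", "small_lesion", "deletion",
                            "duplication"))
  expect_equal(ms$lesion_exon[2], 70L)
  expect_equal(ms$first_exon[3], 52L)       # resolved from HGVS
  expect_equal(ms$phenotype, c("DMD", "DMD", "BMD", "DMD"))

  writeLines(c(
    "id\tmclass\tfirst_exon\tlast_exon\tlesion_site\tphenotype\thgvs",
    "b1\tdeletion\t0\t5\t\tDMD\t"), f)
  expect_error(read_mutation_table(f, tt), "row 1")
  writeLines(c(
    "id\tmclass\tfirst_exon\tlast_exon\tlesion_site\tphenotype\thgvs",
    "b1\tinversion\t3\t5\t\tDMD\t"), f)
  expect_error(read_mutation_table(f, tt), "unknown mutation class")
  writeLines(c(
    "id\tmclass\tfirst_exon\tlast_exon\tlesion_site\tphenotype\thgvs",
    "b1\tdeletion\t3\t5\t\tSEVERE\t"), f)
  expect_error(read_mutation_table(f, tt), "phenotype")
})

test_that("mutation records enforce class-specific field patterns", {
  expect_error(mutation("x", "deletion", 5, NA), "first_exon and last_exon")
  expect_error(mutation("x", "deletion", 5, 3), "out of range")
  expect_error(mutation("x", "small_lesion", lesion_exon = 5), "lesion_exon")
  expect_error(mutation("x", "small_lesion", first_exon = 5, lesion_exon = 5,
                        lesion_site = "intra"), "exon range")
  expect_error(mutation("x", "small_lesion", lesion_exon = 5,
                        lesion_site = "branch"), "lesion_site")
  expect_error(mutation("x", "deletion", 5, 6, phenotype = "nope"),
               "phenotype")
})

test_that("phenotype filtering is order-preserving with DMD default", {
  ms <- rbind(mutation("a", "deletion", 4, 5, phenotype = "DMD"),
              mutation("b", "deletion", 8, 8, phenotype = "BMD"),
              mutation("c", "small_lesion", lesion_exon = 3,
                       lesion_site = "intra", phenotype = "dmd"),
              mutation("d", "duplication", 2, 2, phenotype = "IMD"))
  expect_equal(filter_phenotype(ms)$id, c("a", "c"))
  expect_equal(filter_phenotype(ms, c("DMD", "BMD", "IMD", "DCM",
                                      "pending"))$id, ms$id)
  expect_error(filter_phenotype(ms, "severe"), "phenotype")
})
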
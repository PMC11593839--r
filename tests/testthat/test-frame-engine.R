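tt <- dmd_transcript()
lab <- function(s) sort(s$label)

test_that("frame status follows the mod-3 rule", {
  expect_equal(deletion_frame_status(tt, 52, 52), "frameshift")
  expect_equal(deletion_frame_status(tt, 45, 55), "in_frame")
  expect_equal(deletion_frame_status(tt, 3, 9), "in_frame")
  expect_equal(deletion_frame_status(tt, 3, 7), "frameshift")
  # any single symmetric exon deletion is in frame
  for (e in which(tt$symmetric))
    expect_equal(deletion_frame_status(tt, e, e), "in_frame")
})

test_that("deletion rescue enumeration matches canonical therapy targets", {
  # the approved single-exon ASO targets rescue their canonical deletions
  expect_equal(lab(deletion_skips(tt, 52, 52)), c("51", "53"))
  expect_true("51" %in% deletion_skips(tt, 48, 50)$label)   # eteplirsen-type
  expect_true("51" %in% deletion_skips(tt, 45, 50)$label)
  expect_true("53" %in% deletion_skips(tt, 45, 52)$label)   # golodirsen-type
  expect_true("45" %in% deletion_skips(tt, 46, 47)$label)   # casimersen-type
  expect_true("44" %in% deletion_skips(tt, 45, 45)$label)
  # cross-flank double skip
  expect_equal(lab(deletion_skips(tt, 46, 50)), "45 & 51")
  expect_error(deletion_skips(tt, 45, 55), "in-frame")
})

test_that("small-lesion strategies follow the symmetric/asymmetric rule", {
  cfg <- skip_config()
  # intra lesion in an asymmetric exon needs a frame-neutral adjacent pair
  m70 <- mutation("x", "small_lesion", lesion_exon = 70,
                  lesion_site = "intra")
  expect_equal(lab(small_lesion_skips(tt, m70, cfg)), "69 & 70")
  # intra lesion in a symmetric exon: exactly the exon itself
  m9 <- mutation("x", "small_lesion", lesion_exon = 9, lesion_site = "intra")
  expect_equal(lab(small_lesion_skips(tt, m9, cfg)), "9")
  # donor lesion on exon 52 induces loss of 52, rescued like the deletion
  d52 <- mutation("x", "small_lesion", lesion_exon = 52,
                  lesion_site = "donor")
  expect_equal(lab(small_lesion_skips(tt, d52, cfg)), c("51", "53"))
  # splice lesion on a symmetric exon: induced loss already in frame
  d9 <- mutation("x", "small_lesion", lesion_exon = 9, lesion_site = "donor")
  s <- small_lesion_skips(tt, d9, cfg)
  expect_equal(s$category, "none")
  expect_equal(s$note, "no-ASO-needed")
  expect_length(s$targets[[1]], 0)
  # terminal exons admit no targets
  m1 <- mutation("x", "small_lesion", lesion_exon = 1, lesion_site = "intra")
  expect_equal(nrow(small_lesion_skips(tt, m1, cfg)), 0L)
})

test_that("splice-loss convention switch flips the lost exon", {
  own <- skip_config(splice_loss_convention = "own_exon")
  lit <- skip_config(splice_loss_convention = "paper_literal")
  don51 <- mutation("x", "small_lesion", lesion_exon = 51,
                    lesion_site = "donor")
  # own exon: loss of 51 (asymmetric) -> rescues flank the lost exon
  expect_true(all(c("50", "52") %in% lab(small_lesion_skips(tt, don51, own))))
  # literal: donor loses the downstream exon 52
  expect_equal(lab(small_lesion_skips(tt, don51, lit)), c("51", "53"))
  acc53 <- mutation("x", "small_lesion", lesion_exon = 53,
                    lesion_site = "acceptor")
  # literal: acceptor loses the upstream exon 52
  expect_equal(lab(small_lesion_skips(tt, acc53, lit)), c("51", "53"))
})

test_that("duplication strategies use one-copy-skip arithmetic", {
  # single-exon duplication: skipping the duplicated exon restores wild type
  d2 <- duplication_skips(tt, 2, 2)
  expect_equal(lab(d2), "2")
  # adjacent pair within a multi-exon duplication
  expect_true("6 & 7" %in% duplication_skips(tt, 6, 7)$label)
  expect_error(duplication_skips(tt, 68, 69), "in-frame")  # 279 nt
  # double-copy rescue needs a frame-complementary neighbour
  r <- duplication_double_copy_rescue(tt, 51)
  expect_true("50" %in% r$label)
  expect_true(all(r$note == "rescue-after-double-copy-skip"))
  expect_equal(nrow(duplication_double_copy_rescue(tt, 2)), 0L)
  expect_error(duplication_double_copy_rescue(tt, 9), "symmetric")
})

test_that("multi-exon cocktail applicability is strict containment", {
  cfg <- skip_config()
  del52 <- mutation("x", "deletion", 52, 52)
  expect_true(multi_skip_applicable(tt, del52, 45, 55))
  expect_false(multi_skip_applicable(tt, del52, 3, 9))
  del4450 <- mutation("x", "deletion", 44, 50)
  expect_false(multi_skip_applicable(tt, del4450, 45, 55))
  il6 <- mutation("x", "small_lesion", lesion_exon = 6, lesion_site = "intra")
  expect_true(multi_skip_applicable(tt, il6, 3, 9))
  dup46 <- mutation("x", "duplication", 46, 46)
  expect_false(multi_skip_applicable(tt, dup46, 45, 55))
  # a cocktail range must itself be in frame
  expect_error(multi_skip_applicable(tt, del52, 45, 54), "not in-frame")
})

test_that("annotation dispatches, deduplicates, and handles in-frame events", {
  a <- annotate(tt, parse_hgvs_lite("c.7543_7660del", tt))
  expect_equal(a$frame_status, "frameshift")
  expect_equal(lab(a$strategies), c("45-55", "51", "53"))
  # multi label names the cocktail even though only surviving exons are
  # targeted
  multi <- a$strategies[a$strategies$category == "multi", ]
  expect_equal(multi$label, "45-55")
  expect_equal(multi$targets[[1]], setdiff(45:55, 52))
  expect_equal(multi$excluded[[1]], 45:55)

  infr <- annotate(tt, mutation("y", "deletion", 45, 55))
  expect_equal(infr$frame_status, "in_frame")
  expect_equal(nrow(infr$strategies), 0L)

  dup2 <- annotate(tt, mutation("z", "duplication", 2, 2))
  expect_equal(dup2$frame_status, "frameshift")
  expect_equal(lab(dup2$strategies), "2")

  sl <- annotate(tt, mutation("w", "small_lesion", lesion_exon = 70,
                              lesion_site = "intra"))
  expect_equal(sl$frame_status, "not_applicable")
})

test_that("every emitted deletion/small-lesion strategy is frame-neutral", {
  set.seed(402)
  for (i in 1:200) {
    t <- random_transcript()
    n <- nrow(t)
    m <- if (runif(1) < 0.5) {
      f <- sample(n, 1); l <- min(n, f + sample(0:3, 1))
      mutation("p", "deletion", f, l, t = t)
    } else {
      mutation("p", "small_lesion", lesion_exon = sample(n, 1),
               lesion_site = sample(c("intra", "donor", "acceptor"), 1),
               t = t)
    }
    a <- annotate(t, m, skip_config(multi_ranges = list()))
    for (j in seq_len(nrow(a$strategies))) {
      ex <- a$strategies$excluded[[j]]
      expect_equal(sum(t$coding_length[ex]) %% 3L, 0L)
      expect_true(all(a$strategies$targets[[j]] %in% 2:(n - 1)))
    }
  }
})

test_that("annotation is deterministic and input-order independent", {
  ms <- rbind(mutation("a", "deletion", 48, 50),
              mutation("b", "small_lesion", lesion_exon = 35,
                       lesion_site = "intra"),
              mutation("c", "duplication", 6, 7))
  a1 <- annotate_cohort(tt, ms)
  a2 <- annotate_cohort(tt, ms[c(3, 1, 2), ])
  for (id in ms$id)
    expect_identical(a1[[id]]$strategies, a2[[id]]$strategies)
})
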
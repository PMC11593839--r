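#!/usr/bin/env Rscript
# Step 2: annotate a panel of canonical dystrophin mutations, including the
# targets of the approved exon-skipping ASOs, and inspect the strategies the
# engine proposes.

library(dmdskip)

dir.create("results", showWarnings = FALSE)
t <- dmd_transcript()

panel <- rbind(
  parse_hgvs_lite("c.7543_7660del", t, id = "del_exon52"),
  mutation("del_45_50", "deletion", 45, 50),      # exon 51 skip (eteplirsen)
  mutation("del_45_52", "deletion", 45, 52),      # exon 53 skip (golodirsen)
  mutation("del_46_47", "deletion", 46, 47),      # exon 45 skip (casimersen)
  mutation("del_46_50", "deletion", 46, 50),      # needs a double skip
  mutation("del_45_55", "deletion", 45, 55),      # in frame: no strategy
  mutation("dup_exon2", "duplication", 2, 2),
  mutation("dup_6_7", "duplication", 6, 7),
  mutation("lesion_70", "small_lesion", lesion_exon = 70,
           lesion_site = "intra"),
  parse_hgvs_lite("c.7660+1G>A", t, id = "donor_exon52"),
  parse_hgvs_lite("c.7543-2A>G", t, id = "acceptor_exon52"))

anns <- annotate_cohort(t, panel)
for (a in anns) print(a)

tab <- strategy_table(anns)
write.table(tab, "results/worked_examples.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE, na = "")
write_annotations(anns, "results/worked_examples.json")
cat("\nwrote results/worked_examples.tsv and results/worked_examples.json\n")
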
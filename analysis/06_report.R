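#!/usr/bin/env Rscript
# Stage 6 — combined run report.
#
# Collates the per-variant view (MAF, HWE p, screened raw and shrunken HR
# with CI, pathway-search Bayes Factor), the ten-concept BF table, and the
# top trees with their genotype hazard-ratio grids into report.json /
# report.txt.

library(tampath)

dirc <- "results/analysis/cohort"
dira <- "results/analysis/alps"
# report_run expects everything in one directory
for (f in list.files(dira, full.names = TRUE)) {
  file.copy(f, file.path(dirc, basename(f)), overwrite = TRUE)
}
rep <- report_run(dirc)
message(sprintf("report: %d QC-passed variants, %d concepts, %d top trees",
                nrow(rep$variants), nrow(rep$concepts), nrow(rep$top_trees)))
message("written: ", file.path(dirc, "report.json"), " and report.txt")
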
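#!/usr/bin/env Rscript

# Stage 4: defense-system enrichment screen (Fisher exact + BH) on the
# strain-by-system table, and the host-range-by-serogroup summary of the
# published Adele panel.

suppressPackageStartupMessages(library(phagechar))

dat <- "results/data"
out <- "results"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

tab <- read_presence_absence(file.path(dat, "defense_systems.tsv"))
res <- enrichment_screen(tab, alpha = 0.05, focal = "O11")
write.table(res, file.path(out, "enrichment.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
sig <- res$system[res$significant]
cat(sprintf("screen: %d/%d systems enriched in the focal group at q < 0.05: %s\n",
            length(sig), nrow(res), paste(sig, collapse = ", ")))

panel <- adele_host_range()
hr <- host_range_summary(panel$lysis, panel$serogroup)
write.table(hr, file.path(out, "host_range.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("host range by serogroup (susceptible/total):\n")
for (i in seq_len(nrow(hr)))
  cat(sprintf("  %-4s %d/%d\n", hr$serogroup[i], hr$susceptible[i],
              hr$total[i]))
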
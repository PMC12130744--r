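#!/usr/bin/env Rscript
# Step 4: render the selection reports.
#
# Formats the AIC tables (retained model in bold) and the chosen models'
# estimate tables as markdown, one report per fitted measure.

suppressPackageStartupMessages(library(owlcmr))

for (d in c("results/fits_size", "results/fits_mass")) {
  rep <- render_report(d)
  cat(sprintf("wrote %s (%d lines)\n", file.path(d, "report.md"), length(rep)))
}
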
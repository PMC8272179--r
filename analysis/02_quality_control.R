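#!/usr/bin/env Rscript
# Step 2: record-level quality control.
#
# Excludes records whose maximal AVM exceeds 30 g (sensor error) and
# fall records whose maximal AVM stays below 1.1 g (no recorded
# impact).  Writes results/qc_report.csv.

suppressPackageStartupMessages(library(fallseg))

ds <- read_dataset("results/dataset")
qc <- apply_qc_filters(ds)
write_qc_report(qc, "results/qc_report.csv")

cat("Kept", length(qc$kept), "of", nrow(ds$manifest), "records\n")
if (nrow(qc$excluded)) {
  cat("Excluded by reason:\n")
  print(table(qc$excluded$reason))
}
# the exclusions should coincide with the generator's truth flags
truth <- ds$manifest$record_id[ds$manifest$error_type != "none"]
agree <- setequal(truth, qc$excluded$record_id)
cat("Exclusions match the generator's injected errors:", agree, "\n")
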
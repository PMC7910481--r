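#!/usr/bin/env Rscript
# Apply the duplex variant filter chain to the serial bulk samples and track
# mutation trajectories across timepoints.

suppressMessages(library(clonotrace))
sim <- "results/simdata/bulk"
out <- "results"

calls <- read_tsv(file.path(sim, "calls.tsv"))
comparator <- read_tsv(file.path(sim, "comparator.tsv"))

filtered <- do.call(rbind, lapply(split(calls, calls$age), filter_variants,
                                  comparator = comparator))
filtered <- filtered[order(filtered$age, filtered$pos), ]
write_tsv(filtered, file.path(out, "bulk_filtered.tsv"))

pass <- filtered[filtered$status == "pass", ]
cat("candidate sites per timepoint:", length(unique(calls$locus)),
    "| passing calls:", nrow(pass), "over",
    length(unique(pass$locus)), "mutations\n")
print(table(filtered$reason, useNA = "ifany"))

timelines <- track_clones(filtered)
write_tsv(timelines, file.path(out, "mutation_timelines.tsv"))
cat("\nmutation timelines (fold change = last / first detected VAF):\n")
print(timelines)

truth <- read_tsv(file.path(sim, "truth.tsv"))
detected <- unique(pass$locus)
missed <- setdiff(unique(truth$locus[truth$true_vaf > 0]), detected)
cat("\ntrue mutations never passing the filter:",
    if (length(missed)) paste(missed, collapse = ", ") else "none", "\n")
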
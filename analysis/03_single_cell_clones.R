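#!/usr/bin/env Rscript
# Genotype the single-cell run, quantify allelic and technical dropout, and
# reconstruct the clonal hierarchy with dropout- and doublet-aware merging.

suppressMessages(library(clonotrace))
sim <- "results/simdata/single_cell"
out <- "results"

cells <- call_genotypes(read_tsv(file.path(sim, "cells.tsv")))
loci <- read_tsv(file.path(sim, "loci.tsv"))
snp_loci <- loci$locus[loci$type == "snp"]
somatic <- loci$locus[loci$type == "somatic"]

informative <- informative_snps(cells, snp_loci)
ado <- estimate_ado(cells, informative)
cat(sprintf("sample-level ADO ratio: %.3f (95%% CI %.3f-%.3f) over %d SNPs\n",
            ado$sample_level, ado$ci[1], ado$ci[2], length(ado$per_site)))
jsonlite::write_json(
  list(per_site = as.list(ado$per_site), sample_level = ado$sample_level,
       ci = ado$ci, n_cells = ado$n_cells),
  file.path(out, "ado_report.json"), auto_unbox = TRUE, digits = NA)

bulk <- read_tsv(file.path(out, "bulk_filtered.tsv"))
bulk_pass <- unique(bulk$locus[bulk$status == "pass"])
td <- technical_dropout(cells, bulk_pass, designable = somatic)
cat(sprintf("technical dropout: %d/%d targeted mutations genotyped (%.1f%%)\n",
            length(td$detected), td$n_targeted, 100 * td$fraction))

gm <- genotype_matrix(cells)
cs <- identify_clones(gm, somatic,
                      ado = stats::setNames(rep(ado$sample_level, length(somatic)),
                                            somatic),
                      doublet_rate = 0.02)
ch <- detect_loh_subclones(build_hierarchy(cs))

clones <- data.frame(clone = rownames(ch$genotypes),
                     n_cells = unname(ch$n_cells),
                     frequency = unname(ch$frequency),
                     parent = unname(ch$parent),
                     flags = vapply(ch$flags, paste, character(1), collapse = ","),
                     stringsAsFactors = FALSE)
clones <- cbind(clones, as.data.frame(ch$genotypes, stringsAsFactors = FALSE))
write_tsv(clones, file.path(out, "clones.tsv"))

cat("\nidentified clones (complete cells:", ch$n_complete, "):\n")
print(clones[, c("clone", "n_cells", "frequency", "parent", "flags")])
if (!is.null(ch$merged)) {
  cat("\ngroups merged as dropout spillover:\n")
  print(ch$merged)
}
if (!is.null(ch$loh_report)) {
  cat("\nCN-LOH progression report:\n")
  print(ch$loh_report)
}

gene_map <- stats::setNames(sub("_.*", "", somatic), somatic)
excl <- clone_exclusivity_summary(ch, gene_map)
cat("\nsole-gene clones:\n"); print(excl$sole)
cat("co-mutated clones:", excl$co_mutated, "\n")
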
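#!/usr/bin/env Rscript
# Generate the synthetic study inputs with known ground truth: a single-cell
# genotyping run over a clone hierarchy, serial bulk duplex samples, and an
# exome-style copy-number sample with a panel of normals. All downstream
# analysis scripts read these tables from results/simdata/.

suppressMessages(library(clonotrace))
out <- "results/simdata"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

# clone structure modelled on a typical multi-clone bone-marrow sample:
# independent EIF6- and TP53-mutated clones, one EIF6 subclone, and a
# TP53 CN-LOH progression subclone
h <- sim_hierarchy(
  sim_clone("eif6_a",   0.12, c(EIF6_N106S = "het")),
  sim_clone("eif6_b",   0.03, c(EIF6_R96W = "het")),
  sim_clone("tp53_a",   0.05, c(TP53_R248Q = "het")),
  sim_clone("tp53_loh", 0.02, c(TP53_R248Q = "hom"), parent = "tp53_a"),
  sim_clone("eif6_sub", 0.015, c(EIF6_N106S = "het", EIF6_S86A = "het"),
            parent = "eif6_a"))

cfg <- sim_config(n_cells = 10000, ado_rate = 0.05, doublet_rate = 0.02,
                  bulk_depth = 20000, seed = 20260923L)

sc <- simulate_cells(h, cfg, n_snps = 8)
write_sim(sc, file.path(out, "single_cell"))

ages <- c(8, 12, 16, 20)
traj <- do.call(rbind, lapply(seq_along(ages), function(i) {
  # stable clones except the CN-LOH subclone, which expands over time
  data.frame(age = ages[i],
             clone = c("eif6_a", "eif6_b", "tp53_a", "tp53_loh", "eif6_sub"),
             fraction = c(0.12, 0.03, 0.05, 0.002 * 3^(i - 1), 0.015))
}))
bulk <- simulate_bulk_duplex(h, traj, cfg, n_background = 20)
write_sim(bulk, file.path(out, "bulk"))

seg_truth <- data.frame(chrom = c("chr1", "chr2", "chr7", "chr17", "chr20"),
                        n_targets = c(200, 200, 120, 80, 120),
                        n_snps = c(25, 25, 25, 30, 25),
                        a = c(1, 1, 1, 2, 1),
                        b = c(1, 1, 1, 0, 0))  # 17p CN-LOH and del(20q)
purity <- 0.6
ex <- simulate_exome_counts(seg_truth, purity, cfg)
write_sim(ex, file.path(out, "exome"))
writeLines(as.character(purity), file.path(out, "exome", "purity.txt"))

cat("wrote synthetic single-cell, serial bulk and exome tables under", out, "\n")
cat("clones:", length(h), "| cells:", cfg$n_cells,
    "| bulk timepoints:", length(ages), "\n")
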
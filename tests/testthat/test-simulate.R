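test_that("clone hierarchy validation enforces fractions and ancestry", {
  expect_error(sim_clone("A", 1.2, c(L1 = "het")), "fraction")
  expect_error(sim_clone("A", 0.1, c(L1 = "bad")), "zygosity")
  expect_error(sim_hierarchy(sim_clone("A", 0.7, c(L1 = "het")),
                             sim_clone("B", 0.6, c(L2 = "het"))),
               "sum")
  # child must extend parent or be a single het->hom progression
  expect_error(sim_hierarchy(sim_clone("A", 0.2, c(L1 = "het")),
                             sim_clone("B", 0.1, c(L2 = "het"), parent = "A")),
               "lacks mutations")
  h <- sim_hierarchy(sim_clone("A", 0.2, c(L1 = "het")),
                     sim_clone("B", 0.1, c(L1 = "hom"), parent = "A"))
  expect_s3_class(h, "sim_hierarchy")
  expect_equal(attr(h, "wt_fraction"), 0.7)
})

test_that("fixed seed reproduces simulator outputs exactly", {
  h <- sim_hierarchy(sim_clone("A", 0.2, c(L1 = "het")))
  cfg <- sim_config(n_cells = 500, seed = 42)
  expect_identical(simulate_cells(h, cfg, n_snps = 2),
                   simulate_cells(h, cfg, n_snps = 2))
  traj <- data.frame(age = c(5, 10), clone = "A", fraction = c(0.1, 0.2))
  expect_identical(simulate_bulk_duplex(h, traj, cfg),
                   simulate_bulk_duplex(h, traj, cfg))
  st <- data.frame(chrom = "chr1", n_targets = 30, n_snps = 10, a = 1, b = 1)
  expect_identical(simulate_exome_counts(st, 0.8, cfg),
                   simulate_exome_counts(st, 0.8, cfg))
})

test_that("noiseless heterozygous clone yields alt fraction one half everywhere", {
  h <- sim_hierarchy(sim_clone("A", 1, c(L1 = "het")))
  cfg <- sim_config(n_cells = 300, ado_rate = 0, doublet_rate = 0,
                    seq_error = 0, seed = 1)
  sim <- simulate_cells(h, cfg)
  frac <- sim$cells$alt / sim$cells$depth
  expect_true(all(abs(mean(frac) - 0.5) < 0.02))
  expect_true(all(sim$truth$clone == "A"))
  # per-cell draws are binomial around exactly one half
  expect_true(all(frac > 0.2 & frac < 0.8))
})

test_that("apparent hom/het ratio matches the closed form 2d/(1-d)", {
  d <- 0.05
  h <- sim_hierarchy(sim_clone("A", 0.01, c(L1 = "het")))
  cfg <- sim_config(n_cells = 20000, ado_rate = d, doublet_rate = 0,
                    depth_mean = 100, seed = 99)
  sim <- simulate_cells(h, cfg, n_snps = 2)
  cells <- call_genotypes(sim$cells)
  snp <- cells[cells$locus == "SNP01" & cells$genotype != "missing", ]
  n_hom <- sum(snp$genotype %in% c("hom", "wt"))
  n_het <- sum(snp$genotype == "het")
  ratio <- n_hom / n_het
  expected <- 2 * d / (1 - d)
  # 3 binomial SEs on the hom-appearance proportion propagated to the ratio
  p <- expected / (1 + expected)
  se <- 3 * sqrt(p * (1 - p) / (n_hom + n_het))
  expect_lt(abs(ratio / (1 + ratio) - p), se)
})

test_that("truth clone labels match configured fractions within sampling error", {
  h <- sim_hierarchy(sim_clone("A", 0.15, c(L1 = "het")),
                     sim_clone("B", 0.05, c(L2 = "het")))
  cfg <- sim_config(n_cells = 10000, seed = 5)
  sim <- simulate_cells(h, cfg)
  obs <- table(sim$truth$clone)
  for (nm in c("A", "B")) {
    f <- h[[nm]]$fraction
    se <- sqrt(f * (1 - f) * cfg$n_cells)
    expect_lt(abs(obs[[nm]] - f * cfg$n_cells), 4 * se)
  }
})

test_that("independent clones do not co-occur in single cells beyond doublets", {
  h <- sim_hierarchy(sim_clone("EIF6clone", 0.10, c(EIF6_1 = "het")),
                     sim_clone("TP53clone", 0.10, c(TP53_1 = "het")))
  cfg <- sim_config(n_cells = 5000, doublet_rate = 0, seq_error = 0, seed = 8)
  sim <- simulate_cells(h, cfg)
  cells <- call_genotypes(sim$cells)
  gm <- genotype_matrix(cells)
  both <- gm[, "EIF6_1"] %in% c("het", "hom") & gm[, "TP53_1"] %in% c("het", "hom")
  expect_equal(sum(both), 0)
})

test_that("doublets merge allele sets and are flagged in truth", {
  h <- sim_hierarchy(sim_clone("A", 0.5, c(L1 = "het")))
  cfg <- sim_config(n_cells = 4000, doublet_rate = 0.3, ado_rate = 0,
                    seq_error = 0, seed = 3)
  sim <- simulate_cells(h, cfg)
  expect_gt(sum(sim$truth$is_doublet), 0)
  # an A x wt doublet has 1 alt of 4 alleles: alt fraction near 0.25
  dbl <- sim$truth$is_doublet & sim$truth$clone == "A" &
    sim$truth$partner_clone == ".wt"
  x <- sim$cells[sim$cells$cell_id %in% sim$truth$cell_id[dbl], ]
  expect_lt(abs(mean(x$alt / x$depth) - 0.25), 0.02)
})

test_that("bulk duplex VAF equals clone fraction times multiplicity over two", {
  h <- sim_hierarchy(sim_clone("A", 0.10, c(L1 = "het")),
                     sim_clone("B", 0.10, c(L1 = "hom"), parent = "A"))
  traj <- data.frame(age = c(1, 1), clone = c("A", "B"),
                     fraction = c(0.10, 0.10))
  cfg <- sim_config(bulk_depth = 50000, seq_error = 0, seed = 21)
  bk <- simulate_bulk_duplex(h, traj, cfg, n_background = 0)
  # true VAF = 0.10 * 0.5 + 0.10 * 1 = 0.15
  expect_equal(bk$truth$true_vaf[bk$truth$locus == "L1"], 0.15)
  obs <- bk$calls$alt_count / (bk$calls$alt_count + bk$calls$ref_count)
  se <- sqrt(0.15 * 0.85 / 50000)
  expect_lt(abs(obs - 0.15), 4 * se)
})

test_that("bulk simulation rejects invalid trajectories", {
  h <- sim_hierarchy(sim_clone("A", 0.1, c(L1 = "het")))
  cfg <- sim_config(seed = 1)
  expect_error(simulate_bulk_duplex(h, data.frame(age = 1, clone = "A",
                                                  fraction = 1.4), cfg),
               "fraction")
})

test_that("exome count simulation reproduces the purity mixture means", {
  cfg <- sim_config(seed = 17)
  # diploid everywhere: tCR near 1 and SNP alt fraction near 0.5
  st <- data.frame(chrom = "chr1", n_targets = 200, n_snps = 60, a = 1, b = 1)
  ex <- simulate_exome_counts(st, 1, cfg)
  tcr <- compute_tcr(ex$targets, ex$panel)
  expect_lt(abs(stats::median(tcr$tcr, na.rm = TRUE) - 1), 0.05)
  af <- ex$snps$alt_count / (ex$snps$alt_count + ex$snps$ref_count)
  expect_lt(abs(mean(af) - 0.5), 0.03)

  # CN-LOH at purity 1: alt fraction 1 or 0 according to haplotype
  st2 <- data.frame(chrom = "chr1", n_targets = 50, n_snps = 30, a = 2, b = 0)
  ex2 <- simulate_exome_counts(st2, 1, cfg)
  af2 <- ex2$snps$alt_count / (ex2$snps$alt_count + ex2$snps$ref_count)
  expect_true(all(af2[ex2$snps$truth_hap == "A"] > 0.97))
  expect_true(all(af2[ex2$snps$truth_hap == "B"] < 0.03))

  # deletion at purity 0.6: expected tCR 0.7, retained-haplotype fraction 1/1.4
  # exome-realistic layout: the aberrant chromosome is a small share of targets
  st3 <- data.frame(chrom = c("chr1", "chr2"), n_targets = c(500, 80),
                    n_snps = c(20, 60), a = c(1, 1), b = c(1, 0))
  ex3 <- simulate_exome_counts(st3, 0.6, cfg)
  tcr3 <- compute_tcr(ex3$targets, ex3$panel)
  expect_lt(abs(mean(tcr3$tcr[ex3$truth$segment == 2], na.rm = TRUE) - 0.7), 0.04)
  sn3 <- ex3$snps[ex3$snps$chrom == "chr2", ]
  af3 <- sn3$alt_count / (sn3$alt_count + sn3$ref_count)
  expect_lt(abs(mean(af3[sn3$truth_hap == "A"]) - 1 / 1.4), 0.03)

  expect_error(simulate_exome_counts(
    data.frame(chrom = "chr1", n_targets = 10, n_snps = 0, a = -1, b = 1),
    0.6, cfg), "nonnegative")
})

test_that("simulator outputs round-trip through plain-text files", {
  h <- sim_hierarchy(sim_clone("A", 0.2, c(L1 = "het")))
  cfg <- sim_config(n_cells = 50, seed = 2)
  sim <- simulate_cells(h, cfg, n_snps = 1)
  dir <- tempfile()
  files <- write_sim(sim, dir)
  expect_true(all(file.exists(file.path(dir, c("cells.tsv", "truth.tsv", "loci.tsv")))))
  back <- read_tsv(file.path(dir, "cells.tsv"))
  expect_equal(back$depth, sim$cells$depth)
  expect_equal(back$alt, sim$cells$alt)
})
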
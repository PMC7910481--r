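# direct genotype-matrix construction for controlled grouping tests
gm_from_groups <- function(groups, loci) {
  rows <- lapply(seq_along(groups), function(i) {
    g <- groups[[i]]
    matrix(rep(g$gt, g$n), nrow = g$n, byrow = TRUE,
           dimnames = list(NULL, loci))
  })
  m <- do.call(rbind, rows)
  rownames(m) <- sprintf("c%05d", seq_len(nrow(m)))
  m
}

test_that("clones are exact genotype groups above the size floor", {
  loci <- c("EIF6_1", "TP53_1")
  gm <- gm_from_groups(list(
    list(n = 800, gt = c("wt", "wt")),
    list(n = 150, gt = c("het", "wt")),
    list(n = 50, gt = c("wt", "het")),
    list(n = 3, gt = c("het", "het"))), loci)  # below min_cells
  cs <- identify_clones(gm, loci, ado = 0.10)
  expect_equal(nrow(cs$genotypes), 2)
  expect_equal(sort(unname(cs$n_cells)), c(50, 150))
  expect_equal(cs$n_wt, 800)
  expect_true(sum(cs$frequency) <= 1)
})

test_that("dropout-sized homozygous groups merge; larger ones survive as subclones", {
  loci <- "TP53_1"
  # site ADO ratio 0.05 -> per-cell hom-appearance probability ~0.0244
  # 40 hom vs 800 het rejects the spillover null; ~20 does not
  gm_big <- gm_from_groups(list(list(n = 800, gt = "het"),
                                list(n = 40, gt = "hom")), loci)
  cs_big <- identify_clones(gm_big, loci, ado = c(TP53_1 = 0.05), min_frequency = 0)
  expect_equal(nrow(cs_big$genotypes), 2)

  gm_small <- gm_from_groups(list(list(n = 800, gt = "het"),
                                  list(n = 20, gt = "hom")), loci)
  cs_small <- identify_clones(gm_small, loci, ado = c(TP53_1 = 0.05), min_frequency = 0)
  expect_equal(nrow(cs_small$genotypes), 1)
  expect_equal(unname(cs_small$n_cells), 820)
  expect_equal(cs_small$merged$locus, "TP53_1")
})

test_that("het-to-wt dropout spillover merges into the multi-mutation clone", {
  loci <- c("A", "B")
  gm <- gm_from_groups(list(
    list(n = 500, gt = c("het", "het")),
    list(n = 12, gt = c("het", "wt"))), loci)  # plausible dropout of B
  cs <- identify_clones(gm, loci, ado = 0.05, min_frequency = 0)
  expect_equal(nrow(cs$genotypes), 1)
  expect_equal(unname(cs$n_cells), 512)
})

test_that("a single noiseless clone is recovered at frequency one", {
  loci <- "M1"
  gm <- gm_from_groups(list(list(n = 200, gt = "het")), loci)
  cs <- identify_clones(gm, loci, ado = 0.05)
  expect_equal(nrow(cs$genotypes), 1)
  expect_equal(unname(cs$frequency), 1)
})

test_that("an all-wild-type population yields an empty forest", {
  gm <- gm_from_groups(list(list(n = 100, gt = c("wt", "wt"))), c("A", "B"))
  cs <- identify_clones(gm, c("A", "B"), ado = 0.05)
  expect_equal(nrow(cs$genotypes), 0)
  ch <- build_hierarchy(cs)
  expect_length(ch$parent, 0)
})

test_that("hierarchy attaches subclones to their largest compatible ancestor", {
  loci <- c("A", "B", "C")
  gm <- gm_from_groups(list(
    list(n = 600, gt = c("het", "wt", "wt")),
    list(n = 200, gt = c("het", "het", "wt")),
    list(n = 60, gt = c("het", "het", "het")),
    list(n = 300, gt = c("wt", "wt", "het"))), loci)
  ch <- build_hierarchy(identify_clones(gm, loci, ado = 0.02, min_frequency = 0))
  g <- ch$genotypes
  key <- apply(g, 1, paste, collapse = "")
  id_of <- stats::setNames(rownames(g), key)
  expect_true(is.na(ch$parent[id_of[["hetwtwt"]]]))
  expect_true(is.na(ch$parent[id_of[["wtwthet"]]]))
  expect_equal(unname(ch$parent[id_of[["hethetwt"]]]), unname(id_of[["hetwtwt"]]))
  expect_equal(unname(ch$parent[id_of[["hethethet"]]]), unname(id_of[["hethetwt"]]))
  expect_true("founding" %in% ch$flags[[id_of[["hetwtwt"]]]])
  expect_true("subclone" %in% ch$flags[[id_of[["hethethet"]]]])
})

test_that("LOH progression subclones are flagged only beyond dropout expectation", {
  loci <- "TP53_1"
  # balanced het founding clone and hom progression subclone
  gm <- gm_from_groups(list(list(n = 500, gt = "het"),
                            list(n = 500, gt = "hom")), loci)
  ch <- detect_loh_subclones(build_hierarchy(
    identify_clones(gm, loci, ado = c(TP53_1 = 0.05), min_frequency = 0)))
  expect_true(any(vapply(ch$flags, function(f) "loh_subclone" %in% f, logical(1))))
  expect_equal(ch$loh_report$hom_proportion, 0.5)

  # dropout-consistent hom group: merged during identification, never flagged
  gm2 <- gm_from_groups(list(list(n = 1000, gt = "het"),
                             list(n = 25, gt = "hom")), loci)
  ch2 <- detect_loh_subclones(build_hierarchy(
    identify_clones(gm2, loci, ado = c(TP53_1 = 0.05), min_frequency = 0)))
  expect_false(any(vapply(ch2$flags, function(f) "loh_subclone" %in% f, logical(1))))

  # zero dropout: any hom group rejects the null
  gm3 <- gm_from_groups(list(list(n = 1000, gt = "het"),
                             list(n = 12, gt = "hom")), loci)
  ch3 <- detect_loh_subclones(build_hierarchy(
    identify_clones(gm3, loci, ado = c(TP53_1 = 0), min_frequency = 0)))
  expect_true(any(vapply(ch3$flags, function(f) "loh_subclone" %in% f, logical(1))))
})

test_that("hierarchies from simulated data are acyclic with single parents", {
  for (seed in 1:5) {
    set.seed(seed * 13)
    h <- random_hierarchy(4)
    cfg <- sim_config(n_cells = 4000, seed = seed * 13 + 7)
    fit <- infer_from_sim(h, cfg)
    ch <- fit$hierarchy
    expect_true(sum(ch$frequency) <= 1 + 1e-9)
    # walk every clone to a root without revisiting
    for (id in rownames(ch$genotypes)) {
      seen <- character()
      cur <- id
      while (!is.na(cur)) {
        expect_false(cur %in% seen)
        seen <- c(seen, cur)
        cur <- unname(ch$parent[cur])
      }
    }
  }
})

test_that("known three-clone structure is recovered from simulation", {
  h <- sim_hierarchy(
    sim_clone("A", 0.15, c(EIF6_1 = "het")),
    sim_clone("B", 0.05, c(TP53_1 = "het")),
    sim_clone("C", 0.02, c(EIF6_1 = "het", EIF6_2 = "het"), parent = "A"))
  cfg <- sim_config(n_cells = 8000, seed = 2024)
  fit <- infer_from_sim(h, cfg)
  expect_true(recovered_exactly(h, fit$hierarchy))
})

test_that("mutation timelines report fold change between first and last detection", {
  calls <- data.frame(
    age = rep(c(17.5, 22, 30), each = 2),
    locus = rep(c("EIF6_1", "TP53_1"), 3),
    vaf = c(0.0017, 0.002, 0.0017, 0.004, 0.0017, 0.02),
    status = c("pass", "pass", "pass", "pass", "pass", "pass"),
    stringsAsFactors = FALSE)
  tl <- track_clones(calls)
  expect_equal(tl$fold_change[tl$locus == "EIF6_1"], 1.0)
  expect_equal(tl$fold_change[tl$locus == "TP53_1"], 10)

  single <- calls[c(1, 3, 5, 6), ]
  single$status[4] <- "pass"
  tl2 <- track_clones(single)
  expect_true(is.na(tl2$fold_change[tl2$locus == "TP53_1"]))

  dup <- calls; dup$age[3] <- 17.5
  expect_error(track_clones(dup), "duplicate")
})

test_that("exclusivity summary counts sole-gene and co-mutated clones", {
  loci <- c("EIF6_1", "EIF6_2", "TP53_1")
  gmap <- c(EIF6_1 = "EIF6", EIF6_2 = "EIF6", TP53_1 = "TP53")
  gm <- gm_from_groups(list(
    list(n = 100, gt = c("het", "wt", "wt")),
    list(n = 80, gt = c("wt", "het", "wt")),
    list(n = 60, gt = c("wt", "wt", "het"))), loci)
  cs <- identify_clones(gm, loci, ado = 0.02, min_frequency = 0)
  s <- clone_exclusivity_summary(cs, gmap)
  expect_equal(s$sole[["EIF6"]], 2)
  expect_equal(s$sole[["TP53"]], 1)
  expect_equal(s$co_mutated, 0)

  gm2 <- gm_from_groups(list(list(n = 100, gt = c("het", "wt", "het"))), loci)
  cs2 <- identify_clones(gm2, loci, ado = 0.02)
  s2 <- clone_exclusivity_summary(cs2, gmap)
  expect_equal(s2$co_mutated, 1)
  expect_error(clone_exclusivity_summary(cs2, gmap[1:2]), "unannotated")
})

test_that("doublet images of a homozygous clone are flagged, real clones are not", {
  loci <- c("A", "B")
  # big hom clone at A; ~17 cells reading het at A are the expected image of
  # hom x wild-type doublets at a 2% doublet rate
  gm <- gm_from_groups(list(
    list(n = 7000, gt = c("wt", "wt")),
    list(n = 1000, gt = c("hom", "wt")),
    list(n = 17, gt = c("het", "wt")),
    list(n = 300, gt = c("wt", "het"))), loci)
  cs <- identify_clones(gm, loci, ado = 0.10, doublet_rate = 0.02,
                        min_frequency = 0)
  key <- apply(cs$genotypes, 1, paste, collapse = "|")
  dbl <- vapply(cs$flags, function(f) "putative_doublet" %in% f, logical(1))
  expect_true(dbl[key == "het|wt"])
  expect_false(dbl[key == "hom|wt"])
  expect_false(dbl[key == "wt|het"])

  # a genuine het clone at the same locus is far larger than the image count
  gm2 <- gm_from_groups(list(
    list(n = 7000, gt = c("wt", "wt")),
    list(n = 1000, gt = c("hom", "wt")),
    list(n = 400, gt = c("het", "wt"))), loci)
  cs2 <- identify_clones(gm2, loci, ado = 0.10, doublet_rate = 0.02,
                         min_frequency = 0)
  key2 <- apply(cs2$genotypes, 1, paste, collapse = "|")
  dbl2 <- vapply(cs2$flags, function(f) "putative_doublet" %in% f, logical(1))
  expect_false(dbl2[key2 == "het|wt"])
})
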
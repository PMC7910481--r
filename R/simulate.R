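#' Define a simulated clone
#'
#' A clone is a set of somatic mutations (with zygosity) carried by a fraction
#' of sampled cells. Clones are arranged in a hierarchy: a child carries a
#' superset of its parent's mutations, or differs from the parent only by a
#' het-to-hom zygosity change at a single locus (copy-neutral LOH progression).
#'
#' @param id Clone label.
#' @param fraction Fraction of sampled cells belonging to this clone, in (0, 1].
#' @param mutations Named character vector, `locus -> "het"` or `"hom"`.
#' @param parent Label of the parent clone, or `NA` for a founding clone.
#' @return A `sim_clone` list.
#' @export
sim_clone <- function(id, fraction, mutations = character(), parent = NA_character_) {
  stop_if_not(is.numeric(fraction) && fraction >= 0 && fraction <= 1,
              "clone '%s': fraction must be in [0, 1]", id)
  if (length(mutations)) {
    stop_if_not(!is.null(names(mutations)) && all(nzchar(names(mutations))),
                "clone '%s': mutations must be a named vector", id)
    stop_if_not(all(mutations %in% c("het", "hom")),
                "clone '%s': zygosity must be 'het' or 'hom'", id)
  }
  structure(list(id = as.character(id), fraction = fraction,
                 mutations = mutations, parent = as.character(parent)),
            class = "sim_clone")
}

#' Assemble and validate a clone hierarchy
#'
#' Checks that clone fractions (including the implicit wild-type clone) sum to
#' one, and that every child's mutation set extends its parent's either by
#' additional mutations or by a single het-to-hom change (an LOH edge).
#'
#' @param ... `sim_clone` objects (or a single list of them).
#' @return A `sim_hierarchy` list of clones; the wild-type remainder fraction
#'   is stored as an attribute.
#' @export
sim_hierarchy <- function(...) {
  clones <- list(...)
  if (length(clones) == 1L && !inherits(clones[[1L]], "sim_clone")) {
    clones <- clones[[1L]]
  }
  stop_if_not(all(vapply(clones, inherits, logical(1), "sim_clone")),
              "all elements must be sim_clone objects")
  ids <- vapply(clones, `[[`, character(1), "id")
  stop_if_not(!anyDuplicated(ids), "clone ids must be unique")
  total <- sum(vapply(clones, `[[`, numeric(1), "fraction"))
  stop_if_not(total <= 1 + 1e-9,
              "clone fractions sum to %.4f > 1 (wild-type fraction negative)", total)
  names(clones) <- ids
  for (cl in clones) {
    if (!is.na(cl$parent)) {
      stop_if_not(cl$parent %in% ids, "parent '%s' of clone '%s' not found",
                  cl$parent, cl$id)
      pm <- clones[[cl$parent]]$mutations
      cm <- cl$mutations
      stop_if_not(all(names(pm) %in% names(cm)),
                  "clone '%s' lacks mutations of its parent", cl$id)
      changed <- names(pm)[pm != cm[names(pm)]]
      ok <- length(changed) == 0L ||
        (length(changed) == 1L && pm[changed] == "het" && cm[changed] == "hom")
      stop_if_not(ok, "clone '%s' changes parental zygosity other than one het->hom",
                  cl$id)
      extends <- length(setdiff(names(cm), names(pm))) > 0L || length(changed) == 1L
      stop_if_not(extends, "clone '%s' is identical to its parent", cl$id)
    }
  }
  structure(clones, class = "sim_hierarchy", wt_fraction = max(0, 1 - total))
}

#' Simulation configuration
#'
#' Parameters of the synthetic-data generator. Defaults mirror the scale of a
#' targeted single-cell DNA panel run over a bone-marrow aspirate: thousands of
#' cells, per-allele dropout around 5%, overdispersed amplicon depth around
#' 120x (deep enough that the genotyping criteria essentially never misread a
#' true heterozygote), and duplex-consensus bulk depth of 20,000 templates so
#' that clones at 0.1% variant allele fraction remain detectable.
#'
#' @param n_cells Number of cells per single-cell sample.
#' @param ado_rate Per-allele dropout probability, in `[0, 1)`. Each of a
#'   cell's alleles at a locus fails to amplify independently with this
#'   probability; when all alleles drop, the locus yields no reads.
#' @param doublet_rate Probability that a barcode contains two cells.
#' @param depth_mean,depth_size Negative-binomial mean and size (dispersion)
#'   of per-cell per-locus read depth for a diploid template complement.
#' @param seq_error Per-base probability that a read reports the alternate
#'   allele in error (and vice versa).
#' @param bulk_depth Duplex consensus depth per site for bulk simulation.
#' @param snp_depth Mean template depth at heterozygous SNP sites in the
#'   exome-style copy-number simulation.
#' @param target_depth Mean per-target template count in the copy-number
#'   simulation.
#' @param count_size Negative-binomial size of exome-style target and SNP
#'   template counts (dispersion of deduplicated capture counts around the
#'   target's efficiency-adjusted mean).
#' @param n_panel Number of diploid normal samples emitted as the panel of
#'   normals.
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_cells = 10000, ado_rate = 0.05, doublet_rate = 0.02,
                       depth_mean = 120, depth_size = 25, seq_error = 1e-4,
                       bulk_depth = 20000, snp_depth = 120, target_depth = 400,
                       count_size = 200, n_panel = 8, seed = 1L) {
  probs <- c(ado_rate = ado_rate, doublet_rate = doublet_rate, seq_error = seq_error)
  stop_if_not(all(probs >= 0 & probs < 1),
              "ado_rate, doublet_rate and seq_error must be in [0, 1)")
  stop_if_not(depth_mean > 0 && depth_size > 0 && bulk_depth > 0,
              "depth parameters must be positive")
  stop_if_not(n_cells >= 1, "n_cells must be >= 1")
  structure(list(n_cells = as.integer(n_cells), ado_rate = ado_rate,
                 doublet_rate = doublet_rate, depth_mean = depth_mean,
                 depth_size = depth_size, seq_error = seq_error,
                 bulk_depth = as.integer(bulk_depth),
                 snp_depth = snp_depth, target_depth = target_depth,
                 count_size = count_size,
                 n_panel = as.integer(n_panel), seed = as.integer(seed)),
            class = "sim_config")
}

# zygosity -> number of alternate alleles on a diploid background
.zyg_alt <- function(z) c(wt = 0L, het = 1L, hom = 2L)[z]

#' Simulate a single-cell genotyping run
#'
#' Draws cells from the clone hierarchy by multinomial sampling, forms doublets
#' as unions of two independently drawn cells' allele sets (with doubled
#' expected depth), applies independent per-allele dropout, and emits
#' overdispersed read counts with sequencing error. Read depth reflects the
#' amplicon read budget (amplification saturates), so a cell that lost one
#' allele still reads at full depth from the surviving allele; only loss of
#' all templates silences the locus. Germline heterozygous SNP loci (het in
#' every cell) can be added for allelic-dropout estimation.
#'
#' When every allele at a locus drops out the locus yields zero reads, so the
#' genotype is missing downstream rather than homozygous-appearing; a cell
#' appears homozygous only when exactly one of its two alleles survives.
#'
#' @param hierarchy A [sim_hierarchy()].
#' @param config A [sim_config()].
#' @param n_snps Number of germline heterozygous SNP loci to add.
#' @return A list with `cells` (long data frame: `cell_id`, `locus`, `depth`,
#'   `alt`), `truth` (per cell: `cell_id`, `clone`, `is_doublet`,
#'   `partner_clone`), and `loci` (locus, type).
#' @export
simulate_cells <- function(hierarchy, config, n_snps = 0L) {
  stop_if_not(inherits(hierarchy, "sim_hierarchy"), "hierarchy must be a sim_hierarchy")
  stop_if_not(inherits(config, "sim_config"), "config must be a sim_config")
  local_seed(config$seed, {
    ids <- c(".wt", names(hierarchy))
    fr <- c(attr(hierarchy, "wt_fraction"),
            vapply(hierarchy, `[[`, numeric(1), "fraction"))
    somatic <- sort(unique(unlist(lapply(hierarchy, function(cl) names(cl$mutations)))))
    snps <- if (n_snps > 0) sprintf("SNP%02d", seq_len(n_snps)) else character()
    loci <- c(somatic, snps)
    stop_if_not(length(loci) > 0, "no loci to simulate")
    n <- config$n_cells

    # per-clone alt-allele count at each locus (0/1/2 of 2)
    alt_of <- matrix(0L, nrow = length(ids), ncol = length(loci),
                     dimnames = list(ids, loci))
    for (cl in hierarchy) {
      if (length(cl$mutations)) {
        alt_of[cl$id, names(cl$mutations)] <- .zyg_alt(cl$mutations)
      }
    }
    if (length(snps)) alt_of[, snps] <- 1L

    clone1 <- sample(ids, n, replace = TRUE, prob = fr)
    is_doublet <- stats::runif(n) < config$doublet_rate
    clone2 <- ifelse(is_doublet, sample(ids, n, replace = TRUE, prob = fr),
                     NA_character_)

    nl <- length(loci)
    # allele complements per cell x locus, flattened cell-major
    a1 <- alt_of[clone1, , drop = FALSE]
    alt_alleles <- as.vector(t(a1))
    tot_alleles <- rep(2L, n * nl)
    if (any(is_doublet)) {
      idx <- which(rep(is_doublet, each = nl))
      a2 <- alt_of[clone2[is_doublet], , drop = FALSE]
      alt_alleles[idx] <- alt_alleles[idx] + as.vector(t(a2))
      tot_alleles[idx] <- 4L
    }

    keep_alt <- stats::rbinom(n * nl, alt_alleles, 1 - config$ado_rate)
    keep_ref <- stats::rbinom(n * nl, tot_alleles - alt_alleles, 1 - config$ado_rate)
    surv <- keep_alt + keep_ref

    # amplicon read budget: amplification saturates, so depth does not track
    # the surviving template count (doublets still get double the budget);
    # a locus with no surviving template yields no reads at all
    mu <- config$depth_mean * tot_alleles / 2
    depth <- integer(n * nl)
    pos <- surv > 0
    depth[pos] <- stats::rnbinom(sum(pos), size = config$depth_size, mu = mu[pos])
    af <- ifelse(surv > 0, keep_alt / pmax(surv, 1L), 0)
    f <- af * (1 - config$seq_error) + (1 - af) * config$seq_error
    alt <- integer(n * nl)
    alt[pos] <- stats::rbinom(sum(pos), depth[pos], f[pos])

    cell_id <- sprintf("cell%05d", seq_len(n))
    cells <- data.frame(cell_id = rep(cell_id, each = nl),
                        locus = rep(loci, times = n),
                        depth = depth, alt = alt,
                        stringsAsFactors = FALSE)
    truth <- data.frame(cell_id = cell_id, clone = clone1,
                        is_doublet = is_doublet, partner_clone = clone2,
                        stringsAsFactors = FALSE)
    loci_df <- data.frame(locus = loci,
                          type = c(rep("somatic", length(somatic)),
                                   rep("snp", length(snps))),
                          stringsAsFactors = FALSE)
    list(cells = cells, truth = truth, loci = loci_df)
  })
}

#' Simulate serial bulk duplex-consensus sequencing
#'
#' For each timepoint, draws duplex consensus alt counts binomially around the
#' true variant allele fraction implied by the clone fractions (VAF = sum over
#' carrying clones of fraction times multiplicity / 2), adds background
#' error-only sites, splits counts into forward/reverse strand families, and
#' emits a matched comparator (fibroblast-like germline reference) table.
#'
#' @param hierarchy A [sim_hierarchy()] defining clone genotypes.
#' @param trajectories Data frame with columns `age`, `clone`, `fraction`
#'   giving each clone's cell fraction at each timepoint. Ages must be sorted
#'   increasing and unique.
#' @param config A [sim_config()]; `bulk_depth` and `seq_error` are used.
#' @param n_background Number of truly wild-type sites carried through the
#'   caller (sequencing-error floor).
#' @param locus_spacing Genomic spacing (bp) between simulated sites.
#' @return A list with `calls` (one row per site per timepoint with duplex and
#'   strand counts and annotation columns consumed by [filter_variants()]),
#'   `comparator` (per-site germline reference counts) and `truth` (per-site,
#'   per-timepoint true VAF).
#' @export
simulate_bulk_duplex <- function(hierarchy, trajectories, config,
                                 n_background = 20L, locus_spacing = 1000L) {
  stop_if_not(inherits(hierarchy, "sim_hierarchy"), "hierarchy must be a sim_hierarchy")
  ages <- sort(unique(trajectories$age))
  stop_if_not(identical(ages, unique(trajectories$age)),
              "trajectory ages must be sorted increasing")
  stop_if_not(!anyDuplicated(ages), "duplicate timepoint ages")
  stop_if_not(all(trajectories$fraction >= 0 & trajectories$fraction <= 1),
              "clone fractions must be in [0, 1]")
  local_seed(config$seed, {
    somatic <- sort(unique(unlist(lapply(hierarchy, function(cl) names(cl$mutations)))))
    loci <- c(somatic,
              if (n_background > 0) sprintf("BG%03d", seq_len(n_background)))
    pos <- seq_along(loci) * locus_spacing
    names(pos) <- loci

    # multiplicity (alt alleles of 2) per clone x somatic locus
    mult <- matrix(0, nrow = length(hierarchy), ncol = length(somatic),
                   dimnames = list(names(hierarchy), somatic))
    for (cl in hierarchy) {
      if (length(cl$mutations)) {
        mult[cl$id, names(cl$mutations)] <- .zyg_alt(cl$mutations) / 2
      }
    }

    rows <- list(); truth_rows <- list()
    for (age in ages) {
      tr <- trajectories[trajectories$age == age, , drop = FALSE]
      frac <- stats::setNames(rep(0, length(hierarchy)), names(hierarchy))
      frac[tr$clone] <- tr$fraction
      true_vaf <- stats::setNames(rep(0, length(loci)), loci)
      if (length(somatic)) true_vaf[somatic] <- as.vector(frac %*% mult)
      f <- true_vaf * (1 - config$seq_error) + (1 - true_vaf) * config$seq_error
      depth <- config$bulk_depth
      alt <- stats::rbinom(length(loci), depth, f)
      depth_fwd <- stats::rbinom(length(loci), depth, 0.5)
      alt_fwd <- stats::rbinom(length(loci), alt, 0.5)
      rows[[as.character(age)]] <- data.frame(
        sample_id = sprintf("age_%g", age), age = age,
        locus = loci, chrom = "chr1", pos = unname(pos[loci]),
        ref_count = depth - alt, alt_count = alt,
        depth_fwd = depth_fwd, depth_rev = depth - depth_fwd,
        alt_fwd = alt_fwd, alt_rev = alt - alt_fwd,
        in_target = TRUE, consequence = "nonsynonymous",
        is_indel = FALSE, homopolymer_adjacent = FALSE,
        stringsAsFactors = FALSE)
      truth_rows[[as.character(age)]] <- data.frame(
        age = age, locus = loci, true_vaf = unname(true_vaf),
        stringsAsFactors = FALSE)
    }
    comp_depth <- config$bulk_depth
    comparator <- data.frame(
      locus = loci, chrom = "chr1", pos = unname(pos[loci]),
      ref_count = NA_integer_,
      alt_count = stats::rbinom(length(loci), comp_depth, config$seq_error),
      stringsAsFactors = FALSE)
    comparator$ref_count <- comp_depth - comparator$alt_count
    list(calls = do.call(rbind, c(rows, list(make.row.names = FALSE))),
         comparator = comparator,
         truth = do.call(rbind, c(truth_rows, list(make.row.names = FALSE))))
  })
}

#' Simulate exome-style target counts and heterozygous SNP allele counts
#'
#' Generates per-target template counts for a sample with segmental copy-number
#' truth, plus a matched panel of diploid normals sharing each target's capture
#' efficiency, and heterozygous-SNP allele counts whose expected alternate
#' fraction follows the standard purity/copy-number mixture: with allele pair
#' (a, b) at purity p, expected total copy ratio is `(p*(a+b) + 2*(1-p)) / 2`
#' and the alternate fraction of a SNP whose alternate allele lies on the
#' a-haplotype is `(p*a + (1-p)) / (p*(a+b) + 2*(1-p))`.
#'
#' @param segments_truth Data frame with columns `chrom`, `n_targets`,
#'   `n_snps`, `a`, `b` (nonnegative integer allele-specific copy numbers of
#'   haplotypes A and B).
#' @param purity Fraction of cells belonging to the aberrant clone, in `[0, 1]`.
#' @param config A [sim_config()].
#' @return A list with `targets` (target_id, chrom, start, end, count),
#'   `panel` (targets x panel samples count matrix), `snps` (snp_id, chrom,
#'   pos, target index, ref_count, alt_count, truth_hap) and `truth`
#'   (per-target segment truth).
#' @export
simulate_exome_counts <- function(segments_truth, purity, config) {
  stop_if_not(all(segments_truth$a >= 0) && all(segments_truth$b >= 0),
              "allele-specific copy numbers must be nonnegative")
  stop_if_not(purity >= 0 && purity <= 1, "purity must be in [0, 1]")
  local_seed(config$seed, {
    seg_id <- seq_len(nrow(segments_truth))
    n_t <- segments_truth$n_targets
    tgt_seg <- rep(seg_id, n_t)
    n_targets <- sum(n_t)
    a <- segments_truth$a[tgt_seg]
    b <- segments_truth$b[tgt_seg]
    chrom <- segments_truth$chrom[tgt_seg]
    start <- unlist(lapply(seq_along(seg_id), function(i) seq_len(n_t[i]))) * 2000L
    # restart coordinates per chromosome
    for (ch in unique(chrom)) {
      sel <- chrom == ch
      start[sel] <- seq_len(sum(sel)) * 2000L
    }
    tgt_id <- sprintf("t%04d", seq_len(n_targets))
    eff <- stats::rlnorm(n_targets, 0, 0.25)

    cnfac <- (purity * (a + b) + 2 * (1 - purity)) / 2
    panel <- matrix(stats::rnbinom(n_targets * config$n_panel,
                                   size = config$count_size,
                                   mu = rep(config$target_depth * eff,
                                            config$n_panel)),
                    nrow = n_targets,
                    dimnames = list(tgt_id, sprintf("normal%02d",
                                                    seq_len(config$n_panel))))
    count <- stats::rnbinom(n_targets, size = config$count_size,
                            mu = config$target_depth * eff * cnfac)
    targets <- data.frame(target_id = tgt_id, chrom = chrom,
                          start = start, end = start + 150L,
                          count = count, stringsAsFactors = FALSE)

    # SNPs: spread across each segment's targets
    snp_rows <- lapply(seq_along(seg_id), function(i) {
      k <- segments_truth$n_snps[i]
      if (k == 0) return(NULL)
      tix <- which(tgt_seg == i)
      at <- sort(sample(tix, k, replace = k > length(tix)))
      hap <- sample(c("A", "B"), k, replace = TRUE)
      ai <- segments_truth$a[i]; bi <- segments_truth$b[i]
      denom <- purity * (ai + bi) + 2 * (1 - purity)
      stop_if_not(denom > 0, "segment %d has zero expected copies", i)
      falt <- ifelse(hap == "A",
                     (purity * ai + (1 - purity)) / denom,
                     (purity * bi + (1 - purity)) / denom)
      dp <- stats::rnbinom(k, size = config$count_size,
                           mu = config$snp_depth * denom / 2)
      alt <- stats::rbinom(k, dp, pmin(pmax(falt, config$seq_error),
                                       1 - config$seq_error))
      data.frame(chrom = segments_truth$chrom[i],
                 pos = start[at] + 75L, target_id = tgt_id[at],
                 ref_count = dp - alt, alt_count = alt, truth_hap = hap,
                 stringsAsFactors = FALSE)
    })
    snps <- do.call(rbind, snp_rows)
    if (!is.null(snps) && nrow(snps)) {
      snps <- cbind(snp_id = sprintf("snp%04d", seq_len(nrow(snps))), snps,
                    stringsAsFactors = FALSE)
    }
    truth <- data.frame(target_id = tgt_id, segment = tgt_seg, a = a, b = b,
                        expected_tcr = cnfac, stringsAsFactors = FALSE)
    list(targets = targets, panel = panel, snps = snps, truth = truth)
  })
}

#' Write simulator outputs as plain-text tables plus a JSON truth file
#'
#' @param sim Output of [simulate_cells()], [simulate_bulk_duplex()] or
#'   [simulate_exome_counts()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  for (nm in names(sim)) {
    x <- sim[[nm]]
    if (is.matrix(x)) x <- data.frame(target_id = rownames(x), x,
                                      stringsAsFactors = FALSE)
    if (is.data.frame(x)) {
      p <- file.path(dir, paste0(nm, ".tsv"))
      write_tsv(x, p)
    } else {
      p <- file.path(dir, paste0(nm, ".json"))
      jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA)
    }
    written <- c(written, p)
  }
  invisible(written)
}
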
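#' Draw a random clone hierarchy with known truth
#'
#' Generates a forest of somatic clones for parameter-recovery studies. Each
#' clone is either a new founding clone carrying a fresh heterozygous
#' mutation, a child of an existing clone carrying one additional mutation,
#' or a copy-neutral-LOH progression child (one parental het turned hom).
#' Cell fractions are log-uniform on `[min_frac, max_frac]` and rescaled so
#' the mutated compartment stays below 60% of cells, reflecting the low-
#' abundance clonal hematopoiesis this pipeline targets. Genotype vectors are
#' kept distinct across clones (clones identical in genotype are
#' indistinguishable to any genotype-based method and are not generated).
#'
#' Uses the session RNG; call [set.seed()] beforehand for reproducibility.
#'
#' @param n_clones Number of clones.
#' @param min_frac,max_frac Range of per-clone cell fractions.
#' @param p_child Probability a clone is a mutation-gaining child.
#' @param p_loh Probability a clone is an LOH progression child.
#' @param genes Gene labels cycled through new locus names.
#' @return A [sim_hierarchy()].
#' @export
random_hierarchy <- function(n_clones, min_frac = 0.005, max_frac = 0.12,
                             p_child = 0.35, p_loh = 0.15,
                             genes = c("EIF6", "TP53")) {
  clones <- list()
  locus_i <- 0L
  new_locus <- function() {
    locus_i <<- locus_i + 1L
    sprintf("%s_m%02d", genes[1L + (locus_i %% length(genes))], locus_i)
  }
  mut_key <- function(mut) paste(sort(paste(names(mut), mut)), collapse = ";")
  seen <- character()
  fr <- exp(stats::runif(n_clones, log(min_frac), log(max_frac)))
  if (sum(fr) > 0.6) fr <- fr * 0.6 / sum(fr)
  fr <- pmax(fr, min_frac)
  for (i in seq_len(n_clones)) {
    u <- stats::runif(1)
    placed <- FALSE
    if (i > 1 && u < p_loh) {
      het_parents <- Filter(function(cl) any(cl$mutations == "het"), clones)
      if (length(het_parents)) {
        par <- het_parents[[sample.int(length(het_parents), 1)]]
        mut <- par$mutations
        L <- sample(names(mut)[mut == "het"], 1)
        mut[L] <- "hom"
        if (!(mut_key(mut) %in% seen)) {
          clones[[i]] <- sim_clone(sprintf("C%d", i), fr[i], mut,
                                   parent = par$id)
          placed <- TRUE
        }
      }
    }
    if (!placed && i > 1 && u < p_loh + p_child) {
      par <- clones[[sample.int(length(clones), 1)]]
      mut <- c(par$mutations, stats::setNames("het", new_locus()))
      clones[[i]] <- sim_clone(sprintf("C%d", i), fr[i], mut, parent = par$id)
      placed <- TRUE
    }
    if (!placed) {
      clones[[i]] <- sim_clone(sprintf("C%d", i), fr[i],
                               stats::setNames("het", new_locus()))
    }
    seen <- c(seen, mut_key(clones[[i]]$mutations))
  }
  sim_hierarchy(clones)
}

#' Describe a truth hierarchy as genotype keys and parent keys
#'
#' @param h A [sim_hierarchy()].
#' @param loci Full locus set defining the genotype vectors.
#' @return Data frame with `key` (genotype vector string) and `parent_key`.
#' @export
truth_clone_keys <- function(h, loci) {
  keys <- vapply(h, function(cl) {
    gt <- stats::setNames(rep("wt", length(loci)), loci)
    gt[names(cl$mutations)] <- cl$mutations
    paste(gt, collapse = "|")
  }, character(1))
  parents <- vapply(h, function(cl) {
    if (is.na(cl$parent)) NA_character_ else keys[[cl$parent]]
  }, character(1))
  data.frame(key = unname(keys), parent_key = unname(parents),
             stringsAsFactors = FALSE)
}

#' Describe an inferred hierarchy in the same key format
#'
#' @param ch A `clone_hierarchy` from [build_hierarchy()].
#' @param include_doublets Keep clones flagged `putative_doublet`
#'   (default `FALSE`).
#' @return Data frame with `key` and `parent_key`.
#' @export
inferred_clone_keys <- function(ch, include_doublets = FALSE) {
  g <- ch$genotypes
  keys <- apply(g, 1L, paste, collapse = "|")
  parent_keys <- ifelse(is.na(ch$parent), NA_character_,
                        keys[match(ch$parent, rownames(g))])
  out <- data.frame(key = unname(keys), parent_key = unname(parent_keys),
                    stringsAsFactors = FALSE)
  if (!include_doublets) {
    dbl <- vapply(ch$flags, function(f) "putative_doublet" %in% f, logical(1))
    out <- out[!dbl, , drop = FALSE]
  }
  out
}

#' Did inference recover the truth hierarchy exactly?
#'
#' Exact recovery means the same set of genotype vectors and the same parent
#' edge for every clone.
#'
#' @param h Truth [sim_hierarchy()].
#' @param ch Inferred `clone_hierarchy`.
#' @return Logical scalar.
#' @export
recovered_exactly <- function(h, ch) {
  tk <- truth_clone_keys(h, ch$somatic_loci)
  ik <- inferred_clone_keys(ch)
  if (nrow(tk) != nrow(ik)) return(FALSE)
  tk <- tk[order(tk$key), ]
  ik <- ik[order(ik$key), ]
  identical(tk$key, ik$key) &&
    identical(is.na(tk$parent_key), is.na(ik$parent_key)) &&
    all(tk$parent_key == ik$parent_key, na.rm = TRUE)
}

#' End-to-end single-cell clone inference from a simulated run
#'
#' Convenience driver chaining the pipeline stages: simulate cells, call
#' genotypes, estimate allelic dropout from germline SNPs, identify clones
#' and build the hierarchy.
#'
#' @param h A [sim_hierarchy()].
#' @param cfg A [sim_config()].
#' @param n_snps Germline het SNP loci to simulate for dropout estimation.
#' @param min_cells,alpha Passed to [identify_clones()].
#' @return List with `sim`, `cells`, `ado` and `hierarchy`.
#' @export
infer_from_sim <- function(h, cfg, n_snps = 8L, min_cells = 10L, alpha = 0.01) {
  sim <- simulate_cells(h, cfg, n_snps = n_snps)
  cells <- call_genotypes(sim$cells)
  snp_loci <- sim$loci$locus[sim$loci$type == "snp"]
  ado <- estimate_ado(cells, snp_loci, n_boot = 10L)
  somatic <- sim$loci$locus[sim$loci$type == "somatic"]
  gm <- genotype_matrix(cells)
  cs <- identify_clones(gm, somatic,
                        ado = stats::setNames(
                          rep(ado$sample_level, length(somatic)), somatic),
                        min_cells = min_cells, alpha = alpha,
                        doublet_rate = cfg$doublet_rate,
                        depth_mean = cfg$depth_mean,
                        depth_size = cfg$depth_size)
  list(sim = sim, cells = cells, ado = ado, hierarchy = build_hierarchy(cs))
}
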
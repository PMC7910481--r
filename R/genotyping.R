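#' Call a per-cell genotype from depth and alternate counts
#'
#' Applies the panel genotyping criteria: a locus with total depth below
#' `min_depth` is missing; the variant is present iff the alternate count is
#' at least `min_alt` and the alternate fraction is at least `min_vaf`; a
#' present variant with alternate fraction at or above `hom_vaf` is called
#' homozygous, otherwise heterozygous; anything else is wild type. Vectorized
#' and pure.
#'
#' @param depth,alt Nonnegative integer vectors, `alt <= depth`.
#' @param min_depth Minimum depth for a non-missing call (default 10).
#' @param min_alt Minimum alternate reads for variant presence (default 3).
#' @param min_vaf Minimum alternate fraction for variant presence (default 0.30).
#' @param hom_vaf Alternate fraction at or above which a present variant is
#'   homozygous (default 0.90).
#' @return Character vector in `{"missing", "wt", "het", "hom"}`.
#' @export
call_genotype <- function(depth, alt, min_depth = 10L, min_alt = 3L,
                          min_vaf = 0.30, hom_vaf = 0.90) {
  stop_if_not(all(depth >= 0) && all(alt >= 0), "counts must be nonnegative")
  stop_if_not(all(alt <= depth), "alt exceeds depth")
  frac <- ifelse(depth > 0, alt / depth, 0)
  present <- alt >= min_alt & frac >= min_vaf
  gt <- ifelse(depth < min_depth, "missing",
               ifelse(!present, "wt",
                      ifelse(frac >= hom_vaf, "hom", "het")))
  gt
}

#' Add genotype calls to a long cells table
#'
#' @param cells Long data frame with `cell_id`, `locus`, `depth`, `alt`.
#' @param ... Passed to [call_genotype()].
#' @return `cells` with a `genotype` column added.
#' @export
call_genotypes <- function(cells, ...) {
  cells$genotype <- call_genotype(cells$depth, cells$alt, ...)
  cells
}

#' Pivot a genotyped cells table to a cells x loci matrix
#'
#' @param cells Output of [call_genotypes()].
#' @param value Column to pivot (default `"genotype"`).
#' @return Character (or numeric) matrix with cell ids as rows, loci as
#'   columns; absent combinations are `"missing"` (or `NA`).
#' @export
genotype_matrix <- function(cells, value = "genotype") {
  cell_ids <- unique(cells$cell_id)
  loci <- unique(cells$locus)
  fill <- if (value == "genotype") "missing" else NA
  m <- matrix(fill, nrow = length(cell_ids), ncol = length(loci),
              dimnames = list(cell_ids, loci))
  m[cbind(match(cells$cell_id, cell_ids), match(cells$locus, loci))] <-
    cells[[value]]
  m
}

#' Select informative heterozygous SNP loci for dropout estimation
#'
#' A locus is informative when its pseudobulk alternate fraction over all
#' cells falls in `[0.35, 0.65]` (consistent with a germline heterozygote)
#' and it is called heterozygous in at least `min_het_frac` of genotyped
#' cells.
#'
#' @param cells Genotyped long table ([call_genotypes()]).
#' @param candidates Loci to consider (default: all).
#' @param af_range Pseudobulk alternate-fraction window.
#' @param min_het_frac Minimum fraction of genotyped cells called het.
#' @return Character vector of informative loci.
#' @export
informative_snps <- function(cells, candidates = unique(cells$locus),
                             af_range = c(0.35, 0.65), min_het_frac = 0.20) {
  keep <- character()
  for (loc in candidates) {
    x <- cells[cells$locus == loc, , drop = FALSE]
    dp <- sum(x$depth)
    if (dp == 0) next
    af <- sum(x$alt) / dp
    gt <- x$genotype[x$genotype != "missing"]
    if (!length(gt)) next
    if (af >= af_range[1] && af <= af_range[2] &&
        mean(gt == "het") >= min_het_frac) {
      keep <- c(keep, loc)
    }
  }
  keep
}

#' Estimate allelic dropout from informative heterozygous sites
#'
#' For each informative site, the dropout ratio is the number of cells with a
#' homozygous (reference or variant) genotype divided by the number of cells
#' with a heterozygous genotype, among genotyped cells at that site. The
#' sample-level estimate is the unweighted mean over sites. Under independent
#' per-allele dropout at rate `d`, the expected ratio is `2d / (1 - d)`.
#' Cells with more than `max_missing_frac` missing loci are dropped first;
#' sites with no heterozygous cells are excluded with a message. A bootstrap
#' over cells gives the confidence interval.
#'
#' @param cells Genotyped long table ([call_genotypes()]).
#' @param informative Character vector of informative het-SNP loci.
#' @param n_boot Bootstrap replicates over cells (default 100).
#' @param conf Confidence level for the bootstrap interval.
#' @param max_missing_frac Cells missing more than this fraction of loci are
#'   excluded.
#' @return List with `per_site` (named ratios), `sample_level`, `ci`
#'   (bootstrap percentile interval), `se` (bootstrap standard error) and
#'   `n_cells` used.
#' @export
estimate_ado <- function(cells, informative, n_boot = 100L, conf = 0.95,
                         max_missing_frac = 0.50) {
  stop_if_not(length(informative) > 0, "no informative sites supplied")
  sub <- cells[cells$locus %in% informative, , drop = FALSE]
  miss <- tapply(sub$genotype == "missing", sub$cell_id, mean)
  keep_cells <- names(miss)[miss <= max_missing_frac]
  sub <- sub[sub$cell_id %in% keep_cells, , drop = FALSE]
  stop_if_not(nrow(sub) > 0, "no cells left after missingness filter")

  ratios_for <- function(df) {
    out <- vapply(split(df$genotype, df$locus), function(g) {
      n_het <- sum(g == "het")
      n_hom <- sum(g == "hom" | g == "wt")
      if (n_het == 0) return(NA_real_)
      n_hom / n_het
    }, numeric(1))
    out
  }
  per_site <- ratios_for(sub)
  dropped <- names(per_site)[is.na(per_site)]
  if (length(dropped)) {
    message("sites with no heterozygous cells excluded: ",
            paste(dropped, collapse = ", "))
  }
  per_site <- per_site[!is.na(per_site)]
  stop_if_not(length(per_site) > 0, "no site with heterozygous cells")
  sample_level <- mean(per_site)

  cell_ids <- unique(sub$cell_id)
  split_by_cell <- split(seq_len(nrow(sub)), sub$cell_id)
  boot <- vapply(seq_len(n_boot), function(b) {
    pick <- sample(cell_ids, length(cell_ids), replace = TRUE)
    idx <- unlist(split_by_cell[pick], use.names = FALSE)
    mean(ratios_for(sub[idx, , drop = FALSE]), na.rm = TRUE)
  }, numeric(1))
  alpha <- (1 - conf) / 2
  list(per_site = per_site, sample_level = sample_level,
       ci = unname(stats::quantile(boot, c(alpha, 1 - alpha), na.rm = TRUE)),
       se = stats::sd(boot, na.rm = TRUE), n_cells = length(cell_ids))
}

#' Convert a site-level dropout ratio to a per-allele dropout rate
#'
#' With singlet cells only, the expected hom/het ratio at a germline
#' heterozygous site under independent per-allele dropout at rate `d` is
#' `r = 2d(1-d) / (1-d)^2 = 2d/(1-d)`, inverted as `d = r/(2+r)`. Doublet
#' barcodes deflate the observed ratio: a doublet carries four alleles at a
#' het SNP and virtually always appears heterozygous, adding het calls
#' without hom calls. When the doublet rate `delta` is known, the expected
#' observed ratio is `(1-delta) * 2d(1-d) / ((1-delta)(1-d)^2 + delta)` and
#' is inverted numerically.
#'
#' @param ratio Hom/het dropout ratio (site or sample level).
#' @param doublet_rate Known fraction of doublet barcodes (default 0).
#' @return Per-allele dropout probability.
#' @export
ado_ratio_to_rate <- function(ratio, doublet_rate = 0) {
  if (doublet_rate <= 0 || ratio <= 0) return(ratio / (2 + ratio))
  pred <- function(d) {
    (1 - doublet_rate) * 2 * d * (1 - d) /
      ((1 - doublet_rate) * (1 - d)^2 + doublet_rate) - ratio
  }
  stats::uniroot(pred, c(1e-9, 0.5 - 1e-9), tol = 1e-10)$root
}

#' Technical dropout of targeted mutations in the single-cell assay
#'
#' Targeted mutations are those present in the filtered bulk call set and
#' located in designable amplicons; a targeted mutation is genotyped when at
#' least one cell carries a non-missing variant (het or hom) call at its
#' locus. Returns the fraction genotyped.
#'
#' @param cells Genotyped long table.
#' @param bulk_passing Character vector of loci passing the bulk filter.
#' @param designable Character vector of loci with designable amplicons.
#' @return List with `fraction`, `n_targeted`, `detected` and `undetected`
#'   locus vectors.
#' @export
technical_dropout <- function(cells, bulk_passing, designable) {
  targeted <- intersect(bulk_passing, designable)
  stop_if_not(length(targeted) > 0, "empty targeted mutation set")
  carried <- vapply(targeted, function(loc) {
    g <- cells$genotype[cells$locus == loc]
    any(g %in% c("het", "hom"))
  }, logical(1))
  list(fraction = mean(carried), n_targeted = length(targeted),
       detected = targeted[carried], undetected = targeted[!carried])
}
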
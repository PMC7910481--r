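# A clone's mutation set is the loci at which its genotype is het or hom.
.mut_loci <- function(gt) names(gt)[gt != "wt"]

# row of a genotype matrix as a named vector (single-column subsetting would
# otherwise drop the locus names)
.row_gt <- function(g, i) stats::setNames(as.character(g[i, ]), colnames(g))

# per-cell probability that a true-het cell appears homozygous (or wild type)
# at a site through allelic dropout alone, given the site's hom/het dropout
# ratio r: per-allele rate d (doublet-corrected inversion of r), appearance
# probability d(1-d) + d^2 = d.
.ado_spillover_p <- function(ratio, doublet_rate = 0) {
  d <- ado_ratio_to_rate(ratio, doublet_rate)
  d * (1 - d) + d^2
}

# one-sided upper binomial tail: P(X >= x | n, p)
.binom_upper <- function(x, n, p) stats::pbinom(x - 1, n, p, lower.tail = FALSE)

# genotype-call probability under the panel criteria for a cell with true
# allele fraction af and negative-binomial depth (mu, size), marginalized
# over depth; returns a memoizing closure over (af, call)
.pcall_cache <- function(mu, size, min_depth = 10L, min_alt = 3L,
                         min_vaf = 0.30, hom_vaf = 0.90) {
  d <- 0:max(2000, ceiling(mu * 6))
  w <- stats::dnbinom(d, size = size, mu = mu)
  cache <- new.env(parent = emptyenv())
  function(af, call) {
    key <- paste(af, call)
    if (!is.null(cache[[key]])) return(cache[[key]])
    lo <- pmax(min_alt, ceiling(min_vaf * d))
    hom_lo <- pmax(min_alt, ceiling(hom_vaf * d))
    deep <- d >= min_depth
    val <- switch(call,
      het = sum(w[deep] * pmax(0, stats::pbinom(hom_lo[deep] - 1, d[deep], af) -
                                  stats::pbinom(lo[deep] - 1, d[deep], af))),
      hom = sum(w[deep] * stats::pbinom(hom_lo[deep] - 1, d[deep], af,
                                        lower.tail = FALSE)),
      wt = sum(w[deep] * stats::pbinom(lo[deep] - 1, d[deep], af)),
      missing = sum(w[!deep]))
    cache[[key]] <- val
    val
  }
}

#' Identify clones from a genotyped single-cell matrix
#'
#' Cells with complete (non-missing) genotypes at all somatic loci are grouped
#' by exact genotype vector. Groups smaller than `min_cells` or below
#' `min_frequency` are discarded. A retained group differing from a larger
#' group only by a het-to-wt or het-to-hom change at one locus is tested
#' against the allelic-dropout spillover null: the smaller group's size is
#' compared, by a one-sided binomial test at level `alpha`, with the number of
#' dropout-affected cells expected from the combined group at that site's
#' dropout rate; when the null is not rejected the group is merged into the
#' larger one. Groups whose size is consistent with the expected number of
#' doublet barcodes whose mixed allele fractions would be called exactly that
#' genotype vector (for example, a homozygous cell plus a wild-type cell
#' reads as heterozygous) are flagged `putative_doublet` (retained, not
#' removed).
#'
#' @param gt Character matrix of genotypes, cells x loci (from
#'   [genotype_matrix()]).
#' @param somatic_loci Loci defining clones (must be columns of `gt`).
#' @param ado Named per-site dropout ratios (hom/het, as from
#'   [estimate_ado()]), or a single ratio recycled to all sites.
#' @param min_cells Minimum group size retained (default 10).
#' @param min_frequency Minimum group frequency among complete cells
#'   (default 0.001).
#' @param alpha Level of the dropout-spillover binomial test (default 0.01).
#' @param doublet_rate Doublet probability used for the doublet-image flag
#'   (default 0, disables the flag).
#' @param depth_mean,depth_size Negative-binomial depth model of the panel,
#'   used only to compute genotype-call probabilities under the doublet-image
#'   null (a doublet barcode reads at twice `depth_mean`).
#' @return A `clone_set`: list with `genotypes` (clones x loci matrix ordered
#'   by decreasing size), `n_cells`, `frequency`, `flags`, `n_complete`,
#'   `n_wt` (complete wild-type cells), `merged` (log of dropout merges) and
#'   `somatic_loci`.
#' @export
identify_clones <- function(gt, somatic_loci, ado, min_cells = 10L,
                            min_frequency = 0.001, alpha = 0.01,
                            doublet_rate = 0, depth_mean = 120,
                            depth_size = 25) {
  stop_if_not(all(somatic_loci %in% colnames(gt)),
              "somatic locus absent from genotype matrix")
  sub <- gt[, somatic_loci, drop = FALSE]
  complete <- rowSums(sub == "missing") == 0L
  stop_if_not(any(complete), "no cells with complete genotypes at somatic loci")
  sub <- sub[complete, , drop = FALSE]
  n_complete <- nrow(sub)
  if (length(ado) == 1L && is.null(names(ado))) {
    ado <- stats::setNames(rep(ado, length(somatic_loci)), somatic_loci)
  }
  stop_if_not(all(somatic_loci %in% names(ado)),
              "dropout ratio missing for some somatic loci")

  key <- apply(sub, 1L, paste, collapse = "|")
  counts <- table(key)
  gvec <- do.call(rbind, strsplit(names(counts), "|", fixed = TRUE))
  colnames(gvec) <- somatic_loci
  size <- as.integer(counts)

  is_wt <- rowSums(gvec != "wt") == 0L
  n_wt <- if (any(is_wt)) size[is_wt] else 0L
  keep <- !is_wt & size >= min_cells & size / n_complete >= min_frequency
  gvec <- gvec[keep, , drop = FALSE]
  size <- size[keep]

  merged_log <- list()
  if (nrow(gvec) > 1) {
    repeat {
      ord <- order(size)
      did_merge <- FALSE
      for (gi in ord) {
        diffs_one <- function(pi) {
          dif <- which(gvec[gi, ] != gvec[pi, ])
          if (length(dif) != 1L) return(NA_character_)
          L <- somatic_loci[dif]
          if (gvec[pi, dif] == "het" && gvec[gi, dif] %in% c("wt", "hom")) L
          else NA_character_
        }
        cand <- setdiff(which(size > size[gi]), gi)
        if (!length(cand)) next
        locus_at <- vapply(cand, diffs_one, character(1))
        cand <- cand[!is.na(locus_at)]
        locus_at <- locus_at[!is.na(locus_at)]
        if (!length(cand)) next
        # try every plausible dropout source, largest first; merge into the
        # first one whose spillover null is not rejected
        o <- order(-size[cand])
        for (oi in o) {
          pi <- cand[oi]; L <- locus_at[oi]
          p_cell <- .ado_spillover_p(ado[[L]], doublet_rate)
          pval <- .binom_upper(size[gi], size[gi] + size[pi], p_cell)
          if (pval >= alpha) {
            merged_log[[length(merged_log) + 1L]] <- data.frame(
              merged_genotype = paste(gvec[gi, ], collapse = "|"),
              into_genotype = paste(gvec[pi, ], collapse = "|"),
              locus = L, n_merged = size[gi], p_value = pval,
              stringsAsFactors = FALSE)
            size[pi] <- size[pi] + size[gi]
            gvec <- gvec[-gi, , drop = FALSE]
            size <- size[-gi]
            did_merge <- TRUE
            break
          }
        }
        if (did_merge) break
      }
      if (!did_merge || nrow(gvec) < 2) break
    }
  }

  ord <- order(-size, apply(gvec, 1L, paste, collapse = "|"))
  gvec <- gvec[ord, , drop = FALSE]
  size <- size[ord]
  nclone <- nrow(gvec)
  rownames(gvec) <- if (nclone) sprintf("clone%02d", seq_len(nclone)) else NULL
  names(size) <- rownames(gvec)
  flags <- rep(list(character()), nclone)
  names(flags) <- rownames(gvec)

  if (doublet_rate > 0 && nclone >= 1) {
    # doublet-image null: a barcode holding one cell of population A and one
    # of B reads allele fraction (altA + altB)/4 at each locus; a retained
    # group whose size is consistent with the expected number of doublets
    # called exactly its genotype vector (plus single-locus dropout spillover)
    # is flagged putative_doublet but kept
    pop_gt <- rbind(gvec, wt = rep("wt", ncol(gvec)))
    pop_n <- c(size, n_wt)
    pop_f <- pop_n / n_complete
    pop_alt <- matrix(.zyg_alt(pop_gt), nrow = nrow(pop_gt))
    npop <- nrow(pop_gt)
    pc <- .pcall_cache(2 * depth_mean, depth_size)
    for (i in seq_len(nclone)) {
      lam <- 0
      gi_call <- gvec[i, ]
      for (a in seq_len(npop)) {
        for (b in a:npop) {
          af <- (pop_alt[a, ] + pop_alt[b, ]) / 4
          prob <- prod(vapply(seq_along(af), function(L) {
            pc(af[L], gi_call[L])
          }, numeric(1)))
          if (prob == 0) next
          lam <- lam + (if (a == b) 1 else 2) * pop_f[a] * pop_f[b] * prob
        }
      }
      p_dbl <- doublet_rate * lam
      # dropout spillover into this genotype from any single-locus-het parent
      p_spill <- 0
      for (j in seq_len(nclone)) {
        if (j == i) next
        dif <- which(gvec[j, ] != gvec[i, ])
        if (length(dif) == 1L && gvec[j, dif] == "het" &&
            gvec[i, dif] %in% c("wt", "hom")) {
          p_spill <- max(p_spill, (size[j] / n_complete) *
                           .ado_spillover_p(ado[[somatic_loci[dif]]],
                                            doublet_rate))
        }
      }
      if (.binom_upper(size[i], n_complete, p_dbl + p_spill) >= alpha) {
        flags[[i]] <- union(flags[[i]], "putative_doublet")
      }
    }
  }

  structure(list(genotypes = gvec, n_cells = size,
                 frequency = size / n_complete, flags = flags,
                 n_complete = n_complete, n_wt = n_wt,
                 somatic_loci = somatic_loci, ado = ado,
                 doublet_rate = doublet_rate,
                 merged = if (length(merged_log)) {
                   do.call(rbind, merged_log)
                 } else NULL),
            class = "clone_set")
}

# is p an ancestor-compatible genotype of c? (p's mutations contained in c's,
# allowing het->hom progression at shared loci); strict: p != c
.is_ancestor_genotype <- function(p, c) {
  if (identical(unname(p), unname(c))) return(FALSE)
  mp <- .mut_loci(p)
  if (!all(mp %in% .mut_loci(c))) return(FALSE)
  shared <- mp
  ok <- p[shared] == c[shared] | (p[shared] == "het" & c[shared] == "hom")
  all(ok)
}

#' Build the clonal hierarchy from identified clones
#'
#' The parent of a clone is the retained clone with the largest mutation set
#' that is ancestor-compatible with it (its mutations are a subset, allowing a
#' het-to-hom LOH progression at shared loci). Clones with no compatible
#' ancestor are founding clones; the result is a forest, since independent
#' clones are the rule in this setting. When two incomparable candidate
#' parents have maximal mutation sets, the clone is attached to the larger
#' (by cell count) and flagged `ambiguous_parent`.
#'
#' @param cs A `clone_set` from [identify_clones()].
#' @return A `clone_hierarchy`: the `clone_set` plus `parent` (named vector,
#'   `NA` for founding clones) and per-clone `founding`/`subclone` flags.
#' @export
build_hierarchy <- function(cs) {
  stop_if_not(inherits(cs, "clone_set"), "cs must be a clone_set")
  g <- cs$genotypes
  n <- nrow(g)
  parent <- stats::setNames(rep(NA_character_, n), rownames(g))
  for (i in seq_len(n)) {
    anc <- which(vapply(seq_len(n), function(j) {
      j != i && .is_ancestor_genotype(.row_gt(g, j), .row_gt(g, i))
    }, logical(1)))
    if (!length(anc)) next
    msize <- vapply(anc, function(j) length(.mut_loci(.row_gt(g, j))), integer(1))
    # parsimony: largest contained mutation set, then fewest het->hom
    # transitions separating parent from child
    nloh <- vapply(anc, function(j) {
      sum(g[j, ] == "het" & g[i, ] == "hom")
    }, integer(1))
    best <- anc[msize == max(msize)]
    nloh <- nloh[msize == max(msize)]
    best <- best[nloh == min(nloh)]
    if (length(best) > 1L) {
      # incomparable maximal candidates: attach to the larger clone
      best <- best[order(-cs$n_cells[best])]
      cs$flags[[i]] <- union(cs$flags[[i]], "ambiguous_parent")
    }
    parent[i] <- rownames(g)[best[1L]]
  }
  for (i in seq_len(n)) {
    cs$flags[[i]] <- union(cs$flags[[i]],
                           if (is.na(parent[i])) "founding" else "subclone")
  }
  cs$parent <- parent
  class(cs) <- c("clone_hierarchy", "clone_set")
  cs
}

#' Flag copy-neutral-LOH progression subclones
#'
#' A clone homozygous at exactly one somatic locus where its parent is
#' heterozygous (and otherwise identical) is flagged `loh_subclone` when its
#' size rejects the dropout-spillover null (same one-sided binomial test as in
#' [identify_clones()]). A homozygous clone with no heterozygous parent is
#' flagged `loh_orphan` instead. Returns the hierarchy with flags and a
#' per-pair report of heterozygous:homozygous proportions.
#'
#' @param ch A `clone_hierarchy` from [build_hierarchy()].
#' @param alpha Test level (default 0.01).
#' @return `ch` with updated flags and a `loh_report` data frame.
#' @export
detect_loh_subclones <- function(ch, alpha = 0.01) {
  stop_if_not(inherits(ch, "clone_hierarchy"), "ch must be a clone_hierarchy")
  g <- ch$genotypes
  report <- list()
  for (i in seq_len(nrow(g))) {
    hom_at <- ch$somatic_loci[g[i, ] == "hom"]
    if (!length(hom_at)) next
    pid <- ch$parent[i]
    if (is.na(pid)) {
      ch$flags[[i]] <- union(ch$flags[[i]], "loh_orphan")
      next
    }
    pg <- g[pid, ]
    dif <- which(g[i, ] != pg)
    is_loh_edge <- length(dif) == 1L && pg[dif] == "het" && g[i, dif] == "hom"
    if (!is_loh_edge) next
    L <- ch$somatic_loci[dif]
    n_het <- ch$n_cells[pid]; n_hom <- ch$n_cells[i]
    dr <- if (is.null(ch$doublet_rate)) 0 else ch$doublet_rate
    pval <- .binom_upper(n_hom, n_hom + n_het,
                         .ado_spillover_p(ch$ado[[L]], dr))
    if (pval < alpha) ch$flags[[i]] <- union(ch$flags[[i]], "loh_subclone")
    report[[length(report) + 1L]] <- data.frame(
      clone = rownames(g)[i], parent = pid, locus = L,
      n_het = n_het, n_hom = n_hom,
      hom_proportion = n_hom / (n_hom + n_het), p_value = pval,
      loh_subclone = pval < alpha, stringsAsFactors = FALSE)
  }
  ch$loh_report <- if (length(report)) do.call(rbind, report) else NULL
  ch
}

#' Track mutations across serial bulk samples
#'
#' Builds a per-mutation timeline over filtered serial bulk calls: detection
#' status and VAF at each age, first and last detection, and the VAF fold
#' change between first and most recent detection. Mutations detected at a
#' single timepoint carry an undefined (`NA`) fold change.
#'
#' @param calls Filtered calls ([filter_variants()]) with `age`, `locus`,
#'   `vaf`, `status` columns across timepoints.
#' @return Data frame: one row per mutation ever passing, with
#'   `first_detection_age`, `last_detection_age`, `n_detected`, `vaf_first`,
#'   `vaf_last`, `fold_change`.
#' @export
track_clones <- function(calls) {
  ages <- unique(calls$age)
  stop_if_not(!anyDuplicated(calls[, c("age", "locus")]),
              "duplicate (age, locus) rows")
  stop_if_not(!is.unsorted(ages), "timepoints must be age-sorted")
  pass <- calls[calls$status == "pass", , drop = FALSE]
  loci <- unique(pass$locus)
  rows <- lapply(loci, function(loc) {
    x <- pass[pass$locus == loc, , drop = FALSE]
    x <- x[order(x$age), , drop = FALSE]
    n <- nrow(x)
    data.frame(locus = loc,
               first_detection_age = x$age[1L],
               last_detection_age = x$age[n],
               n_detected = n,
               vaf_first = x$vaf[1L], vaf_last = x$vaf[n],
               fold_change = if (n >= 2L) x$vaf[n] / x$vaf[1L] else NA_real_,
               stringsAsFactors = FALSE)
  })
  if (!length(rows)) {
    return(data.frame(locus = character(), first_detection_age = numeric(),
                      last_detection_age = numeric(), n_detected = integer(),
                      vaf_first = numeric(), vaf_last = numeric(),
                      fold_change = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Count clones carrying mutations in a single gene
#'
#' Summarizes mutational exclusivity across clones: for each gene, the number
#' of clones whose mutation set touches that gene only; clones touching two
#' or more genes are counted as co-mutated.
#'
#' @param cs A `clone_set` (or hierarchy).
#' @param gene_map Named character vector, locus -> gene; every mutated locus
#'   must be annotated.
#' @return List with `sole` (named counts per gene) and `co_mutated` (count).
#' @export
clone_exclusivity_summary <- function(cs, gene_map) {
  g <- cs$genotypes
  sole <- integer(); co <- 0L
  for (i in seq_len(nrow(g))) {
    m <- .mut_loci(.row_gt(g, i))
    stop_if_not(all(m %in% names(gene_map)),
                "unannotated locus in clone %s", rownames(g)[i])
    genes <- unique(gene_map[m])
    if (length(genes) == 1L) {
      sole[genes] <- if (genes %in% names(sole)) sole[[genes]] + 1L else 1L
    } else if (length(genes) > 1L) {
      co <- co + 1L
    }
  }
  list(sole = sole, co_mutated = co)
}
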
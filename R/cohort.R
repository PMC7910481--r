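#' Two-sided Fisher exact test on a 2x2 table
#'
#' Probability-mass convention: the p-value is the sum of hypergeometric
#' probabilities, over all tables with the observed margins, that do not
#' exceed the observed table's probability (within a relative tie tolerance
#' of 1e-7). The tail-doubling convention (twice the smaller one-sided tail,
#' capped at 1) is reported alongside.
#'
#' @param tab 2x2 matrix (or vector a, b, c, d by row) of nonnegative counts.
#' @return List with `p` (probability-mass two-sided), `p_doubled`
#'   (tail-doubling), `odds_ratio` (sample odds ratio).
#' @export
fisher_exact_two_sided <- function(tab) {
  x <- as.vector(t(tab))
  stop_if_not(length(x) == 4 && all(x >= 0) && all(x == round(x)),
              "need a 2x2 table of nonnegative integers")
  a <- x[1]; b <- x[2]; c <- x[3]; d <- x[4]
  m <- a + b; n <- c + d; k <- a + c
  if (m == 0 || n == 0 || k == 0 || (b + d) == 0) {
    warning("degenerate margin; p = 1 by convention")
    return(list(p = 1, p_doubled = 1, odds_ratio = NA_real_))
  }
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  p_mass <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  lower <- sum(probs[support <= a])
  upper <- sum(probs[support >= a])
  p_doubled <- min(1, 2 * min(lower, upper))
  or <- (a * d) / (b * c)
  list(p = min(1, p_mass), p_doubled = p_doubled, odds_ratio = or)
}

#' Prevalence of clonal hematopoiesis by age bin
#'
#' A patient is CH-positive when they carry at least one qualifying somatic
#' alteration (a point mutation passing the bulk filter, or a clonal
#' cytogenetic / copy-number event). Returns the per-bin proportion of
#' CH-positive patients; empty bins are reported with `NA` proportion.
#'
#' @param records Data frame with one row per patient: `id`, `age_years`,
#'   `ch_positive` (logical).
#' @param breaks Age bin boundaries passed to [cut()] (right-closed).
#' @return Data frame: `bin`, `n`, `n_ch`, `proportion`.
#' @export
prevalence_by_age <- function(records, breaks) {
  bin <- cut(records$age_years, breaks = breaks, include.lowest = TRUE)
  n <- tapply(records$ch_positive, bin, length)
  n_ch <- tapply(records$ch_positive, bin, sum)
  n[is.na(n)] <- 0L
  data.frame(bin = levels(bin), n = as.integer(n),
             n_ch = as.integer(n_ch),
             proportion = ifelse(n > 0, n_ch / n, NA_real_),
             stringsAsFactors = FALSE)
}

#' Classify the mechanism of biallelic TP53-locus alteration
#'
#' Given a patient's TP53 mutation calls (with CCF posteriors when two or
#' more mutations are present) and the copy-number class of the segment
#' containing the locus, returns one of `mutation+CN_LOH`,
#' `mutation+deletion`, `two_mutations`, or `monoallelic`. Two mutations are
#' taken to lie in the same clone — biallelic by point mutation — when both
#' CCF central intervals cover 1 (the single-cell criterion when matrix data
#' are absent).
#'
#' @param n_mutations Number of distinct TP53 mutations.
#' @param cn_class Copy-number class of the TP53 segment (`"balanced"`,
#'   `"deletion"`, `"cn_loh"`, `"gain"`, `"indeterminate"`).
#' @param ccf_intervals List of CCF central intervals (length-2 vectors), one
#'   per mutation; required when `n_mutations >= 2`.
#' @return Character scalar mechanism.
#' @export
classify_biallelic_mechanism <- function(n_mutations, cn_class,
                                         ccf_intervals = NULL) {
  stop_if_not(n_mutations >= 1, "patient must have at least one TP53 mutation")
  stop_if_not(length(cn_class) == 1L,
              "conflicting copy-number classes for the TP53 segment")
  if (cn_class == "cn_loh") return("mutation+CN_LOH")
  if (cn_class == "deletion") return("mutation+deletion")
  if (n_mutations >= 2) {
    stop_if_not(!is.null(ccf_intervals) && length(ccf_intervals) >= 2,
                "CCF intervals required for multiple mutations")
    clonal <- vapply(ccf_intervals, function(ci) ci[1] <= 1 && ci[2] >= 1,
                     logical(1))
    if (sum(clonal) >= 2) return("two_mutations")
  }
  "monoallelic"
}

#' Cohort mutation-burden summary
#'
#' Per-gene patient counts and fractions, per-patient mutation counts, and
#' per-gene VAF summaries over a table of filtered somatic calls.
#'
#' @param mutations Data frame with one row per mutation: `patient`, `gene`,
#'   `vaf`.
#' @param n_patients Total patients in the cohort (denominator for
#'   fractions); defaults to the number of distinct patients in `mutations`.
#' @return List with `per_gene` (gene, n_patients, fraction, median_vaf,
#'   min_vaf, max_vaf), `per_patient` (patient, n_mutations),
#'   `fraction_mutated` (patients with >= 1 mutation / n_patients).
#' @export
mutation_burden_summary <- function(mutations,
                                    n_patients = length(unique(mutations$patient))) {
  if (!nrow(mutations)) {
    return(list(per_gene = data.frame(), per_patient = data.frame(),
                fraction_mutated = if (n_patients > 0) 0 else NA_real_))
  }
  genes <- sort(unique(mutations$gene))
  per_gene <- do.call(rbind, lapply(genes, function(g) {
    x <- mutations[mutations$gene == g, , drop = FALSE]
    data.frame(gene = g, n_patients = length(unique(x$patient)),
               fraction = length(unique(x$patient)) / n_patients,
               n_mutations = nrow(x),
               median_vaf = stats::median(x$vaf),
               min_vaf = min(x$vaf), max_vaf = max(x$vaf),
               stringsAsFactors = FALSE)
  }))
  per_patient <- as.data.frame(table(patient = mutations$patient),
                               stringsAsFactors = FALSE)
  names(per_patient)[2] <- "n_mutations"
  list(per_gene = per_gene, per_patient = per_patient,
       fraction_mutated = length(unique(mutations$patient)) / n_patients)
}
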
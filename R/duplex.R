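#' Collapse duplex strand families to per-site consensus counts
#'
#' A sequenced molecule contributes one double-strand consensus read only when
#' both of its strand families (top-strand "ab" and bottom-strand "ba") are
#' present; families whose consensus contains more than `max_n_fraction` N
#' bases are discarded first. Molecules whose two families disagree on the
#' allele are dropped. The result is a per-site table of duplex depth and
#' duplex alternate counts.
#'
#' @param families Data frame with columns `molecule_id`, `locus`,
#'   `orientation` ("ab" or "ba"), `allele` ("ref" or "alt"), `n_reads`,
#'   `n_fraction`.
#' @param max_n_fraction Maximum tolerated fraction of N bases in a family
#'   consensus (default 0.05).
#' @return Data frame with one row per locus: `locus`, `duplex_depth`,
#'   `duplex_alt`.
#' @export
collapse_families <- function(families, max_n_fraction = 0.05) {
  req <- c("molecule_id", "locus", "orientation", "allele", "n_reads", "n_fraction")
  stop_if_not(all(req %in% names(families)),
              "families must have columns: %s", paste(req, collapse = ", "))
  bad_orient <- !(families$orientation %in% c("ab", "ba"))
  if (any(bad_orient)) {
    warning(sprintf("%d family records without a valid orientation label dropped",
                    sum(bad_orient)))
    families <- families[!bad_orient, , drop = FALSE]
  }
  stop_if_not(all(families$n_fraction >= 0 & families$n_fraction <= 1),
              "n_fraction must be in [0, 1]")
  stop_if_not(all(families$n_reads >= 1), "n_reads must be >= 1")
  families <- families[families$n_fraction <= max_n_fraction, , drop = FALSE]

  out <- data.frame(locus = character(), duplex_depth = integer(),
                    duplex_alt = integer(), stringsAsFactors = FALSE)
  if (!nrow(families)) return(out)
  key <- paste(families$locus, families$molecule_id, sep = "\r")
  has_ab <- tapply(families$orientation == "ab", key, any)
  has_ba <- tapply(families$orientation == "ba", key, any)
  n_alleles <- tapply(families$allele, key, function(a) length(unique(a)))
  complete <- has_ab & has_ba & n_alleles == 1L
  if (!any(complete)) return(out)
  allele <- tapply(families$allele, key, `[`, 1L)[complete]
  locus <- vapply(strsplit(names(allele), "\r", fixed = TRUE), `[`, character(1), 1L)
  depth <- as.vector(table(locus))
  alt <- as.vector(tapply(allele == "alt", locus, sum))
  data.frame(locus = sort(unique(locus)), duplex_depth = depth,
             duplex_alt = as.integer(alt), stringsAsFactors = FALSE)
}

#' Default thresholds for the bulk somatic variant filter chain
#'
#' The minimum alternate duplex reads (3) and minimum VAF (0.1%) are the
#' platform's stated detection design; the remaining cutoffs operationalize
#' qualitative exclusion rules (strand bias, regional call density, recurrent
#' low-VAF homopolymer indels, germline subtraction against the fibroblast
#' comparator) and are exposed here for adjustment.
#'
#' @param min_alt Minimum total duplex alternate reads.
#' @param min_vaf Minimum variant allele fraction.
#' @param strand_bias_p Two-sided binomial-test p-value below which the
#'   alternate-read strand split is called biased.
#' @param density_window Window (bp) for the regional call-density rule.
#' @param density_max Maximum candidate calls tolerated within the window.
#' @param homopolymer_vaf VAF below which an indel adjacent to a homopolymer
#'   run is excluded.
#' @param germline_af Comparator alternate fraction at or above which a site
#'   is considered germline.
#' @return Named list of thresholds.
#' @export
filter_config <- function(min_alt = 3L, min_vaf = 0.001, strand_bias_p = 1e-3,
                          density_window = 50L, density_max = 3L,
                          homopolymer_vaf = 0.01, germline_af = 0.20) {
  list(min_alt = min_alt, min_vaf = min_vaf, strand_bias_p = strand_bias_p,
       density_window = density_window, density_max = density_max,
       homopolymer_vaf = homopolymer_vaf, germline_af = germline_af)
}

# two-sided binomial strand-bias test of the alt fwd/rev split against the
# site's overall depth split; vectorized over calls
.strand_bias_p <- function(alt_fwd, alt_rev, depth_fwd, depth_rev) {
  n <- alt_fwd + alt_rev
  p0 <- ifelse(depth_fwd + depth_rev > 0,
               depth_fwd / (depth_fwd + depth_rev), 0.5)
  vapply(seq_along(n), function(i) {
    if (n[i] == 0) return(1)
    stats::binom.test(alt_fwd[i], n[i], p0[i])$p.value
  }, numeric(1))
}

#' Apply the bulk somatic variant filter chain
#'
#' Labels each candidate call pass/fail, recording the first failing rule.
#' Rules are applied in a fixed order: on-target, minimum alternate duplex
#' reads, minimum VAF, strand bias, regional call density, synonymous
#' consequence, recurrent low-VAF homopolymer-adjacent indel, and germline
#' presence in the matched comparator. Sites without comparator counts are
#' labeled `unclassified`, never silently passed.
#'
#' @param calls Data frame with columns `locus`, `chrom`, `pos`, `ref_count`,
#'   `alt_count`, `depth_fwd`, `depth_rev`, `alt_fwd`, `alt_rev`, `in_target`,
#'   `consequence`, `is_indel`, `homopolymer_adjacent` (one sample; run per
#'   sample for serial data).
#' @param comparator Data frame with `locus`, `ref_count`, `alt_count` from
#'   the germline reference tissue.
#' @param config Thresholds from [filter_config()].
#' @return `calls` with added columns `vaf`, `status` ("pass", "fail",
#'   "unclassified") and `reason` (first failing rule, or `NA`).
#' @export
filter_variants <- function(calls, comparator, config = filter_config()) {
  stop_if_not(all(calls$alt_count <= calls$alt_count + calls$ref_count),
              "negative ref counts")
  depth <- calls$ref_count + calls$alt_count
  calls$vaf <- ifelse(depth > 0, calls$alt_count / depth, 0)
  reason <- rep(NA_character_, nrow(calls))
  fail <- function(cond, code) {
    hit <- is.na(reason) & cond
    reason[hit] <<- code
  }
  fail(!calls$in_target, "off_target")
  fail(calls$alt_count < config$min_alt, "min_alt")
  fail(calls$vaf < config$min_vaf, "min_vaf")

  todo <- is.na(reason)
  if (any(todo)) {
    sb <- rep(1, nrow(calls))
    sb[todo] <- .strand_bias_p(calls$alt_fwd[todo], calls$alt_rev[todo],
                               calls$depth_fwd[todo], calls$depth_rev[todo])
    fail(sb < config$strand_bias_p, "strand_bias")
  }

  # regional density: among candidates surviving the preceding rules, more
  # than density_max calls within density_window bp fails all of them
  todo <- which(is.na(reason))
  if (length(todo) > 1) {
    dense <- vapply(todo, function(i) {
      sum(calls$chrom[todo] == calls$chrom[i] &
            abs(calls$pos[todo] - calls$pos[i]) <= config$density_window)
    }, numeric(1))
    fail(seq_len(nrow(calls)) %in% todo[dense > config$density_max],
         "regional_density")
  }

  fail(calls$consequence == "synonymous", "synonymous")
  fail(calls$is_indel & calls$homopolymer_adjacent &
         calls$vaf < config$homopolymer_vaf, "homopolymer_indel")

  m <- match(calls$locus, comparator$locus)
  comp_depth <- comparator$ref_count[m] + comparator$alt_count[m]
  comp_af <- comparator$alt_count[m] / pmax(comp_depth, 1L)
  no_comp <- is.na(m) | is.na(comp_depth) | comp_depth == 0
  fail(!no_comp & comp_af >= config$germline_af, "germline")

  calls$status <- ifelse(!is.na(reason), "fail",
                         ifelse(no_comp, "unclassified", "pass"))
  calls$reason <- reason
  calls
}
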
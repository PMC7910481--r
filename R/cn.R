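#' Compute per-target total copy ratios against a panel of normals
#'
#' Each target's fraction of the sample's total template count is divided by
#' the panel's median per-target fraction. Targets that behave badly in the
#' panel itself — mean within-panel ratio outside `mean_range`, or
#' coefficient of variation above `max_cv` — are blacklisted, as are targets
#' absent from the panel.
#'
#' @param sample_counts Data frame with `target_id`, `chrom`, `start`, `end`,
#'   `count`.
#' @param panel Numeric matrix of counts, targets x normal samples, with
#'   target ids as row names; at least 3 samples.
#' @param mean_range Acceptable range for the panel mean ratio.
#' @param max_cv Maximum coefficient of variation of panel ratios.
#' @param center If `"median"` (default), the profile is re-centered so the
#'   median usable target has tCR 1, the usual guard against aberrant
#'   segments shifting the sample's total count (assumes most targets
#'   diploid); `"none"` disables it.
#' @return `sample_counts` with columns `tcr`, `log2_tcr`, `blacklisted`,
#'   `blacklist_reason` added; blacklisted targets carry `NA` ratios.
#' @export
compute_tcr <- function(sample_counts, panel, mean_range = c(0.25, 4),
                        max_cv = 0.30, center = c("median", "none")) {
  center <- match.arg(center)
  stop_if_not(ncol(panel) >= 3, "panel of normals needs >= 3 samples")
  stop_if_not(all(sample_counts$count >= 0), "counts must be nonnegative")
  m <- match(sample_counts$target_id, rownames(panel))
  reason <- rep(NA_character_, nrow(sample_counts))
  reason[is.na(m)] <- "absent_from_panel"

  panel_frac <- sweep(panel, 2, colSums(panel), "/")
  ref_frac <- apply(panel_frac, 1, stats::median)
  # within-panel behaviour of each target relative to the panel reference
  panel_ratio <- sweep(panel_frac, 1, pmax(ref_frac, .Machine$double.eps), "/")
  panel_mean <- rowMeans(panel_ratio)
  panel_cv <- apply(panel_ratio, 1, stats::sd) / pmax(panel_mean, .Machine$double.eps)

  ok <- !is.na(m)
  pm <- panel_mean[m[ok]]; pcv <- panel_cv[m[ok]]
  bad_mean <- pm < mean_range[1] | pm > mean_range[2]
  bad_cv <- pcv > max_cv
  reason[ok][is.na(reason[ok]) & bad_mean] <- "panel_mean"
  reason[ok][is.na(reason[ok]) & bad_cv] <- "panel_cv"

  samp_frac <- sample_counts$count / sum(sample_counts$count)
  tcr <- rep(NA_real_, nrow(sample_counts))
  use <- is.na(reason)
  tcr[use] <- samp_frac[use] / ref_frac[m[use]]
  if (center == "median" && any(use)) {
    tcr <- tcr / stats::median(tcr[use])
  }
  sample_counts$tcr <- tcr
  sample_counts$log2_tcr <- log2(pmax(tcr, .Machine$double.eps))
  sample_counts$blacklisted <- !is.na(reason)
  sample_counts$blacklist_reason <- reason
  sample_counts
}

# best binary split of x[lo:hi]: returns c(stat, split_index) where stat is
# the maximum two-sample t-like statistic over candidate breakpoints
.best_split <- function(x, min_width) {
  n <- length(x)
  if (n < 2 * min_width) return(c(0, NA))
  cs <- cumsum(x); css <- cumsum(x^2); tot <- cs[n]
  k <- min_width:(n - min_width)
  mu1 <- cs[k] / k
  mu2 <- (tot - cs[k]) / (n - k)
  ss <- css[n] - cs[n]^2 / n
  pooled <- pmax(ss / n, 1e-12)
  stat <- (mu1 - mu2)^2 * (k * (n - k) / n) / pooled
  i <- which.max(stat)
  c(stat[i], k[i])
}

# multi-sample split statistic: sum of per-sample statistics at each k
.best_split_joint <- function(xs, min_width) {
  n <- length(xs[[1]])
  if (n < 2 * min_width) return(c(0, NA))
  k <- min_width:(n - min_width)
  total <- rep(0, length(k))
  for (x in xs) {
    cs <- cumsum(x); css <- cumsum(x^2); tot <- cs[n]
    mu1 <- cs[k] / k
    mu2 <- (tot - cs[k]) / (n - k)
    ss <- css[n] - cs[n]^2 / n
    pooled <- pmax(ss / n, 1e-12)
    total <- total + (mu1 - mu2)^2 * (k * (n - k) / n) / pooled
  }
  i <- which.max(total)
  c(total[i], k[i])
}

#' Segment log2 total copy ratios by recursive binary splitting
#'
#' An adaptation of circular binary segmentation: within each current
#' segment the best mean-shift breakpoint is found, and accepted when its
#' statistic exceeds the `1 - alpha` quantile of the statistic under
#' within-segment permutations; accepted splits recurse. In joint mode the
#' per-sample split statistics are summed across samples of one patient at
#' each candidate breakpoint, so breakpoints shared across samples are
#' favored; accepted breakpoints are applied to all samples.
#'
#' @param tcr Data frame from [compute_tcr()] (blacklisted targets are
#'   skipped), or for joint mode a list of such data frames over the same
#'   targets.
#' @param alpha Permutation-test level to accept a split (default 0.01).
#' @param n_perm Number of permutations (default 100).
#' @param min_width Minimum targets per segment side (default 5).
#' @return Data frame of segments: `chrom`, `start`, `end`, `n_targets`,
#'   `mean_log2_tcr` (per sample columns in joint mode).
#' @export
segment_tcr <- function(tcr, alpha = 0.01, n_perm = 100L, min_width = 5L) {
  joint <- is.list(tcr) && !is.data.frame(tcr)
  samples <- if (joint) tcr else list(tcr)
  base <- samples[[1]]
  keep <- !base$blacklisted
  base <- base[keep, , drop = FALSE]
  base <- base[order(base$chrom, base$start), , drop = FALSE]
  xs_all <- lapply(samples, function(s) {
    s <- s[keep, , drop = FALSE]
    s[order(s$chrom, s$start), "log2_tcr"]
  })

  out <- list()
  for (ch in unique(base$chrom)) {
    sel <- which(base$chrom == ch)
    if (length(sel) < 10L) {
      warning(sprintf("chromosome %s has < 10 usable targets; single segment", ch))
      bounds <- c(1L, length(sel) + 1L)
    } else {
      xs <- lapply(xs_all, `[`, sel)
      bounds <- sort(unique(c(1L, .recurse_segments(xs, alpha, n_perm, min_width),
                              length(sel) + 1L)))
    }
    for (i in seq_len(length(bounds) - 1L)) {
      idx <- sel[bounds[i]:(bounds[i + 1L] - 1L)]
      row <- data.frame(chrom = ch, start = base$start[idx[1L]],
                        end = base$end[idx[length(idx)]],
                        n_targets = length(idx), stringsAsFactors = FALSE)
      for (si in seq_along(xs_all)) {
        nm <- if (length(xs_all) == 1L) "mean_log2_tcr" else
          sprintf("mean_log2_tcr_%d", si)
        row[[nm]] <- mean(xs_all[[si]][idx])
      }
      out[[length(out) + 1L]] <- row
    }
  }
  do.call(rbind, out)
}

# recursive splitting of a list of aligned tracks; returns interior breakpoints
# (1-based index of first element of the right part) relative to the track
.recurse_segments <- function(xs, alpha, n_perm, min_width) {
  n <- length(xs[[1]])
  split_fun <- if (length(xs) == 1L) {
    function(z) .best_split(z[[1]], min_width)
  } else {
    function(z) .best_split_joint(z, min_width)
  }
  obs <- split_fun(xs)
  if (is.na(obs[2])) return(integer())
  perm_stats <- vapply(seq_len(n_perm), function(b) {
    zp <- lapply(xs, function(x) x[sample.int(n)])
    split_fun(zp)[1]
  }, numeric(1))
  pval <- (1 + sum(perm_stats >= obs[1])) / (n_perm + 1)
  if (pval > alpha) return(integer())
  k <- as.integer(obs[2])
  left <- .recurse_segments(lapply(xs, `[`, seq_len(k)), alpha, n_perm, min_width)
  right <- .recurse_segments(lapply(xs, function(x) x[(k + 1):n]),
                             alpha, n_perm, min_width)
  c(left, k + 1L, k + right)
}

# maximize the folded-binomial likelihood of the segment imbalance parameter
# rho (major-haplotype allele fraction, in [0.5, 1)) on a grid
.fit_imbalance <- function(alt, depth, grid = seq(0.5, 0.995, by = 0.005)) {
  ll <- vapply(grid, function(r) {
    sum(log(0.5 * stats::dbinom(alt, depth, r) +
              0.5 * stats::dbinom(alt, depth, 1 - r)))
  }, numeric(1))
  i <- which.max(ll)
  list(rho = grid[i], loglik = ll[i], loglik_null = ll[1L])
}

# Viterbi path of the two-state haplotype-imbalance HMM: state 1 = haplotype A
# over-represented (alt fraction rho for A-alt SNPs), state 2 = B over-
# represented. Emissions are binomial; switch probability tau between
# adjacent SNPs.
.viterbi_hap <- function(alt, depth, rho, tau) {
  n <- length(alt)
  e1 <- stats::dbinom(alt, depth, rho, log = TRUE)
  e2 <- stats::dbinom(alt, depth, 1 - rho, log = TRUE)
  v <- matrix(-Inf, 2, n)
  ptr <- matrix(0L, 2, n)
  v[, 1] <- c(e1[1], e2[1]) + log(0.5)
  lt <- log(c(1 - tau, tau))
  for (i in 2:n) {
    for (s in 1:2) {
      cand <- v[, i - 1] + ifelse(1:2 == s, lt[1], lt[2])
      ptr[s, i] <- which.max(cand)
      v[s, i] <- max(cand) + (if (s == 1) e1[i] else e2[i])
    }
  }
  path <- integer(n)
  path[n] <- which.max(v[, n])
  for (i in (n - 1):1) path[i] <- ptr[path[i + 1], i + 1]
  c("A", "B")[path]
}

#' Phase SNPs within segments and classify allelic imbalance
#'
#' For each segment, the allelic imbalance parameter (major-haplotype allele
#' fraction) is estimated by maximum likelihood under a mirrored binomial
#' model, and significance is assessed by a likelihood-ratio test against
#' balance (0.5). A two-state hidden Markov model over the ordered SNPs —
#' state indicating which haplotype is over-represented, binomial emissions
#' at the fitted imbalance, small switch probability — is decoded by Viterbi
#' to give per-SNP haplotype labels and phased VAFs. Segments are classified
#' by combining imbalance with the mean log2 total copy ratio: significant
#' imbalance with log2 tCR below `-log2_tol` is a deletion, within
#' `c(-log2_tol, log2_tol)` copy-neutral LOH, above it a gain; otherwise
#' balanced. Segments with fewer than `min_snps` heterozygous SNPs are
#' `indeterminate`.
#'
#' @param segments Data frame from [segment_tcr()] with `chrom`, `start`,
#'   `end`, `mean_log2_tcr`.
#' @param snps Data frame with `chrom`, `pos`, `ref_count`, `alt_count`.
#' @param switch_prob HMM haplotype switch probability between adjacent SNPs.
#' @param alpha Level of the imbalance likelihood-ratio test (default 0.01).
#' @param log2_tol Half-width of the copy-neutral log2 tCR band (default 0.15).
#' @param min_snps Minimum SNPs to classify a segment (default 5).
#' @return List with `segments` (input plus `allelic_ratio`, `imbalance_p`,
#'   `class`) and `snps` (input plus `segment`, `hap`, `phased_vaf`).
#' @export
phase_and_classify <- function(segments, snps, switch_prob = 0.005,
                               alpha = 0.01, log2_tol = 0.15, min_snps = 5L) {
  segments$allelic_ratio <- NA_real_
  segments$imbalance_p <- NA_real_
  segments$class <- "indeterminate"
  snps$segment <- NA_integer_
  snps$hap <- NA_character_
  snps$phased_vaf <- NA_real_
  for (i in seq_len(nrow(segments))) {
    in_seg <- which(snps$chrom == segments$chrom[i] &
                      snps$pos >= segments$start[i] &
                      snps$pos <= segments$end[i])
    snps$segment[in_seg] <- i
    if (length(in_seg) < min_snps) next
    s <- snps[in_seg, , drop = FALSE]
    o <- order(s$pos)
    alt <- s$alt_count[o]
    depth <- s$alt_count[o] + s$ref_count[o]
    fit <- .fit_imbalance(alt, depth)
    lrt <- 2 * (fit$loglik - fit$loglik_null)
    pval <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
    segments$allelic_ratio[i] <- fit$rho
    segments$imbalance_p[i] <- pval
    lt <- segments$mean_log2_tcr[i]
    segments$class[i] <- if (pval >= alpha) {
      "balanced"
    } else if (lt < -log2_tol) {
      "deletion"
    } else if (lt > log2_tol) {
      "gain"
    } else {
      "cn_loh"
    }
    hap <- .viterbi_hap(alt, depth, max(fit$rho, 0.501), switch_prob)
    snps$hap[in_seg[o]] <- hap
    snps$phased_vaf[in_seg[o]] <- ifelse(hap == "A", alt / pmax(depth, 1L),
                                         1 - alt / pmax(depth, 1L))
  }
  list(segments = segments, snps = snps)
}

#' Cancer-cell-fraction posterior for a somatic mutation
#'
#' Given sample purity `p`, local total copy number `q` and mutation
#' multiplicity `m`, the expected alternate read fraction of a mutation
#' present in a fraction `c` of clonal cells is
#' `f(c) = p*m*c / (p*q + 2*(1-p))`. The posterior over a uniform grid of
#' `c` in `[0, 1]` is proportional to the binomial likelihood of the observed
#' alternate count under `f(c)`, with a uniform prior.
#'
#' @param alt,depth Observed alternate and total read counts.
#' @param purity Sample purity in (0, 1].
#' @param total_cn Local total copy number `q` (>= 1).
#' @param multiplicity Mutation copies `m`, `1 <= m <= q`.
#' @param grid_size Number of grid points (default 101).
#' @param conf Central interval mass (default 0.95).
#' @return A `ccf_posterior` list: `grid`, `prob` (sums to 1), `mode`,
#'   `interval` (central credible interval).
#' @export
compute_ccf <- function(alt, depth, purity, total_cn = 2L, multiplicity = 1L,
                        grid_size = 101L, conf = 0.95) {
  stop_if_not(purity > 0 && purity <= 1, "purity must be in (0, 1]")
  stop_if_not(total_cn >= 1, "total copy number must be >= 1")
  stop_if_not(multiplicity >= 1 && multiplicity <= total_cn,
              "multiplicity must be in [1, total_cn]")
  stop_if_not(alt <= depth, "alt exceeds depth")
  grid <- seq(0, 1, length.out = grid_size)
  f <- purity * multiplicity * grid / (purity * total_cn + 2 * (1 - purity))
  stop_if_not(all(f <= 1 + 1e-12),
              "expected alt fraction exceeds 1; purity/copy-number inconsistent")
  f <- pmin(f, 1)
  ll <- stats::dbinom(alt, depth, f, log = TRUE)
  prob <- exp(ll - max(ll))
  prob <- prob / sum(prob)
  cum <- cumsum(prob)
  lo <- grid[which(cum >= (1 - conf) / 2)[1L]]
  hi <- grid[which(cum >= 1 - (1 - conf) / 2)[1L]]
  structure(list(grid = grid, prob = prob, mode = grid[which.max(prob)],
                 interval = c(lo, hi)),
            class = "ccf_posterior")
}
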
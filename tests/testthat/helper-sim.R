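# Shared fixture builders for the test suite. Everything is generated in code
# under fixed seeds; no external data.

# long cells table from explicit per-cell genotype specs:
# spec = list(list(n = 90, gt = c(SNP1 = "het", ...)), ...)
# depth chosen high so calls are unambiguous
cells_from_genotypes <- function(spec, depth = 100L) {
  rows <- list()
  cell <- 0L
  alt_for <- c(wt = 0, het = 0.5, hom = 1)
  for (grp in spec) {
    for (i in seq_len(grp$n)) {
      cell <- cell + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        cell_id = sprintf("c%05d", cell),
        locus = names(grp$gt),
        depth = depth,
        alt = as.integer(round(depth * alt_for[unname(grp$gt)])),
        stringsAsFactors = FALSE)
    }
  }
  call_genotypes(do.call(rbind, rows))
}
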
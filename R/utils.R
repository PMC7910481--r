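#' @keywords internal
"_PACKAGE"

# Run code under a fixed RNG seed, restoring the caller's RNG state afterwards.
# All simulators route their randomness through this so a fixed config seed
# gives byte-identical output regardless of surrounding RNG use.
local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

stop_if_not <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

#' Write a plain tab-separated table
#'
#' Thin wrapper around [utils::write.table()] with the conventions used for all
#' pipeline tables (tab-separated, header, no quoting, no row names).
#'
#' @param x A data frame.
#' @param path Output file path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a plain tab-separated table
#'
#' @param path Input file path.
#' @return A data frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}
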
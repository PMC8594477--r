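#' @importFrom rlang abort warn inform .data :=
#' @importFrom dplyr %>%
NULL

# Counts dropped records once, to stderr, so pipeline logs show every filter.
log_count <- function(n, what) {
  if (n > 0) rlang::inform(sprintf("utrdiff: dropped %d %s", n, what))
  invisible(n)
}

# Chromosome ordering used for all sorted output: numeric chromosomes in
# numeric order, then X, Y, MT, then anything else alphabetically.
chrom_rank <- function(chrom) {
  num <- suppressWarnings(as.numeric(chrom))
  special <- match(chrom, c("X", "Y", "MT"))
  rank <- ifelse(!is.na(num), num,
    ifelse(!is.na(special), 1e6 + special, NA_real_)
  )
  other <- is.na(rank)
  if (any(other)) {
    rank[other] <- 2e6 + match(chrom[other], sort(unique(chrom[other])))
  }
  rank
}

is_allowed_chrom <- function(target) {
  grepl("^([0-9]+|X|Y|MT)$", target)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
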
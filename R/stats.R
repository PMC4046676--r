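# Length statistics and evaluation against simulator truth.

#' Assembly contiguity statistics
#'
#' N50 is the length of the smallest element in the minimal prefix of the
#' descending-sorted lengths whose sum reaches 50% of the total; N90
#' analogously at 90%.
#'
#' @param lengths positive integer lengths.
#' @return list with `total`, `mean`, `n50`, `n90`.
#' @export
#' @examples
#' compute_length_stats(c(5, 4, 3, 2, 1))  # N50 = 4, N90 = 2
compute_length_stats <- function(lengths) {
  if (length(lengths) == 0) stop("`lengths` must be non-empty")
  if (any(lengths <= 0)) stop("`lengths` must be positive")
  s <- sort(as.numeric(lengths), decreasing = TRUE)
  cum <- cumsum(s)
  total <- cum[length(cum)]
  list(total = total,
       mean = total / length(s),
       n50 = as.integer(s[which(cum >= 0.5 * total)[1]]),
       n90 = as.integer(s[which(cum >= 0.9 * total)[1]]))
}

#' Evaluate pseudo-Sanger reads against simulator truth
#'
#' Each pseudo-Sanger read is globally aligned (unit costs, banded) to the
#' true fragment of its source anchor pair, looked up through the truth
#' records; errors are mismatch plus indel columns over the aligned reads.
#' The simulation is diploid and the consensus keeps the majority allele at
#' heterozygous sites, so a mismatch column is only charged when the read
#' base matches neither haplotype's allele at that position. The residual
#' profile bins error positions by relative read position.
#'
#' @param ps data frame of pseudo-Sanger reads as returned in
#'   `run_pipeline()$ps` (needs `seq`, `ar_pair`, `ar_lib`), or a `ps_run`.
#' @param dataset the `ps_dataset` the pipeline consumed.
#' @param bins number of relative-position bins for the error profile.
#' @param band extra band width for the global alignment.
#' @return list with `error_rate_pct` (errors per 100 PS bases),
#'   `n_errors`, `total_bases`, `n_reads`, `n_unaligned`, `profile` (data
#'   frame `bin`, `errors`, `bases`, `rate`), `length_stats`.
#' @export
evaluate_against_truth <- function(ps, dataset, bins = 20L, band = 30L) {
  if (inherits(ps, "ps_run")) ps <- ps$ps
  stopifnot(inherits(dataset, "ps_dataset"))
  if (nrow(ps) == 0) stop("no pseudo-Sanger reads to evaluate")
  truth <- do.call(rbind, lapply(dataset$libraries, `[[`, "truth"))
  row <- match(ps$ar_pair, truth$pair_id)
  if (anyNA(row))
    stop("no truth record for anchor pair(s): ",
         paste(utils::head(ps$ar_pair[is.na(row)], 3), collapse = ", "))
  tr <- truth[row, ]
  ref <- dataset$reference
  frag_a <- substring(ref$hap_a, tr$start + 1L, tr$end)
  frag_b <- substring(ref$hap_b, tr$start + 1L, tr$end)
  own <- ifelse(tr$haplotype == "a", frag_a, frag_b)
  other <- ifelse(tr$haplotype == "a", frag_b, frag_a)
  rev <- tr$strand == "-"
  own[rev] <- revcomp_dna(own[rev])
  other[rev] <- revcomp_dna(other[rev])
  n_err <- 0
  total <- 0
  unaligned <- 0
  bin_err <- numeric(bins)
  bin_bases <- numeric(bins)
  for (i in seq_len(nrow(ps))) {
    a <- cpp_align_truth(ps$seq[i], own[i], other[i], as.integer(band))
    len <- nchar(ps$seq[i])
    if (!a$ok) { unaligned <- unaligned + 1; next }
    total <- total + len
    n_err <- n_err + a$errors
    # bases per bin for this read
    b <- tabulate(pmin(floor((seq_len(len) - 1L) * bins / len), bins - 1L) + 1L,
                  nbins = bins)
    bin_bases <- bin_bases + b
    if (length(a$err_pos))
      bin_err <- bin_err + tabulate(
        pmin(floor(a$err_pos * bins / len), bins - 1L) + 1L, nbins = bins)
  }
  if (total == 0) stop("no pseudo-Sanger read could be aligned to its truth")
  list(error_rate_pct = 100 * n_err / total,
       n_errors = n_err, total_bases = total,
       n_reads = nrow(ps), n_unaligned = unaligned,
       profile = data.frame(bin = seq_len(bins), errors = bin_err,
                            bases = bin_bases,
                            rate = ifelse(bin_bases > 0, bin_err / bin_bases, 0)),
       length_stats = compute_length_stats(nchar(ps$seq)))
}
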
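# Diploid read simulator: a modified-wgsim-style generator producing a
# two-haplotype reference, nested paired-end libraries with uniform
# substitution errors, and per-pair truth records for evaluation.

seed_mix <- function(seed, k) {
  # per-library stream derived from one master seed; kept below 2^31
  (as.integer(seed) %% 100000L) * 20011L + as.integer(k) * 7919L
}

#' Simulate a diploid reference
#'
#' Draws haplotype A i.i.d. over `ACGT` at the given base composition, then
#' copies it into haplotype B, mutating each site independently to a
#' different base with probability `het_rate`. The exact variant list is
#' returned so evaluation never needs mapping.
#'
#' @param length genome length in bp (positive integer).
#' @param het_rate per-site heterozygosity, in `[0, 1)`.
#' @param seed optional integer seed; when given, the RNG state is scoped to
#'   this call.
#' @param base_composition probabilities for A, C, G, T.
#' @return an object of class `ps_diploid` with elements `hap_a`, `hap_b`
#'   (character strings of equal length), `length`, `het_rate`, `variants`
#'   (data frame with 0-based `position`, `allele_a`, `allele_b`), and
#'   `repeats` (data frame of seeded repeat intervals, empty by default).
#' @export
#' @examples
#' ref <- make_diploid_reference(1000, het_rate = 0.01, seed = 1)
#' nrow(ref$variants)
make_diploid_reference <- function(length, het_rate, seed = NULL,
                                   base_composition = rep(0.25, 4)) {
  if (length(length) != 1L || is.na(length) || length <= 0)
    stop("`length` must be a positive integer")
  if (het_rate < 0 || het_rate >= 1)
    stop("`het_rate` must be in [0, 1)")
  if (length(base_composition) != 4L || any(base_composition < 0))
    stop("`base_composition` must be four non-negative weights")
  if (!is.null(seed)) withr::local_seed(seed)
  length <- as.integer(length)
  vec_a <- sample(BASES, length, replace = TRUE, prob = base_composition)
  idx <- which(runif(length) < het_rate)
  vec_b <- vec_a
  if (length(idx) > 0) {
    # mutate to one of the three other bases, uniformly
    shift <- sample.int(3L, length(idx), replace = TRUE)
    code <- match(vec_a[idx], BASES)
    vec_b[idx] <- BASES[((code - 1L + shift) %% 4L) + 1L]
  }
  structure(list(
    hap_a = paste(vec_a, collapse = ""),
    hap_b = paste(vec_b, collapse = ""),
    length = length,
    het_rate = het_rate,
    variants = data.frame(position = idx - 1L,
                          allele_a = vec_a[idx], allele_b = vec_b[idx],
                          stringsAsFactors = FALSE),
    repeats = data.frame(start = integer(0), end = integer(0),
                         role = character(0), stringsAsFactors = FALSE)
  ), class = "ps_diploid")
}

#' Seed interspersed repeats into a diploid reference
#'
#' Copies one randomly chosen subsequence of `unit_length` bp to `copies`
#' random non-overlapping positions, identically on both haplotypes, to
#' emulate a more repetitive genome. Copies also avoid the source interval,
#' so all occurrences are mutually identical and disjoint. Variant and
#' repeat annotations are recomputed after pasting.
#'
#' @param reference a `ps_diploid`.
#' @param unit_length repeat unit length in bp.
#' @param copies number of copies to place (0 returns the input unchanged).
#' @param seed optional integer seed.
#' @param max_tries placement attempts per copy before giving up.
#' @return a `ps_diploid` whose `repeats` element lists the source interval
#'   and every placed copy (0-based half-open coordinates).
#' @export
seed_repeats <- function(reference, unit_length, copies, seed = NULL,
                         max_tries = 1000L) {
  stopifnot(inherits(reference, "ps_diploid"))
  if (copies == 0) return(reference)
  if (unit_length <= 0 || unit_length > reference$length)
    stop("`unit_length` must be in [1, genome length]")
  if (unit_length * copies >= reference$length)
    stop("total repeat length must be smaller than the genome")
  if (!is.null(seed)) withr::local_seed(seed)
  len <- reference$length
  src <- sample.int(len - unit_length + 1L, 1L) - 1L  # 0-based
  intervals <- matrix(c(src, src + unit_length), ncol = 2L)
  placed <- integer(0)
  for (k in seq_len(copies)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      s <- sample.int(len - unit_length + 1L, 1L) - 1L
      e <- s + unit_length
      if (all(e <= intervals[, 1] | s >= intervals[, 2])) {
        intervals <- rbind(intervals, c(s, e))
        placed <- c(placed, s)
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("could not place repeat copy ", k,
                  " without overlap after ", max_tries, " tries")
  }
  vec_a <- strsplit(reference$hap_a, "", fixed = TRUE)[[1]]
  vec_b <- strsplit(reference$hap_b, "", fixed = TRUE)[[1]]
  unit <- vec_a[(src + 1L):(src + unit_length)]
  for (s in placed) {
    vec_a[(s + 1L):(s + unit_length)] <- unit
    vec_b[(s + 1L):(s + unit_length)] <- unit
  }
  # pasting on both haplotypes erases variants inside the windows
  idx <- which(vec_a != vec_b)
  structure(list(
    hap_a = paste(vec_a, collapse = ""),
    hap_b = paste(vec_b, collapse = ""),
    length = len,
    het_rate = reference$het_rate,
    variants = data.frame(position = idx - 1L,
                          allele_a = vec_a[idx], allele_b = vec_b[idx],
                          stringsAsFactors = FALSE),
    repeats = data.frame(start = c(src, sort(placed)),
                         end = c(src, sort(placed)) + unit_length,
                         role = c("source", rep("copy", copies)),
                         stringsAsFactors = FALSE)
  ), class = "ps_diploid")
}

#' Describe one paired-end library
#'
#' @param insert_mean mean insert (fragment) size in bp.
#' @param depth fold-coverage contributed by the library.
#' @param read_length read length in bp.
#' @param error_rate per-base substitution probability.
#' @param insert_sd insert-size standard deviation; defaults to 10% of the
#'   mean, the spread a tight gel-based size selection typically achieves.
#' @param name library label used in read ids.
#' @return a `ps_libspec`.
#' @export
library_spec <- function(insert_mean, depth, read_length = 100L,
                         error_rate = 0.005, insert_sd = 0.1 * insert_mean,
                         name = paste0("ins", insert_mean)) {
  if (insert_mean <= read_length)
    stop("`insert_mean` must exceed `read_length`")
  if (error_rate < 0 || error_rate >= 1) stop("`error_rate` must be in [0, 1)")
  if (depth <= 0) stop("`depth` must be positive")
  if (insert_sd < 0) stop("`insert_sd` must be non-negative")
  structure(list(insert_mean = insert_mean, insert_sd = insert_sd,
                 depth = depth, read_length = as.integer(read_length),
                 error_rate = error_rate, name = name),
            class = "ps_libspec")
}

#' Simulate one paired-end library from a diploid reference
#'
#' Fragment starts are uniform, the haplotype and sequencing strand are
#' chosen uniformly, and insert lengths are Normal(mean, sd) rounded and
#' truncated to `[read_length + 1, genome length]`. Read 1 is the fragment's
#' 5' end on the sampled strand and read 2 the reverse complement of its 3'
#' end (FR orientation). Each base is substituted independently with
#' probability `error_rate`, never to itself; no coverage bias, chimeras, or
#' indel errors are simulated.
#'
#' @param reference a `ps_diploid`.
#' @param spec a `ps_libspec`.
#' @param seed optional integer seed.
#' @return a `ps_library`: `spec`, `pairs` (data frame `pair_id`, `seq1`,
#'   `seq2`), and `truth` (data frame `pair_id`, `haplotype`, `start`, `end`
#'   0-based half-open, `strand` of read 1, `err_r1`, `err_r2` as
#'   comma-separated 0-based read offsets).
#' @export
generate_library <- function(reference, spec, seed = NULL) {
  stopifnot(inherits(reference, "ps_diploid"), inherits(spec, "ps_libspec"))
  if (reference$length < spec$insert_mean)
    stop("reference is shorter than the library's mean insert")
  if (!is.null(seed)) withr::local_seed(seed)
  len <- reference$length
  rl <- spec$read_length
  n <- as.integer(round(len * spec$depth / (2 * rl)))
  if (n < 1L) stop("depth too low: no pairs to simulate")
  insert <- as.integer(round(rnorm(n, spec$insert_mean, spec$insert_sd)))
  insert <- pmin(pmax(insert, rl + 1L), len)
  start <- as.integer(floor(runif(n) * (len - insert + 1)))  # 0-based
  hap <- sample(c("a", "b"), n, replace = TRUE)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  frag <- ifelse(hap == "a",
                 substring(reference$hap_a, start + 1L, start + insert),
                 substring(reference$hap_b, start + 1L, start + insert))
  rev <- strand == "-"
  frag[rev] <- revcomp_dna(frag[rev])
  r1 <- substring(frag, 1L, rl)
  r2 <- revcomp_dna(substring(frag, insert - rl + 1L, insert))
  err <- cpp_inject_errors(c(r1, r2), spec$error_rate)
  reads <- err$reads
  pos <- err$positions
  join <- function(p) vapply(p, function(v) paste(v, collapse = ","), "")
  pair_id <- sprintf("%s_%06d", spec$name, seq_len(n))
  structure(list(
    spec = spec,
    pairs = data.frame(pair_id = pair_id,
                       seq1 = reads[seq_len(n)], seq2 = reads[n + seq_len(n)],
                       stringsAsFactors = FALSE),
    truth = data.frame(pair_id = pair_id, haplotype = hap,
                       start = start, end = start + insert, strand = strand,
                       err_r1 = join(pos[seq_len(n)]),
                       err_r2 = join(pos[n + seq_len(n)]),
                       stringsAsFactors = FALSE)
  ), class = "ps_library")
}

#' Simulate the full nested-library study design
#'
#' Convenience wrapper generating a diploid reference and one library per
#' insert size. Defaults reproduce the study conditions used throughout the
#' package: four libraries with insert means 200/300/400/600 bp at 15x each,
#' 100 bp reads, substitution error 0.005, heterozygosity 0.001.
#'
#' @param genome_length genome length in bp.
#' @param het_rate per-site heterozygosity.
#' @param error_rate per-base substitution probability.
#' @param insert_means insert means, any order; stored largest first.
#' @param depths fold-coverage per library (recycled).
#' @param read_length read length in bp.
#' @param insert_sd_frac insert sd as a fraction of the mean.
#' @param seed master seed; per-library streams are derived from it.
#' @param repeats optional `list(unit_length =, copies =)` of interspersed
#'   repeats to seed before read generation.
#' @return a `ps_dataset`: `reference`, `libraries` (largest insert first),
#'   `seed`.
#' @export
simulate_ps_dataset <- function(genome_length = 1e5, het_rate = 0.001,
                                error_rate = 0.005,
                                insert_means = c(200, 300, 400, 600),
                                depths = 15, read_length = 100L,
                                insert_sd_frac = 0.1, seed = 1L,
                                repeats = NULL) {
  ord <- order(insert_means, decreasing = TRUE)
  insert_means <- insert_means[ord]
  depths <- rep_len(depths, length(insert_means))[ord]
  ref <- make_diploid_reference(genome_length, het_rate, seed = seed_mix(seed, 0L))
  if (!is.null(repeats))
    ref <- seed_repeats(ref, repeats$unit_length, repeats$copies,
                        seed = seed_mix(seed, 99L))
  libs <- vector("list", length(insert_means))
  for (i in seq_along(insert_means)) {
    sp <- library_spec(insert_means[i], depths[i], read_length, error_rate,
                       insert_sd = insert_sd_frac * insert_means[i])
    libs[[i]] <- generate_library(ref, sp, seed = seed_mix(seed, i))
  }
  names(libs) <- vapply(libs, function(l) l$spec$name, "")
  structure(list(reference = ref, libraries = libs, seed = seed),
            class = "ps_dataset")
}
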
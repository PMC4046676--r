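# End-to-end driver: iterate anchor libraries from largest insert to
# smallest, assemble every anchor, and collect pseudo-Sanger reads and a
# run report.

#' Anchor demotion between passes
#'
#' A pair is excluded from anchor candidacy iff it was a both-ends-inside
#' contributor to an already emitted pseudo-Sanger read; everything else in
#' the library remains eligible when the library's turn as the anchor
#' library comes.
#'
#' @param library a `ps_library`.
#' @param consumed logical vector over the library's pairs (or a vector of
#'   consumed `pair_id`s).
#' @return the data frame of anchor-candidate pairs.
#' @export
demote_anchors <- function(library, consumed) {
  stopifnot(inherits(library, "ps_library"))
  if (is.character(consumed)) consumed <- library$pairs$pair_id %in% consumed
  stopifnot(length(consumed) == nrow(library$pairs))
  library$pairs[!consumed, , drop = FALSE]
}

#' Run the pseudo-Sanger pipeline
#'
#' Pass 1 uses the largest-insert library's pairs as anchors against all
#' smaller libraries' supporting reads; pass k promotes the next-largest
#' library's unconsumed pairs to anchors over the remaining smaller
#' libraries. Each anchor is clustered, repeat-gated against
#' `repeat_factor * E` (with `E` from [expected_sr_count()] at the summed
#' supporting depth), assembled within its library's insert range
#' (mean plus/minus `insert_range_mult` standard deviations), and refined by
#' inner-pair recruitment. Deterministic: no randomness is consumed.
#'
#' @param x a `ps_dataset` or a list of `ps_library` objects (at least two,
#'   distinct insert means).
#' @param params a [ps_params()].
#' @param out_fastq optional path for the pseudo-Sanger FASTQ.
#' @param unused_fastq optional path for reads never used in any local
#'   assembly (interleaved pairs), kept for downstream gap closing.
#' @param report_path optional path for the JSON run report.
#' @param threads accepted for interface compatibility; the implementation
#'   is single-threaded (anchors are independent work units, so the result
#'   does not depend on scheduling).
#' @param verbose print per-pass progress?
#' @return a `ps_run`: `ps` (data frame `id`, `seq`, `qual`, `length`,
#'   `ar_pair`, `ar_lib`, `pass`, `depth_mean`, `depth_min`), `report`,
#'   `params`, and `anchors` (per-anchor outcome table with verified hit
#'   counts).
#' @export
run_pipeline <- function(x, params = ps_params(), out_fastq = NULL,
                         unused_fastq = NULL, report_path = NULL,
                         threads = 1L, verbose = FALSE) {
  libs <- if (inherits(x, "ps_dataset")) x$libraries else x
  if (!is.list(libs) || length(libs) < 2 ||
      !all(vapply(libs, inherits, TRUE, "ps_library")))
    stop("at least two `ps_library` objects are required: ",
         "anchors can only be gap-filled by smaller-insert libraries")
  means <- vapply(libs, function(l) l$spec$insert_mean, 0)
  libs <- libs[order(means, decreasing = TRUE)]
  means <- sort(means, decreasing = TRUE)
  if (any(diff(means) >= 0))
    stop("library insert means must be pairwise distinct")
  rl <- vapply(libs, function(l) l$spec$read_length, 0L)
  n_lib <- length(libs)
  consumed <- lapply(libs, function(l) logical(nrow(l$pairs)))
  ever_used <- lapply(libs, function(l) logical(nrow(l$pairs)))
  ps_all <- list()
  pass_rows <- list()
  anchor_rows <- list()

  for (k in seq_len(n_lib - 1)) {
    ar_lib <- libs[[k]]
    ar_pairs <- demote_anchors(ar_lib, consumed[[k]])
    sr_libs <- libs[(k + 1):n_lib]
    if (nrow(ar_pairs) == 0) next
    pool <- sr_pool(sr_libs)
    index <- build_spaced_index(pool, params$seed_pattern, params$sr_stride)
    D <- sum(pool$lib_specs$depth)
    E <- expected_sr_count(ar_lib$spec$read_length, params$min_overlap, D)
    irange <- ar_lib$spec$insert_mean +
      c(-1, 1) * params$insert_range_mult * ar_lib$spec$insert_sd
    if (verbose)
      message(sprintf("pass %d: %d anchors (%s) vs %d SR pairs, E = %.2f",
                      k, nrow(ar_pairs), ar_lib$spec$name,
                      nrow(pool$pairs), E))
    res <- cpp_run_pass(index$ptr, as.integer(pool$pairs$lib),
                        pool$lib_specs$insert_mean, pool$lib_specs$insert_sd,
                        ar_pairs$seq1, ar_pairs$seq2,
                        as.integer(round(irange[1])),
                        as.integer(round(irange[2])), E,
                        params_list(params))
    ok <- res$status == 0L
    if (any(ok)) {
      ps_all[[length(ps_all) + 1]] <- data.frame(
        id = paste0("PS_", ar_pairs$pair_id[ok]),
        seq = res$seq[ok], qual = res$qual[ok],
        length = res$span[ok],
        ar_pair = ar_pairs$pair_id[ok],
        ar_lib = ar_lib$spec$name, pass = k,
        depth_mean = res$depth_mean[ok], depth_min = res$depth_min[ok],
        stringsAsFactors = FALSE)
    }
    # map pool-pair classification back to the source libraries
    used_pass <- res$on_layout | res$recruited
    for (j in seq_along(sr_libs)) {
      sel <- pool$pairs$lib == j
      gi <- k + j
      rows <- match(pool$pairs$pair_id[sel], libs[[gi]]$pairs$pair_id)
      consumed[[gi]][rows] <- consumed[[gi]][rows] | res$consumed[sel]
      ever_used[[gi]][rows] <- ever_used[[gi]][rows] | used_pass[sel]
    }
    ar_rows <- match(ar_pairs$pair_id, ar_lib$pairs$pair_id)
    ever_used[[k]][ar_rows] <- ever_used[[k]][ar_rows] | ok
    anchor_rows[[k]] <- data.frame(
      pair_id = ar_pairs$pair_id, pass = k,
      status = c("assembled", "repetitive", "empty_cluster", "no_path",
                 "skipped")[res$status + 1L],
      hitsL = res$hitsL, hitsR = res$hitsR, n_members = res$n_members,
      stringsAsFactors = FALSE)
    pass_rows[[k]] <- data.frame(
      pass = k, ar_lib = ar_lib$spec$name, sr_depth = D, expected_sr = E,
      attempted = nrow(ar_pairs),
      assembled = sum(ok),
      repetitive = sum(res$status == 1L),
      empty_cluster = sum(res$status == 2L),
      no_path = sum(res$status == 3L),
      skipped = sum(res$status == 4L),
      sr_pairs = nrow(pool$pairs),
      sr_on_layout = sum(res$on_layout),
      sr_recruited_only = sum(res$recruited & !res$on_layout),
      sr_unused = sum(!used_pass),
      stringsAsFactors = FALSE)
  }

  ps <- if (length(ps_all)) do.call(rbind, ps_all) else
    data.frame(id = character(0), seq = character(0), qual = character(0),
               length = integer(0), ar_pair = character(0),
               ar_lib = character(0), pass = integer(0),
               depth_mean = numeric(0), depth_min = integer(0),
               stringsAsFactors = FALSE)
  passes <- do.call(rbind, pass_rows)
  stats <- if (nrow(ps)) compute_length_stats(ps$length) else NULL
  report <- list(
    libraries = data.frame(
      name = vapply(libs, function(l) l$spec$name, ""),
      insert_mean = means,
      insert_sd = vapply(libs, function(l) l$spec$insert_sd, 0),
      depth = vapply(libs, function(l) l$spec$depth, 0),
      read_length = rl, pairs = vapply(libs, function(l) nrow(l$pairs), 0L),
      stringsAsFactors = FALSE),
    passes = passes,
    ps_count = nrow(ps),
    ps_stats = stats,
    params = unclass(params))
  run <- structure(list(ps = ps, report = report, params = params,
                        anchors = do.call(rbind, anchor_rows)),
                   class = "ps_run")
  if (!is.null(out_fastq) && nrow(ps)) write_ps_fastq(ps, out_fastq)
  if (!is.null(unused_fastq)) {
    un <- do.call(rbind, lapply(seq_along(libs), function(i) {
      libs[[i]]$pairs[!ever_used[[i]], c("pair_id", "seq1", "seq2")]
    }))
    il <- data.frame(
      pair_id = rep(un$pair_id, each = 2),
      seq = as.vector(rbind(un$seq1, un$seq2)), stringsAsFactors = FALSE)
    il$id <- paste0(il$pair_id, c("/1", "/2"))
    write_ps_fastq(data.frame(id = il$id, seq = il$seq,
                              qual = strrep("?", nchar(il$seq))),
                   unused_fastq)
  }
  if (!is.null(report_path))
    jsonlite::write_json(report, report_path, auto_unbox = TRUE,
                         digits = NA, dataframe = "rows")
  run
}

#' @export
print.ps_run <- function(x, ...) {
  cat("pseudo-Sanger run:", nrow(x$ps), "PS reads\n")
  if (!is.null(x$report$ps_stats)) {
    s <- x$report$ps_stats
    cat(sprintf("  total %.0f bp | mean %.2f bp | N50 %d bp | N90 %d bp\n",
                s$total, s$mean, s$n50, s$n90))
  }
  print(x$report$passes)
  invisible(x)
}
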
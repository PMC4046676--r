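# Inner-pair recruitment and the final consensus.

# one assembled anchor from the shared clean dataset, through the R-level ops
assemble_primitive <- function(ds, i, params = ps_params()) {
  libs <- ds$libraries
  pool <- sr_pool(libs[2:4])
  idx <- build_spaced_index(pool)
  cl <- cluster_for_anchor(c(libs[[1]]$pairs$seq1[i], libs[[1]]$pairs$seq2[i]),
                           idx, params)
  g <- build_overlap_graph(cl, idx, params)
  lay <- traverse(g, libs[[1]]$spec$insert_mean +
                    c(-3, 3) * libs[[1]]$spec$insert_sd)
  if (is.null(lay)) return(NULL)
  list(prim = layout_consensus(lay, g), idx = idx, pool = pool)
}

test_that("recruited pairs sit at their truth offsets and inside the span", {
  ds <- ps_cache("ds_clean",
                 simulate_ps_dataset(genome_length = 15000, het_rate = 0,
                                     error_rate = 0, seed = 23))
  x <- NULL
  for (i in 1:10) { x <- assemble_primitive(ds, i); if (!is.null(x)) break }
  expect_false(is.null(x))
  tr <- ds$libraries[[1]]$truth[i, ]
  rec <- recruit_inner_srs(x$prim, x$idx)
  expect_gt(nrow(rec), 0)
  # both ends of every recruited pair lie inside the primitive, counting the
  # full read footprint even for clipped gapped placements
  len <- nchar(x$idx$reads[rec$read])
  lo <- rec$offset - rec$b_start
  expect_true(all(lo >= 0 & lo + len <= x$prim$span))
  # error-free reads place exactly at their truth offsets
  pt <- do.call(rbind, lapply(ds$libraries[2:4], `[[`, "truth"))
  pt <- pt[match(x$pool$pairs$pair_id, pt$pair_id), ]
  pr <- rec$pair
  fs <- if (tr$strand == "+") pt$start[pr] - tr$start else tr$end - pt$end[pr]
  same_hap <- pt$haplotype[pr] == tr$haplotype
  left_end <- rec$offset[!rec$rc]
  expect_true(all(left_end[same_hap[!rec$rc]] ==
                  fs[!rec$rc][same_hap[!rec$rc]]))
})

test_that("a partner whose window leaves the primitive drops the pair", {
  set.seed(41)
  genome <- rand_dna(400)
  prim <- substr(genome, 101, 300)  # 200 bp primitive
  # pair A inside the primitive; pair B's left read inside but partner beyond
  lay <- data.frame(start = c(120, 230), insert = c(120, 120))
  pool <- manual_pool(genome, lay, insert_mean = 120, insert_sd = 5,
                      read_length = 50)
  idx <- build_spaced_index(pool, step = 1)
  rec <- recruit_inner_srs(prim, idx, ps_params(min_overlap = 20))
  expect_setequal(unique(rec$pair), 1L)
})

test_that("refinement corrects a thin-column error and never drops depth", {
  set.seed(43)
  genome <- rand_dna(460)
  rl <- 50L
  # anchor fragment [0, 300); a single bridging ladder of anchor-overlapping
  # pairs whose partners tile the gap, plus twelve fully-interior pairs that
  # only the second consensus can use
  ar_frag <- substr(genome, 1, 300)
  ar <- c(substr(ar_frag, 1, rl), revcomp_dna(substring(ar_frag, 251)))
  bridge <- data.frame(
    start = c(2, 22, 26, 30, 28, 24, 195, 215),
    insert = c(100, 130, 106, 152, 174, 202, 80, 80))
  inner <- data.frame(start = 60:71, insert = 80)
  pool <- manual_pool(genome, rbind(bridge, inner), insert_mean = 130,
                      insert_sd = 25, read_length = rl, name = "mx")
  # pair 1's partner spans genome [52, 102) and is the only cluster read
  # covering columns 80-81 (the m-reads stop at 80, the next partner starts
  # at 82), so an error planted there survives the layout consensus
  p1 <- pool$pairs$seq2[1]          # reverse complement of [52, 102)
  k <- 50 - (80 - 52)               # fragment-forward offset 28 -> rc position
  substr(p1, k, k) <- chartr("ACGT", "CATG", substr(p1, k, k))
  pool$pairs$seq2[1] <- p1
  pool$reads[2] <- p1
  par <- ps_params(min_overlap = 20)
  idx <- build_spaced_index(pool, step = 1)
  cl <- cluster_for_anchor(ar, idx, par)
  g <- build_overlap_graph(cl, idx, par)
  lay <- traverse(g, c(250, 350))
  expect_false(is.null(lay))
  prim <- layout_consensus(lay, g)
  expect_equal(prim$span, 300)
  wrong <- substr(prim$seq, 81, 81) != substr(ar_frag, 81, 81)
  expect_true(wrong)                # the planted error survives the layout
  rec <- recruit_inner_srs(prim, idx, par)
  expect_gt(nrow(rec), 0)
  fin <- final_consensus(prim, rec, idx, id = "PS_test")
  expect_identical(fin$seq, ar_frag)       # out-voted by the inner pairs
  expect_true(all(fin$depth >= prim$depth))  # never reduces depth
  expect_false(fin$flags$primitive_only)
  expect_equal(nchar(fin$qual), nchar(fin$seq))
  # with no recruitable pairs the primitive is returned as-is
  empty_pool <- manual_pool(genome, data.frame(start = 401, insert = 55),
                            insert_mean = 55, read_length = 20, name = "e")
  eidx <- build_spaced_index(empty_pool, step = 1)
  fin0 <- final_consensus(prim, recruit_inner_srs(prim, eidx, par), eidx)
  expect_true(fin0$flags$primitive_only)
})

test_that("refined reads are at least as accurate as primitive ones", {
  ds <- ps_cache("ds20", simulate_ps_dataset(genome_length = 20000, seed = 5))
  libs <- ds$libraries
  pool <- sr_pool(libs[2:4])
  idx <- build_spaced_index(pool)
  par <- ps_params()
  irange <- c(420, 780)
  err <- function(seq, tr) {
    hap <- if (tr$haplotype == "a") ds$reference$hap_a else ds$reference$hap_b
    oth <- if (tr$haplotype == "a") ds$reference$hap_b else ds$reference$hap_a
    fa <- substr(hap, tr$start + 1, tr$end)
    fb <- substr(oth, tr$start + 1, tr$end)
    if (tr$strand == "-") { fa <- revcomp_dna(fa); fb <- revcomp_dna(fb) }
    pseudosanger:::cpp_align_truth(seq, fa, fb, 30L)$errors
  }
  prim_err <- 0; fin_err <- 0; bases <- 0; n <- 0
  for (i in seq(1, 90, by = 2)) {
    cl <- cluster_for_anchor(c(libs[[1]]$pairs$seq1[i],
                               libs[[1]]$pairs$seq2[i]), idx, par)
    g <- build_overlap_graph(cl, idx, par)
    lay <- traverse(g, irange)
    if (is.null(lay)) next
    prim <- layout_consensus(lay, g)
    fin <- final_consensus(prim, recruit_inner_srs(prim, idx, par), idx)
    tr <- libs[[1]]$truth[i, ]
    prim_err <- prim_err + err(prim$seq, tr)
    fin_err <- fin_err + err(fin$seq, tr)
    bases <- bases + nchar(fin$seq)
    n <- n + 1
  }
  expect_gt(n, 20)
  expect_lte(fin_err, prim_err)  # monotone improvement
  expect_lt(fin_err / bases, 0.005)  # far below the input error rate
})
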
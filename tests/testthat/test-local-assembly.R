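# Overlap graph construction, anchored traversal, primitive consensus.

graph_of <- function(seqs, params = ps_params()) {
  pseudosanger:::cpp_build_graph(seqs, pseudosanger:::params_list(params))
}

test_that("tiled reads give a path graph; short overlaps give no edge", {
  set.seed(3)
  genome <- rand_dna(200)
  reads <- c(substr(genome, 1, 100), substr(genome, 51, 150),
             substr(genome, 101, 200))
  g <- graph_of(reads)
  e <- g$edges[order(g$edges$from), ]
  expect_equal(nrow(e), 2)
  expect_equal(e$from, c(1, 2))
  expect_equal(e$to, c(2, 3))
  expect_equal(e$overlap_len, c(50, 50))
  expect_equal(e$mismatches, c(0, 0))
  # 10 bp overlap < O = 30: no edge
  short <- c(substr(genome, 1, 100), substr(genome, 91, 190))
  expect_equal(nrow(graph_of(short)$edges), 0)
})

test_that("duplicate and contained reads are containments, not edges", {
  set.seed(4)
  genome <- rand_dna(150)
  dup <- c(substr(genome, 1, 100), substr(genome, 1, 100))
  g <- graph_of(dup)
  expect_equal(nrow(g$edges), 0)
  expect_equal(nrow(g$containments), 1)
  nest <- c(substr(genome, 1, 120), substr(genome, 11, 90))
  g2 <- graph_of(nest)
  expect_equal(nrow(g2$edges), 0)
  expect_true(any(g2$containments$inner == 2 & g2$containments$outer == 1))
})

test_that("traversal recovers the true tiling within the insert range", {
  set.seed(6)
  genome <- rand_dna(240)
  # nodes: left anchor, right anchor, three bridging reads, 30 bp overlaps
  seqs <- c(substr(genome, 1, 60), substr(genome, 181, 240),
            substr(genome, 31, 110), substr(genome, 81, 160),
            substr(genome, 131, 210))
  g <- graph_of(seqs)
  lay <- traverse(list(node_len = nchar(seqs), edges = g$edges,
                       left = 1, right = 2), c(200, 320))
  expect_equal(lay$path, c(1, 3, 4, 5, 2))
  expect_equal(lay$offsets, c(0, 30, 80, 130, 180))
  expect_equal(lay$span, 240)
  # the same graph with an infeasible insert range has no path
  expect_null(traverse(list(node_len = nchar(seqs), edges = g$edges,
                            left = 1, right = 2), c(300, 400)))
})

test_that("traversal equals exhaustive simple-path enumeration", {
  set.seed(8)
  n_match <- 0
  for (rep in 1:120) {
    gr <- random_overlap_graph(sample(4:10, 1))
    span_max <- sum(gr$node_len)
    oracle <- traverse_oracle(gr$node_len, gr$edges, gr$left, gr$right,
                              0, span_max)
    got <- traverse(gr, c(0, span_max))
    if (is.null(oracle)) {
      expect_null(got)
    } else {
      expect_equal(got$score, oracle$score)
      expect_equal(got$span, oracle$span)
      expect_equal(got$path, oracle$path)
      n_match <- n_match + 1
    }
  }
  expect_gt(n_match, 30)  # enough non-trivial cases exercised
})

test_that("consensus votes by plurality with offset/anchor tie-breaks", {
  cons <- function(seqs, offsets, priority, span)
    pseudosanger:::cpp_consensus(seqs, as.integer(offsets),
                                 as.integer(priority),
                                 character(length(seqs)), as.integer(span))
  # {A x 10, G x 1} -> A
  r <- cons(c(rep("A", 10), "G"), rep(0, 11), rep(1, 11), 1)
  expect_equal(r$seq, "A")
  expect_equal(r$depth, 11)
  # heterozygous column {A x 8, T x 7}: the higher-frequency allele is kept
  r2 <- cons(c(rep("A", 8), rep("T", 7)), rep(0, 15), rep(1, 15), 1)
  expect_equal(r2$seq, "A")
  # tie: the read with the smaller offset wins
  r3 <- cons(c("GG", "AG", "CA"), c(0, 0, 1), c(1, 1, 1), 3)
  # column 0: G vs A tie -> first read (same offset, earlier) -> G
  expect_equal(substr(r3$seq, 1, 1), "G")
  # anchors outrank supporting reads at equal offsets
  r4 <- cons(c("A", "C"), c(0, 0), c(1, 0), 1)
  expect_equal(r4$seq, "C")
})

test_that("error-free clusters reassemble their true fragment exactly", {
  ds <- ps_cache("ds_clean",
                 simulate_ps_dataset(genome_length = 15000, het_rate = 0,
                                     error_rate = 0, seed = 23))
  libs <- ds$libraries
  pool <- sr_pool(libs[2:4])
  idx <- build_spaced_index(pool)
  par <- ps_params()
  irange <- c(600 - 3 * 60, 600 + 3 * 60)
  n_done <- 0
  for (i in seq(1, 60, by = 3)) {
    tr <- libs[[1]]$truth[i, ]
    cl <- cluster_for_anchor(c(libs[[1]]$pairs$seq1[i],
                               libs[[1]]$pairs$seq2[i]), idx, par)
    g <- build_overlap_graph(cl, idx, par)
    lay <- traverse(g, irange)
    if (is.null(lay)) next
    prim <- layout_consensus(lay, g)
    hap <- if (tr$haplotype == "a") ds$reference$hap_a else ds$reference$hap_b
    frag <- substr(hap, tr$start + 1, tr$end)
    if (tr$strand == "-") frag <- revcomp_dna(frag)
    expect_equal(lay$span, tr$end - tr$start)
    expect_identical(prim$seq, frag)
    expect_true(all(prim$depth >= 1))
    expect_equal(nchar(prim$seq), lay$span)
    n_done <- n_done + 1
  }
  expect_gt(n_done, 15)
})

test_that("assembly output is stable under member order and mirror image", {
  ds <- ps_cache("ds_clean",
                 simulate_ps_dataset(genome_length = 15000, het_rate = 0,
                                     error_rate = 0, seed = 23))
  libs <- ds$libraries
  par <- ps_params()
  irange <- c(420, 780)
  assemble <- function(pool, a) {
    idx <- build_spaced_index(pool)
    cl <- cluster_for_anchor(a, idx, par)
    g <- build_overlap_graph(cl, idx, par)
    lay <- traverse(g, irange)
    if (is.null(lay)) return(NULL)
    layout_consensus(lay, g)$seq
  }
  base_pool <- sr_pool(libs[2:4])
  a <- c(libs[[1]]$pairs$seq1[2], libs[[1]]$pairs$seq2[2])
  ref_seq <- assemble(base_pool, a)
  expect_false(is.null(ref_seq))
  # permuted member insertion order: same consensus sequence
  perm <- libs[2:4]
  set.seed(31)
  for (j in seq_along(perm))
    perm[[j]]$pairs <- perm[[j]]$pairs[sample(nrow(perm[[j]]$pairs)), ]
  expect_identical(assemble(sr_pool(perm), a), ref_seq)
  # mirrored input (read 1 and 2 swapped everywhere): reverse complement
  mir <- lapply(libs[2:4], function(l) {
    l$pairs[, c("seq1", "seq2")] <- l$pairs[, c("seq2", "seq1")]
    l
  })
  expect_identical(assemble(sr_pool(mir), rev(a)), revcomp_dna(ref_seq))
})
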
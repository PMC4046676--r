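# Spaced-seed index, scanning, overlap verification, clustering, repeat gate.

test_that("seed keys apply the mask and skip ambiguous windows", {
  k <- spaced_seed_keys("ACGTACGT", "1111", step = 1)
  expect_length(k, 5)                    # 8 - 4 + 1 positions
  expect_equal(k[1], "ACGT")
  expect_equal(attr(k, "positions"), 0:4)
  expect_equal(as.character(spaced_seed_keys("AACGT", "11011")), "AAGT")
  # N under a don't-care position is harmless; N under a care position is not
  expect_equal(as.character(spaced_seed_keys("AANGT", "11011")), "AAGT")
  expect_true(is.na(spaced_seed_keys("ANCGT", "11011")[1]))
  expect_error(spaced_seed_keys("ACGT", "0110"))  # must start/end with 1
})

test_that("the index covers every stride position and reports skips", {
  idx <- build_spaced_index(c("ACGTACGTACGTACGTACGT", "ACG"), "1111", step = 2)
  expect_equal(idx$info$n_reads, 2)
  expect_equal(idx$info$skipped_short, 1)
  expect_equal(idx$info$n_entries, length(seq(1, 20 - 4 + 1, by = 2)))
  empty <- build_spaced_index(character(0), "1111", step = 1)
  expect_equal(nrow(scan_anchor("ACGTACGT", empty)), 0)
})

test_that("anchor scanning finds shared-seed diagonals on both strands", {
  set.seed(5)
  sr <- rand_dna(60)
  idx <- build_spaced_index(c(sr, rand_dna(60)), step = 1)
  hits <- scan_anchor(sr, idx, both_strands = TRUE)
  expect_true(any(hits$sr_id == 1 & hits$diagonal == 0 & hits$strand == "+"))
  # an anchor sharing one 30 bp block, placed at a known diagonal
  blk <- substr(sr, 21, 50)
  anchor <- paste0(rand_dna(40), blk, rand_dna(30))
  hits2 <- scan_anchor(anchor, idx)
  expect_true(any(hits2$sr_id == 1 & hits2$diagonal == 40 - 20 & hits2$strand == "+"))
  # a reverse-complement anchor is seen on the minus strand only
  hits3 <- scan_anchor(revcomp_dna(sr), idx)
  expect_true(any(hits3$sr_id == 1 & hits3$strand == "-"))
  expect_false(any(hits3$sr_id == 1 & hits3$strand == "+"))
  expect_equal(nrow(scan_anchor(strrep("N", 60), idx)), 0)
})

test_that("gapless extension equals the Hamming distance oracle", {
  set.seed(7)
  for (rep in 1:200) {
    a <- rand_dna(sample(40:100, 1))
    b <- rand_dna(sample(40:100, 1))
    d <- sample(-30:30, 1)
    r <- gapless_extend(a, b, d, min_overlap = 10, max_mismatch_rate = 1)
    s <- max(0, d); e <- min(nchar(a), d + nchar(b))
    if (e - s < 10) {
      expect_false(r$ok)
    } else {
      av <- strsplit(substr(a, s + 1, e), "")[[1]]
      bv <- strsplit(substr(b, s - d + 1, e - d), "")[[1]]
      expect_equal(r$overlap_len, e - s)
      expect_equal(r$mismatches, sum(av != bv))
    }
  }
  # thresholds: 2 substitutions in a 50 bp overlap pass at 8%
  a <- rand_dna(50)
  b <- a
  substr(b, 10, 10) <- chartr("ACGT", "CATG", substr(b, 10, 10))
  substr(b, 40, 40) <- chartr("ACGT", "GTAC", substr(b, 40, 40))
  r <- gapless_extend(a, b, 0, min_overlap = 30, max_mismatch_rate = 0.08)
  expect_true(r$ok)
  expect_equal(r$mismatches, 2)
  # 10 mismatches in 50 bp exceed 8%: failure signals the fallback path
  b10 <- a
  for (p in seq(3, 48, by = 5))
    substr(b10, p, p) <- chartr("ACGT", "TGAC", substr(b10, p, p))
  expect_false(gapless_extend(a, b10, 0, 30, 0.08)$ok)
})

test_that("Smith-Waterman matches a brute-force DP oracle", {
  r <- sw_align("ACGT", "ACGT")
  expect_equal(r$score, 4)
  expect_equal(r$n_match, 4)
  # an internal insertion flanked by unique sequence: the gapped alignment
  # dominates any gapless one
  ga <- "ACGTACGTCGACGACG"
  gb <- "ACGTACGTTCGACGACG"
  g <- sw_align(ga, gb)
  expect_equal(g$score, sw_oracle(ga, gb))
  expect_gte(g$n_gap, 1)
  expect_false(sw_align("AAAA", "TTTT")$found)  # no positive-scoring cell
  set.seed(11)
  for (rep in 1:200) {
    a <- rand_dna(sample(5:30, 1))
    b <- rand_dna(sample(5:30, 1))
    expect_equal(sw_align(a, b)$score, sw_oracle(a, b))
  }
})

test_that("expected supporting-read count follows the coverage formula", {
  expect_equal(expected_sr_count(100, 30, 45), 45 * 141 / 100)
  expect_equal(expected_sr_count(100, 30, 90),
               2 * expected_sr_count(100, 30, 45))  # linear in depth
  expect_equal(expected_sr_count(100, 99, 45), 45 * 3 / 100)
  expect_error(expected_sr_count(100, 100, 45))
})

test_that("clustering admits inward forward overlaps and drops the rest", {
  set.seed(13)
  genome <- rand_dna(900)
  # anchor fragment [100, 700); supporting pairs inside it
  ar_frag <- substr(genome, 101, 700)
  ar <- c(substr(ar_frag, 1, 50), revcomp_dna(substring(ar_frag, 551)))
  lay <- data.frame(start = c(120, 110, 380, 560, 20, 720),
                    insert = c(150, 160, 150, 130, 120, 140),
                    strand = c("+", "-", "+", "-", "+", "+"))
  pool <- manual_pool(genome, lay, insert_mean = 150, read_length = 50)
  idx <- build_spaced_index(pool, step = 1)
  par <- ps_params(min_overlap = 20)
  cl <- cluster_for_anchor(ar, idx, par)
  got <- sort(unique(cl$members$pair))
  # pairs 1-2 overlap the left anchor (either strand), pair 4 the right;
  # pair 3 is wholly interior, pairs 5-6 lie outside the anchor span
  expect_equal(got, c(1L, 2L, 4L))
  # sequencing the same fragment from the other strand swaps the two reads;
  # the pair still points inward and must still be admitted
  out_pool <- manual_pool(genome, data.frame(start = 115, insert = 150,
                                             strand = "+"),
                          insert_mean = 150, read_length = 50)
  rcp <- out_pool$pairs
  rcp[, c("seq1", "seq2")] <- rcp[, c("seq2", "seq1")]
  pool2 <- out_pool; pool2$pairs <- rcp
  pool2$reads <- as.vector(rbind(rcp$seq1, rcp$seq2))
  idx2 <- build_spaced_index(pool2, step = 1)
  expect_equal(nrow(cluster_for_anchor(ar, idx2, par)$members), 1)
  # ... whereas an anchor with no supporting reads yields an empty cluster
  far <- c(rand_dna(50), rand_dna(50))
  expect_equal(nrow(cluster_for_anchor(far, idx, par)$members), 0)
})

test_that("clustering is symmetric under global reverse complement", {
  ds <- ps_cache("ds20", simulate_ps_dataset(genome_length = 20000, seed = 5))
  libs <- ds$libraries
  pool <- sr_pool(libs[2:4])
  idx <- build_spaced_index(pool)
  par <- ps_params()
  # mirror the whole read set: read 1 and read 2 swap roles
  mlibs <- lapply(libs, function(l) {
    l$pairs[, c("seq1", "seq2")] <- l$pairs[, c("seq2", "seq1")]
    l
  })
  mpool <- sr_pool(mlibs[2:4])
  midx <- build_spaced_index(mpool)
  for (i in seq(1, 40, by = 4)) {
    a <- c(libs[[1]]$pairs$seq1[i], libs[[1]]$pairs$seq2[i])
    cl <- cluster_for_anchor(a, idx, par)
    mcl <- cluster_for_anchor(rev(a), midx, par)
    expect_setequal(cl$members$pair_id, mcl$members$pair_id)
  }
})

test_that("the repeat gate separates repeat anchors from unique ones", {
  expect_true(is_repetitive(list(hitsL = 100, hitsR = 10), E = 63.45))
  expect_false(is_repetitive(list(hitsL = 0, hitsR = 0), E = 63.45))
  expect_false(is_repetitive(list(hitsL = 95, hitsR = 95), E = 63.45))  # strict >
  ds <- ps_cache("ds_rep_small",
                 simulate_ps_dataset(genome_length = 30000, seed = 17,
                                     repeats = list(unit_length = 400, copies = 20)))
  pool <- sr_pool(ds$libraries[2:4])
  idx <- build_spaced_index(pool)
  par <- ps_params()
  E <- expected_sr_count(100, 30, sum(pool$lib_specs$depth))
  rp <- ds$reference$repeats
  tr <- ds$libraries[[1]]$truth
  r1s <- ifelse(tr$strand == "+", tr$start, tr$end - 100)
  inside <- vapply(r1s, function(s)
    any(s >= rp$start & s + 100 <= rp$end), TRUE)
  in_id <- which(inside)[1:5]
  away <- vapply(seq_len(nrow(tr)), function(i)
    all(tr$end[i] < rp$start - 100 | tr$start[i] > rp$end + 100), TRUE)
  out_id <- which(away)[1:5]
  for (i in in_id) {
    cl <- cluster_for_anchor(c(ds$libraries[[1]]$pairs$seq1[i],
                               ds$libraries[[1]]$pairs$seq2[i]), idx, par)
    expect_true(is_repetitive(cl, E))
  }
  for (i in out_id) {
    cl <- cluster_for_anchor(c(ds$libraries[[1]]$pairs$seq1[i],
                               ds$libraries[[1]]$pairs$seq2[i]), idx, par)
    expect_false(is_repetitive(cl, E))
  }
})
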
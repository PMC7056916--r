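test_that("block partition greedily fills to the chunk capacity", {
  recs <- seq_records(paste0("s", 1:4),
                      c(strrep("A", 5), strrep("C", 4), strrep("G", 3),
                        strrep("T", 2)))
  blocks <- partition_blocks(recs, chunk_mb = 8e-6)  # 8 bp capacity
  expect_equal(lapply(blocks, function(b) b$id),
               list("s1", c("s2", "s3"), "s4"))

  expect_equal(length(partition_blocks(recs, 1)), 1L)
  expect_equal(length(partition_blocks(recs[0, ], 1)), 0L)
  # a record larger than the chunk still gets a block
  expect_equal(length(partition_blocks(recs, 1e-6)), 4L)
})

test_that("assign_or_promote takes the first satisfying representative", {
  params <- clustering_params(memiden = 90)
  rep_seq <- random_genome(2000, 61)
  idx <- build_index(seq_records("R1", rep_seq), 1L)

  sub <- seq_records("q", substr(rep_seq, 201, 1400))
  a <- assign_or_promote(sub[1, ], idx, params)
  expect_true(a$redundant)
  expect_equal(a$rep_id, "R1")
  expect_equal(a$identity, 1.0)
  expect_equal(a$strand, "+")

  unrel <- seq_records("u", random_genome(1200, 62))
  expect_false(assign_or_promote(unrel[1, ], idx, params)$redundant)

  # 5% substitution copy: engine identity equals the hand-run pipeline
  mut <- mutate_genome(substr(rep_seq, 1, 1500), 0.05, 0, 63)
  qrec <- seq_records("m", mut$seq)
  a2 <- assign_or_promote(qrec[1, ], idx, params)
  expect_true(a2$redundant)
  mems <- collect_mems_filtered(idx, qrec[1, ], 21,
                                min_member_length = qrec$length[1])
  manual <- memclust:::refine_and_score(
    mems[, c("ref_start", "query_start", "length")],
    rep_seq, qrec$seq[1], params$scheme, qrec$length[1])
  expect_equal(a2$identity, manual$ememi)
  expect_gte(a2$identity, 0.90)

  # minus-strand redundancy when both strands are searched
  params2 <- clustering_params(memiden = 90, both_strands = TRUE)
  rcq <- seq_records("rc", reverse_complement(substr(rep_seq, 101, 1300)))
  a3 <- assign_or_promote(rcq[1, ], idx, params2)
  expect_true(a3$redundant)
  expect_equal(a3$strand, "-")
  expect_false(assign_or_promote(rcq[1, ], idx, params)$redundant)
})

test_that("cluster_block groups prefix copies under the longest sequence", {
  base <- random_genome(2000, 71)
  blk <- filter_and_sort(seq_records(
    c("full", "c1", "c2", "c3", "other"),
    c(base, substr(base, 1, 1800), substr(base, 1, 1800),
      substr(base, 1, 1700), random_genome(1900, 72))))
  res <- cluster_block(blk, params = clustering_params(memiden = 90))
  expect_equal(res$representatives$id, c("full", "other"))
  expect_equal(sort(res$assignments$id), c("c1", "c2", "c3"))
  expect_true(all(res$assignments$rep_id == "full"))
  expect_true(all(res$assignments$identity == 1.0))

  # a carried index catches sequences before the intra-block pass
  carried <- build_index(seq_records("carry", base), 1L)
  res2 <- cluster_block(blk, carried_index = carried,
                        params = clustering_params(memiden = 90))
  expect_true(all(res2$assignments$rep_id[res2$assignments$id %in%
                                          c("full", "c1", "c2", "c3")] == "carry"))
  expect_equal(res2$representatives$id, "other")
})

test_that("clustering recovers planted groups and respects the identity floor", {
  recs <- small_benchmark(seed = 15)
  bm <- make_benchmark(6, 2, c(1200, 2200), 0.95, 5, seed = 15)
  cs <- cluster_all(recs, clustering_params(memiden = 90))
  expect_equal(length(cs$clusters), 11L)  # 6 groups + 5 singletons
  part <- cluster_partition(cs)
  truth <- stats::setNames(bm$truth$group_id, bm$truth$id)
  # identical partitions: same groups of ids
  expect_identical(partition_groups(part), partition_groups(truth))
  tb <- cluster_table(cs)
  expect_true(all(tb$identity[!tb$is_rep] >= 0.90))
  # representatives are the longest member of each cluster
  for (cl in cs$clusters) {
    expect_true(all(cl$rep_length >= cl$members$length))
  }
})

test_that("clustering is deterministic and invariant to threads, blocks, and rebuild mode", {
  recs <- small_benchmark(seed = 16)
  base <- cluster_signature(cluster_all(recs, clustering_params(memiden = 90)))

  expect_identical(
    cluster_signature(cluster_all(recs, clustering_params(memiden = 90))),
    base)
  expect_identical(
    cluster_signature(cluster_all(recs, clustering_params(memiden = 90, threads = 4))),
    base)
  # many small blocks vs one big block
  expect_identical(
    cluster_signature(cluster_all(recs, clustering_params(memiden = 90, chunk_mb = 4e-3))),
    base)
  # rebuild schedule must not affect the result
  expect_identical(
    cluster_signature(cluster_all(recs, clustering_params(memiden = 90, rebuild = FALSE))),
    base)
  expect_identical(
    cluster_signature(cluster_all(recs, clustering_params(
      memiden = 90, rebuild = TRUE, rebuild_interval = 2))),
    base)
})

test_that("cluster count is monotone in the identity threshold", {
  recs <- small_benchmark(seed = 17, identity = 0.93)
  counts <- vapply(c(80, 90, 95, 100), function(thr) {
    length(cluster_all(recs, clustering_params(memiden = thr))$clusters)
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
  expect_lt(counts[1], counts[4])  # thresholds actually bite on this fixture
})

test_that("equal-length exact duplicates cluster together", {
  s <- random_genome(800, 91)
  recs <- filter_and_sort(seq_records(c("dup1", "dup2"), c(s, s)))
  cs <- cluster_all(recs, clustering_params(memiden = 100))
  expect_equal(length(cs$clusters), 1L)
  expect_equal(cs$clusters[[1]]$representative, "dup1")
  expect_equal(cs$clusters[[1]]$members$identity, 1.0)
})

test_that("unsorted input is rejected", {
  recs <- seq_records(c("a", "b"), c("ACGTACGTACGTACGTACGTA",
                                     strrep("ACGTT", 10)))
  expect_error(cluster_all(recs, clustering_params()), "sorted")
})
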
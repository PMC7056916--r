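mk_mems <- function(rs, qs, len) {
  data.frame(ref_start = as.integer(rs), query_start = as.integer(qs),
             length = as.integer(len))
}

test_that("containment removal drops MEMs inside a larger MEM or a neighbour union", {
  # single-containment on the representative projection
  m <- mk_mems(c(0, 10), c(50, 90), c(30, 10))
  out <- remove_contained(m)
  expect_equal(nrow(out), 1L)
  expect_equal(out$ref_start, 0L)

  # containment in the union of the two flanking neighbours
  m2 <- mk_mems(c(0, 8, 12), c(0, 8, 12), c(20, 8, 18))
  out2 <- remove_contained(m2)
  expect_equal(out2$ref_start, c(0L, 12L))

  # containment on the query projection only
  m3 <- mk_mems(c(0, 40), c(10, 12), c(30, 5))
  expect_equal(nrow(remove_contained(m3)), 1L)

  # pairwise disjoint input is unchanged
  m4 <- mk_mems(c(0, 30, 60), c(0, 30, 60), c(10, 10, 10))
  expect_equal(remove_contained(m4), m4)
})

test_that("overlap trimming shifts starts on both sequences and drops empty MEMs", {
  # representative overlap of 5: B's starts shift right by 5
  m <- mk_mems(c(0, 15), c(0, 100), c(20, 20))
  out <- trim_overlaps(m)
  expect_equal(out$ref_start, c(0L, 20L))
  expect_equal(out$query_start, c(0L, 105L))
  expect_equal(out$length, c(20L, 15L))

  # overlap on the query only: trimmed by the query amount
  m2 <- mk_mems(c(0, 50), c(0, 12), c(20, 20))
  out2 <- trim_overlaps(m2)
  expect_equal(out2$ref_start, c(0L, 58L))
  expect_equal(out2$query_start, c(0L, 20L))
  expect_equal(out2$length, c(20L, 12L))

  # disjoint input unchanged
  m3 <- mk_mems(c(0, 30), c(0, 40), c(10, 10))
  expect_equal(trim_overlaps(m3), m3)

  # full shadowing drops the shorter MEM
  m4 <- mk_mems(c(0, 5), c(0, 5), c(30, 10))
  m4 <- remove_contained(m4)
  expect_equal(nrow(trim_overlaps(m4)), 1L)
})

test_that("refinement yields disjoint projections bounded by the query on random fixtures", {
  set.seed(77)
  for (t in 1:400) {
    k <- sample(1:12, 1)
    lq <- 120L
    m <- random_mem_fixture(k, lr = 200L, lq = lq)
    union_len <- function(st, len) {
      o <- order(st); st <- st[o]; en <- st + len[o]
      tot <- 0L; cur_s <- st[1]; cur_e <- en[1]
      for (i in seq_along(st)[-1]) {
        if (st[i] > cur_e) { tot <- tot + cur_e - cur_s; cur_s <- st[i]; cur_e <- en[i] }
        else cur_e <- max(cur_e, en[i])
      }
      tot + cur_e - cur_s
    }
    before_union <- union_len(m$query_start, m$length)
    out <- trim_overlaps(remove_contained(m))
    expect_true(projections_disjoint(out))
    expect_lte(sum(out$length), lq)
    expect_lte(sum(out$length), before_union)
  }
})

test_that("ungapped extension grows through matches and stops at the x-drop", {
  sc <- score_scheme(xdrop = 5)
  # MEM of 10 flanked by 5 identical bases both sides on both sequences
  core <- random_genome(10, 301)
  lf <- random_genome(5, 302); rf <- random_genome(5, 303)
  rep_seq <- paste0(lf, core, rf)
  qry <- rep_seq
  m <- mk_mems(5, 5, 10)
  ext <- extend_matches(m, rep_seq, qry, sc)
  expect_equal(ext$ext_ref_start, 0L)
  expect_equal(ext$ext_ref_end, 20L)
  expect_equal(ext$ext_query_start, 0L)
  expect_equal(ext$ext_query_end, 20L)
  expect_equal(ext$n_match, 20L)

  # immediate mismatch wall: extension adds nothing
  rep2 <- paste0(strrep("A", 6), core, strrep("A", 6))
  qry2 <- paste0(strrep("C", 6), core, strrep("C", 6))
  ext2 <- extend_matches(mk_mems(6, 6, 10), rep2, qry2, sc)
  expect_equal(ext2$ext_ref_start, 6L)
  expect_equal(ext2$ext_ref_end, 16L)
  expect_equal(ext2$n_match, 10L)
})

test_that("ungapped extension matches the exhaustive best-prefix oracle", {
  set.seed(88)
  for (t in 1:200) {
    n <- sample(1:60, 1)
    a <- random_genome(n, 6000 + 2 * t)
    # correlated flank: copy with mutations so scores wander
    b <- mutate_genome(a, 0.3, 0, 6001 + 2 * t)$seq
    b <- substr(b, 1, n)
    if (nchar(b) < n) a <- substr(a, 1, nchar(b))
    xd <- sample(1:6, 1)
    got <- memclust:::cpp_xdrop_ungapped(a, b, 1L, -1L, xd)
    want <- xdrop_prefix_oracle(a, b, 1, -1, xd)
    expect_equal(got$steps, want$steps)
    expect_equal(got$matches, want$matches)
  }
  # spec-style flank M M X M X X X..., xdrop 2: first best prefix is "MM"
  a <- "AAAAAAA"; b <- "AACACCC"
  got <- memclust:::cpp_xdrop_ungapped(a, b, 1L, -1L, 2L)
  want <- xdrop_prefix_oracle(a, b, 1, -1, 2)
  expect_equal(got$steps, want$steps)
  expect_equal(got$steps, 2L)
  expect_equal(got$matches, 2L)
})

test_that("extension clips at neighbour midpoints so eMEMs stay disjoint", {
  sc <- score_scheme(xdrop = 50)  # would extend far without clipping
  rep_seq <- random_genome(100, 401)
  qry <- rep_seq
  m <- mk_mems(c(10, 50), c(10, 50), c(10, 10))
  ext <- extend_matches(m, rep_seq, qry, sc)
  # gap between MEMs is [20,50); midpoint split: left gets [20,35), right [35,50)
  expect_equal(ext$ext_ref_end[1], 35L)
  expect_equal(ext$ext_ref_start[2], 35L)
  expect_true(projections_disjoint(data.frame(
    ref_start = ext$ext_ref_start, query_start = ext$ext_query_start,
    length = ext$ext_ref_end - ext$ext_ref_start)))
  # n_match never below the seed length, spans contain the seed
  expect_true(all(ext$n_match >= m$length))
  expect_true(all(ext$ext_ref_start <= m$ref_start &
                  ext$ext_ref_end >= m$ref_start + m$length))
})

test_that("gapped extension bridges indels and never loses to ungapped on indel copies", {
  set.seed(99)
  wins <- 0
  for (t in 1:40) {
    rep_seq <- random_genome(600, 7000 + t)
    mut <- mutate_genome(rep_seq, 0.01, 0.01, 7100 + t)
    qry <- mut$seq
    idx <- build_index(seq_records("r", rep_seq), 1L)
    mems <- collect_mems_filtered(idx, qry, 21, 0)
    mems <- mems[, c("ref_start", "query_start", "length")]
    mems <- trim_overlaps(remove_contained(mems))
    if (nrow(mems) == 0) next
    ug <- sum(extend_matches(mems, rep_seq, qry, score_scheme())$n_match)
    gp <- sum(extend_matches(mems, rep_seq, qry,
                             score_scheme(gapped = TRUE))$n_match)
    expect_gte(gp, ug)
    if (gp > ug) wins <- wins + 1
  }
  expect_gt(wins, 0)  # gaps actually get bridged on indel-mutated copies
})

test_that("eMEM identity follows matched bases over query length", {
  ext <- data.frame(n_match = c(40L, 50L))
  r <- compute_ememi(ext, 100)
  expect_equal(r$ememi, 0.90)
  expect_equal(r$n_match_total, 90L)
  expect_s3_class(r, "identity_result")

  expect_equal(compute_ememi(ext[0, , drop = FALSE], 100)$ememi, 0)
  expect_error(compute_ememi(ext, 0), "l_query")
  # cap at 1
  expect_equal(compute_ememi(data.frame(n_match = 150L), 100)$ememi, 1)

  # exact substring query: full pipeline reaches identity 1 for any L
  rep_seq <- random_genome(1500, 11)
  qry <- substr(rep_seq, 301, 1100)
  idx <- build_index(seq_records("r", rep_seq), 1L)
  for (L in c(10, 21, 100, 800)) {
    mems <- collect_mems_filtered(idx, qry, L, 0)
    r <- memclust:::refine_and_score(
      mems[, c("ref_start", "query_start", "length")],
      rep_seq, qry, score_scheme(), nchar(qry))
    expect_equal(r$ememi, 1.0)
  }
})
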
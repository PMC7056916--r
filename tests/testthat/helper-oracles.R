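# Independent oracles and fixture builders used across the suite.

# Concatenated text with pairwise-distinct terminators that sort below 'A'
# (bytes 0x01, 0x02, ...), realizing the position tie-break between equal
# terminators of the package's index.
oracle_text <- function(seqs) {
  stopifnot(length(seqs) <= 60)
  paste0(mapply(function(s, i) paste0(s, rawToChar(as.raw(i))),
                seqs, seq_along(seqs)), collapse = "")
}

# naive sparse suffix array: sort sampled (non-terminator) suffixes as plain
# byte strings (radix = locale-independent)
sa_oracle <- function(seqs, K = 1L) {
  text <- oracle_text(seqs)
  n <- nchar(text)
  pos <- seq(0L, n - 1L, by = K)
  is_term <- substring(text, pos + 1L, pos + 1L) < "A"
  pos <- pos[!is_term]
  suf <- substring(text, pos + 1L, n)
  pos[order(match(suf, sort(suf, method = "radix")))]
}

# direct pairwise longest-common-prefix of adjacent oracle SA entries
lcp_oracle <- function(seqs, K = 1L) {
  text <- strsplit(oracle_text(seqs), "")[[1]]
  sa <- sa_oracle(seqs, K)
  n <- length(text)
  vapply(seq_along(sa), function(i) {
    if (i == 1) return(0L)
    a <- sa[i - 1] + 1L; b <- sa[i] + 1L
    h <- 0L
    while (a + h <= n && b + h <= n && text[a + h] == text[b + h]) h <- h + 1L
    h
  }, integer(1))
}

with_strand <- function(d, st) {
  d$strand <- rep(st, nrow(d))
  d
}

mem_key <- function(d) {
  strand <- if ("strand" %in% names(d)) d$strand else "+"
  sort(paste(d$ref_start, d$query_start, d$length, strand))
}

# exhaustive best-scoring-prefix x-drop oracle (ungapped); a/b are flank
# strings ordered outward from the seed edge
xdrop_prefix_oracle <- function(a, b, match = 1, mismatch = -1, xdrop = 5) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- min(length(av), length(bv))
  best <- 0; best_at <- 0; best_matches <- 0; score <- 0; matches <- 0
  for (i in seq_len(n)) {
    hit <- av[i] == bv[i] && av[i] %in% c("A", "C", "G", "T")
    score <- score + if (hit) match else mismatch
    matches <- matches + hit
    if (score > best) { best <- score; best_at <- i; best_matches <- matches }
    if (best - score > xdrop) break
  }
  list(steps = best_at, matches = best_matches, score = best)
}

# random raw MEM-set fixture for refinement geometry: k spans with
# arbitrary (possibly crossing, nested, overlapping) placements inside a
# ref of length lr and a query of length lq
random_mem_fixture <- function(k, lr = 200L, lq = 120L) {
  len <- sample(3:40, k, replace = TRUE)
  data.frame(ref_start = vapply(len, function(l) sample(0:(lr - l), 1), 1L),
             query_start = vapply(len, function(l) sample(0:(lq - l), 1), 1L),
             length = len)
}

projections_disjoint <- function(mems) {
  ok <- function(st, len) {
    o <- order(st)
    all(st[o][-1] >= (st + len)[o][-length(o)])
  }
  nrow(mems) <= 1 ||
    (ok(mems$ref_start, mems$length) && ok(mems$query_start, mems$length))
}

# canonical flat signature of a clustering for identity comparisons
cluster_signature <- function(cs) {
  tb <- cluster_table(cs)
  tb <- tb[order(tb$id), c("cluster", "id", "is_rep", "identity", "strand")]
  rownames(tb) <- NULL
  tb
}

# membership partition as a named vector id -> representative id
cluster_partition <- function(cs) {
  out <- unlist(lapply(cs$clusters, function(cl) {
    ids <- c(cl$representative, cl$members$id)
    stats::setNames(rep(cl$representative, length(ids)), ids)
  }))
  out[order(names(out))]
}

# a labelled partition (id -> group label) as canonical unnamed group strings
partition_groups <- function(labels) {
  unname(sort(vapply(split(names(labels), labels),
                     function(x) paste(sort(x), collapse = ","), "")))
}

small_benchmark <- function(seed = 5L, identity = 0.95, indel_rate = 0,
                            n_groups = 6, copies = 2, singletons = 5,
                            len_range = c(1200, 2200)) {
  bm <- make_benchmark(n_groups, copies, len_range, identity, singletons,
                       seed = seed, indel_rate = indel_rate)
  filter_and_sort(bm$records)
}
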
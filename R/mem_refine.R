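#' Score scheme for seed extension
#'
#' Parameters of the x-drop extension of refined MEMs. Defaults follow
#' common seed-extension practice (match +1, mismatch -1, affine gaps -2/-1,
#' x-drop 5); they are configuration, to be tuned per application.
#'
#' @param match reward for an identical aligned pair (> 0).
#' @param mismatch penalty for a mismatched pair (< 0).
#' @param gap_open penalty for opening a gap (< 0; gapped mode only).
#' @param gap_extend penalty for extending a gap (< 0; gapped mode only).
#' @param xdrop extension stops once the running score falls more than this
#'   below the best score seen (> 0).
#' @param gapped allow insertions/deletions during extension.
#' @return object of class `score_scheme`.
#' @export
score_scheme <- function(match = 1L, mismatch = -1L, gap_open = -2L,
                         gap_extend = -1L, xdrop = 5L, gapped = FALSE) {
  stopifnot(match > 0, mismatch < 0, gap_open < 0, gap_extend < 0, xdrop > 0)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 xdrop = as.integer(xdrop), gapped = isTRUE(gapped)),
            class = "score_scheme")
}

# [s, e) containment helpers on 0-based half-open spans
.spans <- function(mems) {
  list(rs = mems$ref_start, re = mems$ref_start + mems$length,
       qs = mems$query_start, qe = mems$query_start + mems$length)
}

# is [s,e) a subset of [a1,b1) U [a2,b2)?
.covered_by_union <- function(s, e, a1, b1, a2, b2) {
  if (a1 > a2) { tmp <- a1; a1 <- a2; a2 <- tmp; tmp <- b1; b1 <- b2; b2 <- tmp }
  if (s < a1) return(FALSE)
  if (e <= b1) return(TRUE)
  if (s >= a2) return(e <= b2)
  b1 >= a2 && e <= max(b1, b2)
}

#' Remove contained MEMs
#'
#' First removes every MEM whose projection on the representative or on the
#' query is contained in a single larger MEM's projection; then, in
#' representative begin-position order, removes every MEM whose projection
#' (on either sequence) is covered by the union of its two flanking
#' neighbours. All MEMs must belong to one (representative, query, strand)
#' triple.
#'
#' @param mems `data.frame` with columns ref_start, query_start, length
#'   (0-based starts).
#' @return the surviving MEMs, sorted by ref_start.
#' @export
remove_contained <- function(mems) {
  n <- nrow(mems)
  if (n <= 1) return(mems)
  s <- .spans(mems)
  # (1) containment in a single larger MEM, either projection; ties in
  # length (identical spans) keep the earlier row
  drop <- rep(FALSE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      larger <- mems$length[j] > mems$length[i] ||
        (mems$length[j] == mems$length[i] && j < i)
      if (!larger) next
      if ((s$rs[j] <= s$rs[i] && s$re[j] >= s$re[i]) ||
          (s$qs[j] <= s$qs[i] && s$qe[j] >= s$qe[i])) {
        drop[i] <- TRUE
        break
      }
    }
  }
  mems <- mems[!drop, , drop = FALSE]
  mems <- mems[order(mems$ref_start, mems$query_start), , drop = FALSE]
  n <- nrow(mems)
  if (n >= 3) {
    s <- .spans(mems)
    mid <- 2:(n - 1)
    drop2 <- vapply(mid, function(i) {
      .covered_by_union(s$rs[i], s$re[i],
                        s$rs[i - 1], s$re[i - 1], s$rs[i + 1], s$re[i + 1]) ||
      .covered_by_union(s$qs[i], s$qe[i],
                        s$qs[i - 1], s$qe[i - 1], s$qs[i + 1], s$qe[i + 1])
    }, logical(1))
    mems <- mems[!c(FALSE, drop2, FALSE), , drop = FALSE]
  }
  rownames(mems) <- NULL
  mems
}

# one right-to-left trimming sweep along the given axis ("ref" or "query");
# the start of each MEM is shifted right on BOTH sequences by the overlap
# with its leftward neighbour (on either projection). Trimming only shrinks
# spans, so it can never create a new overlap.
.trim_pass <- function(mems, axis) {
  n <- nrow(mems)
  if (n <= 1) return(mems)
  if (axis == "ref") {
    o <- order(mems$ref_start, mems$query_start)
  } else {
    o <- order(mems$query_start, mems$ref_start)
  }
  mems <- mems[o, , drop = FALSE]
  keep <- rep(TRUE, n)
  for (i in n:2) {
    # nearest surviving left neighbour
    j <- i - 1L
    while (j >= 1 && !keep[j]) j <- j - 1L
    if (j < 1) next
    ov_r <- (mems$ref_start[j] + mems$length[j]) - mems$ref_start[i]
    ov_q <- (mems$query_start[j] + mems$length[j]) - mems$query_start[i]
    trim <- max(0L, ov_r, ov_q)
    if (trim == 0L) next
    if (trim >= mems$length[i]) {
      keep[i] <- FALSE
    } else {
      mems$ref_start[i] <- mems$ref_start[i] + trim
      mems$query_start[i] <- mems$query_start[i] + trim
      mems$length[i] <- mems$length[i] - trim
    }
  }
  mems[keep, , drop = FALSE]
}

.projections_disjoint <- function(mems) {
  ok_axis <- function(st, len) {
    o <- order(st)
    all(st[o][-1] >= (st + len)[o][-length(o)])
  }
  nrow(mems) <= 1 ||
    (ok_axis(mems$ref_start, mems$length) &&
     ok_axis(mems$query_start, mems$length))
}

#' Trim partially overlapping MEMs
#'
#' Sweeps the MEMs from the last to the first in representative
#' begin-position order; whenever a MEM overlaps its leftward neighbour on
#' either sequence, its start coordinates on both sequences are shifted
#' rightward by the overlap amount (and the MEM is dropped if its length
#' falls below 1). A symmetric sweep in query order follows, so that the
#' projections on both sequences end up pairwise disjoint even for crossing
#' (non-collinear) inputs; sweeps repeat until stable.
#'
#' @param mems `data.frame` with columns ref_start, query_start, length, with
#'   no containments remaining (see [remove_contained()]).
#' @return the trimmed MEMs, sorted by ref_start, with pairwise-disjoint
#'   projections on both sequences.
#' @export
trim_overlaps <- function(mems) {
  if (nrow(mems) > 1) {
    for (it in 1:10) {
      mems <- .trim_pass(mems, "ref")
      mems <- .trim_pass(mems, "query")
      if (.projections_disjoint(mems)) break
    }
  }
  mems <- mems[order(mems$ref_start, mems$query_start), , drop = FALSE]
  rownames(mems) <- NULL
  mems
}

.rev_chars <- function(x) {
  paste(rev(strsplit(x, "")[[1]]), collapse = "")
}

#' Extend refined MEMs with the score scheme
#'
#' Extends each MEM leftward from its start and rightward from its end under
#' the x-drop rule: ungapped mode advances while the running score stays
#' within `xdrop` of the best score and keeps the (first) best-scoring
#' endpoint; gapped mode runs a banded affine-gap extension with the same
#' drop-off. Extensions are clipped at the midpoint of the gap to the
#' neighbouring MEM on each sequence (and at sequence ends), so the extended
#' projections stay disjoint. `n_match` counts identical aligned bases in the
#' final segment (matches only, also in gapped mode).
#'
#' @param mems refined MEMs (disjoint projections on both sequences).
#' @param rep_seq representative sequence string.
#' @param query_seq query sequence string, in the same frame as the MEM
#'   coordinates (reverse-complemented for minus-strand sets).
#' @param scheme a [score_scheme()].
#' @return `data.frame` of extended matches: the source columns plus
#'   ext_ref_start, ext_ref_end, ext_query_start, ext_query_end (half-open)
#'   and n_match.
#' @export
extend_matches <- function(mems, rep_seq, query_seq, scheme = score_scheme()) {
  stopifnot(inherits(scheme, "score_scheme"))
  n <- nrow(mems)
  empty <- data.frame(ref_start = integer(), query_start = integer(),
                      length = integer(), ext_ref_start = integer(),
                      ext_ref_end = integer(), ext_query_start = integer(),
                      ext_query_end = integer(), n_match = integer())
  if (n == 0) return(empty)
  mems <- mems[order(mems$ref_start, mems$query_start), , drop = FALSE]
  rs <- mems$ref_start; re <- rs + mems$length
  qs <- mems$query_start; qe <- qs + mems$length
  lr <- nchar(rep_seq); lq <- nchar(query_seq)

  # midpoint budgets between neighbours, per axis; the right half of each
  # gap belongs to the left MEM (ceiling), the left half to the right MEM
  budgets <- function(st, en, total) {
    o <- order(st)
    gl <- gr <- integer(length(st))
    prev_end <- c(0L, en[o][-length(o)])
    next_start <- c(st[o][-1], total)
    gap_l <- st[o] - prev_end
    gap_r <- next_start - en[o]
    gl[o] <- ifelse(seq_along(o) == 1, st[o], gap_l %/% 2L)
    gr[o] <- ifelse(seq_along(o) == length(o), total - en[o],
                    gap_r - gap_r %/% 2L)
    list(left = gl, right = gr)
  }
  br <- budgets(rs, re, lr)
  bq <- budgets(qs, qe, lq)

  out <- mems
  out$ext_ref_start <- rs; out$ext_ref_end <- re
  out$ext_query_start <- qs; out$ext_query_end <- qe
  out$n_match <- mems$length

  for (i in seq_len(n)) {
    if (scheme$gapped) {
      la <- br$left[i]; lb <- bq$left[i]
      if (la > 0 && lb > 0) {
        a <- .rev_chars(substr(rep_seq, rs[i] - la + 1L, rs[i]))
        b <- .rev_chars(substr(query_seq, qs[i] - lb + 1L, qs[i]))
        r <- cpp_xdrop_gapped(a, b, scheme$match, scheme$mismatch,
                              scheme$gap_open, scheme$gap_extend, scheme$xdrop)
        out$ext_ref_start[i] <- rs[i] - r$steps_a
        out$ext_query_start[i] <- qs[i] - r$steps_b
        out$n_match[i] <- out$n_match[i] + r$matches
      }
      ra <- br$right[i]; rb <- bq$right[i]
      if (ra > 0 && rb > 0) {
        a <- substr(rep_seq, re[i] + 1L, re[i] + ra)
        b <- substr(query_seq, qe[i] + 1L, qe[i] + rb)
        r <- cpp_xdrop_gapped(a, b, scheme$match, scheme$mismatch,
                              scheme$gap_open, scheme$gap_extend, scheme$xdrop)
        out$ext_ref_end[i] <- re[i] + r$steps_a
        out$ext_query_end[i] <- qe[i] + r$steps_b
        out$n_match[i] <- out$n_match[i] + r$matches
      }
    } else {
      lsteps <- min(br$left[i], bq$left[i])
      if (lsteps > 0) {
        a <- .rev_chars(substr(rep_seq, rs[i] - lsteps + 1L, rs[i]))
        b <- .rev_chars(substr(query_seq, qs[i] - lsteps + 1L, qs[i]))
        r <- cpp_xdrop_ungapped(a, b, scheme$match, scheme$mismatch,
                                scheme$xdrop)
        out$ext_ref_start[i] <- rs[i] - r$steps
        out$ext_query_start[i] <- qs[i] - r$steps
        out$n_match[i] <- out$n_match[i] + r$matches
      }
      rsteps <- min(br$right[i], bq$right[i])
      if (rsteps > 0) {
        a <- substr(rep_seq, re[i] + 1L, re[i] + rsteps)
        b <- substr(query_seq, qe[i] + 1L, qe[i] + rsteps)
        r <- cpp_xdrop_ungapped(a, b, scheme$match, scheme$mismatch,
                                scheme$xdrop)
        out$ext_ref_end[i] <- re[i] + r$steps
        out$ext_query_end[i] <- qe[i] + r$steps
        out$n_match[i] <- out$n_match[i] + r$matches
      }
    }
  }
  rownames(out) <- NULL
  out
}

#' Extended-MEM identity between a query and a representative
#'
#' The identity statistic is the total number of matched bases within the
#' extended MEMs divided by the query length (the query is the shorter
#' sequence under long-to-short processing), capped at 1.
#'
#' @param ext extended matches from [extend_matches()] (projections
#'   disjoint).
#' @param l_query query length in bp (>= 1).
#' @param strand strand of the match set ("+" or "-").
#' @return object of class `identity_result`: list with `ememi` (fraction in
#'   0..1), `n_match_total`, `l_query`, `strand`.
#' @export
compute_ememi <- function(ext, l_query, strand = "+") {
  if (!is.numeric(l_query) || l_query < 1) stop("l_query must be >= 1")
  n_match_total <- if (nrow(ext)) sum(ext$n_match) else 0L
  structure(list(ememi = min(1, n_match_total / l_query),
                 n_match_total = as.integer(n_match_total),
                 l_query = as.integer(l_query), strand = strand),
            class = "identity_result")
}

# full refinement pipeline for one (representative, query, strand) MEM set,
# in the matching frame (query already reverse-complemented for "-")
refine_and_score <- function(mems, rep_seq, query_seq, scheme, l_query,
                             strand = "+") {
  mems <- remove_contained(mems)
  mems <- trim_overlaps(mems)
  ext <- extend_matches(mems, rep_seq, query_seq, scheme)
  compute_ememi(ext, l_query, strand)
}
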
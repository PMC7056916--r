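#' Build a sparse suffix array index over representative sequences
#'
#' Concatenates the member sequences (each followed by a terminator that
#' sorts below all nucleotides and never matches across members), builds the
#' full suffix array by prefix doubling, derives the LCP array (Kasai), and
#' keeps every K-th suffix. Construction is deterministic.
#'
#' @param records sequence records (see [seq_records()]); order is preserved
#'   and defines member serial numbers.
#' @param K sparse step, every K-th text position is indexed. The operating
#'   range is 1-4: K = 1 resolves seeds down to any minimum MEM length, while
#'   K = 2-4 trades index size for a higher minimum seed length (searches
#'   require `L >= K`).
#' @return an object of class `suffix_index`.
#' @export
build_index <- function(records, K = 1L) {
  if (!is.numeric(K) || K < 1) stop("sparse step K must be an integer >= 1")
  K <- as.integer(K)
  if (nrow(records) == 0) stop("cannot build an index over zero sequences")
  text <- paste0(records$seq, "$", collapse = "")
  # member k starts after all previous members and their terminators
  starts <- cumsum(c(0L, head(records$length + 1L, -1L)))
  idx <- cpp_build_index(text, K)
  structure(list(
    text = text, K = K, sa = idx$sa, lcp = idx$lcp,
    boundaries = as.integer(starts),
    member_ids = records$id,
    member_lengths = as.integer(records$length),
    member_seqs = records$seq
  ), class = "suffix_index")
}

#' @export
print.suffix_index <- function(x, ...) {
  cat(sprintf("suffix_index: %d members, %d bp text, K=%d, %d sampled suffixes\n",
              length(x$member_ids), nchar(x$text), x$K, length(x$sa)))
  invisible(x)
}

#' Map a text position to its member sequence
#'
#' @param index a `suffix_index`.
#' @param text_pos 0-based position(s) in the concatenated text; terminator
#'   positions are an error.
#' @return `data.frame` with columns `member` (1-based serial number),
#'   `sequence_id`, and `offset` (0-based within the member).
#' @export
locate <- function(index, text_pos) {
  stopifnot(inherits(index, "suffix_index"))
  n <- nchar(index$text)
  if (any(text_pos < 0 | text_pos >= n)) stop("text position out of range")
  mi <- findInterval(text_pos, index$boundaries)
  off <- text_pos - index$boundaries[mi]
  if (any(off >= index$member_lengths[mi])) {
    stop("text position falls on a terminator")
  }
  data.frame(member = mi, sequence_id = index$member_ids[mi],
             offset = as.integer(off), stringsAsFactors = FALSE)
}

#' Longest-prefix search of a pattern in the sampled suffix array
#'
#' Top-down narrowing search. Returns the suffix-array interval `d` of
#' sampled suffixes sharing a prefix of at least `min_len` with the pattern,
#' the subinterval `q` achieving the longest match, and the longest match
#' length. N (and any non-ACGT character) never matches, so the effective
#' pattern stops at the first such character.
#'
#' @param index a `suffix_index`.
#' @param pattern nonempty nucleotide string.
#' @param min_len search threshold (>= 1). When the longest match is shorter
#'   than `min_len`, the `d` interval equals the `q` interval.
#' @return list with `d_start`, `d_end`, `q_start`, `q_end` (1-based, closed
#'   indices into the sampled suffix array), and `match_len`. If no sampled
#'   suffix matches at least one character, all indices are `NA` and
#'   `match_len` is 0 (the empty-interval sentinel).
#' @export
search_longest <- function(index, pattern, min_len = 1L) {
  stopifnot(inherits(index, "suffix_index"), nzchar(pattern))
  min_len <- max(1L, as.integer(min_len))
  r <- cpp_search_longest(index$text, index$sa, pattern, min_len)
  if (r$match_len == 0) {
    return(list(d_start = NA_integer_, d_end = NA_integer_,
                q_start = NA_integer_, q_end = NA_integer_, match_len = 0L))
  }
  if (r$d_lo < 0) {  # threshold depth not reached
    r$d_lo <- r$t_lo; r$d_hi <- r$t_hi
  }
  list(d_start = r$d_lo + 1L, d_end = r$d_hi,
       q_start = r$t_lo + 1L, q_end = r$t_hi,
       match_len = r$match_len)
}
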
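.empty_mems <- function() {
  data.frame(ref_id = character(), ref_start = integer(),
             query_start = integer(), length = integer(),
             strand = character(), stringsAsFactors = FALSE)
}

.query_seq <- function(query) {
  if (is.character(query) && length(query) == 1) return(sanitize_seq(query))
  if (is.data.frame(query) && nrow(query) == 1) return(query$seq)
  stop("query must be a single nucleotide string or a one-row record")
}

.find_mems_strand <- function(index, qseq, L, strand, min_member_length) {
  search_q <- if (strand == "-") reverse_complement(qseq) else qseq
  m <- cpp_find_mems(index$text, index$sa, index$lcp, index$K, search_q,
                     as.integer(L), index$boundaries, index$member_lengths,
                     as.integer(min_member_length))
  if (nrow(m) == 0) return(.empty_mems())
  mi <- findInterval(m[, "text_pos"], index$boundaries)
  qs <- m[, "query_pos"]
  if (strand == "-") {
    # report on the forward query frame
    qs <- nchar(qseq) - (qs + m[, "length"])
  }
  out <- data.frame(ref_id = index$member_ids[mi],
                    ref_start = as.integer(m[, "text_pos"] - index$boundaries[mi]),
                    query_start = as.integer(qs),
                    length = as.integer(m[, "length"]),
                    strand = strand, stringsAsFactors = FALSE)
  out[order(match(out$ref_id, index$member_ids), out$ref_start,
            out$query_start), , drop = FALSE]
}

#' Enumerate maximal exact matches between a query and indexed members
#'
#' Finds every MEM of length at least `L` between the query and each indexed
#' member, on the forward strand and (optionally) the reverse strand.
#' Coordinates are 0-based; minus-strand hits are mapped back to the forward
#' query frame (`query_start = |query| - (rc_start + length)`). N never
#' matches anything, and no match crosses a member boundary. The result is
#' independent of the index's sparse step K (valid combinations require
#' `L >= K`).
#'
#' @param index a `suffix_index`.
#' @param query a single nucleotide string or a one-row sequence record.
#' @param L minimum MEM length (>= 1 and >= the index's sparse step).
#' @param both_strands also search the reverse complement of the query.
#' @return `data.frame` with columns ref_id, ref_start, query_start, length,
#'   strand; no duplicates.
#' @export
find_mems <- function(index, query, L, both_strands = FALSE) {
  collect_mems_filtered(index, query, L, min_member_length = 0L,
                        both_strands = both_strands)
}

#' Enumerate MEMs, discarding hits on members shorter than a cutoff
#'
#' Identical to [find_mems()] except that MEMs located on members shorter
#' than `min_member_length` are discarded during collection (they are never
#' emitted), which is how the clustering engine restricts comparisons to
#' representatives at least as long as the query. `min_member_length = 0`
#' disables the filter.
#'
#' @inheritParams find_mems
#' @param min_member_length discard MEMs on members shorter than this.
#' @return as [find_mems()].
#' @export
collect_mems_filtered <- function(index, query, L, min_member_length,
                                  both_strands = FALSE) {
  stopifnot(inherits(index, "suffix_index"), L >= 1)
  qseq <- .query_seq(query)
  if (!nzchar(qseq)) return(.empty_mems())
  out <- .find_mems_strand(index, qseq, L, "+", min_member_length)
  if (both_strands) {
    out <- rbind(out, .find_mems_strand(index, qseq, L, "-", min_member_length))
  }
  rownames(out) <- NULL
  out
}

#' Brute-force MEM enumeration (quadratic oracle)
#'
#' Enumerates all maximal exact matches of length >= `L` between two strings
#' by scanning every diagonal for runs of matching characters. N never
#' matches. Definitionally complete; intended as an independent reference for
#' small inputs (the diagonal scan touches |ref| x |query| cells).
#'
#' @param ref,query nucleotide strings.
#' @param L minimum MEM length.
#' @return `data.frame` with columns ref_start, query_start, length
#'   (0-based starts), sorted by ref_start then query_start.
#' @export
brute_force_mems <- function(ref, query, L) {
  a <- strsplit(ref, "")[[1]]
  b <- strsplit(query, "")[[1]]
  n <- length(a); m <- length(b)
  out <- list()
  for (d in (-(m - 1)):(n - 1)) {
    # diagonal: ref index = query index + d
    qi <- max(0L, -d):(min(m - 1L, n - 1L - d))
    ri <- qi + d
    eq <- a[ri + 1L] == b[qi + 1L] & a[ri + 1L] %in% BASES
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= L
    if (any(keep)) {
      out[[length(out) + 1L]] <- data.frame(
        ref_start = ri[starts[keep]],
        query_start = qi[starts[keep]],
        length = r$lengths[keep])
    }
  }
  if (!length(out)) {
    return(data.frame(ref_start = integer(), query_start = integer(),
                      length = integer()))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$ref_start, res$query_start), , drop = FALSE]
  rownames(res) <- NULL
  res
}
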
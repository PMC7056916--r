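#' Clustering parameters
#'
#' @param minlen minimum MEM length L in bp (default 21: under a uniform
#'   Bernoulli null no chance match materially longer than 21 bp is expected
#'   between Mbp-scale random genomes, so shorter seeds are mostly spurious).
#' @param memiden identity threshold in percent (0 < memiden <= 100).
#' @param sparse_k sparse suffix-array step K (>= 1; searches need
#'   `minlen >= sparse_k`).
#' @param chunk_mb block size in Mbp of representative text per suffix array.
#' @param both_strands compare both strands of the query.
#' @param gapped allow gaps during seed extension.
#' @param rebuild rebuild the block suffix array over all accumulated
#'   representatives every `rebuild_interval` promotions; when off, newly
#'   promoted representatives stay in a side buffer for the rest of the
#'   block. Either setting yields the same clustering.
#' @param rebuild_interval promotions between rebuilds when `rebuild` is on.
#' @param threads number of worker processes for the inter-block screening
#'   pass; the clustering result is identical for every value.
#' @param scheme a [score_scheme()]; its `gapped` flag is overridden by the
#'   `gapped` argument.
#' @return object of class `clustering_params`.
#' @export
clustering_params <- function(minlen = 21L, memiden = 90, sparse_k = 1L,
                              chunk_mb = 400, both_strands = FALSE,
                              gapped = FALSE, rebuild = TRUE,
                              rebuild_interval = 64L, threads = 1L,
                              scheme = score_scheme()) {
  stopifnot(minlen >= 1, memiden > 0, memiden <= 100, sparse_k >= 1,
            chunk_mb > 0, threads >= 1, rebuild_interval >= 1)
  if (minlen < sparse_k) {
    stop("minlen (", minlen, ") must be >= sparse_k (", sparse_k, ")")
  }
  scheme$gapped <- isTRUE(gapped)
  structure(list(minlen = as.integer(minlen), memiden = as.numeric(memiden),
                 sparse_k = as.integer(sparse_k), chunk_mb = chunk_mb,
                 both_strands = isTRUE(both_strands), gapped = isTRUE(gapped),
                 rebuild = isTRUE(rebuild),
                 rebuild_interval = as.integer(rebuild_interval),
                 threads = as.integer(threads), scheme = scheme),
            class = "clustering_params")
}

#' Partition length-sorted records into blocks
#'
#' Greedy fill: consecutive records accumulate into a block until the total
#' length would exceed `chunk_mb` Mbp; a single record larger than the chunk
#' gets its own block.
#'
#' @param records sequence records sorted long-to-short.
#' @param chunk_mb block capacity in Mbp.
#' @return list of record `data.frame`s, order preserved.
#' @export
partition_blocks <- function(records, chunk_mb) {
  stopifnot(chunk_mb > 0)
  n <- nrow(records)
  if (n == 0) return(list())
  cap <- chunk_mb * 1e6
  blocks <- list()
  start <- 1L
  acc <- 0
  for (i in seq_len(n)) {
    if (i > start && acc + records$length[i] > cap) {
      blocks[[length(blocks) + 1L]] <- records[start:(i - 1L), , drop = FALSE]
      start <- i
      acc <- 0
    }
    acc <- acc + records$length[i]
  }
  blocks[[length(blocks) + 1L]] <- records[start:n, , drop = FALSE]
  blocks
}

# evaluate one query against one index: first member (in index order, i.e.
# representative discovery order) whose best-strand eMEMi meets the
# threshold wins. Returns NULL if none does.
.screen_against_index <- function(qrec, index, params) {
  mems <- collect_mems_filtered(index, qrec, params$minlen,
                                min_member_length = qrec$length,
                                both_strands = params$both_strands)
  if (nrow(mems) == 0) return(NULL)
  thr <- params$memiden / 100
  lq <- qrec$length
  q_rc <- if (params$both_strands) reverse_complement(qrec$seq) else NULL
  for (mi in seq_along(index$member_ids)) {
    mid <- index$member_ids[mi]
    sub <- mems[mems$ref_id == mid, , drop = FALSE]
    if (nrow(sub) == 0) next
    best <- NULL
    for (st in unique(sub$strand)) {
      ss <- sub[sub$strand == st, , drop = FALSE]
      if (st == "-") {
        # refine in the reverse-complement frame, where matches are collinear
        ss$query_start <- lq - (ss$query_start + ss$length)
        qseq <- q_rc
      } else {
        qseq <- qrec$seq
      }
      res <- refine_and_score(ss[, c("ref_start", "query_start", "length")],
                              index$member_seqs[mi], qseq, params$scheme,
                              lq, st)
      if (is.null(best) || res$ememi > best$ememi) best <- res
    }
    if (best$ememi >= thr) {
      return(list(rep_id = mid, identity = best$ememi, strand = best$strand))
    }
  }
  NULL
}

#' Decide whether a query is redundant or a new representative
#'
#' Runs the filtered MEM collection, per-representative per-strand
#' refinement and extension, and the extended-MEM identity against the
#' indexed representatives; the query is assigned to the first
#' representative, in discovery order, whose best-strand identity meets the
#' threshold, and is otherwise promoted.
#'
#' @param query a one-row sequence record.
#' @param index a `suffix_index` over current representatives, all at least
#'   as long as the query.
#' @param params a [clustering_params()].
#' @return list with `redundant` (logical) and, when redundant, `rep_id`,
#'   `identity`, `strand`.
#' @export
assign_or_promote <- function(query, index, params) {
  hit <- .screen_against_index(query, index, params)
  if (is.null(hit)) list(redundant = FALSE)
  else c(list(redundant = TRUE), hit)
}

# internal: greedy intra-block pass over `block` records (already sorted).
# Representatives live in two places: a main index (rebuilt every
# `rebuild_interval` promotions when params$rebuild) and a buffer index over
# representatives promoted since the last rebuild. Candidate order is main
# members then buffer members, which is exactly discovery order.
.intra_block <- function(block, params, verbose = FALSE) {
  n <- nrow(block)
  assignments <- list()
  main_records <- block[0, , drop = FALSE]
  buffer_records <- block[0, , drop = FALSE]
  main_index <- NULL
  buffer_index <- NULL
  for (i in seq_len(n)) {
    qrec <- block[i, , drop = FALSE]
    hit <- NULL
    if (!is.null(main_index)) {
      hit <- .screen_against_index(qrec, main_index, params)
    }
    if (is.null(hit) && !is.null(buffer_index)) {
      hit <- .screen_against_index(qrec, buffer_index, params)
    }
    if (!is.null(hit)) {
      assignments[[length(assignments) + 1L]] <-
        data.frame(id = qrec$id, rep_id = hit$rep_id, identity = hit$identity,
                   strand = hit$strand, length = qrec$length,
                   stringsAsFactors = FALSE)
      if (verbose) {
        message(sprintf("  %s -> %s (%.4f, %s)", qrec$id, hit$rep_id,
                        hit$identity, hit$strand))
      }
    } else {
      buffer_records <- rbind(buffer_records, qrec)
      buffer_index <- build_index(buffer_records, params$sparse_k)
      if (params$rebuild &&
          nrow(buffer_records) >= params$rebuild_interval) {
        main_records <- rbind(main_records, buffer_records)
        main_index <- build_index(main_records, params$sparse_k)
        buffer_records <- block[0, , drop = FALSE]
        buffer_index <- NULL
      }
      if (verbose) message(sprintf("  %s -> representative", qrec$id))
    }
  }
  reps <- rbind(main_records, buffer_records)
  assignments <- if (length(assignments)) do.call(rbind, assignments) else
    data.frame(id = character(), rep_id = character(), identity = numeric(),
               strand = character(), length = integer(),
               stringsAsFactors = FALSE)
  list(assignments = assignments, representatives = reps)
}

#' Cluster one block of sequences
#'
#' Sequentially tests each sequence of the block (sorted long-to-short)
#' against the block's accumulated representatives; sequences may first be
#' screened against an optional carried index of earlier representatives.
#'
#' @param block sequence records sorted long-to-short.
#' @param carried_index optional `suffix_index` over representatives from
#'   earlier blocks (tested first, preserving discovery order).
#' @param params a [clustering_params()].
#' @return list with `assignments` (data.frame id, rep_id, identity, strand,
#'   length) and `representatives` (record data.frame in discovery order).
#' @export
cluster_block <- function(block, carried_index = NULL, params) {
  if (!is.null(carried_index)) {
    pre <- lapply(seq_len(nrow(block)), function(i) {
      .screen_against_index(block[i, , drop = FALSE], carried_index, params)
    })
    hit <- !vapply(pre, is.null, logical(1))
    carried_assign <- do.call(rbind, lapply(which(hit), function(i) {
      data.frame(id = block$id[i], rep_id = pre[[i]]$rep_id,
                 identity = pre[[i]]$identity, strand = pre[[i]]$strand,
                 length = block$length[i], stringsAsFactors = FALSE)
    }))
    res <- .intra_block(block[!hit, , drop = FALSE], params)
    res$assignments <- rbind(carried_assign, res$assignments)
    return(res)
  }
  .intra_block(block, params)
}

#' Greedy incremental clustering of all sequences
#'
#' Partitions the length-sorted records into blocks, clusters each block with
#' the greedy intra-block pass, and after each block screens all still
#' unassigned sequences of later blocks against the block's representatives
#' (so every sequence is eventually compared, in rank order, to all earlier
#' representatives). The result is deterministic and identical for every
#' `threads` value and for any block partition.
#'
#' @param records sequence records, already filtered and sorted
#'   (see [filter_and_sort()]).
#' @param params a [clustering_params()].
#' @param verbose log per-sequence decisions.
#' @return object of class `cluster_set`: list of clusters (each with
#'   `representative`, `rep_length`, `rep_seq`, and a member data.frame with
#'   id, length, identity, strand) plus the parameters used.
#' @export
cluster_all <- function(records, params = clustering_params(),
                        verbose = FALSE) {
  stopifnot(inherits(params, "clustering_params"))
  if (nrow(records) > 1 &&
      any(diff(records$length) > 0)) {
    stop("records must be sorted long-to-short; run filter_and_sort() first")
  }
  blocks <- partition_blocks(records, params$chunk_mb)
  assigned <- stats::setNames(vector("list", nrow(records)), records$id)
  rep_ids <- character(0)
  rep_rows <- list()

  for (b in seq_along(blocks)) {
    blk <- blocks[[b]]
    blk_todo <- blk[vapply(blk$id, function(id) is.null(assigned[[id]]),
                           logical(1)), , drop = FALSE]
    if (verbose) message(sprintf("block %d: %d sequences", b, nrow(blk_todo)))
    res <- .intra_block(blk_todo, params, verbose = verbose)
    for (k in seq_len(nrow(res$assignments))) {
      a <- res$assignments[k, , drop = FALSE]
      assigned[[a$id]] <- a
    }
    rep_ids <- c(rep_ids, res$representatives$id)
    rep_rows[[b]] <- res$representatives

    # inter-block screening of later, still-unassigned sequences against
    # this block's representatives (independent searches; parallelizable)
    if (b < length(blocks) && nrow(res$representatives) > 0) {
      later <- do.call(rbind, blocks[(b + 1):length(blocks)])
      later <- later[vapply(later$id, function(id) is.null(assigned[[id]]),
                            logical(1)), , drop = FALSE]
      if (nrow(later) > 0) {
        idx <- build_index(res$representatives, params$sparse_k)
        screen_one <- function(i) {
          .screen_against_index(later[i, , drop = FALSE], idx, params)
        }
        hits <- if (params$threads > 1) {
          parallel::mclapply(seq_len(nrow(later)), screen_one,
                             mc.cores = params$threads)
        } else {
          lapply(seq_len(nrow(later)), screen_one)
        }
        for (i in seq_len(nrow(later))) {
          if (!is.null(hits[[i]])) {
            assigned[[later$id[i]]] <- data.frame(
              id = later$id[i], rep_id = hits[[i]]$rep_id,
              identity = hits[[i]]$identity, strand = hits[[i]]$strand,
              length = later$length[i], stringsAsFactors = FALSE)
          }
        }
      }
    }
  }

  reps <- do.call(rbind, rep_rows)
  amat <- do.call(rbind, assigned[!vapply(assigned, is.null, logical(1))])
  clusters <- lapply(seq_len(nrow(reps)), function(i) {
    rid <- reps$id[i]
    mb <- if (!is.null(amat) && nrow(amat)) {
      amat[amat$rep_id == rid, c("id", "length", "identity", "strand"),
           drop = FALSE]
    } else {
      data.frame(id = character(), length = integer(), identity = numeric(),
                 strand = character(), stringsAsFactors = FALSE)
    }
    rownames(mb) <- NULL
    list(representative = rid, rep_length = reps$length[i],
         rep_seq = reps$seq[i], members = mb)
  })
  structure(list(clusters = clusters, params = params), class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  nmem <- sum(vapply(x$clusters, function(cl) nrow(cl$members), integer(1)))
  cat(sprintf("cluster_set: %d clusters over %d sequences (memiden %.1f%%, minlen %d, K %d)\n",
              length(x$clusters), length(x$clusters) + nmem,
              x$params$memiden, x$params$minlen, x$params$sparse_k))
  invisible(x)
}

#' Cluster membership as a flat table
#'
#' @param clusters a `cluster_set`.
#' @return `data.frame` with columns cluster (1-based), id, is_rep,
#'   identity, strand.
#' @export
cluster_table <- function(clusters) {
  out <- lapply(seq_along(clusters$clusters), function(i) {
    cl <- clusters$clusters[[i]]
    rbind(data.frame(cluster = i, id = cl$representative, is_rep = TRUE,
                     identity = 1, strand = "+", stringsAsFactors = FALSE),
          if (nrow(cl$members)) {
            data.frame(cluster = i, id = cl$members$id, is_rep = FALSE,
                       identity = cl$members$identity,
                       strand = cl$members$strand, stringsAsFactors = FALSE)
          })
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
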
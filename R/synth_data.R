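# run expr with a private RNG stream: the global .Random.seed is restored
# afterwards, so generators are deterministic per seed and leak no state
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generate a uniform-random nucleotide sequence
#'
#' Bases are i.i.d. uniform over A/C/G/T (the Bernoulli null model under
#' which chance MEM lengths are calibrated). Deterministic per
#' (length, seed); the global RNG state is untouched.
#'
#' @param length sequence length in bp (>= 1).
#' @param seed integer seed.
#' @return a nucleotide string.
#' @export
random_genome <- function(length, seed) {
  stopifnot(length >= 1)
  .with_seed(seed, paste(sample(BASES, length, replace = TRUE), collapse = ""))
}

#' Mutate a sequence with substitutions and short indels
#'
#' Each position is substituted to a different base with probability
#' `sub_rate`; with probability `indel_rate` an indel event of length 1-3
#' starts at the position (insertion before it or deletion from it, equally
#' likely). Deterministic per seed.
#'
#' @param seq nucleotide string.
#' @param sub_rate per-position substitution probability, in [0, 0.5).
#' @param indel_rate per-position indel event probability, in [0, 0.5).
#' @param seed integer seed.
#' @return list with `seq` (mutated string), `n_sub`, `n_ins_bases`,
#'   `n_del_bases`, and `identity_est` = (L - n_sub - n_del_bases)/L, the
#'   planted-identity bookkeeping estimate.
#' @export
mutate_genome <- function(seq, sub_rate, indel_rate, seed) {
  stopifnot(sub_rate >= 0, sub_rate < 0.5, indel_rate >= 0, indel_rate < 0.5)
  x <- strsplit(seq, "")[[1]]
  n <- length(x)
  .with_seed(seed, {
    sub_at <- which(stats::runif(n) < sub_rate)
    if (length(sub_at)) {
      shift <- sample(1:3, length(sub_at), replace = TRUE)
      x[sub_at] <- BASES[(match(x[sub_at], BASES) - 1L + shift) %% 4L + 1L]
    }
    keep <- rep(TRUE, n)
    ins <- vector("list", n)
    n_ins <- 0L
    if (indel_rate > 0) {
      ev_at <- which(stats::runif(n) < indel_rate)
      for (i in ev_at) {
        len <- sample(1:3, 1)
        if (stats::runif(1) < 0.5) {
          ins[[i]] <- sample(BASES, len, replace = TRUE)
          n_ins <- n_ins + len
        } else {
          keep[i:min(n, i + len - 1L)] <- FALSE
        }
      }
    }
    n_del <- sum(!keep)
    pieces <- character(0)
    if (n_ins > 0 || n_del > 0) {
      out <- vector("list", n)
      for (i in seq_len(n)) {
        out[[i]] <- c(ins[[i]], if (keep[i]) x[i])
      }
      pieces <- unlist(out)
    } else {
      pieces <- x
    }
    # substitutions landing on deleted positions don't count against identity
    n_sub_eff <- sum(keep[sub_at])
    list(seq = paste(pieces, collapse = ""),
         n_sub = n_sub_eff, n_ins_bases = n_ins, n_del_bases = n_del,
         identity_est = (n - n_sub_eff - n_del) / n)
  })
}

#' Build a synthetic benchmark with known redundancy structure
#'
#' Generates `n_groups` independent uniform-random representative genomes;
#' each receives `copies_per_group` redundant copies, taken as a random
#' window of the representative (so the representative is the unique longest
#' group member) and mutated to approximately `identity_target`;
#' `n_singletons` unrelated random sequences are added. Fully deterministic
#' per seed.
#'
#' @param n_groups number of planted redundancy groups.
#' @param copies_per_group redundant copies per group (besides the
#'   representative).
#' @param rep_length_range representative length range in bp, e.g.
#'   `c(3000, 6000)`.
#' @param identity_target planted identity of copies, in (0.5, 1].
#' @param n_singletons number of unrelated sequences.
#' @param seed integer seed.
#' @param indel_rate per-position indel rate for copies (default 0:
#'   substitution-only mutation at rate `1 - identity_target`).
#' @param truncate_range copies span this fraction range of the
#'   representative.
#' @param out_prefix if non-NULL, write `<prefix>.fasta` and a
#'   `<prefix>.truth.tsv` with columns id, group_id, planted_identity,
#'   is_representative.
#' @return object of class `benchmark_truth`: list with `records` (sequence
#'   records in generation order) and `truth` (the table above).
#' @export
make_benchmark <- function(n_groups, copies_per_group,
                           rep_length_range = c(3000, 6000),
                           identity_target = 0.95, n_singletons = 0,
                           seed = 1, indel_rate = 0,
                           truncate_range = c(0.7, 0.95),
                           out_prefix = NULL) {
  stopifnot(identity_target > 0.5, identity_target <= 1,
            n_groups >= 1, copies_per_group >= 0)
  sub_rate <- max(0, 1 - identity_target - 2 * indel_rate)
  ids <- seqs <- groups <- character(0)
  ident <- numeric(0)
  is_rep <- logical(0)
  .with_seed(seed, {
    for (g in seq_len(n_groups)) {
      gid <- sprintf("G%02d", g)
      len <- sample(rep_length_range[1]:rep_length_range[2], 1)
      rep_seq <- paste(sample(BASES, len, replace = TRUE), collapse = "")
      ids <- c(ids, paste0(gid, "_rep")); seqs <- c(seqs, rep_seq)
      groups <- c(groups, gid); ident <- c(ident, 1); is_rep <- c(is_rep, TRUE)
      for (k in seq_len(copies_per_group)) {
        frac <- stats::runif(1, truncate_range[1], truncate_range[2])
        wlen <- max(1L, as.integer(round(frac * len)))
        start <- sample(seq_len(len - wlen + 1L), 1)
        window <- substr(rep_seq, start, start + wlen - 1L)
        mut <- mutate_genome(window, sub_rate, indel_rate,
                             seed = sample.int(.Machine$integer.max - 1L, 1))
        ids <- c(ids, sprintf("%s_c%d", gid, k))
        seqs <- c(seqs, mut$seq)
        groups <- c(groups, gid)
        ident <- c(ident, mut$identity_est)
        is_rep <- c(is_rep, FALSE)
      }
    }
    for (s in seq_len(n_singletons)) {
      len <- sample(rep_length_range[1]:rep_length_range[2], 1)
      ids <- c(ids, sprintf("S%02d", s))
      seqs <- c(seqs, paste(sample(BASES, len, replace = TRUE), collapse = ""))
      groups <- c(groups, sprintf("singleton_%02d", s))
      ident <- c(ident, 1)
      is_rep <- c(is_rep, TRUE)
    }
  })
  records <- seq_records(ids, seqs)
  truth <- data.frame(id = ids, group_id = groups, planted_identity = ident,
                      is_representative = is_rep, stringsAsFactors = FALSE)
  if (!is.null(out_prefix)) {
    set <- Biostrings::BStringSet(records$seq)
    names(set) <- records$id
    Biostrings::writeXStringSet(set, paste0(out_prefix, ".fasta"))
    utils::write.table(truth, paste0(out_prefix, ".truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  structure(list(records = records, truth = truth), class = "benchmark_truth")
}
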
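BASES <- c("A", "C", "G", "T")
# IUPAC ambiguity codes other than N collapse to N: the MEM alphabet must be
# small and unknown bases must never produce exact matches.
AMBIG <- "RYSWKMBDHV"

#' Construct a set of sequence records
#'
#' A sequence record set is a plain `data.frame` with columns `id`, `seq`,
#' `length`, and `input_rank` (0-based position in the input). Sequences are
#' sanitized to uppercase A/C/G/T/N; `U` is converted to `T` and IUPAC
#' ambiguity codes other than `N` become `N`.
#'
#' @param ids character vector of sequence identifiers.
#' @param seqs character vector of nucleotide sequences.
#' @return a `data.frame` with one row per sequence.
#' @export
seq_records <- function(ids, seqs) {
  stopifnot(length(ids) == length(seqs))
  if (length(ids) == 0) {
    return(data.frame(id = character(), seq = character(),
                      length = integer(), input_rank = integer(),
                      stringsAsFactors = FALSE))
  }
  if (anyDuplicated(ids)) stop("duplicate sequence ids in input")
  seqs <- sanitize_seq(seqs)
  data.frame(id = as.character(ids), seq = seqs,
             length = nchar(seqs), input_rank = seq_along(ids) - 1L,
             stringsAsFactors = FALSE)
}

sanitize_seq <- function(x) {
  x <- toupper(x)
  x <- chartr("U", "T", x)
  x <- chartr(AMBIG, strrep("N", nchar(AMBIG)), x)
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    stop("sequence ", which(bad)[1],
         " contains characters outside the A/C/G/T/N/IUPAC alphabet")
  }
  x
}

#' Read a FASTA file into sequence records
#'
#' Reads plain or gzip-compressed FASTA. Lowercase letters are uppercased and
#' IUPAC ambiguity codes other than N are mapped to N. Records keep their
#' file order through `input_rank`.
#'
#' @param path path to a FASTA (optionally gzipped) file.
#' @return sequence records as from [seq_records()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) return(seq_records(character(), character()))
  ids <- names(set)
  ids <- sub("\\s.*$", "", ids)  # header token up to first whitespace
  seqs <- as.character(set)
  empty_id <- !nzchar(ids)
  if (any(empty_id)) {
    stop("malformed FASTA: record ", which(empty_id)[1], " has an empty header")
  }
  empty_seq <- !nzchar(seqs)
  if (any(empty_seq)) {
    stop("malformed FASTA: record ", which(empty_seq)[1],
         " (", ids[which(empty_seq)[1]], ") has an empty sequence")
  }
  seq_records(ids, seqs)
}

#' Filter short sequences and sort long-to-short
#'
#' Removes sequences shorter than `min_keep` (default 21 bp, below which no
#' seed of the default minimum MEM length can exist) and sorts the remainder
#' by decreasing length, breaking ties by input order. Idempotent.
#'
#' @param records sequence records.
#' @param min_keep minimum length (bp) to keep; must be >= 1.
#' @return the filtered, sorted records.
#' @export
filter_and_sort <- function(records, min_keep = 21L) {
  stopifnot(is.numeric(min_keep), min_keep >= 1)
  records <- records[records$length >= min_keep, , drop = FALSE]
  records <- records[order(-records$length, records$input_rank), , drop = FALSE]
  rownames(records) <- NULL
  records
}

#' Reverse complement of a nucleotide string
#'
#' @param seq string over A/C/G/T/N.
#' @return the reverse complement; N maps to N.
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1)
  if (grepl("[^ACGTN]", seq)) {
    stop("reverse_complement: sequence contains characters outside A/C/G/T/N")
  }
  if (!nzchar(seq)) return(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Write clustering results
#'
#' Writes three files: `<prefix>.rep.fasta` with the representative
#' sequences, `<prefix>.clstr` in the CD-HIT membership dialect (one
#' `>Cluster n` header per cluster, one indented line per member carrying its
#' length and either `*` for the representative or `at <strand>/<identity>%`),
#' and `<prefix>.tsv`, a tab-separated summary with columns cluster_id,
#' representative_id, member_id, identity_pct, strand.
#'
#' @param clusters a `cluster_set` as returned by [cluster_all()].
#' @param out_prefix output path prefix.
#' @return invisibly, the paths written.
#' @export
write_cluster_output <- function(clusters, out_prefix) {
  stopifnot(inherits(clusters, "cluster_set"))
  dir <- dirname(out_prefix)
  if (!dir.exists(dir)) stop("output directory does not exist: ", dir)
  fa_path <- paste0(out_prefix, ".rep.fasta")
  clstr_path <- paste0(out_prefix, ".clstr")
  tsv_path <- paste0(out_prefix, ".tsv")

  cl <- clusters$clusters
  if (length(cl) == 0) {
    file.create(fa_path); file.create(clstr_path)
    writeLines("cluster_id\trepresentative_id\tmember_id\tidentity_pct\tstrand",
               tsv_path)
    return(invisible(c(fa_path, clstr_path, tsv_path)))
  }

  reps <- Biostrings::BStringSet(vapply(cl, function(x) x$rep_seq, ""))
  names(reps) <- vapply(cl, function(x) x$representative, "")
  Biostrings::writeXStringSet(reps, fa_path)

  lines <- character(0)
  tsv <- c("cluster_id\trepresentative_id\tmember_id\tidentity_pct\tstrand")
  for (i in seq_along(cl)) {
    x <- cl[[i]]
    lines <- c(lines, sprintf(">Cluster %d", i - 1L),
               sprintf("0\t%dnt, >%s... *", x$rep_length, x$representative))
    tsv <- c(tsv, sprintf("%d\t%s\t%s\t%.4f\t%s", i - 1L, x$representative,
                          x$representative, 100, "+"))
    mb <- x$members
    if (nrow(mb)) {
      lines <- c(lines, sprintf("%d\t%dnt, >%s... at %s/%.2f%%",
                                seq_len(nrow(mb)), mb$length, mb$id,
                                mb$strand, 100 * mb$identity))
      tsv <- c(tsv, sprintf("%d\t%s\t%s\t%.4f\t%s", i - 1L, x$representative,
                            mb$id, 100 * mb$identity, mb$strand))
    }
  }
  writeLines(lines, clstr_path)
  writeLines(tsv, tsv_path)
  invisible(c(fa_path, clstr_path, tsv_path))
}

#' Parse a CD-HIT style .clstr file
#'
#' Round-trip companion of [write_cluster_output()].
#'
#' @param path path to a `.clstr` file.
#' @return `data.frame` with columns cluster, id, length, is_rep, identity
#'   (fraction; NA for representatives), strand.
#' @export
parse_clstr <- function(path) {
  lines <- readLines(path)
  out <- list()
  cluster <- NA_integer_
  for (ln in lines) {
    if (startsWith(ln, ">Cluster")) {
      cluster <- as.integer(sub("^>Cluster\\s+", "", ln))
    } else if (nzchar(ln)) {
      m <- regmatches(ln, regexec(
        "^\\d+\t(\\d+)nt, >(.*)\\.\\.\\. (\\*|at ([+-])/([0-9.]+)%)$", ln))[[1]]
      if (length(m) == 0) stop("unparseable .clstr line: ", ln)
      is_rep <- m[4] == "*"
      out[[length(out) + 1L]] <- data.frame(
        cluster = cluster, id = m[3], length = as.integer(m[2]),
        is_rep = is_rep,
        identity = if (is_rep) NA_real_ else as.numeric(m[6]) / 100,
        strand = if (is_rep) "+" else m[5],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(cluster = integer(), id = character(),
                      length = integer(), is_rep = logical(),
                      identity = numeric(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
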
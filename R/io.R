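#' Read a FASTA file
#'
#' Thin wrapper around seqinr's parser: preserves record order, ids and
#' residue case (lower-case letters carry soft-masking information),
#' tolerates wrapped lines and trailing whitespace.
#'
#' @param path FASTA file
#' @param toupper force sequences to upper case (default `FALSE`)
#' @return named character vector of sequences
#' @export
read_fasta <- function(path, toupper = FALSE) {
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  if (length(recs) == 0L) stop("no records in ", path)
  seqs <- trimws(unlist(recs, use.names = FALSE))
  ids <- vapply(recs, attr, character(1), "name")
  if (anyDuplicated(ids)) stop("duplicate sequence ids in ", path)
  if (any(nchar(seqs) == 0L)) stop("empty record in ", path)
  if (toupper) seqs <- base::toupper(seqs)
  names(seqs) <- ids
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector
#' @param path output path
#' @param width line-wrap width
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  if (is.null(names(seqs))) stop("sequences must be named")
  seqinr::write.fasta(as.list(unname(seqs)), names = names(seqs),
                      file.out = path, nbchar = width, as.string = TRUE)
  invisible(path)
}

#' Write / read hit tables
#'
#' Tab-separated with a header (`query_id`, `target_id`, `score`,
#' `n_matches`); scores keep full double precision so round-trips are
#' stable.
#'
#' @param hits hit data.frame from [search_sequences()]
#' @param path file path
#' @export
write_hits <- function(hits, path) {
  out <- hits
  out$score <- sprintf("%.12g", out$score)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hits
#' @export
read_hits <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(query_id = "character",
                                         target_id = "character"))
  need <- c("query_id", "target_id", "score", "n_matches")
  if (!all(need %in% names(df)))
    stop("hit file missing columns: ", paste(setdiff(need, names(df)), collapse = ", "))
  bad <- which(!is.finite(df$score))
  if (length(bad)) stop("malformed score at line ", bad[1] + 1L)
  df
}

#' Write / read training-pair tables
#'
#' Tab-separated records `id_a  id_b  seq_a  seq_b  cols` where `cols` is the
#' 1-based aligned column list `"i:j,i:j,..."`.
#'
#' @param pairs list of training pairs (see [make_training_batch()])
#' @param path file path
#' @export
write_pairs <- function(pairs, path) {
  lines <- vapply(pairs, function(p) {
    cols <- as.matrix(p$cols)
    paste(p$id_a, p$id_b, p$seq_a, p$seq_b,
          paste(sprintf("%d:%d", cols[, 1], cols[, 2]), collapse = ","),
          sep = "\t")
  }, character(1))
  writeLines(c("id_a\tid_b\tseq_a\tseq_b\tcols", lines), path)
  invisible(path)
}

#' @rdname write_pairs
#' @export
read_pairs <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 1L || lines[1] != "id_a\tid_b\tseq_a\tseq_b\tcols")
    stop("not a training-pairs file: ", path)
  lapply(seq_along(lines[-1]), function(i) {
    f <- strsplit(lines[i + 1L], "\t", fixed = TRUE)[[1]]
    if (length(f) != 5L) stop("malformed pair record at line ", i + 1L)
    ij <- do.call(rbind, lapply(strsplit(f[5], ",")[[1]], function(s)
      as.integer(strsplit(s, ":")[[1]])))
    list(id_a = f[1], id_b = f[2], seq_a = f[3], seq_b = f[4], cols = ij)
  })
}

#' Extract aligned columns from a gapped sequence pair
#'
#' Takes the two rows of a pairwise alignment (gaps as `-`) and returns the
#' 1-based residue index pairs that share a column, plus the ungapped
#' sequences.
#'
#' @param aln_a,aln_b aligned strings of equal length
#' @return list with `seq_a`, `seq_b`, `cols`
#' @export
alignment_to_pair <- function(aln_a, aln_b) {
  ca <- strsplit(aln_a, "")[[1]]; cb <- strsplit(aln_b, "")[[1]]
  if (length(ca) != length(cb)) stop("aligned rows differ in length")
  ia <- cumsum(ca != "-"); ib <- cumsum(cb != "-")
  both <- ca != "-" & cb != "-"
  list(seq_a = gsub("-", "", aln_a, fixed = TRUE),
       seq_b = gsub("-", "", aln_b, fixed = TRUE),
       cols = cbind(ia[both], ib[both]))
}

#' Read training pairs from an aligned FASTA
#'
#' Consecutive records are taken two at a time as the gapped rows of a
#' pairwise alignment; aligned columns are extracted with
#' [alignment_to_pair()].
#'
#' @param path FASTA file with an even number of records
#' @return list of training pairs (see [make_training_batch()])
#' @export
read_aligned_fasta <- function(path) {
  recs <- read_fasta(path)
  if (length(recs) %% 2L != 0L)
    stop("aligned FASTA must contain an even number of records")
  lapply(seq_len(length(recs) / 2L), function(i) {
    a <- recs[[2L * i - 1L]]; b <- recs[[2L * i]]
    p <- alignment_to_pair(a, b)
    list(id_a = names(recs)[2L * i - 1L], id_b = names(recs)[2L * i],
         seq_a = p$seq_a, seq_b = p$seq_b, cols = p$cols)
  })
}

#' Write / read an embedding store
#'
#' A single-file container holding one named `n x d` matrix per sequence
#' (RDS serialization of a named list).
#'
#' @param embeddings named list of embedding matrices
#' @param path file path
#' @export
write_embeddings <- function(embeddings, path) {
  if (is.null(names(embeddings))) stop("embeddings must be named")
  saveRDS(embeddings, path)
  invisible(path)
}

#' @rdname write_embeddings
#' @export
read_embeddings <- function(path) {
  emb <- readRDS(path)
  if (!is.list(emb) || is.null(names(emb))) stop("not an embedding store")
  emb
}

#' Write / read truth tables
#'
#' @param truth truth-table data.frame (`query_id`, `target_id`, `label`
#'   and/or `evalue`)
#' @param path file path
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(query_id = "character",
                                   target_id = "character"))
}
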
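#' Read repeat masks from lower-case FASTA or BED intervals
#'
#' Two conventions are accepted, matching what repeat maskers such as tantan
#' emit: (a) a soft-masked FASTA in which repetitive residues are lower-case
#' (bit 0) and everything else upper-case (bit 1); (b) a BED-style interval
#' file (`seq_id  start  end`, 0-based half-open) whose intervals get bit 0.
#' Every named sequence must exist and intervals must fall inside it.
#'
#' @param path path to a FASTA or BED file (FASTA is detected by a leading
#'   `>`)
#' @param sequences named character vector of the sequences being masked
#' @return named list of binary mask vectors (1 = keep, 0 = repetitive)
#' @export
read_mask <- function(path, sequences) {
  if (is.null(names(sequences))) stop("sequences must be named")
  first <- readLines(path, n = 1L)
  masks <- lapply(sequences, function(s) rep(1, nchar(s)))
  if (length(first) && startsWith(trimws(first), ">")) {
    fa <- read_fasta(path, toupper = FALSE)
    for (id in names(fa)) {
      if (!id %in% names(sequences)) stop("mask names unknown sequence: ", id)
      if (nchar(fa[[id]]) != nchar(sequences[[id]]))
        stop("mask FASTA length differs from sequence for ", id)
      chars <- strsplit(fa[[id]], "")[[1]]
      masks[[id]] <- as.numeric(chars == toupper(chars))
    }
  } else {
    lines <- readLines(path)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    for (ln in lines) {
      f <- strsplit(ln, "[ \t]+")[[1]]
      if (length(f) < 3L) stop("malformed BED line: ", ln)
      id <- f[1L]; a <- as.integer(f[2L]); b <- as.integer(f[3L])
      if (!id %in% names(sequences)) stop("mask names unknown sequence: ", id)
      n <- nchar(sequences[[id]])
      if (is.na(a) || is.na(b) || a < 0L || b > n || a >= b)
        stop("interval outside sequence bounds: ", ln)
      masks[[id]][(a + 1L):b] <- 0
    }
  }
  masks
}

#' Entropy-based low-complexity mask
#'
#' A light-weight repeat/low-complexity masker used when no external masker
#' output is supplied: residue i receives bit 0 if any length-`window` window
#' covering it has Shannon entropy (bits, over residue frequencies) at or
#' below `max_entropy_bits`. The default window of 16 mirrors common repeat-
#' masker settings; the default threshold of 1.5 bits flags homopolymers and
#' short-period repeats while leaving typical protein sequence untouched.
#' Sequences shorter than the window are evaluated as a single window.
#'
#' @param seq amino-acid string
#' @param window window length (>= 2)
#' @param max_entropy_bits entropy threshold in bits
#' @return binary mask vector (1 = keep, 0 = low complexity)
#' @export
builtin_mask <- function(seq, window = 16L, max_entropy_bits = 1.5) {
  stopifnot(window >= 2L)
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  if (n == 0L) stop("empty sequence")
  bits <- rep(1, n)
  w <- min(window, n)
  code <- match(toupper(chars), unique(toupper(chars)))
  for (s in seq_len(n - w + 1L)) {
    win <- code[s:(s + w - 1L)]
    p <- tabulate(win) / w
    p <- p[p > 0]
    if (-sum(p * log2(p)) <= max_entropy_bits)
      bits[s:(s + w - 1L)] <- 0
  }
  bits
}

#' Indices kept by a mask
#'
#' @param mask binary mask vector
#' @return integer vector of 1-based indices whose bit is 1, in order
#' @export
masked_positions <- function(mask) {
  if (!all(mask %in% c(0, 1))) stop("mask must be binary")
  which(mask == 1)
}

#' Apply the built-in masker to a set of sequences
#'
#' @param seqs named character vector
#' @inheritParams builtin_mask
#' @return named list of mask bit vectors
#' @export
builtin_masks <- function(seqs, window = 16L, max_entropy_bits = 1.5) {
  out <- lapply(seqs, builtin_mask, window = window,
                max_entropy_bits = max_entropy_bits)
  names(out) <- names(seqs)
  out
}
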
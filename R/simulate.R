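#' Simulation configuration for synthetic homolog pairs
#'
#' The simulator stands in for alignment-derived training and evaluation
#' data: an ancestor is drawn uniformly over the 20 canonical amino acids and
#' two descendants evolve from it independently by per-residue substitution
#' and geometric-length insertions/deletions, so the true residue-level
#' column pairing is known by construction.
#'
#' @param ancestor_len ancestor length (default 128)
#' @param sub_rate per-residue substitution probability per copy, in `[0, 1)`
#'   (default 0.15)
#' @param indel_rate per-position probability of starting an indel, in
#'   `[0, 1)` (default 0.02)
#' @param indel_len_mean mean of the geometric indel length (default 3)
#' @param n_pairs number of pairs for bulk generation (default 500)
#' @param seed RNG seed
#' @return object of class `sim_config`
#' @export
sim_config <- function(ancestor_len = 128L, sub_rate = 0.15, indel_rate = 0.02,
                       indel_len_mean = 3, n_pairs = 500L, seed = 1L) {
  stopifnot(ancestor_len >= 1, sub_rate >= 0, sub_rate < 1,
            indel_rate >= 0, indel_rate < 1, indel_len_mean >= 1,
            n_pairs >= 1)
  structure(list(alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                 ancestor_len = as.integer(ancestor_len), sub_rate = sub_rate,
                 indel_rate = indel_rate, indel_len_mean = indel_len_mean,
                 n_pairs = as.integer(n_pairs), seed = as.integer(seed)),
            class = "sim_config")
}

## Evolve one descendant from ancestor indices; returns the residue string
## and, per ancestor position, its 1-based position in the descendant (NA if
## deleted).
evolve_copy <- function(anc, cfg) {
  ab <- cfg$alphabet
  n <- length(anc)
  p_geom <- 1 / cfg$indel_len_mean
  out <- character(0)
  posmap <- rep(NA_integer_, n)
  i <- 1L
  while (i <= n) {
    if (cfg$indel_rate > 0 && stats::runif(1) < cfg$indel_rate) {
      len <- stats::rgeom(1, p_geom) + 1L
      if (stats::runif(1) < 0.5) {                  # deletion of len ancestors
        i <- i + len
        next
      } else {                                      # insertion before position i
        out <- c(out, sample(ab, len, replace = TRUE))
      }
    }
    r <- ab[anc[i]]
    if (cfg$sub_rate > 0 && stats::runif(1) < cfg$sub_rate)
      r <- sample(setdiff(ab, r), 1L)
    out <- c(out, r)
    posmap[i] <- length(out)
    i <- i + 1L
  }
  list(seq = paste(out, collapse = ""), posmap = posmap)
}

#' Simulate one homologous sequence pair with its true alignment
#'
#' @param cfg a [sim_config()]
#' @param seed optional seed (defaults to `cfg$seed`)
#' @param max_retry resample attempts if a degenerate draw empties a sequence
#' @return list with `seq_a`, `seq_b` (strings) and `cols`, the two-column
#'   matrix of truly aligned residue indices (ancestor positions surviving in
#'   both copies), strictly increasing in both coordinates
#' @export
simulate_homolog_pair <- function(cfg, seed = NULL, max_retry = 20L) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  for (try in seq_len(max_retry)) {
    anc <- sample.int(length(cfg$alphabet), cfg$ancestor_len, replace = TRUE)
    a <- evolve_copy(anc, cfg)
    b <- evolve_copy(anc, cfg)
    both <- which(!is.na(a$posmap) & !is.na(b$posmap))
    if (nchar(a$seq) > 0L && nchar(b$seq) > 0L && length(both) > 0L)
      return(list(seq_a = a$seq, seq_b = b$seq,
                  cols = cbind(a$posmap[both], b$posmap[both])))
  }
  stop("could not simulate a non-degenerate homolog pair; check sim_config")
}

#' Simulate a pool of training pairs
#'
#' @param cfg a [sim_config()] (`n_pairs` pairs, seeded by `cfg$seed`)
#' @return list of training pairs in the format expected by
#'   [make_training_batch()]
#' @export
simulate_training_pairs <- function(cfg) {
  set.seed(cfg$seed)
  lapply(seq_len(cfg$n_pairs), function(i) {
    p <- simulate_homolog_pair(cfg)
    list(id_a = sprintf("pairA_%04d", i), id_b = sprintf("pairB_%04d", i),
         seq_a = p$seq_a, seq_b = p$seq_b, cols = p$cols)
  })
}

#' Simulate a miniature search benchmark
#'
#' Emulates the structure of a homology-search evaluation: each query gets at
#' least one homologous target (`true_strong`), extra unrelated targets from
#' independent ancestors (`unlabeled`), and a shuffled decoy set built from
#' the true targets (`decoy_shuffled`, one pair per query x decoy).
#'
#' @param cfg a [sim_config()]
#' @param n_queries number of query sequences
#' @param n_targets_per_query targets drawn per query (1 homolog + the rest
#'   unrelated)
#' @param seed RNG seed
#' @return list with `queries`, `targets_pos`, `targets_neg` (named character
#'   vectors) and `truth` (truth-table data.frame)
#' @export
simulate_benchmark <- function(cfg, n_queries = 50L, n_targets_per_query = 1L,
                               seed = 1L) {
  stopifnot(n_queries >= 1L, n_targets_per_query >= 1L)
  set.seed(as.integer(seed))
  queries <- character(n_queries); tpos <- character(0)
  truth <- list()
  for (q in seq_len(n_queries)) {
    qid <- sprintf("query_%03d", q)
    p <- simulate_homolog_pair(cfg)
    tid <- sprintf("target_%03d_hom", q)
    queries[q] <- p$seq_a; names(queries)[q] <- qid
    tpos[tid] <- p$seq_b
    truth[[length(truth) + 1L]] <- data.frame(
      query_id = qid, target_id = tid, label = "true_strong",
      stringsAsFactors = FALSE)
    if (n_targets_per_query > 1L) {
      for (u in seq_len(n_targets_per_query - 1L)) {
        uid <- sprintf("target_%03d_unrel%02d", q, u)
        anc <- sample.int(length(cfg$alphabet), cfg$ancestor_len, replace = TRUE)
        tpos[uid] <- paste(cfg$alphabet[anc], collapse = "")
      }
    }
  }
  tneg <- shuffle_decoys(tpos, seed = seed + 1L)
  grid <- expand.grid(query_id = names(queries), target_id = names(tneg),
                      stringsAsFactors = FALSE)
  truth[[length(truth) + 1L]] <- data.frame(grid, label = "decoy_shuffled",
                                            stringsAsFactors = FALSE)
  truth_df <- do.call(rbind, truth)
  ## unrelated true-set targets: unlabeled for every query
  hom_ids <- grep("_hom$", names(tpos), value = TRUE)
  unrel_ids <- setdiff(names(tpos), hom_ids)
  if (length(unrel_ids)) {
    g2 <- expand.grid(query_id = names(queries), target_id = unrel_ids,
                      stringsAsFactors = FALSE)
    truth_df <- rbind(truth_df, data.frame(g2, label = "unlabeled",
                                           stringsAsFactors = FALSE))
  }
  ## a query's non-partner homologous targets carry no asserted relation
  hom_grid <- expand.grid(query_id = names(queries), target_id = hom_ids,
                          stringsAsFactors = FALSE)
  key <- paste(truth_df$query_id, truth_df$target_id)
  extra <- hom_grid[!paste(hom_grid$query_id, hom_grid$target_id) %in% key, ]
  if (nrow(extra))
    truth_df <- rbind(truth_df, data.frame(extra, label = "unlabeled",
                                           stringsAsFactors = FALSE))
  rownames(truth_df) <- NULL
  list(queries = queries, targets_pos = tpos, targets_neg = tneg,
       truth = truth_df)
}

#' Insert a tandem repeat into a sequence
#'
#' @param seq amino-acid string
#' @param motif repeat unit (non-empty string)
#' @param n_copies number of copies inserted (0 = unchanged)
#' @param pos 0-based insertion offset (0 = before the first residue)
#' @return list with `seq` (modified string) and `interval`, the 0-based
#'   half-open interval covering the inserted repeat (ground truth for
#'   masking)
#' @export
insert_repeat <- function(seq, motif, n_copies, pos) {
  if (nchar(motif) == 0L) stop("empty motif")
  n <- nchar(seq)
  pos <- as.integer(pos)
  if (pos < 0L || pos > n) stop("pos out of bounds")
  ins <- strrep(motif, n_copies)
  list(seq = paste0(substr(seq, 1L, pos), ins, substr(seq, pos + 1L, n)),
       interval = c(pos, pos + nchar(ins)))
}
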
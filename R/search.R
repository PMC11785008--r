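#' Search configuration
#'
#' Defaults follow the search pipeline's published settings: 150 nearest
#' neighbours per query residue and noise-gate delta = 3. The gate subtracts
#' `delta / d^gate_exponent` from each cosine similarity; with the default
#' exponent 1/2 the gate sits at delta standard deviations of the cosine
#' noise of random d-dimensional vectors (sd ~ 1/sqrt(d)), so delta = 3
#' removes an expected 99.9% of chance similarities at any dimensionality.
#'
#' @param k neighbours retrieved per query residue (default 150)
#' @param delta noise-gate multiplier (default 3)
#' @param backend `"exact"` (full cosine scan) or `"quantized"`
#'   (inverted-file + product-quantization approximation)
#' @param reversed if `TRUE`, the index is built over the queries and target
#'   residues are streamed against it; hits are still keyed
#'   (query_id, target_id)
#' @param d embedding dimensionality the index expects
#' @param gate_exponent exponent of d in the gate denominator (default 0.5)
#' @return object of class `search_config`
#' @export
search_config <- function(k = 150L, delta = 3, backend = c("exact", "quantized"),
                          reversed = FALSE, d = 256L, gate_exponent = 0.5) {
  k <- as.integer(k)
  stopifnot(k >= 1L, delta >= 0, d >= 1L)
  backend <- match.arg(backend)
  structure(list(k = k, delta = delta, backend = backend,
                 reversed = isTRUE(reversed), d = as.integer(d),
                 gate_exponent = gate_exponent),
            class = "search_config")
}

#' Noise-gated similarity score
#'
#' `max(0, cosine - delta / d^gate_exponent)`: cosine similarities at chance
#' level for d-dimensional random vectors are clamped to zero so they cannot
#' accumulate into sequence scores.
#'
#' @param cosine cosine similarity (vectorized)
#' @param d embedding dimensionality
#' @param delta gate multiplier
#' @param gate_exponent exponent on d (default 0.5)
#' @return non-negative gated score(s)
#' @export
noise_gated_score <- function(cosine, d, delta = 3, gate_exponent = 0.5) {
  stopifnot(d >= 1)
  pmax(0, cosine - delta / d^gate_exponent)
}

#' Monte-Carlo estimate of noise-gate coverage
#'
#' Fraction (as a percentage) of cosine similarities between independent
#' standard-normal d-dimensional vector pairs that fall below the gate
#' `delta / sqrt(d)` — the share of pure noise the gate removes.
#'
#' @param n_pairs number of random vector pairs
#' @param d dimensionality (default 256)
#' @param delta gate multiplier (default 3)
#' @param seed RNG seed
#' @return percentage in `[0, 100]`
#' @export
noise_gate_coverage <- function(n_pairs = 100000L, d = 256L, delta = 3,
                                seed = 1L) {
  set.seed(as.integer(seed))
  gate <- delta / sqrt(d)
  below <- 0L
  chunk <- 10000L
  done <- 0L
  while (done < n_pairs) {
    m <- min(chunk, n_pairs - done)
    A <- matrix(stats::rnorm(m * d), m, d)
    B <- matrix(stats::rnorm(m * d), m, d)
    cs <- rowSums(A * B) / (sqrt(rowSums(A^2)) * sqrt(rowSums(B^2)))
    below <- below + sum(cs < gate)
    done <- done + m
  }
  100 * below / n_pairs
}

## Row-normalize to unit L2 norm; zero rows stay zero.
l2_normalize_rows <- function(M) {
  nrm <- sqrt(rowSums(M^2))
  nrm[nrm == 0] <- 1
  M / nrm
}

#' Build a residue-level vector index
#'
#' Collects every unmasked residue embedding (L2-normalized, so inner product
#' = cosine) into a searchable structure with back-references
#' (seq_id, position). The `"exact"` backend stores the full matrix; the
#' `"quantized"` backend additionally builds an inverted-file coarse
#' quantizer (k-means, list count scaled to the data as ~sqrt(N)) with
#' product-quantization codes per list, in the spirit of IVF+PQ indexes, and
#' answers queries approximately by probing the nearest lists.
#'
#' @param embeddings named list of `n x d` embedding matrices
#' @param masks optional named list of binary masks (1 = indexed); default
#'   keeps every residue
#' @param cfg a [search_config()]
#' @param seed seed for the quantizer's k-means
#' @return object of class `vector_index` with elements `backend`, `refs`
#'   (data.frame seq_id, pos), `count`, `d`
#' @export
build_index <- function(embeddings, masks = NULL, cfg = search_config(),
                        seed = 1L) {
  if (is.null(names(embeddings))) stop("embeddings must be named by sequence id")
  d <- unique(vapply(embeddings, ncol, 1L))
  if (length(d) != 1L) stop("embeddings have differing widths")
  if (d != cfg$d) stop(sprintf("embedding width %d does not match cfg$d = %d", d, cfg$d))
  rows <- list(); ids <- list(); poss <- list()
  for (id in names(embeddings)) {
    n <- nrow(embeddings[[id]])
    keep <- if (!is.null(masks) && !is.null(masks[[id]]))
      masked_positions(masks[[id]]) else seq_len(n)
    if (length(keep) == 0L) next
    rows[[id]] <- embeddings[[id]][keep, , drop = FALSE]
    ids[[id]] <- rep(id, length(keep))
    poss[[id]] <- keep
  }
  if (length(rows) == 0L) stop("no unmasked residues to index")
  V <- do.call(rbind, rows)
  refs <- data.frame(seq_id = unlist(ids, use.names = FALSE),
                     pos = unlist(poss, use.names = FALSE),
                     stringsAsFactors = FALSE)
  Vn <- l2_normalize_rows(V)
  ## precomputed lexicographic (seq_id, pos) rank for deterministic ties
  tie <- order(refs$seq_id, refs$pos)
  tie_rank <- integer(nrow(refs)); tie_rank[tie] <- seq_along(tie)
  idx <- structure(list(backend = cfg$backend, refs = refs, count = nrow(Vn),
                        d = as.integer(d), vectors = Vn, tie_rank = tie_rank),
                   class = "vector_index")
  if (cfg$backend == "quantized") idx <- add_quantizer(idx, seed)
  idx
}

#' @exportS3Method base::print
print.vector_index <- function(x, ...) {
  cat(sprintf("vector_index (%s): %d residue vectors of dim %d from %d sequences\n",
              x$backend, x$count, x$d, length(unique(x$refs$seq_id))))
  invisible(x)
}

## IVF + PQ structures. Coarse lists via k-means on the normalized vectors;
## PQ sub-quantizers: d split into m contiguous sub-vectors, each encoded by
## its nearest of up to 256 k-means centroids learned on the data.
add_quantizer <- function(idx, seed = 1L) {
  set.seed(as.integer(seed))
  V <- idx$vectors
  N <- nrow(V); d <- ncol(V)
  ## k-means needs centers <= N - 1; degenerate sizes collapse to one list
  safe_kmeans <- function(X, centers) {
    centers <- max(1L, min(as.integer(centers), nrow(X) - 1L,
                           nrow(unique(X)) - 1L))
    if (centers < 2L)
      return(list(centers = matrix(colMeans(X), 1L),
                  cluster = rep(1L, nrow(X))))
    suppressWarnings(stats::kmeans(X, centers = centers, iter.max = 25L,
                                   nstart = 1L))
  }
  km <- safe_kmeans(V, round(sqrt(N)))
  nlist <- nrow(km$centers)
  m <- max(Filter(function(x) d %% x == 0 && d / x >= 2, c(1L, 2L, 4L, 8L, 16L, 32L)))
  sub <- d / m
  codebooks <- vector("list", m)
  codes <- matrix(0L, N, m)
  for (s in seq_len(m)) {
    colsel <- ((s - 1L) * sub + 1L):(s * sub)
    kms <- safe_kmeans(V[, colsel, drop = FALSE], 256L)
    codebooks[[s]] <- kms$centers
    codes[, s] <- kms$cluster
  }
  idx$quant <- list(nlist = nlist, centers = km$centers, assign = km$cluster,
                    m = m, sub = sub, codebooks = codebooks, codes = codes,
                    nprobe = max(1L, ceiling(nlist / 4)))
  idx
}

## Approximate scores of q (unit vector) against all vectors of the probed
## lists, via PQ lookup tables (asymmetric distance).
quantized_scores <- function(idx, qn) {
  qz <- idx$quant
  cd <- qz$centers %*% qn
  probe <- order(cd, decreasing = TRUE)[seq_len(min(qz$nprobe, qz$nlist))]
  cand <- which(qz$assign %in% probe)
  if (length(cand) == 0L) cand <- seq_len(idx$count)
  sc <- numeric(length(cand))
  for (s in seq_len(qz$m)) {
    colsel <- ((s - 1L) * qz$sub + 1L):(s * qz$sub)
    lut <- as.vector(qz$codebooks[[s]] %*% qn[colsel])
    sc <- sc + lut[qz$codes[cand, s]]
  }
  list(cand = cand, scores = sc)
}

#' k-nearest-neighbour lookup for one residue vector
#'
#' With the exact backend this returns the true top-k by cosine similarity
#' (descending, ties broken by lexicographic (seq_id, pos)); the quantized
#' backend returns the approximate top-k from the probed inverted lists,
#' re-ranked with exact cosines. If fewer than k vectors exist, all are
#' returned.
#'
#' @param index a [build_index()] result
#' @param q length-d numeric query vector
#' @param k number of neighbours
#' @return data.frame with `seq_id`, `pos`, `cosine`, sorted
#' @export
knn <- function(index, q, k = 150L) {
  stopifnot(inherits(index, "vector_index"))
  if (index$count == 0L) stop("empty index")
  if (length(q) != index$d) stop("query vector width mismatch")
  qn <- as.numeric(q)
  nq <- sqrt(sum(qn^2)); if (nq > 0) qn <- qn / nq
  if (index$backend == "quantized" && !is.null(index$quant)) {
    qs <- quantized_scores(index, qn)
    keep <- qs$cand[order(-qs$scores, index$tie_rank[qs$cand])]
    keep <- keep[seq_len(min(k, length(keep)))]
    cs <- as.vector(index$vectors[keep, , drop = FALSE] %*% qn)
    o <- order(-cs, index$tie_rank[keep])
    keep <- keep[o]; cs <- cs[o]
  } else {
    cs_all <- as.vector(index$vectors %*% qn)
    keep <- order(-cs_all, index$tie_rank)[seq_len(min(k, index$count))]
    cs <- cs_all[keep]
  }
  data.frame(seq_id = index$refs$seq_id[keep], pos = index$refs$pos[keep],
             cosine = cs, stringsAsFactors = FALSE)
}

## Batched exact/quantized k-NN over the rows of Q (already unnormalized);
## returns a data.table of (qrow, seq_id, pos, cosine). Used by search().
knn_batch <- function(index, Q, k) {
  Qn <- l2_normalize_rows(Q)
  nq <- nrow(Qn)
  out <- vector("list", nq)
  if (index$backend == "quantized" && !is.null(index$quant)) {
    for (i in seq_len(nq)) {
      nb <- knn(index, Qn[i, ], k)
      out[[i]] <- data.table::data.table(qrow = i, seq_id = nb$seq_id,
                                         pos = nb$pos, cosine = nb$cosine)
    }
  } else {
    block <- max(1L, as.integer(2e7 / index$count))
    for (s in seq(1L, nq, by = block)) {
      e <- min(nq, s + block - 1L)
      S <- Qn[s:e, , drop = FALSE] %*% t(index$vectors)
      for (i in seq_len(e - s + 1L)) {
        cs_all <- S[i, ]
        keep <- order(-cs_all, index$tie_rank)[seq_len(min(k, index$count))]
        out[[s + i - 1L]] <- data.table::data.table(
          qrow = s + i - 1L, seq_id = index$refs$seq_id[keep],
          pos = index$refs$pos[keep], cosine = cs_all[keep])
      }
    }
  }
  data.table::rbindlist(out)
}

#' Accumulate residue matches into per-pair hit scores
#'
#' Sums the noise-gated scores of all residue matches between each
#' (query_id, target_id) pair — the pre-filter's sequence-level score.
#' Multiple matches into the same target residue all count; a pair appears
#' iff it has at least one match (its score may be 0 if every match was
#' gated away).
#'
#' @param matches data.frame with columns `query_id`, `target_id`,
#'   `gated_score`
#' @return data.frame of hits: `query_id`, `target_id`, `score`, `n_matches`,
#'   sorted by query then score descending (ties by target_id)
#' @export
accumulate_matches <- function(matches) {
  if (NROW(matches) == 0L)
    return(data.frame(query_id = character(), target_id = character(),
                      score = numeric(), n_matches = integer(),
                      stringsAsFactors = FALSE))
  dt <- data.table::as.data.table(matches)
  hits <- dt[, list(score = sum(gated_score), n_matches = .N),
             by = c("query_id", "target_id")]
  data.table::setorder(hits, query_id, -score, target_id)
  as.data.frame(hits)
}

#' End-to-end pre-filter search
#'
#' Embeds queries and targets with the model, applies masks, indexes one side
#' (targets normally; queries in reversed mode), retrieves k nearest
#' neighbours for every unmasked residue of the other side, applies the noise
#' gate and accumulates gated scores into ranked (query, target) hits.
#' Reversed mode returns hits keyed identically, so downstream evaluation is
#' orientation-agnostic.
#'
#' @param queries,targets named character vectors of sequences
#' @param params `model_params`
#' @param cfg a [search_config()]; `cfg$d` must equal the model dimensionality
#' @param query_masks,target_masks optional named lists of binary masks
#' @param seed seed for the quantized backend's training
#' @return hits data.frame as from [accumulate_matches()]
#' @export
search_sequences <- function(queries, targets, params, cfg = NULL,
                             query_masks = NULL, target_masks = NULL,
                             seed = 1L) {
  stopifnot(inherits(params, "model_params"))
  if (is.null(cfg)) cfg <- search_config(d = params$config$embed_dim)
  if (cfg$d != params$config$embed_dim)
    stop("search config dimensionality does not match the model")
  embQ <- encode_sequences(queries, params)
  embT <- encode_sequences(targets, params)
  gate_d <- cfg$d
  if (cfg$reversed) {
    index <- build_index(embQ, query_masks, cfg, seed = seed)
    probe_emb <- embT; probe_masks <- target_masks
  } else {
    index <- build_index(embT, target_masks, cfg, seed = seed)
    probe_emb <- embQ; probe_masks <- query_masks
  }
  all_matches <- list()
  for (id in names(probe_emb)) {
    E <- probe_emb[[id]]
    keep <- if (!is.null(probe_masks) && !is.null(probe_masks[[id]]))
      masked_positions(probe_masks[[id]]) else seq_len(nrow(E))
    if (length(keep) == 0L) next
    nb <- knn_batch(index, E[keep, , drop = FALSE], cfg$k)
    if (nrow(nb) == 0L) next
    gs <- noise_gated_score(nb$cosine, gate_d, cfg$delta, cfg$gate_exponent)
    all_matches[[id]] <- if (cfg$reversed)
      data.table::data.table(query_id = nb$seq_id, target_id = id,
                             gated_score = gs)
    else
      data.table::data.table(query_id = id, target_id = nb$seq_id,
                             gated_score = gs)
  }
  if (length(all_matches) == 0L)
    return(accumulate_matches(NULL))
  accumulate_matches(data.table::rbindlist(all_matches))
}

#' Recall of a quantized index against the exact backend
#'
#' Fraction of each query's exact top-k neighbours that the quantized index
#' also returns, averaged over queries. Reported as a measured quantity of a
#' given dataset, never assumed.
#'
#' @param exact_index,quant_index indexes over the same vectors
#' @param Q matrix of query vectors (rows)
#' @param k neighbours
#' @return recall in `[0, 1]`
#' @export
backend_recall <- function(exact_index, quant_index, Q, k = 10L) {
  recs <- vapply(seq_len(nrow(Q)), function(i) {
    a <- knn(exact_index, Q[i, ], k)
    b <- knn(quant_index, Q[i, ], k)
    key <- function(x) paste(x$seq_id, x$pos)
    length(intersect(key(a), key(b))) / nrow(a)
  }, numeric(1))
  mean(recs)
}
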
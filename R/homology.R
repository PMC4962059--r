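#' Search parameters for the homology engine
#'
#' The engine is a self-contained seed-and-extend local-similarity search:
#' exact words of `word_size` seed candidate diagonals, each diagonal is
#' scored position-wise (match/mismatch for nucleotides, a substitution
#' matrix for peptides) and the maximal-scoring ungapped segment is
#' reported. Raw scores are normalised with Karlin-Altschul statistics:
#' `bit = (lambda * raw - ln K) / ln 2` and `E = m * n * 2^(-bit)` where `m`
#' is the query length and `n` the summed library length.
#'
#' When `min_identity_pct = 100` the engine restricts itself to maximal
#' exact runs of length at least `word_size` (the small-RNA / TE matching
#' mode of the lncRNA pipeline). Hits must satisfy `E < max_evalue`
#' (strict), `identity_pct >= min_identity_pct` and, when set,
#' `aln_len >= min_aln_len`.
#'
#' @param word_size seed length in residues (default 11, classic blastn).
#' @param min_identity_pct minimum percent identity; 100 selects exact-run
#'   mode.
#' @param max_evalue strict E-value cutoff.
#' @param min_aln_len optional minimum alignment length.
#' @param reward,penalty nucleotide match reward and (positive) mismatch
#'   penalty; defaults +1/-2.
#' @param lambda,K Karlin-Altschul constants; defaults 1.28 and 0.46
#'   (ungapped, +1/-2 nucleotide scoring).
#' @param mode `"nucleotide"` or `"translated-query"`.
#' @return a `search_params` list.
#' @export
search_params <- function(word_size = 11L, min_identity_pct = 0,
                          max_evalue = 10, min_aln_len = NULL,
                          reward = 1, penalty = 2,
                          lambda = 1.28, K = 0.46,
                          mode = c("nucleotide", "translated-query")) {
  mode <- match.arg(mode)
  stopifnot(word_size >= 4, max_evalue > 0, reward > 0, penalty > 0)
  if (!is.null(min_aln_len) && word_size > min_aln_len)
    stop("word_size must not exceed min_aln_len")
  structure(list(word_size = as.integer(word_size),
                 min_identity_pct = min_identity_pct,
                 max_evalue = max_evalue, min_aln_len = min_aln_len,
                 reward = reward, penalty = penalty,
                 lambda = lambda, K = K, mode = mode),
            class = "search_params")
}

#' @rdname search_params
#' @details `protein_search_params()` is the translated-query preset:
#'   BLOSUM62 scoring with ungapped constants `lambda = 0.318`,
#'   `K = 0.13` and a strict E-value cutoff of `1e-3`.
#' @export
protein_search_params <- function(word_size = 4L, max_evalue = 1e-3,
                                  min_identity_pct = 0, min_aln_len = NULL) {
  search_params(word_size = word_size, min_identity_pct = min_identity_pct,
                max_evalue = max_evalue, min_aln_len = min_aln_len,
                lambda = 0.318, K = 0.13, mode = "translated-query")
}

hit_tbl <- function() {
  tibble(query_id = character(0), subject_id = character(0),
         q_start = integer(0), q_end = integer(0),
         s_start = integer(0), s_end = integer(0),
         identity_pct = numeric(0), aln_len = integer(0),
         mismatches = integer(0), gaps = integer(0),
         raw_score = numeric(0), bit_score = numeric(0),
         e_value = numeric(0), query_coverage_pct = numeric(0),
         frame = integer(0))
}

seq_kmers <- function(seq, w) {
  n <- nchar(seq)
  if (n < w) return(character(0))
  substring(seq, 1:(n - w + 1L), w:n)
}

#' Precompute a seed index for a sequence library
#'
#' Hashes every word of `word_size` in the library. Building the index once
#' and passing it to [hom_search()] avoids re-hashing the library for every
#' query.
#'
#' @param library sequence library tibble (see [sequence_library()]).
#' @param word_size seed length.
#' @return an opaque index object.
#' @export
hom_index <- function(library, word_size) {
  stopifnot(nrow(library) > 0)
  word_size <- as.integer(word_size)
  ids <- library$id
  seqs <- toupper(library$sequence)
  kml <- lapply(seqs, seq_kmers, w = word_size)
  nk <- lengths(kml)
  km <- unlist(kml, use.names = FALSE)
  entry <- rep.int(seq_along(seqs), nk)
  pos <- unlist(lapply(nk, function(n) seq_len(n) - 1L), use.names = FALSE)
  if (length(km)) {
    ord <- order(km, method = "radix")
    km_s <- km[ord]
    r <- rle(km_s)
    keys <- r$values
    key_end <- cumsum(r$lengths)
    key_start <- key_end - r$lengths + 1L
    entry_s <- entry[ord]
    pos_s <- pos[ord]
  } else {
    keys <- character(0); key_start <- key_end <- integer(0)
    entry_s <- pos_s <- integer(0)
  }
  list(keys = keys, key_start = key_start, key_end = key_end,
       entry_s = entry_s, pos_s = pos_s,
       word_size = word_size, ids = ids, seqs = seqs,
       raws = lapply(seqs, charToRaw), lens = nchar(seqs),
       total_len = sum(nchar(seqs)))
}

# Maximal-scoring contiguous segment (ungapped extension along a diagonal).
# Returns c(start0, end0, score) in 0-based half-open window coordinates.
max_segment <- function(scores) {
  cs <- cumsum(scores)
  prevmin <- cummin(c(0, cs))[seq_along(cs)]
  seg <- cs - prevmin
  j <- which.max(seg)
  start <- which(c(0, cs)[seq_len(j)] == prevmin[j])[1] - 1L
  c(start, j, seg[j])
}

ka_bits <- function(raw, lambda, K) (lambda * raw - log(K)) / log(2)

finalize_hits <- function(hits, params, m_len, n_len) {
  if (!nrow(hits)) return(hit_tbl())
  hits$identity_pct <- 100 * hits$matches / hits$aln_len
  hits$mismatches <- hits$aln_len - hits$matches
  hits$gaps <- 0L
  hits$bit_score <- ka_bits(hits$raw_score, params$lambda, params$K)
  hits$e_value <- m_len * n_len * 2^(-hits$bit_score)
  hits$query_coverage_pct <- 100 * hits$aln_len / m_len
  keep <- hits$e_value < params$max_evalue &
    hits$identity_pct >= params$min_identity_pct &
    hits$aln_len >= params$word_size
  if (!is.null(params$min_aln_len))
    keep <- keep & hits$aln_len >= params$min_aln_len
  hits <- hits[keep, , drop = FALSE]
  hits <- dplyr::distinct(hits, .data$subject_id, .data$q_start, .data$q_end,
                          .data$s_start, .data$s_end, .keep_all = TRUE)
  hits <- dplyr::arrange(hits, dplyr::desc(.data$bit_score),
                         .data$subject_id, .data$q_start)
  hits[, names(hit_tbl())]
}

diagonal_hits <- function(qraw, index, params, query_id, frame = 0L,
                          score_fun = NULL) {
  w <- index$word_size
  qn <- length(qraw)
  qseq <- rawToChar(qraw)
  qk <- seq_kmers(qseq, w)
  ki <- match(qk, index$keys)
  qi <- which(!is.na(ki))
  if (!length(qi)) return(hit_tbl())
  js <- ki[qi]
  lens <- index$key_end[js] - index$key_start[js] + 1L
  sel <- sequence(lens, from = index$key_start[js])
  seeds_entry <- index$entry_s[sel]
  seeds_diag <- index$pos_s[sel] - rep.int(qi - 1L, lens)
  key <- seeds_entry * 2^26 + seeds_diag
  uniq <- !duplicated(key)
  seeds_entry <- seeds_entry[uniq]; seeds_diag <- seeds_diag[uniq]
  exact_mode <- params$min_identity_pct >= 100 && is.null(score_fun)
  # accumulators (one tibble built at the end)
  o_sub <- character(0); o_qs <- o_qe <- o_ss <- o_se <- integer(0)
  o_match <- o_aln <- integer(0); o_raw <- numeric(0)
  for (k in seq_along(seeds_entry)) {
    j <- seeds_entry[k]; d <- seeds_diag[k]
    sraw <- index$raws[[j]]
    slen <- index$lens[j]
    qlo <- max(0L, -d)
    qhi <- min(qn, slen - d)
    if (qhi - qlo < w) next
    qs <- qraw[(qlo + 1L):qhi]
    ss <- sraw[(qlo + d + 1L):(qhi + d)]
    mvec <- qs == ss
    if (exact_mode) {
      r <- rle(mvec)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      runs <- which(r$values & r$lengths >= w)
      for (ri in runs) {
        len <- r$lengths[ri]
        o_sub <- c(o_sub, index$ids[j])
        o_qs <- c(o_qs, qlo + starts[ri] - 1L)
        o_qe <- c(o_qe, qlo + ends[ri])
        o_ss <- c(o_ss, qlo + d + starts[ri] - 1L)
        o_se <- c(o_se, qlo + d + ends[ri])
        o_match <- c(o_match, len); o_aln <- c(o_aln, len)
        o_raw <- c(o_raw, params$reward * len)
      }
    } else {
      scores <- if (is.null(score_fun))
        ifelse(mvec, params$reward, -params$penalty)
      else score_fun(qs, ss)
      seg <- max_segment(scores)
      if (seg[3] <= 0) next
      a <- as.integer(seg[1]); b <- as.integer(seg[2])
      o_sub <- c(o_sub, index$ids[j])
      o_qs <- c(o_qs, qlo + a); o_qe <- c(o_qe, qlo + b)
      o_ss <- c(o_ss, qlo + d + a); o_se <- c(o_se, qlo + d + b)
      o_match <- c(o_match, sum(mvec[(a + 1L):b]))
      o_aln <- c(o_aln, b - a)
      o_raw <- c(o_raw, seg[3])
    }
  }
  if (!length(o_sub)) return(hit_tbl())
  tibble(query_id = query_id, subject_id = o_sub,
         q_start = o_qs, q_end = o_qe, s_start = o_ss, s_end = o_se,
         matches = o_match, aln_len = o_aln, raw_score = o_raw,
         frame = frame)
}

#' Nucleotide local-similarity search
#'
#' Seed-and-extend search of one query against a sequence library. See
#' [search_params()] for the scoring model and thresholds. A query shorter
#' than the word size yields an empty result with a warning.
#'
#' @param query nucleotide sequence (character scalar).
#' @param library sequence library tibble, ignored when `index` is given.
#' @param params a [search_params()] object.
#' @param query_id id recorded in the hit table.
#' @param index optional prebuilt [hom_index()] (must match `word_size`).
#' @return tibble of hits sorted by descending bit score then subject id,
#'   with 0-based half-open query/subject coordinates.
#' @export
hom_search <- function(query, library = NULL, params = search_params(),
                       query_id = "query", index = NULL) {
  query <- toupper(query)
  if (nchar(query) < params$word_size) {
    warning("query '", query_id, "' shorter than word_size; no search done")
    return(hit_tbl())
  }
  index <- index %||% hom_index(library, params$word_size)
  if (index$word_size != params$word_size)
    stop("index word_size does not match params$word_size")
  hits <- diagonal_hits(charToRaw(query), index, params, query_id)
  finalize_hits(hits, params, nchar(query), index$total_len)
}

#' Peptide search against a protein library
#'
#' BLOSUM62-scored ungapped search of a single peptide, used for the
#' protein-match criterion of the coding-potential filter.
#'
#' @param peptide amino-acid sequence (character scalar).
#' @param library protein sequence library, ignored when `index` is given.
#' @param params a [protein_search_params()] object.
#' @inheritParams hom_search
#' @return hit tibble as in [hom_search()].
#' @export
hom_search_protein <- function(peptide, library = NULL,
                               params = protein_search_params(),
                               query_id = "query", index = NULL) {
  peptide <- toupper(peptide)
  if (nchar(peptide) < params$word_size) {
    warning("peptide '", query_id, "' shorter than word_size; no search done")
    return(hit_tbl())
  }
  index <- index %||% hom_index(library, params$word_size)
  b62 <- blosum62_matrix()
  score_fun <- function(qs, ss) {
    qc <- strsplit(rawToChar(qs), "")[[1]]
    sc <- strsplit(rawToChar(ss), "")[[1]]
    qc[!qc %in% rownames(b62)] <- "X"
    sc[!sc %in% rownames(b62)] <- "X"
    b62[cbind(qc, sc)]
  }
  hits <- diagonal_hits(charToRaw(peptide), index, params, query_id,
                        score_fun = score_fun)
  finalize_hits(hits, params, nchar(peptide), index$total_len)
}

blosum62_env <- new.env(parent = emptyenv())
blosum62_matrix <- function() {
  if (is.null(blosum62_env$m)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    blosum62_env$m <- e$BLOSUM62
  }
  blosum62_env$m
}

translate_nt <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  n <- n - n %% 3L
  if (n < 3L) return("")
  codons <- substring(seq, seq(1L, n - 2L, 3L), seq(3L, n, 3L))
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Translated-query search
#'
#' Translates a nucleotide query in the requested sense frames and searches
#' each frame peptide against a protein library. Frames are 1, 2, 3 on the
#' given strand; negative frames translate the reverse complement.
#'
#' @inheritParams hom_search
#' @param library protein sequence library.
#' @param frames integer vector from \{1, 2, 3, -1, -2, -3\}.
#' @return hit tibble with a `frame` column; query coordinates are in
#'   amino acids of the frame peptide.
#' @export
hom_search_translated <- function(query, library,
                                  params = protein_search_params(),
                                  query_id = "query", frames = 1:3,
                                  index = NULL) {
  query <- toupper(query)
  if (grepl("[^ACGTN]", query))
    stop("translated search requires an ACGTN nucleotide query")
  index <- index %||% hom_index(library, params$word_size)
  rc <- if (any(frames < 0)) revcomp(query) else NULL
  out <- lapply(frames, function(f) {
    s <- if (f > 0) substr(query, f, nchar(query))
         else substr(rc, -f, nchar(rc))
    pep <- translate_nt(s)
    if (nchar(pep) < params$word_size) return(hit_tbl())
    h <- hom_search_protein(pep, params = params,
                            query_id = query_id, index = index)
    if (nrow(h)) h$frame <- as.integer(f)
    h
  })
  hits <- dplyr::bind_rows(out)
  if (!nrow(hits)) return(hit_tbl())
  dplyr::arrange(hits, dplyr::desc(.data$bit_score), .data$subject_id,
                 .data$q_start)
}

#' Best hit of a search
#'
#' Highest bit score; ties broken by larger alignment length, then by
#' lexicographically smallest subject id, so the choice is deterministic.
#'
#' @param hits hit tibble from [hom_search()] and relatives.
#' @return one-row tibble, or `NULL` when `hits` is empty.
#' @export
best_hit <- function(hits) {
  if (is.null(hits) || nrow(hits) == 0) return(NULL)
  hits <- dplyr::arrange(hits, dplyr::desc(.data$bit_score),
                         dplyr::desc(.data$aln_len), .data$subject_id)
  hits[1, ]
}

#' Format hits in BLAST outfmt-6 column order
#'
#' Converts internal 0-based half-open coordinates to the 1-based closed
#' convention of tabular BLAST output.
#'
#' @param hits hit tibble.
#' @return tibble with the twelve standard columns.
#' @export
as_outfmt6 <- function(hits) {
  tibble(qseqid = hits$query_id, sseqid = hits$subject_id,
         pident = round_half_up(hits$identity_pct, 3),
         length = hits$aln_len, mismatch = hits$mismatches,
         gapopen = hits$gaps,
         qstart = hits$q_start + 1L, qend = hits$q_end,
         sstart = hits$s_start + 1L, send = hits$s_end,
         evalue = hits$e_value, bitscore = round_half_up(hits$bit_score, 1))
}
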
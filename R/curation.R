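#' Curation parameters
#'
#' @param min_novel_len minimum length (nt) of newly assembled transcripts;
#'   novel transcripts strictly shorter are discarded. The default 57
#'   corresponds to the shortest transcript of the reference annotation
#'   being curated, so no novel model is shorter than any reference one.
#' @param max_cluster_gap monoexonic intergenic fragments separated by
#'   strictly less than this many nucleotides are fused (default 500).
#' @param verify_clusters when TRUE (and a genome is supplied), a fusion is
#'   additionally checked by requiring the merged genomic sequence to
#'   contain every member's sequence as an exact substring.
#' @return parameter list.
#' @export
curation_params <- function(min_novel_len = 57L, max_cluster_gap = 500L,
                            verify_clusters = FALSE) {
  stopifnot(min_novel_len > 0, max_cluster_gap > 0)
  list(min_novel_len = as.integer(min_novel_len),
       max_cluster_gap = as.integer(max_cluster_gap),
       verify_clusters = isTRUE(verify_clusters))
}

exon_chain_key <- function(annotation) {
  paste(annotation$chrom, annotation$strand,
        vapply(annotation$exons,
               function(e) paste(e[, 1], e[, 2], sep = "-", collapse = ";"),
               character(1)),
        sep = "|")
}

#' Merge duplicate annotations of one locus
#'
#' Transcripts with an identical chromosome, strand and exon chain (the
#' situation of one miRNA locus annotated under two gene ids) are collapsed
#' to a single record; the lexicographically smallest transcript id
#' survives and the other ids are kept as aliases.
#'
#' @param annotation annotation tibble.
#' @return list with `annotation` (deduplicated) and `log` (tibble of
#'   `kept_id`, `merged_ids`).
#' @export
merge_duplicate_reference <- function(annotation) {
  key <- exon_chain_key(annotation)
  ord <- order(key, annotation$transcript_id)
  ann <- annotation[ord, ]
  key <- key[ord]
  grp <- match(key, unique(key))
  keep_idx <- !duplicated(grp)
  log_rows <- list()
  for (g in unique(grp[duplicated(grp)])) {
    members <- which(grp == g)
    k <- members[1]
    extra <- ann$transcript_id[members[-1]]
    ann$aliases[[k]] <- unique(c(ann$aliases[[k]], extra,
                                 unlist(ann$aliases[members[-1]])))
    log_rows[[length(log_rows) + 1L]] <-
      tibble(kept_id = ann$transcript_id[k],
             merged_ids = paste(extra, collapse = ","))
  }
  merged <- ann[keep_idx, ]
  merged <- merged[order(match(merged$transcript_id,
                               annotation$transcript_id)), ]
  list(annotation = merged,
       log = if (length(log_rows)) dplyr::bind_rows(log_rows)
             else tibble(kept_id = character(0), merged_ids = character(0)))
}

#' Discard short novel transcripts
#'
#' Novel transcripts (classes J, O, X, U) strictly shorter than
#' `min_novel_len` are removed; reference and EST transcripts are exempt.
#'
#' @param annotation annotation tibble.
#' @param params see [curation_params()].
#' @return list with `annotation` and `removed` (the discarded rows).
#' @export
filter_min_length <- function(annotation, params = curation_params()) {
  drop <- annotation$class_code %in% NOVEL_CLASSES &
    annotation$length_nt < params$min_novel_len
  list(annotation = annotation[!drop, ], removed = annotation[drop, ])
}

tx_span_start <- function(annotation) {
  vapply(annotation$exons, function(e) min(e[, 1]), numeric(1))
}

conforming_id <- function(id, class_code) {
  suffix <- ifelse(class_code == "J", "j", class_code)
  mapply(function(i, s, cls) {
    if (cls == "U")
      grepl("^TCONS_\\d{8}$", i) || grepl("^Cluster_t_\\d+$", i)
    else
      grepl(paste0("_", s, "_\\d+$"), i)
  }, id, suffix, class_code, USE.NAMES = FALSE)
}

#' Rename novel transcripts by their class code
#'
#' Novel isoforms and overlapping/antisense transcripts are renamed to
#' `<hostTx>_<j|O|X>_<k>` — the host being the first reference transcript
#' of the same gene, or the gene id when none exists — and intergenic
#' transcripts to sequential `TCONS_########` ids. Numbering follows
#' genomic order and continues after any ids already in the scheme, so the
#' operation is idempotent and injective.
#'
#' @param annotation annotation tibble.
#' @return renamed annotation tibble.
#' @export
rename_by_class <- function(annotation) {
  ann <- annotation
  starts <- tx_span_start(ann)
  g_order <- order(ann$chrom, starts, ann$transcript_id)
  novel <- ann$class_code %in% NOVEL_CLASSES
  conf <- conforming_id(ann$transcript_id, ann$class_code)
  # reference host per gene: first reference transcript id
  ref <- ann[ann$class_code == "reference", ]
  host_by_gene <- ref %>%
    group_by(.data$gene_id) %>%
    summarise(host = min(.data$transcript_id), .groups = "drop")
  hosts <- stats::setNames(host_by_gene$host, host_by_gene$gene_id)
  existing <- ann$transcript_id
  tcons_used <- as.integer(sub("^TCONS_", "",
                               grep("^TCONS_\\d{8}$", existing,
                                    value = TRUE)))
  next_tcons <- if (length(tcons_used)) max(tcons_used) + 1L else 1L
  counters <- new.env(parent = emptyenv())
  new_ids <- ann$transcript_id
  for (i in g_order) {
    if (!novel[i] || conf[i]) next
    cls <- ann$class_code[i]
    if (cls == "U") {
      repeat {
        cand <- sprintf("TCONS_%08d", next_tcons)
        next_tcons <- next_tcons + 1L
        if (!cand %in% existing) break
      }
    } else {
      base <- if (ann$gene_id[i] %in% names(hosts))
        hosts[[ann$gene_id[i]]] else ann$gene_id[i]
      suffix <- if (cls == "J") "j" else cls
      ckey <- paste(base, suffix)
      k <- (get0(ckey, envir = counters) %||% 0L)
      repeat {
        k <- k + 1L
        cand <- sprintf("%s_%s_%d", base, suffix, k)
        if (!cand %in% existing) break
      }
      assign(ckey, k, envir = counters)
    }
    existing <- c(existing, cand)
    new_ids[i] <- cand
  }
  ann$transcript_id <- new_ids
  validate_annotation(ann)
}

#' Fuse nearby monoexonic intergenic transcripts
#'
#' Monoexonic class-U transcripts on one chromosome and strand whose
#' genomic gap to the next fragment is strictly less than
#' `max_cluster_gap` are chained (single linkage) and each chain of two or
#' more is replaced by one fused single-exon transcript named
#' `Cluster_t_<k>`, numbered in genomic order. With
#' `params$verify_clusters` and a genome, a chain is only fused when the
#' merged genomic sequence contains every member's sequence exactly.
#'
#' @param annotation annotation tibble.
#' @param params see [curation_params()].
#' @param genome optional genome (see [extract_transcript_sequences()]),
#'   needed for verification and for re-extracting fused sequences.
#' @return list with `annotation` and `clusters` (tibble of `cluster_id`,
#'   `member_ids` list column, `chrom`, `strand`, `start`, `end`,
#'   `fused_length`, `n_members`).
#' @export
cluster_monoexonic <- function(annotation, params = curation_params(),
                               genome = NULL) {
  mono <- annotation$class_code == "U" &
    vapply(annotation$exons, nrow, integer(1)) == 1L
  cand <- annotation[mono, ]
  empty_clusters <- tibble(cluster_id = character(0), member_ids = list(),
                           chrom = character(0), strand = character(0),
                           start = integer(0), end = integer(0),
                           fused_length = integer(0), n_members = integer(0))
  if (nrow(cand) < 2)
    return(list(annotation = annotation, clusters = empty_clusters))
  if (!is.null(genome)) genome <- as_genome(genome)
  existing_cluster_no <- as.integer(sub("^Cluster_t_", "",
                                        grep("^Cluster_t_\\d+$",
                                             annotation$transcript_id,
                                             value = TRUE)))
  counter <- if (length(existing_cluster_no)) max(existing_cluster_no) + 1L
             else 1L
  chains <- list()
  for (ch in sort(unique(cand$chrom))) {
    for (st in c("+", "-", "unknown")) {
      sel <- cand[cand$chrom == ch & cand$strand == st, ]
      if (nrow(sel) < 2) next
      s <- vapply(sel$exons, function(e) e[1, 1], numeric(1))
      e <- vapply(sel$exons, function(e) e[1, 2], numeric(1))
      ord <- order(s, e)
      sel <- sel[ord, ]; s <- s[ord]; e <- e[ord]
      reach <- cummax(e)
      gap <- s[-1] - reach[-length(reach)]
      brk <- c(0, which(gap >= params$max_cluster_gap), nrow(sel))
      for (b in seq_len(length(brk) - 1L)) {
        members <- (brk[b] + 1L):brk[b + 1L]
        if (length(members) < 2) next
        chains[[length(chains) + 1L]] <-
          list(rows = sel[members, ], chrom = ch, strand = st,
               start = min(s[members]), end = max(e[members]))
      }
    }
  }
  if (!length(chains))
    return(list(annotation = annotation, clusters = empty_clusters))
  ord <- order(vapply(chains, `[[`, character(1), "chrom"),
               vapply(chains, `[[`, numeric(1), "start"))
  chains <- chains[ord]
  fused_rows <- list(); cluster_rows <- list(); drop_ids <- character(0)
  for (chain in chains) {
    if (params$verify_clusters && !is.null(genome)) {
      span_seq <- substring(genome[[chain$chrom]], chain$start + 1L,
                            chain$end)
      if (chain$strand == "-") span_seq <- revcomp(span_seq)
      member_seqs <- chain$rows$sequence
      if (any(is.na(member_seqs))) {
        member_seqs <- extract_transcript_sequences(chain$rows,
                                                    genome)$sequence
      }
      if (!all(vapply(member_seqs, grepl, logical(1), x = span_seq,
                      fixed = TRUE)))
        next
    }
    cid <- sprintf("Cluster_t_%d", counter)
    counter <- counter + 1L
    fused <- annotation_tbl(
      transcript_id = cid, gene_id = cid, chrom = chain$chrom,
      strand = chain$strand, class_code = "U",
      exons = list(cbind(chain$start, chain$end)),
      aliases = list(chain$rows$transcript_id))
    if (!is.null(genome))
      fused <- extract_transcript_sequences(fused, genome)
    fused_rows[[length(fused_rows) + 1L]] <- fused
    cluster_rows[[length(cluster_rows) + 1L]] <-
      tibble(cluster_id = cid, member_ids = list(chain$rows$transcript_id),
             chrom = chain$chrom, strand = chain$strand,
             start = as.integer(chain$start), end = as.integer(chain$end),
             fused_length = as.integer(chain$end - chain$start),
             n_members = nrow(chain$rows))
    drop_ids <- c(drop_ids, chain$rows$transcript_id)
  }
  if (!length(fused_rows))
    return(list(annotation = annotation, clusters = empty_clusters))
  ann <- bind_rows(annotation[!annotation$transcript_id %in% drop_ids, ],
                   dplyr::bind_rows(fused_rows))
  list(annotation = validate_annotation(ann),
       clusters = dplyr::bind_rows(cluster_rows))
}

#' Integrate an external (EST) transcript set
#'
#' Appends EST-class transcripts, dropping any whose exon chain duplicates
#' a transcript already in the annotation (non-redundant integration).
#'
#' @param annotation annotation tibble.
#' @param est_set annotation tibble of EST transcripts (class `EST`).
#' @return combined annotation tibble.
#' @export
integrate_external <- function(annotation, est_set) {
  if (is.null(est_set) || nrow(est_set) == 0) return(annotation)
  stopifnot(all(est_set$class_code == "EST"))
  key_have <- exon_chain_key(annotation)
  key_est <- exon_chain_key(est_set)
  add <- est_set[!key_est %in% key_have & !duplicated(key_est), ]
  add <- add[!add$transcript_id %in% annotation$transcript_id, ]
  validate_annotation(bind_rows(annotation, add))
}

#' Run the full curation pipeline
#'
#' Fixed order: duplicate merge, minimum-length filter, class-code
#' renaming, monoexonic clustering, EST integration. Re-running the
#' pipeline on its own output is a no-op.
#'
#' @param annotation annotation tibble (post-assembly, class codes set).
#' @param est_set optional EST annotation tibble.
#' @param params see [curation_params()].
#' @param genome optional genome for cluster verification/sequences.
#' @return list: `annotation`, `merge_log`, `removed`, `clusters`.
#' @export
curate_annotation <- function(annotation, est_set = NULL,
                              params = curation_params(), genome = NULL) {
  m <- merge_duplicate_reference(annotation)
  f <- filter_min_length(m$annotation, params)
  r <- rename_by_class(f$annotation)
  cl <- cluster_monoexonic(r, params, genome)
  out <- integrate_external(cl$annotation, est_set)
  list(annotation = out, merge_log = m$log, removed = f$removed,
       clusters = cl$clusters)
}
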
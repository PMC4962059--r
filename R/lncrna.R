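#' Search parameters of the non-coding homology match
#'
#' The small-RNA-precursor / transposon match of the lncRNA pipeline:
#' exact-run mode with a 16-nt word, 100 percent identity and a strict
#' E-value cutoff of 0.01.
#'
#' @export
lnc_match_params <- function() {
  search_params(word_size = 16L, min_identity_pct = 100, max_evalue = 0.01)
}

#' Subclassify potential lncRNAs by library homology
#'
#' Each potential lncRNA is searched against the small-RNA-precursor
#' library first and the transposable-element library second (exact-run
#' mode, see [lnc_match_params()]). A small-RNA match labels it
#' `siRNA_precursor`; otherwise a TE match labels it `TE_derived`;
#' otherwise it is a truly `lncRNA`. The small-RNA-first precedence keeps
#' the three subcategories disjoint and is configurable via `order`.
#'
#' @param annotation annotation tibble restricted to potential lncRNAs,
#'   sequences populated.
#' @param smallrna_db,te_db [sequence_library()] tibbles (zero rows allowed).
#' @param params [search_params()]; default [lnc_match_params()].
#' @param order precedence of the two libraries.
#' @return tibble: `transcript_id`, `subcategory`, `evidence` (matched
#'   library entry id, NA for truly lncRNAs).
#' @export
match_noncoding_dbs <- function(annotation, smallrna_db, te_db,
                                params = lnc_match_params(),
                                order = c("smallrna", "te")) {
  order <- match.arg(order, c("smallrna", "te"), several.ok = TRUE)
  idx <- list(
    smallrna = if (!is.null(smallrna_db) && nrow(smallrna_db) > 0)
      hom_index(smallrna_db, params$word_size) else NULL,
    te = if (!is.null(te_db) && nrow(te_db) > 0)
      hom_index(te_db, params$word_size) else NULL)
  label <- c(smallrna = "siRNA_precursor", te = "TE_derived")
  out <- lapply(seq_len(nrow(annotation)), function(i) {
    for (db in order) {
      if (is.null(idx[[db]])) next
      hits <- hom_search(annotation$sequence[i], params = params,
                         query_id = annotation$transcript_id[i],
                         index = idx[[db]])
      if (nrow(hits))
        return(list(subcategory = unname(label[db]),
                    evidence = hits$subject_id[1]))
    }
    list(subcategory = "lncRNA", evidence = NA_character_)
  })
  tibble(transcript_id = annotation$transcript_id,
         subcategory = vapply(out, `[[`, character(1), "subcategory"),
         evidence = vapply(out, `[[`, character(1), "evidence"))
}

#' Antisense exon overlaps of lncRNAs
#'
#' Finds, for each candidate lncRNA, the transcripts of *other* genes on
#' the opposite strand whose exons overlap one of its exons by a contiguous
#' run of at least `min_overlap` nucleotides. Overlap is measured exon to
#' exon (not transcript span to span), reflecting sequence-level
#' complementarity of the mature transcripts.
#'
#' @param annotation full annotation tibble.
#' @param lnc_ids transcript ids of the truly lncRNAs to classify.
#' @param min_overlap minimum contiguous antisense overlap, nt (default 10).
#' @return tibble of qualifying partners: `lncnat_id`, `partner_id`,
#'   `partner_gene`, `overlap_nt` (maximum exon-pair intersection).
#' @export
nat_partner_overlaps <- function(annotation, lnc_ids, min_overlap = 10L) {
  ex <- exon_table(annotation)
  lnc_ex <- ex %>% filter(.data$transcript_id %in% lnc_ids,
                          .data$strand %in% c("+", "-"))
  other_ex <- ex %>% filter(.data$strand %in% c("+", "-"))
  res <- list()
  for (ch in unique(lnc_ex$chrom)) {
    q <- lnc_ex %>% filter(.data$chrom == ch)
    s <- other_ex %>% filter(.data$chrom == ch)
    if (!nrow(q) || !nrow(s)) next
    qr <- IRanges::IRanges(start = q$start + 1L, end = q$end)
    sr <- IRanges::IRanges(start = s$start + 1L, end = s$end)
    ov <- IRanges::findOverlaps(qr, sr, minoverlap = as.integer(min_overlap))
    if (!length(ov)) next
    qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
    keep <- q$strand[qi] != s$strand[si] & q$gene_id[qi] != s$gene_id[si]
    if (!any(keep)) next
    qi <- qi[keep]; si <- si[keep]
    w <- IRanges::width(IRanges::pintersect(qr[qi], sr[si]))
    res[[ch]] <- tibble(lncnat_id = q$transcript_id[qi],
                        partner_id = s$transcript_id[si],
                        partner_gene = s$gene_id[si],
                        overlap_nt = as.integer(w))
  }
  pairs <- dplyr::bind_rows(res)
  if (!nrow(pairs))
    return(tibble(lncnat_id = character(0), partner_id = character(0),
                  partner_gene = character(0), overlap_nt = integer(0)))
  pairs %>%
    group_by(.data$lncnat_id, .data$partner_id, .data$partner_gene) %>%
    summarise(overlap_nt = max(.data$overlap_nt), .groups = "drop") %>%
    arrange(.data$lncnat_id, .data$partner_id)
}

#' Natural antisense versus intergenic lncRNA classification
#'
#' A truly lncRNA with at least one qualifying antisense exon overlap (see
#' [nat_partner_overlaps()]) is a lncNAT; the rest are lincRNAs.
#' Unknown-strand transcripts cannot enter the antisense logic and are
#' returned with `lnc_type = NA` and a warning.
#'
#' @inheritParams nat_partner_overlaps
#' @return tibble: `transcript_id`, `lnc_type` (`"lncNAT"`, `"lincRNA"` or
#'   NA), `n_partners`, `max_overlap_nt`.
#' @export
classify_nat_linc <- function(annotation, lnc_ids, min_overlap = 10L) {
  strand <- annotation$strand[match(lnc_ids, annotation$transcript_id)]
  unknown <- is.na(strand) | strand == "unknown"
  if (any(unknown))
    warning(sum(unknown), " lncRNA(s) with unknown strand excluded from ",
            "antisense classification")
  partners <- nat_partner_overlaps(annotation, lnc_ids[!unknown],
                                   min_overlap)
  per_lnc <- if (nrow(partners)) {
    partners %>%
      group_by(.data$lncnat_id) %>%
      summarise(n_partners = dplyr::n(),
                max_overlap_nt = max(.data$overlap_nt), .groups = "drop")
  } else {
    tibble(lncnat_id = character(0), n_partners = integer(0),
           max_overlap_nt = integer(0))
  }
  tibble(transcript_id = lnc_ids) %>%
    left_join(per_lnc, by = c(transcript_id = "lncnat_id")) %>%
    mutate(
      n_partners = ifelse(is.na(.data$n_partners), 0L, .data$n_partners),
      lnc_type = dplyr::case_when(
        unknown ~ NA_character_,
        .data$n_partners > 0 ~ "lncNAT",
        TRUE ~ "lincRNA"),
      max_overlap_nt = ifelse(is.na(.data$max_overlap_nt), 0L,
                              .data$max_overlap_nt)) %>%
    select(all_of(c("transcript_id", "lnc_type", "n_partners",
                    "max_overlap_nt")))
}

#' Type NAT pairs by the partner's classification
#'
#' Combines antisense partner records with the coding and lncRNA verdicts
#' to type each pair as lncNAT/coding-mRNA, lncNAT/lncNAT (deduplicated as
#' unordered pairs) or lncNAT/siRNA-precursor. Partners outside these three
#' kinds (for example transposon-derived transcripts) are not typed.
#'
#' @param partners output of [nat_partner_overlaps()] for the lncNATs.
#' @param coding_verdicts output of [classify_coding()].
#' @param lnc_verdicts output of [match_noncoding_dbs()].
#' @param nat_types output of [classify_nat_linc()].
#' @return tibble: `lncnat_id`, `partner_id`, `partner_kind`, `overlap_nt`.
#' @export
build_nat_pairs <- function(partners, coding_verdicts, lnc_verdicts,
                            nat_types) {
  if (!nrow(partners))
    return(tibble(lncnat_id = character(0), partner_id = character(0),
                  partner_kind = character(0), overlap_nt = integer(0)))
  coding_ids <- coding_verdicts$transcript_id[
    coding_verdicts$category == "coding"]
  sirna_ids <- lnc_verdicts$transcript_id[
    lnc_verdicts$subcategory == "siRNA_precursor"]
  lncnat_ids <- nat_types$transcript_id[
    !is.na(nat_types$lnc_type) & nat_types$lnc_type == "lncNAT"]
  pairs <- partners %>%
    mutate(partner_kind = dplyr::case_when(
      .data$partner_id %in% coding_ids ~ "coding_mRNA",
      .data$partner_id %in% lncnat_ids ~ "lncNAT",
      .data$partner_id %in% sirna_ids ~ "siRNA_precursor",
      TRUE ~ NA_character_)) %>%
    filter(!is.na(.data$partner_kind)) %>%
    select(all_of(c("lncnat_id", "partner_id", "partner_kind",
                    "overlap_nt")))
  # unordered dedup of lncNAT-lncNAT pairs
  is_nn <- pairs$partner_kind == "lncNAT"
  key <- ifelse(is_nn,
                paste(pmin(pairs$lncnat_id, pairs$partner_id),
                      pmax(pairs$lncnat_id, pairs$partner_id)),
                paste(pairs$lncnat_id, pairs$partner_id))
  pairs[!duplicated(key), ]
}

#' Candidate coding-gene targets of lincRNAs
#'
#' Searches each lincRNA against the coding-sequence library and keeps
#' alignments of at least `min_overlap` nucleotides with identity above 95
#' percent. A target match is `perfect` at 100 percent identity and
#' `near_exact` between 95 and 100; a lincRNA with any perfect match is
#' counted in the perfect class only.
#'
#' @param annotation annotation tibble restricted to lincRNAs, sequences
#'   populated.
#' @param cds_lib coding-sequence [sequence_library()].
#' @param min_overlap minimum alignment length, nt (default 100).
#' @param min_identity_pct strict lower identity bound (default 95).
#' @return tibble: `lincrna_id`, `target_transcript_id`, `match_class`,
#'   `identity_pct`, `overlap_nt`.
#' @export
find_linc_targets <- function(annotation, cds_lib, min_overlap = 100L,
                              min_identity_pct = 95) {
  if (is.null(cds_lib) || nrow(cds_lib) == 0)
    return(tibble(lincrna_id = character(0),
                  target_transcript_id = character(0),
                  match_class = character(0), identity_pct = numeric(0),
                  overlap_nt = integer(0)))
  # a perfect target is a 100%-identity alignment of >= min_overlap nt,
  # i.e. a maximal exact run; near-exact targets come from the scored
  # search (which may extend an exact run through flanking mismatches)
  exact_pars <- search_params(word_size = 16L, min_identity_pct = 100,
                              max_evalue = 10,
                              min_aln_len = as.integer(min_overlap))
  scored_pars <- search_params(word_size = 11L, min_identity_pct = 0,
                               max_evalue = 10, min_aln_len = NULL)
  exact_idx <- hom_index(cds_lib, exact_pars$word_size)
  scored_idx <- hom_index(cds_lib, scored_pars$word_size)
  res <- lapply(seq_len(nrow(annotation)), function(i) {
    id <- annotation$transcript_id[i]
    perf <- hom_search(annotation$sequence[i], params = exact_pars,
                       query_id = id, index = exact_idx) %>%
      group_by(.data$subject_id) %>% dplyr::slice(1) %>% ungroup()
    near <- hom_search(annotation$sequence[i], params = scored_pars,
                       query_id = id, index = scored_idx) %>%
      filter(.data$aln_len >= min_overlap,
             .data$identity_pct > min_identity_pct,
             !.data$subject_id %in% perf$subject_id) %>%
      group_by(.data$subject_id) %>% dplyr::slice(1) %>% ungroup()
    hits <- bind_rows(
      if (nrow(perf)) tibble(lincrna_id = id,
                             target_transcript_id = perf$subject_id,
                             match_class = "perfect",
                             identity_pct = perf$identity_pct,
                             overlap_nt = perf$aln_len),
      if (nrow(near)) tibble(lincrna_id = id,
                             target_transcript_id = near$subject_id,
                             match_class = "near_exact",
                             identity_pct = near$identity_pct,
                             overlap_nt = near$aln_len))
    if (is.null(hits) || !nrow(hits)) NULL else hits
  })
  out <- dplyr::bind_rows(res)
  if (!nrow(out))
    return(tibble(lincrna_id = character(0),
                  target_transcript_id = character(0),
                  match_class = character(0), identity_pct = numeric(0),
                  overlap_nt = integer(0)))
  arrange(out, .data$lincrna_id, .data$target_transcript_id)
}

#' Count lincRNAs by target match class
#'
#' @param targets output of [find_linc_targets()].
#' @return tibble with `match_class` and `n_lincrnas`; a lincRNA with any
#'   perfect target is counted as perfect only.
#' @export
linc_target_summary <- function(targets) {
  if (!nrow(targets))
    return(tibble(match_class = character(0), n_lincrnas = integer(0)))
  per_linc <- targets %>%
    group_by(.data$lincrna_id) %>%
    summarise(match_class = ifelse(any(.data$match_class == "perfect"),
                                   "perfect", "near_exact"),
              .groups = "drop")
  dplyr::count(per_linc, .data$match_class, name = "n_lincrnas")
}

#' Length summary of a transcript group
#'
#' @param lengths integer vector of transcript lengths (nt), or an
#'   annotation tibble (its `length_nt` column is used).
#' @return one-row tibble: `n`, `min`, `max`, `mean`.
#' @export
length_stats <- function(lengths) {
  if (is.data.frame(lengths)) lengths <- lengths$length_nt
  if (!length(lengths)) stop("length_stats: empty group")
  tibble(n = length(lengths), min = min(lengths), max = max(lengths),
         mean = mean(lengths))
}
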
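#' Canonical TE superfamily report order
#'
#' LTR retroelements first (Gypsy, Copia, unclassified LTR, L1), then the
#' class II DNA superfamilies, then tRNA-related retroelements; anything
#' else is appended alphabetically.
#' @export
TE_SUPERFAMILY_ORDER <- c("RLG", "RLC", "RLX", "RIL", "DTA", "DTC", "DHH",
                          "DTM", "DTH", "DTT", "RST")

#' Best-hit transposable-element classification
#'
#' Every transcript is searched against the TE library (any-identity
#' scored mode) and its best hit, chosen by bit score with deterministic
#' tie-breaking, is thresholded into two confidence classes:
#' high-confidence (`HC`: bit score > 500 **and** query coverage > 50
#' percent) and putative/relic (`PR`: not HC, and bit score > 250 **or**
#' coverage > 30 percent). All bounds are strict. Coverage is *query*
#' coverage — the fraction of the transcript aligned to the element —
#' since the question asked is how much of a transcript is TE-derived.
#' Family and superfamily are copied from the best hit's library metadata.
#'
#' @param annotation annotation tibble with sequences populated.
#' @param te_db TE [sequence_library()] with `family`/`superfamily`.
#' @param params engine parameters; default word 11, any identity.
#' @param hc_bit,hc_cov,pr_bit,pr_cov the four thresholds.
#' @return tibble: `transcript_id`, `confidence` (`HC`/`PR`/`none`),
#'   `family`, `superfamily`, `subject_id`, `bit_score`,
#'   `query_coverage_pct`, `identity_pct`, `aln_len`.
#' @export
classify_te <- function(annotation, te_db,
                        params = search_params(word_size = 11L,
                                               min_identity_pct = 0,
                                               max_evalue = 10),
                        hc_bit = 500, hc_cov = 50,
                        pr_bit = 250, pr_cov = 30) {
  empty <- tibble(transcript_id = character(0), confidence = character(0),
                  family = character(0), superfamily = character(0),
                  subject_id = character(0), bit_score = numeric(0),
                  query_coverage_pct = numeric(0), identity_pct = numeric(0),
                  aln_len = integer(0))
  if (nrow(annotation) == 0) return(empty)
  index <- if (!is.null(te_db) && nrow(te_db) > 0)
    hom_index(te_db, params$word_size) else NULL
  meta <- if (!is.null(te_db) && nrow(te_db) > 0)
    stats::setNames(split(te_db[, c("family", "superfamily")],
                          seq_len(nrow(te_db))), te_db$id) else list()
  rows <- lapply(seq_len(nrow(annotation)), function(i) {
    none <- tibble(transcript_id = annotation$transcript_id[i],
                   confidence = "none", family = NA_character_,
                   superfamily = NA_character_, subject_id = NA_character_,
                   bit_score = NA_real_, query_coverage_pct = NA_real_,
                   identity_pct = NA_real_, aln_len = NA_integer_)
    if (is.null(index)) return(none)
    hits <- hom_search(annotation$sequence[i], params = params,
                       query_id = annotation$transcript_id[i], index = index)
    top <- best_hit(hits)
    if (is.null(top)) return(none)
    conf <- if (top$bit_score > hc_bit && top$query_coverage_pct > hc_cov)
      "HC"
    else if (top$bit_score > pr_bit || top$query_coverage_pct > pr_cov)
      "PR"
    else "none"
    m <- meta[[top$subject_id]]
    tibble(transcript_id = annotation$transcript_id[i], confidence = conf,
           family = if (conf == "none") NA_character_ else m$family,
           superfamily = if (conf == "none") NA_character_
                         else m$superfamily,
           subject_id = top$subject_id, bit_score = top$bit_score,
           query_coverage_pct = top$query_coverage_pct,
           identity_pct = top$identity_pct, aln_len = top$aln_len)
  })
  dplyr::bind_rows(rows)
}

#' TE-related fraction of a transcript subset
#'
#' @param te_annotations output of [classify_te()].
#' @param id_subset transcript ids to tabulate (must all be annotated).
#' @param digits decimal places of the percentage (default 1, the precision
#'   of published TE-fraction tables).
#' @return one-row tibble: `count` (confidence not `none`), `total`,
#'   `percent`.
#' @export
te_fraction <- function(te_annotations, id_subset, digits = 1) {
  if (!length(id_subset)) stop("te_fraction: empty id subset")
  missing_ids <- setdiff(id_subset, te_annotations$transcript_id)
  if (length(missing_ids))
    stop("ids not present in TE annotations: ",
         paste(utils::head(missing_ids, 3), collapse = ", "))
  sub <- te_annotations[te_annotations$transcript_id %in% id_subset, ]
  cnt <- sum(sub$confidence != "none")
  tibble(count = cnt, total = length(id_subset),
         percent = round_half_up(100 * cnt / length(id_subset), digits))
}

#' Superfamily breakdown of TE-related transcripts
#'
#' Counts the TE-related transcripts of a subset per superfamily, with
#' percentages relative to the TE-related count, rows in the canonical
#' superfamily order (see [TE_SUPERFAMILY_ORDER]).
#'
#' @inheritParams te_fraction
#' @return tibble: `superfamily`, `count`, `percent`.
#' @export
superfamily_table <- function(te_annotations, id_subset, digits = 1) {
  if (!length(id_subset)) stop("superfamily_table: empty id subset")
  sub <- te_annotations[te_annotations$transcript_id %in% id_subset &
                          te_annotations$confidence != "none", ]
  lev <- c(TE_SUPERFAMILY_ORDER,
           sort(setdiff(unique(sub$superfamily), TE_SUPERFAMILY_ORDER)))
  counts <- table(factor(sub$superfamily, levels = lev))
  tot <- sum(counts)
  tibble(superfamily = lev, count = as.integer(counts),
         percent = if (tot > 0)
           round_half_up(100 * as.integer(counts) / tot, digits)
         else rep(0, length(lev)))
}
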
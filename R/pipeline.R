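#' Classify a transcriptome
#'
#' Runs the full classification cascade on a curated annotation with
#' sequences: the coding/potential-lncRNA decision tree
#' ([classify_coding()]), homology subclassification of potential lncRNAs
#' ([match_noncoding_dbs()]), the antisense/intergenic split of truly
#' lncRNAs ([classify_nat_linc()]), NAT pair typing, lincRNA target search
#' and best-hit TE classification of every transcript ([classify_te()]).
#'
#' @param annotation annotation tibble, sequences populated.
#' @param protein_db,smallrna_db,te_db,cds_db sequence libraries
#'   ([sequence_library()]); `cds_db = NULL` skips the target search.
#' @param coding_pars see [coding_params()].
#' @param match_pars see [lnc_match_params()].
#' @param min_nat_overlap minimum antisense exon overlap, nt.
#' @param te_pars engine parameters of the TE search.
#' @return an object of class `lnc_classification`: a list with
#'   `transcripts` (one row per transcript: `category`, `reason`,
#'   `subcategory`, `lnc_type`, `te_confidence`, `te_superfamily`,
#'   `target_class`, `category_final`), `nat_pairs`, `linc_targets`,
#'   `te`, and `summary` (per-class coding counts).
#' @export
classify_transcriptome <- function(annotation, protein_db, smallrna_db,
                                   te_db, cds_db = NULL,
                                   coding_pars = coding_params(),
                                   match_pars = lnc_match_params(),
                                   min_nat_overlap = 10L,
                                   te_pars = search_params(
                                     word_size = 11L, min_identity_pct = 0,
                                     max_evalue = 10)) {
  coding <- classify_coding(annotation, protein_db, coding_pars)
  pot_ids <- coding$transcript_id[coding$category == "pot_lncRNA"]
  pot_ann <- annotation[annotation$transcript_id %in% pot_ids, ]
  lncv <- match_noncoding_dbs(pot_ann, smallrna_db, te_db, match_pars)
  truly_ids <- lncv$transcript_id[lncv$subcategory == "lncRNA"]
  natlinc <- classify_nat_linc(annotation, truly_ids, min_nat_overlap)
  nat_ids <- natlinc$transcript_id[!is.na(natlinc$lnc_type) &
                                     natlinc$lnc_type == "lncNAT"]
  partners <- nat_partner_overlaps(annotation, nat_ids, min_nat_overlap)
  nat_pairs <- build_nat_pairs(partners, coding, lncv, natlinc)
  linc_ids <- natlinc$transcript_id[!is.na(natlinc$lnc_type) &
                                      natlinc$lnc_type == "lincRNA"]
  linc_targets <- if (!is.null(cds_db))
    find_linc_targets(annotation[annotation$transcript_id %in% linc_ids, ],
                      cds_db)
  else tibble(lincrna_id = character(0),
              target_transcript_id = character(0),
              match_class = character(0), identity_pct = numeric(0),
              overlap_nt = integer(0))
  te_tbl <- classify_te(annotation, te_db, params = te_pars)

  per_linc_target <- linc_targets %>%
    group_by(.data$lincrna_id) %>%
    summarise(target_class = ifelse(any(.data$match_class == "perfect"),
                                    "perfect", "near_exact"),
              .groups = "drop")

  transcripts <- coding %>%
    left_join(lncv %>% select(all_of(c("transcript_id", "subcategory",
                                       "evidence"))),
              by = "transcript_id") %>%
    left_join(natlinc %>% select(all_of(c("transcript_id", "lnc_type",
                                          "n_partners"))),
              by = "transcript_id") %>%
    left_join(te_tbl %>%
                select(all_of(c("transcript_id", "confidence",
                                "superfamily"))) %>%
                rename(te_confidence = "confidence",
                       te_superfamily = "superfamily"),
              by = "transcript_id") %>%
    left_join(per_linc_target, by = c(transcript_id = "lincrna_id")) %>%
    mutate(category_final = ifelse(.data$category == "coding", "coding",
                                   .data$subcategory))

  structure(list(transcripts = transcripts,
                 nat_pairs = nat_pairs,
                 linc_targets = linc_targets,
                 te = te_tbl,
                 summary = coding_summary(coding)),
            class = "lnc_classification")
}

#' Curate and classify in one call
#'
#' Convenience wrapper: runs [curate_annotation()] (duplicate merge,
#' length filter, renaming, monoexonic clustering, EST integration),
#' re-extracts sequences for any transcript the curation created, then
#' classifies with [classify_transcriptome()].
#'
#' @param annotation pre-curation annotation tibble.
#' @param genome genome (see [extract_transcript_sequences()]).
#' @param libraries list with `protein`, `smallrna`, `te` and optionally
#'   `cds` sequence libraries (the layout of
#'   [simulate_transcriptome()]`$libraries`).
#' @param est_set optional EST annotation tibble.
#' @param curation_pars see [curation_params()].
#' @param ... passed on to [classify_transcriptome()].
#' @return list with `curation` (see [curate_annotation()]) and
#'   `classification` (an `lnc_classification`).
#' @export
run_reannotation_pipeline <- function(annotation, genome, libraries,
                                      est_set = NULL,
                                      curation_pars = curation_params(),
                                      ...) {
  cur <- curate_annotation(annotation, est_set = est_set,
                           params = curation_pars, genome = genome)
  ann <- cur$annotation
  if (any(is.na(ann$sequence)))
    ann <- extract_transcript_sequences(ann, genome)
  cls <- classify_transcriptome(ann,
                                protein_db = libraries$protein,
                                smallrna_db = libraries$smallrna,
                                te_db = libraries$te,
                                cds_db = libraries$cds, ...)
  list(curation = cur, classification = cls)
}

#' @export
print.lnc_classification <- function(x, ...) {
  tx <- x$transcripts
  cat("Transcriptome classification\n")
  cat("  transcripts:      ", nrow(tx), "\n")
  cat("  coding:           ", sum(tx$category == "coding"), "\n")
  cat("  pot-lncRNA:       ", sum(tx$category == "pot_lncRNA"), "\n")
  cat("    siRNA precursor:", sum(tx$subcategory %in% "siRNA_precursor"),
      "\n")
  cat("    TE-derived:     ", sum(tx$subcategory %in% "TE_derived"), "\n")
  cat("    truly lncRNA:   ", sum(tx$subcategory %in% "lncRNA"), "\n")
  cat("      lncNAT:       ", sum(tx$lnc_type %in% "lncNAT"), "\n")
  cat("      lincRNA:      ", sum(tx$lnc_type %in% "lincRNA"), "\n")
  cat("  TE-related (HC/PR):",
      sum(x$te$confidence == "HC"), "/", sum(x$te$confidence == "PR"), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy per-transcript classification table
#'
#' @param x an `lnc_classification`.
#' @param ... unused.
#' @return the per-transcript verdict tibble.
#' @export
tidy.lnc_classification <- function(x, ...) x$transcripts

#' One-row summary of a classification
#'
#' @param x an `lnc_classification`.
#' @param ... unused.
#' @return one-row tibble of headline counts.
#' @export
glance.lnc_classification <- function(x, ...) {
  tx <- x$transcripts
  tibble(
    n_transcripts = nrow(tx),
    n_coding = sum(tx$category == "coding"),
    n_pot_lncrna = sum(tx$category == "pot_lncRNA"),
    n_sirna_precursor = sum(tx$subcategory %in% "siRNA_precursor"),
    n_te_derived = sum(tx$subcategory %in% "TE_derived"),
    n_lncrna = sum(tx$subcategory %in% "lncRNA"),
    n_lncnat = sum(tx$lnc_type %in% "lncNAT"),
    n_lincrna = sum(tx$lnc_type %in% "lincRNA"),
    n_te_hc = sum(x$te$confidence == "HC"),
    n_te_pr = sum(x$te$confidence == "PR"),
    n_nat_pairs = nrow(x$nat_pairs)
  )
}

#' Stacked class-by-category bar chart of a classification
#'
#' @param object an `lnc_classification`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.lnc_classification <- function(object, ...) {
  tx <- object$transcripts %>%
    mutate(category_final = ifelse(is.na(.data$category_final),
                                   "coding", .data$category_final))
  ggplot2::ggplot(tx, ggplot2::aes(x = .data$class_code,
                                   fill = .data$category_final)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "annotation class", y = "transcripts",
                  fill = "category") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Ring-style summary of up/down regulated features by category
#'
#' @param filtered output of [filter_de()].
#' @param verdicts classification tibble (see [classify_transcriptome()]).
#' @return a ggplot object (side-by-side bars of up- and down-regulated
#'   counts per category).
#' @export
plot_de_summary <- function(filtered, verdicts) {
  xt <- cross_tabulate(filtered, verdicts)$by_category %>%
    tidyr::pivot_longer(c("up", "down"), names_to = "direction",
                        values_to = "n")
  ggplot2::ggplot(xt, ggplot2::aes(x = .data$category_final, y = .data$n,
                                   fill = .data$direction)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "category", y = "differentially expressed features") +
    ggplot2::theme_minimal()
}

#' Scatter plot of paired log2 fold changes
#'
#' @param pairs data frame with columns `x` and `y`.
#' @param xlab,ylab axis labels.
#' @return a ggplot object annotated with the Pearson correlation.
#' @export
plot_lfc_correlation <- function(pairs, xlab = "log2 FC (test A)",
                                 ylab = "log2 FC (test B)") {
  r <- correlate_lfc(pairs)
  ggplot2::ggplot(pairs, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::annotate("text", x = -Inf, y = Inf, hjust = -0.2, vjust = 2,
                      label = sprintf("Pearson r = %.3f", r)) +
    ggplot2::labs(x = xlab, y = ylab) +
    ggplot2::theme_minimal()
}
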
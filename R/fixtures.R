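#' Reference summary tables of the maize leaf transcriptome study
#'
#' Machine-readable copies of the published summary tables of the maize
#' B73 / *rmr6* leaf total-transcriptome reannotation that this package
#' models: the per-class coding / potential-lncRNA counts, the
#' TE-superfamily breakdown of up-regulated transcripts, headline lncRNA
#' classification counts, and the RPKM worked-example tables. They serve
#' as worked examples for the tabulation functions and as arithmetic
#' consistency fixtures; RPKM cells are transcribed verbatim, including
#' one decimal-comma cell that exercises the reader's locale handling.
#'
#' @return named list of tibbles: `class_summary`, `te_superfamily`,
#'   `te_totals`, `lnc_counts`, `rpkm_tps`, `rpkm_tcons`,
#'   `rpkm_lnc_targets`.
#' @export
study_tables <- function() {
  p <- function(f) system.file("extdata", f, package = "lncraft",
                               mustWork = TRUE)
  read_chr <- function(f)
    readr::read_tsv(p(f), col_types = readr::cols(.default = "c"),
                    progress = FALSE)
  num_cols <- function(d, skip = 1) {
    for (j in setdiff(seq_along(d), seq_len(skip)))
      d[[j]] <- parse_decimal(d[[j]])
    d
  }
  list(
    class_summary = num_cols(read_chr("maize_class_summary.tsv")),
    te_superfamily = num_cols(read_chr("maize_te_superfamily_up.tsv")),
    te_totals = num_cols(read_chr("maize_te_totals.tsv")),
    lnc_counts = num_cols(read_chr("maize_lnc_counts.tsv")),
    rpkm_tps = num_cols(read_chr("maize_rpkm_tps.tsv"), skip = 2),
    rpkm_tcons = num_cols(read_chr("maize_rpkm_tcons.tsv"), skip = 2),
    rpkm_lnc_targets = num_cols(read_chr("maize_rpkm_lnc_targets.tsv"),
                                skip = 2)
  )
}
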
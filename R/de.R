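#' Differential-expression filter parameters
#'
#' The significance rule applied to Cuffdiff-style tables: test status
#' `OK`, absolute log2 fold change of at least `min_abs_log2fc` (inclusive)
#' and FDR-adjusted p value at most `max_q` (inclusive). Features whose
#' status is in `excluded_statuses` are treated as not expressed. An
#' optional genomic exclusion region drops features inside it — used to
#' mask a window of introgressed polymorphism around a mutant locus, where
#' apparent differential expression can be a mapping artefact.
#'
#' @param min_abs_log2fc minimum |log2FC| (default 1).
#' @param max_q maximum q value (default 0.05).
#' @param excluded_statuses statuses treated as not expressed.
#' @param exclusion_region optional `list(chrom =, start =, end =)`
#'   (0-based half-open).
#' @return parameter list.
#' @export
de_filter_params <- function(min_abs_log2fc = 1, max_q = 0.05,
                             excluded_statuses = c("NOTEST", "LOWDATA"),
                             exclusion_region = NULL) {
  stopifnot(min_abs_log2fc > 0, max_q > 0)
  if (!is.null(exclusion_region))
    stopifnot(all(c("chrom", "start", "end") %in% names(exclusion_region)),
              exclusion_region$start < exclusion_region$end)
  list(min_abs_log2fc = min_abs_log2fc, max_q = max_q,
       excluded_statuses = excluded_statuses,
       exclusion_region = exclusion_region)
}

#' log2 fold change from a pair of RPKM values
#'
#' `log2(rpkm_b / rpkm_a)`, rounded half away from zero to `digits`
#' decimals (published tables print two). Zero or negative inputs are an
#' error: a zero baseline has no defined ratio, and the pseudocount
#' conventions of upstream quantifiers are deliberately not reproduced.
#'
#' @param rpkm_a,rpkm_b expression of the two conditions (vectorised).
#' @param digits decimal places (NULL for the unrounded value).
#' @return numeric vector of log2 fold changes.
#' @export
compute_log2fc <- function(rpkm_a, rpkm_b, digits = 2) {
  if (any(rpkm_a <= 0 | rpkm_b <= 0))
    stop("compute_log2fc requires strictly positive RPKM values")
  v <- log2(rpkm_b / rpkm_a)
  if (is.null(digits)) v else round_half_up(v, digits)
}

#' Apply the significance filter to a DE table
#'
#' @param records DE tibble as read by [read_de_table()].
#' @param params see [de_filter_params()].
#' @return the records with three added columns: `excluded_region`
#'   (inside the exclusion window), `significant`, and `direction`
#'   (`"up"`, `"down"` or `"ns"`).
#' @export
filter_de <- function(records, params = de_filter_params()) {
  excl <- rep(FALSE, nrow(records))
  r <- params$exclusion_region
  if (!is.null(r))
    excl <- !is.na(records$chrom) & records$chrom == r$chrom &
      !is.na(records$position) & records$position >= r$start &
      records$position < r$end
  sig <- records$status == "OK" &
    !records$status %in% params$excluded_statuses &
    !is.na(records$log2fc) &
    abs(records$log2fc) >= params$min_abs_log2fc &
    !is.na(records$q_value) & records$q_value <= params$max_q &
    !excl
  records %>%
    mutate(excluded_region = excl,
           significant = sig,
           direction = dplyr::case_when(
             sig & .data$log2fc > 0 ~ "up",
             sig & .data$log2fc < 0 ~ "down",
             TRUE ~ "ns"))
}

#' Cross-tabulate significant features by annotation class and category
#'
#' @param filtered output of [filter_de()].
#' @param verdicts pipeline classification tibble with `transcript_id`,
#'   `class_code` and a `category_final` column (see
#'   [classify_transcriptome()]); features absent from it are tabulated as
#'   `unclassified`.
#' @return named list of two tibbles, `by_class` and `by_category`, each
#'   with `up`, `down` and `total` counts.
#' @export
cross_tabulate <- function(filtered, verdicts) {
  sig <- filtered %>% filter(.data$significant)
  lab <- sig %>%
    left_join(verdicts %>%
                select(all_of(c("transcript_id", "class_code",
                                "category_final"))),
              by = c(feature_id = "transcript_id")) %>%
    mutate(class_code = ifelse(is.na(.data$class_code), "unclassified",
                               .data$class_code),
           category_final = ifelse(is.na(.data$category_final),
                                   "unclassified", .data$category_final))
  tab <- function(col) {
    lab %>%
      dplyr::count(.data[[col]], .data$direction) %>%
      tidyr::pivot_wider(names_from = "direction", values_from = "n",
                         values_fill = 0L) %>%
      (function(d) {
        for (cc in c("up", "down")) if (!cc %in% names(d)) d[[cc]] <- 0L
        d
      }) %>%
      mutate(total = .data$up + .data$down) %>%
      select(all_of(c(col, "up", "down", "total")))
  }
  list(by_class = tab("class_code"), by_category = tab("category_final"))
}

#' Sizes of all combinations of named id sets
#'
#' For every non-empty combination of the input sets the function reports
#' the plain intersection size and the exclusive (Venn-region) size, so
#' inclusion-exclusion identities can be checked directly.
#'
#' @param sets named list (>= 2) of character vectors.
#' @return tibble: `combination` (set names joined by `&`), `degree`,
#'   `n_intersection`, `n_exclusive`.
#' @export
intersect_sets <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2, !is.null(names(sets)))
  sets <- lapply(sets, unique)
  nms <- names(sets)
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1)
  combos <- unlist(lapply(seq_along(nms), function(k)
    utils::combn(nms, k, simplify = FALSE)), recursive = FALSE)
  rows <- lapply(combos, function(cb) {
    inside <- rowSums(member[, cb, drop = FALSE]) == length(cb)
    outside <- if (length(cb) < length(nms))
      rowSums(member[, setdiff(nms, cb), drop = FALSE]) == 0
    else rep(TRUE, length(universe))
    tibble(combination = paste(cb, collapse = "&"),
           degree = length(cb),
           n_intersection = sum(inside),
           n_exclusive = sum(inside & outside))
  })
  dplyr::bind_rows(rows)
}

#' Pearson correlation of paired log2 fold changes
#'
#' @param pairs data frame with numeric columns `x` and `y` (>= 3 complete
#'   pairs, both with positive variance).
#' @return scalar Pearson r.
#' @export
correlate_lfc <- function(pairs) {
  ok <- stats::complete.cases(pairs$x, pairs$y)
  x <- pairs$x[ok]; y <- pairs$y[ok]
  if (length(x) < 3) stop("correlate_lfc needs at least 3 complete pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("correlate_lfc requires positive variance in both coordinates")
  stats::cor(x, y)
}
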
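STOP_CODONS <- c("TAA", "TAG", "TGA")

translate_codons <- function(codons) {
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Find open reading frames in a transcript sequence
#'
#' An ORF runs from an ATG to the next in-frame stop codon (TAA/TAG/TGA);
#' its nucleotide span includes the stop codon and `aa_length` excludes it.
#' An ATG with no downstream in-frame stop yields a 3'-partial ORF (flagged
#' `partial`, `aa_length = span/3`). Negative frames scan the reverse
#' complement; their coordinates are reported on the reverse-complemented
#' sequence.
#'
#' @param sequence nucleotide string (ACGTN), length >= 3.
#' @param frames subset of \{1, 2, 3, -1, -2, -3\}; default the three sense
#'   frames (assembled transcripts are strand-specific).
#' @param include_partial keep 3'-partial ORFs (default TRUE).
#' @param peptides attach translated peptides (default TRUE; turn off for
#'   speed when only spans are needed).
#' @return tibble with columns `frame`, `start`, `end` (0-based half-open
#'   nucleotide coordinates), `aa_length`, `partial`, `peptide` (stop
#'   excluded; NA when `peptides = FALSE`), sorted by decreasing
#'   `aa_length`.
#' @export
find_orfs <- function(sequence, frames = 1:3, include_partial = TRUE,
                      peptides = TRUE) {
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence))
    stop("sequence contains non-nucleotide characters")
  if (nchar(sequence) < 3) stop("sequence shorter than one codon")
  stopifnot(all(frames %in% c(1:3, -(1:3))))
  rc <- if (any(frames < 0)) revcomp(sequence) else NULL
  out <- lapply(frames, function(f) {
    s <- if (f > 0) sequence else rc
    off <- abs(f) - 1L
    n <- nchar(s) - off
    nc <- n %/% 3L
    if (nc < 1) return(NULL)
    codons <- substring(s, off + seq(1L, by = 3L, length.out = nc),
                        off + seq(3L, by = 3L, length.out = nc))
    starts <- which(codons == "ATG")
    if (!length(starts)) return(NULL)
    stops <- which(codons %in% STOP_CODONS)
    # smallest stop index >= each start
    nxt <- if (length(stops)) stops[findInterval(starts - 1L, stops) + 1L]
           else rep(NA_integer_, length(starts))
    complete <- !is.na(nxt)
    if (!include_partial) {
      starts <- starts[complete]; nxt <- nxt[complete]
      complete <- complete[complete]
      if (!length(starts)) return(NULL)
    }
    end_codon <- ifelse(complete, nxt, nc)
    pep <- NA_character_
    if (peptides) {
      aa <- Biostrings::GENETIC_CODE[codons]
      aa[is.na(aa)] <- "X"
      aa_str <- paste(aa, collapse = "")
      pep <- substr(rep(aa_str, length(starts)), starts,
                    end_codon - ifelse(complete, 1L, 0L))
    }
    tibble(frame = as.integer(f),
           start = off + (starts - 1L) * 3L,
           end = off + end_codon * 3L,
           aa_length = as.integer(end_codon - starts +
                                    ifelse(complete, 0L, 1L)),
           partial = !complete,
           peptide = pep)
  })
  orfs <- dplyr::bind_rows(out)
  if (!nrow(orfs))
    return(tibble(frame = integer(0), start = integer(0), end = integer(0),
                  aa_length = integer(0), partial = logical(0),
                  peptide = character(0)))
  dplyr::arrange(orfs, dplyr::desc(.data$aa_length), .data$frame, .data$start)
}

#' Parameters of the coding-potential filter
#'
#' The filter labels a transcript a potential lncRNA only when it is at
#' least `min_lnc_len` nucleotides long (default 200), carries no ORF of
#' `orf_aa_max` (default 120) or more amino acids, and the peptide of its
#' longest ORF, when one exists, matches no protein in the supplied
#' library. Thresholds follow the conventional lncRNA definition: the
#' length bound is inclusive (>= 200 bp) and the ORF bound strict
#' (< 120 aa).
#'
#' @param min_lnc_len minimum lncRNA length, nucleotides.
#' @param orf_aa_max coding ORF threshold, amino acids (strict `<`).
#' @param frames frames scanned by [find_orfs()].
#' @param protein_params [protein_search_params()] for the protein match.
#' @return a parameter list.
#' @export
coding_params <- function(min_lnc_len = 200L, orf_aa_max = 120L,
                          frames = 1:3,
                          protein_params = protein_search_params()) {
  stopifnot(min_lnc_len > 0, orf_aa_max > 0)
  list(min_lnc_len = as.integer(min_lnc_len),
       orf_aa_max = as.integer(orf_aa_max),
       frames = frames, protein_params = protein_params)
}

orf_peptide <- function(sequence, orf) {
  s <- if (orf$frame > 0) sequence else revcomp(sequence)
  nt <- substr(s, orf$start + 1L,
               orf$end - if (orf$partial) 0L else 3L)
  translate_nt(nt)
}

classify_coding_one <- function(sequence, protein_index, params) {
  orfs <- find_orfs(sequence, frames = params$frames, peptides = FALSE)
  longest_aa <- if (nrow(orfs)) orfs$aa_length[1] else 0L
  peptide <- if (nrow(orfs)) orf_peptide(sequence, orfs[1, ])
             else NA_character_
  if (longest_aa >= params$orf_aa_max)
    return(list(category = "coding", reason = "long_orf",
                longest_orf_aa = longest_aa))
  if (nchar(sequence) < params$min_lnc_len)
    return(list(category = "coding", reason = "short_transcript",
                longest_orf_aa = longest_aa))
  if (!is.na(peptide) && nchar(peptide) >= params$protein_params$word_size &&
      !is.null(protein_index)) {
    hits <- hom_search_protein(peptide, params = params$protein_params,
                               index = protein_index)
    if (nrow(hits))
      return(list(category = "coding", reason = "protein_match",
                  longest_orf_aa = longest_aa))
  }
  list(category = "pot_lncRNA", reason = "passes_lnc_criteria",
       longest_orf_aa = longest_aa)
}

#' Coding versus potential-lncRNA classification
#'
#' Applies the three-criterion decision tree to every transcript of an
#' annotation: (1) any ORF of `orf_aa_max` or more amino acids makes the
#' transcript coding (`long_orf`); (2) transcripts shorter than
#' `min_lnc_len` fall into the coding bucket (`short_transcript`), keeping
#' the output a two-way partition of the transcriptome; (3) a protein-library
#' match of the longest ORF's peptide makes it coding (`protein_match`);
#' (4) everything else is a potential lncRNA.
#'
#' @param annotation annotation tibble with `sequence` populated.
#' @param protein_db protein [sequence_library()] (may have zero rows).
#' @param params see [coding_params()].
#' @return tibble with one verdict per transcript: `transcript_id`,
#'   `class_code`, `length_nt`, `category`, `reason`, `longest_orf_aa`.
#' @export
classify_coding <- function(annotation, protein_db,
                            params = coding_params()) {
  if (any(is.na(annotation$sequence)))
    stop("all transcripts need a sequence; run extract_transcript_sequences()")
  protein_index <- if (!is.null(protein_db) && nrow(protein_db) > 0)
    hom_index(protein_db, params$protein_params$word_size) else NULL
  verdicts <- lapply(annotation$sequence, classify_coding_one,
                     protein_index = protein_index, params = params)
  tibble(
    transcript_id = annotation$transcript_id,
    class_code = annotation$class_code,
    length_nt = annotation$length_nt,
    category = vapply(verdicts, `[[`, character(1), "category"),
    reason = vapply(verdicts, `[[`, character(1), "reason"),
    longest_orf_aa = vapply(verdicts, function(v)
      as.integer(v$longest_orf_aa), integer(1))
  )
}

#' Per-class summary of coding verdicts
#'
#' Counts coding and potential-lncRNA transcripts per annotation class, the
#' layout used by published transcriptome-reannotation summaries.
#'
#' @param verdicts output of [classify_coding()].
#' @return tibble with columns `class_code`, `coding`, `pot_lncRNA`,
#'   `total`, plus a final `Total` row.
#' @export
coding_summary <- function(verdicts) {
  by_class <- verdicts %>%
    dplyr::count(.data$class_code, .data$category) %>%
    tidyr::pivot_wider(names_from = "category", values_from = "n",
                       values_fill = 0L)
  for (col in c("coding", "pot_lncRNA"))
    if (!col %in% names(by_class)) by_class[[col]] <- 0L
  by_class <- by_class %>%
    mutate(total = .data$coding + .data$pot_lncRNA) %>%
    select(all_of(c("class_code", "coding", "pot_lncRNA", "total")))
  bind_rows(by_class,
            tibble(class_code = "Total",
                   coding = sum(by_class$coding),
                   pot_lncRNA = sum(by_class$pot_lncRNA),
                   total = sum(by_class$total)))
}
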
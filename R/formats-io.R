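#' @importFrom dplyr %>% mutate filter select arrange group_by ungroup summarise
#'   bind_rows left_join rename n distinct across all_of row_number
#' @importFrom rlang .data
#' @importFrom tibble tibble as_tibble
NULL

CLASS_CODES <- c("reference", "J", "O", "X", "U", "EST")
NOVEL_CLASSES <- c("J", "O", "X", "U")

#' Build a transcript annotation table
#'
#' The central container of the package is an ordinary tibble with one row
#' per transcript and the exon chain held in a list column, so every
#' downstream classifier can be chained with the pipe. Internal coordinates
#' are 0-based half-open; GTF I/O converts at the boundary.
#'
#' @param transcript_id,gene_id,chrom character vectors, one per transcript.
#' @param strand character, one of `"+"`, `"-"`, `"unknown"`.
#' @param class_code one of `reference`, `J`, `O`, `X`, `U`, `EST`
#'   (Cufflinks-style relation of an assembled transcript to the reference:
#'   novel isoform, generic exonic overlap, antisense overlap, intergenic,
#'   plus integrated ESTs).
#' @param exons list of two-column integer matrices (`start`, `end`),
#'   0-based half-open, sorted, non-overlapping.
#' @param sequence optional spliced sense-strand sequence (NA until
#'   extracted with [extract_transcript_sequences()]).
#' @param aliases optional list of character vectors of merged duplicate ids.
#' @return a tibble with columns `transcript_id`, `gene_id`, `chrom`,
#'   `strand`, `class_code`, `exons`, `length_nt`, `sequence`, `aliases`.
#' @export
annotation_tbl <- function(transcript_id, gene_id, chrom, strand, class_code,
                           exons, sequence = NA_character_, aliases = NULL) {
  exons <- lapply(exons, normalize_exons)
  ann <- tibble(
    transcript_id = as.character(transcript_id),
    gene_id = as.character(gene_id),
    chrom = as.character(chrom),
    strand = as.character(strand),
    class_code = as.character(class_code),
    exons = exons,
    length_nt = vapply(exons, function(e) sum(e[, 2] - e[, 1]), integer(1)),
    sequence = as.character(sequence),
    aliases = aliases %||% rep(list(character(0)), length(transcript_id))
  )
  validate_annotation(ann)
}

empty_annotation <- function() {
  tibble(
    transcript_id = character(0), gene_id = character(0),
    chrom = character(0), strand = character(0), class_code = character(0),
    exons = list(), length_nt = integer(0), sequence = character(0),
    aliases = list()
  )
}

normalize_exons <- function(e) {
  e <- matrix(as.integer(e), ncol = 2,
              dimnames = list(NULL, c("start", "end")))
  e <- e[order(e[, 1]), , drop = FALSE]
  if (any(e[, 2] <= e[, 1])) stop("exon with non-positive width")
  if (nrow(e) > 1 && any(e[-1, 1] < e[-nrow(e), 2]))
    stop("overlapping exons within one transcript")
  e
}

validate_annotation <- function(ann) {
  stopifnot(is.data.frame(ann))
  if (anyDuplicated(ann$transcript_id))
    stop("duplicate transcript_id in annotation")
  bad <- setdiff(unique(ann$class_code), CLASS_CODES)
  if (length(bad))
    stop("unknown class_code: ", paste(bad, collapse = ", "))
  bad_strand <- setdiff(unique(ann$strand), c("+", "-", "unknown"))
  if (length(bad_strand))
    stop("unknown strand value: ", paste(bad_strand, collapse = ", "))
  if (any(ann$length_nt < 1)) stop("transcript with length_nt < 1")
  has_seq <- !is.na(ann$sequence)
  if (any(nchar(ann$sequence[has_seq]) != ann$length_nt[has_seq]))
    stop("sequence length does not match exon lengths")
  ann
}

#' Flatten the exon list column
#'
#' @param annotation annotation tibble (see [annotation_tbl()]).
#' @return tibble with one row per exon: `transcript_id`, `gene_id`,
#'   `chrom`, `strand`, `class_code`, `exon_rank`, `start`, `end`
#'   (0-based half-open).
#' @export
exon_table <- function(annotation) {
  if (nrow(annotation) == 0)
    return(tibble(transcript_id = character(0), gene_id = character(0),
                  chrom = character(0), strand = character(0),
                  class_code = character(0), exon_rank = integer(0),
                  start = integer(0), end = integer(0)))
  n_ex <- vapply(annotation$exons, nrow, integer(1))
  ex <- do.call(rbind, annotation$exons)
  tibble(
    transcript_id = rep(annotation$transcript_id, n_ex),
    gene_id = rep(annotation$gene_id, n_ex),
    chrom = rep(annotation$chrom, n_ex),
    strand = rep(annotation$strand, n_ex),
    class_code = rep(annotation$class_code, n_ex),
    exon_rank = unlist(lapply(n_ex, seq_len)),
    start = as.integer(ex[, 1]),
    end = as.integer(ex[, 2])
  )
}

#' Read a GTF annotation
#'
#' Parses exon records of an Ensembl-dialect GTF into the package's
#' annotation tibble. GTF coordinates (1-based, closed) are converted to
#' internal 0-based half-open intervals. The transcript class code is read
#' from a configurable attribute key and defaults to `"reference"` when the
#' attribute is absent.
#'
#' @param path path to a GTF file.
#' @param class_attr attribute key carrying the class code
#'   (default `"class_code"`).
#' @param source_tag unused label recorded as an attribute of the result.
#' @return annotation tibble.
#' @export
read_gtf <- function(path, class_attr = "class_code", source_tag = "lncraft") {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) return(empty_annotation())
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9))
    stop("malformed GTF line ", idx[which(nf != 9)[1]],
         ": expected 9 tab-separated fields, found ", nf[nf != 9][1])
  m <- matrix(unlist(fields), ncol = 9, byrow = TRUE)
  is_exon <- m[, 3] == "exon"
  if (!any(is_exon)) return(empty_annotation())
  m <- m[is_exon, , drop = FALSE]
  line_no <- idx[is_exon]
  attrs <- m[, 9]
  get_attr <- function(key) {
    v <- stringr::str_match(attrs, paste0(key, ' "([^"]*)"'))[, 2]
    v
  }
  tx <- get_attr("transcript_id")
  if (anyNA(tx))
    stop("GTF line ", line_no[which(is.na(tx))[1]],
         ": exon record without transcript_id attribute")
  gene <- get_attr("gene_id")
  gene[is.na(gene)] <- tx[is.na(gene)]
  cls <- get_attr(class_attr)
  cls[is.na(cls)] <- "reference"
  alias <- get_attr("aliases")
  ex <- tibble(
    transcript_id = tx, gene_id = gene, chrom = m[, 1],
    strand = ifelse(m[, 7] == ".", "unknown", m[, 7]),
    class_code = cls, alias = alias,
    start = suppressWarnings(as.integer(m[, 4])) - 1L,
    end = suppressWarnings(as.integer(m[, 5]))
  )
  if (anyNA(ex$start) || anyNA(ex$end))
    stop("GTF line ", line_no[which(is.na(ex$start) | is.na(ex$end))[1]],
         ": non-integer coordinates")
  by_tx <- split(ex, factor(ex$transcript_id, levels = unique(ex$transcript_id)))
  ann <- annotation_tbl(
    transcript_id = names(by_tx),
    gene_id = unname(vapply(by_tx, function(d) d$gene_id[1], character(1))),
    chrom = unname(vapply(by_tx, function(d) d$chrom[1], character(1))),
    strand = unname(vapply(by_tx, function(d) d$strand[1], character(1))),
    class_code = unname(vapply(by_tx, function(d) d$class_code[1],
                               character(1))),
    exons = unname(lapply(by_tx, function(d) cbind(d$start, d$end))),
    aliases = unname(lapply(by_tx, function(d) {
      a <- d$alias[1]
      if (is.na(a) || !nzchar(a)) character(0) else strsplit(a, ",")[[1]]
    }))
  )
  attr(ann, "source_tag") <- source_tag
  ann
}

#' Write a GTF annotation
#'
#' Inverse of [read_gtf()]: emits one exon record per exon with 1-based
#' closed coordinates and `gene_id`, `transcript_id`, `class_code` and
#' (when present) `aliases` attributes. Unknown strand is written as `"."`.
#'
#' @param annotation annotation tibble.
#' @param path output path.
#' @param source_tag value of the GTF source column.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(annotation, path, source_tag = "lncraft") {
  header <- "##provider: lncraft"
  if (nrow(annotation) == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  ex <- exon_table(annotation)
  alias_by_tx <- stats::setNames(annotation$aliases, annotation$transcript_id)
  alias_str <- vapply(alias_by_tx[ex$transcript_id], function(a) {
    if (length(a)) sprintf(' aliases "%s";', paste(a, collapse = ",")) else ""
  }, character(1))
  attrs <- sprintf('gene_id "%s"; transcript_id "%s"; class_code "%s";%s',
                   ex$gene_id, ex$transcript_id, ex$class_code, alias_str)
  lines <- sprintf("%s\t%s\texon\t%d\t%d\t.\t%s\t.\t%s",
                   ex$chrom, source_tag, ex$start + 1L, ex$end,
                   ifelse(ex$strand == "unknown", ".", ex$strand), attrs)
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Export transcript spans as BED6
#'
#' @param annotation annotation tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(annotation, path) {
  if (nrow(annotation) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  span <- t(vapply(annotation$exons,
                   function(e) c(min(e[, 1]), max(e[, 2])), numeric(2)))
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                   annotation$chrom, as.integer(span[, 1]),
                   as.integer(span[, 2]), annotation$transcript_id,
                   ifelse(annotation$strand == "unknown", ".",
                          annotation$strand))
  writeLines(lines, path)
  invisible(path)
}

as_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  if (methods::is(genome, "DNAStringSet")) {
    nm <- sub("\\s.*$", "", names(genome))
    genome <- stats::setNames(as.character(genome), nm)
  }
  if (!is.character(genome) || is.null(names(genome)))
    stop("genome must be a named character vector, DNAStringSet or FASTA path")
  genome
}

#' Extract spliced transcript sequences from a genome
#'
#' Concatenates exon sequences in genomic order and reverse-complements the
#' result for minus-strand transcripts, filling the `sequence` column.
#'
#' @param annotation annotation tibble.
#' @param genome named character vector of chromosome sequences, a
#'   `DNAStringSet`, or a FASTA path.
#' @return the annotation with `sequence` populated.
#' @export
extract_transcript_sequences <- function(annotation, genome) {
  genome <- as_genome(genome)
  seqs <- vapply(seq_len(nrow(annotation)), function(i) {
    chrom <- annotation$chrom[i]
    if (!chrom %in% names(genome))
      stop("transcript ", annotation$transcript_id[i],
           ": chromosome ", chrom, " absent from genome")
    clen <- nchar(genome[[chrom]])
    e <- annotation$exons[[i]]
    if (any(e[, 1] < 0) || any(e[, 2] > clen))
      stop("transcript ", annotation$transcript_id[i],
           ": exon beyond end of ", chrom)
    s <- paste(substring(genome[[chrom]], e[, 1] + 1L, e[, 2]), collapse = "")
    if (annotation$strand[i] == "-") revcomp(s) else s
  }, character(1))
  annotation$sequence <- seqs
  validate_annotation(annotation)
}

#' Build or read a sequence library
#'
#' A sequence library is a tibble of reference sequences searched by the
#' homology engine: proteins, small-RNA precursors, transposable elements
#' (with family/superfamily metadata) or coding sequences.
#'
#' @param id,sequence character vectors.
#' @param role one of `"protein"`, `"smallrna"`, `"te"`, `"cds"`.
#' @param name library label.
#' @param family,superfamily TE metadata (required for `role = "te"`).
#' @return tibble with columns `id`, `sequence` (and `family`,
#'   `superfamily` for TE libraries); attributes `role` and `name`.
#' @export
sequence_library <- function(id, sequence, role = c("cds", "protein",
                                                    "smallrna", "te"),
                             name = role, family = NULL, superfamily = NULL) {
  role <- match.arg(role)
  if (anyDuplicated(id)) stop("duplicate ids in sequence library")
  lib <- tibble(id = as.character(id),
                sequence = toupper(as.character(sequence)))
  if (role == "te") {
    if (is.null(family) || is.null(superfamily))
      stop("TE library entries need family and superfamily")
    lib$family <- as.character(family)
    lib$superfamily <- as.character(superfamily)
  }
  attr(lib, "role") <- role
  attr(lib, "name") <- name
  lib
}

#' @rdname sequence_library
#' @param path FASTA file. For TE libraries headers are parsed as
#'   `id family superfamily` (whitespace-separated).
#' @export
read_fasta_library <- function(path, role = c("cds", "protein", "smallrna",
                                              "te"), name = role) {
  role <- match.arg(role)
  set <- if (role == "protein") Biostrings::readAAStringSet(path)
         else Biostrings::readDNAStringSet(path)
  headers <- names(set)
  parts <- strsplit(headers, "\\s+")
  ids <- vapply(parts, `[`, character(1), 1)
  if (role == "te") {
    fam <- vapply(parts, function(p) p[2] %||% NA_character_, character(1))
    sup <- vapply(parts, function(p) p[3] %||% NA_character_, character(1))
    if (anyNA(fam) || anyNA(sup))
      stop("TE FASTA headers must carry 'id family superfamily'")
    sequence_library(ids, as.character(set), role, name, fam, sup)
  } else {
    sequence_library(ids, as.character(set), role, name)
  }
}

#' Write a sequence library to FASTA
#'
#' @param lib sequence library tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta_library <- function(lib, path) {
  headers <- if ("family" %in% names(lib))
    sprintf("%s %s %s", lib$id, lib$family, lib$superfamily) else lib$id
  writeLines(paste0(">", headers, "\n", lib$sequence), path)
  invisible(path)
}

parse_decimal <- function(x) {
  x <- trimws(as.character(x))
  x[!nzchar(x)] <- NA_character_
  suppressWarnings(as.numeric(gsub(",", ".", x, fixed = TRUE)))
}

#' Read a differential-expression table
#'
#' Reads the package's tab-separated DE dialect (one Cuffdiff-style test per
#' row). Decimal commas are accepted alongside decimal points, matching how
#' some published tables print RPKM values. `q_value` is only meaningful for
#' rows with test status `OK`.
#'
#' @param path TSV with columns `feature_id`, `status`, `rpkm_a`, `rpkm_b`,
#'   `log2fc` and optionally `level`, `q_value`, `chrom`, `position`.
#' @return tibble of DE records; zero rows for an empty file.
#' @export
read_de_table <- function(path) {
  template <- tibble(feature_id = character(0), level = character(0),
                     status = character(0), rpkm_a = numeric(0),
                     rpkm_b = numeric(0), log2fc = numeric(0),
                     q_value = numeric(0), chrom = character(0),
                     position = numeric(0))
  info <- file.info(path)
  if (is.na(info$size) || info$size == 0) return(template)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (nrow(raw) == 0 && ncol(raw) <= 1) return(template)
  need <- c("feature_id", "status", "rpkm_a", "rpkm_b", "log2fc")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop("DE table missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  tibble(
    feature_id = raw$feature_id,
    level = if ("level" %in% names(raw)) raw$level else "transcript",
    status = toupper(trimws(raw$status)),
    rpkm_a = parse_decimal(raw$rpkm_a),
    rpkm_b = parse_decimal(raw$rpkm_b),
    log2fc = parse_decimal(raw$log2fc),
    q_value = if ("q_value" %in% names(raw)) parse_decimal(raw$q_value)
              else NA_real_,
    chrom = if ("chrom" %in% names(raw)) raw$chrom else NA_character_,
    position = if ("position" %in% names(raw)) parse_decimal(raw$position)
               else NA_real_
  )
}

#' Write a set of result tables as TSV reports
#'
#' One file per table, rows sorted by the first column for deterministic
#' output.
#'
#' @param tables named list of data frames.
#' @param path output directory (created if needed).
#' @return character vector of file paths, invisibly.
#' @export
write_report <- function(tables, path) {
  stopifnot(is.list(tables), !is.null(names(tables)), all(nzchar(names(tables))))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  out <- vapply(names(tables), function(nm) {
    tb <- as_tibble(tables[[nm]])
    if (nrow(tb) > 1) tb <- tb[order(tb[[1]]), ]
    f <- file.path(path, paste0(nm, ".tsv"))
    readr::write_tsv(tb, f, progress = FALSE)
    f
  }, character(1))
  invisible(out)
}
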
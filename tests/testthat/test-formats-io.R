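test_that("GTF exon records are converted to 0-based half-open intervals", {
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'c1\tsrc\texon\t100\t150\t.\t+\t.\tgene_id "g1"; transcript_id "t1"; class_code "U";',
    'c1\tsrc\texon\t200\t260\t.\t+\t.\tgene_id "g1"; transcript_id "t1"; class_code "U";'
  ), f)
  ann <- read_gtf(f)
  expect_equal(nrow(ann), 1)
  expect_equal(ann$exons[[1]][1, ], c(start = 99L, end = 150L))
  expect_equal(ann$length_nt, 51L + 61L)
  expect_equal(ann$class_code, "U")
})

test_that("GTF reading rejects malformed input with the line number", {
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c("# header",
               'c1\tsrc\texon\t1\t10\t.\t+\t.\tgene_id "g"; transcript_id "t";',
               "c1\tsrc\texon\t1\t10"), f)
  expect_error(read_gtf(f), "line 3")
  writeLines('c1\tsrc\texon\t1\t10\t.\t+\t.\tgene_id "g";', f)
  expect_error(read_gtf(f), "transcript_id")
})

test_that("GTF round-trip is lossless for all parsed fields", {
  ann <- shared_sim$annotation
  ann$sequence <- NA_character_
  f <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(ann, f)
  back <- read_gtf(f)
  ord <- match(ann$transcript_id, back$transcript_id)
  expect_false(anyNA(ord))
  back <- back[ord, ]
  for (col in c("transcript_id", "gene_id", "chrom", "strand",
                "class_code", "length_nt"))
    expect_equal(back[[col]], ann[[col]], ignore_attr = TRUE)
  expect_equal(lapply(back$exons, unname), lapply(ann$exons, unname))
  # second round trip is byte-identical
  f2 <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(back, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("empty annotations and unknown strands survive GTF I/O", {
  f <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(shared_sim$annotation[0, ], f)
  expect_true(all(grepl("^#", readLines(f))))
  expect_equal(nrow(read_gtf(f)), 0)

  ann <- annotation_tbl("t1", "g1", "c1", "unknown", "U",
                        list(cbind(0L, 50L)))
  write_gtf(ann, f)
  expect_match(grep("exon", readLines(f), value = TRUE)[1], "\t\\.\t\\.\t")
  expect_equal(read_gtf(f)$strand, "unknown")
})

test_that("sequence extraction splices and reverse-complements correctly", {
  genome <- c(c1 = "ACGTACGTGGCCAATT")
  plus <- annotation_tbl("p", "gp", "c1", "+", "reference",
                         list(cbind(0L, 4L)))
  expect_equal(extract_transcript_sequences(plus, genome)$sequence, "ACGT")
  minus <- annotation_tbl("m", "gm", "c1", "-", "reference",
                          list(cbind(0L, 4L)))
  expect_equal(extract_transcript_sequences(minus, genome)$sequence, "ACGT")
  bad <- annotation_tbl("b", "gb", "c1", "+", "reference",
                        list(cbind(10L, 30L)))
  expect_error(extract_transcript_sequences(bad, genome), "b")
})

test_that("extraction equals a per-base brute-force oracle on random models", {
  set.seed(101)
  chrom <- rand_dna(4000)
  genome <- c(c1 = chrom)
  bases <- strsplit(chrom, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (i in 1:150) {
    n_ex <- sample(1:4, 1)
    pts <- sort(sample(0:3999, 2 * n_ex))
    e <- matrix(pts, ncol = 2, byrow = TRUE)
    e[, 2] <- e[, 2] + 1L
    keep <- c(TRUE, if (n_ex > 1) e[-1, 1] > e[-n_ex, 2])
    e <- e[keep, , drop = FALSE]
    strand <- sample(c("+", "-"), 1)
    ann <- annotation_tbl("t", "g", "c1", strand, "reference", list(e))
    got <- extract_transcript_sequences(ann, genome)$sequence
    base_idx <- unlist(lapply(seq_len(nrow(e)),
                              function(j) (e[j, 1] + 1):e[j, 2]))
    want <- bases[base_idx]
    if (strand == "-") want <- rev(comp[want])
    expect_identical(got, paste(want, collapse = ""))
  }
})

test_that("DE tables parse statuses, decimal commas and blanks", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature_id\tstatus\trpkm_a\trpkm_b\tlog2fc\tq_value",
               "GRMZM2G046615\tOK\t7.68\t45.13\t2.55\t0.001",
               "geneB\tOK\t10,14\t25.32\t1.32\t0.02",
               "geneC\tNOTEST\t0\t0.12\t\t"), f)
  de <- read_de_table(f)
  expect_equal(de$rpkm_a, c(7.68, 10.14, 0))
  expect_equal(de$status, c("OK", "OK", "NOTEST"))
  expect_true(is.na(de$log2fc[3]) && is.na(de$q_value[3]))

  empty <- withr::local_tempfile(fileext = ".tsv")
  file.create(empty)
  expect_equal(nrow(read_de_table(empty)), 0)

  writeLines(c("feature_id\tstatus\trpkm_a", "x\tOK\t1"), f)
  expect_error(read_de_table(f), "rpkm_b")
})

test_that("reports are written deterministically, one TSV per table", {
  d <- withr::local_tempdir()
  tabs <- list(a = data.frame(id = c("z", "a"), n = c(1, 2)),
               b = data.frame(x = 1))
  files <- write_report(tabs, d)
  expect_setequal(basename(unname(files)), c("a.tsv", "b.tsv"))
  a <- readr::read_tsv(file.path(d, "a.tsv"), show_col_types = FALSE)
  expect_equal(a$id, c("a", "z"))
})

test_that("fasta libraries round-trip including TE metadata", {
  lib <- shared_sim$libraries$te
  f <- withr::local_tempfile(fileext = ".fa")
  write_fasta_library(lib, f)
  back <- read_fasta_library(f, role = "te")
  expect_equal(back$id, lib$id)
  expect_equal(back$sequence, lib$sequence)
  expect_equal(back$superfamily, lib$superfamily)
  expect_error(sequence_library("x", "ACGT", role = "te"), "family")
})
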
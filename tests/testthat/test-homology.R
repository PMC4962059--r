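exact_pars <- search_params(word_size = 16, min_identity_pct = 100,
                            max_evalue = 0.01)

test_that("an exact library copy is found with full identity and coverage", {
  set.seed(11)
  lib <- sequence_library(c("a", "b"), c(rand_dna(200), rand_dna(300)),
                          role = "smallrna")
  h <- hom_search(lib$sequence[1], lib, exact_pars)
  expect_equal(nrow(h), 1)
  expect_equal(h$subject_id, "a")
  expect_equal(h$identity_pct, 100)
  expect_equal(h$aln_len, 200L)
  expect_equal(h$query_coverage_pct, 100)
  expect_lt(h$e_value, 0.01)
})

test_that("shared words below the seed length yield no hits", {
  set.seed(12)
  core <- rand_dna(10)
  lib <- sequence_library("s", paste0(rand_dna(100), core, rand_dna(100)),
                          role = "smallrna")
  q <- paste0(rand_dna(50), core, rand_dna(50))
  expect_equal(nrow(hom_search(q, lib, exact_pars)), 0)
  expect_warning(hom_search(rand_dna(10), lib, exact_pars), "word_size")
})

test_that("100%-identity mode equals substring enumeration on random pairs", {
  set.seed(13)
  for (rep in 1:25) {
    s <- rand_dna(sample(300:800, 1))
    q <- rand_dna(sample(80:200, 1))
    # plant one or two shared segments
    for (k in seq_len(sample(1:2, 1))) {
      seg_len <- sample(16:60, 1)
      so <- sample(1, 1) + sample(0:(nchar(s) - seg_len), 1)
      qo <- sample(0:(nchar(q) - seg_len), 1)
      substr(q, qo + 1, qo + seg_len) <- substr(s, so + 1, so + seg_len)
    }
    lib <- sequence_library("s", s, role = "smallrna")
    got <- hom_search(q, lib, search_params(word_size = 16,
                                            min_identity_pct = 100,
                                            max_evalue = 1e6))
    want <- common_substring_oracle(q, s, 16)
    key <- function(a, b, c, d) paste(a, b, c, d)
    expect_setequal(key(got$q_start, got$q_end, got$s_start, got$s_end),
                    key(want$q_start, want$q_end, want$s_start, want$s_end))
  }
})

test_that("scored search matches the planted mutated segment", {
  set.seed(14)
  te <- rand_dna(1000)
  lib <- sequence_library("te1", te, role = "smallrna")
  frag <- mutate_sequence(substr(te, 201, 600), 0.05)
  q <- paste0(rand_dna(150), frag, rand_dna(150))
  h <- hom_search(q, lib, search_params(word_size = 11))
  top <- best_hit(h)
  expect_gt(top$aln_len, 300)
  expect_gt(top$identity_pct, 90)
  expect_lt(top$identity_pct, 100)
  expect_gt(top$query_coverage_pct, 50)
})

test_that("Karlin-Altschul statistics behave as m*n scaling laws", {
  p <- search_params()
  # E strictly decreases with raw score at fixed m, n
  bits <- (p$lambda * (10:200) - log(p$K)) / log(2)
  e <- 500 * 10000 * 2^(-bits)
  expect_true(all(diff(e) < 0))
  # doubling the library doubles every hit's E-value
  set.seed(15)
  s1 <- rand_dna(400)
  q <- paste0(rand_dna(30), substr(s1, 101, 180), rand_dna(30))
  lib1 <- sequence_library("a", s1, role = "smallrna")
  lib2 <- sequence_library(c("a", "b"), c(s1, rand_dna(400)),
                           role = "smallrna")
  h1 <- hom_search(q, lib1, exact_pars)
  h2 <- hom_search(q, lib2, exact_pars)
  expect_equal(h2$e_value[1] / h1$e_value[1], 2, tolerance = 1e-12)
})

test_that("best_hit tie-breaking is deterministic and exhaustively correct", {
  expect_null(best_hit(NULL))
  expect_null(best_hit(hom_search("ACGTACGTACGTACGTACGT",
                                  sequence_library("x", rand_dna(100),
                                                   role = "smallrna"),
                                  exact_pars)))
  hits <- tibble::tibble(
    query_id = "q", subject_id = c("z", "a", "m", "b"),
    q_start = 0L, q_end = 10L, s_start = 0L, s_end = 10L,
    identity_pct = 100, aln_len = c(50L, 80L, 80L, 40L),
    mismatches = 0L, gaps = 0L, raw_score = c(520, 410, 410, 520),
    bit_score = c(520, 410, 410, 520), e_value = 1e-5,
    query_coverage_pct = 50, frame = 0L)
  top <- best_hit(hits)
  # exhaustive comparator: max bit, then max aln_len, then min subject_id
  ord <- order(-hits$bit_score, -hits$aln_len, hits$subject_id)
  expect_equal(top$subject_id, hits$subject_id[ord[1]])
  expect_equal(top$subject_id, "z")  # bit ties at 520: aln 50 beats 40
})

test_that("translated search finds a planted ORF peptide", {
  set.seed(16)
  orf_nt <- paste0("ATG", paste(
    sample(setdiff(names(Biostrings::GENETIC_CODE),
                   c("TAA", "TAG", "TGA")), 80, TRUE), collapse = ""),
    "TAA")
  pep <- sub("\\*$", "", lncraft:::translate_nt(orf_nt))
  lib <- sequence_library(c("p1", "p2"), c(pep, paste(
    sample(c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I", "L", "K"),
           120, TRUE), collapse = "")), role = "protein")
  q <- paste0(rand_dna(33), orf_nt, rand_dna(60))
  h <- hom_search_translated(q, lib)
  expect_gt(nrow(h), 0)
  expect_equal(h$subject_id[1], "p1")
  expect_equal(h$identity_pct[1], 100)
  expect_error(hom_search_translated("ACGTXX", lib), "ACGTN")
  empty <- sequence_library(character(0), character(0), role = "protein")
  expect_equal(nrow(suppressWarnings(
    hom_search_protein("MKLV", empty,
                       index = list(keys = character(0),
                                    key_start = integer(0),
                                    key_end = integer(0),
                                    entry_s = integer(0),
                                    pos_s = integer(0),
                                    word_size = 4L, ids = character(0),
                                    seqs = character(0), raws = list(),
                                    lens = integer(0), total_len = 0)))), 0)
})

test_that("random queries rarely reach the null E-value threshold", {
  set.seed(17)
  lib <- sequence_library(sprintf("p%02d", 1:20),
                          vapply(rep(150, 20), function(n)
                            paste(sample(c("A", "R", "N", "D", "C", "E",
                                           "Q", "G", "H", "I", "L", "K",
                                           "M", "F", "P", "S", "T", "W",
                                           "Y", "V"), n, TRUE),
                                  collapse = ""), character(1)),
                          role = "protein")
  idx <- hom_index(lib, 4)
  n_hit <- 0
  for (i in 1:100) {
    q <- rand_dna(240)
    h <- hom_search_translated(q, lib, index = idx)
    if (nrow(h)) n_hit <- n_hit + 1
  }
  # with a strict E < 1e-3 cutoff chance hits should be very rare
  expect_lte(n_hit, 2)
})

test_that("outfmt-6 export uses 1-based closed coordinates", {
  set.seed(18)
  lib <- sequence_library("a", rand_dna(200), role = "smallrna")
  h <- hom_search(lib$sequence[1], lib, exact_pars)
  o <- as_outfmt6(h)
  expect_equal(names(o)[1:4], c("qseqid", "sseqid", "pident", "length"))
  expect_equal(o$qstart, 1L)
  expect_equal(o$qend, 200L)
})
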
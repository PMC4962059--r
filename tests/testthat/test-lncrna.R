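test_that("library matching follows the small-RNA-first precedence", {
  set.seed(41)
  sr <- sequence_library("sr1", rand_dna(120), role = "smallrna")
  te <- sequence_library("te1", rand_dna(800), role = "te",
                         family = "Gypsy", superfamily = "RLG")
  mk <- function(seq) {
    a <- annotation_tbl("t", "g", "c1", "+", "U",
                        list(cbind(0L, nchar(seq))))
    a$sequence <- seq
    a
  }
  # exact 24-nt copy of a small-RNA entry
  sr_tx <- mk(paste0(rand_dna(150), substr(sr$sequence, 11, 34),
                     rand_dna(120)))
  expect_equal(match_noncoding_dbs(sr_tx, sr, te)$subcategory,
               "siRNA_precursor")
  # match in both libraries: small-RNA wins; reversed order flips it
  both <- mk(paste0(substr(sr$sequence, 1, 40), rand_dna(80),
                    substr(te$sequence, 101, 200)))
  expect_equal(match_noncoding_dbs(both, sr, te)$subcategory,
               "siRNA_precursor")
  expect_equal(match_noncoding_dbs(both, sr, te,
                                   order = c("te", "smallrna"))$subcategory,
               "TE_derived")
  # neither library
  none <- mk(rand_dna(300))
  v <- match_noncoding_dbs(none, sr, te)
  expect_equal(v$subcategory, "lncRNA")
  expect_true(is.na(v$evidence))
})

test_that("the antisense overlap boundary sits exactly at 10 nt", {
  mk_pair <- function(ov) {
    annotation_tbl(
      c("gene_T01", "lnc"), c("gene", "lncg"), "c1", c("+", "-"),
      c("reference", "U"),
      list(cbind(0L, 500L), cbind(500L - ov, 1000L - ov)))
  }
  expect_equal(classify_nat_linc(mk_pair(10L), "lnc")$lnc_type, "lncNAT")
  expect_equal(classify_nat_linc(mk_pair(9L), "lnc")$lnc_type, "lincRNA")
  # same-strand overlap never counts
  same <- annotation_tbl(c("gene_T01", "lnc"), c("gene", "lncg"), "c1",
                         "+", c("reference", "U"),
                         list(cbind(0L, 500L), cbind(0L, 500L)))
  expect_equal(classify_nat_linc(same, "lnc")$lnc_type, "lincRNA")
  # a transcript of the same gene is not a partner
  self <- annotation_tbl(c("a", "b"), c("g", "g"), "c1", c("+", "-"),
                         c("reference", "U"),
                         list(cbind(0L, 500L), cbind(100L, 400L)))
  expect_equal(classify_nat_linc(self, "b")$lnc_type, "lincRNA")
  # unknown strand is excluded with a warning
  unk <- annotation_tbl(c("a", "b"), c("ga", "gb"), "c1",
                        c("+", "unknown"), c("reference", "U"),
                        list(cbind(0L, 500L), cbind(100L, 400L)))
  expect_warning(r <- classify_nat_linc(unk, "b"), "unknown strand")
  expect_true(is.na(r$lnc_type))
})

test_that("antisense classification equals the per-base brute force", {
  set.seed(42)
  n_checked <- 0
  while (n_checked < 200) {
    ann <- random_overlap_annotation(sample(6:12, 1))
    for (id in ann$transcript_id) {
      got <- classify_nat_linc(ann, id)$lnc_type
      want <- antisense_oracle(ann, id)
      expect_identical(got, want)
      n_checked <- n_checked + 1
    }
  }
})

test_that("overlap symmetry: both sides of a NAT pair see the same overlap", {
  set.seed(43)
  for (i in 1:20) {
    ann <- random_overlap_annotation(8)
    ov <- nat_partner_overlaps(ann, ann$transcript_id)
    if (!nrow(ov)) next
    key_ab <- paste(ov$lncnat_id, ov$partner_id, ov$overlap_nt)
    key_ba <- paste(ov$partner_id, ov$lncnat_id, ov$overlap_nt)
    expect_setequal(key_ab, key_ba)
  }
})

test_that("NAT pairs are typed from partner verdicts and deduplicated", {
  partners <- tibble::tibble(
    lncnat_id = c("n1", "n2", "n3", "n2"),
    partner_id = c("cod_T01", "n3", "n2", "sir1"),
    partner_gene = c("g1", "g2", "g3", "g4"),
    overlap_nt = c(50L, 20L, 20L, 15L))
  coding_v <- tibble::tibble(transcript_id = c("cod_T01", "n1", "n2", "n3",
                                               "sir1"),
                             category = c("coding", rep("pot_lncRNA", 4)))
  lnc_v <- tibble::tibble(transcript_id = c("n1", "n2", "n3", "sir1"),
                          subcategory = c("lncRNA", "lncRNA", "lncRNA",
                                          "siRNA_precursor"))
  nat_t <- tibble::tibble(transcript_id = c("n1", "n2", "n3"),
                          lnc_type = "lncNAT")
  pairs <- build_nat_pairs(partners, coding_v, lnc_v, nat_t)
  expect_equal(sum(pairs$partner_kind == "coding_mRNA"), 1)
  expect_equal(sum(pairs$partner_kind == "lncNAT"), 1)     # n2~n3 deduped
  expect_equal(sum(pairs$partner_kind == "siRNA_precursor"), 1)
})

test_that("lincRNA target classes follow the identity arithmetic", {
  set.seed(44)
  cds <- sequence_library("cds1", rand_dna(600), role = "cds")
  embed <- function(frag) {
    s <- paste0(rand_dna(100), frag, rand_dna(100))
    a <- annotation_tbl("linc", "lg", "c1", "+", "U",
                        list(cbind(0L, nchar(s))))
    a$sequence <- s
    a
  }
  mism <- function(frag, k) {
    pos <- round(seq(20, nchar(frag) - 20, length.out = k))
    for (p in pos) {
      b <- substr(frag, p, p)
      substr(frag, p, p) <- setdiff(c("A", "C", "G", "T"), b)[1]
    }
    frag
  }
  frag150 <- substr(cds$sequence, 201, 350)
  t_perf <- find_linc_targets(embed(frag150), cds)
  expect_equal(t_perf$match_class, "perfect")
  expect_gte(t_perf$overlap_nt, 150L)

  t_near <- find_linc_targets(embed(mism(frag150, 4)), cds)
  expect_equal(t_near$match_class, "near_exact")   # 146/150 = 97.3%
  expect_gt(t_near$identity_pct, 95)

  t_none <- find_linc_targets(embed(mism(frag150, 8)), cds)
  expect_equal(nrow(t_none), 0)                    # 142/150 = 94.7%

  # a lincRNA with a perfect hit is counted perfect only
  summ <- linc_target_summary(tibble::tibble(
    lincrna_id = c("a", "a", "b"),
    target_transcript_id = c("x", "y", "z"),
    match_class = c("perfect", "near_exact", "near_exact"),
    identity_pct = c(100, 96, 97), overlap_nt = c(120L, 150L, 150L)))
  expect_equal(summ$n_lincrnas[summ$match_class == "perfect"], 1)
  expect_equal(summ$n_lincrnas[summ$match_class == "near_exact"], 1)
})

test_that("length summaries are plain arithmetic and reject empty groups", {
  one <- length_stats(c(300L))
  expect_equal(unlist(one), c(n = 1, min = 300, max = 300, mean = 300))
  expect_error(length_stats(integer(0)), "empty")
  st <- length_stats(shared_sim$annotation)
  expect_equal(st$mean, mean(shared_sim$annotation$length_nt))
})
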
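mk_ann <- function(ids, class, starts, ends, strand = "+", chrom = "c1",
                   genes = NULL) {
  annotation_tbl(ids, genes %||% paste0(ids, "_g"), chrom, strand, class,
                 mapply(function(s, e) cbind(s, e), starts, ends,
                        SIMPLIFY = FALSE))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("duplicate reference models merge on exact exon chains only", {
  ann <- annotation_tbl(
    c("GRMZM_A", "zma-MIR-A", "B", "C"),
    c("gA", "gA2", "gB", "gC"),
    "c1", c("+", "+", "+", "-"), "reference",
    list(cbind(0L, 100L), cbind(0L, 100L), cbind(200L, 300L),
         cbind(200L, 300L)))
  m <- merge_duplicate_reference(ann)
  expect_equal(nrow(m$annotation), 3)           # strand guard keeps B and C
  kept <- m$annotation[m$annotation$transcript_id == "GRMZM_A", ]
  expect_equal(kept$aliases[[1]], "zma-MIR-A")
  expect_equal(m$log$kept_id, "GRMZM_A")

  # planted random duplicates: post-merge count equals set-based dedup
  set.seed(31)
  n <- 40
  starts <- sample(seq(0, 20000, by = 250), n)
  base <- mk_ann(sprintf("t%02d", 1:n), "reference", starts, starts + 100)
  dup_idx <- sample(n, 8)
  dups <- base[dup_idx, ]
  dups$transcript_id <- paste0("dup_", dups$transcript_id)
  both <- dplyr::bind_rows(base, dups)
  m2 <- merge_duplicate_reference(both)
  key <- paste(lncraft::exon_table(both)$chrom,
               lncraft::exon_table(both)$strand,
               lncraft::exon_table(both)$start,
               lncraft::exon_table(both)$end)
  expect_equal(nrow(m2$annotation), length(unique(key)))
})

test_that("the minimum-length filter spares reference models", {
  ann <- mk_ann(c("n56", "n57", "ref30", "est40"),
                c("U", "U", "reference", "EST"),
                c(0, 1000, 2000, 3000), c(56, 1057, 2030, 3040))
  f <- filter_min_length(ann)
  expect_setequal(f$annotation$transcript_id, c("n57", "ref30", "est40"))
  expect_equal(f$removed$transcript_id, "n56")
})

test_that("class-code renaming follows the host scheme and is idempotent", {
  ann <- annotation_tbl(
    c("HOST_T01", "CUFF.1", "CUFF.2", "CUFF.3", "CUFF.4"),
    c("gH", "gH", "gH", "cuffg3", "cuffg4"),
    "c1", "+", c("reference", "J", "J", "U", "X"),
    list(cbind(0L, 500L), cbind(0L, 520L), cbind(100L, 700L),
         cbind(5000L, 5400L), cbind(9000L, 9300L)))
  r <- rename_by_class(ann)
  expect_setequal(
    r$transcript_id,
    c("HOST_T01", "HOST_T01_j_1", "HOST_T01_j_2", "TCONS_00000001",
      "cuffg4_X_1"))
  # deterministic numbering by genomic order: CUFF.1 starts before CUFF.2
  expect_equal(r$transcript_id[match("CUFF.1", ann$transcript_id)],
               "HOST_T01_j_1")
  # idempotent and injective
  r2 <- rename_by_class(r)
  expect_identical(r2$transcript_id, r$transcript_id)
  expect_false(anyDuplicated(r$transcript_id) > 0)
})

test_that("monoexonic clustering fuses below 500 nt and not at 500", {
  two <- function(gap) {
    mk_ann(c("TCONS_00000001", "TCONS_00000002"), "U",
           c(0, 300 + gap), c(300, 600 + gap))
  }
  fused <- cluster_monoexonic(two(499))
  expect_equal(nrow(fused$clusters), 1)
  expect_equal(fused$clusters$n_members, 2)
  expect_true("Cluster_t_1" %in% fused$annotation$transcript_id)
  not_fused <- cluster_monoexonic(two(500))
  expect_equal(nrow(not_fused$clusters), 0)

  # transitive chain of three
  chain <- mk_ann(sprintf("TCONS_%08d", 1:3), "U",
                  c(0, 400, 800), c(300, 700, 1100))
  f3 <- cluster_monoexonic(chain)
  expect_equal(f3$clusters$n_members, 3)
  expect_equal(f3$clusters$fused_length, 1100L)
})

test_that("cluster partitions equal brute-force single linkage", {
  set.seed(32)
  # all-pairs single-linkage closure: i and j connect when their genomic
  # gap is strictly below the threshold, then components are transitive
  single_linkage <- function(starts, ends, thr = 500) {
    n <- length(starts)
    comp <- seq_len(n)
    repeat {
      changed <- FALSE
      for (i in seq_len(n)) for (j in seq_len(n)) {
        if (i == j || comp[i] == comp[j]) next
        gap <- max(starts[i], starts[j]) - min(ends[i], ends[j])
        if (gap < thr) {
          cc <- min(comp[i], comp[j])
          comp[comp %in% c(comp[i], comp[j])] <- cc
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    comp
  }
  for (rep in 1:30) {
    n <- sample(5:20, 1)
    starts <- sort(sample(seq(0, 40000, by = 10), n))
    lens <- sample(100:400, n, TRUE)
    ends <- starts + lens
    # keep fragments non-overlapping
    ok <- c(TRUE, starts[-1] > ends[-n])
    starts <- starts[ok]; ends <- ends[ok]; n <- sum(ok)
    if (n < 2) next
    ann <- mk_ann(sprintf("TCONS_%08d", seq_len(n)), "U", starts, ends)
    res <- cluster_monoexonic(ann)
    grp <- single_linkage(starts, ends)
    want_sizes <- sort(unname(table(grp)[table(grp) >= 2]))
    got_sizes <- sort(res$clusters$n_members)
    expect_equal(as.integer(got_sizes), as.integer(want_sizes))
  }
})

test_that("cluster verification requires members inside the fused span", {
  genome <- c(c1 = rand_dna(2000))
  ann <- mk_ann(sprintf("TCONS_%08d", 1:2), "U", c(0, 500), c(300, 900))
  ann <- extract_transcript_sequences(ann, genome)
  v <- cluster_monoexonic(ann, curation_params(verify_clusters = TRUE),
                          genome = genome)
  expect_equal(nrow(v$clusters), 1)
  expect_equal(nchar(v$annotation$sequence[
    v$annotation$transcript_id == "Cluster_t_1"]), 900L)
})

test_that("EST integration is non-redundant", {
  ann <- mk_ann(c("A", "B"), "reference", c(0, 1000), c(500, 1500))
  est <- annotation_tbl(c("E1", "E2"), c("e1", "e2"), "c1", "+", "EST",
                        list(cbind(0L, 500L), cbind(3000L, 3400L)))
  out <- integrate_external(ann, est)
  expect_setequal(out$transcript_id, c("A", "B", "E2"))
})

test_that("the curation pipeline is idempotent and conserves coordinates", {
  sim <- shared_sim
  cur <- curate_annotation(sim$annotation, est_set = sim$est_set,
                           genome = sim$genome)
  again <- curate_annotation(cur$annotation, genome = sim$genome)
  expect_identical(sort(again$annotation$transcript_id),
                   sort(cur$annotation$transcript_id))
  expect_equal(nrow(again$merge_log), 0)
  expect_equal(nrow(again$removed), 0)
  expect_equal(nrow(again$clusters), 0)
  # surviving transcripts keep their exon coordinates
  shared <- intersect(cur$annotation$transcript_id,
                      sim$annotation$transcript_id)
  a <- cur$annotation[match(shared, cur$annotation$transcript_id), ]
  b <- sim$annotation[match(shared, sim$annotation$transcript_id), ]
  expect_equal(lapply(a$exons, unname), lapply(b$exons, unname))
  # curation matched the generator's plan
  expect_setequal(cur$clusters$cluster_id, sim$truth$clusters$cluster_id)
  expect_setequal(cur$removed$transcript_id, sim$truth$curation$short_ids)
  expect_setequal(cur$merge_log$kept_id, sim$truth$curation$dup_log$kept_id)
})
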
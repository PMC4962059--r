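# Shared fixtures: small simulated datasets and brute-force oracles.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# small but complete study conditions (every planted feature present)
small_config <- function(seed) {
  sim_config(seed = seed, n_coding = 12, n_novel_isoform = 3,
             n_lincrna = 10, n_lncnat = 5, n_nat_near = 2, n_sirna = 8,
             n_te_hc = 3, n_te_pr = 3, chain_sizes = c(2L, 2L),
             n_u_decoy_pairs = 1, n_short_novel = 2, n_dup_ref = 2,
             n_est = 4, n_est_coding = 2, n_smallrna = 10,
             n_te_entries = 6, n_protein_decoys = 10,
             n_linc_perfect = 2, n_linc_near = 2,
             chrom_len = 4e5)
}

# minimal configuration for the many-seed invariant runs
invariant_config <- function(seed) {
  sim_config(seed = seed, n_coding = 6, n_novel_isoform = 1,
             n_lincrna = 5, n_lncnat = 2, n_nat_near = 1, n_sirna = 3,
             n_te_hc = 2, n_te_pr = 2, chain_sizes = c(2L),
             n_u_decoy_pairs = 1, n_short_novel = 1, n_dup_ref = 1,
             n_est = 3, n_est_coding = 1, n_smallrna = 6,
             n_te_entries = 4, n_protein_decoys = 6,
             n_linc_perfect = 1, n_linc_near = 1,
             chrom_len = 1.2e5)
}

# one shared small simulation, reused across test files
shared_sim <- simulate_transcriptome(small_config(42))

# NA-tolerant equality
eq_na <- function(a, b) (is.na(a) & is.na(b)) | (!is.na(a) & !is.na(b) & a == b)

# compare a pipeline result against planted truth; returns mismatch count
truth_mismatches <- function(sim, result) {
  tx <- tidy(result$classification)
  truth <- sim$truth$transcripts
  cmp <- dplyr::full_join(truth, tx, by = "transcript_id",
                          suffix = c(".t", ".p"))
  sum(is.na(cmp$category.t) | is.na(cmp$category.p) |
        !eq_na(cmp$category.t, cmp$category.p) |
        !eq_na(cmp$subcategory.t, cmp$subcategory.p) |
        !eq_na(cmp$lnc_type.t, cmp$lnc_type.p) |
        !eq_na(cmp$te_confidence.t,
               ifelse(is.na(cmp$te_confidence.p), "none",
                      cmp$te_confidence.p)) |
        !eq_na(cmp$target_class.t, cmp$target_class.p))
}

# brute-force ORF oracle: scan every (ATG, next in-frame stop) pair
orf_oracle <- function(seq, frames = 1:3) {
  stops3 <- c("TAA", "TAG", "TGA")
  out <- list()
  for (f in frames) {
    s <- if (f > 0) seq else lncraft::revcomp(seq)
    off <- abs(f) - 1L
    n <- (nchar(s) - off) %/% 3L
    if (n < 1) next
    codons <- substring(s, off + 3 * (seq_len(n) - 1) + 1,
                        off + 3 * seq_len(n))
    for (i in seq_len(n)) {
      if (codons[i] != "ATG") next
      stop_at <- NA_integer_
      j <- i
      while (j <= n) {
        if (codons[j] %in% stops3) { stop_at <- j; break }
        j <- j + 1L
      }
      if (!is.na(stop_at)) {
        out[[length(out) + 1L]] <- data.frame(
          frame = f, start = off + (i - 1L) * 3L, end = off + stop_at * 3L,
          aa_length = stop_at - i, partial = FALSE)
      } else {
        out[[length(out) + 1L]] <- data.frame(
          frame = f, start = off + (i - 1L) * 3L, end = off + n * 3L,
          aa_length = n - i + 1L, partial = TRUE)
      }
    }
  }
  if (!length(out))
    return(data.frame(frame = integer(0), start = integer(0),
                      end = integer(0), aa_length = integer(0),
                      partial = logical(0)))
  do.call(rbind, out)
}

# brute-force maximal common substrings of length >= w between two strings
common_substring_oracle <- function(q, s, w) {
  nq <- nchar(q); ns <- nchar(s)
  qr <- charToRaw(q); sr <- charToRaw(s)
  out <- list()
  for (d in (-(nq - 1)):(ns - 1)) {
    qlo <- max(0L, -d); qhi <- min(nq, ns - d)
    if (qhi - qlo < w) next
    m <- qr[(qlo + 1):qhi] == sr[(qlo + d + 1):(qhi + d)]
    r <- rle(m)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= w)) {
      out[[length(out) + 1L]] <- data.frame(
        q_start = qlo + starts[k] - 1L, q_end = qlo + ends[k],
        s_start = qlo + d + starts[k] - 1L, s_end = qlo + d + ends[k],
        len = r$lengths[k])
    }
  }
  if (!length(out))
    return(data.frame(q_start = integer(0), q_end = integer(0),
                      s_start = integer(0), s_end = integer(0),
                      len = integer(0)))
  do.call(rbind, out)
}

# random single/multi-exon annotation for antisense-overlap property tests
random_overlap_annotation <- function(n_tx, chrom_len = 6000) {
  ids <- sprintf("T%03d", seq_len(n_tx))
  exons <- vector("list", n_tx)
  for (i in seq_len(n_tx)) {
    n_ex <- sample(1:3, 1)
    pts <- sort(sample(0:(chrom_len - 1), 2 * n_ex))
    e <- matrix(pts, ncol = 2, byrow = TRUE)
    e[, 2] <- e[, 2] + 1L                    # ensure width >= 1
    # enforce gaps >= 1 between exons so coverage runs match exon pairs
    keep <- rep(TRUE, nrow(e))
    if (nrow(e) > 1)
      for (j in 2:nrow(e)) if (e[j, 1] <= e[j - 1, 2]) keep[j] <- FALSE
    e <- e[keep, , drop = FALSE]
    exons[[i]] <- e
  }
  annotation_tbl(
    transcript_id = ids,
    gene_id = sprintf("G%03d", seq_len(n_tx)),
    chrom = "c1",
    strand = sample(c("+", "-"), n_tx, TRUE),
    class_code = "reference",
    exons = exons)
}

# per-base brute-force antisense classification of one transcript
antisense_oracle <- function(ann, id, min_overlap = 10, chrom_len = 6000) {
  me <- ann[ann$transcript_id == id, ]
  cov_of <- function(row) {
    v <- logical(chrom_len)
    e <- row$exons[[1]]
    for (j in seq_len(nrow(e))) v[(e[j, 1] + 1):e[j, 2]] <- TRUE
    v
  }
  mycov <- cov_of(me)
  best <- 0L
  for (i in seq_len(nrow(ann))) {
    other <- ann[i, ]
    if (other$transcript_id == me$transcript_id) next
    if (other$gene_id == me$gene_id) next
    if (other$chrom != me$chrom) next
    if (other$strand == me$strand) next
    common <- mycov & cov_of(other)
    if (!any(common)) next
    r <- rle(common)
    best <- max(best, max(r$lengths[r$values]))
  }
  if (best >= min_overlap) "lncNAT" else "lincRNA"
}
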
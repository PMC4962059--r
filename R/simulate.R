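#' Configuration of the synthetic transcriptome generator
#'
#' The generator emulates the input of a reference-guided total-RNA-Seq
#' reannotation: a genome, an annotation mixing reference and novel
#' (J/O/X/U) transcripts, sequence libraries (proteins, small-RNA
#' precursors, transposable elements, coding sequences) and a
#' differential-expression table — every planted label guaranteed
#' consistent with its construction, so the full pipeline can be checked
#' against known truth. Defaults give two 1-Mb chromosomes and roughly 300
#' transcripts.
#'
#' Non-coding length models: lncRNA lengths are drawn from a shifted
#' exponential truncated to \[`lnc_len_min`, max\], with mean about 465 nt
#' for lincRNAs (max 4,179) and about 535 nt for antisense lncRNAs
#' (max 3,780) — the right-skewed shape and the summary statistics
#' reported for plant lncRNA populations.
#'
#' @param seed integer master seed; identical seeds give byte-identical
#'   output.
#' @param n_chrom,chrom_len genome shape.
#' @param n_coding reference protein-coding genes (planted ORF of
#'   `orf_aa_range` amino acids; peptides enter the protein library).
#' @param n_novel_isoform class-J novel isoforms at coding loci (coding).
#' @param n_lincrna,n_lncnat,n_nat_near intergenic lncRNAs, antisense
#'   lncRNAs (exon overlap drawn from `nat_overlap_range`), and antisense
#'   placements with overlap below 10 nt (true lincRNAs).
#' @param n_sirna small-RNA-precursor transcripts (exact embedded copy of
#'   `sirna_copy_range` nt of a library entry).
#' @param n_te_hc,n_te_pr transposon-derived transcripts planted at
#'   high-confidence and putative/relic signal levels.
#' @param chain_sizes monoexonic intergenic fragment chains (gaps from
#'   `chain_gap_range`, all below the 500-nt fusion threshold).
#' @param n_u_decoy_pairs fragment pairs with gaps from `decoy_gap_range`
#'   (at or above the threshold; never fused).
#' @param n_short_novel novel fragments of 20-56 nt (curation removes
#'   them).
#' @param n_dup_ref duplicated reference annotations (curation merges
#'   them).
#' @param n_est,n_est_coding external EST transcripts (two of them exact
#'   duplicates of existing models, dropped at integration).
#' @param n_smallrna,n_te_entries,n_protein_decoys library sizes.
#' @param orf_aa_range planted coding ORF length, amino acids.
#' @param linc_len_mean,nat_len_mean,lnc_len_min,linc_len_max,nat_len_max
#'   lncRNA length model (nt).
#' @param sirna_copy_range embedded small-RNA copy length (nt).
#' @param te_mut_rate substitution rate applied to planted TE fragments
#'   (0 = noiseless).
#' @param nat_overlap_range antisense exon overlap (nt).
#' @param u_frag_len_range,chain_gap_range,decoy_gap_range monoexonic
#'   fragment geometry (nt).
#' @param n_linc_perfect,n_linc_near lincRNAs carrying an exact, or a
#'   roughly 97-percent-identity, coding-sequence fragment of at least
#'   100 nt.
#' @param de_fraction,de_lfc_range,de_frac_notest differential-expression
#'   table model: fraction of features planted as DE, |log2FC| range of
#'   the planted effects, fraction of untestable (NOTEST/LOWDATA) rows.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_chrom = 2L, chrom_len = 1e6,
                       n_coding = 60L, n_novel_isoform = 15L,
                       n_lincrna = 50L, n_lncnat = 25L, n_nat_near = 5L,
                       n_sirna = 40L, n_te_hc = 15L, n_te_pr = 15L,
                       chain_sizes = c(3L, 2L, 2L), n_u_decoy_pairs = 2L,
                       n_short_novel = 5L, n_dup_ref = 4L,
                       n_est = 10L, n_est_coding = 4L,
                       n_smallrna = 30L, n_te_entries = 11L,
                       n_protein_decoys = 50L,
                       orf_aa_range = c(120L, 400L),
                       linc_len_mean = 465, nat_len_mean = 535,
                       lnc_len_min = 201L, linc_len_max = 4179L,
                       nat_len_max = 3780L,
                       sirna_copy_range = c(24L, 80L),
                       te_mut_rate = 0,
                       nat_overlap_range = c(10L, 60L),
                       u_frag_len_range = c(210L, 400L),
                       chain_gap_range = c(100L, 499L),
                       decoy_gap_range = c(500L, 900L),
                       n_linc_perfect = 8L, n_linc_near = 6L,
                       de_fraction = 0.3, de_lfc_range = c(1, 5),
                       de_frac_notest = 0.15) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_chrom >= 1, cfg$chrom_len > 1e4,
            all(unlist(cfg[grep("^n_", names(cfg))]) >= 0),
            orf_aa_range[1] >= 120,
            lnc_len_min <= linc_len_max, lnc_len_min <= nat_len_max,
            n_lncnat <= n_coding, n_novel_isoform <= n_coding,
            n_linc_perfect + n_linc_near <= n_lincrna,
            te_mut_rate >= 0, te_mut_rate < 1)
  structure(cfg, class = "sim_config")
}

# shifted exponential truncated to [min, max]; right-skewed like observed
# lncRNA length distributions
rlnc_len <- function(n, mean, min, max) {
  if (n == 0) return(integer(0))
  out <- integer(0)
  while (length(out) < n) {
    x <- min + stats::rexp(2 * n, rate = 1 / (mean - min))
    out <- c(out, as.integer(x[x <= max]))
  }
  out[seq_len(n)]
}

NON_STOP_CODONS <- setdiff(names(Biostrings::GENETIC_CODE),
                           c("TAA", "TAG", "TGA"))
AA20 <- setdiff(unique(unname(Biostrings::GENETIC_CODE)), "*")

random_protein <- function(n) paste(sample(AA20, n, TRUE), collapse = "")

random_orf <- function(aa_len) {
  paste0("ATG",
         paste(sample(NON_STOP_CODONS, aa_len - 1L, TRUE), collapse = ""),
         sample(c("TAA", "TAG", "TGA"), 1))
}

# random DNA in which every sense-frame ATG reaches a stop within 119
# codons (no ORF of >= 120 aa, complete or 3'-partial)
orf_free_dna <- function(n, max_aa = 119L) {
  s <- random_dna(n)
  repeat {
    orfs <- find_orfs(s, frames = 1:3, peptides = FALSE)
    bad <- orfs[orfs$aa_length > max_aa, ]
    if (!nrow(bad)) return(s)
    pos <- bad$start[1] + 3L * sample.int(max_aa - 1L, 1)
    substr(s, pos + 1L, pos + 3L) <- "TAA"
  }
}

#' Apply independent substitutions to a sequence
#'
#' Each position mutates with probability `rate` to one of the three other
#' bases, so expected identity to the original is `100 * (1 - rate)`.
#'
#' @param seq nucleotide string.
#' @param rate substitution probability per base, in \[0, 1).
#' @param seed optional seed for a self-contained draw (the caller's RNG
#'   stream is untouched when given).
#' @return mutated sequence.
#' @export
mutate_sequence <- function(seq, rate, seed = NULL) {
  stopifnot(rate >= 0, rate < 1)
  doit <- function() {
    n <- nchar(seq)
    hit <- which(stats::runif(n) < rate)
    if (!length(hit)) return(seq)
    chars <- strsplit(seq, "")[[1]]
    chars[hit] <- vapply(chars[hit], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
    paste(chars, collapse = "")
  }
  if (is.null(seed)) doit() else with_seed(seed, doit())
}

# split a spliced sequence into exon parts (5'->3'), first/last >= 80 nt
split_exon_parts <- function(seq, n_ex) {
  L <- nchar(seq)
  n_ex <- max(1L, min(n_ex, L %/% 90L))
  if (n_ex == 1) return(seq)
  repeat {
    cuts <- sort(sample(90:(L - 90), n_ex - 1L))
    lens <- diff(c(0, cuts, L))
    if (all(lens >= 80)) break
  }
  substring(seq, c(1, cuts + 1), c(cuts, L))
}

# genomic block of one spliced transcript. Returns plus-strand content,
# exon coords relative to block start, and span.
make_spliced_block <- function(seq, strand, n_ex, intron_range = c(60, 300)) {
  parts <- split_exon_parts(seq, n_ex)
  k <- length(parts)
  exon_contents <- if (strand == "+") parts else rev(revcomp(parts))
  introns <- if (k > 1)
    vapply(seq_len(k - 1), function(i)
      random_dna(sample(intron_range[1]:intron_range[2], 1)), character(1))
  else character(0)
  pieces <- character(0)
  exons <- matrix(0L, nrow = k, ncol = 2)
  pos <- 0L
  for (i in seq_len(k)) {
    el <- nchar(exon_contents[i])
    exons[i, ] <- c(pos, pos + el)
    pieces <- c(pieces, exon_contents[i])
    pos <- pos + el
    if (i < k) {
      pieces <- c(pieces, introns[i])
      pos <- pos + nchar(introns[i])
    }
  }
  list(content = paste(pieces, collapse = ""), exons = exons, span = pos)
}

# validity of a planted non-coding transcript: no long ORF, no protein
# match of the longest ORF, and the required presence/absence of
# small-RNA / TE library homology
nc_valid <- function(seq, protein_index, sr_index, te_index,
                     need_sr = FALSE, need_te = FALSE,
                     coding_pars = NULL, match_pars = NULL) {
  coding_pars <- coding_pars %||% coding_params()
  match_pars <- match_pars %||% lnc_match_params()
  orfs <- find_orfs(seq, frames = coding_pars$frames, peptides = FALSE)
  if (nrow(orfs) && orfs$aa_length[1] >= coding_pars$orf_aa_max)
    return(FALSE)
  if (nrow(orfs) && !is.null(protein_index)) {
    pep <- orf_peptide(seq, orfs[1, ])
    if (nchar(pep) >= coding_pars$protein_params$word_size) {
      ph <- suppressWarnings(
        hom_search_protein(pep, params = coding_pars$protein_params,
                           index = protein_index))
      if (nrow(ph)) return(FALSE)
    }
  }
  sr_hit <- if (!is.null(sr_index))
    nrow(hom_search(seq, params = match_pars, index = sr_index)) > 0
  else FALSE
  if (sr_hit != need_sr) return(FALSE)
  if (!need_sr) {
    te_hit <- if (!is.null(te_index))
      nrow(hom_search(seq, params = match_pars, index = te_index)) > 0
    else FALSE
    if (te_hit != need_te) return(FALSE)
  }
  TRUE
}

draw_until <- function(max_tries, draw, valid) {
  for (i in seq_len(max_tries)) {
    x <- draw()
    if (valid(x)) return(x)
  }
  stop("synthetic generator: could not draw a valid sequence in ",
       max_tries, " attempts")
}

#' Generate a synthetic transcriptome with planted ground truth
#'
#' See [sim_config()] for the generative model. All randomness is driven
#' by `config$seed` through per-component derived seeds.
#'
#' @param config a [sim_config()].
#' @return list with elements `genome` (named character vector),
#'   `annotation` (pre-curation annotation tibble, sequences filled),
#'   `est_set` (EST annotation tibble), `libraries` (list `protein`,
#'   `smallrna`, `te`, `cds`), `de_table` (tibble in the
#'   [read_de_table()] schema), and `truth` (list: `transcripts` — the
#'   planted post-curation labels; `clusters`; `curation`; `de`).
#' @export
simulate_transcriptome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config

  ## -- libraries ---------------------------------------------------------
  libs <- with_seed(derive_seed(cfg$seed, 1), {
    smallrna <- sequence_library(
      sprintf("srna_%03d", seq_len(cfg$n_smallrna)),
      vapply(sample(80:300, cfg$n_smallrna, TRUE), random_dna,
             character(1)),
      role = "smallrna", name = "smallrna_precursors")
    sup <- rep_len(TE_SUPERFAMILY_ORDER, cfg$n_te_entries)
    fam_names <- c(RLG = "Gypsy", RLC = "Copia", RLX = "UnknownLTR",
                   RIL = "L1", DTA = "hAT", DTC = "CACTA",
                   DHH = "Helitron", DTM = "Mutator", DTH = "Harbinger",
                   DTT = "Mariner", RST = "tRNA")
    te <- sequence_library(
      sprintf("te_%03d", seq_len(cfg$n_te_entries)),
      vapply(sample(1500:2500, cfg$n_te_entries, TRUE), orf_free_dna,
             character(1)),
      role = "te", name = "te_library",
      family = unname(fam_names[sup]), superfamily = sup)
    decoys <- vapply(sample(100:300, cfg$n_protein_decoys, TRUE),
                     random_protein, character(1))
    list(smallrna = smallrna, te = te, decoys = decoys)
  })

  ## -- transcript construction (sequence space) --------------------------
  built <- with_seed(derive_seed(cfg$seed, 2), {
    blocks <- list()
    truth <- list()
    add_block <- function(b) blocks[[length(blocks) + 1L]] <<- b
    add_truth <- function(...) truth[[length(truth) + 1L]] <<- tibble(...)

    tx_row <- function(id, gene, strand, class, exons, seq) {
      list(transcript_id = id, gene_id = gene, strand = strand,
           class_code = class, exons = exons, seq = seq)
    }

    # coding reference genes
    coding <- lapply(seq_len(cfg$n_coding), function(i) {
      aa <- sample(cfg$orf_aa_range[1]:cfg$orf_aa_range[2], 1)
      orf <- random_orf(aa)
      seq <- paste0(random_dna(sample(30:150, 1)), orf,
                    random_dna(sample(100:300, 1)))
      list(gene = sprintf("GRMZM2G%06d", i),
           tx = sprintf("GRMZM2G%06d_T01", i),
           strand = sample(c("+", "-"), 1),
           seq = seq, orf_nt = orf,
           peptide = sub("\\*$", "", translate_nt(orf)),
           n_ex = sample(1:4, 1))
    })
    protein_db <- sequence_library(
      c(vapply(coding, `[[`, character(1), "tx"),
        sprintf("decoy_%03d", seq_along(libs$decoys))),
      c(vapply(coding, `[[`, character(1), "peptide"), libs$decoys),
      role = "protein", name = "proteins")
    cds_db <- sequence_library(
      vapply(coding, `[[`, character(1), "tx"),
      vapply(coding, `[[`, character(1), "orf_nt"),
      role = "cds", name = "coding_sequences")
    cp <- coding_params()
    mp <- lnc_match_params()
    p_idx <- hom_index(protein_db, cp$protein_params$word_size)
    sr_idx <- if (nrow(libs$smallrna)) hom_index(libs$smallrna,
                                                 mp$word_size) else NULL
    te_idx16 <- if (nrow(libs$te)) hom_index(libs$te, mp$word_size)
                else NULL
    ok_nc <- function(seq, need_sr = FALSE, need_te = FALSE)
      nc_valid(seq, p_idx, sr_idx, te_idx16, need_sr, need_te, cp, mp)

    # hosts for antisense lncRNAs and for class-J isoforms (disjoint;
    # J hosts restricted to plus-strand genes to keep 3' extension on the
    # genomic right)
    plus_idx <- which(vapply(coding, `[[`, character(1), "strand") == "+")
    if (length(plus_idx) < cfg$n_novel_isoform)
      stop("synthetic generator: not enough plus-strand coding genes for ",
           "novel isoforms; increase n_coding")
    j_hosts <- sample(plus_idx, cfg$n_novel_isoform)
    nat_hosts <- sample(setdiff(seq_len(cfg$n_coding), j_hosts),
                        cfg$n_lncnat + cfg$n_nat_near)

    nat_of_host <- integer(0)
    ov_of_host <- integer(0)
    nat_idx_all <- c(rep("nat", cfg$n_lncnat), rep("near", cfg$n_nat_near))
    for (k in seq_along(nat_hosts)) {
      nat_of_host[nat_hosts[k]] <- k
      ov_of_host[nat_hosts[k]] <-
        if (nat_idx_all[k] == "nat")
          sample(cfg$nat_overlap_range[1]:cfg$nat_overlap_range[2], 1)
        else sample(1:9, 1)
    }

    for (i in seq_len(cfg$n_coding)) {
      g <- coding[[i]]
      blk <- make_spliced_block(g$seq, g$strand, g$n_ex)
      txs <- list(tx_row(g$tx, g$gene, g$strand, "reference", blk$exons,
                         g$seq))
      add_truth(transcript_id = g$tx, class_code = "reference",
                category = "coding", subcategory = NA_character_,
                lnc_type = NA_character_, nat_partner_gene = NA_character_,
                te_confidence = "none", te_superfamily = NA_character_,
                target_class = NA_character_)
      content <- blk$content
      span <- blk$span
      if (i %in% j_hosts) {
        ext <- random_dna(sample(100:300, 1))
        jid <- paste0(g$tx, "_j_1")
        j_exons <- blk$exons
        j_exons[nrow(j_exons), 2] <- span + nchar(ext)
        txs[[length(txs) + 1L]] <- tx_row(jid, g$gene, "+", "J", j_exons,
                                          paste0(g$seq, ext))
        content <- paste0(content, ext)
        span <- span + nchar(ext)
        add_truth(transcript_id = jid, class_code = "J",
                  category = "coding", subcategory = NA_character_,
                  lnc_type = NA_character_,
                  nat_partner_gene = NA_character_,
                  te_confidence = "none", te_superfamily = NA_character_,
                  target_class = NA_character_)
      }
      if (!is.na(nat_of_host[i] %||% NA) && i %in% nat_hosts) {
        ov <- ov_of_host[i]
        L <- rlnc_len(1, cfg$nat_len_mean, max(cfg$lnc_len_min, ov + 50),
                      cfg$nat_len_max)
        plus_ov <- if (g$strand == "+")
          substr(content, span - ov + 1L, span)
        else revcomp(substr(g$seq, 1, ov))
        nat_strand <- if (g$strand == "+") "-" else "+"
        tail_seq <- draw_until(80, function() random_dna(L - ov),
          function(tl) {
            s <- if (nat_strand == "-") revcomp(paste0(plus_ov, tl))
                 else paste0(plus_ov, tl)
            ok_nc(s)
          })
        # recompute final sequence from the accepted tail
        nat_seq <- if (nat_strand == "-") revcomp(paste0(plus_ov, tail_seq))
                   else paste0(plus_ov, tail_seq)
        nid <- paste0(g$tx, "_X_1")
        n_exons <- matrix(c(span - ov, span - ov + L), nrow = 1)
        txs[[length(txs) + 1L]] <- tx_row(nid, paste0(g$gene, "_X"),
                                          nat_strand, "X", n_exons, nat_seq)
        content <- paste0(content, tail_seq)
        span <- span + nchar(tail_seq)
        is_true_nat <- ov >= 10
        add_truth(transcript_id = nid, class_code = "X",
                  category = "pot_lncRNA", subcategory = "lncRNA",
                  lnc_type = if (is_true_nat) "lncNAT" else "lincRNA",
                  nat_partner_gene = if (is_true_nat) g$gene
                                     else NA_character_,
                  te_confidence = "none", te_superfamily = NA_character_,
                  target_class = NA_character_)
      }
      add_block(list(content = content, txs = txs))
    }

    # small-RNA precursor transcripts (reference-class ncRNA loci)
    for (i in seq_len(cfg$n_sirna)) {
      entry <- libs$smallrna[sample.int(nrow(libs$smallrna), 1), ]
      seq <- draw_until(80, function() {
        cl <- sample(cfg$sirna_copy_range[1]:
                       min(cfg$sirna_copy_range[2], nchar(entry$sequence)),
                     1)
        off <- sample.int(nchar(entry$sequence) - cl + 1L, 1)
        copy <- substr(entry$sequence, off, off + cl - 1L)
        L <- sample(250:600, 1)
        at <- sample.int(L - cl + 1L, 1)
        paste0(random_dna(at - 1L), copy, random_dna(L - cl - at + 1L))
      }, function(s) ok_nc(s, need_sr = TRUE))
      gid <- sprintf("GRMZM2G8%05d", i)
      tid <- paste0(gid, "_T01")
      add_block(list(content = seq, txs = list(
        tx_row(tid, gid, "+", "reference",
               matrix(c(0L, nchar(seq)), 1), seq))))
      add_truth(transcript_id = tid, class_code = "reference",
                category = "pot_lncRNA", subcategory = "siRNA_precursor",
                lnc_type = NA_character_, nat_partner_gene = NA_character_,
                te_confidence = "none", te_superfamily = NA_character_,
                target_class = NA_character_)
    }

    # transposon-derived transcripts (intergenic, class U)
    te_plan <- tibble(
      conf = c(rep("HC", cfg$n_te_hc), rep("PR", cfg$n_te_pr)),
      frag = c(rep(500L, cfg$n_te_hc), rep(200L, cfg$n_te_pr)),
      flank = c(rep(200L, cfg$n_te_hc), rep(350L, cfg$n_te_pr)))
    te_txs <- lapply(seq_len(nrow(te_plan)), function(i) {
      entry <- libs$te[sample.int(nrow(libs$te), 1), ]
      seq <- draw_until(80, function() {
        off <- sample.int(nchar(entry$sequence) - te_plan$frag[i] + 1L, 1)
        frag <- substr(entry$sequence, off, off + te_plan$frag[i] - 1L)
        if (cfg$te_mut_rate > 0)
          frag <- mutate_sequence(frag, cfg$te_mut_rate)
        paste0(random_dna(te_plan$flank[i]), frag,
               random_dna(te_plan$flank[i]))
      }, function(s) ok_nc(s, need_te = TRUE))
      list(seq = seq, conf = te_plan$conf[i],
           superfamily = entry$superfamily, family = entry$family)
    })

    # intergenic lncRNAs, some with planted coding-sequence targets
    linc_target_class <- c(rep("perfect", cfg$n_linc_perfect),
                           rep("near_exact", cfg$n_linc_near),
                           rep("none", cfg$n_lincrna - cfg$n_linc_perfect -
                                 cfg$n_linc_near))
    linc_txs <- lapply(seq_len(cfg$n_lincrna), function(i) {
      tcl <- linc_target_class[i]
      L <- rlnc_len(1, cfg$linc_len_mean, max(cfg$lnc_len_min, 260),
                    cfg$linc_len_max)
      seq <- draw_until(120, function() {
        base <- random_dna(L)
        if (tcl == "none") return(base)
        cds <- cds_db$sequence[sample.int(nrow(cds_db), 1)]
        fl <- if (tcl == "perfect")
          sample(100:min(200, nchar(cds)), 1) else 150L
        off <- sample.int(nchar(cds) - fl + 1L, 1)
        frag <- substr(cds, off, off + fl - 1L)
        if (tcl == "near_exact") {
          # four interior mismatches: identity 146/150 = 97.33%
          for (pos in c(25L, 55L, 85L, 115L)) {
            b <- substr(frag, pos, pos)
            substr(frag, pos, pos) <- sample(setdiff(c("A", "C", "G", "T"),
                                                     b), 1)
          }
        }
        at <- sample.int(L - fl + 1L, 1)
        paste0(substr(base, 1, at - 1L), frag,
               substr(base, at + fl, L))
      }, ok_nc)
      list(seq = seq, target_class = tcl)
    })

    list(blocks = blocks, truth = dplyr::bind_rows(truth),
         coding = coding, protein_db = protein_db, cds_db = cds_db,
         te_txs = te_txs, linc_txs = linc_txs, ok_nc = ok_nc)
  })

  ## -- more sequence-space material needing the validators ---------------
  extra <- with_seed(derive_seed(cfg$seed, 3), {
    ok_nc <- built$ok_nc
    # monoexonic intergenic chains (fused by curation) and decoy pairs
    chains <- lapply(seq_along(cfg$chain_sizes), function(ci) {
      k <- cfg$chain_sizes[ci]
      draw_until(80, function() {
        frag_len <- sample(cfg$u_frag_len_range[1]:cfg$u_frag_len_range[2],
                           k, TRUE)
        gaps <- sample(cfg$chain_gap_range[1]:cfg$chain_gap_range[2],
                       k - 1L, TRUE)
        pieces <- character(0)
        rel <- matrix(0L, k, 2)
        pos <- 0L
        for (j in seq_len(k)) {
          pieces <- c(pieces, random_dna(frag_len[j]))
          rel[j, ] <- c(pos, pos + frag_len[j])
          pos <- pos + frag_len[j]
          if (j < k) {
            pieces <- c(pieces, random_dna(gaps[j]))
            pos <- pos + gaps[j]
          }
        }
        list(content = paste(pieces, collapse = ""), rel = rel, span = pos)
      }, function(ch) ok_nc(ch$content))
    })
    decoys <- lapply(seq_len(cfg$n_u_decoy_pairs), function(i) {
      f1 <- draw_until(80, function()
        random_dna(sample(cfg$u_frag_len_range[1]:
                            cfg$u_frag_len_range[2], 1)), ok_nc)
      f2 <- draw_until(80, function()
        random_dna(sample(cfg$u_frag_len_range[1]:
                            cfg$u_frag_len_range[2], 1)), ok_nc)
      gap <- sample(cfg$decoy_gap_range[1]:cfg$decoy_gap_range[2], 1)
      list(content = paste0(f1, random_dna(gap), f2),
           rel = matrix(c(0L, nchar(f1),
                          nchar(f1) + gap, nchar(f1) + gap + nchar(f2)),
                        2, 2, byrow = TRUE))
    })
    shorts <- lapply(seq_len(cfg$n_short_novel), function(i)
      random_dna(sample(20:56, 1)))
    # external ESTs: coding ones carry a 150-aa ORF, the rest validated nc
    est_seqs <- lapply(seq_len(max(0L, cfg$n_est - 2L)), function(i) {
      if (i <= cfg$n_est_coding) {
        paste0(random_dna(60), random_orf(150L), random_dna(120))
      } else {
        draw_until(80, function() random_dna(sample(300:800, 1)), ok_nc)
      }
    })
    list(chains = chains, decoys = decoys, shorts = shorts,
         est_seqs = est_seqs)
  })

  ## -- placement on the genome -------------------------------------------
  placed <- with_seed(derive_seed(cfg$seed, 4), {
    blocks <- built$blocks
    # wrap remaining material as blocks
    for (te in built$te_txs)
      blocks[[length(blocks) + 1L]] <- list(
        content = te$seq,
        txs = list(list(transcript_id = NA, gene_id = NA, strand = "+",
                        class_code = "U",
                        exons = matrix(c(0L, nchar(te$seq)), 1),
                        seq = te$seq, kind = "te",
                        te_confidence = te$conf,
                        te_superfamily = te$superfamily)))
    for (i in seq_along(built$linc_txs)) {
      lt <- built$linc_txs[[i]]
      cls <- if (i %% 5 < 3) "reference" else "U"   # 60/40 split
      blocks[[length(blocks) + 1L]] <- list(
        content = lt$seq,
        txs = list(list(transcript_id = NA, gene_id = NA, strand = "+",
                        class_code = cls,
                        exons = matrix(c(0L, nchar(lt$seq)), 1),
                        seq = lt$seq, kind = "linc",
                        target_class = lt$target_class,
                        linc_no = i)))
    }
    for (ci in seq_along(extra$chains)) {
      ch <- extra$chains[[ci]]
      k <- nrow(ch$rel)
      blocks[[length(blocks) + 1L]] <- list(
        content = ch$content, chain_id = ci,
        txs = lapply(seq_len(k), function(j)
          list(transcript_id = NA, gene_id = NA, strand = "+",
               class_code = "U",
               exons = ch$rel[j, , drop = FALSE],
               seq = substr(ch$content, ch$rel[j, 1] + 1L, ch$rel[j, 2]),
               kind = "chain_frag", chain = ci)))
    }
    for (di in seq_along(extra$decoys)) {
      d <- extra$decoys[[di]]
      blocks[[length(blocks) + 1L]] <- list(
        content = d$content,
        txs = lapply(1:2, function(j)
          list(transcript_id = NA, gene_id = NA, strand = "+",
               class_code = "U",
               exons = d$rel[j, , drop = FALSE],
               seq = substr(d$content, d$rel[j, 1] + 1L, d$rel[j, 2]),
               kind = "decoy_frag")))
    }
    for (si in seq_along(extra$shorts)) {
      s <- extra$shorts[[si]]
      blocks[[length(blocks) + 1L]] <- list(
        content = s,
        txs = list(list(transcript_id = sprintf("CUFF.SHORT.%d", si),
                        gene_id = sprintf("CUFF.SHORTG.%d", si),
                        strand = "+", class_code = "U",
                        exons = matrix(c(0L, nchar(s)), 1),
                        seq = s, kind = "short")))
    }
    for (ei in seq_along(extra$est_seqs)) {
      s <- extra$est_seqs[[ei]]
      blocks[[length(blocks) + 1L]] <- list(
        content = s,
        txs = list(list(transcript_id = sprintf("EST_%03d", ei),
                        gene_id = sprintf("ESTG_%03d", ei),
                        strand = "+", class_code = "EST",
                        exons = matrix(c(0L, nchar(s)), 1),
                        seq = s, kind = "est",
                        est_coding = ei <= cfg$n_est_coding)))
    }

    # shuffle blocks, deal them round-robin over chromosomes
    blocks <- blocks[sample.int(length(blocks))]
    chrom_names <- sprintf("chr%d", seq_len(cfg$n_chrom))
    cursors <- stats::setNames(rep(0L, cfg$n_chrom), chrom_names)
    segments <- stats::setNames(vector("list", cfg$n_chrom), chrom_names)
    tx_rows <- list()
    for (bi in seq_along(blocks)) {
      b <- blocks[[bi]]
      ch <- chrom_names[(bi - 1L) %% cfg$n_chrom + 1L]
      gap <- sample(600:3000, 1)
      offset <- cursors[[ch]] + gap
      if (offset + nchar(b$content) > cfg$chrom_len)
        stop("impossible placement: chromosome ", ch,
             " too small for the configured transcript load")
      segments[[ch]] <- c(segments[[ch]], random_dna(gap), b$content)
      cursors[[ch]] <- offset + nchar(b$content)
      for (tx in b$txs) {
        tx$chrom <- ch
        tx$exons <- tx$exons + offset
        tx$chain_id <- b$chain_id %||% NA
        tx_rows[[length(tx_rows) + 1L]] <- tx
      }
    }
    # pad chromosomes to their configured length
    for (ch in chrom_names) {
      pad <- cfg$chrom_len - cursors[[ch]]
      if (pad > 0) segments[[ch]] <- c(segments[[ch]], random_dna(pad))
    }
    genome <- vapply(segments, paste, character(1), collapse = "")
    list(genome = genome, tx_rows = tx_rows)
  })

  ## -- identifiers, annotation assembly, truth ---------------------------
  rows <- placed$tx_rows
  starts <- vapply(rows, function(r) r$exons[1, 1], numeric(1))
  chroms <- vapply(rows, function(r) r$chrom, character(1))
  needs_tcons <- vapply(rows, function(r)
    is.na(r$transcript_id %||% NA) &&
      (r$kind %||% "") %in% c("te", "linc", "chain_frag", "decoy_frag") &&
      r$class_code == "U", logical(1))
  ord <- order(chroms, starts)
  counter <- 0L
  for (i in ord) {
    if (!needs_tcons[i]) next
    counter <- counter + 1L
    rows[[i]]$transcript_id <- sprintf("TCONS_%08d", counter)
    rows[[i]]$gene_id <- sprintf("XLOC_%06d", counter)
  }
  # reference-class lincRNAs and siRNA loci already named; remaining
  # reference-class lincs get stable GRMZM5G ids
  for (i in seq_along(rows)) {
    if (is.na(rows[[i]]$transcript_id %||% NA)) {
      lid <- sprintf("GRMZM5G%05d", rows[[i]]$linc_no)
      rows[[i]]$gene_id <- lid
      rows[[i]]$transcript_id <- paste0(lid, "_T01")
    }
  }

  ann <- annotation_tbl(
    transcript_id = vapply(rows, `[[`, character(1), "transcript_id"),
    gene_id = vapply(rows, `[[`, character(1), "gene_id"),
    chrom = vapply(rows, `[[`, character(1), "chrom"),
    strand = vapply(rows, `[[`, character(1), "strand"),
    class_code = vapply(rows, `[[`, character(1), "class_code"),
    exons = lapply(rows, `[[`, "exons"),
    sequence = vapply(rows, `[[`, character(1), "seq")
  )
  est_mask <- ann$class_code == "EST"
  est_set <- ann[est_mask, ]
  ann <- ann[!est_mask, ]

  # duplicated reference annotations (merged away by curation)
  dup_log <- tibble(kept_id = character(0), dup_id = character(0))
  if (cfg$n_dup_ref > 0) {
    ref_idx <- which(ann$class_code == "reference" &
                       grepl("^GRMZM2G0", ann$transcript_id))
    pick <- with_seed(derive_seed(cfg$seed, 5),
                      sample(ref_idx, min(cfg$n_dup_ref, length(ref_idx))))
    dup <- ann[pick, ]
    dup$transcript_id <- sprintf("zma-DUP%02d", seq_along(pick))
    dup$gene_id <- sprintf("zma-DUPG%02d", seq_along(pick))
    dup_log <- tibble(kept_id = ann$transcript_id[pick],
                      dup_id = dup$transcript_id)
    ann <- bind_rows(ann, dup)
  }

  # EST duplicates of existing models (dropped at integration)
  if (cfg$n_est >= 2 && nrow(ann) > 0) {
    src <- with_seed(derive_seed(cfg$seed, 6), {
      ref_idx <- which(ann$class_code == "reference")
      sample(ref_idx, 2)
    })
    dup_est <- ann[src, ]
    dup_est$transcript_id <- sprintf("EST_DUP_%02d", 1:2)
    dup_est$gene_id <- sprintf("ESTG_DUP_%02d", 1:2)
    dup_est$class_code <- "EST"
    est_set <- bind_rows(est_set, dup_est)
  }

  ## predicted post-curation truth rows for the later material
  extra_truth <- list()
  for (r in rows) {
    kind <- r$kind %||% ""
    if (kind == "te") {
      extra_truth[[length(extra_truth) + 1L]] <- tibble(
        transcript_id = r$transcript_id, class_code = "U",
        category = "pot_lncRNA", subcategory = "TE_derived",
        lnc_type = NA_character_, nat_partner_gene = NA_character_,
        te_confidence = r$te_confidence, te_superfamily = r$te_superfamily,
        target_class = NA_character_)
    } else if (kind == "linc") {
      extra_truth[[length(extra_truth) + 1L]] <- tibble(
        transcript_id = r$transcript_id, class_code = r$class_code,
        category = "pot_lncRNA", subcategory = "lncRNA",
        lnc_type = "lincRNA", nat_partner_gene = NA_character_,
        te_confidence = "none", te_superfamily = NA_character_,
        target_class = if (r$target_class == "none") NA_character_
                       else r$target_class)
    } else if (kind == "decoy_frag") {
      extra_truth[[length(extra_truth) + 1L]] <- tibble(
        transcript_id = r$transcript_id, class_code = "U",
        category = "pot_lncRNA", subcategory = "lncRNA",
        lnc_type = "lincRNA", nat_partner_gene = NA_character_,
        te_confidence = "none", te_superfamily = NA_character_,
        target_class = NA_character_)
    } else if (kind == "est") {
      extra_truth[[length(extra_truth) + 1L]] <- tibble(
        transcript_id = r$transcript_id, class_code = "EST",
        category = if (isTRUE(r$est_coding)) "coding" else "pot_lncRNA",
        subcategory = if (isTRUE(r$est_coding)) NA_character_
                      else "lncRNA",
        lnc_type = if (isTRUE(r$est_coding)) NA_character_ else "lincRNA",
        nat_partner_gene = NA_character_,
        te_confidence = "none", te_superfamily = NA_character_,
        target_class = NA_character_)
    }
  }

  # predicted fused clusters: chains numbered in genomic order
  chain_rows <- Filter(function(r) (r$kind %||% "") == "chain_frag", rows)
  cluster_truth <- tibble(cluster_id = character(0), chrom = character(0),
                          start = integer(0), end = integer(0),
                          n_members = integer(0), member_ids = list())
  if (length(chain_rows)) {
    by_chain <- split(chain_rows,
                      vapply(chain_rows, `[[`, numeric(1), "chain"))
    spans <- lapply(by_chain, function(cr) {
      st <- min(vapply(cr, function(r) r$exons[1, 1], numeric(1)))
      en <- max(vapply(cr, function(r) r$exons[1, 2], numeric(1)))
      list(chrom = cr[[1]]$chrom, start = st, end = en,
           ids = vapply(cr, `[[`, character(1), "transcript_id"))
    })
    sp_ord <- order(vapply(spans, `[[`, character(1), "chrom"),
                    vapply(spans, `[[`, numeric(1), "start"))
    spans <- spans[sp_ord]
    cluster_truth <- dplyr::bind_rows(lapply(seq_along(spans), function(k) {
      s <- spans[[k]]
      tibble(cluster_id = sprintf("Cluster_t_%d", k), chrom = s$chrom,
             start = as.integer(s$start), end = as.integer(s$end),
             n_members = length(s$ids), member_ids = list(s$ids))
    }))
    for (k in seq_len(nrow(cluster_truth))) {
      extra_truth[[length(extra_truth) + 1L]] <- tibble(
        transcript_id = cluster_truth$cluster_id[k], class_code = "U",
        category = "pot_lncRNA", subcategory = "lncRNA",
        lnc_type = "lincRNA", nat_partner_gene = NA_character_,
        te_confidence = "none", te_superfamily = NA_character_,
        target_class = NA_character_)
    }
  }

  truth_template <- tibble(
    transcript_id = character(0), class_code = character(0),
    category = character(0), subcategory = character(0),
    lnc_type = character(0), nat_partner_gene = character(0),
    te_confidence = character(0), te_superfamily = character(0),
    target_class = character(0))
  truth_tx <- bind_rows(truth_template, built$truth,
                        dplyr::bind_rows(extra_truth))

  ## -- differential-expression table -------------------------------------
  de <- with_seed(derive_seed(cfg$seed, 7), {
    ids <- truth_tx$transcript_id
    n <- length(ids)
    notest <- stats::runif(n) < cfg$de_frac_notest
    is_de <- !notest & stats::runif(n) < cfg$de_fraction
    lfc <- numeric(n)
    lfc[is_de] <- sample(c(-1, 1), sum(is_de), TRUE) *
      stats::runif(sum(is_de), cfg$de_lfc_range[1], cfg$de_lfc_range[2])
    small <- !notest & !is_de & stats::runif(n) < 0.5
    lfc[small] <- stats::runif(sum(small), -0.9, 0.9)
    big_ns <- !notest & !is_de & !small
    lfc[big_ns] <- sample(c(-1, 1), sum(big_ns), TRUE) *
      stats::runif(sum(big_ns), 1, cfg$de_lfc_range[2])
    q <- rep(NA_real_, n)
    q[is_de] <- stats::runif(sum(is_de), 0, 0.049)
    q[small] <- stats::runif(sum(small), 0, 1)
    q[big_ns] <- stats::runif(sum(big_ns), 0.051, 1)
    rpkm_a <- 2^stats::runif(n, 0, 7)
    rpkm_a[notest] <- stats::runif(sum(notest), 0, 0.9)
    rpkm_b <- rpkm_a * 2^lfc
    tab <- tibble(
      feature_id = ids, level = "transcript",
      status = ifelse(notest, sample(c("NOTEST", "LOWDATA"), n, TRUE),
                      "OK"),
      rpkm_a = round(rpkm_a, 4), rpkm_b = round(rpkm_b, 4),
      log2fc = ifelse(notest, NA_real_,
                      round_half_up(log2(rpkm_b / rpkm_a), 2)),
      q_value = round(q, 5),
      chrom = NA_character_, position = NA_real_)
    list(table = tab,
         truth = tibble(feature_id = ids, is_de = is_de,
                        direction = dplyr::case_when(
                          is_de & lfc > 0 ~ "up",
                          is_de & lfc < 0 ~ "down",
                          TRUE ~ "ns")))
  })

  list(genome = placed$genome,
       annotation = ann,
       est_set = est_set,
       libraries = list(protein = built$protein_db,
                        smallrna = libs$smallrna,
                        te = libs$te,
                        cds = built$cds_db),
       de_table = de$table,
       truth = list(transcripts = truth_tx,
                    clusters = cluster_truth,
                    curation = list(
                      dup_log = dup_log,
                      short_ids = grep("^CUFF\\.SHORT\\.",
                                       ann$transcript_id, value = TRUE),
                      est_added = setdiff(est_set$transcript_id,
                                          sprintf("EST_DUP_%02d", 1:2)),
                      est_dropped = intersect(est_set$transcript_id,
                                              sprintf("EST_DUP_%02d", 1:2))),
                    de = de$truth),
       config = cfg)
}

#' Write a simulated dataset to disk
#'
#' Emits `genome.fa`, `annotation.gtf`, `est.gtf`, one FASTA per library,
#' `de_table.tsv` and `truth_transcripts.tsv` under `dir`.
#'
#' @param sim output of [simulate_transcriptome()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(paste0(">", names(sim$genome), "\n", sim$genome),
             file.path(dir, "genome.fa"))
  write_gtf(sim$annotation, file.path(dir, "annotation.gtf"))
  write_gtf(sim$est_set, file.path(dir, "est.gtf"))
  for (nm in names(sim$libraries))
    write_fasta_library(sim$libraries[[nm]],
                        file.path(dir, paste0(nm, ".fa")))
  readr::write_tsv(sim$de_table, file.path(dir, "de_table.tsv"),
                   progress = FALSE)
  readr::write_tsv(sim$truth$transcripts,
                   file.path(dir, "truth_transcripts.tsv"),
                   progress = FALSE)
  invisible(dir)
}
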
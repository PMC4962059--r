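test_that("log2 fold change reproduces published worked rows", {
  expect_equal(compute_log2fc(10.14, 25.32), 1.32)
  expect_equal(compute_log2fc(16.88, 65.19), 1.95)
  expect_equal(compute_log2fc(7.68, 45.13), 2.55)
  expect_equal(compute_log2fc(5, 5), 0)
  expect_equal(compute_log2fc(c(2, 4), c(4, 2)), c(1, -1))
  expect_error(compute_log2fc(0, 5), "positive")
  expect_error(compute_log2fc(5, 0), "positive")
})

de_tbl <- function(log2fc, q, status = "OK", chrom = NA_character_,
                   position = NA_real_) {
  tibble::tibble(feature_id = sprintf("f%03d", seq_along(log2fc)),
                 level = "gene", status = status,
                 rpkm_a = 10, rpkm_b = 10 * 2^ifelse(is.na(log2fc), 0,
                                                     log2fc),
                 log2fc = log2fc, q_value = q, chrom = chrom,
                 position = position)
}

test_that("significance bounds are inclusive and statuses excluded", {
  d <- de_tbl(log2fc = c(1.0, 0.99, -1.0, 2, 2, NA),
              q = c(0.05, 0.01, 0.05, 0.051, 0.01, NA),
              status = c("OK", "OK", "OK", "OK", "NOTEST", "LOWDATA"))
  f <- filter_de(d)
  expect_equal(f$significant, c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(f$direction[1], "up")
  expect_equal(f$direction[3], "down")
  # up and down partition the significant set
  expect_equal(sum(f$direction != "ns"), sum(f$significant))
})

test_that("an exclusion region masks features inside it", {
  d <- de_tbl(log2fc = c(3, 3, 3), q = c(0.01, 0.01, 0.01),
              chrom = c("c5", "c5", "c2"),
              position = c(15e6, 40e6, 15e6))
  p <- de_filter_params(exclusion_region = list(chrom = "c5", start = 0,
                                                end = 30e6))
  f <- filter_de(d, p)
  expect_equal(f$excluded_region, c(TRUE, FALSE, FALSE))
  expect_equal(f$significant, c(FALSE, TRUE, TRUE))
})

test_that("relaxing thresholds never shrinks the significant set", {
  set.seed(61)
  d <- de_tbl(log2fc = round(runif(300, -4, 4), 2),
              q = round(runif(300), 4))
  base <- filter_de(d, de_filter_params(min_abs_log2fc = 1.5, max_q = 0.02))
  for (p in list(de_filter_params(min_abs_log2fc = 1.0, max_q = 0.02),
                 de_filter_params(min_abs_log2fc = 1.5, max_q = 0.1),
                 de_filter_params(min_abs_log2fc = 0.5, max_q = 0.2))) {
    wider <- filter_de(d, p)
    expect_true(all(wider$significant[base$significant]))
  }
  # brute-force agreement
  p <- de_filter_params()
  want <- d$status == "OK" & abs(d$log2fc) >= 1 & d$q_value <= 0.05
  expect_equal(filter_de(d, p)$significant, want)
})

test_that("cross-tabulation conserves row and column totals", {
  sim <- shared_sim
  res <- run_reannotation_pipeline(sim$annotation, sim$genome,
                                   sim$libraries, est_set = sim$est_set)
  f <- filter_de(sim$de_table)
  xt <- cross_tabulate(f, tidy(res$classification))
  n_sig <- sum(f$significant)
  expect_equal(sum(xt$by_class$total), n_sig)
  expect_equal(sum(xt$by_category$total), n_sig)
  expect_equal(sum(xt$by_class$up) + sum(xt$by_class$down), n_sig)
  # planted truth: filter_de recovers the generator's DE labels
  joined <- dplyr::left_join(f, sim$truth$de, by = "feature_id")
  expect_equal(joined$significant, joined$is_de)
  # all-up table has an empty down column
  up_only <- filter_de(de_tbl(log2fc = c(2, 3), q = c(0.01, 0.01)))
  xt2 <- cross_tabulate(up_only, tidy(res$classification))
  expect_true(all(xt2$by_category$down == 0))
})

test_that("set intersections agree with brute-force set algebra", {
  di <- intersect_sets(list(A = c("a", "b"), B = c("c", "d")))
  expect_equal(di$n_intersection[di$combination == "A&B"], 0)
  same <- intersect_sets(list(A = c("a", "b"), B = c("a", "b")))
  expect_equal(same$n_intersection[same$combination == "A&B"], 2)
  expect_equal(same$n_exclusive[same$combination == "A"], 0)
  set.seed(62)
  for (rep in 1:20) {
    sets <- list(A = sample(letters, sample(5:15, 1)),
                 B = sample(letters, sample(5:15, 1)),
                 C = sample(letters, sample(5:15, 1)))
    tab <- intersect_sets(sets)
    for (i in seq_len(nrow(tab))) {
      nm <- strsplit(tab$combination[i], "&", fixed = TRUE)[[1]]
      inter <- Reduce(intersect, sets[nm])
      excl <- setdiff(inter, unlist(sets[setdiff(names(sets), nm)]))
      expect_equal(tab$n_intersection[i], length(inter))
      expect_equal(tab$n_exclusive[i], length(excl))
    }
    # inclusion-exclusion closure: exclusive regions partition the union
    expect_equal(sum(tab$n_exclusive), length(unique(unlist(sets))))
  }
})

test_that("Pearson correlation behaves on exact and planted inputs", {
  x <- c(1, 2, 3, 4)
  expect_equal(correlate_lfc(data.frame(x = x, y = x)), 1)
  expect_equal(correlate_lfc(data.frame(x = x, y = -x)), -1)
  expect_error(correlate_lfc(data.frame(x = 1:2, y = 1:2)), "3")
  expect_error(correlate_lfc(data.frame(x = x, y = rep(1, 4))), "variance")
  set.seed(63)
  n <- 1000; rho <- 0.7
  x <- rnorm(n)
  y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
  expect_lt(abs(correlate_lfc(data.frame(x = x, y = y)) - rho), 0.05)
})
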
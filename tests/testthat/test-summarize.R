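# Descriptive statistics over filtered sets.

mk_uniques <- function(jc, pc = NULL, fc = NULL, freq = NULL) {
  n <- length(jc)
  calls <- do.call(rbind, lapply(seq_len(n), function(i) {
    f <- if (is.null(freq)) 1 else freq[i]
    do.call(rbind, lapply(seq_len(f), function(s)
      make_call("A", paste0("B", i), "chr1", i, "+", "chr2", 20, "+",
                sample_id = paste0("s", s))))
  }))
  idx <- match(paste0("B", seq_len(n)), calls$gene3)
  map <- function(x) if (is.null(x)) rep("na", n) else x
  calls$junction_class <- jc[match(calls$gene3, paste0("B", seq_len(n)))]
  calls$pair_class <- map(pc)[match(calls$gene3, paste0("B", seq_len(n)))]
  calls$frame_class <- map(fc)[match(calls$gene3, paste0("B", seq_len(n)))]
  dedupe(calls)
}

test_that("stage distributions normalize class proportions", {
  all_u <- mk_uniques(c(rep("EE", 4), rep("MM", 12), rep("EM", 4)),
                      pc = rep(c("read_through", "inter_chromosomal"), 10))
  non_mm <- mk_uniques(c(rep("EE", 4), rep("EM", 4)))
  rec <- mk_uniques(rep("EE", 3))
  d <- stage_distributions(all_u, non_mm, rec)
  expect_equal(unname(d$all$junction_class["EE"]), 0.20)
  expect_equal(sum(d$all$junction_class), 1)
  expect_equal(sum(d$all$pair_class), 1)
  expect_equal(unname(d$non_mm_recurrent$junction_class["EE"]), 1.0)
  empty_u <- rec
  empty_u$table <- rec$table[0, ]
  expect_error(stage_distributions(all_u, non_mm, empty_u), "empty")
})

test_that("splice-motif percentages exclude undefined flags and empty classes", {
  u <- mk_uniques(c("EE", "EE", "EE", "EE", "MM"))
  u$table$donor_motif <- c(TRUE, TRUE, FALSE, NA, FALSE)
  u$table$acceptor_motif <- c(TRUE, FALSE, FALSE, FALSE, TRUE)
  s <- splice_motif_summary(u)
  ee <- s[s$junction_class == "EE", ]
  expect_equal(ee$donor_pct, round(100 * 2 / 3, 1))   # NA excluded
  expect_equal(ee$n_donor, 3)
  expect_equal(ee$acceptor_pct, 25)
  ## no ME row at all, rather than a 0% row
  expect_false("ME" %in% s$junction_class)
})

test_that("frequency histogram counts by value and conserves totals", {
  u <- mk_uniques(rep("EE", 4), freq = c(1, 1, 2, 5))
  h <- frequency_histogram(u)
  expect_equal(h[["1"]], 2)
  expect_equal(h[["2"]], 1)
  expect_equal(h[["5"]], 1)
  expect_equal(sum(h), nrow(u$table))
  empty <- mk_uniques(rep("EE", 1))
  empty$table <- empty$table[0, ]
  expect_length(frequency_histogram(empty), 0)
})

test_that("relative-expression CDF is a nondecreasing step function", {
  calls <- rbind(
    make_call("A", "B", "chr1", 1, "+", "chr2", 2, "+",
              chimera_expr = 10, gene5_expr = 20, gene3_expr = 20),
    make_call("C", "D", "chr1", 3, "+", "chr2", 4, "+",
              chimera_expr = 10, gene5_expr = 20, gene3_expr = 20)
  )
  res <- relative_expression_cdf(calls)
  expect_equal(res$cdf$cdf5[res$cdf$grid < 0.5], rep(0, sum(res$cdf$grid < 0.5)))
  expect_equal(res$cdf$cdf5[res$cdf$grid >= 0.5], rep(1, sum(res$cdf$grid >= 0.5)))
  expect_true(all(diff(res$cdf$cdf5) >= 0))
  expect_equal(res$cdf$cdf5[nrow(res$cdf)], 1)
  ## per-chimera aggregation takes the maximum supporting call by default
  calls2 <- rbind(
    make_call("A", "B", "chr1", 1, "+", "chr2", 2, "+", sample_id = "s1",
              chimera_expr = 5, gene5_expr = 20),
    make_call("A", "B", "chr1", 1, "+", "chr2", 2, "+", sample_id = "s2",
              chimera_expr = 15, gene5_expr = 20)
  )
  expect_equal(relative_expression_cdf(calls2)$ratios$ratio5, 0.75)
  expect_equal(relative_expression_cdf(calls2, aggregate = "mean")$ratios$ratio5, 0.5)
  ## brute-force empirical CDF agreement on random data
  set.seed(4)
  calls3 <- do.call(rbind, lapply(1:50, function(i)
    make_call("A", paste0("B", i), "chr1", i, "+", "chr2", 2, "+",
              chimera_expr = runif(1, 0, 30), gene5_expr = runif(1, 10, 40))))
  res3 <- relative_expression_cdf(calls3)
  for (g in res3$cdf$grid)
    expect_equal(res3$cdf$cdf5[res3$cdf$grid == g],
                 mean(res3$ratios$ratio5 <= g))
})

test_that("rank-sum test matches an exact enumeration oracle on small groups", {
  exact_p <- function(x, y) {
    ## enumerate all assignments of the pooled values to group 1
    pooled <- c(x, y); n1 <- length(x)
    W_obs <- sum(rank(pooled)[seq_len(n1)])
    combos <- utils::combn(length(pooled), n1)
    W_all <- apply(combos, 2, function(idx) sum(rank(pooled)[idx]))
    EW <- n1 * (length(pooled) + 1) / 2
    mean(abs(W_all - EW) >= abs(W_obs - EW) - 1e-9)
  }
  set.seed(10)
  for (i in 1:25) {
    x <- round(runif(sample(3:8, 1)) * 1000)
    y <- round(runif(sample(3:8, 1)) * 1000)
    if (any(duplicated(c(x, y)))) next
    expect_equal(rank_sum_test(x, y)$p_value, exact_p(x, y), tolerance = 1e-9)
  }
  expect_error(rank_sum_test(1, c(2, 3)), "at least 2")
})

test_that("3'UTR comparison returns near-1 p for identical groups", {
  starts <- seq(101, by = 1000, length.out = 12)
  utrs <- rep(c(30, 60, 90, 120), 3)
  feats <- do.call(rbind, lapply(1:12, function(i)
    gene_features(sprintf("G%02d", i), "chr1", "+",
                  iv(starts[i], starts[i] + 299),
                  cds = iv(starts[i], starts[i] + 299 - utrs[i]))))
  ann <- build_annotation(feats)
  same <- sprintf("G%02d", 1:12)
  res <- utr3_comparison(same, same, ann)
  expect_equal(res$p_5p_vs_3p, 1, tolerance = 0.05)
  expect_equal(sort(res$utr3_5p), sort(rep(c(30, 60, 90, 120), 3)))
  expect_error(utr3_comparison("G01", "G02", ann), "fewer than 2")
})

test_that("chromosome correlation is 1 for proportional counts and flags degeneracy", {
  feats <- do.call(rbind, lapply(1:3, function(ci)
    do.call(rbind, lapply(seq_len(2 * ci), function(i)
      gene_features(sprintf("C%d_%d", ci, i), paste0("chr", ci), "+",
                    iv(1000 * i, 1000 * i + 99))))))
  ann <- build_annotation(feats)
  ## pick half the genes of each chromosome as parents: proportional counts
  parents <- unlist(lapply(1:3, function(ci) sprintf("C%d_%d", ci, seq_len(ci))))
  calls <- do.call(rbind, lapply(seq_along(parents), function(i)
    make_call(parents[i], parents[i], "chr1", 1, "+", "chr1", 2, "+",
              sample_id = paste0("s", i))))
  u <- dedupe(calls)
  res <- chromosome_correlation(u, ann)
  expect_equal(res$correlation, 1)
  expect_equal(res$counts$n_genes, c(2, 4, 6))
  ## constant annotated-gene counts -> degenerate, NA
  feats2 <- do.call(rbind, lapply(1:3, function(ci)
    gene_features(paste0("X", ci), paste0("chr", ci), "+", iv(1000, 1099))))
  ann2 <- build_annotation(feats2)
  calls2 <- make_call("X1", "X2", "chr1", 1, "+", "chr2", 2, "+")
  res2 <- chromosome_correlation(dedupe(calls2), ann2)
  expect_true(res2$degenerate)
  expect_true(is.na(res2$correlation))
  expect_error(chromosome_correlation(u, build_annotation(feats2[1:2, ])),
               "3 chromosomes")
})

test_that("flank windows equal direct sequence slices", {
  set.seed(23)
  chr <- rand_dna(5000)
  genome <- c(c1 = chr)
  calls <- do.call(rbind, lapply(1:30, function(i)
    make_call("A", paste0("B", i), "c1", sample(300:4700, 1),
              sample(c("+", "-"), 1), "c1", sample(300:4700, 1),
              sample(c("+", "-"), 1), sample_id = "s1")))
  u <- dedupe(calls)
  w <- flank_windows(u, genome, width = 200)
  expect_length(w, 4)
  expect_length(w$flank_5p_upstream, nrow(u$table))
  for (i in seq_len(nrow(u$table))) {
    r <- u$table[i, ]
    up_want <- if (r$strand5 == "+") substr(chr, r$pos5 - 199, r$pos5)
               else revcomp(substr(chr, r$pos5, r$pos5 + 199))
    dn_want <- if (r$strand3 == "+") substr(chr, r$pos3, r$pos3 + 199)
               else revcomp(substr(chr, r$pos3 - 199, r$pos3))
    expect_equal(unname(w$flank_5p_upstream[paste0(r$key, "|flank_5p_upstream")]),
                 up_want)
    expect_equal(unname(w$flank_3p_downstream[paste0(r$key, "|flank_3p_downstream")]),
                 dn_want)
  }
  ## widths are exactly `width` away from contig edges; one chimera yields
  ## four records
  expect_true(all(nchar(w$flank_5p_upstream) == 200))
})
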
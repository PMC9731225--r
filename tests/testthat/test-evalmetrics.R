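# hand-built dosage set over explicit sites and dosages
eval_fixture <- function(ds_mat, truth_haps, typed = NULL, est_r2 = NULL) {
  S <- ncol(ds_mat)
  if (is.null(typed)) typed <- rep(FALSE, S)
  sites <- data.frame(contig = "chr1",
                      pos = seq(0L, by = 100L, length.out = S),
                      ref = "A", alt = "G", typed = typed,
                      stringsAsFactors = FALSE)
  n <- nrow(ds_mat)
  hds <- matrix(0, 2 * n, S)
  hds[seq(1, 2 * n, 2), ] <- ds_mat / 2
  hds[seq(2, 2 * n, 2), ] <- ds_mat / 2
  if (is.null(est_r2)) est_r2 <- apply(hds, 2, estimated_r2)
  d <- structure(list(sites = sites, hds = hds, ds = ds_mat,
                      loo = NULL, est_r2 = est_r2,
                      typed_idx = which(typed),
                      sample_ids = paste0("S", seq_len(n)),
                      panel_id = "fix", n_dropped_typed = 0L),
                 class = "dosage_set")
  truth <- haplotype_panel(sites[, 1:4], truth_haps, paste0("S", seq_len(n)))
  list(d = d, truth = truth)
}

test_that("perfect dosages score one in every occupied bin", {
  set.seed(55)
  n <- 20; S <- 40
  truth_h <- matrix(rbinom(2 * n * S, 1, 0.3), 2 * n, S)
  g <- truth_h[seq(1, 2 * n, 2), ] + truth_h[seq(2, 2 * n, 2), ]
  fx <- eval_fixture(g + 0.0, truth_h)
  r <- aggregated_r2(fx$d, fx$truth)
  occ <- r$per_bin$n_sites > 0
  expect_true(any(occ))
  expect_true(all(abs(r$per_bin$mean_r2[occ] - 1) < 1e-12))
  expect_true(all(abs(r$per_bin$pooled_r2[occ] - 1) < 1e-12))
})

test_that("per-site R2 equals the hand-computed squared correlation", {
  ds <- matrix(c(0.1, 0.9, 1.8, 0.2), 1)
  dim(ds) <- c(4, 1)
  truth_h <- matrix(c(0L, 0L, 0L, 1L, 1L, 1L, 0L, 0L), 8, 1)
  fx <- eval_fixture(ds, truth_h)
  # independent arithmetic: r = S_xy / sqrt(S_xx S_yy)
  x <- c(0.1, 0.9, 1.8, 0.2); y <- c(0, 1, 2, 0)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  expected <- (sxy / sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2)))^2
  r <- aggregated_r2(fx$d, fx$truth)
  occ <- which(r$per_bin$n_sites > 0)
  expect_equal(r$per_bin$mean_r2[occ], expected, tolerance = 1e-12)
})

test_that("zero-variance sites are excluded with a logged count", {
  truth_h <- matrix(c(0L, 1L, 1L, 0L, 0L, 1L, 0L, 0L), 8, 1)
  fx <- eval_fixture(matrix(0.7, 4, 1), truth_h)   # constant dosage
  r <- aggregated_r2(fx$d, fx$truth)
  expect_equal(r$n_excluded_zero_var, 1L)
  expect_equal(sum(r$per_bin$n_sites), 0L)
})

test_that("per-site R2 is invariant under affine dosage rescaling", {
  set.seed(56)
  n <- 15; S <- 10
  truth_h <- matrix(rbinom(2 * n * S, 1, 0.4), 2 * n, S)
  g <- truth_h[seq(1, 2 * n, 2), ] + truth_h[seq(2, 2 * n, 2), ]
  noisy <- g + matrix(rnorm(n * S, 0, 0.3), n, S)
  r1 <- aggregated_r2(eval_fixture(noisy, truth_h)$d,
                      eval_fixture(noisy, truth_h)$truth)
  r2 <- aggregated_r2(eval_fixture(noisy * 0.5 + 0.2, truth_h)$d,
                      eval_fixture(noisy, truth_h)$truth)
  occ <- r1$per_bin$n_sites > 0
  expect_equal(r1$per_bin$mean_r2[occ], r2$per_bin$mean_r2[occ],
               tolerance = 1e-12)
})

test_that("AF bin assignment partitions sites with left-closed edges", {
  b <- af_bins()
  expect_equal(b$labels, c("<0.2%", "0.2%-0.5%", "0.5%-5%", ">=5%"))
  af <- c(0.001, 0.002, 0.004, 0.005, 0.049, 0.05, 0.3, 0.9999)
  bin <- findInterval(af, c(0, b$edges))
  expect_equal(bin, c(1, 2, 2, 3, 3, 4, 4, 4))
  set.seed(57)
  af2 <- runif(500)
  bin2 <- findInterval(af2, c(0, b$edges))
  expect_true(all(bin2 >= 1 & bin2 <= 4))   # every site in exactly one bin
})

test_that("percent well-imputed is exact counting arithmetic", {
  set.seed(59)
  truth_h <- matrix(rbinom(16 * 4, 1, 0.4), 16, 4)
  fx <- eval_fixture(matrix(runif(8 * 4, 0, 2), 8, 4), truth_h,
                     est_r2 = c(0.9, 0.85, 0.7, 0.95))
  r <- pct_well_imputed(fx$d, threshold = 0.8, truth = fx$truth)
  tot_pct <- 100 * r$total_well_imputed / r$total_imputed
  expect_identical(tot_pct, 75)
  expect_equal(r$total_imputed, 4L)
  # threshold 0 -> 100% in every occupied bin
  r0 <- pct_well_imputed(fx$d, threshold = 0, truth = fx$truth)
  occ <- !r0$per_bin$empty_bin
  expect_true(all(r0$per_bin$pct_well_imputed[occ] == 100))
})

test_that("all-typed dosage sets leave every bin undefined and flagged", {
  set.seed(60)
  truth_h <- matrix(rbinom(16 * 4, 1, 0.4), 16, 4)
  fx <- eval_fixture(matrix(runif(8 * 4, 0, 2), 8, 4), truth_h,
                     typed = rep(TRUE, 4))
  r <- pct_well_imputed(fx$d, truth = fx$truth)
  expect_true(all(r$per_bin$empty_bin))
  expect_true(all(is.na(r$per_bin$pct_well_imputed)))
})

test_that("report comparison is long-format, ranked and shape-stable", {
  set.seed(58)
  n <- 20; S <- 30
  truth_h <- matrix(rbinom(2 * n * S, 1, 0.3), 2 * n, S)
  g <- truth_h[seq(1, 2 * n, 2), ] + truth_h[seq(2, 2 * n, 2), ]
  fx1 <- eval_fixture(g + 0.0, truth_h)
  fx2 <- eval_fixture(pmin(pmax(g + matrix(rnorm(n * S, 0, 0.5), n, S), 0), 2),
                      truth_h)
  r1 <- evaluate_imputation(fx1$d, fx1$truth)
  r2 <- evaluate_imputation(fx2$d, fx2$truth)
  cmp <- compare_reports(list(r1, r2))
  n_metrics <- length(unique(cmp$metric))
  expect_equal(nrow(cmp), 2 * 4 * n_metrics)
  same <- compare_reports(list(r1, r1))
  expect_true(all(same$rank == 1, na.rm = TRUE))
  # the perfect panel ranks first wherever both values are defined
  mr <- cmp[cmp$metric == "mean_r2" & !is.na(cmp$value), ]
  for (b in unique(mr$bin))
    expect_equal(mr$rank[mr$bin == b][1], 1L)
  expect_error(compare_reports(list(r1)), "two reports")
})
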
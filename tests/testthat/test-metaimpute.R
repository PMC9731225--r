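test_that("panel weights match exhaustive path enumeration", {
  set.seed(29)
  params <- meta_params()
  for (rep in 1:5) {
    obs <- rbinom(3, 1, 0.5)
    loo <- list(runif(3), runif(3))
    w <- panel_weight_hmm(obs, loo, params)
    oracle <- enum_meta_weights(obs, loo, params$switch_prob,
                                params$weight_floor)
    expect_lt(max(abs(w - oracle)), 1e-12)
    expect_equal(rowSums(w), rep(1, 3), tolerance = 1e-12)
  }
})

test_that("identical panels share the weight evenly", {
  loo <- runif(10)
  w <- panel_weight_hmm(rbinom(10, 1, 0.5), list(loo, loo))
  expect_equal(w, matrix(0.5, 10, 2), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("a loo-perfect panel dominates an uninformative one", {
  set.seed(7)
  obs <- rbinom(25, 1, 0.5)
  w <- panel_weight_hmm(obs, list(as.numeric(obs), rep(0.5, 25)),
                        meta_params(switch_prob = 0.01))
  expect_true(all(w[, 1] > 0.99))
})

test_that("weight HMM rejects degenerate inputs", {
  expect_error(panel_weight_hmm(c(1, 0), list(c(0.5, 0.5))), "two panels")
  expect_error(panel_weight_hmm(integer(0), list(numeric(0), numeric(0))),
               "empty")
  expect_error(panel_weight_hmm(c(1, 0), list(c(0.5, 0.5), c(0.5))),
               "align")
})

# small two-panel imputation fixture reused below
meta_fixture <- function(drop_site_from_b = NULL) {
  cfg <- sim_config(n_sites = 120, seq_length_cM = 1,
                    pops = list(A = list(Ne = 150, n = 60)),
                    split_generations = 30, seed = 41)
  pop <- simulate_populations(cfg)$A
  sp <- split_reference_target(pop, 15, seed = 5)
  ref <- sp$reference
  ref <- subset_sites(ref, ref$sites$af > 0 & ref$sites$af < 1)
  m <- design_array(ref, 20, maf_floor = 0.05)
  typed <- mask_to_array(sp$target, m, maf_floor = 0)
  tg <- phase_targets(sp$target, typed)
  refB <- if (is.null(drop_site_from_b)) ref else
    subset_sites(ref, setdiff(seq_len(n_sites(ref)), drop_site_from_b))
  list(tg = tg, truth = sp$target,
       dA = impute(tg, ref, panel_id = "A"),
       dB = impute(tg, refB, panel_id = "B"))
}

test_that("meta-combining identical dosage sets is the identity", {
  fx <- meta_fixture()
  md <- meta_combine(list(fx$dA, fx$dB), fx$tg)
  expect_equal(md$hds, fx$dA$hds, tolerance = 1e-9)
  expect_equal(md$ds, fx$dA$ds, tolerance = 1e-9)
  expect_equal(md$est_r2, fx$dA$est_r2, tolerance = 1e-9)
  expect_equal(site_keys(md), site_keys(fx$dA))
})

test_that("sites private to one panel keep that panel's dosage", {
  drop <- 60L   # drop an untyped site from panel B's reference
  fx <- meta_fixture(drop_site_from_b = drop)
  md <- meta_combine(list(fx$dA, fx$dB), fx$tg)
  # union coverage: meta carries the union of panel sites
  expect_setequal(site_keys(md),
                  union(site_keys(fx$dA), site_keys(fx$dB)))
  private <- setdiff(site_keys(fx$dA), site_keys(fx$dB))
  j_meta <- match(private, site_keys(md))
  j_a <- match(private, site_keys(fx$dA))
  expect_equal(md$hds[, j_meta], fx$dA$hds[, j_a], tolerance = 1e-12)
})

test_that("meta dosages converge to a loo-perfect panel's dosages", {
  # hand-built dosage sets: panel A is oracle-accurate (loo equals the
  # observed alleles), panel B is pure noise with uninformative loo
  set.seed(13)
  S <- 30L; Tn <- 10L; n_hap <- 8L
  typed_idx <- seq(2L, 29L, by = 3L)
  sites <- data.frame(contig = "chr1", pos = seq(0L, by = 500L, length.out = S),
                      ref = "A", alt = "G",
                      typed = seq_len(S) %in% typed_idx,
                      stringsAsFactors = FALSE)
  truth_h <- matrix(rbinom(n_hap * S, 1, 0.5), n_hap, S)
  make_ds <- function(hds, loo, id) {
    structure(list(sites = sites, hds = hds,
                   ds = hds[c(1, 3, 5, 7), ] + hds[c(2, 4, 6, 8), ],
                   loo = loo, est_r2 = apply(hds, 2, estimated_r2),
                   typed_idx = typed_idx, sample_ids = paste0("S", 1:4),
                   panel_id = id, n_dropped_typed = 0L),
              class = "dosage_set")
  }
  dA <- make_ds(truth_h + 0, truth_h[, typed_idx] + 0, "A")
  dB <- make_ds(matrix(runif(n_hap * S), n_hap, S),
                matrix(0.5, n_hap, Tn), "B")
  tsites <- sites[typed_idx, c("contig", "pos", "ref", "alt")]
  tg <- haplotype_panel(tsites, truth_h[, typed_idx], paste0("S", 1:4))
  md <- meta_combine(list(dA, dB), tg)
  untyped <- !md$sites$typed
  expect_lt(max(abs(md$hds[, untyped] - truth_h[, untyped])), 1e-2)
})

test_that("meta-combine validates its inputs", {
  fx <- meta_fixture()
  expect_error(meta_combine(list(fx$dA), fx$tg), "two dosage sets")
  bad <- fx$dA; bad$sample_ids <- rev(bad$sample_ids)
  expect_error(meta_combine(list(bad, fx$dB), fx$tg), "inconsistent|match")
})
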
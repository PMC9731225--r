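test_that("the MAF floor excludes monomorphic sites from the manifest", {
  # 8 sites, only sites 2,4,6 polymorphic at MAF >= 0.05
  haps <- matrix(0L, 20, 8)
  haps[1:10, 2] <- 1L
  haps[1:6, 4] <- 1L
  haps[1:12, 6] <- 1L
  p <- make_panel(haps)
  m <- design_array(p, 3, maf_floor = 0.05)
  expect_lte(nrow(m), 3)
  expect_true(all(m$pos %in% p$sites$pos[c(2, 4, 6)]))
  expect_error(design_array(make_panel(matrix(0L, 20, 8)), 2),
               "MAF floor")
})

test_that("greedy tag pick ties the brute-force optimum on two LD blocks", {
  # 10 sites in two perfect-LD blocks of five; any 2-tag manifest
  # covering all sites must take one site per block
  x <- rep(c(0L, 1L), each = 10)
  y <- rep(c(0L, 1L, 0L, 1L), each = 5)
  haps <- cbind(x, x, x, x, x, y, y, y, y, y)
  p <- make_panel(haps)
  m <- design_array(p, 2, maf_floor = 0.05, ld_r2_tag = 0.8)
  expect_equal(nrow(m), 2)
  in_block1 <- m$pos %in% p$sites$pos[1:5]
  expect_equal(sum(in_block1), 1)

  # brute force: coverage (sites tagged at r2 >= 0.8) of every 2-subset
  r2 <- suppressWarnings(stats::cor(haps))^2
  best <- 0
  for (i in 1:9) for (j in (i + 1):10)
    best <- max(best, sum(r2[i, ] >= 0.8 | r2[j, ] >= 0.8))
  got_idx <- match(m$pos, p$sites$pos)
  got <- sum(r2[got_idx[1], ] >= 0.8 | r2[got_idx[2], ] >= 0.8)
  expect_equal(got, best)
})

test_that("a manifest is enriched for its design population's common alleles", {
  cfg <- sim_config(n_sites = 300, seq_length_cM = 2,
                    pops = list(A = list(Ne = 300, n = 100),
                                B = list(Ne = 300, n = 100)),
                    split_generations = 200, seed = 21)
  pans <- simulate_populations(cfg)
  mA <- design_array(pans$A, 40, design_pop = "A")
  mB <- design_array(pans$B, 40, design_pop = "B")
  maf_in <- function(m, panel) {
    idx <- match(paste(m$contig, m$pos, m$ref, m$alt, sep = ":"),
                 site_keys(panel))
    mean(pmin(panel$sites$af[idx], 1 - panel$sites$af[idx]))
  }
  expect_gt(maf_in(mA, pans$A), maf_in(mB, pans$A))
  expect_gt(maf_in(mB, pans$B), maf_in(mA, pans$B))

  # manifest validity: all sites exist and pass the floor in design pop
  idx <- match(paste(mA$contig, mA$pos, mA$ref, mA$alt, sep = ":"),
               site_keys(pans$A))
  expect_false(anyNA(idx))
  expect_true(all(pmin(pans$A$sites$af[idx], 1 - pans$A$sites$af[idx]) >= 0.05))
  expect_false(any(duplicated(mA$pos)))
  expect_true(all(diff(mA$pos) > 0))
})

test_that("array masking extracts exact genotypes and applies its floor", {
  set.seed(42)
  haps <- matrix(rbinom(40 * 12, 1, 0.4), 40, 12)
  storage.mode(haps) <- "integer"
  p <- make_panel(haps)
  m <- design_array(p, sum(pmin(p$sites$af, 1 - p$sites$af) >= 0.05),
                    maf_floor = 0.05)
  g <- mask_to_array(p, m, maf_floor = 0)
  idx <- match(site_keys(g), site_keys(p))
  expect_identical(g$geno, unname(genotypes(p))[, idx])
})

test_that("masking drops absent and below-floor manifest sites with a log", {
  # truth: 4 sites over 100 samples; site3 is a singleton below the
  # 1% floor, site4 a doubleton exactly at it
  haps <- matrix(0L, 200, 4)
  haps[1:80, 1] <- 1L
  haps[1:60, 2] <- 1L
  haps[1, 3] <- 1L        # sample MAF 0.005 < default floor 0.01
  haps[1:2, 4] <- 1L      # MAF 0.01 passes the floor
  p <- make_panel(haps)
  manifest <- structure(
    data.frame(contig = "chr1",
               pos = c(p$sites$pos, 99999L),  # one site absent from truth
               ref = "A", alt = "G", stringsAsFactors = FALSE),
    design_pop = "toy", target_density = 5L,
    class = c("array_manifest", "data.frame"))
  g <- mask_to_array(p, manifest, maf_floor = 0.01)
  expect_equal(n_sites(g), 3)
  expect_identical(attr(g, "drop_log"),
                   c(absent = 1L, below_floor = 1L))
})

test_that("phase_targets restricts truth phase to the typed sites", {
  set.seed(43)
  haps <- matrix(rbinom(60 * 20, 1, 0.3), 60, 20)
  storage.mode(haps) <- "integer"
  p <- make_panel(haps)
  m <- design_array(p, 5, maf_floor = 0.05)
  g <- mask_to_array(p, m, maf_floor = 0)
  tg <- phase_targets(p, g)
  expect_equal(site_keys(tg), site_keys(g))
  expect_identical(unname(genotypes(tg)), g$geno)
  tg2 <- phase_targets(p, g, switch_rate = 0.5, seed = 3)
  expect_identical(genotypes(tg2), genotypes(tg))
})
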
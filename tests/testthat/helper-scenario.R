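# Standard benchmark scenario: two populations (KOR-like design pop and
# EUR-like outgroup) at the generator defaults (Ne = 500, 200
# generations of divergence), two population-optimized arrays, both
# reference panels, and meta-imputation of the pair.  Computed once per
# test session and shared by the acceptance blocks.

.scenario_env <- new.env(parent = emptyenv())

benchmark_one_seed <- function(s, array_density = 70L, n_target = 50L) {
  cfg <- sim_config(seed = s)
  pans <- simulate_populations(cfg)
  spl_k <- split_reference_target(pans$KOR, n_target, seed = s + 1000L)
  spl_e <- split_reference_target(pans$EUR, n_target, seed = s + 2000L)
  polymorphic <- function(p) subset_sites(p, p$sites$af > 0 & p$sites$af < 1)
  refs <- list(KOR = polymorphic(spl_k$reference),
               EUR = polymorphic(spl_e$reference))
  arrays <- list(KOR = design_array(refs$KOR, array_density, design_pop = "KOR"),
                 EUR = design_array(refs$EUR, array_density, design_pop = "EUR"))
  truth <- spl_k$target

  r2_common <- c()
  dsets_matched_array <- NULL
  tg_matched <- NULL
  for (ap in c("KOR", "EUR")) {
    typed <- mask_to_array(truth, arrays[[ap]])
    tg <- phase_targets(truth, typed)
    dd <- list()
    for (rp in c("KOR", "EUR")) {
      dd[[rp]] <- impute(tg, refs[[rp]], panel_id = rp)
      r <- aggregated_r2(dd[[rp]], truth)
      r2_common[paste(ap, rp, sep = ".")] <-
        r$per_bin$mean_r2[r$per_bin$bin == ">=5%"]
    }
    if (ap == "KOR") { dsets_matched_array <- dd; tg_matched <- tg }
  }

  md <- meta_combine(dsets_matched_array, tg_matched)
  # paired per-bin comparison on each single panel's own imputed sites
  meta_bin_ok <- TRUE
  for (d in dsets_matched_array) {
    own <- site_keys(d)[!d$sites$typed]
    rs <- aggregated_r2(d, truth)
    rm_ <- aggregated_r2(md, truth, restrict_to = own)
    occ <- which(rs$per_bin$n_sites > 0 & rm_$per_bin$n_sites > 0)
    meta_bin_ok <- meta_bin_ok &&
      all(rm_$per_bin$mean_r2[occ] >= rs$per_bin$mean_r2[occ] - 0.02)
  }
  wi <- vapply(c(dsets_matched_array, list(meta = md)), function(d)
    pct_well_imputed(d, truth = truth)$total_well_imputed, integer(1))

  list(r2_common = r2_common, meta_bin_ok = meta_bin_ok, wi = wi)
}

benchmark_runs <- function(seeds = 1:10) {
  key <- paste0("seeds_", paste(seeds, collapse = "_"))
  if (is.null(.scenario_env[[key]]))
    .scenario_env[[key]] <- lapply(seeds, benchmark_one_seed)
  .scenario_env[[key]]
}

# Pure-copy recovery fixture: targets are literal copies of reference
# samples.  Untyped variation hidden inside groups of reference
# haplotypes that are identical across all typed sites is collapsed to
# the group representative first: at such sites no method (not even the
# exact posterior) could tell the group members apart, so they test data
# ambiguity rather than model correctness.  The switch prior is left to
# the caller; pure copies justify a low one.
copy_recovery_fixture <- function(seed, n_sites = 300, density = 50L) {
  cfg <- sim_config(n_sites = n_sites, seq_length_cM = 2,
                    pops = list(A = list(Ne = 200, n = 80)),
                    split_generations = 50, seed = seed)
  ref <- simulate_populations(cfg)$A
  ref <- subset_sites(ref, ref$sites$af > 0 & ref$sites$af < 1)
  m <- design_array(ref, density, maf_floor = 0.05)
  ti <- match(paste(m$contig, m$pos, m$ref, m$alt, sep = ":"),
              site_keys(ref))
  pat <- apply(ref$haplotypes[, ti, drop = FALSE], 1, paste, collapse = "")
  h2 <- ref$haplotypes
  for (gp in split(seq_len(nrow(h2)), pat))
    h2[gp, ] <- rep(h2[gp[1L], ], each = length(gp))
  ref2 <- haplotype_panel(ref$sites[, c("contig", "pos", "ref", "alt", "gpos")],
                          h2, ref$sample_ids)
  ref2 <- subset_sites(ref2, ref2$sites$af > 0 & ref2$sites$af < 1)
  tgt <- subset_samples(ref2, 1:20)
  tgt$sample_ids <- paste0("T", 1:20)
  typed <- mask_to_array(tgt, m, maf_floor = 0)
  list(ref = ref2, truth = tgt, tg = phase_targets(tgt, typed))
}
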
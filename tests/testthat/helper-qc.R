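# Build the 10-site QC fixture: one site violating exactly one filter
# each (in cascade order) plus three clean sites.  50 samples.
qc_fixture <- function() {
  n <- 50L
  H <- 2L * n
  haps <- matrix(0L, H, 10)
  # clean polymorphic baseline for all sites: ~30% alt, HWE-consistent
  set.seed(99)
  base <- matrix(rbinom(H * 10, 1, 0.3), H, 10)
  haps[] <- base
  # site 1: missingness > 5% (4 of 50 genotypes missing)
  haps[1:8, 1] <- NA
  # site 2: extreme heterozygote excess -> exact HWE p << 1e-6
  haps[, 2] <- rep(c(0L, 1L), n)
  # site 3: clean genotypes but inside the low-complexity mask
  # site 4: indel allele
  # site 5: 12 alternative alleles upstream of biallelic reduction
  # site 6: singleton (alt allele count 1)
  haps[, 6] <- 0L; haps[1, 6] <- 1L
  # site 7: clean but absent from the external site lists
  # sites 8-10: clean
  sites <- data.frame(contig = "chr1", pos = seq(0L, 9000L, by = 1000L),
                      ref = "A", alt = "G", stringsAsFactors = FALSE)
  sites$ref[4] <- "AT"
  sites$n_alt <- 1L; sites$n_alt[5] <- 12L
  panel <- haplotype_panel(sites, haps, sprintf("S%02d", 1:n))
  mask <- data.frame(contig = "chr1", start = 1500L, end = 2500L)  # site 3
  keys <- panel$sites[, c("contig", "pos", "ref", "alt")]
  ext <- keys[-7L, ]
  list(panel = panel, mask = mask, ext = list(ext, ext))
}

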
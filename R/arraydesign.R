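#' Design a population-optimized tag-SNP array manifest
#'
#' Greedy genome-wide-coverage design in the spirit of biobank arrays:
#' candidate sites must reach \code{maf_floor} minor-allele frequency in
#' the design population; tags are then picked one at a time, each time
#' taking the site that covers the largest number of still-uncovered
#' common sites at \code{r^2 >= ld_r2_tag} (a site covers itself), with
#' ties broken by lower position.  Selection stops at
#' \code{target_density} tags or when every common site is covered, so
#' the manifest can be shorter than requested.
#'
#' @param panel \code{haplotype_panel} of the design population.
#' @param target_density maximum number of typed sites.
#' @param maf_floor design-population MAF floor in (0, 0.5) (default 0.05).
#' @param ld_r2_tag r-squared threshold defining tag coverage (default 0.8).
#' @param design_pop name recorded on the manifest (defaults to "panel").
#' @return data.frame of class \code{array_manifest} with columns
#'   \code{contig}, \code{pos}, \code{ref}, \code{alt}, ordered by
#'   position, plus attributes \code{design_pop} and
#'   \code{target_density}.
#' @export
design_array <- function(panel, target_density, maf_floor = 0.05,
                         ld_r2_tag = 0.8, design_pop = "panel") {
  stopifnot(inherits(panel, "haplotype_panel"))
  if (maf_floor <= 0 || maf_floor >= 0.5)
    stop("maf_floor must lie in (0, 0.5)")
  maf <- pmin(panel$sites$af, 1 - panel$sites$af)
  cand <- which(!is.na(maf) & maf >= maf_floor)
  if (length(cand) == 0L)
    stop("no site passes the design-population MAF floor of ", maf_floor)
  if (target_density > length(cand))
    stop("target_density (", target_density, ") exceeds the ",
         length(cand), " sites passing the MAF floor")
  h <- panel$haplotypes[, cand, drop = FALSE]
  r2 <- suppressWarnings(stats::cor(h))^2
  r2[is.na(r2)] <- 0
  covers <- r2 >= ld_r2_tag
  diag(covers) <- TRUE
  uncovered <- rep(TRUE, length(cand))
  chosen <- integer(0)
  while (length(chosen) < target_density && any(uncovered)) {
    gain <- as.vector(covers %*% uncovered)
    gain[chosen] <- -1
    best <- which(gain == max(gain))
    if (length(best) > 1L)                      # tie: lower position wins
      best <- best[which.min(panel$sites$pos[cand[best]])]
    chosen <- c(chosen, best)
    uncovered <- uncovered & !covers[, best]
  }
  idx <- sort(cand[chosen])
  manifest <- panel$sites[idx, c("contig", "pos", "ref", "alt")]
  rownames(manifest) <- NULL
  structure(manifest, design_pop = design_pop,
            target_density = as.integer(target_density),
            class = c("array_manifest", "data.frame"))
}

#' Mask a truth panel down to an array-typed genotype panel
#'
#' Extracts the manifest sites from sequencing-derived truth haplotypes,
#' discards phase, and applies the pre-phasing minor-allele-frequency
#' floor computed on the genotype panel's own samples (sites below the
#' floor are treated as un-genotypable on the array and removed before
#' phasing/imputation).
#'
#' @param truth \code{haplotype_panel} with the full (WGS-like) site set.
#' @param manifest an \code{array_manifest}.
#' @param maf_floor sample-MAF floor (default 0.01).
#' @param error_rate optional symmetric per-allele genotyping error rate
#'   (default 0: calls are extracted exactly).
#' @param seed RNG seed used only when \code{error_rate > 0}.
#' @return \code{genotype_panel} whose attribute \code{drop_log} records
#'   \code{absent} (manifest sites missing from truth) and
#'   \code{below_floor} counts.
#' @export
mask_to_array <- function(truth, manifest, maf_floor = 0.01,
                          error_rate = 0, seed = 1L) {
  stopifnot(inherits(truth, "haplotype_panel"),
            inherits(manifest, "array_manifest"))
  mk <- paste(manifest$contig, manifest$pos, manifest$ref, manifest$alt, sep = ":")
  tk <- site_keys(truth)
  idx <- match(mk, tk)
  absent <- sum(is.na(idx))
  idx <- idx[!is.na(idx)]
  if (length(idx) == 0L)
    stop("no manifest site is present in the truth panel")
  g <- genotypes(truth)[, idx, drop = FALSE]
  if (error_rate > 0) {
    set.seed(seed)
    down <- matrix(stats::rbinom(length(g), g, error_rate), nrow(g))
    up <- matrix(stats::rbinom(length(g), 2L - g, error_rate), nrow(g))
    g <- g - down + up
  }
  af <- colMeans(g, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  keep <- !is.na(maf) & maf >= maf_floor
  below_floor <- sum(!keep)
  if (!any(keep))
    stop("no manifest site passes the sample MAF floor of ", maf_floor)
  sites <- truth$sites[idx[keep], c("contig", "pos", "ref", "alt",
                                    intersect("gpos", names(truth$sites)))]
  out <- genotype_panel(sites, g[, keep, drop = FALSE], truth$sample_ids,
                        source_manifest = attr(manifest, "design_pop"))
  attr(out, "drop_log") <- c(absent = absent, below_floor = below_floor)
  out
}

#' Restrict truth haplotypes to a genotype panel's typed sites
#'
#' The imputation stage consumes pre-phased targets.  Statistical
#' phasing itself is out of scope here, so target phase is taken from
#' the simulated truth, optionally perturbed with
#' \code{\link{inject_switch_errors}} to emulate phasing imperfection.
#'
#' @param truth \code{haplotype_panel} covering the typed sites.
#' @param typed a \code{genotype_panel} from \code{\link{mask_to_array}}.
#' @param switch_rate per-het switch-error rate (default 0).
#' @param seed RNG seed for switch errors.
#' @return Phased \code{haplotype_panel} at exactly the typed sites.
#' @export
phase_targets <- function(truth, typed, switch_rate = 0, seed = 1L) {
  idx <- match(site_keys(typed), site_keys(truth))
  if (anyNA(idx)) stop("typed sites missing from truth panel")
  out <- subset_sites(truth, idx)
  if (switch_rate > 0) out <- inject_switch_errors(out, switch_rate, seed)
  out
}
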
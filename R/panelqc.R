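#' Reference-panel QC thresholds
#'
#' Defaults reproduce a stringent short-read reference-panel cascade:
#' exclude sites with exact Hardy-Weinberg p-value below 1e-6, diploid
#' missing rate above 5%, position inside a low-complexity mask, indel
#' alleles, more than 10 alternative alleles, singletons (non-reference
#' allele count = 1), and sites seen in fewer than
#' \code{min_external_datasets} of the supplied external site lists.
#'
#' @param hwe_p_max_exclusive exclude if HWE p < this (default 1e-6).
#' @param missing_rate_max exclude if missing rate > this (default 0.05).
#' @param max_alt_alleles exclude if more than this many alternative
#'   alleles (default 10).
#' @param drop_indels drop non-SNV alleles (default TRUE).
#' @param drop_singletons drop allele-count-1 sites (default TRUE).
#' @param min_external_datasets minimum number of external datasets a
#'   site must appear in (default 2; the filter is skipped when no
#'   external lists are supplied).
#' @return List of class \code{qc_thresholds}.
#' @export
qc_thresholds <- function(hwe_p_max_exclusive = 1e-6,
                          missing_rate_max = 0.05,
                          max_alt_alleles = 10L,
                          drop_indels = TRUE,
                          drop_singletons = TRUE,
                          min_external_datasets = 2L) {
  stopifnot(hwe_p_max_exclusive >= 0, hwe_p_max_exclusive <= 1,
            missing_rate_max >= 0, missing_rate_max <= 1,
            max_alt_alleles >= 1, min_external_datasets >= 0)
  structure(list(hwe_p_max_exclusive = hwe_p_max_exclusive,
                 missing_rate_max = missing_rate_max,
                 max_alt_alleles = as.integer(max_alt_alleles),
                 drop_indels = isTRUE(drop_indels),
                 drop_singletons = isTRUE(drop_singletons),
                 min_external_datasets = as.integer(min_external_datasets)),
            class = "qc_thresholds")
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Conditional exact test: given the observed allele counts, the
#' probability of every possible heterozygote count is computed by the
#' standard recurrence and the p-value is the summed probability of all
#' configurations no more probable than the observed one.  Preferred
#' over the chi-squared test because exclusion decisions at p < 1e-6 on
#' modest sample sizes are tail-sensitive.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (non-negative, total >= 1).
#' @return Two-sided exact p-value in (0, 1]; symmetric in swapping
#'   \code{n_AA} and \code{n_aa}.
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  counts <- c(n_AA, n_Aa, n_aa)
  if (any(counts < 0)) stop("genotype counts must be non-negative")
  n <- sum(counts)
  if (n < 1) stop("at least one genotype observation is required")
  rare <- 2L * min(n_AA, n_aa) + n_Aa     # minor allele count
  if (rare == 0L) return(1)               # monomorphic: single configuration
  n_het_possible <- seq.int(rare %% 2L, rare, by = 2L)
  logp <- numeric(length(n_het_possible))
  # log-probability recurrence upward in het count, anchored arbitrarily
  for (i in seq_along(n_het_possible)[-1]) {
    het <- n_het_possible[i]
    homr <- (rare - het) / 2
    homc <- n - het - homr
    logp[i] <- logp[i - 1] +
      log(4 * (homr + 1) * (homc + 1)) - log(het * (het - 1))
  }
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- match(n_Aa, n_het_possible)
  if (is.na(obs)) stop("heterozygote count inconsistent with allele counts")
  min(1, sum(pr[pr <= pr[obs] * (1 + 1e-12)]))
}

#' Apply the reference-panel QC cascade
#'
#' Filters are applied in a fixed order so that audit counts are
#' reproducible: missingness, HWE, low-complexity region mask, indels,
#' multi-allelic sites, singletons, external-dataset presence.  Each
#' removed site is counted at the first filter that triggers; the
#' survivor set itself is order-invariant.
#'
#' @param panel a \code{haplotype_panel}; \code{NA} alleles encode
#'   missing calls (a genotype with either allele missing counts as
#'   missing).
#' @param region_mask optional data.frame of half-open 0-based intervals
#'   (\code{contig}, \code{start}, \code{end}), e.g. from
#'   \code{\link{read_bed}}.
#' @param external_site_lists list of site data.frames (columns
#'   \code{contig}, \code{pos}, \code{ref}, \code{alt}) against which
#'   the presence filter is evaluated; empty list skips the filter.
#' @param thresholds a \code{\link{qc_thresholds}}.
#' @return List with elements \code{panel} (surviving sites) and
#'   \code{report} (class \code{qc_report}: per-filter removal counts in
#'   application order plus input/surviving totals).
#' @export
apply_qc_cascade <- function(panel, region_mask = NULL,
                             external_site_lists = list(),
                             thresholds = qc_thresholds()) {
  stopifnot(inherits(panel, "haplotype_panel"),
            inherits(thresholds, "qc_thresholds"))
  g <- genotypes(panel)
  n_in <- n_sites(panel)

  miss_rate <- colMeans(is.na(g))
  f_missing <- miss_rate > thresholds$missing_rate_max

  f_hwe <- vapply(seq_len(n_in), function(j) {
    gj <- g[, j]; gj <- gj[!is.na(gj)]
    if (length(gj) == 0L) return(FALSE)
    p <- hwe_exact_test(sum(gj == 0L), sum(gj == 1L), sum(gj == 2L))
    p < thresholds$hwe_p_max_exclusive
  }, logical(1))

  f_mask <- rep(FALSE, n_in)
  if (!is.null(region_mask) && nrow(region_mask) > 0L) {
    for (i in seq_len(nrow(region_mask))) {
      f_mask <- f_mask | (panel$sites$contig == region_mask$contig[i] &
                            panel$sites$pos >= region_mask$start[i] &
                            panel$sites$pos < region_mask$end[i])
    }
  }

  f_indel <- if (thresholds$drop_indels)
    nchar(panel$sites$ref) != 1L | nchar(panel$sites$alt) != 1L
  else rep(FALSE, n_in)

  f_multi <- panel$sites$n_alt > thresholds$max_alt_alleles

  ac <- colSums(panel$haplotypes, na.rm = TRUE)
  f_singleton <- if (thresholds$drop_singletons) ac == 1L else rep(FALSE, n_in)

  f_external <- rep(FALSE, n_in)
  if (length(external_site_lists) > 0L && thresholds$min_external_datasets > 0L) {
    keys <- site_keys(panel)
    presence <- rep(0L, n_in)
    for (sl in external_site_lists) {
      lk <- paste(sl$contig, sl$pos, sl$ref, sl$alt, sep = ":")
      presence <- presence + (keys %in% lk)
    }
    f_external <- presence < thresholds$min_external_datasets
  }

  flags <- cbind(missingness = f_missing, hwe = f_hwe, region_mask = f_mask,
                 indel = f_indel, multi_allelic = f_multi,
                 singleton = f_singleton, external_presence = f_external)
  first <- apply(flags, 1L, function(r) if (any(r)) which(r)[1L] else 0L)
  removed <- vapply(seq_len(ncol(flags)), function(k) sum(first == k),
                    integer(1))
  names(removed) <- colnames(flags)
  keep <- first == 0L

  report <- structure(
    list(input_sites = n_in,
         removed = removed,
         surviving_sites = sum(keep),
         surviving_samples = n_samples(panel)),
    class = "qc_report")
  list(panel = subset_sites(panel, keep), report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC cascade report\n")
  cat(sprintf("  input sites:     %d\n", x$input_sites))
  for (nm in names(x$removed))
    cat(sprintf("  - %-18s %d removed\n", paste0(nm, ":"), x$removed[[nm]]))
  cat(sprintf("  surviving sites: %d (%d samples)\n",
              x$surviving_sites, x$surviving_samples))
  invisible(x)
}
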
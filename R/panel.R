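#' Construct a phased haplotype panel
#'
#' The central container of the package: an ordered table of biallelic
#' sites plus a binary haplotype matrix with two rows per sample
#' (rows \code{2i - 1} and \code{2i} are the two haplotypes of sample
#' \code{i}).  Positions are 0-based internally; VCF emission converts
#' to 1-based.
#'
#' @param sites data.frame with columns \code{contig}, \code{pos}
#'   (0-based integer, strictly increasing within contig), \code{ref},
#'   \code{alt}; optional \code{gpos} (genetic position, cM) and
#'   \code{n_alt} (number of alternative alleles observed upstream of
#'   biallelic reduction, default 1).
#' @param haplotypes integer matrix, \code{2 * n_samples} rows by
#'   \code{nrow(sites)} columns, entries in \code{0, 1} (\code{NA}
#'   allowed to represent missing calls).
#' @param sample_ids character vector of sample identifiers.
#' @param phased logical; whether haplotype phase is meaningful.
#'
#' @details The per-site non-reference allele frequency is always
#'   recomputed from the haplotype matrix (column mean over non-missing
#'   entries) and stored in \code{sites$af}, so the stored frequency can
#'   never drift from the data.
#'
#' @return An object of class \code{haplotype_panel}.
#' @export
haplotype_panel <- function(sites, haplotypes, sample_ids, phased = TRUE) {
  stopifnot(is.data.frame(sites), is.matrix(haplotypes))
  required <- c("contig", "pos", "ref", "alt")
  missing_cols <- setdiff(required, names(sites))
  if (length(missing_cols) > 0L)
    stop("sites is missing column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(haplotypes) != 2L * length(sample_ids))
    stop("haplotypes must have exactly two rows per sample")
  if (ncol(haplotypes) != nrow(sites))
    stop("haplotypes must have one column per site")
  vals <- haplotypes[!is.na(haplotypes)]
  if (length(vals) > 0L && !all(vals %in% c(0L, 1L)))
    stop("haplotype entries must be 0, 1 or NA")
  ord <- order(sites$contig, sites$pos)
  if (is.unsorted(ord, strictly = TRUE) || any(ord != seq_len(nrow(sites)))) {
    sites <- sites[ord, , drop = FALSE]
    haplotypes <- haplotypes[, ord, drop = FALSE]
  }
  dup <- duplicated(paste(sites$contig, sites$pos))
  if (any(dup))
    stop("duplicate site positions: ", paste(sites$pos[dup], collapse = ", "))
  rownames(sites) <- NULL
  if (is.null(sites$n_alt)) sites$n_alt <- 1L
  sites$af <- .col_af(haplotypes)
  storage.mode(haplotypes) <- "integer"
  dimnames(haplotypes) <- NULL
  structure(
    list(sites = sites, haplotypes = haplotypes,
         sample_ids = as.character(sample_ids), phased = isTRUE(phased)),
    class = "haplotype_panel"
  )
}

.col_af <- function(m) {
  af <- colMeans(m, na.rm = TRUE)
  af[is.nan(af)] <- NA_real_
  af
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf(
    "haplotype_panel: %d samples (%d haplotypes) x %d sites [%s]\n",
    n_samples(x), nrow(x$haplotypes), n_sites(x),
    if (x$phased) "phased" else "unphased"))
  invisible(x)
}

#' Number of samples in a panel
#' @param panel a \code{haplotype_panel} or \code{genotype_panel}.
#' @export
n_samples <- function(panel) length(panel$sample_ids)

#' Number of sites in a panel
#' @param panel a \code{haplotype_panel} or \code{genotype_panel}.
#' @export
n_sites <- function(panel) nrow(panel$sites)

#' Canonical site keys ("contig:pos:ref:alt", 0-based pos)
#' @param x a panel-like object carrying a \code{sites} data.frame, or a
#'   sites data.frame itself.
#' @export
site_keys <- function(x) {
  s <- if (is.data.frame(x)) x else x$sites
  paste(s$contig, s$pos, s$ref, s$alt, sep = ":")
}

#' Diploid genotype matrix (n_samples x n_sites, values 0/1/2)
#'
#' A genotype is \code{NA} when either constituent haplotype allele is
#' missing (half-calls count as missing).
#' @param panel a \code{haplotype_panel}.
#' @export
genotypes <- function(panel) {
  h <- panel$haplotypes
  n <- length(panel$sample_ids)
  g <- h[seq(1L, 2L * n, by = 2L), , drop = FALSE] +
    h[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  rownames(g) <- panel$sample_ids
  g
}

#' Subset a panel by site index
#' @param panel a \code{haplotype_panel}.
#' @param idx integer or logical index into the site table.
#' @export
subset_sites <- function(panel, idx) {
  haplotype_panel(panel$sites[idx, , drop = FALSE],
                  panel$haplotypes[, idx, drop = FALSE],
                  panel$sample_ids, panel$phased)
}

#' Subset a panel by sample index
#' @param panel a \code{haplotype_panel}.
#' @param idx integer index into the sample vector.
#' @export
subset_samples <- function(panel, idx) {
  idx <- as.integer(idx)
  rows <- as.vector(rbind(2L * idx - 1L, 2L * idx))
  haplotype_panel(panel$sites, panel$haplotypes[rows, , drop = FALSE],
                  panel$sample_ids[idx], panel$phased)
}

#' Construct an unphased genotype panel (array-typed targets)
#'
#' @param sites site data.frame as in \code{\link{haplotype_panel}}.
#' @param geno integer matrix n_samples x n_sites with entries 0/1/2 or NA.
#' @param sample_ids character sample identifiers.
#' @param source_manifest optional identifier of the array manifest the
#'   panel was masked to.
#' @return An object of class \code{genotype_panel}.
#' @export
genotype_panel <- function(sites, geno, sample_ids, source_manifest = NA_character_) {
  stopifnot(is.data.frame(sites), is.matrix(geno))
  if (nrow(geno) != length(sample_ids))
    stop("geno must have one row per sample")
  if (ncol(geno) != nrow(sites))
    stop("geno must have one column per site")
  vals <- geno[!is.na(geno)]
  if (length(vals) > 0L && !all(vals %in% 0:2))
    stop("genotype entries must be 0, 1, 2 or NA")
  rownames(sites) <- NULL
  sites$af <- colMeans(geno, na.rm = TRUE) / 2
  storage.mode(geno) <- "integer"
  dimnames(geno) <- NULL
  structure(
    list(sites = sites, geno = geno, sample_ids = as.character(sample_ids),
         source_manifest = source_manifest),
    class = "genotype_panel"
  )
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("genotype_panel: %d samples x %d typed sites (manifest: %s)\n",
              length(x$sample_ids), nrow(x$sites), x$source_manifest))
  invisible(x)
}

#' Hudson's Fst estimator between two panels
#'
#' Ratio-of-averages Hudson estimator over sites present in both panels,
#' using the unbiased within-population heterozygosity correction.
#' Sites monomorphic across both panels contribute zero to both sums.
#'
#' @param panel_a,panel_b \code{haplotype_panel}s sharing (some) sites.
#' @param min_maf pooled minor-allele-frequency floor for site inclusion
#'   (default 0, all shared polymorphic sites).
#' @return Scalar Fst estimate.
#' @export
hudson_fst <- function(panel_a, panel_b, min_maf = 0) {
  ka <- site_keys(panel_a); kb <- site_keys(panel_b)
  shared <- intersect(ka, kb)
  if (length(shared) == 0L) stop("panels share no sites")
  ia <- match(shared, ka); ib <- match(shared, kb)
  p1 <- panel_a$sites$af[ia]; p2 <- panel_b$sites$af[ib]
  n1 <- nrow(panel_a$haplotypes); n2 <- nrow(panel_b$haplotypes)
  pbar <- (p1 * n1 + p2 * n2) / (n1 + n2)
  maf <- pmin(pbar, 1 - pbar)
  keep <- maf > min_maf | (min_maf == 0 & maf > 0)
  if (!any(keep)) stop("no polymorphic shared sites above min_maf")
  p1 <- p1[keep]; p2 <- p2[keep]
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  sum(num) / sum(den)
}
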
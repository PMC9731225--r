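#' Allele-frequency bin specification
#'
#' Default bins follow the usual accuracy-reporting convention on the
#' non-reference allele frequency: \code{<0.2\%}, \code{0.2-0.5\%},
#' \code{0.5-5\%} and \code{>=5\%}.  Bins partition (0, 1]; a site's bin
#' is decided by its truth-panel AF by default.
#'
#' @param edges increasing numeric vector of inner bin edges in (0, 1).
#' @param af_source which AF assigns the bin: \code{"truth"} (default)
#'   or \code{"reference"}.
#' @return List of class \code{af_bins} with \code{edges} and
#'   \code{labels}.
#' @export
af_bins <- function(edges = c(0.002, 0.005, 0.05),
                    af_source = c("truth", "reference")) {
  af_source <- match.arg(af_source)
  edges <- sort(unique(edges))
  if (any(edges <= 0) || any(edges >= 1)) stop("edges must lie in (0, 1)")
  pct <- function(x) {
    v <- x * 100
    ifelse(v == round(v), sprintf("%d%%", as.integer(round(v))),
           sprintf("%g%%", v))
  }
  lab <- character(length(edges) + 1L)
  lab[1L] <- paste0("<", pct(edges[1L]))
  if (length(edges) > 1L)
    for (i in 2:length(edges))
      lab[i] <- paste0(pct(edges[i - 1L]), "-", pct(edges[i]))
  lab[length(lab)] <- paste0(">=", pct(edges[length(edges)]))
  structure(list(edges = edges, labels = lab, af_source = af_source),
            class = "af_bins")
}

# Left-closed bins on the non-reference AF: an AF exactly at an edge
# belongs to the higher bin (AF = 5% is ">=5%", AF = 0.2% is "0.2-0.5%").
.bin_of <- function(af, bins) {
  findInterval(af, c(0, bins$edges))
}

.truth_aligned <- function(dosages, truth) {
  if (!identical(dosages$sample_ids, truth$sample_ids))
    stop("dosage and truth sample sets differ")
  idx <- match(site_keys(dosages), site_keys(truth))
  list(idx = idx, geno = genotypes(truth))
}

#' Aggregated R-squared of imputed dosages against truth
#'
#' Per-site squared Pearson correlation between imputed diploid dosages
#' and true genotype dosages across samples, summarized per
#' allele-frequency bin as the mean and SD over sites; a pooled
#' R-squared (correlation over all site-sample pairs in the bin) is
#' also reported as a cross-check.  Sites with zero variance in either
#' vector are excluded with a logged count, not scored 0.
#'
#' @param dosages a \code{dosage_set}.
#' @param truth \code{haplotype_panel} with the same samples carrying
#'   the true genotypes.
#' @param bins an \code{\link{af_bins}}.
#' @param include_typed score typed sites too (default FALSE: imputed
#'   sites only, the quantity of interest).
#' @param restrict_to optional character vector of site keys
#'   (\code{\link{site_keys}}); when given, only these sites are scored.
#'   Use it for paired comparisons between dosage sets whose site
#'   coverage differs (e.g. meta-imputation versus a single panel), so
#'   the mean is taken over a common site set.
#' @return An \code{eval_report} (see \code{\link{evaluate_imputation}})
#'   carrying the R-squared columns.
#' @export
aggregated_r2 <- function(dosages, truth, bins = af_bins(),
                          include_typed = FALSE, restrict_to = NULL) {
  al <- .truth_aligned(dosages, truth)
  sel <- which(!is.na(al$idx) & (include_typed | !dosages$sites$typed))
  if (!is.null(restrict_to))
    sel <- sel[site_keys(dosages)[sel] %in% restrict_to]
  tg <- al$geno[, al$idx[sel], drop = FALSE]
  ds <- t(dosages$ds[, sel, drop = FALSE])
  tg <- t(tg)
  r2 <- vapply(seq_along(sel), function(j) {
    x <- ds[j, ]; y <- tg[j, ]
    ok <- !is.na(y)
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) return(NA_real_)
    stats::cor(x[ok], y[ok])^2
  }, numeric(1))
  af <- truth$sites$af[al$idx[sel]]
  b <- .bin_of(af, bins)
  included <- !is.na(r2)
  nb <- length(bins$labels)
  per_bin <- data.frame(
    bin = bins$labels,
    n_sites = vapply(seq_len(nb), function(k) sum(included & b == k), integer(1)),
    mean_r2 = vapply(seq_len(nb), function(k) {
      v <- r2[included & b == k]
      if (length(v) == 0L) NA_real_ else mean(v)
    }, numeric(1)),
    sd_r2 = vapply(seq_len(nb), function(k) {
      v <- r2[included & b == k]
      if (length(v) < 2L) NA_real_ else stats::sd(v)
    }, numeric(1)),
    pooled_r2 = vapply(seq_len(nb), function(k) {
      j <- which(included & b == k)
      if (length(j) == 0L) return(NA_real_)
      x <- as.vector(ds[j, , drop = FALSE])
      y <- as.vector(tg[j, , drop = FALSE])
      ok <- !is.na(y)
      if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) return(NA_real_)
      stats::cor(x[ok], y[ok])^2
    }, numeric(1)),
    stringsAsFactors = FALSE)
  structure(list(panel_id = dosages$panel_id, bins = bins,
                 per_bin = per_bin,
                 overall_mean_r2 = mean(r2[included]),
                 n_excluded_zero_var = sum(!included)),
            class = "eval_report")
}

#' Percentage of well-imputed variants per AF bin
#'
#' \code{100 * (number of imputed sites with estimated r2 >= threshold)
#' / (number of imputed sites)} per bin; typed sites are excluded from
#' numerator and denominator.  Empty bins are reported as \code{NA} and
#' flagged, not as 0.  A relaxed threshold (default 0.4) is computed
#' alongside.
#'
#' @param dosages a \code{dosage_set}.
#' @param threshold info-score cutoff defining "well-imputed"
#'   (default 0.8).
#' @param bins an \code{\link{af_bins}}.
#' @param truth optional truth \code{haplotype_panel} supplying the
#'   binning AF (falls back to the dosage-set AF estimate when absent).
#' @param relaxed_threshold secondary cutoff (default 0.4).
#' @return An \code{eval_report} carrying the well-imputed columns:
#'   per bin \code{n_imputed}, \code{n_well_imputed},
#'   \code{pct_well_imputed}, \code{n_well_imputed_relaxed},
#'   \code{pct_well_imputed_relaxed}, \code{empty_bin}.
#' @export
pct_well_imputed <- function(dosages, threshold = 0.8, bins = af_bins(),
                             truth = NULL, relaxed_threshold = 0.4) {
  sel <- which(!dosages$sites$typed)
  if (!is.null(truth)) {
    idx <- match(site_keys(dosages), site_keys(truth))
    af <- truth$sites$af[idx[sel]]
  } else {
    af <- colMeans(dosages$ds[, sel, drop = FALSE]) / 2
  }
  r2 <- dosages$est_r2[sel]
  keep <- !is.na(af) & af > 0
  af <- af[keep]; r2 <- r2[keep]
  b <- .bin_of(af, bins)
  nb <- length(bins$labels)
  n_imp <- vapply(seq_len(nb), function(k) sum(b == k), integer(1))
  n_wi <- vapply(seq_len(nb), function(k) sum(b == k & r2 >= threshold),
                 integer(1))
  n_wi_rel <- vapply(seq_len(nb), function(k)
    sum(b == k & r2 >= relaxed_threshold), integer(1))
  per_bin <- data.frame(
    bin = bins$labels, n_imputed = n_imp, n_well_imputed = n_wi,
    pct_well_imputed = ifelse(n_imp > 0L, 100 * n_wi / n_imp, NA_real_),
    n_well_imputed_relaxed = n_wi_rel,
    pct_well_imputed_relaxed = ifelse(n_imp > 0L, 100 * n_wi_rel / n_imp,
                                      NA_real_),
    empty_bin = n_imp == 0L,
    stringsAsFactors = FALSE)
  structure(list(panel_id = dosages$panel_id, bins = bins,
                 per_bin = per_bin,
                 threshold = threshold,
                 relaxed_threshold = relaxed_threshold,
                 total_imputed = sum(n_imp),
                 total_well_imputed = sum(n_wi)),
            class = "eval_report")
}

#' Full per-panel imputation evaluation
#'
#' Joins \code{\link{aggregated_r2}} and \code{\link{pct_well_imputed}}
#' into one report over the same bins (truth-panel AF binning for both).
#'
#' @inheritParams aggregated_r2
#' @inheritParams pct_well_imputed
#' @return An \code{eval_report} whose \code{per_bin} table carries both
#'   metric families.
#' @export
evaluate_imputation <- function(dosages, truth, bins = af_bins(),
                                threshold = 0.8, relaxed_threshold = 0.4) {
  a <- aggregated_r2(dosages, truth, bins)
  p <- pct_well_imputed(dosages, threshold, bins, truth = truth,
                        relaxed_threshold = relaxed_threshold)
  per_bin <- cbind(a$per_bin, p$per_bin[, -1L, drop = FALSE])
  structure(list(panel_id = dosages$panel_id, bins = bins, per_bin = per_bin,
                 overall_mean_r2 = a$overall_mean_r2,
                 n_excluded_zero_var = a$n_excluded_zero_var,
                 threshold = threshold,
                 relaxed_threshold = relaxed_threshold,
                 total_imputed = p$total_imputed,
                 total_well_imputed = p$total_well_imputed),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report [%s]\n", x$panel_id))
  print(x$per_bin, row.names = FALSE, digits = 4)
  if (!is.null(x$overall_mean_r2))
    cat(sprintf("overall mean aggregated R2: %.4f (%d zero-variance sites excluded)\n",
                x$overall_mean_r2, x$n_excluded_zero_var))
  invisible(x)
}

#' Long-format comparison of evaluation reports
#'
#' @param reports list (length >= 2) of \code{eval_report}s over
#'   identical bins.
#' @return data.frame (panel, bin, metric, value) in deterministic
#'   order, with a \code{rank} column per (bin, metric) ranking panels
#'   best-first (higher is better for every emitted metric).
#' @export
compare_reports <- function(reports) {
  if (length(reports) < 2L) stop("at least two reports are required")
  labs <- lapply(reports, function(r) r$bins$labels)
  if (!all(vapply(labs, identical, logical(1), y = labs[[1]])))
    stop("reports use different bin definitions")
  metrics <- c("mean_r2", "sd_r2", "pooled_r2", "pct_well_imputed",
               "n_well_imputed")
  rows <- list()
  for (r in reports) {
    pb <- r$per_bin
    for (m in intersect(metrics, names(pb))) {
      rows[[length(rows) + 1L]] <- data.frame(
        panel = r$panel_id, bin = pb$bin, metric = m, value = pb[[m]],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$metric, out$bin, out$panel), , drop = FALSE]
  rownames(out) <- NULL
  out$rank <- NA_integer_
  for (key in unique(paste(out$metric, out$bin))) {
    i <- which(paste(out$metric, out$bin) == key)
    out$rank[i] <- rank(-out$value[i], ties.method = "min", na.last = "keep")
  }
  out
}

#' Plot per-bin aggregated R2 for one or more reports
#'
#' @param reports list of \code{eval_report}s.
#' @return A ggplot object (requires the ggplot2 package).
#' @export
plot_aggregated_r2 <- function(reports) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  df <- do.call(rbind, lapply(reports, function(r)
    data.frame(panel = r$panel_id, bin = factor(r$per_bin$bin,
                                                levels = r$bins$labels),
               mean_r2 = r$per_bin$mean_r2, sd_r2 = r$per_bin$sd_r2)))
  ggplot2::ggplot(df, ggplot2::aes(x = bin, y = mean_r2, group = panel,
                                   colour = panel)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = mean_r2 - sd_r2,
                                        ymax = mean_r2 + sd_r2),
                           width = 0.15) +
    ggplot2::labs(x = "non-reference allele frequency",
                  y = "aggregated R²") +
    ggplot2::ylim(0, 1)
}
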
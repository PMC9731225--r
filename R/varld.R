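#' varLD scan configuration
#'
#' @param window_size number of consecutive shared sites per window
#'   (default 50, >= 2).
#' @param step sites to slide between windows (default half a window).
#' @param top_pct percentile width of the region calls (default 1, i.e.
#'   windows above the top-1\% threshold).
#' @param min_maf minor-allele-frequency floor a site must reach in both
#'   populations to enter the scan (default 0.05).
#' @return List of class \code{varld_config}.
#' @export
varld_config <- function(window_size = 50L, step = NULL, top_pct = 1,
                         min_maf = 0.05) {
  if (window_size < 2L) stop("window_size must be >= 2")
  if (is.null(step)) step <- max(1L, window_size %/% 2L)
  if (top_pct <= 0 || top_pct >= 100) stop("top_pct must lie in (0, 100)")
  structure(list(window_size = as.integer(window_size),
                 step = as.integer(step), top_pct = top_pct,
                 min_maf = min_maf),
            class = "varld_config")
}

#' Raw varLD score of one window
#'
#' Signed Pearson correlation matrices of genotype dosages are computed
#' per population over the same ordered site set, eigendecomposed, and
#' compared as the summed absolute difference of the rank-ordered
#' eigenvalues.  Sites with zero variance in either population are
#' dropped pairwise (so both matrices stay on identical sites).
#'
#' @param geno_a,geno_b samples x sites genotype-dosage matrices for the
#'   two populations over the same ordered sites.
#' @return Scalar raw score, with attribute \code{"n_sites"} (sites
#'   actually compared) — or \code{NA} when fewer than 2 variable sites
#'   remain.
#' @export
varld_raw_score <- function(geno_a, geno_b) {
  if (ncol(geno_a) != ncol(geno_b))
    stop("windows must cover the same ordered site set")
  if (nrow(geno_a) < 2L || nrow(geno_b) < 2L)
    stop("at least two samples per population are required")
  va <- apply(geno_a, 2L, stats::sd)
  vb <- apply(geno_b, 2L, stats::sd)
  keep <- va > 0 & vb > 0
  if (sum(keep) < 2L) {
    out <- NA_real_
    attr(out, "n_sites") <- sum(keep)
    return(out)
  }
  ca <- stats::cor(geno_a[, keep, drop = FALSE])
  cb <- stats::cor(geno_b[, keep, drop = FALSE])
  ea <- sort(eigen(ca, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  eb <- sort(eigen(cb, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  out <- sum(abs(ea - eb))
  attr(out, "n_sites") <- sum(keep)
  out
}

#' Sliding-window varLD scan over two populations
#'
#' @param panel_a,panel_b \code{haplotype_panel} or
#'   \code{genotype_panel} objects; only sites shared by both (by
#'   contig/pos/ref/alt) and reaching \code{min_maf} in both populations
#'   are scanned.
#' @param config a \code{\link{varld_config}}.
#' @return data.frame of class \code{varld_result} with one row per
#'   scored window: \code{contig}, \code{start}, \code{end} (half-open
#'   bp span), \code{n_sites}, \code{raw}; windows with fewer than two
#'   variable sites are skipped (counted in attribute
#'   \code{"n_skipped"}).
#' @export
varld_scan <- function(panel_a, panel_b, config = varld_config()) {
  ga <- if (inherits(panel_a, "haplotype_panel")) genotypes(panel_a) else panel_a$geno
  gb <- if (inherits(panel_b, "haplotype_panel")) genotypes(panel_b) else panel_b$geno
  ka <- site_keys(panel_a); kb <- site_keys(panel_b)
  shared <- intersect(ka, kb)
  ia <- match(shared, ka); ib <- match(shared, kb)
  afa <- colMeans(ga[, ia, drop = FALSE], na.rm = TRUE) / 2
  afb <- colMeans(gb[, ib, drop = FALSE], na.rm = TRUE) / 2
  ok <- pmin(afa, 1 - afa) >= config$min_maf &
    pmin(afb, 1 - afb) >= config$min_maf
  ia <- ia[ok]; ib <- ib[ok]
  ord <- order(panel_a$sites$contig[ia], panel_a$sites$pos[ia])
  ia <- ia[ord]; ib <- ib[ord]
  S <- length(ia)
  if (S < config$window_size)
    stop("fewer shared sites (", S, ") than one window")
  starts <- seq.int(1L, S - config$window_size + 1L, by = config$step)
  rows <- vector("list", length(starts))
  skipped <- 0L
  for (j in seq_along(starts)) {
    w <- starts[j]:(starts[j] + config$window_size - 1L)
    raw <- varld_raw_score(ga[, ia[w], drop = FALSE],
                           gb[, ib[w], drop = FALSE])
    if (is.na(raw)) { skipped <- skipped + 1L; next }
    rows[[j]] <- data.frame(
      contig = panel_a$sites$contig[ia[w[1L]]],
      start = panel_a$sites$pos[ia[w[1L]]],
      end = panel_a$sites$pos[ia[w[length(w)]]] + 1L,
      n_sites = attr(raw, "n_sites"),
      raw = as.numeric(raw),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  structure(out, n_skipped = skipped,
            class = c("varld_result", "data.frame"))
}

#' Standardize varLD scores and call top-percentile regions
#'
#' Scores are standardized to zero mean and unit SD over all windows;
#' the call threshold is the nearest-rank \code{100 - top_pct}
#' percentile of the standardized scores, and called regions are the
#' maximal merged half-open bp spans of windows strictly above it.
#'
#' @param scores a \code{varld_result} from \code{\link{varld_scan}}
#'   (>= 10 windows).
#' @param config a \code{\link{varld_config}}.
#' @return List with \code{windows} (the input plus a
#'   \code{standardized} column and logical \code{called}),
#'   \code{threshold}, and \code{regions} (merged data.frame
#'   \code{contig}, \code{start}, \code{end}).
#' @export
standardize_and_call <- function(scores, config = varld_config()) {
  if (nrow(scores) < 10L) stop("at least 10 windows are required")
  mu <- mean(scores$raw)
  sdev <- stats::sd(scores$raw)
  if (sdev == 0) stop("degenerate input: zero SD across window scores")
  scores$standardized <- (scores$raw - mu) / sdev
  n <- nrow(scores)
  srt <- sort(scores$standardized)
  rank_idx <- ceiling((100 - config$top_pct) / 100 * n)   # nearest rank
  threshold <- srt[max(1L, rank_idx)]
  scores$called <- scores$standardized > threshold
  called <- scores[scores$called, , drop = FALSE]
  regions <- .merge_intervals(called)
  list(windows = scores, threshold = threshold, regions = regions)
}

.merge_intervals <- function(df) {
  if (nrow(df) == 0L)
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  df <- df[order(df$contig, df$start), , drop = FALSE]
  out <- df[1L, c("contig", "start", "end")]
  for (i in seq_len(nrow(df))[-1L]) {
    last <- nrow(out)
    if (df$contig[i] == out$contig[last] && df$start[i] <= out$end[last]) {
      out$end[last] <- max(out$end[last], df$end[i])
    } else {
      out <- rbind(out, df[i, c("contig", "start", "end")])
    }
  }
  rownames(out) <- NULL
  out
}
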
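#' Li-Stephens haplotype-copying model parameters
#'
#' @param n_eff effective-size scale of the recombination (switch) rate;
#'   the per-interval switch probability is
#'   \code{1 - exp(-4 * n_eff * d / H)} for genetic distance \code{d}
#'   (Morgans) and \code{H} reference haplotypes.
#' @param err allele-mismatch emission probability (mutation/error
#'   term), in (0, 0.5).
#' @param min_recomb floor on the per-interval switch probability.
#' @return List of class \code{ls_params}.
#' @export
ls_params <- function(n_eff = 1e4, err = 1e-3, min_recomb = 1e-8) {
  if (err <= 0 || err >= 0.5) stop("err must lie in (0, 0.5)")
  if (n_eff <= 0) stop("n_eff must be positive")
  structure(list(n_eff = n_eff, err = err, min_recomb = min_recomb),
            class = "ls_params")
}

# Genetic positions in cM for a site table: explicit gpos column if
# present, else a uniform 1 cM/Mb map over physical positions.
.gpos_cM <- function(sites) {
  if (!is.null(sites$gpos)) sites$gpos else sites$pos / 1e6
}

#' Scaled forward-backward pass of the haplotype-copying HMM
#'
#' The hidden state is the reference haplotype being copied; the
#' emission is the observed target allele with mismatch probability
#' \code{err}; transitions between consecutive typed sites switch to a
#' uniformly chosen haplotype with probability
#' \code{1 - exp(-4 n_eff d / H)}.  Per-site rescaling keeps the pass
#' underflow-free for arbitrarily many sites.
#'
#' @param target_hap 0/1 vector of observed alleles at the typed sites
#'   (NA allowed: uninformative emission).
#' @param ref reference \code{haplotype_panel} restricted to the typed
#'   sites, or an H x T 0/1 allele matrix (rows = reference haplotypes).
#' @param params an \code{\link{ls_params}}.
#' @param dist_cM optional vector of \code{T - 1} inter-site genetic
#'   distances in centimorgans (derived from the panel when omitted).
#' @return T x H matrix of posterior copying probabilities (rows sum to
#'   1).  Attribute \code{"loo"} holds the leave-one-out posterior in
#'   which each site's own emission is withheld, the signal used for
#'   empirical (leave-one-out) dosages.
#' @export
ls_forward_backward <- function(target_hap, ref, params = ls_params(),
                                dist_cM = NULL) {
  if (inherits(ref, "haplotype_panel")) {
    if (is.null(dist_cM)) dist_cM <- diff(.gpos_cM(ref$sites))
    A <- ref$haplotypes
  } else A <- ref
  H <- nrow(A); T_ <- ncol(A)
  if (is.null(H) || H < 1L) stop("at least one reference haplotype required")
  if (H < 2L) stop("at least two reference haplotypes required")
  if (T_ < 1L) stop("at least one typed site required")
  if (length(target_hap) != T_)
    stop("target_hap length must equal the number of typed sites")
  if (is.null(dist_cM)) dist_cM <- rep(0.01, max(T_ - 1L, 0L))
  theta <- 1 - exp(-4 * params$n_eff * (dist_cM / 100) / H)
  theta <- pmin(pmax(theta, params$min_recomb), 1 - 1e-12)

  emis <- matrix(params$err, T_, H)
  for (t in seq_len(T_)) {
    if (is.na(target_hap[t])) emis[t, ] <- 1
    else emis[t, A[, t] == target_hap[t]] <- 1 - params$err
  }

  alpha <- matrix(0, T_, H)
  pred <- matrix(0, T_, H)          # prior at t given sites < t
  pred[1L, ] <- 1 / H
  a <- emis[1L, ] / H
  a <- a / sum(a)
  alpha[1L, ] <- a
  for (t in seq_len(T_)[-1L]) {
    pr <- (1 - theta[t - 1L]) * a + theta[t - 1L] / H
    pred[t, ] <- pr
    a <- emis[t, ] * pr
    a <- a / sum(a)
    alpha[t, ] <- a
  }

  beta <- matrix(0, T_, H)
  b <- rep(1 / H, H)
  beta[T_, ] <- b
  if (T_ > 1L) {
    for (t in rev(seq_len(T_ - 1L))) {
      v <- emis[t + 1L, ] * b
      b <- (1 - theta[t]) * v + (theta[t] / H) * sum(v)
      b <- b / sum(b)
      beta[t, ] <- b
    }
  }

  gamma <- alpha * beta
  gamma <- gamma / rowSums(gamma)
  loo <- pred * beta
  loo <- loo / rowSums(loo)
  attr(gamma, "loo") <- loo
  gamma
}

#' Estimated imputation r-squared (info score) from haplotype dosages
#'
#' Ratio of the empirical (divisor-n) variance of the haplotype dosages
#' to its binomial expectation \code{p(1 - p)} at the mean dosage
#' \code{p}; clamped to [0, 1] and defined as 0 for monomorphic dosage
#' vectors.  Hard calls (all dosages 0/1) give exactly 1.
#'
#' @param hds numeric vector of per-haplotype alt-allele dosages in
#'   [0, 1] (length >= 2).
#' @return Scalar in [0, 1].
#' @export
estimated_r2 <- function(hds) {
  stopifnot(length(hds) >= 2L)
  p <- mean(hds)
  if (p <= 0 || p >= 1) return(0)
  v <- mean(hds^2) - p^2
  min(1, max(0, v / (p * (1 - p))))
}

#' Impute untyped sites with the Li-Stephens model
#'
#' For each pre-phased target haplotype, the copying posterior is
#' computed at the typed sites and linearly interpolated (in genetic
#' distance) to every untyped reference site; the haplotype dosage is
#' the posterior-weighted reference allele.  Typed-site dosages are
#' emission-dominated (they honor the observed allele), while
#' leave-one-out dosages re-predict every typed site with its own
#' emission withheld.
#'
#' @param targets phased \code{haplotype_panel} at the typed sites.
#' @param ref phased reference \code{haplotype_panel}.
#' @param params an \code{\link{ls_params}}.
#' @param panel_id identifier stored on the result.
#' @return A \code{dosage_set}: list with \code{sites} (reference sites
#'   plus logical \code{typed}), \code{hds} (2N x S haplotype dosages),
#'   \code{ds} (N x S diploid dosages), \code{loo} (2N x n_typed
#'   leave-one-out dosages), \code{est_r2} (per-site info score),
#'   \code{typed_idx}, \code{sample_ids}, \code{panel_id} and
#'   \code{n_dropped_typed} (typed sites absent from the reference).
#' @export
impute <- function(targets, ref, params = ls_params(), panel_id = "ref") {
  stopifnot(inherits(targets, "haplotype_panel"),
            inherits(ref, "haplotype_panel"))
  if (!targets$phased) stop("targets must be phased")
  tk <- site_keys(targets); rk <- site_keys(ref)
  keep <- tk %in% rk
  n_dropped <- sum(!keep)
  if (!any(keep)) stop("no overlap between typed sites and reference sites")
  targets <- if (n_dropped > 0L) subset_sites(targets, keep) else targets
  typed_idx <- match(site_keys(targets), rk)

  A_all <- ref$haplotypes                      # H x S
  A_typed <- A_all[, typed_idx, drop = FALSE]  # H x T
  g_all <- .gpos_cM(ref$sites)
  g_typed <- g_all[typed_idx]
  dist_cM <- diff(g_typed)
  S <- n_sites(ref); T_ <- length(typed_idx)
  n_hap <- nrow(targets$haplotypes)

  # interpolation anchors for every reference site
  left <- findInterval(g_all, g_typed)               # 0 .. T
  right <- pmin(left + 1L, T_)
  left_cl <- pmax(left, 1L)
  w <- rep(0, S)
  interior <- left >= 1L & left < T_ & g_all > g_typed[left_cl]
  span <- g_typed[right[interior]] - g_typed[left_cl[interior]]
  w[interior] <- ifelse(span > 0,
                        (g_all[interior] - g_typed[left_cl[interior]]) / span, 0)
  w[left == 0L] <- 0                                  # before first typed site
  # typed sites anchor exactly on their own posterior row
  at_typed <- rep(FALSE, S); at_typed[typed_idx] <- TRUE
  w[at_typed] <- 0
  left_cl[at_typed] <- match(which(at_typed), typed_idx)
  right[at_typed] <- left_cl[at_typed]

  hds <- matrix(0, n_hap, S)
  loo <- matrix(0, n_hap, T_)
  tA_typed <- t(A_typed)                              # T x H
  for (i in seq_len(n_hap)) {
    gam <- ls_forward_backward(targets$haplotypes[i, ], A_typed, params,
                               dist_cM = dist_cM)
    B <- gam %*% A_all                                # T x S anchor dosages
    hds[i, ] <- (1 - w) * B[cbind(left_cl, seq_len(S))] +
      w * B[cbind(right, seq_len(S))]
    loo[i, ] <- rowSums(attr(gam, "loo") * tA_typed)
  }
  hds <- pmin(pmax(hds, 0), 1)
  n <- n_samples(targets)
  ds <- hds[seq(1L, 2L * n, 2L), , drop = FALSE] +
    hds[seq(2L, 2L * n, 2L), , drop = FALSE]
  est_r2 <- apply(hds, 2L, estimated_r2)

  sites <- ref$sites
  sites$typed <- at_typed
  structure(list(sites = sites, hds = hds, ds = ds, loo = loo,
                 est_r2 = est_r2, typed_idx = typed_idx,
                 sample_ids = targets$sample_ids, panel_id = panel_id,
                 n_dropped_typed = n_dropped),
            class = "dosage_set")
}

#' @export
print.dosage_set <- function(x, ...) {
  cat(sprintf(
    "dosage_set [%s]: %d samples x %d sites (%d typed, %d imputed)\n",
    x$panel_id, length(x$sample_ids), nrow(x$sites),
    sum(x$sites$typed), sum(!x$sites$typed)))
  invisible(x)
}
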
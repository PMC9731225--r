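#' Meta-imputation combiner parameters
#'
#' @param switch_prob per-typed-interval probability that the best
#'   copying panel changes (default 0.01).
#' @param weight_floor floor applied to emission likelihoods so a single
#'   bad site cannot zero out a panel (default 1e-6).
#' @return List of class \code{meta_params}.
#' @export
meta_params <- function(switch_prob = 0.01, weight_floor = 1e-6) {
  if (switch_prob <= 0 || switch_prob >= 1)
    stop("switch_prob must lie in (0, 1)")
  structure(list(switch_prob = switch_prob, weight_floor = weight_floor),
            class = "meta_params")
}

#' Panel-selection HMM weights for one target haplotype
#'
#' Hidden state: which reference panel the haplotype is best imputed
#' from locally.  Emission at a typed site for panel k is that panel's
#' leave-one-out dosage if the observed allele is 1, else one minus it
#' (floored at \code{weight_floor}); transitions stay on the same panel
#' with probability \code{1 - switch_prob} and otherwise move uniformly
#' to another panel.  Forward-backward posteriors are the per-site panel
#' weights.
#'
#' @param observed_alleles 0/1 vector at the typed sites.
#' @param loo_per_panel list (length >= 2) of leave-one-out dosage
#'   vectors aligned to the same typed sites.
#' @param params a \code{\link{meta_params}}.
#' @return T x K matrix of panel weights; rows sum to 1.
#' @export
panel_weight_hmm <- function(observed_alleles, loo_per_panel,
                             params = meta_params()) {
  K <- length(loo_per_panel)
  if (K < 2L) stop("at least two panels are required for meta-imputation")
  T_ <- length(observed_alleles)
  if (T_ < 1L) stop("empty typed-site intersection")
  if (any(vapply(loo_per_panel, length, integer(1)) != T_))
    stop("leave-one-out vectors must align to the typed sites")
  emis <- vapply(loo_per_panel, function(l)
    ifelse(observed_alleles == 1L, l, 1 - l), numeric(T_))
  emis <- matrix(pmax(emis, params$weight_floor), T_, K)
  stay <- 1 - params$switch_prob
  move <- params$switch_prob / (K - 1)

  alpha <- matrix(0, T_, K)
  a <- emis[1L, ] / K
  a <- a / sum(a)
  alpha[1L, ] <- a
  if (T_ > 1L) for (t in 2:T_) {
    pr <- stay * a + move * (sum(a) - a)
    a <- emis[t, ] * pr
    a <- a / sum(a)
    alpha[t, ] <- a
  }
  beta <- matrix(0, T_, K)
  b <- rep(1 / K, K)
  beta[T_, ] <- b
  if (T_ > 1L) for (t in (T_ - 1L):1L) {
    v <- emis[t + 1L, ] * b
    b <- stay * v + move * (sum(v) - v)
    b <- b / sum(b)
    beta[t, ] <- b
  }
  w <- alpha * beta
  w / rowSums(w)
}

#' Combine per-panel dosage sets into a meta-imputed dosage set
#'
#' For every target haplotype the panel-selection weights are estimated
#' at the typed sites shared by all panels, linearly interpolated in
#' genetic position across the union of imputed sites (held constant
#' beyond the outermost typed sites), renormalized over the panels that
#' actually carry each site, and used to average the per-panel haplotype
#' dosages.  The info score is recomputed from the combined dosages.
#'
#' @param dosage_sets list (length >= 2) of \code{dosage_set}s imputed
#'   from the same targets against different reference panels.
#' @param targets_typed phased \code{haplotype_panel} of the targets at
#'   their typed sites (the observed-allele signal for the weight HMM).
#' @param params a \code{\link{meta_params}}.
#' @param emit_weights if TRUE, attach the per-haplotype typed-site
#'   weight matrices as attribute \code{"weights"}.
#' @return A \code{dosage_set} over the union of panel sites with
#'   \code{panel_id} \code{"meta(<id1>+<id2>+...)"}.
#' @export
meta_combine <- function(dosage_sets, targets_typed, params = meta_params(),
                         emit_weights = FALSE) {
  K <- length(dosage_sets)
  if (K < 2L) stop("at least two dosage sets are required")
  ids <- vapply(dosage_sets, function(d) d$panel_id, character(1))
  smp <- lapply(dosage_sets, function(d) d$sample_ids)
  if (!all(vapply(smp, identical, logical(1), y = smp[[1]])))
    stop("dosage sets come from inconsistent sample sets")
  if (!identical(targets_typed$sample_ids, smp[[1]]))
    stop("targets_typed samples do not match the dosage sets")

  keys <- lapply(dosage_sets, site_keys)
  typed_keys <- lapply(seq_len(K), function(k)
    keys[[k]][dosage_sets[[k]]$sites$typed])
  shared_typed <- Reduce(intersect, typed_keys)
  shared_typed <- intersect(site_keys(targets_typed), shared_typed)
  if (length(shared_typed) == 0L) stop("empty typed-site intersection")

  # union site table, ordered by contig/pos
  all_sites <- do.call(rbind, lapply(dosage_sets, function(d)
    d$sites[, intersect(c("contig", "pos", "ref", "alt", "gpos"),
                        names(d$sites)), drop = FALSE]))
  all_sites <- all_sites[!duplicated(paste(all_sites$contig, all_sites$pos,
                                           all_sites$ref, all_sites$alt)), ,
                         drop = FALSE]
  all_sites <- all_sites[order(all_sites$contig, all_sites$pos), , drop = FALSE]
  rownames(all_sites) <- NULL
  ukeys <- paste(all_sites$contig, all_sites$pos, all_sites$ref,
                 all_sites$alt, sep = ":")
  S <- length(ukeys)
  map_k <- lapply(keys, function(k) match(ukeys, k))   # union -> panel col
  avail <- vapply(map_k, function(m) !is.na(m), logical(S))
  avail <- matrix(avail, S, K)

  tt_idx <- match(shared_typed, site_keys(targets_typed))
  tt_ord <- order(targets_typed$sites$pos[tt_idx])
  tt_idx <- tt_idx[tt_ord]
  shared_typed <- shared_typed[tt_ord]
  g_typed <- .gpos_cM(targets_typed$sites)[tt_idx]
  T_ <- length(tt_idx)
  loo_cols <- lapply(seq_len(K), function(k)
    match(shared_typed, typed_keys[[k]]))

  g_all <- .gpos_cM(all_sites)
  left <- findInterval(g_all, g_typed)
  right <- pmin(left + 1L, T_)
  left_cl <- pmax(left, 1L)
  w_int <- rep(0, S)
  interior <- left >= 1L & left < T_
  span <- g_typed[right[interior]] - g_typed[left_cl[interior]]
  w_int[interior] <- ifelse(span > 0,
                            (g_all[interior] - g_typed[left_cl[interior]]) / span,
                            0)

  n_hap <- nrow(dosage_sets[[1]]$hds)
  hds <- matrix(0, n_hap, S)
  wlist <- if (emit_weights) vector("list", n_hap) else NULL
  for (i in seq_len(n_hap)) {
    obs <- targets_typed$haplotypes[i, tt_idx]
    loo_i <- lapply(seq_len(K), function(k)
      dosage_sets[[k]]$loo[i, loo_cols[[k]]])
    wt <- panel_weight_hmm(obs, loo_i, params)          # T x K
    if (emit_weights) wlist[[i]] <- wt
    # interpolate weights to the union sites
    w_site <- (1 - w_int) * wt[left_cl, , drop = FALSE] +
      w_int * wt[right, , drop = FALSE]                 # S x K
    w_site[!avail] <- 0
    rs <- rowSums(w_site)
    zero <- rs <= 0
    if (any(zero)) {                                    # no panel carries site
      w_site[zero, ] <- avail[zero, ] / pmax(rowSums(avail[zero, , drop = FALSE]), 1)
      rs <- rowSums(w_site)
    }
    w_site <- w_site / rs
    d_site <- vapply(seq_len(K), function(k) {
      v <- rep(0, S)
      m <- map_k[[k]]
      v[avail[, k]] <- dosage_sets[[k]]$hds[i, m[avail[, k]]]
      v
    }, numeric(S))
    hds[i, ] <- rowSums(w_site * d_site)
  }
  hds <- pmin(pmax(hds, 0), 1)
  n <- n_hap / 2L
  ds <- hds[seq(1L, n_hap, 2L), , drop = FALSE] +
    hds[seq(2L, n_hap, 2L), , drop = FALSE]
  est_r2 <- apply(hds, 2L, estimated_r2)

  typed_flag <- ukeys %in% shared_typed
  typed_idx <- which(typed_flag)
  loo_meta <- matrix(0, n_hap, T_)
  ucols <- match(shared_typed, ukeys)
  for (k in seq_len(K)) loo_meta <- loo_meta +
    dosage_sets[[k]]$loo[, loo_cols[[k]], drop = FALSE] / K
  all_sites$typed <- typed_flag

  out <- structure(list(sites = all_sites, hds = hds, ds = ds,
                        loo = loo_meta, est_r2 = est_r2,
                        typed_idx = typed_idx,
                        sample_ids = smp[[1]],
                        panel_id = paste0("meta(", paste(ids, collapse = "+"), ")"),
                        n_dropped_typed = 0L),
                   class = "dosage_set")
  if (emit_weights) attr(out, "weights") <- wlist
  out
}
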
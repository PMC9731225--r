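# Independent brute-force oracles used to pin expected values.
# These deliberately re-derive each quantity from first principles and
# share no code with the package implementation.

# Build a haplotype panel from a plain matrix (rows = haplotypes).
make_panel <- function(haps, pos = NULL, phased = TRUE, gpos = NULL) {
  S <- ncol(haps)
  if (is.null(pos)) pos <- seq(0L, by = 1000L, length.out = S)
  sites <- data.frame(contig = "chr1", pos = as.integer(pos),
                      ref = rep("A", S), alt = rep("G", S),
                      stringsAsFactors = FALSE)
  if (!is.null(gpos)) sites$gpos <- gpos
  haplotype_panel(sites, haps, sprintf("S%03d", seq_len(nrow(haps) / 2)),
                  phased = phased)
}

# Exhaustive path enumeration of the haplotype-copying posterior.
# Transition over interval t-1 -> t: (1 - theta_t) * I + theta_t / H.
enum_ls_posterior <- function(target, A, err, theta) {
  H <- nrow(A); T_ <- ncol(A)
  emis <- function(t, k) {
    if (is.na(target[t])) return(1)
    if (A[k, t] == target[t]) 1 - err else err
  }
  paths <- as.matrix(expand.grid(rep(list(seq_len(H)), T_)))
  w <- numeric(nrow(paths))
  for (i in seq_len(nrow(paths))) {
    z <- paths[i, ]
    lw <- log(1 / H) + log(emis(1L, z[1L]))
    for (t in seq_len(T_)[-1L]) {
      tr <- theta[t - 1L] / H + if (z[t] == z[t - 1L]) 1 - theta[t - 1L] else 0
      lw <- lw + log(tr) + log(emis(t, z[t]))
    }
    w[i] <- exp(lw)
  }
  post <- matrix(0, T_, H)
  for (t in seq_len(T_))
    for (k in seq_len(H))
      post[t, k] <- sum(w[paths[, t] == k])
  post / rowSums(post)
}

# Exhaustive path enumeration of the panel-selection weight HMM.
enum_meta_weights <- function(obs, loo_list, switch_prob, weight_floor) {
  K <- length(loo_list); T_ <- length(obs)
  emis <- function(t, k) {
    e <- if (obs[t] == 1L) loo_list[[k]][t] else 1 - loo_list[[k]][t]
    max(e, weight_floor)
  }
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T_)))
  w <- numeric(nrow(paths))
  for (i in seq_len(nrow(paths))) {
    z <- paths[i, ]
    pw <- (1 / K) * emis(1L, z[1L])
    for (t in seq_len(T_)[-1L]) {
      tr <- if (z[t] == z[t - 1L]) 1 - switch_prob else
        switch_prob / (K - 1)
      pw <- pw * tr * emis(t, z[t])
    }
    w[i] <- pw
  }
  post <- matrix(0, T_, K)
  for (t in seq_len(T_))
    for (k in seq_len(K))
      post[t, k] <- sum(w[paths[, t] == k])
  post / rowSums(post)
}

# Exact HWE p-value by direct enumeration of the conditional
# heterozygote distribution (multinomial / hypergeometric form).
hwe_enum_pvalue <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2L * nAA + nAa
  if (min(nA, 2L * n - nA) == 0L) return(1)
  hets <- seq.int(nA %% 2L, min(nA, 2L * n - nA), by = 2L)
  logp <- vapply(hets, function(h) {
    hAA <- (nA - h) / 2
    haa <- n - hAA - h
    lfactorial(n) - lfactorial(hAA) - lfactorial(h) - lfactorial(haa) +
      h * log(2) - (lchoose(2 * n, nA))
  }, numeric(1))
  pr <- exp(logp)
  pr <- pr / sum(pr)
  obs <- pr[hets == nAa]
  sum(pr[pr <= obs * (1 + 1e-12)])
}

# Scalar, loop-based Hudson Fst estimator.
fst_hudson_oracle <- function(h1, h2) {
  n1 <- nrow(h1); n2 <- nrow(h2)
  nums <- dens <- numeric(0)
  for (j in seq_len(ncol(h1))) {
    p1 <- mean(h1[, j]); p2 <- mean(h2[, j])
    pbar <- (p1 * n1 + p2 * n2) / (n1 + n2)
    if (pbar == 0 || pbar == 1) next
    nums <- c(nums, (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) -
                p2 * (1 - p2) / (n2 - 1))
    dens <- c(dens, p1 * (1 - p2) + p2 * (1 - p1))
  }
  sum(nums) / sum(dens)
}
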
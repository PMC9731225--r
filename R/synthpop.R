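#' Simulation configuration for multi-population haplotype data
#'
#' Defines a forward Wright-Fisher scenario: a shared founder haplotype
#' pool is built once, each population inherits an independent draw from
#' it, and then drifts for \code{split_generations} generations of
#' random mating with recombination and symmetric mutation.  Divergence
#' between populations is therefore controlled by the number of
#' generations of independent drift.
#'
#' @param n_sites number of candidate biallelic sites (>= 1).
#' @param seq_length_cM genetic length of the simulated region in
#'   centimorgans; physical coordinates use a uniform 1 cM/Mb map.
#' @param pops named list of populations, each a list with elements
#'   \code{Ne} (effective diploid size, >= 2) and \code{n} (diploid
#'   sample size emitted, \code{2n <= 2Ne}).
#' @param split_generations generations of independent drift after the
#'   founder split (>= 0).
#' @param mu per-site per-generation allele flip probability.
#' @param recomb_per_cM crossover probability per centimorgan per
#'   meiosis (default 0.01, i.e. 1 crossover per Morgan).
#' @param n_ancestral number of seed haplotypes drawn site-wise from the
#'   Beta spectrum before the copying process starts; smaller values
#'   give stronger haplotype sharing and longer-range LD.
#' @param founder_xo_per_cM template-switch rate (per cM) of the founder
#'   copying process; controls baseline LD decay.
#' @param founder_mu per-site copy-mutation probability of the founder
#'   process; the source of the rare-variant tail.
#' @param seed integer RNG seed; a fixed seed makes the whole scenario
#'   bit-reproducible.
#' @return A validated list of class \code{sim_config}.
#' @export
sim_config <- function(n_sites = 600,
                       seq_length_cM = 4,
                       pops = list(KOR = list(Ne = 500, n = 150),
                                   EUR = list(Ne = 500, n = 150)),
                       split_generations = 200,
                       mu = 1e-5,
                       recomb_per_cM = 0.01,
                       n_ancestral = 25,
                       founder_xo_per_cM = 2,
                       founder_mu = 0.008,
                       seed = 1L) {
  if (n_sites < 1) stop("degenerate config: n_sites must be >= 1")
  if (length(pops) < 1) stop("degenerate config: at least one population required")
  if (is.null(names(pops)) || any(names(pops) == ""))
    stop("populations must be named")
  for (nm in names(pops)) {
    p <- pops[[nm]]
    if (is.null(p$Ne) || p$Ne < 2) stop("population ", nm, ": Ne must be >= 2")
    if (is.null(p$n) || p$n < 1) stop("degenerate config: population ", nm,
                                      " has no samples")
    if (p$n > p$Ne) stop("population ", nm, ": sample size n must be <= Ne")
  }
  if (split_generations < 0) stop("split_generations must be >= 0")
  if (mu < 0 || mu >= 1) stop("mu must lie in [0, 1)")
  if (seq_length_cM <= 0) stop("seq_length_cM must be positive")
  structure(list(n_sites = as.integer(n_sites),
                 seq_length_cM = seq_length_cM,
                 pops = pops,
                 split_generations = as.integer(split_generations),
                 mu = mu,
                 recomb_per_cM = recomb_per_cM,
                 n_ancestral = as.integer(n_ancestral),
                 founder_xo_per_cM = founder_xo_per_cM,
                 founder_mu = founder_mu,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# One generation of Wright-Fisher random mating over a haplotype pool.
# Each child haplotype copies one parent haplotype and, where crossovers
# occur, alternates segments with a second parent; mutation flips
# alleles symmetrically at rate mu.
.wf_generation <- function(pool, gpos, xo_lambda, mu) {
  H <- nrow(pool); S <- ncol(pool)
  par1 <- sample.int(H, H, replace = TRUE)
  par2 <- sample.int(H, H, replace = TRUE)
  ncx <- stats::rpois(H, xo_lambda)
  child <- pool[par1, , drop = FALSE]
  L <- gpos[S]
  for (i in which(ncx > 0L)) {
    bps <- sort(stats::runif(ncx[i], 0, L))
    seg <- findInterval(gpos, bps) %% 2L
    take2 <- seg == 1L
    if (any(take2)) child[i, take2] <- pool[par2[i], take2]
  }
  n_mut <- stats::rbinom(1L, H * S, mu)
  if (n_mut > 0L) {
    idx <- sample.int(H * S, n_mut)
    child[idx] <- 1L - child[idx]
  }
  child
}

# Founder pool: every founder haplotype is a single-depth recombinant
# mosaic of n_seed ancestral haplotypes (drawn site-wise Bernoulli(p)
# from the Beta-shaped spectrum), plus a sprinkle of private copy
# mutations.  Depth-1 copying keeps local haplotype diversity bounded
# by n_seed, so panels of a few hundred haplotypes can represent it,
# while the mutations supply a genuine rare-variant tail.
.founder_pool <- function(p, gpos, n_haps, n_seed, xo_lambda, copy_mu) {
  S <- length(p)
  anc <- matrix(stats::rbinom(n_seed * S, 1L, rep(p, each = n_seed)),
                n_seed, S)
  pool <- matrix(0L, n_haps, S)
  L <- gpos[S]
  for (i in seq_len(n_haps)) {
    ncx <- stats::rpois(1L, xo_lambda)
    if (ncx == 0L) {
      pool[i, ] <- anc[sample.int(n_seed, 1L), ]
    } else {
      bps <- sort(stats::runif(ncx, 0, L))
      seg <- findInterval(gpos, bps)
      ids <- sample.int(n_seed, ncx + 1L, replace = TRUE)
      pool[i, ] <- anc[cbind(ids[seg + 1L], seq_len(S))]
    }
    n_mut <- stats::rbinom(1L, S, copy_mu)
    if (n_mut > 0L) {
      idx <- sample.int(S, n_mut)
      pool[i, idx] <- 1L - pool[i, idx]
    }
  }
  pool
}

#' Simulate diverged populations of phased haplotypes
#'
#' Builds a shared site set (physical positions uniform on a 1 cM/Mb
#' map, founder allele frequencies drawn from a Beta(0.2, 0.2) spectrum
#' so rare variants are plentiful), stitches founder haplotypes as
#' mosaics of a small ancestral pool (creating realistic LD decay), and
#' drifts each population independently for
#' \code{config$split_generations} Wright-Fisher generations.
#'
#' @param config a \code{\link{sim_config}}.
#' @return Named list of \code{\link{haplotype_panel}}s, one per
#'   population, all sharing the founder site set.
#' @export
simulate_populations <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  set.seed(config$seed)
  S <- config$n_sites
  L <- config$seq_length_cM
  bp <- sort(sample.int(max(S, round(L * 1e6)), S))
  gpos <- bp / 1e6                       # 1 cM per Mb
  acgt <- c("A", "C", "G", "T")
  ref <- sample(acgt, S, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(acgt, r), 1L), character(1))
  p <- stats::rbeta(S, 0.2, 0.2)
  xo_lambda <- L * config$recomb_per_cM       # crossovers per meiosis
  founder_lambda <- L * config$founder_xo_per_cM
  sites <- data.frame(contig = "chr1", pos = bp - 1L, ref = ref, alt = alt,
                      gpos = gpos, stringsAsFactors = FALSE)
  max_ne <- max(vapply(config$pops, function(x) x$Ne, numeric(1)))
  founder <- .founder_pool(p, gpos, 2L * max_ne, config$n_ancestral,
                           founder_lambda, config$founder_mu)
  out <- list()
  for (nm in names(config$pops)) {
    popcfg <- config$pops[[nm]]
    pool <- founder[sample.int(2L * max_ne, 2L * popcfg$Ne, replace = TRUE), ,
                    drop = FALSE]
    g <- 0L
    while (g < config$split_generations) {
      pool <- .wf_generation(pool, gpos, xo_lambda, config$mu)
      g <- g + 1L
    }
    ind <- sample.int(popcfg$Ne, popcfg$n)
    rows <- as.vector(rbind(2L * ind - 1L, 2L * ind))
    ids <- sprintf("%s_%04d", nm, seq_len(popcfg$n))
    out[[nm]] <- haplotype_panel(sites, pool[rows, , drop = FALSE], ids,
                                 phased = TRUE)
  }
  out
}

#' Split a panel into disjoint reference and target sets
#'
#' Mirrors the benchmark construction in which target samples are held
#' out of the reference panel entirely.
#'
#' @param panel a \code{haplotype_panel}.
#' @param n_target number of samples to hold out (\code{< n_samples}).
#' @param seed RNG seed for the sample draw.
#' @return List with elements \code{reference} and \code{target}.
#' @export
split_reference_target <- function(panel, n_target, seed = 1L) {
  n <- n_samples(panel)
  if (n_target >= n)
    stop("n_target must be smaller than the number of samples (", n, ")")
  if (n_target < 1) stop("n_target must be at least 1")
  set.seed(seed)
  tgt <- sort(sample.int(n, n_target))
  list(reference = subset_samples(panel, setdiff(seq_len(n), tgt)),
       target = subset_samples(panel, tgt))
}

#' Inject phase switch errors into a phased panel
#'
#' Emulates imperfect statistical phasing: walking along each sample's
#' sites, at every heterozygous site the maternal/paternal assignment
#' toggles with probability \code{switch_rate} and stays toggled until
#' the next switch.  Diploid genotypes are untouched by construction.
#'
#' @param panel a phased \code{haplotype_panel}.
#' @param switch_rate per-heterozygous-site toggle probability in [0, 1].
#' @param seed RNG seed.
#' @return A \code{haplotype_panel} with perturbed phase.
#' @export
inject_switch_errors <- function(panel, switch_rate, seed = 1L) {
  stopifnot(inherits(panel, "haplotype_panel"))
  if (!panel$phased) stop("panel must be phased")
  if (switch_rate < 0 || switch_rate > 1)
    stop("switch_rate must lie in [0, 1]")
  if (switch_rate == 0) return(panel)
  set.seed(seed)
  h <- panel$haplotypes
  n <- n_samples(panel)
  for (i in seq_len(n)) {
    r1 <- 2L * i - 1L; r2 <- 2L * i
    het <- which(h[r1, ] != h[r2, ])
    if (length(het) == 0L) next
    toggles <- stats::runif(length(het)) < switch_rate
    state <- cumsum(toggles) %% 2L == 1L   # swapped from this het onward
    # a swap state that starts at het site k applies to all sites from k
    # up to (but not including) the het site where the state flips back
    bounds <- c(het, ncol(h) + 1L)
    for (k in seq_along(het)) {
      if (!state[k]) next
      span <- bounds[k]:(bounds[k + 1L] - 1L)
      tmp <- h[r1, span]
      h[r1, span] <- h[r2, span]
      h[r2, span] <- tmp
    }
  }
  haplotype_panel(panel$sites, h, panel$sample_ids, phased = TRUE)
}
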
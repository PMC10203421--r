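# Shared fixtures, generated once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Reference planted fixture: 4 balanced tissues x 20 samples, 2000 genes,
# 50 planted markers per tissue with log2 effect 6 over noise SD 0.3.
fix_planted <- function() cached("planted", {
  sim <- generate_expression(synth_config(
    n_tissues = 4, samples_per_tissue = rep(20L, 4), n_genes = 2000L,
    planted_per_tissue = 50L, effect_size = 6, noise_sd = 0.3,
    tissue_names = c("leaf", "root", "seed", "seedling"), seed = 1L))
  sim$log2 <- log2_transform(sim$matrix)
  sim$truth_set <- truth_geneset(sim$truth)
  sim
})

# Small fast fixture for unit tests (300 genes, 10 planted per tissue).
fix_small <- function(effect = 6, seed = 4L, noise_sd = 0.5) {
  key <- sprintf("small_%g_%d_%g", effect, seed, noise_sd)
  cached(key, {
    sim <- generate_expression(synth_config(
      n_tissues = 3, samples_per_tissue = rep(12L, 3), n_genes = 300L,
      planted_per_tissue = 10L, effect_size = effect, noise_sd = noise_sd,
      tissue_names = c("leaf", "root", "seed"), seed = seed))
    sim$log2 <- log2_transform(sim$matrix)
    sim$truth_set <- truth_geneset(sim$truth)
    sim
  })
}

# Clustering-validation fixture: same planted layout but heavy background
# noise (SD 3), so a coherent marker panel outperforms diluted random
# panels instead of both saturating near V = 1.
fix_noisy <- function() cached("noisy", {
  sim <- generate_expression(synth_config(
    n_tissues = 4, samples_per_tissue = rep(20L, 4), n_genes = 2000L,
    planted_per_tissue = 50L, effect_size = 6, noise_sd = 3,
    tissue_names = c("leaf", "root", "seed", "seedling"), seed = 1L))
  sim$log2 <- log2_transform(sim$matrix)
  sim$truth_set <- truth_geneset(sim$truth)
  sim
})

# Independent V-measure oracle: entropies computed directly from the
# contingency table with explicit loops (natural log).
oracle_vmeasure <- function(truth, clus) {
  n <- length(truth)
  cs <- unique(truth); ks <- unique(clus)
  ent <- function(sizes) {
    p <- sizes[sizes > 0] / n
    -sum(p * log(p))
  }
  H_C <- ent(vapply(cs, function(c) sum(truth == c), 0))
  H_K <- ent(vapply(ks, function(k) sum(clus == k), 0))
  H_CK <- 0; H_KC <- 0
  for (c in cs) for (k in ks) {
    nck <- sum(truth == c & clus == k)
    if (nck > 0) {
      H_CK <- H_CK - nck / n * log(nck / sum(clus == k))
      H_KC <- H_KC - nck / n * log(nck / sum(truth == c))
    }
  }
  h <- if (H_C == 0) 1 else 1 - H_CK / H_C
  cc <- if (H_K == 0) 1 else 1 - H_KC / H_K
  v <- if (h + cc > 0) 2 * h * cc / (h + cc) else 0
  c(h = h, c = cc, v = v)
}

# All set partitions of 1..n as label vectors (restricted growth strings).
all_partitions <- function(n) {
  out <- list()
  grow <- function(labels, mx) {
    if (length(labels) == n) {
      out[[length(out) + 1L]] <<- labels
      return(invisible())
    }
    for (l in seq_len(mx + 1L)) grow(c(labels, l), max(mx, l))
  }
  grow(integer(0), 0L)
  out
}

# Brute-force BH oracle: adj_i = min_{j >= i} p_(j) * m / j (sorted order),
# clipped at 1, mapped back to the input order.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) adj[i] <- min(1, min(ps[i:m] * m / (i:m)))
  out <- numeric(m)
  out[o] <- adj
  out
}
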
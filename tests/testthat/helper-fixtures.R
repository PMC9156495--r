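# Fixtures are built in code; independent oracles live here so every
# dual-route check has a second implementation to compare against.

tiny_network <- function() {
  traffic_network(c("serum", "liver", "brain"),
                  list(c("serum", "liver"), c("serum", "brain")))
}

# Build a single- or multi-lipid abundance table from per-group signal
# vectors. `signals` is a named list phenotype -> compartment -> lipid ->
# numeric vector (one entry per sample; zeros are explicit records so the
# group size is well defined).
make_table <- function(signals, network = tiny_network()) {
  rows <- list()
  for (g in names(signals)) {
    for (comp in names(signals[[g]])) {
      for (lip in names(signals[[g]][[comp]])) {
        sig <- signals[[g]][[comp]][[lip]]
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sprintf("%s_%d", g, seq_along(sig)),
          phenotype = g, compartment = comp, lipid = lip, signal = sig)
      }
    }
  }
  abundance_table(do.call(rbind, rows), network, warn_unknown_head = FALSE)
}

# One lipid present at chosen (compartment, phenotype) cells of a network,
# n samples each; presence is noise-free (all samples positive or all zero).
presence_table <- function(present_at, network, lipids = "PC(34:1)", n = 3L) {
  signals <- list()
  for (g in unique(present_at$phenotype)) signals[[g]] <- list()
  for (g in names(signals)) {
    for (comp in network$compartments) {
      signals[[g]][[comp]] <- list()
      for (lip in lipids) {
        hit <- any(present_at$phenotype == g & present_at$compartment == comp &
                   present_at$lipid == lip)
        signals[[g]][[comp]][[lip]] <- if (hit) rep(1, n) else rep(0, n)
      }
    }
  }
  make_table(signals, network)
}

# --- independent oracles -------------------------------------------------

# Set-arithmetic Jaccard, no vector algebra shared with the implementation.
jaccard_bruteforce <- function(u, v) {
  iu <- which(u == 1)
  iv <- which(v == 1)
  ni <- length(intersect(iu, iv))
  nu <- length(union(iu, iv))
  if (nu == 0) 1 else ni / nu
}

# Permutation p-value by literally permuting v with sample(), the stated
# null the implementation samples through the hypergeometric identity.
jaccard_perm_oracle <- function(u, v, B, seed,
                                alternative = "two_sided") {
  set.seed(seed)
  J_obs <- jaccard_bruteforce(u, v)
  J_perm <- replicate(B, jaccard_bruteforce(u, sample(v)))
  eps <- 1e-12
  mu <- mean(J_perm)
  switch(alternative,
    two_sided = (1 + sum(abs(J_perm - mu) >= abs(J_obs - mu) - eps)) / (B + 1),
    less_similar = (1 + sum(J_perm <= J_obs + eps)) / (B + 1),
    more_similar = (1 + sum(J_perm >= J_obs - eps)) / (B + 1))
}

# Exact null of J under margin-preserving permutation: enumerate the
# hypergeometric overlap support with choose() weights.
jaccard_exact_null <- function(n, ku, kv) {
  x <- max(0L, ku + kv - n):min(ku, kv)
  weight <- choose(ku, x) * choose(n - ku, kv - x)
  data.frame(J = x / (ku + kv - x), prob = weight / sum(weight))
}

jaccard_exact_p <- function(u, v, alternative = "two_sided") {
  n <- length(u); ku <- sum(u); kv <- sum(v)
  null <- jaccard_exact_null(n, ku, kv)
  J_obs <- jaccard_bruteforce(u, v)
  eps <- 1e-12
  mu <- sum(null$J * null$prob)
  switch(alternative,
    two_sided = sum(null$prob[abs(null$J - mu) >= abs(J_obs - mu) - eps]),
    less_similar = sum(null$prob[null$J <= J_obs + eps]),
    more_similar = sum(null$prob[null$J >= J_obs - eps]))
}

# Delta-method standardized log2 fold change, coded from the formula
# independently of the package.
enfc_oracle <- function(m1, s1, n1, m2, s2, n2) {
  lfc <- log(m2 / m1) / log(2)
  se <- sqrt(s2^2 / (n2 * m2^2) + s1^2 / (n1 * m1^2)) / log(2)
  lfc / se
}
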
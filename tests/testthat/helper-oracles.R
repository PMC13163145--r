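# Independent oracles and small fixture builders shared across tests.
# Everything here is deliberately naive/literal so it cannot share a bug
# with the package implementation it checks.

# textbook Benjamini-Hochberg step-up, computed from the definition
bh_textbook <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) adj[i] <- min(ranked[i:m] * m / (i:m))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# hypergeometric upper tail P(X >= k) by direct enumeration with choose()
hyper_tail_enum <- function(k, K, n, N) {
  upper <- min(K, n)
  if (k > upper) return(0)
  sum(vapply(k:upper, function(i)
    choose(K, i) * choose(N - K, n - i), numeric(1))) / choose(N, n)
}

# Rand index between two labelings (pair-counting form)
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  ta <- table(a); tb <- table(b); tab <- table(a, b)
  n <- length(a)
  sum_comb <- function(x) sum(choose(x, 2))
  (choose(n, 2) + 2 * sum_comb(tab) - sum_comb(ta) - sum_comb(tb)) /
    choose(n, 2)
}

# random orthogroup table: presence with prob p_present (focal-first species
# always present when force_focal), gene count 1 + Poisson(lambda)
random_og_table <- function(n_og, species, p_present = 0.7, lambda = 0.5,
                            force_first = FALSE) {
  counter <- stats::setNames(integer(length(species)), species)
  members <- lapply(seq_len(n_og), function(i) {
    m <- lapply(stats::setNames(species, species), function(sp) {
      present <- stats::runif(1) < p_present ||
        (force_first && sp == species[1])
      if (!present) return(character(0))
      ng <- 1L + stats::rpois(1, lambda)
      ids <- sprintf("%s_g%04d", sp, counter[sp] + seq_len(ng))
      counter[sp] <<- counter[sp] + ng
      ids
    })
    m
  })
  names(members) <- sprintf("OG%04d", seq_len(n_og))
  orthogroup_table(members, species = species)
}

# a tiny three-species table used in several parsing/assignment tests
toy_og_table <- function() {
  orthogroup_table(list(
    OG1 = list(A = c("a1", "a2"), B = "b1", C = "c1"),
    OG2 = list(A = "a3", B = character(0), C = "c2"),
    OG3 = list(A = "a4", B = "b2", C = character(0))
  ), species = c("A", "B", "C"))
}

# minimal two-condition sample sheet for one species
toy_samples <- function(sp = "A", n1 = 3L, n2 = 3L) {
  data.frame(
    sample_id = paste0(sp, "_", rep(c("control", "cold"), c(n1, n2)), "_",
                       c(seq_len(n1), seq_len(n2))),
    species_id = sp,
    condition = rep(c("control", "cold"), c(n1, n2)),
    replicate = c(seq_len(n1), seq_len(n2)),
    stringsAsFactors = FALSE)
}
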
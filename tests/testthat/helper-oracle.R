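# Exact finite-state oracle for small lattices, independent of the
# package's C++ update kernel: builds the 2^n x 2^n one-step transition
# matrix of the automaton by enumerating every update permutation and
# every Bernoulli outcome, using only the R-level rule lookups.

# probability that node i flips, given the current joint state bits
flip_prob <- function(lat, bits, i, table, rates, kphr) {
  if (bits[i] == 1) {
    return(dephosphorylation_probability(lat$species[i], rates))
  }
  ns <- neighbour_state(lat, bits, i)
  pa <- allosteric_parameter(table, ns$class, ns$state)
  kph <- if (lat$species[i] == "S") rates$kphs else kphr
  pa * kph
}

# 2^n x 2^n matrix for updating node i alone (rows = from-state)
node_update_matrix <- function(lat, i, table, rates, kphr) {
  n <- length(lat$species)
  ns <- 2^n
  M <- matrix(0, ns, ns)
  for (s in 0:(ns - 1)) {
    bits <- as.integer(bitwAnd(bitwShiftR(s, 0:(n - 1)), 1L))
    p <- flip_prob(lat, bits, i, table, rates, kphr)
    s_flip <- bitwXor(s, bitwShiftL(1L, i - 1L))
    M[s + 1, s_flip + 1] <- M[s + 1, s_flip + 1] + p
    M[s + 1, s + 1] <- M[s + 1, s + 1] + (1 - p)
  }
  M
}

# permutations of 1..n
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (k in seq_len(n)) {
    for (p in all_perms(n - 1)) {
      out[[length(out) + 1]] <- c(k, ifelse(p >= k, p + 1L, p))
    }
  }
  out
}

# one-step transition matrix with in-place sequential updates, averaged
# over all n! update orders
exact_transition_matrix <- function(lat, table, rates, kphr = rates$kphr) {
  n <- length(lat$species)
  perms <- all_perms(n)
  Ms <- lapply(seq_len(n), node_update_matrix, lat = lat, table = table,
               rates = rates, kphr = kphr)
  Tm <- 0
  for (perm in perms) {
    P <- diag(2^n)
    for (i in perm) P <- P %*% Ms[[i]]
    Tm <- Tm + P
  }
  Tm / length(perms)
}

# stationary distribution of a transition matrix (power iteration)
stationary_distribution <- function(Tm, iter = 5000, tol = 1e-14) {
  p <- rep(1 / nrow(Tm), nrow(Tm))
  for (k in seq_len(iter)) {
    p2 <- as.numeric(p %*% Tm)
    if (max(abs(p2 - p)) < tol) return(p2)
    p <- p2
  }
  p
}

# joint-state index (0-based) of a bit matrix, one row per time point
state_index <- function(bits) {
  as.integer(bits %*% 2^(seq_len(ncol(bits)) - 1))
}

# cached canonical lattice for the whole suite
canonical_graph <- stressosome_graph()
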
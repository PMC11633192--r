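# Independent oracles used across the suite. These deliberately use brute
# force / closed forms, never the package's own code paths.

# Exact two-sided Mann-Whitney p by enumeration of all group labelings.
mw_brute_force_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  na <- length(a)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - na * (na + 1) / 2
  u_obs <- u_of(seq_len(na))
  mu <- na * length(b) / 2
  us <- apply(utils::combn(n, na), 2, u_of)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Permutation-null Kruskal-Wallis p: enumerate all assignments of the pooled
# observations to the given group sizes (feasible for total n <= ~8).
kw_brute_force_p <- function(groups) {
  sizes <- lengths(groups)
  pooled <- unlist(groups)
  n <- length(pooled)
  h_of <- function(vals) {
    r <- rank(unlist(vals))
    off <- 0
    s <- 0
    for (sz in sizes) {
      s <- s + sum(r[off + seq_len(sz)])^2 / sz
      off <- off + sz
    }
    12 / (n * (n + 1)) * s - 3 * (n + 1)
  }
  h_obs <- h_of(groups)
  perms <- all_permutations(n)
  hs <- apply(perms, 1, function(p) {
    off <- 0
    g <- vector("list", length(sizes))
    for (i in seq_along(sizes)) {
      g[[i]] <- pooled[p[off + seq_len(sizes[i])]]
      off <- off + sizes[i]
    }
    h_of(g)
  })
  mean(hs >= h_obs - 1e-9)
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

# A random internally consistent isotopocule record on the raw scale.
random_consistent_record <- function(id = "r") {
  alpha <- stats::runif(1, -30, 30)
  beta <- stats::runif(1, -80, 0)
  isotope_measurement(id, substrate = "NO3",
                      d15N_alpha = alpha, d15N_beta = beta,
                      d15N_bulk = (alpha + beta) / 2,
                      d18O = stats::runif(1, 0, 40), SP = alpha - beta)
}
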
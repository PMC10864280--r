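# Shared fixtures and independent oracles for the test suite.

# Metadata with the canonical published pair structure: 97 MZ pairs
# (28 discordant / 22 both-affected / 47 both-healthy) and 122 DZ pairs
# (46 / 13 / 63), two members per pair.
table1_metadata <- function() {
  blocks <- list(c("MZ", 28, 1, 0), c("MZ", 22, 1, 1), c("MZ", 47, 0, 0),
                 c("DZ", 46, 1, 0), c("DZ", 13, 1, 1), c("DZ", 63, 0, 0))
  i <- 0L
  rows <- lapply(blocks, function(b) {
    n <- as.integer(b[2])
    do.call(rbind, lapply(seq_len(n), function(k) {
      i <<- i + 1L
      pid <- sprintf("%s%03d", b[1], i)
      data.frame(sample_id = paste0(pid, c("a", "b")), pair_id = pid,
                 zygosity = b[1], md = as.integer(c(b[3], b[4])),
                 stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}

# small default simulation config for fast tests
small_config <- function(...) {
  args <- utils::modifyList(
    list(n_mz_pairs = 20L, n_dz_pairs = 25L, n_genera = 20L,
         n_metabolites = 15L, n_pathways = 10L, seq_depth = 5000L,
         seed = 101L),
    list(...))
  do.call(sim_config, args)
}

# Brute-force two-sided exact signed-rank p-value: enumerates all 2^n sign
# assignments of the ranked |d| (zeros dropped, no ties assumed) and applies
# the same two-sided doubling rule as the classical test.
brute_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  p_ge <- mean(w_all >= w_obs)
  p_le <- mean(w_all <= w_obs)
  min(1, 2 * min(p_ge, p_le))
}

# Quadrature oracle for the liability-threshold model: proband-wise
# concordance = P(co-twin affected | twin affected)
#   = P(L1 > t, L2 > t) / P(L > t),  t = qnorm(1 - prev),
# with the orthant probability reduced to a 1-D integral
#   P11 = int_t^inf pnorm((r z - t)/sqrt(1 - r^2)) phi(z) dz.
concordance_oracle <- function(r, prev) {
  t <- qnorm(1 - prev)
  if (r == 1) return(1)
  p11 <- stats::integrate(function(z)
    stats::pnorm((r * z - t) / sqrt(1 - r^2)) * stats::dnorm(z),
    lower = t, upper = Inf, rel.tol = 1e-10)$value
  p11 / prev
}

# dense multivariate-normal log-likelihood oracle for the pair-block model
dense_lmm_loglik <- function(y, X, pair, zygosity, s2, szM, szD, beta) {
  n <- length(y)
  V <- diag(s2, n)
  for (p in unique(pair)) {
    idx <- which(pair == p)
    sz <- if (zygosity[idx[1]] == "MZ") szM else szD
    V[idx, idx] <- V[idx, idx] + sz
  }
  r <- y - as.vector(X %*% beta)
  ch <- chol(V)
  -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(ch))) +
            sum(backsolve(ch, r, transpose = TRUE)^2))
}

# random small twin design for LMM tests
random_twin_design <- function(n_pairs, p_covar = 1) {
  pair <- rep(sprintf("p%03d", seq_len(n_pairs)), each = 2L)
  zyg <- rep(rep(c("MZ", "DZ"), length.out = n_pairs), each = 2L)
  X <- cbind("(Intercept)" = 1, md = rbinom(2 * n_pairs, 1, 0.4))
  if (p_covar > 0)
    X <- cbind(X, matrix(rnorm(2 * n_pairs * p_covar), ncol = p_covar,
                         dimnames = list(NULL, paste0("c", seq_len(p_covar)))))
  list(pair = pair, zygosity = zyg, X = X)
}

# simulate a Gaussian response from the twin LMM itself
simulate_lmm_response <- function(design, beta, s2, szM, szD) {
  n <- nrow(design$X)
  u_pair <- rnorm(n / 2, sd = sqrt(ifelse(
    design$zygosity[seq(1, n, 2)] == "MZ", szM, szD)))
  as.vector(design$X %*% beta) + rep(u_pair, each = 2L) +
    rnorm(n, sd = sqrt(s2))
}
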
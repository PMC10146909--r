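# JTT amino-acid substitution model: rate matrix, transition probabilities.
#
# The generator Q is built from the published exchangeabilities S and
# equilibrium frequencies pi as Q_ij = S_ij * pi_j (i != j), diagonal set so
# rows sum to zero, and the whole matrix scaled so that the expected number
# of substitutions per site per unit time at equilibrium, -sum(pi_i Q_ii),
# equals 1. Time-reversibility (pi_i Q_ij = pi_j Q_ji) lets us diagonalize
# the symmetric similarity transform once and get P(t) = exp(Qt) cheaply.

.jtt_env <- new.env(parent = emptyenv())

#' JTT substitution model components
#'
#' Returns the normalized JTT generator, equilibrium frequencies and a
#' cached eigendecomposition used to compute transition probabilities.
#'
#' @return A list with `Q` (20x20 generator, rows sum to zero, scaled to one
#'   expected substitution per site per unit time), `pi` (equilibrium
#'   frequencies, PAML residue order), and eigendecomposition parts.
#' @export
jtt_model <- function() {
  if (!is.null(.jtt_env$model)) return(.jtt_env$model)
  s <- matrix(0, 20L, 20L, dimnames = list(JTT_ALPHABET, JTT_ALPHABET))
  s[lower.tri(s)] <- .jtt_exchangeability
  s <- s + t(s)
  pi <- .jtt_freq_raw / sum(.jtt_freq_raw)
  names(pi) <- JTT_ALPHABET
  q <- s * rep(pi, each = 20L)   # Q_ij = S_ij * pi_j
  diag(q) <- -rowSums(q)
  q <- q / sum(pi * -diag(q))    # 1 expected substitution/site at equilibrium
  # symmetrize: B = D^(1/2) Q D^(-1/2) with D = diag(pi)
  d <- sqrt(pi)
  b <- q * (d %o% (1 / d))
  b <- (b + t(b)) / 2            # clean numerical asymmetry
  eig <- eigen(b, symmetric = TRUE)
  model <- list(
    Q = q, pi = pi,
    values = eig$values,
    left = (1 / d) * eig$vectors,      # D^(-1/2) U
    right = t(eig$vectors * d)         # U' D^(1/2)
  )
  .jtt_env$model <- model
  model
}

#' JTT transition probability matrix P(t) = exp(Qt)
#'
#' @param t Evolutionary time in expected substitutions per site (>= 0).
#' @return A 20x20 row-stochastic matrix in PAML residue order.
#' @export
jtt_prob <- function(t) {
  stopifnot(length(t) == 1L, is.finite(t), t >= 0)
  m <- jtt_model()
  p <- m$left %*% (exp(m$values * t) * m$right)
  p[p < 0] <- 0                  # clip eigen round-off
  dimnames(p) <- dimnames(m$Q)
  p
}

# integer codes 1..20 for standard residues, NA for gap/X/anything else
aa_code <- function(chars) {
  match(chars, JTT_ALPHABET)
}

# sample n residues from the JTT equilibrium distribution (codes 1..20)
jtt_sample_equilibrium <- function(n) {
  sample.int(20L, n, replace = TRUE, prob = jtt_model()$pi)
}

# evolve integer-coded states along one branch of length t
jtt_evolve <- function(states, t) {
  if (t == 0) return(states)
  p <- jtt_prob(t)
  vapply(states, function(s) sample.int(20L, 1L, prob = p[s, ]), integer(1L))
}
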
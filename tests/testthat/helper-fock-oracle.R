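# Independent truncated-Fock-space simulator. Probabilities are obtained by
# explicit operator algebra -- ladder-operator matrix exponentials applied to
# a state tensor -- with the interferometer factored into Givens rotations by
# the oracle's own QR routine. No hafnians anywhere: this is the cross-check
# route for the pattern-probability formula and the exact sampler.

fock_annihilator <- function(d) {
  a <- matrix(0, d, d)
  if (d > 1L) a[cbind(seq_len(d - 1L), 2:d)] <- sqrt(seq_len(d - 1L))
  a
}

# Single-mode squeezer exp(r/2 (ad^2 - a^2)) on a d-level truncation.
fock_squeezer <- function(r, d) {
  a <- fock_annihilator(d)
  ad <- t(a)
  G <- (r / 2) * (ad %*% ad - a %*% a)
  as.matrix(Matrix::expm(G))
}

# Two-mode passive operator for a 2x2 unitary V: exp(i sum K_jk ad_j a_k)
# with V = exp(iK). Composite index has mode 1 fastest.
fock_two_mode_unitary <- function(V, d) {
  ev <- eigen(V)
  P <- ev$vectors
  # orthonormalize (V is normal; guard the degenerate case)
  P <- qr.Q(qr(P))
  mu <- Arg(diag(Conj(t(P)) %*% V %*% P))
  K <- P %*% diag(mu, 2) %*% Conj(t(P))
  a <- fock_annihilator(d)
  ad <- t(a)
  id <- diag(1, d)
  op <- function(O1, O2) kron_fast(O2, O1)  # mode-1 index fastest
  H <- K[1, 1] * op(ad %*% a, id) + K[2, 2] * op(id, ad %*% a) +
    K[1, 2] * op(ad, a) + K[2, 1] * op(a, ad)
  eh <- eigen((H + Conj(t(H))) / 2, symmetric = TRUE)
  eh$vectors %*% diag(exp(1i * eh$values)) %*% Conj(t(eh$vectors))
}

kron_fast <- function(A, B) kronecker(A, B)

# Givens factorization U = G1^H G2^H ... Gk^H D from the oracle's own QR:
# returns ops to apply right-to-left on a state.
oracle_givens_factors <- function(U) {
  N <- nrow(U)
  W <- U
  gs <- list()
  if (N > 1L) {
    for (cc in seq_len(N - 1L)) {
      for (rr in N:(cc + 1L)) {
        a <- W[rr - 1L, cc]
        b <- W[rr, cc]
        nrm <- sqrt(Mod(a)^2 + Mod(b)^2)
        if (nrm < 1e-14) next
        g <- rbind(c(Conj(a), Conj(b)), c(-b, a)) / nrm
        G <- diag(1 + 0i, N)
        G[(rr - 1L):rr, (rr - 1L):rr] <- g
        W <- G %*% W
        gs[[length(gs) + 1L]] <- list(modes = c(rr - 1L, rr), g = g)
      }
    }
  }
  list(gs = gs, phases = Arg(diag(W)))
}

# Apply a d^m x d^m operator to modes `modes` of a state tensor.
apply_modes <- function(psi, op, modes, d, N) {
  perm <- c(modes, setdiff(seq_len(N), modes))
  psi <- aperm(psi, perm)
  dm <- d^length(modes)
  m <- matrix(psi, nrow = dm)
  m <- op %*% m
  psi <- array(m, rep(d, N))
  aperm(psi, order(perm))
}

# Full oracle: state tensor of the circuit (squeezers then interferometer),
# truncated at d levels per mode.
fock_oracle_state <- function(r, U, d) {
  N <- length(r)
  psi <- array(0 + 0i, rep(d, N))
  psi[matrix(1L, 1, N)] <- 1
  for (m in seq_len(N)) {
    if (r[m] != 0) {
      psi <- apply_modes(psi, fock_squeezer(r[m], d), m, d, N)
    }
  }
  fac <- oracle_givens_factors(U)
  # U = G1^H ... Gk^H D: apply D first, then Gk^H ... G1^H
  nvec <- 0:(d - 1L)
  for (m in seq_len(N)) {
    ph <- exp(1i * fac$phases[m] * nvec)
    psi <- apply_modes(psi, diag(ph, d), m, d, N)
  }
  for (f in rev(fac$gs)) {
    psi <- apply_modes(psi, fock_two_mode_unitary(Conj(t(f$g)), d), f$modes,
                       d, N)
  }
  psi
}

# Probability of a collision-free pattern (vector of detected modes).
fock_oracle_probability <- function(psi, modes, N) {
  idx <- rep(1L, N)
  idx[modes] <- 2L
  Mod(psi[matrix(idx, 1)])^2
}
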
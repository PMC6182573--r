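# Independent direct-summation oracle: every formula evaluated with explicit
# loops, including an O(L^2) DFT-based analytic signal, sharing no code with
# the package internals.

oracle_analytic <- function(z) {
  L <- length(z)
  k <- 0:(L - 1)
  X <- vapply(k, function(kk) sum(z * exp(-2i * pi * kk * k / L)),
              complex(1))
  w <- numeric(L)
  if (L %% 2 == 0) { w[1] <- 1; w[L / 2 + 1] <- 1; w[2:(L / 2)] <- 2 }
  else { w[1] <- 1; w[2:((L + 1) / 2)] <- 2 }
  vapply(k, function(nn) sum(w * X * exp(2i * pi * k * nn / L)) / L,
         complex(1))
}

oracle_measures <- function(spec) {
  U <- spec$coeffs[, 1, ]; V <- spec$coeffs[, 2, ]
  N <- nrow(U); nf <- ncol(U)
  S_uv <- S_uu <- S_vv <- complex(nf)
  for (n in seq_len(N)) {
    S_uv <- S_uv + U[n, ] * Conj(V[n, ]) / N
    S_uu <- S_uu + U[n, ] * Conj(U[n, ]) / N
    S_vv <- S_vv + V[n, ] * Conj(V[n, ]) / N
  }
  C <- S_uv / sqrt(Re(S_uu) * Re(S_vv))
  plv <- pli <- complex(nf)
  wnum <- wden <- ienv <- numeric(nf)
  for (n in seq_len(N)) {
    P <- U[n, ] * Conj(V[n, ])
    plv <- plv + exp(1i * (Arg(U[n, ]) - Arg(V[n, ]))) / N
    pli <- pli + sign(Im(P)) / N
    wnum <- wnum + Im(P) / N
    wden <- wden + abs(Im(P)) / N
    ienv <- ienv + Mod(oracle_analytic(Im(P))) / N
  }
  icoh2 <- wnum / ienv
  list(COH = Mod(C), PLV = Mod(plv), ICOH1 = Im(C),
       ICOH2 = icoh2, PLI = Mod(pli), WPLI = abs(wnum) / wden,
       LCOH = Im(C)^2 / (1 - Re(C)^2),
       EIC1 = Mod(oracle_analytic(Im(C))),
       EIC2 = Mod(oracle_analytic(icoh2)))
}
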
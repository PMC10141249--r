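# shared fixture builders -------------------------------------------------

# write a minimal XYZ file and return its path
write_xyz_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".xyz",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

write_text_fixture <- function(lines, ext = ".tsv") {
  path <- withr::local_tempfile(fileext = ext,
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# diatomic fixture with chosen masses and force constant (hartree/bohr^2)
diatomic <- function(m1, m2, k = 0.3) {
  gen_coupled_oscillator(2, masses = c(m1, m2), springs = k)
}

# independent brute-force KED oracle: mass-weighted diagonalization done
# by hand, then the per-atom statistic evaluated directly from raw
# eigenvectors (r_i = q_i / sqrt(m_i); KED_i = m_i |r_i|^2 / sum_k ...)
ked_oracle <- function(hessian, structure, zero_tol = 1) {
  m3 <- rep(structure$masses, each = 3)
  mw <- unclass(as.matrix(hessian)) / sqrt(outer(m3, m3))
  eig <- eigen(mw, symmetric = TRUE)
  freq <- sign(eig$values) * sqrt(abs(eig$values)) *
    reactfactors:::.freq_factor
  keep <- which(abs(freq) >= zero_tol)
  n <- length(structure$masses)
  ked <- sapply(keep, function(j) {
    r <- eig$vectors[, j] / sqrt(m3)
    num <- sapply(seq_len(n), function(i) {
      structure$masses[i] * sum(r[(3 * i - 2):(3 * i)]^2)
    })
    num / sum(num)
  })
  list(freq = sort(freq[keep]),
       ked = ked[, order(freq[keep]), drop = FALSE])
}

# per-model step-1 cycles from a generated series
series_cycles <- function(series) {
  led <- as.data.frame(series$ledger)
  lapply(series$legs$model, function(m)
    build_step1_cycle(fe_ledger(led[led$model == m, ])))
}
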
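# Synthetic emulation of quantum-chemistry outputs: harmonic-chain and
# random Hessians, constructed transition-state modes, linear charge
# responses, and a five-model free-energy series with the trend structure
# of a cofactor maturation study. All generators are bit-reproducible
# under a fixed seed; truth values are synthetic, never measured data.

.polarization_presets <- c(A = 1.34, B = 1.26, C = 1.18, D = 1.10, E = 1.02)

#' Linear-chain coupled-oscillator fixture
#'
#' Atoms on the z axis, 1 Angstrom apart, coupled by nearest-neighbour
#' springs acting along z. For a uniform free chain the nonzero
#' longitudinal frequencies have closed forms (e.g. ratio 1 : sqrt(3) for
#' the three-atom chain), making this the workhorse oracle fixture for
#' normal-mode code.
#'
#' @param n_atoms number of atoms (>= 2).
#' @param masses amu; default drawn uniformly in [1, 20] from `seed`.
#' @param springs force constants (hartree/bohr^2), length `n_atoms - 1`;
#'   default drawn uniformly in [0.05, 0.5] from `seed`.
#' @param frozen integer indices of frozen atoms.
#' @param seed RNG seed for the default draws.
#' @return list with elements `structure` ([xyz_structure()]) and `hessian`
#'   ([cart_hessian()], unprojected).
#' @export
gen_coupled_oscillator <- function(n_atoms, masses = NULL, springs = NULL,
                                   frozen = integer(0), seed = NULL) {
  if (n_atoms < 2) stop("need at least 2 atoms")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(masses)) masses <- stats::runif(n_atoms, 1, 20)
  if (is.null(springs)) springs <- stats::runif(n_atoms - 1L, 0.05, 0.5)
  if (length(masses) != n_atoms || length(springs) != n_atoms - 1L)
    stop("inconsistent masses/springs lengths")
  if (any(springs <= 0)) stop("spring constants must be positive")
  coords <- cbind(0, 0, seq_len(n_atoms) - 1)
  st <- xyz_structure(rep("X", n_atoms), coords, frozen = frozen,
                      masses = masses, label = "linear chain")
  H <- matrix(0, 3 * n_atoms, 3 * n_atoms)
  z <- 3 * seq_len(n_atoms)          # z-coordinate rows
  for (b in seq_len(n_atoms - 1L)) {
    k <- springs[b]
    i <- z[b]; j <- z[b + 1L]
    H[i, i] <- H[i, i] + k
    H[j, j] <- H[j, j] + k
    H[i, j] <- H[i, j] - k
    H[j, i] <- H[j, i] - k
  }
  list(structure = st, hessian = cart_hessian(H, st))
}

#' Random dense symmetric Hessian fixture
#'
#' A random symmetric matrix (not derived from any potential) for
#' stress-testing diagonalization and KED normalization.
#'
#' @param n_atoms number of atoms.
#' @param seed RNG seed.
#' @param frozen integer indices of frozen atoms.
#' @param scale magnitude of the entries (hartree/bohr^2).
#' @return list with `structure` and `hessian` (unprojected).
#' @export
gen_random_hessian <- function(n_atoms, seed = NULL, frozen = integer(0),
                               scale = 0.05) {
  if (!is.null(seed)) set.seed(seed)
  d <- 3L * n_atoms
  A <- matrix(stats::rnorm(d * d), d, d)
  st <- xyz_structure(rep("X", n_atoms),
                      matrix(stats::runif(3 * n_atoms, -3, 3), n_atoms, 3),
                      frozen = frozen,
                      masses = stats::runif(n_atoms, 1, 30),
                      label = "random fixture")
  list(structure = st, hessian = cart_hessian(scale * (A + t(A)) / 2, st))
}

#' Constructed transition-state mode set
#'
#' Builds one imaginary-frequency mode whose fragment KED equals
#' `target_share` exactly (the mass-weighted displacement is solved from
#' the KED definition), plus random real modes spanning the orthogonal
#' complement of the free subspace. Emulates the reactive mode of an
#' S-CH3 cleavage transition state with a prescribed methyl share.
#'
#' @param structure an [xyz_structure()]; frozen atoms get exactly zero
#'   displacement.
#' @param frag a [fragment()] or integer atom indices carrying the target
#'   share (must contain at least one unfrozen atom).
#' @param target_share fraction of the reactive mode's kinetic energy on
#'   the fragment, in (0, 1]; `1` requires the fragment to cover all
#'   unfrozen atoms' complement trivially (no unfrozen atoms outside it
#'   carry amplitude).
#' @param seed RNG seed.
#' @param imag_freq wavenumber of the reactive mode (cm^-1, negative).
#' @return a [mode_set()] with exactly one imaginary mode.
#' @export
gen_ts_mode <- function(structure, frag, target_share, seed = NULL,
                        imag_freq = -500) {
  if (inherits(frag, "fragment")) frag <- frag$atoms
  frag <- as.integer(frag)
  n <- length(structure$elements)
  if (!length(frag) || any(frag < 1 | frag > n)) stop("invalid fragment")
  if (target_share <= 0 || target_share > 1)
    stop("target_share must lie in (0, 1]")
  if (imag_freq >= 0) stop("imag_freq must be negative")
  if (!is.null(seed)) set.seed(seed)
  free <- which(!structure$frozen)
  frag_free <- intersect(frag, free)
  off_free <- setdiff(free, frag)
  if (!length(frag_free)) stop("fragment contains no unfrozen atoms")
  if (!length(off_free) && target_share < 1)
    stop("fragment covers all unfrozen atoms: share < 1 is infeasible")
  rows_of <- function(at) as.vector(rbind(3 * at - 2, 3 * at - 1, 3 * at))
  u <- numeric(3 * n)
  uf <- stats::rnorm(3 * length(frag_free))
  u[rows_of(frag_free)] <- uf / sqrt(sum(uf^2)) * sqrt(target_share)
  if (length(off_free) && target_share < 1) {
    uo <- stats::rnorm(3 * length(off_free))
    u[rows_of(off_free)] <- uo / sqrt(sum(uo^2)) * sqrt(1 - target_share)
  }
  # orthonormal real modes spanning the rest of the free subspace
  free_rows <- rows_of(free)
  n_free <- length(free_rows)
  B <- cbind(u[free_rows],
             matrix(stats::rnorm(n_free * (n_free - 1L)), n_free))
  Q <- qr.Q(qr(B))
  Q[, 1] <- u[free_rows]             # keep the constructed vector exact
  n_real <- n_free - 1L
  vec <- matrix(0, 3 * n, n_free)
  vec[free_rows, ] <- Q
  freq <- c(imag_freq,
            if (n_real > 0) sort(stats::runif(n_real, 200, 1600)))
  m3 <- rep(structure$masses, each = 3L)
  mode_set(freq, vec / sqrt(m3), structure)
}

#' Synthetic linear charge-response table
#'
#' Per-atom linear response coefficients `a_i` with `sum |a_i|` equal to
#' the truth slope, so the noise-free polarization curve is exactly
#' `P(q_P) = slope_truth * q_P`. Gaussian noise of sd `noise_sd` is added
#' to every charge except at `q_P = 0` (the reference column stays exact).
#'
#' @param n_atoms number of ligand atoms (default 25).
#' @param slope_truth true polarization slope (e per e); alternatively give
#'   `preset` ("A" ... "E", slopes 1.34, 1.26, 1.18, 1.10, 1.02; only the
#'   end members mirror printed values, B-D are interpolated).
#' @param noise_sd Gaussian charge noise (e), default 0.
#' @param grid probe-charge grid (e), default 0 to 1 in 0.1 steps.
#' @param seed RNG seed.
#' @param preset model preset letter, overrides `slope_truth`.
#' @return a [charge_response()] with attribute `"slope_truth"`.
#' @export
gen_charge_response <- function(n_atoms = 25, slope_truth = NULL,
                                noise_sd = 0, grid = seq(0, 1, by = 0.1),
                                seed = NULL, preset = NULL) {
  if (!is.null(preset)) {
    if (!preset %in% names(.polarization_presets))
      stop("unknown preset '", preset, "'")
    slope_truth <- .polarization_presets[[preset]]
  }
  if (is.null(slope_truth) || slope_truth < 0)
    stop("slope_truth must be a nonnegative number (or give a preset)")
  if (!length(grid)) stop("empty probe grid")
  if (grid[1] != 0) stop("probe grid must start at 0")
  if (!is.null(seed)) set.seed(seed)
  a <- stats::rnorm(n_atoms)
  a <- if (sum(abs(a)) > 0 && slope_truth > 0)
         a / sum(abs(a)) * slope_truth else rep(0, n_atoms)
  q0 <- stats::runif(n_atoms, -0.5, 0.5)
  ch <- outer(q0, rep(1, length(grid))) + outer(a, grid)
  if (noise_sd > 0) {
    noise <- matrix(stats::rnorm(length(ch), sd = noise_sd), nrow = n_atoms)
    noise[, grid == 0] <- 0
    ch <- ch + noise
  }
  out <- charge_response(ch, grid,
                         label = if (!is.null(preset)) preset else "")
  attr(out, "slope_truth") <- slope_truth
  out
}

#' Specification of a synthetic five-model series
#'
#' Truth values for an A-E-like series of cofactor models. Defaults are
#' chosen so the series reproduces the qualitative structure of a
#' maturation study: a constant homolytic-cleavage leg, Ni-S and
#' electron-transfer legs linear in the overall step-1 free energy with
#' slopes 2.8 and -1.8, late transition states (TS within `ts_window`
#' kcal/mol of the following intermediate, hence a ~1:1 barrier/driving
#' force relation), reduction potentials increasing along B < A < C < D <
#' E, and the Ni-S bond shortest / most covalent for the last model.
#' All values are synthetic constructions.
#'
#' @param labels model labels.
#' @param total_step1 overall step-1 free energies dG'_0,1 (kcal/mol).
#' @param slope_NiS,slope_ET leg-vs-total slopes (dimensionless).
#' @param NiS_mean,ET_mean series means of the two legs (kcal/mol).
#' @param ss_leg constant S-S formation leg of step 3 (kcal/mol).
#' @param e0_ref_couple reduction potential of the thiyl/thiolate reference
#'   couple (V), fixing the absolute scale of the model potentials.
#' @param ts_window range (kcal/mol) for the late-TS gap G_TS - G_Int.
#' @param polarization_slopes per-model polarization slope truths (e/e).
#' @param ked_targets per-model fragment KED of the reactive mode.
#' @param p_C,p_S per-model sigma* orbital percentages.
#' @param noise_sd_charges charge noise for generated response tables (e).
#' @param seed RNG seed used by [gen_model_series()].
#' @return object of class `series_spec` (a validated list).
#' @export
series_spec <- function(labels = c("A", "B", "C", "D", "E"),
                        total_step1 = c(22, 26, 12, 8, 3),
                        slope_NiS = 2.8, slope_ET = -1.8,
                        NiS_mean = -25, ET_mean = -40,
                        ss_leg = -80, e0_ref_couple = 0.75,
                        ts_window = c(2, 5),
                        polarization_slopes = c(1.34, 1.26, 1.18, 1.10, 1.02),
                        ked_targets = c(0.80, 0.79, 0.83, 0.85, 0.88),
                        p_C = c(40, 39, 41, 42, 43),
                        p_S = c(24, 25, 22, 20.5, 19),
                        noise_sd_charges = 0.005,
                        seed = 1) {
  k <- length(labels)
  stopifnot(length(total_step1) == k, length(polarization_slopes) == k,
            length(ked_targets) == k, length(p_C) == k, length(p_S) == k)
  if (length(ts_window) != 2 || diff(ts_window) < 0 || ts_window[1] <= 0)
    stop("ts_window must be a positive increasing range")
  structure(list(labels = labels, total_step1 = total_step1,
                 slope_NiS = slope_NiS, slope_ET = slope_ET,
                 NiS_mean = NiS_mean, ET_mean = ET_mean, ss_leg = ss_leg,
                 e0_ref_couple = e0_ref_couple, ts_window = ts_window,
                 polarization_slopes = polarization_slopes,
                 ked_targets = ked_targets, p_C = p_C, p_S = p_S,
                 noise_sd_charges = noise_sd_charges, seed = seed),
            class = "series_spec")
}

#' Generate the synthetic model series
#'
#' Materializes a [series_spec()] into per-model free-energy ledgers (whose
#' step-1 and step-3 cycles close exactly on the specified legs), step
#' energetics with late transition states, leg truths, reduction
#' potentials, and a bond-descriptor table.
#'
#' @param spec a [series_spec()].
#' @param seed RNG seed (default `spec$seed`).
#' @return list with elements:
#' \describe{
#'   \item{ledger}{an [fe_ledger()] with a `model` column; per model the
#'     corner species of both cycles.}
#'   \item{energetics}{data.frame `model`, `dG_act`, `dG0`, `window`
#'     (kcal/mol), suitable for [bep_regression()].}
#'   \item{legs}{data.frame of true leg values per model.}
#'   \item{potentials}{data.frame `model`, `E0` (V).}
#'   \item{descriptors}{bond-descriptor table (distances, delocalization
#'     indices, bond orders, AIM charges, KED and orbital targets).}
#' }
#' @export
gen_model_series <- function(spec = series_spec(), seed = spec$seed) {
  set.seed(seed)
  k <- length(spec$labels)
  tot <- spec$total_step1
  tbar <- mean(tot)
  NiS <- spec$slope_NiS * (tot - tbar) + spec$NiS_mean
  ET <- spec$slope_ET * (tot - tbar) + spec$ET_mean
  cleav <- tot - NiS - ET            # constant by construction
  if (max(abs(cleav - cleav[1])) > 1e-9)
    stop("leg construction failed closure")

  # absolute free energies (kcal/mol); cycle corners close on the legs
  g_ch3scom <- 0; g_scom_rad <- 30; g_ch3_rad <- cleav[1] - g_scom_rad
  g_scom_anion <- -20; g_ni1 <- 0
  g_ni2 <- ET + g_ni1 + g_scom_rad - g_scom_anion
  g_ni2_scom <- NiS + g_ni2 + g_scom_anion
  g_cobs_rad <- 10
  g_ss <- spec$ss_leg + g_scom_rad + g_cobs_rad

  ledger <- do.call(rbind, lapply(seq_len(k), function(i) {
    data.frame(
      model = spec$labels[i],
      species = c("ch3scom", "ch3_rad", "scom_rad", "scom_anion",
                  "ni1", "ni2", "ni2_scom", "cobs_rad", "ss_adduct"),
      E_el = c(g_ch3scom, g_ch3_rad, g_scom_rad, g_scom_anion,
               g_ni1, g_ni2[i], g_ni2_scom[i], g_cobs_rad, g_ss),
      stringsAsFactors = FALSE)
  }))
  ledger <- fe_ledger(ledger)

  window <- stats::runif(k, spec$ts_window[1], spec$ts_window[2])
  energetics <- data.frame(model = spec$labels, dG_act = tot + window,
                           dG0 = tot, window = window,
                           stringsAsFactors = FALSE)

  legs <- data.frame(model = spec$labels, cleavage = cleav, ET = ET,
                     NiS = NiS, total = tot,
                     NiS_cleavage = -NiS, ET_step3 = -ET, S_S = spec$ss_leg,
                     total_step3 = -NiS - ET + spec$ss_leg,
                     stringsAsFactors = FALSE)

  potentials <- data.frame(
    model = spec$labels,
    E0 = spec$e0_ref_couple + ET / unit_constants[["ev_kcal"]],
    stringsAsFactors = FALSE)

  # bond descriptors: Ni-S shortens and gains covalency along the series
  # while the mean Ni-N lengthens and loses it (electron-donation
  # competition); AIM charges drift accordingly
  rank01 <- (spec$ked_targets - min(spec$ked_targets)) /
            diff(range(spec$ked_targets))
  descriptors <- data.frame(
    model = spec$labels,
    NiS_dist = 2.44 - 0.14 * rank01,
    NiN_dist = 2.04 + 0.07 * rank01,
    di_NiS = 0.86 + 0.26 * rank01,
    di_NiN = 0.56 - 0.10 * rank01,
    bo_NiS = 0.78 + 0.24 * rank01,
    bo_NiN = 0.52 - 0.09 * rank01,
    q_Ni = 1.22 - 0.05 * rank01,
    q_N = -1.175 + 0.025 * rank01,
    ked_ch3 = spec$ked_targets,
    p_C = spec$p_C, p_S = spec$p_S,
    F_ch3 = f_ch3(spec$p_C, spec$p_S),
    stringsAsFactors = FALSE)

  list(ledger = ledger, energetics = energetics, legs = legs,
       potentials = potentials, descriptors = descriptors, spec = spec)
}

#' Bivariate series with a target correlation
#'
#' Standard-normal pair construction `y = r x + sqrt(1 - r^2) z`, giving a
#' population Pearson correlation equal to `r_target`; used to test
#' correlation recovery by [trend_fit()].
#'
#' @param n points.
#' @param r_target population correlation in [-1, 1].
#' @param seed RNG seed.
#' @return data.frame with columns `x`, `y`.
#' @export
gen_correlated_series <- function(n, r_target, seed = NULL) {
  if (abs(r_target) > 1) stop("r_target must lie in [-1, 1]")
  if (!is.null(seed)) set.seed(seed)
  x <- stats::rnorm(n)
  y <- r_target * x + sqrt(1 - r_target^2) * stats::rnorm(n)
  data.frame(x = x, y = y)
}
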
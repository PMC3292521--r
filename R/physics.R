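# The physics-based scoring function: a seven-term weighted sum for
# folding (bend, Lennard-Jones, helix, beta, ionic, solvation,
# disulfide) and a three-term sum for binding (inter-molecular LJ and
# ionic terms plus the change in solvation on complex formation).
# Every term is evaluated from a "measurement" list extracted once per
# structure, so Random-Energy-Model decoys can re-score the same
# sequence on independently shuffled measurements.

FOLD_TERMS <- c("bend", "lj", "helix", "beta", "ion", "solv", "ss")
BIND_TERMS <- c("blj", "bion", "bdsolv")
BIND_SIGNS <- c(blj = 1, bion = 1, bdsolv = -1)

# wrap an angle difference in degrees to (-180, 180]
wrap_deg <- function(x) {
  y <- (x + 180) %% 360 - 180
  ifelse(y == -180, 180, y)
}

#' Extract the geometric measurements consumed by the physics terms
#'
#' Returns bend angles, backbone torsions, the i,i+2 / i,i+3 Calpha
#' distances, the three bead-pair distance classes
#' (Calpha--Calpha, Calpha--Cbeta, Cbeta--Cbeta interaction centers),
#' and per-residue solvent exposure. These are the shuffling units of
#' the geometry decoy generator.
#'
#' @param structure A `coarse_structure`.
#' @param const Physics constants.
#' @return A list of measurement vectors/matrices.
#' @keywords internal
physics_measurements <- function(structure, const = physics_constants()) {
  n <- nrow(structure)
  ca <- cs_ca(structure)
  int <- cs_interaction(structure)
  r13 <- if (n >= 3) sqrt(rowSums((ca[-c(1:2), , drop = FALSE] -
                                   ca[seq_len(n - 2), , drop = FALSE])^2)) else numeric(0)
  r14 <- if (n >= 4) sqrt(rowSums((ca[-(1:3), , drop = FALSE] -
                                   ca[seq_len(n - 3), , drop = FALSE])^2)) else numeric(0)
  list(
    n = n, aa = structure$aa,
    theta = structure$theta,
    phi = structure$phi,
    r13 = r13, r14 = r14,
    d_caca = pair_dist(ca),
    d_cacb = pair_dist(ca, int),
    d_cbcb = pair_dist(int),
    sasa = sasa_fraction_points(int, cutoff = const$nv_cutoff)
  )
}

# --- term evaluators over measurements ------------------------------------

term_bend <- function(m, sp, const) {
  th <- m$theta; th0 <- sp$theta0; n <- m$n
  s1 <- s2 <- 0
  i1 <- which(!is.na(th) & seq_len(n) >= 2)
  if (length(i1)) s1 <- sum((th[i1] - th0[i1])^2)
  i2 <- which(!is.na(th[-1]))            # i in 1..n-1 with theta[i+1] defined
  if (length(i2)) s2 <- sum((th[i2 + 1] - th0[i2])^2)
  0.5 * const$k_theta * (s1 + s2)
}

term_lj <- function(m, sp, const) {
  n <- m$n
  has_cb <- m$aa != "G"
  lj <- function(d, eps, sig) {
    if (any(d == 0)) stop("coincident beads: zero inter-bead distance")
    x6 <- (sig / d)^6
    4 * sum(eps * (x6^2 - x6))
  }
  tot <- 0
  # Calpha-Calpha: i < j, excluding bonded neighbors (j = i + 1)
  ut <- which(upper.tri(m$d_caca), arr.ind = TRUE)
  keep <- ut[, 2] - ut[, 1] > 1
  if (any(keep)) {
    d <- m$d_caca[ut[keep, , drop = FALSE]]
    tot <- tot + lj(d, const$ca_epsilon, 2 * const$ca_radius)
  }
  # Calpha(i)-Cbeta(j): all ordered pairs i != j with a Cbeta at j
  idx <- which(outer(seq_len(n), seq_len(n), "!=") &
                 matrix(has_cb, n, n, byrow = TRUE), arr.ind = TRUE)
  if (nrow(idx)) {
    d <- m$d_cacb[idx]
    epsj <- sqrt(const$ca_epsilon * sp$h[idx[, 2]])
    sigj <- const$ca_radius + sp$r[idx[, 2]]
    tot <- tot + lj(d, epsj, sigj)
  }
  # Cbeta-Cbeta: i < j, both non-glycine
  ut <- which(upper.tri(m$d_cbcb), arr.ind = TRUE)
  keep <- has_cb[ut[, 1]] & has_cb[ut[, 2]]
  if (any(keep)) {
    ij <- ut[keep, , drop = FALSE]
    d <- m$d_cbcb[ij]
    tot <- tot + lj(d, sqrt(sp$h[ij[, 1]] * sp$h[ij[, 2]]),
                    sp$r[ij[, 1]] + sp$r[ij[, 2]])
  }
  tot
}

.rollmean <- function(x, k) {
  cs <- cumsum(c(0, x))
  (cs[(k + 1):length(cs)] - cs[seq_len(length(cs) - k)]) / k
}

term_helix <- function(m, sp, const) {
  n <- m$n
  if (n < 6) return(0)
  i <- 3:(n - 3)
  k13 <- .rollmean(sp$helix_prop, 3)[i]
  k14 <- .rollmean(sp$helix_prop, 4)[i]
  sum(0.5 * k13 * (m$r13[i] - const$r_h)^2 +
        0.5 * k14 * (m$r14[i] - const$r_h)^2)
}

term_beta <- function(m, sp, const) {
  n <- m$n
  if (n < 4) return(0)
  i <- 2:(n - 2)
  ok <- i[!is.na(m$phi[i])]
  if (!length(ok)) return(0)
  k <- .rollmean(sp$beta_prop, 4)[ok - 1]
  dphi <- wrap_deg(m$phi[ok] * 180 / pi - const$phi_b)
  sum(k * const$c_b * dphi^2)
}

term_ion <- function(m, sp, const) {
  buried <- which(sp$charge != 0 & m$sasa < const$burial_sasa)
  if (length(buried) < 2) return(0)
  pr <- utils::combn(buried, 2)
  d <- m$d_cbcb[cbind(pr[1, ], pr[2, ])]
  const$c_c * sum(sp$charge[pr[1, ]] * sp$charge[pr[2, ]] / (const$epsilon * d))
}

term_solv <- function(m, sp, const) {
  sum(sp$h * m$sasa + sp$p * (1 - m$sasa))
}

term_ss <- function(m, sp, const) {
  cys <- which(m$aa == "C")
  if (length(cys) < 2) return(0)
  pr <- utils::combn(cys, 2)
  d <- m$d_cbcb[cbind(pr[1, ], pr[2, ])]
  -sum(d < const$r_ss)
}

fold_terms_meas <- function(m, sp, const = physics_constants()) {
  c(bend = term_bend(m, sp, const),
    lj = term_lj(m, sp, const),
    helix = term_helix(m, sp, const),
    beta = term_beta(m, sp, const),
    ion = term_ion(m, sp, const),
    solv = term_solv(m, sp, const),
    ss = term_ss(m, sp, const))
}

# --- exported per-term interface ------------------------------------------

.term_on_structure <- function(structure, fn, const, sasa = NULL) {
  m <- physics_measurements(structure, const)
  if (!is.null(sasa)) m$sasa <- sasa
  sp <- sequence_params(cs_sequence(structure))
  fn(m, sp, const)
}

#' Individual terms of the physics-based folding score
#'
#' `v_bend()`: harmonic bending energy about the residue-type
#' equilibrium angles (both printed half-sums; interior angles
#' contribute twice). `v_lj()`: Lennard-Jones sum over all bead pairs
#' (Calpha--Calpha, Calpha--Cbeta, Cbeta--Cbeta), excluding same-residue
#' and directly bonded pairs. `v_helix()`: harmonic restraints of the
#' i,i+2 and i,i+3 Calpha distances to 5.5 A, force constants averaged
#' helical propensities. `v_beta()`: harmonic restraint of backbone
#' torsions to 210 degrees (circular difference), scaled by 0.01 and
#' averaged beta propensities. `v_ion()`: Coulomb sum over buried
#' charged pairs (both exposure fractions < 0.25). `v_solv()`:
#' SASA-weighted hydropathy/polarity sum. `v_ss()`: -1 per cysteine
#' Cbeta pair closer than 4.5 A.
#'
#' @param structure A `coarse_structure` (already carrying the sequence
#'   of interest).
#' @param sasa Optional per-residue exposure fractions; computed from
#'   the structure when omitted.
#' @param const Physics constants, see [physics_constants()].
#' @return Numeric energy (dimensionless model units).
#' @export
v_bend <- function(structure, const = physics_constants()) {
  .term_on_structure(structure, term_bend, const)
}

#' @rdname v_bend
#' @export
v_lj <- function(structure, const = physics_constants()) {
  .term_on_structure(structure, term_lj, const)
}

#' @rdname v_bend
#' @export
v_helix <- function(structure, const = physics_constants()) {
  .term_on_structure(structure, term_helix, const)
}

#' @rdname v_bend
#' @export
v_beta <- function(structure, const = physics_constants()) {
  .term_on_structure(structure, term_beta, const)
}

#' @rdname v_bend
#' @export
v_ion <- function(structure, sasa = NULL, const = physics_constants()) {
  .term_on_structure(structure, term_ion, const, sasa = sasa)
}

#' @rdname v_bend
#' @export
v_solv <- function(structure, sasa = NULL, const = physics_constants()) {
  .term_on_structure(structure, term_solv, const, sasa = sasa)
}

#' @rdname v_bend
#' @export
v_ss <- function(structure, const = physics_constants()) {
  .term_on_structure(structure, term_ss, const)
}

# --- weight vectors --------------------------------------------------------

#' Term weight vectors
#'
#' A weight vector is a named numeric with one entry per scoring term
#' (folding: `bend`, `lj`, `helix`, `beta`, `ion`, `solv`, `ss`;
#' binding: `blj`, `bion`, `bdsolv`), each strictly inside (0, 1).
#'
#' @param kind `"fold"` or `"bind"`.
#' @param value Common default value for all terms.
#' @param w Named numeric to validate.
#' @return Named numeric weight vector.
#' @export
default_weights <- function(kind = c("fold", "bind"), value = 0.5) {
  kind <- match.arg(kind)
  nm <- if (kind == "fold") FOLD_TERMS else BIND_TERMS
  stats::setNames(rep(value, length(nm)), nm)
}

#' @rdname default_weights
#' @param strict Enforce the optimizer's (0, 1) search-space bounds;
#'   plain scoring accepts any finite non-negative weights.
#' @export
validate_weights <- function(w, kind = c("fold", "bind"), strict = FALSE) {
  kind <- match.arg(kind)
  nm <- if (kind == "fold") FOLD_TERMS else BIND_TERMS
  if (!all(nm %in% names(w))) {
    stop("weight vector must name all terms: ", paste(nm, collapse = ", "))
  }
  w <- w[nm]
  if (any(!is.finite(w) | w < 0)) stop("weights must be finite and non-negative")
  if (strict && any(w <= 0 | w >= 1)) {
    stop("weights must lie strictly inside (0, 1)")
  }
  w
}

# --- composite scores ------------------------------------------------------

#' Physics-based folding score
#'
#' Computes the seven raw term values on a coarse structure and their
#' weighted sum (lower is better). If `sequence` is supplied and
#' differs from the structure's own sequence, it is first threaded onto
#' the backbone with [thread()].
#'
#' @param conformation A `coarse_structure`.
#' @param weights Named weight vector (see [default_weights()]).
#' @param sequence Optional sequence to thread before scoring.
#' @param thread_config Threading configuration, see [threading_config()].
#' @param const Physics constants.
#' @return An object of class `physics_score`: list with `terms` (named
#'   numeric raw term values), `weights`, `total`, and the scored
#'   `structure`.
#' @export
score_fold_physics <- function(conformation, weights = default_weights("fold"),
                               sequence = NULL,
                               thread_config = threading_config(),
                               const = physics_constants()) {
  weights <- validate_weights(weights, "fold")
  structure <- conformation
  if (!is.null(sequence) && sequence != cs_sequence(conformation)) {
    structure <- thread(sequence, conformation, thread_config, const = const)
  }
  m <- physics_measurements(structure, const)
  sp <- sequence_params(cs_sequence(structure))
  terms <- fold_terms_meas(m, sp, const)
  out <- list(terms = terms, weights = weights,
              total = sum(weights * terms), structure = structure)
  class(out) <- "physics_score"
  out
}

#' @export
print.physics_score <- function(x, ...) {
  cat("<physics_score> total =", format(x$total, digits = 6), "\n")
  print(tidy.physics_score(x))
  invisible(x)
}

#' Tidy a physics score into a per-term table
#' @param x A `physics_score`.
#' @param ... Unused.
#' @return Tibble with columns `term`, `value`, `weight`,
#'   `contribution` (signed, as it enters the total).
#' @export
tidy.physics_score <- function(x, ...) {
  sgn <- if (all(names(x$terms) %in% BIND_TERMS)) BIND_SIGNS[names(x$terms)] else 1
  tibble::tibble(term = names(x$terms), value = unname(x$terms),
                 weight = unname(x$weights[names(x$terms)]),
                 contribution = unname(sgn * x$weights[names(x$terms)] * x$terms))
}

# --- binding ---------------------------------------------------------------

bind_measurements <- function(protein, ligand, const = physics_constants()) {
  ip <- cs_interaction(protein); il <- cs_interaction(ligand)
  np <- nrow(protein); nl <- nrow(ligand)
  all_pts <- rbind(ip, il)
  sasa_cx <- sasa_fraction_points(all_pts, cutoff = const$nv_cutoff)
  list(
    np = np, nl = nl, aa_p = protein$aa, aa_l = ligand$aa,
    d_caca = pair_dist(cs_ca(protein), cs_ca(ligand)),
    d_cacb = pair_dist(cs_ca(protein), il),
    d_cbca = pair_dist(ip, cs_ca(ligand)),
    d_cbcb = pair_dist(ip, il),
    sasa_p = sasa_fraction_points(ip, cutoff = const$nv_cutoff),
    sasa_l = sasa_fraction_points(il, cutoff = const$nv_cutoff),
    sasa_cx_p = sasa_cx[seq_len(np)],
    sasa_cx_l = sasa_cx[np + seq_len(nl)]
  )
}

bind_terms_meas <- function(bm, sp_p, sp_l, const = physics_constants()) {
  lj <- function(d, eps, sig) {
    if (any(d == 0)) stop("coincident beads: zero inter-bead distance")
    x6 <- (sig / d)^6
    4 * sum(eps * (x6^2 - x6))
  }
  has_p <- bm$aa_p != "G"; has_l <- bm$aa_l != "G"
  blj <- lj(bm$d_caca, const$ca_epsilon, 2 * const$ca_radius)
  if (any(has_l)) {
    blj <- blj + lj(bm$d_cacb[, has_l, drop = FALSE],
                    sqrt(const$ca_epsilon * rep(sp_l$h[has_l], each = bm$np)),
                    rep(const$ca_radius + sp_l$r[has_l], each = bm$np))
  }
  if (any(has_p)) {
    blj <- blj + lj(bm$d_cbca[has_p, , drop = FALSE],
                    sqrt(const$ca_epsilon * sp_p$h[has_p]),
                    const$ca_radius + sp_p$r[has_p])
  }
  if (any(has_p) && any(has_l)) {
    dm <- bm$d_cbcb[has_p, has_l, drop = FALSE]
    blj <- blj + lj(dm, outer(sqrt(sp_p$h[has_p]), sqrt(sp_l$h[has_l])),
                    outer(sp_p$r[has_p], sp_l$r[has_l], "+"))
  }
  # ionic: buried charged cross-pairs, burial judged in the complex frame
  ip <- which(sp_p$charge != 0 & bm$sasa_cx_p < const$burial_sasa)
  il <- which(sp_l$charge != 0 & bm$sasa_cx_l < const$burial_sasa)
  bion <- 0
  if (length(ip) && length(il)) {
    qq <- outer(sp_p$charge[ip], sp_l$charge[il])
    bion <- const$c_c * sum(qq / (const$epsilon *
                                    bm$d_cbcb[ip, il, drop = FALSE]))
  }
  solv_of <- function(sp, sasa) sum(sp$h * sasa + sp$p * (1 - sasa))
  bdsolv <- solv_of(sp_p, bm$sasa_p) + solv_of(sp_l, bm$sasa_l) -
    (solv_of(sp_p, bm$sasa_cx_p) + solv_of(sp_l, bm$sasa_cx_l))
  c(blj = blj, bion = bion, bdsolv = bdsolv)
}

#' Physics-based binding score
#'
#' Scores a two-body complex with inter-molecular Lennard-Jones and
#' ionic terms plus the change in solvation on binding
#' (`bdsolv = V_solv(protein) + V_solv(ligand) - V_solv(complex)`,
#' entering the total with a negative weight so that burying
#' hydrophobic surface is favorable). Both structures must already be
#' positioned in the complex frame.
#'
#' @param protein,ligand `coarse_structure` objects in the complex frame.
#' @param weights Named weight vector over `blj`, `bion`, `bdsolv`.
#' @param const Physics constants.
#' @return A `physics_score` (terms `blj`, `bion`, `bdsolv`).
#' @export
score_bind_physics <- function(protein, ligand,
                               weights = default_weights("bind"),
                               const = physics_constants()) {
  weights <- validate_weights(weights, "bind")
  bm <- bind_measurements(protein, ligand, const)
  terms <- bind_terms_meas(bm, sequence_params(cs_sequence(protein)),
                           sequence_params(cs_sequence(ligand)), const)
  out <- list(terms = terms, weights = weights,
              total = sum(BIND_SIGNS * weights * terms))
  class(out) <- "physics_score"
  out
}
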
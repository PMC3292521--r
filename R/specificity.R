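# Specificity measures: how much better the native state scores than a
# distribution G of alternative states (Random-Energy-Model decoys or
# random sequences). Because the alternative-state score distributions
# are heavily skewed (steric clashes produce a long tail), location and
# dispersal are estimated robustly: location = median, dispersal =
# median minus first quartile (type-7 linear-interpolation quantiles).

#' Robust score distribution summary
#'
#' @param values Numeric scores of the alternative states.
#' @return Object of class `score_distribution`: list with `values`,
#'   `location` (median), `dispersal` (median - first quartile), `n`.
#' @export
score_distribution <- function(values) {
  values <- as.numeric(values)
  stopifnot(length(values) >= 2, all(is.finite(values)))
  q <- stats::quantile(values, c(0.25, 0.5), names = FALSE, type = 7)
  structure(list(values = values, location = q[2], dispersal = q[2] - q[1],
                 n = length(values)),
            class = "score_distribution")
}

#' @export
print.score_distribution <- function(x, ...) {
  cat("<score_distribution> n =", x$n, " location =", format(x$location),
      " dispersal =", format(x$dispersal), "\n")
  invisible(x)
}

#' Fold and binding specificity measures
#'
#' `z_fold()` is the robust Z-score of the native energy against the
#' alternative-state distribution, `(location(G) - g_nat) / dispersal(G)`
#' (higher = more specific; native well below the decoy median gives a
#' large positive Z). `s_gap()` is the un-normalized gap
#' `location(G) - g_nat`; with the dispersal frozen at its starting
#' value, `s_gap = dispersal * z_fold`. `z_bind()` is the same Z
#' computed against a distribution of random partner sequences.
#'
#' @param g_nat Native-state energy.
#' @param g A `score_distribution` (or numeric vector of alternative
#'   scores).
#' @return Numeric scalar.
#' @export
z_fold <- function(g_nat, g) {
  if (!inherits(g, "score_distribution")) g <- score_distribution(g)
  if (g$dispersal <= 0) stop("zero dispersal in alternative-state scores")
  (g$location - g_nat) / g$dispersal
}

#' @rdname z_fold
#' @export
s_gap <- function(g_nat, g) {
  if (!inherits(g, "score_distribution")) g <- score_distribution(g)
  g$location - g_nat
}

#' @rdname z_fold
#' @export
z_bind <- function(g_nat, g) z_fold(g_nat, g)

#' Metropolis acceptance rule
#'
#' Accepts an uphill move (positive objective change) with probability
#' 1 and a downhill move with probability `exp(delta / temperature)`.
#' Shared by the weight optimizer and the sequence sampler.
#'
#' @param delta Objective change (new minus old; the objective is
#'   maximized).
#' @param temperature Positive temperature.
#' @return Logical.
#' @export
metropolis_accept <- function(delta, temperature) {
  delta > 0 || stats::runif(1) < exp(delta / temperature)
}

# --- decoy generators ------------------------------------------------------

.perm_classes <- c("theta", "phi", "r13", "r14", "caca", "cacb", "cbcb", "sasa")

#' Random-Energy-Model geometry decoys
#'
#' Each decoy independently permutes every class of geometric
#' measurement consumed by the physics terms -- bend angles, backbone
#' torsions, the i,i+2 and i,i+3 Calpha distances, each bead-pair
#' distance class, and the per-residue exposure fractions -- while the
#' sequence is left unchanged. Scoring a decoy therefore evaluates the
#' printed term formulas on shuffled measurements, in accordance with
#' the Random Energy Model. Cysteine-pair and charged-pair distances
#' are read from the shuffled Cbeta--Cbeta class.
#'
#' @param structure The native `coarse_structure` (permutation sizes
#'   are taken from it).
#' @param n Number of decoys.
#' @param seed RNG seed; decoys are reproducible given the seed.
#' @return Object of class `geometry_decoys`: list with `n`,
#'   `template` (residue count) and `perms` (per-decoy permutation
#'   index lists).
#' @export
make_geometry_decoys <- function(structure, n, seed = 1L) {
  stopifnot(n >= 1)
  nr <- nrow(structure)
  sizes <- list(theta = nr, phi = nr,
                r13 = max(nr - 2, 0), r14 = max(nr - 3, 0),
                caca = nr * (nr - 1) / 2, cacb = nr * (nr - 1),
                cbcb = nr * (nr - 1) / 2, sasa = nr)
  perms <- with_seed(seed, {
    lapply(seq_len(n), function(k) {
      lapply(sizes, function(s) if (s > 1) sample.int(s) else seq_len(max(s, 0)))
    })
  })
  structure(list(n = n, n_residues = nr, perms = perms, seed = seed),
            class = "geometry_decoys")
}

# permute the defined entries of v according to the full-length
# permutation perm, leaving undefined (NA) positions in place
.permute_defined <- function(v, perm) {
  idx <- which(!is.na(v))
  if (length(idx) > 1) v[idx] <- v[idx[order(perm[idx])]]
  v
}

# apply one permutation set to a measurement list
permute_measurements <- function(m, perm) {
  n <- m$n
  m$theta <- .permute_defined(m$theta, perm$theta)
  m$phi <- .permute_defined(m$phi, perm$phi)
  if (length(m$r13)) m$r13 <- m$r13[perm$r13]
  if (length(m$r14)) m$r14 <- m$r14[perm$r14]
  ut <- upper.tri(m$d_caca)
  v <- m$d_caca[ut][perm$caca]
  m$d_caca[ut] <- v
  m$d_caca[lower.tri(m$d_caca)] <- t(m$d_caca)[lower.tri(m$d_caca)]
  off <- which(!diag(n))
  m$d_cacb[off] <- m$d_cacb[off][perm$cacb]
  v <- m$d_cbcb[ut][perm$cbcb]
  m$d_cbcb[ut] <- v
  m$d_cbcb[lower.tri(m$d_cbcb)] <- t(m$d_cbcb)[lower.tri(m$d_cbcb)]
  m$sasa <- m$sasa[perm$sasa]
  m
}

#' Score a structure's sequence on its geometry decoys
#'
#' Evaluates the seven physics term values on each decoy's shuffled
#' measurements for the sequence carried by `structure` (which may be a
#' re-threaded structure on the native backbone).
#'
#' @param decoys A `geometry_decoys` object.
#' @param structure A `coarse_structure` with the same residue count as
#'   the decoy template.
#' @param const Physics constants.
#' @return Tibble with one row per decoy and one column per term.
#' @export
decoy_term_table <- function(decoys, structure, const = physics_constants()) {
  stopifnot(inherits(decoys, "geometry_decoys"),
            nrow(structure) == decoys$n_residues)
  m0 <- physics_measurements(structure, const)
  sp <- sequence_params(cs_sequence(structure))
  rows <- lapply(decoys$perms, function(p) {
    fold_terms_meas(permute_measurements(m0, p), sp, const)
  })
  dplyr::bind_rows(lapply(rows, function(r) tibble::as_tibble(as.list(r))))
}

#' Contact-map decoys for the informational model
#'
#' Each decoy keeps the native number of contacts but redraws the
#' contacting pairs uniformly among all pairs separated by more than
#' `min_sep` positions in sequence.
#'
#' @param cmap Native `contact_map` (intra-molecular).
#' @param n Number of decoys.
#' @param seed RNG seed.
#' @return Object of class `contact_decoys`: list of `contact_map`s.
#' @export
make_contact_decoys <- function(cmap, n, seed = 1L) {
  stopifnot(inherits(cmap, "contact_map"), !is.na(cmap$min_sep))
  nr <- cmap$n
  idx <- which(upper.tri(matrix(0, nr, nr)), arr.ind = TRUE)
  idx <- idx[idx[, 2] - idx[, 1] > cmap$min_sep, , drop = FALSE]
  n_contacts <- sum(cmap$contacts) / 2
  if (n_contacts > nrow(idx)) stop("more contacts than admissible pairs")
  maps <- with_seed(seed, {
    lapply(seq_len(n), function(k) {
      pick <- idx[sample.int(nrow(idx), n_contacts), , drop = FALSE]
      cm <- matrix(FALSE, nr, nr)
      cm[pick] <- TRUE
      cm <- cm | t(cm)
      structure(list(contacts = cm, cutoff = cmap$cutoff,
                     min_sep = cmap$min_sep, n = nr),
                class = "contact_map")
    })
  })
  structure(list(n = n, maps = maps, seed = seed), class = "contact_decoys")
}

#' Uniform random amino-acid sequences
#'
#' @param n_len Sequence length.
#' @param count Number of sequences.
#' @param seed RNG seed.
#' @return Character vector of `count` sequences, each drawn i.i.d.
#'   uniformly over the 20 amino acids.
#' @export
make_random_sequences <- function(n_len, count, seed = 1L) {
  with_seed(seed, {
    vapply(seq_len(count), function(k) {
      paste(sample(AA_ALPHABET, n_len, replace = TRUE), collapse = "")
    }, character(1))
  })
}
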
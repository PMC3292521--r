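# Side-chain replacement on a fixed backbone: thread an arbitrary
# sequence onto a conformation's Calpha trace. Each non-glycine Cbeta
# bead is placed at its tabulated bond length and equilibrium bend
# angle, and the remaining degree of freedom (the azimuth about the
# incoming backbone direction) is refined by Metropolis MCMC that
# minimizes the bead's Lennard-Jones energy against all other beads.
# Backbone coordinates are never adjusted.

#' Threading configuration
#'
#' @param n_steps MCMC sweeps over all residues (default 50).
#' @param temperature Metropolis acceptance temperature in LJ energy
#'   units (default 0.1).
#' @param proposal_sd Gaussian azimuth perturbation, radians
#'   (default 0.3).
#' @param seed RNG seed.
#' @return A list of class `threading_config`.
#' @export
threading_config <- function(n_steps = 50L, temperature = 0.1,
                             proposal_sd = 0.3, seed = 1L) {
  stopifnot(n_steps >= 1, temperature > 0, proposal_sd > 0)
  structure(list(n_steps = as.integer(n_steps), temperature = temperature,
                 proposal_sd = proposal_sd, seed = as.integer(seed)),
            class = "threading_config")
}

#' Thread a sequence onto a fixed backbone
#'
#' Returns a new `coarse_structure` with the conformation's exact
#' Calpha coordinates and rebuilt Cbeta beads for `sequence`. The
#' configuration visited during MCMC with the lowest total placed-bead
#' Lennard-Jones energy is returned, so the objective is monotone
#' non-increasing in the best-so-far sense and the result is
#' deterministic for a given seed.
#'
#' @param sequence Amino-acid string, same length as the conformation.
#' @param conformation A `coarse_structure` supplying the backbone.
#' @param config A [threading_config()].
#' @param params Residue parameter table.
#' @param const Physics constants.
#' @param context Optional `coarse_structure` whose beads are included
#'   as fixed obstacles in the Lennard-Jones objective (e.g. the other
#'   partner when placing side chains of a bound peptide).
#' @return A `coarse_structure` carrying `sequence`.
#' @export
thread <- function(sequence, conformation, config = threading_config(),
                   params = residue_params(), const = physics_constants(),
                   context = NULL) {
  aa <- strsplit(sequence, "")[[1]]
  n <- nrow(conformation)
  if (length(aa) != n) {
    stop("sequence length (", length(aa), ") does not match conformation (", n, ")")
  }
  sp <- params[match(aa, params$aa), ]
  if (anyNA(match(aa, params$aa))) stop("unknown residue letter in sequence")
  ca <- cs_ca(conformation)
  place <- which(aa != "G")

  # side-chain replacement: inherit each azimuth from the conformation's
  # own side-chain bead where one exists (bond length and bend angle are
  # reset to the new residue's table values), so refinement starts from
  # the replaced geometry
  cb_old <- cs_cb(conformation)
  az <- stats::setNames(rep(0, n), seq_len(n))
  for (i in place) {
    if (!is.na(cb_old[i, 1])) {
      az[i] <- cb_azimuth(ca, i, cb_old[i, ])
    }
  }
  cb <- matrix(NA_real_, n, 3)
  for (i in place) cb[i, ] <- cb_from_azimuth(ca, i, sp$b[i], sp$theta0[i], az[i])
  if (!length(place)) {
    return(coarse_structure(sequence, ca, cb, provenance = "threaded",
                            params = params))
  }

  ctx <- NULL
  if (!is.null(context)) {
    csp <- sequence_params(cs_sequence(context), params)
    has <- context$aa != "G"
    ctx <- list(
      pos = rbind(cs_ca(context), cs_cb(context)[has, , drop = FALSE]),
      eps = c(rep(const$ca_epsilon, nrow(context)), csp$h[has]),
      sig = c(rep(const$ca_radius, nrow(context)), csp$r[has])
    )
  }

  # LJ energy of side-chain bead i against all other beads
  eps_cb <- sp$h; sig_cb <- sp$r
  bead_energy <- function(i, pos, cb_now) {
    oca <- ca[-i, , drop = FALSE]
    d2_ca <- (oca[, 1] - pos[1])^2 + (oca[, 2] - pos[2])^2 + (oca[, 3] - pos[3])^2
    e <- sqrt(const$ca_epsilon * eps_cb[i])
    s <- const$ca_radius + sig_cb[i]
    x6 <- (s * s / d2_ca)^3
    tot <- 4 * sum(e * (x6^2 - x6))
    oth <- place[place != i]
    if (length(oth)) {
      ocb <- cb_now[oth, , drop = FALSE]
      d2 <- (ocb[, 1] - pos[1])^2 + (ocb[, 2] - pos[2])^2 + (ocb[, 3] - pos[3])^2
      s2 <- sig_cb[i] + sig_cb[oth]
      x6 <- (s2 * s2 / d2)^3
      tot <- tot + 4 * sum(sqrt(eps_cb[i] * eps_cb[oth]) * (x6^2 - x6))
    }
    if (!is.null(ctx)) {
      d2 <- (ctx$pos[, 1] - pos[1])^2 + (ctx$pos[, 2] - pos[2])^2 +
        (ctx$pos[, 3] - pos[3])^2
      s3 <- sig_cb[i] + ctx$sig
      x6 <- (s3 * s3 / d2)^3
      tot <- tot + 4 * sum(sqrt(eps_cb[i] * ctx$eps) * (x6^2 - x6))
    }
    tot
  }

  with_seed(config$seed, {
    # objective tracked relative to the initial placement: each accepted
    # move changes the total placed-bead LJ energy by exactly the change
    # in the moved bead's own energy
    e_cur <- 0
    best <- list(cb = cb, az = az, e = e_cur)
    for (sweep_k in seq_len(config$n_steps)) {
      order_k <- sample(place)
      for (i in order_k) {
        az_new <- az[i] + stats::rnorm(1, 0, config$proposal_sd)
        pos_new <- cb_from_azimuth(ca, i, sp$b[i], sp$theta0[i], az_new)
        de <- bead_energy(i, pos_new, cb) - bead_energy(i, cb[i, ], cb)
        if (de < 0 || stats::runif(1) < exp(-de / config$temperature)) {
          az[i] <- az_new
          cb[i, ] <- pos_new
          e_cur <- e_cur + de
          if (e_cur < best$e) best <- list(cb = cb, az = az, e = e_cur)
        }
      }
    }
    coarse_structure(sequence, ca, best$cb, provenance = "threaded",
                     params = params)
  })
}
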
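# Deterministic synthetic structures: ideal helices and sheets, random
# coils, a compact two-segment fold with a designed hydrophobic core,
# and a toy protein-peptide complex. These make every operation in the
# package testable without downloading real structures.

# place point D given A,B,C with |CD| = l, angle(B,C,D) = bend and
# dihedral(A,B,C,D) = tau (radians); NeRF construction
.place_next <- function(a, b, c, l, bend, tau) {
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-l * cos(bend), l * sin(bend) * cos(tau), -l * sin(bend) * sin(tau))
  c + cbind(bc, m, n) %*% d2
}

# Calpha trace from internal coordinates (virtual bond length l,
# virtual bend angles and torsions in radians, recycled)
.build_trace <- function(n, l = 3.8, bend = 2 * pi / 3, tau = 0) {
  bend <- rep_len(bend, n); tau <- rep_len(tau, n)
  ca <- matrix(0, n, 3)
  ca[2, ] <- c(l, 0, 0)
  if (n >= 3) ca[3, ] <- ca[2, ] + l * c(-cos(bend[3]), sin(bend[3]), 0)
  if (n >= 4) for (i in 4:n) {
    ca[i, ] <- .place_next(ca[i - 3, ], ca[i - 2, ], ca[i - 1, ],
                           l, bend[i], tau[i - 1])
  }
  ca
}

# Cbeta placement at template geometry: distance b from Calpha, bend
# angle theta0 against the incoming backbone direction, azimuth az
# about that direction. Shared with the threading module.
cb_from_azimuth <- function(ca, i, b, theta0, az) {
  n <- nrow(ca)
  prev <- if (i > 1) ca[i - 1, ] else 2 * ca[1, ] - ca[2, ]
  ex <- ca[i, ] - prev
  ex <- ex / sqrt(sum(ex^2))
  ref <- if (i < n) ca[i + 1, ] - ca[i, ] else ca[i, ] - prev
  u <- ref - sum(ref * ex) * ex
  if (sum(u^2) < 1e-8) {
    ref <- c(0, 0, 1)
    u <- ref - sum(ref * ex) * ex
    if (sum(u^2) < 1e-8) { ref <- c(0, 1, 0); u <- ref - sum(ref * ex) * ex }
  }
  u <- u / sqrt(sum(u^2))
  v <- c(ex[2] * u[3] - ex[3] * u[2],
         ex[3] * u[1] - ex[1] * u[3],
         ex[1] * u[2] - ex[2] * u[1])
  dir <- cos(theta0) * ex + sin(theta0) * (cos(az) * u + sin(az) * v)
  ca[i, ] + b * dir
}

# inverse of cb_from_azimuth: the azimuth of an existing side-chain bead
# in residue i's local frame
cb_azimuth <- function(ca, i, cb_pos) {
  n <- nrow(ca)
  prev <- if (i > 1) ca[i - 1, ] else 2 * ca[1, ] - ca[2, ]
  ex <- ca[i, ] - prev
  ex <- ex / sqrt(sum(ex^2))
  ref <- if (i < n) ca[i + 1, ] - ca[i, ] else ca[i, ] - prev
  u <- ref - sum(ref * ex) * ex
  if (sum(u^2) < 1e-8) {
    ref <- c(0, 0, 1)
    u <- ref - sum(ref * ex) * ex
    if (sum(u^2) < 1e-8) { ref <- c(0, 1, 0); u <- ref - sum(ref * ex) * ex }
  }
  u <- u / sqrt(sum(u^2))
  v <- c(ex[2] * u[3] - ex[3] * u[2],
         ex[3] * u[1] - ex[1] * u[3],
         ex[1] * u[2] - ex[2] * u[1])
  d <- cb_pos - ca[i, ]
  atan2(sum(d * v), sum(d * u))
}

.template_cb <- function(ca, aa, params, az = 0) {
  n <- nrow(ca)
  az <- rep_len(az, n)
  sp <- params[match(aa, params$aa), ]
  cb <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    if (aa[i] == "G") next
    cb[i, ] <- cb_from_azimuth(ca, i, sp$b[i], sp$theta0[i], az[i])
  }
  cb
}

.default_seq <- function(kind, n) {
  switch(kind,
    ideal_helix = paste(rep_len(c("A", "L", "E", "K", "M", "Q"), n), collapse = ""),
    ideal_sheet = paste(rep_len(c("V", "T", "I", "S", "F", "T"), n), collapse = ""),
    coil = paste(rep_len(c("G", "S", "N", "P", "D", "T"), n), collapse = ""),
    stop("no default sequence for kind ", kind)
  )
}

#' Generate synthetic coarse-grained structures
#'
#' Supported kinds: `"ideal_helix"` (Calpha beads on a helical curve
#' whose pitch and radius make both the i,i+2 and i,i+3 Calpha distances
#' equal the equilibrium helix distance of 5.5 A), `"ideal_sheet"`
#' (extended chain built with every backbone torsion at the equilibrium
#' beta value of 210 degrees), `"coil"` (seeded random torsions),
#' `"two_domain_fold"` (two packed strands joined by a loop, with
#' designed hydrophobic core positions facing a 8 A groove), and
#' `"toy_complex"` (the two-segment fold plus an 11-residue peptide
#' lying in its groove with a buried hydrophobic patch; returns a list
#' with elements `protein` and `ligand`).
#'
#' @param kind Fixture kind (see above).
#' @param n_residues Chain length (`>= 5`). For `toy_complex` this sets
#'   the protein length (default 45; at least 33 is needed for the fold
#'   to have a non-binding core groove); the ligand is always 11
#'   residues.
#' @param sequence Optional amino-acid string overriding the designed
#'   default for the kind.
#' @param seed RNG seed (used by `"coil"`; all other kinds are fully
#'   deterministic).
#' @param params Residue parameter table.
#' @return A `coarse_structure`, or `list(protein, ligand)` for
#'   `"toy_complex"`.
#' @export
#' @examples
#' hx <- make_fixture("ideal_helix", 12)
#' cx <- make_fixture("toy_complex")
make_fixture <- function(kind, n_residues = 20, sequence = NULL, seed = 1,
                         params = residue_params()) {
  if (!kind %in% c("ideal_helix", "ideal_sheet", "coil", "two_domain_fold",
                   "toy_complex")) {
    stop("unsupported fixture kind: ", kind)
  }
  if (kind == "toy_complex") {
    n_prot <- if (missing(n_residues)) 45L else n_residues
    return(.toy_complex(sequence, params, n_protein = n_prot))
  }
  if (kind == "two_domain_fold") return(.two_domain_fold(n_residues, sequence, params))
  n <- n_residues
  stopifnot(n >= 5)
  if (is.null(sequence)) sequence <- .default_seq(kind, n)
  aa <- strsplit(sequence, "")[[1]]
  stopifnot(length(aa) == n)

  if (kind == "ideal_helix") {
    # radius and rise solved so r(i,i+2) = r(i,i+3) = r_h = 5.5 A
    dt <- 100 * pi / 180
    R <- sqrt(5.5^2 / (4 * sin(dt)^2 + 4 * 4 * (sin(dt)^2 - sin(1.5 * dt)^2) / 5))
    d <- sqrt(4 * R^2 * (sin(dt)^2 - sin(1.5 * dt)^2) / 5)
    i <- seq_len(n)
    ca <- cbind(R * cos(i * dt), R * sin(i * dt), d * i)
    # Cbeta pointing radially outward from the helix axis
    cb <- matrix(NA_real_, n, 3)
    sp <- params[match(aa, params$aa), ]
    for (k in i) {
      if (aa[k] == "G") next
      dir <- c(cos(k * dt), sin(k * dt), 0)
      cb[k, ] <- ca[k, ] + sp$b[k] * dir
    }
    return(coarse_structure(sequence, ca, cb, provenance = "synthetic:ideal_helix",
                            params = params))
  }
  if (kind == "ideal_sheet") {
    ca <- .build_trace(n, l = 3.8, bend = 2 * pi / 3, tau = 210 * pi / 180)
    cb <- .template_cb(ca, aa, params)
    return(coarse_structure(sequence, ca, cb, provenance = "synthetic:ideal_sheet",
                            params = params))
  }
  # coil
  ca <- with_seed(seed, {
    .build_trace(n, l = 3.8,
                 bend = stats::runif(n, 90, 150) * pi / 180,
                 tau = stats::runif(n, -180, 180) * pi / 180)
  })
  cb <- .template_cb(ca, aa, params)
  coarse_structure(sequence, ca, cb, provenance = "synthetic:coil", params = params)
}

# serpentine sheet: antiparallel strands (Calpha spacing 3.8 A along x)
# stacked 8 A apart in y and joined by 3-residue loops. Within each
# strand the side-chain beads alternate between the groove above (+y)
# and the groove below (-y); beads facing an interior groove form the
# hydrophobic core, outward-facing and loop positions are polar.
.two_domain_fold <- function(n, sequence = NULL, params = residue_params()) {
  stopifnot(n >= 11)
  n_strands <- max(2L, (n + 3L) %/% 12L)
  in_strands <- n - 3L * (n_strands - 1L)
  strand_len <- rep(in_strands %/% n_strands, n_strands)
  extra <- in_strands - sum(strand_len)
  if (extra > 0) strand_len[seq_len(extra)] <- strand_len[seq_len(extra)] + 1L
  stopifnot(all(strand_len >= 3))

  ca <- matrix(0, n, 3)
  role <- character(n)     # "up", "down", "loop"
  strand_of <- integer(n)
  i <- 0L
  x <- 0
  for (s in seq_len(n_strands)) {
    dirx <- if (s %% 2 == 1) 1 else -1
    y <- 8 * (s - 1)
    for (j in seq_len(strand_len[s])) {
      i <- i + 1L
      # pleated strand: alternate z so backbone torsions are defined
      ca[i, ] <- c(x, y, 0.8 * (-1)^j)
      # parity flips on even strands so that beads aligned in x across a
      # groove face each other
      role[i] <- if ((j + s) %% 2 == 0) "up" else "down"
      strand_of[i] <- s
      if (j < strand_len[s]) x <- x + dirx * 3.3
    }
    if (s < n_strands) {
      ca[i + 1L, ] <- c(x + dirx * 3.0, y + 2.0, 0)
      ca[i + 2L, ] <- c(x + dirx * 4.5, y + 5.0, 0.5)
      ca[i + 3L, ] <- c(x + dirx * 3.0, y + 7.7, 0)
      role[i + 1:3] <- "loop"
      strand_of[i + 1:3] <- 0L
      i <- i + 3L
    }
  }

  # groove-facing = "up" below the top strand, or "down" above the bottom
  facing <- (role == "up" & strand_of < n_strands & strand_of > 0) |
    (role == "down" & strand_of > 1)
  if (is.null(sequence)) {
    core_cycle <- c("V", "I")
    out_cycle <- c("S", "E", "K", "T", "N", "Q")
    aa <- character(n)
    aa[role == "loop"] <- rep_len(c("G", "N", "G"), sum(role == "loop"))
    aa[facing] <- rep_len(core_cycle, sum(facing))
    rest <- !facing & role != "loop"
    aa[rest] <- rep_len(out_cycle, sum(rest))
    sequence <- paste(aa, collapse = "")
  }
  aa <- strsplit(sequence, "")[[1]]
  stopifnot(length(aa) == n)
  sp <- params[match(aa, params$aa), ]

  cb <- matrix(NA_real_, n, 3)
  for (ii in seq_len(n)) {
    if (aa[ii] == "G") next
    dir <- switch(role[ii],
                  up = c(0, 1, 0),
                  down = c(0, -1, 0),
                  loop = c(0, 0, -1))   # below the sheet plane, away from
                                        # the ligand groove

    cb[ii, ] <- ca[ii, ] + sp$b[ii] * dir
  }
  coarse_structure(sequence, ca, cb, provenance = "synthetic:two_domain_fold",
                   params = params)
}

# serpentine-sheet protein + 11-residue peptide lying above the first
# groove with its hydrophobic face buried
.toy_complex <- function(sequence = NULL, params = residue_params(),
                         n_protein = 45L) {
  protein <- .two_domain_fold(n_protein, params = params)
  nl <- 11L
  lig_seq <- sequence %||% "SLIVLIVLIVS"
  aa <- strsplit(lig_seq, "")[[1]]
  stopifnot(length(aa) == nl)
  sp <- params[match(aa, params$aa), ]
  ca <- cbind((seq_len(nl) - 1) * 3.2 - 2.0, 4.0,
              4.3 + 0.4 * (-1)^seq_len(nl))
  cb <- matrix(NA_real_, nl, 3)
  for (i in seq_len(nl)) {
    if (aa[i] == "G") next
    cb[i, ] <- ca[i, ] + sp$b[i] * c(0, 0, -1)   # face the groove
  }
  ligand <- coarse_structure(lig_seq, ca, cb, provenance = "synthetic:toy_peptide",
                             params = params)
  # the native peptide is shape-optimized in its groove, as a bound
  # peptide would be: refine its side-chain beads with the protein's
  # beads as fixed context
  ligand <- thread(lig_seq, ligand, threading_config(n_steps = 80, seed = 11L),
                   params = params, context = protein)
  attr(ligand, "provenance") <- "synthetic:toy_peptide"
  list(protein = protein, ligand = ligand)
}

#' Emit a minimal all-atom PDB rendering of a synthetic fixture
#'
#' Writes a syntactically valid single-chain PDB in which each residue
#' carries backbone N, CA, C atoms plus four side-chain pseudo-atoms
#' placed so that (i) the centroid of the side-chain atoms together with
#' the Calpha equals the fixture's Cbeta bead center exactly and (ii)
#' their radius of gyration about that centroid matches the tabulated
#' bead radius. Glycine rows carry backbone atoms only, so
#' [coarse_grain()] round-trips the fixture.
#'
#' @param structure A `coarse_structure` (e.g. from [make_fixture()]).
#' @param file Output path; if `NULL`, the PDB text is returned as a
#'   character vector instead.
#' @param chain Chain identifier to write.
#' @return The PDB lines, invisibly if written to `file`.
#' @export
make_all_atom_fixture <- function(structure, file = NULL, chain = "A") {
  ca <- cs_ca(structure); cb <- cs_cb(structure)
  aa <- structure$aa
  params <- residue_params()
  sp <- params[match(aa, params$aa), ]
  lines <- character(0)
  serial <- 0L
  emit <- function(name, res3, resno, xyz) {
    serial <<- serial + 1L
    sprintf("ATOM  %5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            serial, name, res3, chain, resno, xyz[1], xyz[2], xyz[3], 1, 0,
            substr(name, 1, 1))
  }
  for (i in seq_along(aa)) {
    res3 <- bio3d::aa123(aa[i])
    # nominal backbone neighbors (positions only need to be near CA)
    lines <- c(lines,
               emit("N", res3, i, ca[i, ] + c(-1.2, 0.4, 0)),
               emit("CA", res3, i, ca[i, ]),
               emit("C", res3, i, ca[i, ] + c(1.2, 0.4, 0)))
    if (aa[i] == "G") next
    b <- sp$b[i]; r <- sp$r[i]
    target <- cb[i, ]
    k <- 4
    cen <- target + (target - ca[i, ]) / k
    axis <- (target - ca[i, ]) / b
    e1 <- c(axis[2], -axis[1], 0)
    if (sum(e1^2) < 1e-8) e1 <- c(1, 0, 0)
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
            axis[3] * e1[1] - axis[1] * e1[3],
            axis[1] * e1[2] - axis[2] * e1[1])
    a <- sqrt(max(r^2 - (b / k)^2, 1e-6))
    for (j in seq_len(k)) {
      delta <- switch(j, a * e1, -a * e1, a * e2, -a * e2)
      lines <- c(lines, emit(c("CB", "CG", "CD", "CE")[j], res3, i, cen + delta))
    }
  }
  lines <- c(lines, "TER", "END")
  if (is.null(file)) return(lines)
  writeLines(lines, file)
  invisible(lines)
}

#' Evaluate code with a temporary RNG seed
#'
#' Saves and restores the global RNG state so seeded helpers do not
#' disturb the caller's random stream.
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
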
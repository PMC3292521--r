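# The two-bead coarse-grained representation: one backbone bead (Calpha,
# radius 1.8 A) and one side-chain bead (Cbeta) per residue. Glycine is
# represented by its Calpha bead alone. Derived geometry: theta_i is the
# angle Calpha(i-1)-Calpha(i)-Cbeta(i) (defined for i >= 2, non-Gly);
# phi_i is the torsion over Calpha(i-1..i+2) (defined for 2 <= i <= N-2).

#' Construct a coarse structure from bead coordinates
#'
#' Builds the package's central container: a tibble with one row per
#' residue (columns `resno`, `aa`, `ca_x/y/z`, `cb_x/y/z`, `radius`,
#' `theta`, `phi`) of class `coarse_structure`. Bend angles and backbone
#' torsions are (re)computed from the coordinates, so the object is
#' always internally consistent.
#'
#' @param sequence Amino-acid string (one-letter codes), length N.
#' @param ca N x 3 matrix of Calpha positions (Angstrom).
#' @param cb N x 3 matrix of Cbeta bead centers; rows for glycine are
#'   ignored and stored as `NA`.
#' @param radii Optional numeric vector of Cbeta radii; defaults to the
#'   packaged geometry table.
#' @param provenance Source tag (e.g. `"1ABC_A"` or `"synthetic"`).
#' @param params Residue parameter table.
#' @return A `coarse_structure` tibble.
#' @export
coarse_structure <- function(sequence, ca, cb = NULL, radii = NULL,
                             provenance = "synthetic",
                             params = residue_params()) {
  aa <- strsplit(sequence, "")[[1]]
  n <- length(aa)
  ca <- as.matrix(ca)
  stopifnot(nrow(ca) == n, ncol(ca) == 3, all(is.finite(ca)))
  sp <- params[match(aa, params$aa), , drop = FALSE]
  if (anyNA(match(aa, params$aa))) stop("unknown residue letter in sequence")

  if (is.null(cb)) cb <- matrix(NA_real_, n, 3) else cb <- as.matrix(cb)
  stopifnot(nrow(cb) == n, ncol(cb) == 3)
  cb[aa == "G", ] <- NA_real_
  if (any(!is.finite(cb[aa != "G", ]))) stop("non-finite Cbeta coordinates")
  if (is.null(radii)) radii <- sp$r

  theta <- rep(NA_real_, n)
  for (i in seq_len(n)[-1]) {
    if (aa[i] != "G") theta[i] <- vec_angle(ca[i - 1, ] - ca[i, ], cb[i, ] - ca[i, ])
  }
  phi <- rep(NA_real_, n)
  if (n >= 4) {
    for (i in 2:(n - 2)) {
      phi[i] <- vec_dihedral(ca[i - 1, ], ca[i, ], ca[i + 1, ], ca[i + 2, ])
    }
  }

  out <- tibble::tibble(
    resno = seq_len(n), aa = aa,
    ca_x = ca[, 1], ca_y = ca[, 2], ca_z = ca[, 3],
    cb_x = cb[, 1], cb_y = cb[, 2], cb_z = cb[, 3],
    radius = radii, theta = theta, phi = phi
  )
  attr(out, "provenance") <- provenance
  class(out) <- c("coarse_structure", class(out))
  out
}

#' @export
print.coarse_structure <- function(x, ...) {
  cat("<coarse_structure> ", nrow(x), " residues, provenance: ",
      attr(x, "provenance") %||% "?", "\n", sep = "")
  NextMethod()
}

# --- accessors -------------------------------------------------------------

#' Extract bead coordinates and sequence from a coarse structure
#'
#' `cs_ca()`/`cs_cb()` return N x 3 coordinate matrices (Cbeta rows are
#' `NA` for glycine); `cs_interaction()` returns the interaction centers
#' used for contacts and SASA (Cbeta, with Calpha substituted for
#' glycine); `cs_sequence()` the amino-acid string.
#'
#' @param x A `coarse_structure`.
#' @return Matrix or character scalar.
#' @export
cs_ca <- function(x) unname(as.matrix(x[, c("ca_x", "ca_y", "ca_z")]))

#' @rdname cs_ca
#' @export
cs_cb <- function(x) unname(as.matrix(x[, c("cb_x", "cb_y", "cb_z")]))

#' @rdname cs_ca
#' @export
cs_interaction <- function(x) {
  m <- cs_cb(x)
  g <- x$aa == "G"
  m[g, ] <- cs_ca(x)[g, ]
  m
}

#' @rdname cs_ca
#' @export
cs_sequence <- function(x) paste(x$aa, collapse = "")

# --- geometry helpers ------------------------------------------------------

vec_angle <- function(u, v) {
  acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2)))))
}

# torsion over points p1..p4, radians in (-pi, pi]
vec_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2))
}

pair_dist <- function(a, b = a) {
  # rows of a vs rows of b
  an <- rowSums(a^2); bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

#' Apply a rigid-body motion to a coarse structure
#'
#' @param x A `coarse_structure`.
#' @param rotation 3 x 3 rotation matrix.
#' @param translation Length-3 translation vector (Angstrom).
#' @return Transformed `coarse_structure`.
#' @export
transform_structure <- function(x, rotation = diag(3), translation = c(0, 0, 0)) {
  ca <- cs_ca(x) %*% t(rotation)
  cb <- cs_cb(x)
  ok <- !is.na(cb[, 1])
  cb[ok, ] <- cb[ok, , drop = FALSE] %*% t(rotation)
  ca <- sweep(ca, 2, translation, "+")
  cb[ok, ] <- sweep(cb[ok, , drop = FALSE], 2, translation, "+")
  coarse_structure(cs_sequence(x), ca, cb, radii = x$radius,
                   provenance = attr(x, "provenance"))
}

# --- PDB ingestion ---------------------------------------------------------

.BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")
.RES_MAP <- c(MSE = "MET", SEP = "SER", TPO = "THR", PTR = "TYR")

#' Coarse-grain an all-atom PDB structure
#'
#' Reduces one chain of an all-atom structure to the two-bead model: the
#' Calpha bead sits on the Calpha atom (radius 1.8 A); the Cbeta bead
#' center is the geometric centroid of the side-chain heavy atoms
#' together with the Calpha atom, with a residue-dependent radius from
#' the packaged geometry table. Glycine gets no Cbeta bead. The first
#' model is used, alternate locations restricted to '' / 'A'. A
#' Calpha--Calpha step longer than 4.5 A is recorded as a chain break in
#' the provenance tag (with a warning).
#'
#' @param pdb Path to a PDB file, or a `bio3d` `pdb` object.
#' @param chain Chain identifier; default: the first chain present.
#' @param params Residue parameter table.
#' @return A `coarse_structure`.
#' @export
coarse_grain <- function(pdb, chain = NULL, params = residue_params()) {
  src <- if (is.character(pdb)) sub("\\.pdb$", "", basename(pdb)) else "pdb"
  if (is.character(pdb)) pdb <- bio3d::read.pdb(pdb, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM" | at$resid %in% names(.RES_MAP), , drop = FALSE]
  at <- at[is.na(at$alt) | at$alt %in% c("", "A"), , drop = FALSE]
  if (is.null(chain)) chain <- at$chain[1]
  at <- at[at$chain == chain, , drop = FALSE]
  if (!nrow(at)) stop("no atoms found for chain ", chain)
  at$resid <- ifelse(at$resid %in% names(.RES_MAP), .RES_MAP[at$resid], at$resid)
  at <- at[!grepl("^[0-9]*H", at$elety), , drop = FALSE]  # drop hydrogens

  key <- paste(at$resno, at$insert, sep = "_")
  res_keys <- unique(key)
  n <- length(res_keys)
  aa <- character(n); ca <- matrix(NA_real_, n, 3); cb <- matrix(NA_real_, n, 3)
  notes <- character(0)
  for (k in seq_len(n)) {
    rows <- at[key == res_keys[k], , drop = FALSE]
    a1 <- bio3d::aa321(rows$resid[1])
    if (is.na(a1) | a1 == "X") stop("nonstandard residue ", rows$resid[1], " at index ", k)
    aa[k] <- a1
    ca_row <- rows[rows$elety == "CA", , drop = FALSE]
    if (!nrow(ca_row)) stop("missing Calpha atom at residue index ", k)
    ca[k, ] <- as.numeric(ca_row[1, c("x", "y", "z")])
    if (a1 != "G") {
      sc <- rows[!(rows$elety %in% .BACKBONE_ATOMS), , drop = FALSE]
      pts <- rbind(as.matrix(sc[, c("x", "y", "z")]), ca[k, ])
      if (nrow(sc) == 0) notes <- c(notes, paste0("no side-chain atoms at ", k))
      cb[k, ] <- colMeans(pts)
    }
  }
  steps <- sqrt(rowSums((ca[-1, , drop = FALSE] - ca[-n, , drop = FALSE])^2))
  if (any(steps > 4.5)) {
    notes <- c(notes, paste0("chain break after residue ",
                             paste(which(steps > 4.5), collapse = ",")))
    warning("chain break(s) detected: Calpha-Calpha step > 4.5 A")
  }
  prov <- paste0(src, "_", chain)
  if (length(notes)) prov <- paste(c(prov, notes), collapse = "; ")
  coarse_structure(paste(aa, collapse = ""), ca, cb, provenance = prov,
                   params = params)
}

# --- tabular round trip ----------------------------------------------------

#' Read and write the tabular coarse-structure format
#'
#' One row per residue: `resno`, `aa`, Calpha xyz, Cbeta xyz, `radius`,
#' tab-separated with a header. The round trip is lossless up to
#' numerical print precision (15 significant digits are written).
#'
#' @param x A `coarse_structure`.
#' @param file Path.
#' @return `read_coarse()` returns a `coarse_structure`;
#'   `write_coarse()` returns `file` invisibly.
#' @export
write_coarse <- function(x, file) {
  df <- as.data.frame(x[, c("resno", "aa", "ca_x", "ca_y", "ca_z",
                            "cb_x", "cb_y", "cb_z", "radius")])
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.15g", v))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste0("# provenance: ", attr(x, "provenance") %||% "unknown"), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_coarse
#' @export
read_coarse <- function(file) {
  first <- readLines(file, n = 1)
  prov <- if (startsWith(first, "# provenance:")) trimws(sub("# provenance:", "", first)) else "unknown"
  df <- utils::read.table(file, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE, strip.white = TRUE,
                          colClasses = c("integer", "character",
                                         rep("numeric", 7)))
  coarse_structure(paste(df$aa, collapse = ""),
                   ca = as.matrix(df[, c("ca_x", "ca_y", "ca_z")]),
                   cb = as.matrix(df[, c("cb_x", "cb_y", "cb_z")]),
                   radii = df$radius, provenance = prov)
}

# --- solvent exposure ------------------------------------------------------

#' Per-residue solvent exposure by the neighbor-vector method
#'
#' Approximates the fraction of solvent-accessible surface area from
#' bead geometry alone: for each residue the unit vectors from its
#' interaction center (Cbeta; Calpha for glycine) to all neighbor
#' centers within `cutoff` are summed with distance weights
#' `1 - d/cutoff`; the norm of the weighted mean vector is close to 1
#' when all neighbors lie to one side (exposed) and close to 0 when the
#' residue is surrounded isotropically (buried). The norm is mapped
#' linearly from `[map_lo, map_hi]` onto the exposure fraction `[0, 1]`
#' (clamped).
#'
#' @param structure A `coarse_structure`.
#' @param cutoff Neighbor sphere radius, Angstrom (default 10).
#' @param map_lo,map_hi Norm values mapped to fraction 0 and 1.
#' @return Numeric vector of exposure fractions in `[0, 1]`. A residue
#'   with no neighbors inside the cutoff gets 1.0 (with a warning).
#' @export
sasa_fraction <- function(structure, cutoff = physics_constants()$nv_cutoff,
                          map_lo = 0, map_hi = 1) {
  pts <- cs_interaction(structure)
  sasa_fraction_points(pts, cutoff = cutoff, map_lo = map_lo, map_hi = map_hi)
}

# core computation on an m x 3 matrix of interaction centers; exposure is
# evaluated for rows 'focal' against all other rows
sasa_fraction_points <- function(pts, focal = seq_len(nrow(pts)),
                                 cutoff = 10, map_lo = 0, map_hi = 1) {
  n <- nrow(pts)
  if (n < 1) stop("need at least one residue")
  d <- pair_dist(pts)
  out <- numeric(length(focal))
  isolated <- FALSE
  for (ii in seq_along(focal)) {
    i <- focal[ii]
    nb <- which(d[i, ] < cutoff & seq_len(n) != i)
    if (!length(nb)) { out[ii] <- 1; isolated <- TRUE; next }
    w <- 1 - d[i, nb] / cutoff
    u <- sweep(pts[nb, , drop = FALSE], 2, pts[i, ], "-") / d[i, nb]
    res <- colSums(u * w)
    m <- sqrt(sum(res^2)) / sum(w)
    out[ii] <- max(0, min(1, (m - map_lo) / (map_hi - map_lo)))
  }
  if (isolated) warning("isolated bead(s): no neighbors within cutoff, exposure set to 1")
  out
}

# --- contact maps ----------------------------------------------------------

#' Residue-residue contact maps
#'
#' A contact joins two residues whose Cbeta beads (Calpha substituted
#' for glycine) are closer than `cutoff` (center-to-center by default)
#' and that are separated by more than `min_sep` positions in primary
#' sequence. `inter_contact_map()` evaluates contacts between two
#' molecules (a rectangular map, no sequence-separation filter).
#'
#' @param structure,a,b `coarse_structure` objects.
#' @param cutoff Contact distance threshold, Angstrom (default 4.5).
#' @param min_sep Minimum primary-sequence separation (default 4:
#'   contacts require `|i - j| > 4`).
#' @param mode `"center"` (default) for center-to-center bead distance,
#'   `"surface"` for surface-to-surface (center distance minus radii).
#' @return An object of class `contact_map`: list with `contacts`
#'   (logical matrix), `cutoff`, `min_sep` (`NA` for inter-molecular
#'   maps), `n` (and `m` for rectangular maps).
#' @export
contact_map <- function(structure, cutoff = 4.5, min_sep = 4L, mode = "center") {
  pts <- cs_interaction(structure)
  d <- .contact_dist(pair_dist(pts), structure$radius, structure$radius, mode)
  n <- nrow(pts)
  sep <- abs(outer(seq_len(n), seq_len(n), "-"))
  contacts <- d < cutoff & sep > min_sep
  diag(contacts) <- FALSE
  structure(list(contacts = contacts, cutoff = cutoff, min_sep = min_sep, n = n),
            class = "contact_map")
}

#' @rdname contact_map
#' @export
inter_contact_map <- function(a, b, cutoff = 4.5, mode = "center") {
  d <- .contact_dist(pair_dist(cs_interaction(a), cs_interaction(b)),
                     a$radius, b$radius, mode)
  structure(list(contacts = d < cutoff, cutoff = cutoff, min_sep = NA,
                 n = nrow(a), m = nrow(b)),
            class = "contact_map")
}

.contact_dist <- function(d, ra, rb, mode) {
  if (mode == "surface") {
    ra[is.na(ra)] <- physics_constants()$ca_radius
    rb[is.na(rb)] <- physics_constants()$ca_radius
    d <- d - outer(ra, rb, "+")
  } else if (mode != "center") stop("mode must be 'center' or 'surface'")
  d
}

#' @export
print.contact_map <- function(x, ...) {
  cat("<contact_map> ", sum(x$contacts) / (if (is.na(x$min_sep)) 1 else 2),
      " contacts, cutoff ", x$cutoff, " A\n", sep = "")
  invisible(x)
}

#' Tidy a contact map into a pair table
#' @param x A `contact_map`.
#' @param ... Unused.
#' @return Tibble with columns `i`, `j` (one row per contact; `i < j`
#'   for intra-molecular maps).
#' @export
tidy.contact_map <- function(x, ...) {
  idx <- which(x$contacts, arr.ind = TRUE)
  out <- tibble::tibble(i = idx[, 1], j = idx[, 2])
  if (!is.na(x$min_sep)) out <- dplyr::filter(out, .data$i < .data$j)
  dplyr::arrange(out, .data$i, .data$j)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
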
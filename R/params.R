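# Residue-level parameter tables for the two-bead model.
#
# Each scale ships as its own whitespace-separated text file under
# inst/extdata/params/ and is assembled into one master tibble by
# residue_params(). All tables are overridable by path so users can swap
# in alternative scales without touching package code.

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

.twobead <- new.env(parent = emptyenv())

.param_file <- function(name, path = NULL) {
  if (!is.null(path)) return(path)
  system.file("extdata", "params", name, package = "twobead", mustWork = TRUE)
}

.read_scale <- function(file) {
  df <- utils::read.table(file, header = TRUE, stringsAsFactors = FALSE,
                          comment.char = "#")
  stopifnot(all(AA_ALPHABET %in% df$aa))
  df[match(AA_ALPHABET, df$aa), , drop = FALSE]
}

#' Residue parameter table for the two-bead model
#'
#' Assembles the per-residue parameters used throughout the package: bead
#' geometry (Calpha--Cbeta bond length `b`, Cbeta radius `r`, equilibrium
#' bend angle `theta0` in radians), the hydropathy-derived interaction
#' parameter `h` (Kyte--Doolittle values shifted so the scale is
#' non-negative; `h` doubles as the like-pair Lennard-Jones well depth),
#' the polarity index `p = (h_max - h_min) - h`, integer side-chain
#' charge `charge` (Asp/Glu -1, Lys/Arg +1, His neutral), and the helix
#' and beta propensity force constants `helix_prop` and `beta_prop`
#' (energy units; the beta scale is affinely rescaled onto the numeric
#' range of the helix scale, see the methods vignette).
#'
#' Glycine carries no Cbeta bead, so its `b` and `r` are `NA`.
#'
#' @param geometry,hydropathy,helix,beta Optional paths to replacement
#'   scale files (same column layout as the packaged defaults).
#' @return A tibble with one row per amino acid (20 rows), keyed by
#'   one-letter code in column `aa`.
#' @export
#' @examples
#' residue_params()
residue_params <- function(geometry = NULL, hydropathy = NULL,
                           helix = NULL, beta = NULL) {
  cache_ok <- is.null(geometry) && is.null(hydropathy) &&
    is.null(helix) && is.null(beta)
  if (cache_ok && !is.null(.twobead$params)) return(.twobead$params)

  geo <- .read_scale(.param_file("bead_geometry.tsv", geometry))
  hyd <- .read_scale(.param_file("hydropathy.tsv", hydropathy))
  hel <- .read_scale(.param_file("helix_propensity.tsv", helix))
  bet <- .read_scale(.param_file("beta_propensity.tsv", beta))

  h <- hyd$kd - min(hyd$kd)                 # shift to non-negative
  span <- max(hyd$kd) - min(hyd$kd)         # h_max - h_min after shift
  charge <- ifelse(AA_ALPHABET %in% c("D", "E"), -1L,
                   ifelse(AA_ALPHABET %in% c("K", "R"), 1L, 0L))

  # beta scale rescaled onto the helix force-constant range
  hk <- max(hel$k) - hel$k + 0.05           # invert: strong formers pull hardest
  bres <- (bet$raw - min(bet$raw)) / (max(bet$raw) - min(bet$raw))
  bk <- bres * (max(hk) - min(hk)) + min(hk)

  out <- tibble::tibble(
    aa = AA_ALPHABET,
    b = geo$b,
    r = geo$r,
    theta0 = geo$theta0,
    h = h,
    p = span - h,
    charge = charge,
    helix_prop = hk,
    beta_prop = bk
  )
  if (cache_ok) .twobead$params <- out
  out
}

#' Physical constants of the physics-based scoring function
#'
#' Defaults: bend force constant `k_theta` = 10 kJ mol^-1 rad^-2;
#' equilibrium helix inter-bead distance `r_h` = 5.5 A; beta scaling
#' constant `c_b` = 0.01 with equilibrium torsion `phi_b` = 210 degrees;
#' Coulomb scaling `c_c` = 1000 with interior dielectric `epsilon` = 3.0
#' and burial threshold `burial_sasa` = 0.25; disulfide cutoff `r_ss` =
#' 4.5 A; Calpha bead radius `ca_radius` = 1.8 A and a single backbone
#' Lennard-Jones well depth `ca_epsilon`.
#'
#' @param ... Named overrides of any constant.
#' @return A named list of constants.
#' @export
physics_constants <- function(...) {
  const <- list(
    k_theta = 10.0,
    r_h = 5.5,
    c_b = 0.01,
    phi_b = 210,
    c_c = 1000,
    epsilon = 3.0,
    burial_sasa = 0.25,
    r_ss = 4.5,
    ca_radius = 1.8,
    ca_epsilon = 1.0,
    nv_cutoff = 10.0
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(const))
    if (length(bad)) stop("unknown physics constant(s): ", paste(bad, collapse = ", "))
    const[names(dots)] <- dots
    stopifnot(all(vapply(const, function(x) is.numeric(x) && x > 0, logical(1))))
  }
  const
}

#' Pairwise Lennard-Jones well depth
#'
#' Like pairs use the hydropathy parameter (`epsilon_ii = h_i`); unlike
#' pairs the geometric mean of the like-pair values. Calpha beads carry
#' a single backbone value.
#'
#' @param h_i,h_j Like-pair well depths of the two beads.
#' @return Numeric well depth.
#' @keywords internal
lj_epsilon <- function(h_i, h_j) sqrt(h_i * h_j)

#' Look up per-residue parameters for a sequence
#' @param sequence Character scalar of one-letter codes.
#' @param params Parameter table from [residue_params()].
#' @return Tibble with one row per residue.
#' @keywords internal
sequence_params <- function(sequence, params = residue_params()) {
  aa <- strsplit(sequence, "")[[1]]
  bad <- setdiff(unique(aa), AA_ALPHABET)
  if (length(bad)) stop("unknown residue letter(s): ", paste(bad, collapse = ", "))
  params[match(aa, params$aa), , drop = FALSE]
}
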
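# Two-bead representation: ingestion, geometry, exposure, contacts.

make_rot <- function(seed) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]   # proper rotation only
  q
}

test_that("coarse graining an all-atom fixture recovers bead geometry", {
  fx <- make_fixture("two_domain_fold", 25)
  pdb_file <- withr::local_tempfile(fileext = ".pdb")
  make_all_atom_fixture(fx, pdb_file)
  cg <- coarse_grain(pdb_file)

  expect_equal(cs_sequence(cg), cs_sequence(fx))
  expect_lt(sqrt(mean((cs_ca(cg) - cs_ca(fx))^2)), 0.01)
  expect_lt(max(abs(cs_cb(cg) - cs_cb(fx)), na.rm = TRUE), 1e-6)
  # glycine carries no side-chain bead, Calpha radius is the backbone value
  gly <- which(cg$aa == "G")
  expect_true(length(gly) > 0)
  expect_true(all(is.na(cg$cb_x[gly])))
  expect_true(all(is.na(cs_cb(cg)[gly, ])))
})

test_that("Cbeta center is the centroid of side-chain atoms plus Calpha", {
  # hand-built single-residue PDB: alanine with 4 pseudo atoms placed
  # symmetrically about P, so centroid(P-atoms + CA) is computable by hand
  ca <- c(0, 0, 0)
  p <- c(2, 0, 0)
  offs <- rbind(c(0.5, 0, 0), c(-0.5, 0, 0), c(0, 0.5, 0), c(0, -0.5, 0))
  lines <- c(
    sprintf("ATOM  %5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            1, "CA", "ALA", "A", 1, ca[1], ca[2], ca[3], 1, 0, "C"),
    vapply(1:4, function(j) {
      xyz <- p + offs[j, ]
      sprintf("ATOM  %5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
              j + 1, c("CB", "CG", "CD", "CE")[j], "ALA", "A", 1,
              xyz[1], xyz[2], xyz[3], 1, 0, "C")
    }, character(1)),
    "END")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, f)
  cg <- coarse_grain(f)
  expected <- (4 * p + ca) / 5    # mean of the 4 atoms and the Calpha
  expect_equal(unname(cs_cb(cg)[1, ]), expected, tolerance = 1e-3)
})

test_that("bend angles and torsions are defined exactly where they should be", {
  fx <- make_fixture("coil", 5, sequence = "AAAAA", seed = 2)
  expect_true(is.na(fx$theta[1]))
  expect_true(all(!is.na(fx$theta[2:5])))
  expect_true(all(!is.na(fx$phi[2:3])))
  expect_true(all(is.na(fx$phi[c(1, 4, 5)])))
})

test_that("missing Calpha is reported with the residue index", {
  fx <- make_fixture("two_domain_fold", 12)
  f <- withr::local_tempfile(fileext = ".pdb")
  lines <- make_all_atom_fixture(fx)
  is_ca3 <- grepl("^ATOM", lines) & grepl(" CA ", lines) &
    suppressWarnings(as.integer(substr(lines, 23, 26))) == 3
  writeLines(lines[!is_ca3 | is.na(is_ca3)], f)
  expect_error(coarse_grain(f), "Calpha.*3")
})

test_that("geometry, exposure and contacts are rigid-motion invariant", {
  fx <- make_fixture("two_domain_fold", 21)
  rot <- make_rot(7)
  fx2 <- transform_structure(fx, rot, c(11.3, -5.2, 104.8))
  expect_equal(fx2$theta, fx$theta, tolerance = 1e-9)
  expect_equal(abs(fx2$phi), abs(fx$phi), tolerance = 1e-9)
  expect_equal(sasa_fraction(fx2), sasa_fraction(fx), tolerance = 1e-9)
  expect_identical(contact_map(fx2)$contacts, contact_map(fx)$contacts)
  d1 <- dist(cs_interaction(fx)); d2 <- dist(cs_interaction(fx2))
  expect_equal(as.vector(d2), as.vector(d1), tolerance = 1e-9)
})

test_that("exposure fractions behave at the geometric extremes", {
  # a single residue alone in space is fully exposed
  one <- coarse_structure("AA", rbind(c(0, 0, 0), c(100, 0, 0)),
                          rbind(c(1.5, 0, 0), c(101.5, 0, 0)))
  expect_warning(sa <- sasa_fraction(one), "isolated")
  expect_equal(sa, c(1, 1))

  # bead inside an isotropic cage of 30 neighbors is nearly buried
  set.seed(4)
  z <- matrix(rnorm(15 * 3), ncol = 3)
  z <- 6 * z / sqrt(rowSums(z^2))
  pts <- rbind(c(0, 0, 0), z, -z)
  frac <- twobead:::sasa_fraction_points(pts, focal = 1)
  expect_lt(frac, 0.1)

  # all neighbors in one half-space leave the bead exposed
  half <- rbind(c(0, 0, 0), cbind(runif(10, 2, 6), runif(10, -2, 2), runif(10, -2, 2)))
  frac_half <- twobead:::sasa_fraction_points(half, focal = 1)
  expect_gt(frac_half, 0.5)

  # adding a neighbor on the empty side never increases exposure
  more <- rbind(half, c(-4, 0, 0))
  expect_lte(twobead:::sasa_fraction_points(more, focal = 1), frac_half)
})

pair_dist_min <- function(s) min(dist(cs_interaction(s)))

test_that("contact maps apply the distance cutoff and sequence separation", {
  # two residues 4.4 A apart: contact iff separated by > 4 in sequence
  n <- 12
  ca <- cbind(seq_len(n) * 50, 0, 0)   # far apart by default
  cb <- ca + cbind(1.5, 0, 0)[rep(1, n), ]
  cb[1, ] <- c(0, 0, 0); cb[11, ] <- c(4.4, 0, 0)   # |i-j| = 10
  cb[2, ] <- c(1000, 0, 0); cb[6, ] <- c(1004.4, 0, 0)  # |i-j| = 4
  st <- coarse_structure(paste(rep("A", n), collapse = ""), ca, cb)
  cm <- contact_map(st)
  expect_true(cm$contacts[1, 11])
  expect_false(cm$contacts[2, 6])
  expect_false(any(diag(cm$contacts)))
  expect_identical(cm$contacts, t(cm$contacts))

  # fully extended chain: no contacts at all
  ext <- make_fixture("ideal_sheet", 15)
  expect_true(all(pair_dist_min(ext) > 0))
  expect_equal(sum(contact_map(ext, cutoff = 3)$contacts), 0)
})

test_that("contact_map equals a brute-force double loop", {
  for (seed in c(1, 2)) {
    st <- random_structure(10, seed)
    cm <- contact_map(st)
    pts <- cs_interaction(st)
    for (i in 1:10) {
      for (j in 1:10) {
        expected <- i != j && abs(i - j) > 4 &&
          sqrt(sum((pts[i, ] - pts[j, ])^2)) < 4.5
        expect_identical(cm$contacts[i, j], expected)
      }
    }
  }
})

test_that("inter-molecular maps have no separation filter and empty at distance", {
  cx <- make_fixture("toy_complex")
  icm <- inter_contact_map(cx$protein, cx$ligand)
  expect_gt(sum(icm$contacts), 0)
  far <- transform_structure(cx$ligand, diag(3), c(0, 0, 100))
  expect_equal(sum(inter_contact_map(cx$protein, far)$contacts), 0)

  # identical molecules superposed: map equals the intra distance test
  # without the separation rule, by brute force
  st <- random_structure(8, 3)
  icm2 <- inter_contact_map(st, st)
  pts <- cs_interaction(st)
  for (i in 1:8) {
    for (j in 1:8) {
      expect_identical(icm2$contacts[i, j],
                       sqrt(sum((pts[i, ] - pts[j, ])^2)) < 4.5)
    }
  }
})

test_that("tabular round trip is lossless", {
  fx <- make_fixture("toy_complex")$protein
  f <- withr::local_tempfile(fileext = ".tsv")
  write_coarse(fx, f)
  back <- read_coarse(f)
  expect_equal(cs_sequence(back), cs_sequence(fx))
  expect_equal(cs_ca(back), cs_ca(fx), tolerance = 1e-12)
  expect_equal(cs_cb(back), cs_cb(fx), tolerance = 1e-12)
  expect_equal(back$radius, fx$radius)
})

test_that("residue parameter table satisfies its invariants", {
  p <- residue_params()
  expect_equal(nrow(p), 20)
  expect_true(all(p$r[p$aa != "G"] > 0))
  expect_true(all(p$b[p$aa != "G"] > 0))
  expect_true(all(is.na(p$b[p$aa == "G"])))
  span <- max(p$h) - min(p$h)
  expect_equal(p$p, span - p$h)
  expect_identical(p$aa[p$charge == -1], c("D", "E"))
  expect_identical(sort(p$aa[p$charge == 1]), c("K", "R"))
  expect_equal(p$charge[p$aa == "H"], 0L)
})
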
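# Physics-based scoring terms against hand evaluations and brute-force
# oracles.

# structure with all bend angles at their equilibrium except one
bent_structure <- function(displace = 0) {
  n <- 6
  p <- residue_params()
  th0 <- p$theta0[p$aa == "A"]
  ca <- cbind((seq_len(n) - 1) * 3.8, 0, 0)
  cb <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    ang <- th0 + if (i == 3) displace else 0
    # theta_i is measured against the incoming backbone direction (-x)
    cb[i, ] <- ca[i, ] + 1.53 * c(-cos(ang), sin(ang), 0)
  }
  coarse_structure(paste(rep("A", n), collapse = ""), ca, cb)
}

test_that("bending term matches the printed double-sum", {
  expect_equal(v_bend(bent_structure(0)), 0, tolerance = 1e-10)
  # one interior angle displaced by 0.5 rad enters both half-sums:
  # 2 * (1/2) * 10 * 0.5^2 = 2.5
  expect_equal(v_bend(bent_structure(0.5)), 2.5, tolerance = 1e-8)
  # linear in the force constant
  expect_equal(v_bend(bent_structure(0.5), physics_constants(k_theta = 20)),
               5, tolerance = 1e-8)
})

test_that("Lennard-Jones term vanishes at sigma and is -eps at the minimum", {
  p <- residue_params()
  h_l <- p$h[p$aa == "L"]; r_l <- p$r[p$aa == "L"]
  sig <- 2 * r_l
  for (scale in c(1, 2^(1 / 6))) {
    d <- scale * sig
    x6 <- (sig / d)^6
    e_pair <- 4 * h_l * (x6^2 - x6)
    if (scale == 1) expect_equal(e_pair, 0, tolerance = 1e-12)
    else expect_equal(e_pair, -h_l, tolerance = 1e-12)
    # the same pair embedded in a 2-residue structure: total = cb-cb pair
    # plus the two ca-cb cross pairs (bonded ca-ca excluded), as by oracle
    ca <- rbind(c(0, 0, 0), c(300, 0, 0))
    cb <- rbind(c(100, 0, 0), c(100 + d, 0, 0))
    st <- coarse_structure("LL", ca, cb)
    expect_equal(v_lj(st), oracle_lj(st), tolerance = 1e-10)
  }
  # coincident beads are an error
  ca <- rbind(c(0, 0, 0), c(3.8, 0, 0))
  cb <- rbind(c(1, 1, 0), c(1, 1, 0))
  expect_error(v_lj(coarse_structure("LL", ca, cb)), "coincident")
})

test_that("helix term is zero at the equilibrium distances and scales with K", {
  hx <- make_fixture("ideal_helix", 12, sequence = strrep("A", 12))
  expect_lt(v_helix(hx), 1e-20)
  co <- make_fixture("coil", 12, sequence = strrep("A", 12), seed = 5)
  expect_gt(v_helix(co), v_helix(hx))

  # homopolymer: value proportional to the residue propensity
  p <- residue_params()
  for (aa in c("A", "T")) {
    co_aa <- make_fixture("coil", 12, sequence = strrep(aa, 12), seed = 5)
    k <- p$helix_prop[p$aa == aa]
    expect_equal(v_helix(co_aa) / k, v_helix(co) / p$helix_prop[p$aa == "A"],
                 tolerance = 1e-9)
  }
})

test_that("beta term uses circular angle arithmetic at 210 degrees", {
  sh <- make_fixture("ideal_sheet", 10)
  expect_equal(v_beta(sh), 0, tolerance = 1e-10)

  # a single torsion moved to 220 degrees in an all-Ala chain scores
  # K_Ala * 0.01 * 10^2
  chain_with_tau <- function(tau_deg) {
    ca <- twobead:::.build_trace(10, bend = 2 * pi / 3, tau = tau_deg * pi / 180)
    cb <- twobead:::.template_cb(ca, rep("A", 10), residue_params())
    coarse_structure(strrep("A", 10), ca, cb)
  }
  tau <- rep(210, 10)
  tau[6] <- 220   # torsion placing point 7: phi_5
  st <- chain_with_tau(tau)
  moved <- which(abs(twobead:::wrap_deg(st$phi * 180 / pi - 210)) > 1e-6)
  expect_length(moved, 1)
  k_ala <- residue_params()$beta_prop[residue_params()$aa == "A"]
  expect_equal(v_beta(st), k_ala * 0.01 * 100, tolerance = 1e-6)

  # wrapping: 210 + 360 is equivalent to 210
  expect_equal(v_beta(chain_with_tau(rep(210 + 360, 10))), 0, tolerance = 1e-8)
})

test_that("ionic term applies the burial filter literally", {
  ca <- rbind(c(0, 0, 0), c(300, 0, 0))
  cb <- rbind(c(2, 0, 0), c(12, 0, 0))   # Cbeta centers 10 A apart
  st <- coarse_structure("DK", ca, cb)
  expect_equal(suppressWarnings(v_ion(st, sasa = c(0.1, 0.2))),
               1000 * (-1) / (3 * 10), tolerance = 1e-10)
  expect_equal(suppressWarnings(v_ion(st, sasa = c(0.1, 0.3))), 0)
  st2 <- coarse_structure("ST", ca, cb)
  expect_equal(suppressWarnings(v_ion(st2, sasa = c(0, 0))), 0)
})

test_that("solvation term interpolates between hydropathy and polarity", {
  p <- residue_params()
  st <- coarse_structure("IN", rbind(c(0, 0, 0), c(3.8, 0, 0)),
                         rbind(c(0, 2.3, 0), c(3.8, 2.5, 0)))
  h_i <- p$h[p$aa == "I"]; p_n <- p$p[p$aa == "N"]
  expect_equal(v_solv(st, sasa = c(1, 0)), h_i + p_n, tolerance = 1e-12)
  # polarity is the reflected hydropathy
  expect_equal(p_n, (max(p$h) - min(p$h)) - p$h[p$aa == "N"])
})

test_that("disulfide term counts all cysteine pairs under 4.5 A", {
  mk <- function(d12, d13 = 1000, d23 = 1000) {
    ca <- rbind(c(0, -3, 0), c(d12, -3, 0), c(d13, -3 - d23, 0))
    cb <- rbind(c(0, 0, 0), c(d12, 0, 0), c(d13, -d23, 0))
    coarse_structure("CCC", ca, cb)
  }
  expect_equal(suppressWarnings(v_ss(mk(4.0))), -1)
  expect_equal(suppressWarnings(v_ss(mk(5.0))), 0)
  # three mutually close cysteines: all three pairs count
  ca <- rbind(c(0, -3, 0), c(3, -3, 0), c(1.5, -3, 2.6))
  cb <- rbind(c(0, 0, 0), c(3, 0, 0), c(1.5, 0, 2.6))
  st3 <- coarse_structure("CCC", ca, cb)
  expect_equal(v_ss(st3), -3)
})

test_that("every folding term matches its brute-force oracle on random structures", {
  for (seed in 1:6) {
    st <- random_structure(8 + seed %% 3, seed * 13)
    sasa <- sasa_fraction(st)
    expect_equal(v_bend(st), oracle_bend(st), tolerance = 1e-10)
    expect_equal(v_lj(st), oracle_lj(st), tolerance = 1e-10)
    expect_equal(v_helix(st), oracle_helix(st), tolerance = 1e-10)
    expect_equal(v_beta(st), oracle_beta(st), tolerance = 1e-10)
    expect_equal(v_ion(st, sasa), oracle_ion(st, sasa), tolerance = 1e-10)
    expect_equal(v_solv(st, sasa), oracle_solv(st, sasa), tolerance = 1e-10)
    expect_equal(v_ss(st), oracle_ss(st))
  }
})

test_that("the folding total is linear in the weights", {
  st <- make_fixture("two_domain_fold", 21)
  s1 <- score_fold_physics(st, default_weights("fold", 0.5))
  s2 <- score_fold_physics(st, default_weights("fold", 1.0))
  expect_equal(2 * s1$total, s2$total, tolerance = 1e-12)
  # term vector equals independent term calls
  expect_equal(unname(s1$terms["bend"]), v_bend(st))
  expect_equal(unname(s1$terms["lj"]), v_lj(st))
  expect_equal(unname(s1$terms["solv"]), v_solv(st))
  # zeroing one weight removes exactly that contribution
  w <- default_weights("fold", 0.5)
  w["beta"] <- 0
  s3 <- score_fold_physics(st, w)
  expect_equal(s3$total, s1$total - 0.5 * s1$terms[["beta"]], tolerance = 1e-10)
})

test_that("terms are invariant under rigid motion of the whole system", {
  st <- random_structure(9, 77)
  set.seed(8)
  rot <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(rot) < 0) rot[, 1] <- -rot[, 1]
  st2 <- transform_structure(st, rot, c(-31, 8, 12))
  f1 <- score_fold_physics(st)$terms
  f2 <- score_fold_physics(st2)$terms
  expect_equal(f1, f2, tolerance = 1e-8)
})

test_that("binding terms vanish for well-separated partners", {
  cx <- make_fixture("toy_complex")
  far <- transform_structure(cx$ligand, diag(3), c(0, 0, 500))
  bs <- score_bind_physics(cx$protein, far)
  expect_equal(unname(bs$terms), c(0, 0, 0), tolerance = 1e-6)
  expect_equal(bs$total, 0, tolerance = 1e-6)
})

test_that("inter-molecular ionic term follows the Coulomb form", {
  # an Asp on one molecule and an Arg on the other, each buried inside a
  # neutral cage, with Cbeta centers 8 A apart
  cage <- function(center, seed) {
    # antipodal pairs: the neighbor vectors cancel exactly
    set.seed(seed)
    z <- matrix(rnorm(24), ncol = 3)
    z <- 5 * z / sqrt(rowSums(z^2))
    sweep(rbind(z, -z), 2, center, "+")
  }
  mk <- function(aa1, cb1, cage_seed) {
    pts <- cage(cb1, cage_seed)
    ca <- rbind(cb1 + c(0, 2.5, 0), pts + 1.2)
    cb <- rbind(cb1, pts)
    coarse_structure(paste(c(aa1, rep("A", 16)), collapse = ""), ca, cb)
  }
  prot <- mk("D", c(0, 0, 0), 1)
  lig <- mk("R", c(8, 0, 0), 3)
  bm <- twobead:::bind_measurements(prot, lig)
  expect_lt(bm$sasa_cx_p[1], 0.25)
  expect_lt(bm$sasa_cx_l[1], 0.25)
  bs <- score_bind_physics(prot, lig)
  expect_equal(unname(bs$terms["bion"]), 1000 * (-1) / (3 * 8), tolerance = 1e-8)
})

test_that("burying a hydrophobic interface gives positive delta-solvation", {
  # two all-Leu half-shells with their open faces toward each other:
  # alone, each focal residue is exposed on one side; in the complex the
  # partner fills the empty half-space and buries it
  half_shell <- function(z_center, open_up) {
    sgn <- if (open_up) -1 else 1
    dirs <- rbind(c(0.7, 0, sgn * 0.71), c(-0.7, 0, sgn * 0.71),
                  c(0, 0.7, sgn * 0.71), c(0, -0.7, sgn * 0.71),
                  c(0.5, 0.5, sgn * 0.71), c(-0.5, -0.5, sgn * 0.71),
                  c(0.5, -0.5, sgn * 0.71), c(-0.5, 0.5, sgn * 0.71))
    dirs <- dirs / sqrt(rowSums(dirs^2))
    cb <- rbind(c(0, 0, z_center), sweep(5 * dirs, 2, c(0, 0, z_center), "+"))
    ca <- cb + 2.4
    coarse_structure(strrep("L", 9), ca, cb)
  }
  a <- half_shell(0, open_up = TRUE)
  b <- half_shell(6, open_up = FALSE)
  sasa_alone <- sasa_fraction(a)
  bm <- twobead:::bind_measurements(a, b)
  expect_lt(bm$sasa_cx_p[1], sasa_alone[1])   # the focal bead is buried
  bs <- score_bind_physics(a, b)
  expect_gt(unname(bs$terms["bdsolv"]), 0)
  # and the signed contribution to the total is favorable (negative)
  expect_lt(-bs$weights[["bdsolv"]] * bs$terms[["bdsolv"]], 0)
})
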
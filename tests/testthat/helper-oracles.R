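# Independent brute-force evaluations of the scoring formulas, written
# as naive loops straight from their printed definitions. These stay
# deliberately separate from the package implementations.

o_params <- function() residue_params()

o_lookup <- function(str) {
  p <- o_params()
  p[match(str$aa, p$aa), ]
}

oracle_bend <- function(str, K = 10) {
  th <- str$theta
  th0 <- o_lookup(str)$theta0
  n <- nrow(str)
  s <- 0
  for (i in 2:n) if (!is.na(th[i])) s <- s + 0.5 * K * (th[i] - th0[i])^2
  for (i in 1:(n - 1)) if (!is.na(th[i + 1])) s <- s + 0.5 * K * (th[i + 1] - th0[i])^2
  s
}

# flat list of beads: residue index, kind, position, eps, sigma
o_beads <- function(str, ca_eps = 1, ca_rad = 1.8) {
  sp <- o_lookup(str)
  ca <- cs_ca(str); cb <- cs_cb(str)
  beads <- list()
  for (i in seq_len(nrow(str))) {
    beads[[length(beads) + 1]] <- list(res = i, kind = "ca", pos = ca[i, ],
                                       eps = ca_eps, sig = ca_rad)
    if (str$aa[i] != "G") {
      beads[[length(beads) + 1]] <- list(res = i, kind = "cb", pos = cb[i, ],
                                         eps = sp$h[i], sig = sp$r[i])
    }
  }
  beads
}

oracle_lj <- function(str) {
  beads <- o_beads(str)
  tot <- 0
  for (a in seq_along(beads)) {
    for (b in seq_len(a - 1)) {
      ba <- beads[[a]]; bb <- beads[[b]]
      if (ba$res == bb$res) next
      if (ba$kind == "ca" && bb$kind == "ca" && abs(ba$res - bb$res) == 1) next
      r <- sqrt(sum((ba$pos - bb$pos)^2))
      eps <- sqrt(ba$eps * bb$eps)
      sig <- ba$sig + bb$sig
      tot <- tot + 4 * eps * ((sig / r)^12 - (sig / r)^6)
    }
  }
  tot
}

oracle_helix <- function(str, r_h = 5.5) {
  sp <- o_lookup(str)
  ca <- cs_ca(str)
  n <- nrow(str)
  if (n < 6) return(0)
  s <- 0
  for (i in 3:(n - 3)) {
    k13 <- mean(sp$helix_prop[i:(i + 2)])
    k14 <- mean(sp$helix_prop[i:(i + 3)])
    r13 <- sqrt(sum((ca[i, ] - ca[i + 2, ])^2))
    r14 <- sqrt(sum((ca[i, ] - ca[i + 3, ])^2))
    s <- s + 0.5 * k13 * (r13 - r_h)^2 + 0.5 * k14 * (r14 - r_h)^2
  }
  s
}

oracle_beta <- function(str, c_b = 0.01, phi_b = 210) {
  sp <- o_lookup(str)
  n <- nrow(str)
  s <- 0
  for (i in 2:(n - 2)) {
    if (is.na(str$phi[i])) next
    k <- mean(sp$beta_prop[(i - 1):(i + 2)])
    d <- str$phi[i] * 180 / pi - phi_b
    d <- d - 360 * round(d / 360)
    s <- s + k * c_b * d^2
  }
  s
}

oracle_ion <- function(str, sasa, c_c = 1000, dielec = 3, burial = 0.25) {
  sp <- o_lookup(str)
  pts <- cs_interaction(str)
  n <- nrow(str)
  s <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (sp$charge[i] == 0 || sp$charge[j] == 0) next
      if (sasa[i] >= burial || sasa[j] >= burial) next
      r <- sqrt(sum((pts[i, ] - pts[j, ])^2))
      s <- s + c_c * sp$charge[i] * sp$charge[j] / (dielec * r)
    }
  }
  s
}

oracle_solv <- function(str, sasa) {
  sp <- o_lookup(str)
  sum(sp$h * sasa + sp$p * (1 - sasa))
}

oracle_ss <- function(str, r_ss = 4.5) {
  pts <- cs_interaction(str)
  cys <- which(str$aa == "C")
  s <- 0
  if (length(cys) >= 2) {
    for (a in seq_along(cys)) {
      for (b in seq_len(a - 1)) {
        r <- sqrt(sum((pts[cys[a], ] - pts[cys[b], ])^2))
        if (r < r_ss) s <- s - 1
      }
    }
  }
  s
}

oracle_info_fold <- function(sequence, cmap, u) {
  aa <- strsplit(sequence, "")[[1]]
  s <- 0
  for (i in seq_len(cmap$n - 1)) {
    for (j in (i + 1):cmap$n) {
      if (cmap$contacts[i, j]) s <- s + u[aa[i], aa[j]]
    }
  }
  s
}

oracle_info_bind <- function(seq1, seq2, icm, u) {
  a1 <- strsplit(seq1, "")[[1]]; a2 <- strsplit(seq2, "")[[1]]
  s <- 0
  for (i in seq_along(a1)) {
    for (j in seq_along(a2)) {
      if (icm$contacts[i, j]) s <- s + u[a1[i], a2[j]]
    }
  }
  s
}

# random compact-ish structures for oracle comparisons (<= 10 residues)
random_structure <- function(n, seed, aa_pool = twobead:::AA_ALPHABET) {
  set.seed(seed)
  aa <- sample(aa_pool, n, replace = TRUE)
  repeat {
    ca <- matrix(0, n, 3)
    for (i in 2:n) {
      d <- stats::rnorm(3)
      ca[i, ] <- ca[i - 1, ] + 3.8 * d / sqrt(sum(d^2))
    }
    p <- o_params()
    sp <- p[match(aa, p$aa), ]
    cb <- matrix(NA_real_, n, 3)
    for (i in seq_len(n)) {
      if (aa[i] == "G") next
      d <- stats::rnorm(3)
      cb[i, ] <- ca[i, ] + sp$b[i] * d / sqrt(sum(d^2))
    }
    pts <- rbind(ca, cb[!is.na(cb[, 1]), , drop = FALSE])
    if (min(dist(pts)) > 0.5) break   # no near-coincident beads
  }
  coarse_structure(paste(aa, collapse = ""), ca, cb)
}

# exhaustive pathway-enumeration dN/dS oracle (independent recoding of
# the degeneracy-class bookkeeping)
o_gc <- function() Biostrings::GENETIC_CODE

o_degeneracy <- function(codon) {
  gc <- o_gc()
  sapply(1:3, function(p) {
    same <- 0
    for (b in c("A", "C", "G", "T")) {
      v <- codon
      substr(v, p, p) <- b
      if (gc[[v]] == gc[[codon]]) same <- same + 1
    }
    if (same == 4) 4 else if (same == 1) 0 else 2
  })
}

o_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in o_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}

oracle_pbl <- function(dna_a, dna_b) {
  gc <- o_gc()
  nc <- nchar(dna_a) / 3
  ts_map <- c(A = "G", G = "A", C = "T", T = "C")
  L <- S <- V <- c(`0` = 0, `2` = 0, `4` = 0)
  for (k in seq_len(nc)) {
    c1 <- substr(dna_a, 3 * k - 2, 3 * k)
    c2 <- substr(dna_b, 3 * k - 2, 3 * k)
    for (cod in c(c1, c2)) {
      dg <- o_degeneracy(cod)
      for (p in 1:3) L[as.character(dg[p])] <- L[as.character(dg[p])] + 0.5
    }
    if (c1 == c2) next
    diffs <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
    paths <- list()
    for (ord in o_perms(diffs)) {
      cur <- c1; steps <- list(); ok <- TRUE
      for (p in ord) {
        nxt <- cur
        substr(nxt, p, p) <- substr(c2, p, p)
        if (gc[[nxt]] == "*" && nxt != c2) { ok <- FALSE; break }
        steps[[length(steps) + 1]] <- c(cur, nxt, p)
        cur <- nxt
      }
      if (ok) paths[[length(paths) + 1]] <- steps
    }
    if (!length(paths)) next
    for (st_path in paths) {
      for (st in st_path) {
        p <- as.numeric(st[3])
        b1 <- substr(st[1], p, p); b2 <- substr(st[2], p, p)
        is_ts <- ts_map[[b1]] == b2
        for (cod in c(st[1], st[2])) {
          dd <- as.character(o_degeneracy(cod)[p])
          if (is_ts) S[dd] <- S[dd] + 0.5 / length(paths)
          else V[dd] <- V[dd] + 0.5 / length(paths)
        }
      }
    }
  }
  AB <- sapply(c("0", "2", "4"), function(i) {
    P <- S[[i]] / L[[i]]; Q <- V[[i]] / L[[i]]
    c(A = 0.5 * log(1 / (1 - 2 * P - Q)) - 0.25 * log(1 / (1 - 2 * Q)),
      B = 0.5 * log(1 / (1 - 2 * Q)))
  })
  ds <- (L[["2"]] * AB["A", "2"] + L[["4"]] * AB["A", "4"]) /
    (L[["2"]] + L[["4"]]) + AB["B", "4"]
  dn <- AB["A", "0"] + (L[["0"]] * AB["B", "0"] + L[["2"]] * AB["B", "2"]) /
    (L[["0"]] + L[["2"]])
  list(dn = dn, ds = ds)
}
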
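# Post-simulation analytics: structural site classes (core / surface /
# binding), the Pamilo-Bianchi-Li dN/dS estimator with Kimura
# two-parameter correction, hydrophobicity partitioning, and
# maximum-likelihood comparison of among-site rate-heterogeneity
# models on per-site substitution counts.

#' Classify residues as binding, core or surface
#'
#' Binding: any inter-molecular Cbeta--Cbeta (interaction center)
#' distance below `contact_cutoff` in the complex frame. Core:
#' non-binding residues whose exposure fraction (protein alone) is
#' below `burial`. Surface: the rest. Binding overrides surface and
#' core; the three labels partition all positions.
#'
#' @param protein,ligand `coarse_structure`s in the complex frame.
#' @param contact_cutoff Interface distance threshold, Angstrom.
#' @param burial Exposure fraction below which a residue is core.
#' @param const Physics constants (neighbor-vector cutoff).
#' @return Tibble of class `site_class_map` (`position`, `aa`, `class`,
#'   `sasa`), attribute `thresholds`.
#' @export
classify_sites <- function(protein, ligand, contact_cutoff = 4.5,
                           burial = physics_constants()$burial_sasa,
                           const = physics_constants()) {
  icm <- inter_contact_map(protein, ligand, cutoff = contact_cutoff)
  is_binding <- rowSums(icm$contacts) > 0
  sasa <- sasa_fraction(protein, cutoff = const$nv_cutoff)
  cls <- ifelse(is_binding, "binding",
                ifelse(sasa < burial, "core", "surface"))
  out <- tibble::tibble(position = seq_len(nrow(protein)), aa = protein$aa,
                        class = cls, sasa = sasa)
  attr(out, "thresholds") <- c(contact_cutoff = contact_cutoff, burial = burial)
  class(out) <- c("site_class_map", class(out))
  out
}

# --- PBL dN/dS -------------------------------------------------------------

.codon_table <- function() Biostrings::GENETIC_CODE

# degeneracy class (0, 2 or 4) of each position of a codon:
# 4 nucleotides synonymous -> 4-fold; only itself -> 0-fold; else 2-fold
.codon_degeneracy <- function(codon, gc = .codon_table()) {
  vapply(1:3, function(p) {
    variants <- vapply(DNA_ALPHABET, function(b) {
      v <- codon
      substr(v, p, p) <- b
      unname(gc[v])
    }, character(1))
    nsyn <- sum(variants == gc[codon])
    if (nsyn == 4) 4 else if (nsyn == 1) 0 else 2
  }, numeric(1))
}

# all minimal substitution pathways between two codons, as lists of
# (from, to, pos) steps; pathways through stop codons are dropped
.codon_pathways <- function(c1, c2, gc = .codon_table()) {
  diffs <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (!length(diffs)) return(list())
  orders <- if (length(diffs) == 1) list(diffs) else
    apply(.permutations(diffs), 1, as.numeric, simplify = FALSE)
  paths <- list()
  for (ord in orders) {
    cur <- c1
    steps <- list()
    ok <- TRUE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (gc[nxt] == "*" && nxt != c2) { ok <- FALSE; break }
      steps[[length(steps) + 1]] <- list(from = cur, to = nxt, pos = p)
      cur <- nxt
    }
    if (ok) paths[[length(paths) + 1]] <- steps
  }
  paths
}

.permutations <- function(v) {
  if (length(v) == 1) return(matrix(v, 1, 1))
  out <- NULL
  for (i in seq_along(v)) {
    rest <- .permutations(v[-i])
    out <- rbind(out, cbind(v[i], rest))
  }
  out
}

#' Pamilo-Bianchi-Li estimate of dN and dS
#'
#' Sites of each codon are classified as nondegenerate, twofold or
#' fourfold degenerate (threefold counted as twofold) and site totals
#' averaged over the two sequences. Transitional and transversional
#' differences are counted per degeneracy class by averaging over all
#' minimal substitution pathways between differing codons (pathways
#' through stop codons excluded; each step's site class is split
#' equally between its two flanking codons). Kimura two-parameter
#' corrections per class are combined into
#' `dS = (L2 A2 + L4 A4)/(L2 + L4) + B4` and
#' `dN = A0 + (L0 B0 + L2 B2)/(L0 + L2)`.
#'
#' @param dna_a,dna_b In-frame coding sequences of equal length.
#' @param site_mask Optional logical/integer mask selecting codons
#'   (e.g. a structural site class).
#' @return Tibble with one row: `dn`, `ds`, `ratio` (`NA` when dS is
#'   undefined or zero), `l0`, `l2`, `l4`.
#' @export
dnds_pbl <- function(dna_a, dna_b, site_mask = NULL) {
  if (nchar(dna_a) != nchar(dna_b)) stop("sequences must have equal length")
  if (nchar(dna_a) %% 3 != 0) stop("sequences must be in frame (length %% 3 == 0)")
  gc <- .codon_table()
  nc <- nchar(dna_a) / 3
  cod_a <- substring(dna_a, 3 * seq_len(nc) - 2, 3 * seq_len(nc))
  cod_b <- substring(dna_b, 3 * seq_len(nc) - 2, 3 * seq_len(nc))
  keep <- seq_len(nc)
  if (!is.null(site_mask)) keep <- keep[site_mask]
  L <- c(`0` = 0, `2` = 0, `4` = 0)
  S <- c(`0` = 0, `2` = 0, `4` = 0)   # transitions
  V <- c(`0` = 0, `2` = 0, `4` = 0)   # transversions
  for (k in keep) {
    da <- .codon_degeneracy(cod_a[k], gc)
    db <- .codon_degeneracy(cod_b[k], gc)
    for (p in 1:3) {
      L[as.character(da[p])] <- L[as.character(da[p])] + 0.5
      L[as.character(db[p])] <- L[as.character(db[p])] + 0.5
    }
    if (cod_a[k] == cod_b[k]) next
    paths <- .codon_pathways(cod_a[k], cod_b[k], gc)
    if (!length(paths)) next
    wpath <- 1 / length(paths)
    for (path in paths) {
      for (st in path) {
        b1 <- substr(st$from, st$pos, st$pos)
        b2 <- substr(st$to, st$pos, st$pos)
        is_ts <- .TRANSITION[[b1]] == b2
        d1 <- .codon_degeneracy(st$from, gc)[st$pos]
        d2 <- .codon_degeneracy(st$to, gc)[st$pos]
        for (dd in c(d1, d2)) {
          if (is_ts) S[as.character(dd)] <- S[as.character(dd)] + 0.5 * wpath
          else V[as.character(dd)] <- V[as.character(dd)] + 0.5 * wpath
        }
      }
    }
  }
  k2p <- function(i) {
    if (L[i] == 0) return(c(A = 0, B = 0))
    P <- S[i] / L[i]; Q <- V[i] / L[i]
    x <- 1 - 2 * P - Q; y <- 1 - 2 * Q
    if (x <= 0 || y <= 0) return(c(A = NaN, B = NaN))
    c(A = 0.5 * log(1 / x) - 0.25 * log(1 / y), B = 0.5 * log(1 / y))
  }
  ab <- vapply(c("0", "2", "4"), k2p, c(A = 0, B = 0))
  A <- ab["A", ]; B <- ab["B", ]
  ds <- if ((L["2"] + L["4"]) > 0)
    (L["2"] * A["2"] + L["4"] * A["4"]) / (L["2"] + L["4"]) + B["4"] else NaN
  dn <- if ((L["0"] + L["2"]) > 0)
    A["0"] + (L["0"] * B["0"] + L["2"] * B["2"]) / (L["0"] + L["2"]) else NaN
  ratio <- if (is.finite(ds) && ds > 0 && is.finite(dn)) dn / ds else NA_real_
  tibble::tibble(dn = unname(dn), ds = unname(ds), ratio = ratio,
                 l0 = unname(L["0"]), l2 = unname(L["2"]), l4 = unname(L["4"]))
}

#' dN/dS partitioned by structural site class
#'
#' @param dna_ref Reference (starting) coding DNA.
#' @param dna_obs Observed coding DNA (e.g. most common allele).
#' @param site_classes A `site_class_map` with one row per codon.
#' @return Tibble with one row per class plus an `all` row.
#' @export
dnds_by_site_class <- function(dna_ref, dna_obs, site_classes) {
  stopifnot(nrow(site_classes) == nchar(dna_ref) / 3)
  rows <- lapply(c("core", "surface", "binding"), function(cl) {
    mask <- site_classes$class == cl
    if (!any(mask)) {
      return(tibble::tibble(class = cl, dn = NA_real_, ds = NA_real_,
                            ratio = NA_real_, n_sites = 0L))
    }
    r <- dnds_pbl(dna_ref, dna_obs, mask)
    tibble::tibble(class = cl, dn = r$dn, ds = r$ds, ratio = r$ratio,
                   n_sites = sum(mask))
  })
  all_r <- dnds_pbl(dna_ref, dna_obs)
  dplyr::bind_rows(c(rows, list(
    tibble::tibble(class = "all", dn = all_r$dn, ds = all_r$ds,
                   ratio = all_r$ratio, n_sites = nrow(site_classes)))))
}

#' Hydrophobic fraction per structural class
#'
#' Percentage of residues in each site class belonging to the
#' hydrophobic set (default: the positive-hydropathy residues
#' A, V, L, I, M, F, W, C). An empty class yields `NA` percent.
#'
#' @param protein_seq Amino-acid string.
#' @param site_classes A `site_class_map`.
#' @param hydrophobic_set Character vector of hydrophobic residues.
#' @return Tibble (`class`, `n`, `n_hydrophobic`, `pct`).
#' @export
hydrophobic_fraction <- function(protein_seq, site_classes,
                                 hydrophobic_set = c("A", "V", "L", "I",
                                                     "M", "F", "W", "C")) {
  aa <- strsplit(protein_seq, "")[[1]]
  stopifnot(length(aa) == nrow(site_classes))
  tibble::tibble(aa = aa, class = site_classes$class) |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(n = dplyr::n(),
                     n_hydrophobic = sum(.data$aa %in% hydrophobic_set)) |>
    dplyr::right_join(tibble::tibble(class = c("core", "surface", "binding")),
                      by = "class") |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L),
                  n_hydrophobic = dplyr::coalesce(.data$n_hydrophobic, 0L),
                  pct = ifelse(.data$n > 0, 100 * .data$n_hydrophobic / .data$n,
                               NA_real_))
}

# --- rate heterogeneity ----------------------------------------------------

# mean-one discrete gamma category rates (quantile medians, normalized)
.discrete_gamma_rates <- function(alpha, k = 4) {
  r <- stats::qgamma((2 * seq_len(k) - 1) / (2 * k), shape = alpha, rate = alpha)
  r / mean(r)
}

#' Among-site rate heterogeneity from substitution counts
#'
#' Fits three models to per-site substitution counts (number of
#' replicate lineages differing from the reference at each position):
#' a single-rate Poisson, a discrete-gamma (4 equal-probability
#' categories, quantile-median rates normalized to mean one) Poisson
#' mixture, and a single rate plus an invariant-site class. Models are
#' compared by Akaike weights (AICc and BIC selectable); the gamma
#' shape and posterior-mean per-site rates are reported for the gamma
#' model. An alignment identical to the reference yields equal-rates
#' support 1 by convention (shape undefined).
#'
#' @param seqs Character vector of aligned sequences (e.g. most common
#'   alleles across replicates).
#' @param reference Reference sequence (defaults to the first of
#'   `seqs`, which is then excluded from counting).
#' @param counts Alternatively, a precomputed vector of per-site
#'   substitution counts (overrides `seqs`).
#' @param n_categories Discrete gamma categories (default 4).
#' @param criterion `"AIC"`, `"AICc"` or `"BIC"`.
#' @return Object of class `rate_report`: list with `table` (model
#'   comparison tibble), `alpha`, `p_invariant`, `site_rates`,
#'   `counts`.
#' @export
rate_heterogeneity <- function(seqs = NULL, reference = NULL, counts = NULL,
                               n_categories = 4, criterion = c("AIC", "AICc", "BIC")) {
  criterion <- match.arg(criterion)
  if (is.null(counts)) {
    if (is.null(seqs) || length(seqs) < 1) stop("need sequences or counts")
    if (is.null(reference)) {
      reference <- seqs[1]
      seqs <- seqs[-1]
    }
    if (!length(seqs)) stop("need at least one non-reference sequence")
    if (any(nchar(seqs) != nchar(reference))) stop("sequences must be aligned")
    ref <- strsplit(reference, "")[[1]]
    mat <- do.call(rbind, strsplit(seqs, ""))
    counts <- colSums(mat != matrix(ref, nrow(mat), length(ref), byrow = TRUE))
  }
  x <- as.numeric(counts)
  s <- length(x)
  n_obs <- s

  if (all(x == 0)) {
    tab <- tibble::tibble(model = c("equal_rates", "gamma", "invariant"),
                          k = c(1, 2, 2), log_lik = c(0, NA, NA),
                          aic = c(2, NA, NA), weight = c(1, 0, 0))
    out <- list(table = tab, alpha = NA_real_, p_invariant = NA_real_,
                site_rates = rep(NA_real_, s), counts = x,
                criterion = criterion)
    class(out) <- "rate_report"
    return(out)
  }

  ll_equal <- sum(stats::dpois(x, mean(x), log = TRUE))

  ll_gamma_fn <- function(par) {
    lam <- exp(par[1]); alpha <- exp(par[2])
    r <- .discrete_gamma_rates(alpha, n_categories)
    pm <- vapply(r, function(rk) stats::dpois(x, lam * rk), numeric(s))
    pm <- matrix(pm, nrow = s)
    -sum(log(rowMeans(pm) + 1e-300))
  }
  fit_g <- stats::optim(c(log(mean(x) + 0.01), 0), ll_gamma_fn, method = "Nelder-Mead")
  ll_gamma <- -fit_g$value
  alpha_hat <- exp(fit_g$par[2])

  ll_inv_fn <- function(par) {
    w <- stats::plogis(par[1]); lam <- exp(par[2])
    -sum(log(w * (x == 0) + (1 - w) * stats::dpois(x, lam) + 1e-300))
  }
  fit_i <- stats::optim(c(0, log(mean(x) + 0.01)), ll_inv_fn, method = "Nelder-Mead")
  ll_inv <- -fit_i$value
  p_inv <- stats::plogis(fit_i$par[1])

  k <- c(1, 2, 2)
  ll <- c(ll_equal, ll_gamma, ll_inv)
  ic <- switch(criterion,
               AIC = 2 * k - 2 * ll,
               AICc = 2 * k - 2 * ll + 2 * k * (k + 1) / pmax(n_obs - k - 1, 1),
               BIC = k * log(n_obs) - 2 * ll)
  w <- exp(-(ic - min(ic)) / 2)
  w <- w / sum(w)
  tab <- tibble::tibble(model = c("equal_rates", "gamma", "invariant"),
                        k = k, log_lik = ll, aic = ic, weight = w)

  r <- .discrete_gamma_rates(alpha_hat, n_categories)
  lam <- exp(fit_g$par[1])
  pm <- vapply(r, function(rk) stats::dpois(x, lam * rk), numeric(s))
  pm <- matrix(pm, nrow = s)
  site_rates <- as.vector((pm %*% r) / rowSums(pm))

  out <- list(table = tab, alpha = alpha_hat, p_invariant = p_inv,
              site_rates = site_rates, counts = x, criterion = criterion)
  class(out) <- "rate_report"
  out
}

#' @export
print.rate_report <- function(x, ...) {
  cat("<rate_report> (", x$criterion, " weights)\n", sep = "")
  print(x$table)
  cat("gamma shape =", format(x$alpha, digits = 4),
      "; invariant fraction =", format(x$p_invariant, digits = 4), "\n")
  invisible(x)
}

#' Tidy / summarize a rate-heterogeneity report
#'
#' `tidy()` returns the model-comparison table; `glance()` a one-row
#' summary with the Akaike weights ("support") and gamma shape.
#'
#' @param x A `rate_report`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.rate_report <- function(x, ...) x$table

#' @rdname tidy.rate_report
#' @export
glance.rate_report <- function(x, ...) {
  w <- stats::setNames(x$table$weight, x$table$model)
  tibble::tibble(equal_support = w[["equal_rates"]],
                 gamma_support = w[["gamma"]],
                 invariant_support = w[["invariant"]],
                 alpha = x$alpha, p_invariant = x$p_invariant)
}
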
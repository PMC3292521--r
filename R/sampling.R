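# Sequence-space exploration of the fold-score gap landscape: Metropolis
# sampling over single substitutions scored by S_gap, stable-optimum
# discovery with thinning, Sammon projection, and per-position
# information content of sampled sequence sets.

#' Build an S_gap scorer for a fixed native conformation
#'
#' Returns a function `f(sequence) -> S_gap` against a fixed set of
#' Random-Energy-Model decoys generated once from the native
#' conformation (100 by default) and held fixed, so scores are
#' comparable across sequences. For the physics model each candidate
#' sequence is threaded onto the backbone and the weighted seven-term
#' score is evaluated on the native and on each decoy's shuffled
#' measurements; for the informational model the native contact map and
#' fixed contact-shuffled decoy maps are rescored with the candidate
#' sequence. The dispersal of the decoy distribution is frozen at the
#' value observed for `start_seq` (attribute `dispersal`), so
#' `Z = S_gap / dispersal`.
#'
#' @param conformation Native `coarse_structure`.
#' @param model `"physics"` or `"info"`.
#' @param weights Folding weight vector (physics model).
#' @param u Contact matrix (informational model).
#' @param n_decoys Number of fixed decoys (default 100).
#' @param start_seq Sequence at which the dispersal is frozen
#'   (default: the conformation's own sequence).
#' @param seed Seed for decoy generation.
#' @param thread_config Threading configuration (physics model).
#' @param const Physics constants.
#' @return A function with attributes `dispersal`, `model`,
#'   `n_decoys`.
#' @export
gap_scorer <- function(conformation, model = c("physics", "info"),
                       weights = default_weights("fold"),
                       u = contact_matrix(), n_decoys = 100L,
                       start_seq = cs_sequence(conformation), seed = 1L,
                       thread_config = threading_config(),
                       const = physics_constants()) {
  model <- match.arg(model)
  if (model == "physics") {
    weights <- validate_weights(weights, "fold")
    decoys <- make_geometry_decoys(conformation, n_decoys, seed = seed)
    f <- function(sequence) {
      str_s <- if (sequence == cs_sequence(conformation)) conformation else
        thread(sequence, conformation, thread_config, const = const)
      sp <- sequence_params(sequence)
      g_nat <- sum(weights * fold_terms_meas(physics_measurements(str_s, const),
                                             sp, const))
      tab <- decoy_term_table(decoys, str_s, const)
      g <- as.vector(as.matrix(tab[, FOLD_TERMS]) %*% weights)
      stats::median(g) - g_nat
    }
  } else {
    cmap <- contact_map(conformation)
    dec <- make_contact_decoys(cmap, n_decoys, seed = seed)
    f <- function(sequence) {
      g_nat <- score_fold_info(sequence, cmap, u)
      g <- vapply(dec$maps, function(m) score_fold_info(sequence, m, u), numeric(1))
      stats::median(g) - g_nat
    }
  }
  # freeze the dispersal at the starting sequence
  disp <- local({
    if (model == "physics") {
      str_s <- if (start_seq == cs_sequence(conformation)) conformation else
        thread(start_seq, conformation, thread_config, const = const)
      tab <- decoy_term_table(make_geometry_decoys(conformation, n_decoys, seed = seed),
                              str_s, const)
      g <- as.vector(as.matrix(tab[, FOLD_TERMS]) %*% weights)
    } else {
      cmap <- contact_map(conformation)
      dec <- make_contact_decoys(cmap, n_decoys, seed = seed)
      g <- vapply(dec$maps, function(m) score_fold_info(start_seq, m, u), numeric(1))
    }
    q <- stats::quantile(g, c(0.25, 0.5), names = FALSE, type = 7)
    q[2] - q[1]
  })
  attr(f, "dispersal") <- disp
  attr(f, "model") <- model
  attr(f, "n_decoys") <- n_decoys
  f
}

#' Sampler configuration
#'
#' @param temperature Metropolis temperature on the S_gap scale.
#' @param n_steps Attempted substitutions.
#' @param max_divergence Maximum fraction of positions differing from
#'   the start sequence (`NULL` = unrestricted).
#' @param seed RNG seed.
#' @param alphabet Proposal alphabet (default: all 20 amino acids).
#' @return List of class `sampler_config`.
#' @export
sampler_config <- function(temperature = 10, n_steps = 1000L,
                           max_divergence = NULL, seed = 1L,
                           alphabet = AA_ALPHABET) {
  stopifnot(temperature > 0, n_steps >= 1)
  structure(list(temperature = temperature, n_steps = as.integer(n_steps),
                 max_divergence = max_divergence, seed = as.integer(seed),
                 alphabet = alphabet),
            class = "sampler_config")
}

#' Metropolis sampling of sequences on a fold-score landscape
#'
#' Runs a Markov chain over single-residue substitutions: a proposal is
#' accepted with probability 1 when its S_gap improves and
#' `exp((S_gap_new - S_gap_old)/T)` otherwise. Proposals whose Hamming
#' divergence from the start sequence exceeds `max_divergence` are
#' rejected outright (they count as attempted moves).
#'
#' @param start_seq Starting amino-acid sequence.
#' @param scorer Function `f(sequence) -> S_gap`, e.g. from
#'   [gap_scorer()].
#' @param config A [sampler_config()].
#' @param record `"unique"` (default) returns unique visited states in
#'   first-visit order; `"trace"` returns the chain's state after every
#'   attempted move (for occupancy statistics).
#' @return Tibble of unique visited states in first-visit order
#'   (`sequence`, `s_gap`, `first_step`), or the full trace, with
#'   attributes `acceptance_rate`, `n_attempted`, `final_sequence`.
#' @export
sample_sequences <- function(start_seq, scorer, config = sampler_config(),
                             record = c("unique", "trace")) {
  record <- match.arg(record)
  aa0 <- strsplit(start_seq, "")[[1]]
  n <- length(aa0)
  with_seed(config$seed, {
    cur <- aa0
    s_cur <- scorer(start_seq)
    seen <- new.env(parent = emptyenv())
    assign(start_seq, TRUE, envir = seen)
    recs <- list(list(sequence = start_seq, s_gap = s_cur, first_step = 0L))
    trace_seq <- if (record == "trace") character(config$n_steps) else NULL
    n_acc <- 0L
    for (k in seq_len(config$n_steps)) {
      pos <- sample.int(n, 1)
      alt <- setdiff(config$alphabet, cur[pos])
      letter <- alt[sample.int(length(alt), 1)]
      prop <- cur
      prop[pos] <- letter
      diverged <- !is.null(config$max_divergence) &&
        sum(prop != aa0) / n > config$max_divergence
      if (!diverged) {
        prop_seq <- paste(prop, collapse = "")
        s_new <- scorer(prop_seq)
        if (metropolis_accept(s_new - s_cur, config$temperature)) {
          cur <- prop
          s_cur <- s_new
          n_acc <- n_acc + 1L
          if (!exists(prop_seq, envir = seen, inherits = FALSE)) {
            assign(prop_seq, TRUE, envir = seen)
            recs[[length(recs) + 1]] <- list(sequence = prop_seq, s_gap = s_new,
                                             first_step = k)
          }
        }
      }
      if (record == "trace") trace_seq[k] <- paste(cur, collapse = "")
    }
    out <- if (record == "trace") {
      tibble::tibble(step = seq_len(config$n_steps), sequence = trace_seq)
    } else {
      dplyr::bind_rows(recs)
    }
    attr(out, "acceptance_rate") <- n_acc / config$n_steps
    attr(out, "n_attempted") <- config$n_steps
    attr(out, "final_sequence") <- paste(cur, collapse = "")
    out
  })
}

#' Discover stable optima of the fold-score landscape
#'
#' Runs replicate low-temperature chains without divergence
#' restrictions, thins each chain by keeping every fourth unique sample
#' and retaining the final `keep` of those, and pools the chains
#' (`n_chains * keep` sequences when chains are long enough; a chain
#' with fewer unique samples keeps what exists, with a warning).
#'
#' @param start_seq Starting sequence.
#' @param scorer S_gap scorer.
#' @param n_chains Number of replicate chains (default 10).
#' @param n_steps Attempted steps per chain.
#' @param temperature Chain temperature (low; e.g. 0.1 for the
#'   informational model, 1.5 for the physics model).
#' @param stride Thinning stride (default 4: every fourth unique
#'   sample).
#' @param keep Samples retained per chain after thinning (default 100).
#' @param seed Base seed; chain `i` uses `seed + i`.
#' @return Tibble (`chain`, `sequence`, `s_gap`).
#' @export
find_stable_optima <- function(start_seq, scorer, n_chains = 10L,
                               n_steps = 100000L, temperature = 0.1,
                               stride = 4L, keep = 100L, seed = 1L) {
  res <- purrr::map(seq_len(n_chains), function(ci) {
    smp <- sample_sequences(start_seq, scorer,
                            sampler_config(temperature = temperature,
                                           n_steps = n_steps,
                                           seed = seed + ci))
    thinned <- smp[seq(stride, nrow(smp), by = stride), , drop = FALSE]
    if (nrow(thinned) < keep) {
      warning("chain ", ci, ": only ", nrow(thinned),
              " thinned samples available (wanted ", keep, ")")
    }
    dplyr::mutate(utils::tail(thinned, keep), chain = ci, .before = 1)
  })
  dplyr::bind_rows(res)
}

#' Sammon projection of a sequence set
#'
#' Projects points with pairwise distances (Hamming distance for
#' sequences) onto two dimensions by Sammon's non-linear mapping
#' (iterative stress minimization, classical-scaling initialization).
#' Duplicate points are collapsed to one representative (with their
#' multiplicity recorded) before mapping, since Sammon stress is
#' undefined for zero distances.
#'
#' @param x Character vector of equal-length sequences, a numeric
#'   matrix of coordinates, or a `dist` object.
#' @param ... Passed to [MASS::sammon()] (e.g. `niter`, `tol`).
#' @return Tibble (`label`, `multiplicity`, `x`, `y`) with attribute
#'   `stress`.
#' @export
sammon_map <- function(x, ...) {
  if (is.character(x)) {
    labs <- x
    d <- hamming_distance(x)
  } else if (inherits(x, "dist")) {
    d <- x
    labs <- attr(x, "Labels") %||% as.character(seq_len(attr(x, "Size")))
  } else {
    labs <- rownames(x) %||% as.character(seq_len(nrow(x)))
    d <- stats::dist(x)
  }
  dm <- as.matrix(d)
  keep <- !vapply(seq_len(nrow(dm)), function(i) {
    i > 1 && any(dm[i, seq_len(i - 1)] == 0)
  }, logical(1))
  mult <- vapply(which(keep), function(i) sum(dm[i, ] == 0), numeric(1))
  if (any(!keep)) warning(sum(!keep), " duplicate point(s) collapsed before mapping")
  dm <- dm[keep, keep, drop = FALSE]
  if (nrow(dm) < 3) stop("need at least 3 distinct points")
  init <- stats::cmdscale(dm, k = 2)
  if (ncol(init) < 2) init <- cbind(init, 0)
  sm <- MASS::sammon(stats::as.dist(dm), y = init, trace = FALSE, ...)
  out <- tibble::tibble(label = labs[keep], multiplicity = mult,
                        x = sm$points[, 1], y = sm$points[, 2])
  attr(out, "stress") <- sm$stress
  out
}

#' Hamming distances among equal-length sequences
#' @param seqs Character vector.
#' @return A `dist` object (substitution counts).
#' @export
hamming_distance <- function(seqs) {
  mat <- do.call(rbind, strsplit(seqs, ""))
  n <- nrow(mat)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) d[i, j] <- d[j, i] <- sum(mat[i, ] != mat[j, ])
  }
  stats::as.dist(d)
}

#' Per-position information content of an aligned sequence set
#'
#' Shannon information in bits relative to a uniform 20-letter
#' background: `bits = log2(20) - H(position)`. Positions above
#' `threshold` bits are flagged; the consensus letter is the most
#' frequent (alphabetical tie-break).
#'
#' @param seqs Character vector of equal-length sequences.
#' @param threshold Bits above which a position is flagged (default 2).
#' @return Tibble of class `info_content` (`position`, `bits`,
#'   `consensus`, `flagged`).
#' @export
information_content <- function(seqs, threshold = 2) {
  if (!length(seqs)) stop("empty sequence set")
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1) stop("sequences must be aligned (equal length)")
  mat <- do.call(rbind, strsplit(seqs, ""))
  res <- purrr::map(seq_len(ncol(mat)), function(j) {
    tab <- table(mat[, j])
    p <- as.numeric(tab) / sum(tab)
    h <- -sum(p * log2(p))
    cons <- names(tab)[order(-as.numeric(tab), names(tab))][1]
    tibble::tibble(position = j, bits = log2(20) - h, consensus = cons)
  })
  out <- dplyr::bind_rows(res) |>
    dplyr::mutate(flagged = .data$bits > threshold)
  class(out) <- c("info_content", class(out))
  attr(out, "threshold") <- threshold
  out
}

#' Bar plot of per-position information content
#' @param object An `info_content` table.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.info_content <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$position, y = .data$bits,
                                       fill = .data$flagged)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = attr(object, "threshold"),
                        linetype = "dashed", color = "grey40") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey65", `TRUE` = "firebrick"),
                               guide = "none") +
    ggplot2::labs(y = "information (bits)") +
    ggplot2::theme_minimal()
}

#' Acceptance frequency of a sampling chain
#'
#' @param start_seq Starting sequence.
#' @param scorer S_gap scorer.
#' @param temperature Chain temperature.
#' @param n_steps Attempted moves.
#' @param seed RNG seed.
#' @return Fraction of attempted moves accepted.
#' @export
acceptance_frequency <- function(start_seq, scorer, temperature,
                                 n_steps = 1000L, seed = 1L) {
  smp <- sample_sequences(start_seq, scorer,
                          sampler_config(temperature = temperature,
                                         n_steps = n_steps, seed = seed))
  attr(smp, "acceptance_rate")
}

#' Calibrate a sampling temperature to a target acceptance frequency
#'
#' Finds the temperature at which one scoring model reproduces the
#' acceptance frequency observed under another model (e.g. matching the
#' physics-based sampler to an informational-model trace). A proposal
#' ensemble is first collected by running the chain with every proposal
#' accepted (near-unbiased sampling), recording the S_gap change
#' `delta` of each proposed substitution. The expected acceptance
#' frequency at temperature `T`,
#' `A(T) = mean(pmin(1, exp(delta / T)))`,
#' is strictly increasing in `T`, so a log-scale bisection solves
#' `A(T) = target` to within `tol`.
#'
#' @param start_seq Starting sequence.
#' @param scorer S_gap scorer whose temperature is being calibrated.
#' @param target Target acceptance frequency in (0, 1).
#' @param t_range Bracketing temperatures `c(lo, hi)`; widened
#'   automatically if the target lies outside the initial bracket.
#' @param tol Acceptance-frequency tolerance (default 0.02).
#' @param n_steps Proposals in the collection run.
#' @param seed RNG seed for the collection run.
#' @param max_iter Maximum bisection iterations.
#' @return List with `temperature`, `acceptance` (expected acceptance
#'   at that temperature), `iterations`, `deltas` (the collected
#'   proposal ensemble).
#' @export
calibrate_temperature <- function(start_seq, scorer, target,
                                  t_range = c(1e-3, 1e6), tol = 0.02,
                                  n_steps = 300L, seed = 1L, max_iter = 60L) {
  stopifnot(target > 0, target < 1, t_range[1] < t_range[2])
  deltas <- with_seed(seed, {
    aa <- strsplit(start_seq, "")[[1]]
    n <- length(aa)
    s_cur <- scorer(start_seq)
    out <- numeric(n_steps)
    for (k in seq_len(n_steps)) {
      pos <- sample.int(n, 1)
      alt <- setdiff(AA_ALPHABET, aa[pos])
      prop <- aa
      prop[pos] <- alt[sample.int(length(alt), 1)]
      s_new <- scorer(paste(prop, collapse = ""))
      out[k] <- s_new - s_cur
      aa <- prop            # accept everything: near-unbiased exploration
      s_cur <- s_new
    }
    out
  })
  a_of <- function(t) mean(pmin(1, exp(pmin(deltas, 0) / t)))
  lo <- t_range[1]; hi <- t_range[2]
  for (w in 1:20) {         # widen the bracket if needed
    if (a_of(lo) <= target || lo < 1e-12) break
    lo <- lo / 10
  }
  for (w in 1:20) {
    if (a_of(hi) >= target || hi > 1e15) break
    hi <- hi * 10
  }
  mid <- sqrt(lo * hi); a_mid <- a_of(mid)
  for (it in seq_len(max_iter)) {
    mid <- sqrt(lo * hi)    # bisection on the log scale
    a_mid <- a_of(mid)
    if (abs(a_mid - target) <= tol) break
    if (a_mid < target) lo <- mid else hi <- mid
  }
  list(temperature = mid, acceptance = a_mid, iterations = it,
       deltas = deltas)
}
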
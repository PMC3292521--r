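# Per-protein choice of term weights: build a cached table of raw term
# scores for the native state and its alternative states (shuffled
# geometry decoys G_struct and random sequences threaded onto the
# native backbone G_seq), rescale each term column to a common range,
# then run Metropolis-Hastings over the weight hypercube maximizing the
# robust Z of the native total against the union distribution. Because
# term scores are cached, each Z evaluation is a reweighting, not a
# rescoring.

#' Build the reference term-score table for weight optimization
#'
#' Rows: the native state, `n_struct` geometry decoys (the native
#' sequence on shuffled measurements) and `n_seq` random sequences
#' threaded onto the native conformation. Columns: the seven folding
#' terms plus bookkeeping (`state`, `id`).
#'
#' @param native A `coarse_structure` carrying the native sequence.
#' @param n_struct Number of geometry decoys (0 allowed).
#' @param n_seq Number of random threaded sequences (0 allowed).
#' @param seed RNG seed (decoys, random sequences and threading all
#'   derive from it).
#' @param thread_config Threading configuration for the random
#'   sequences.
#' @param const Physics constants.
#' @return Tibble of `n_struct + n_seq + 1` rows; attribute `terms`
#'   names the term columns.
#' @export
build_reference_scores <- function(native, n_struct = 1000, n_seq = 1000,
                                   seed = 1L,
                                   thread_config = threading_config(),
                                   const = physics_constants()) {
  sp <- sequence_params(cs_sequence(native))
  m0 <- physics_measurements(native, const)
  rows <- list(tibble::as_tibble(as.list(fold_terms_meas(m0, sp, const))) |>
                 dplyr::mutate(state = "native", id = 0L))
  if (n_struct > 0) {
    dec <- make_geometry_decoys(native, n_struct, seed = seed)
    rows <- c(rows, list(decoy_term_table(dec, native, const) |>
                           dplyr::mutate(state = "struct", id = dplyr::row_number())))
  }
  if (n_seq > 0) {
    seqs <- make_random_sequences(nrow(native), n_seq, seed = seed + 1L)
    seq_rows <- purrr::map2(seqs, seq_along(seqs), function(s, k) {
      cfg <- thread_config
      cfg$seed <- thread_config$seed + k
      str_k <- thread(s, native, cfg, const = const)
      m <- physics_measurements(str_k, const)
      tibble::as_tibble(as.list(fold_terms_meas(m, sequence_params(s), const))) |>
        dplyr::mutate(state = "seq", id = k)
    })
    rows <- c(rows, list(dplyr::bind_rows(seq_rows)))
  }
  out <- dplyr::bind_rows(rows) |>
    dplyr::select(dplyr::all_of(c("state", "id", FOLD_TERMS)))
  attr(out, "terms") <- FOLD_TERMS
  out
}

#' Reference table for binding-weight optimization
#'
#' Random sequences are threaded through the conformation of one
#' binding partner (`vary = "ligand"` by default, mirroring a peptide
#' ligand being randomized) while the other partner stays fixed in both
#' sequence and structure; each complex is scored with the three
#' binding terms.
#'
#' @param protein,ligand `coarse_structure`s in the complex frame.
#' @param n_seq Number of random partner sequences.
#' @param vary Which partner to randomize: `"ligand"` or `"protein"`.
#' @param seed RNG seed.
#' @param thread_config Threading configuration.
#' @param const Physics constants.
#' @return Tibble of `n_seq + 1` rows with columns `state`, `id`,
#'   `blj`, `bion`, `bdsolv`; attribute `terms`.
#' @export
build_reference_scores_bind <- function(protein, ligand, n_seq = 1000,
                                        vary = c("ligand", "protein"),
                                        seed = 1L,
                                        thread_config = threading_config(),
                                        const = physics_constants()) {
  vary <- match.arg(vary)
  score_terms <- function(p, l) {
    bind_terms_meas(bind_measurements(p, l, const),
                    sequence_params(cs_sequence(p)),
                    sequence_params(cs_sequence(l)), const)
  }
  rows <- list(tibble::as_tibble(as.list(score_terms(protein, ligand))) |>
                 dplyr::mutate(state = "native", id = 0L))
  template <- if (vary == "ligand") ligand else protein
  seqs <- make_random_sequences(nrow(template), n_seq, seed = seed)
  seq_rows <- purrr::map2(seqs, seq_along(seqs), function(s, k) {
    cfg <- thread_config
    cfg$seed <- thread_config$seed + k
    str_k <- thread(s, template, cfg, const = const)
    tv <- if (vary == "ligand") score_terms(protein, str_k) else score_terms(str_k, ligand)
    tibble::as_tibble(as.list(tv)) |> dplyr::mutate(state = "seq", id = k)
  })
  out <- dplyr::bind_rows(c(rows, seq_rows)) |>
    dplyr::select(dplyr::all_of(c("state", "id", BIND_TERMS)))
  attr(out, "terms") <- BIND_TERMS
  out
}

#' Rescale term columns to a common range
#'
#' Applies an affine map to each term column so that the minimum and
#' maximum over all states (native included) are 0 and 1; the native
#' row is mapped by the same transform. Idempotent; a zero-range column
#' is left untouched with a warning.
#'
#' @param table Reference table from [build_reference_scores()] or
#'   [build_reference_scores_bind()].
#' @return Rescaled table (same shape, same attributes).
#' @export
rescale_terms <- function(table) {
  terms <- attr(table, "terms") %||% intersect(c(FOLD_TERMS, BIND_TERMS), names(table))
  for (tm in terms) {
    v <- table[[tm]]
    rng <- range(v)
    if (diff(rng) == 0) {
      warning("term '", tm, "' has zero range; left unscaled")
      next
    }
    table[[tm]] <- (v - rng[1]) / diff(rng)
  }
  attr(table, "terms") <- terms
  table
}

# Z of the native total against all alternative rows, for weights w
.table_z <- function(term_mat, native_row, w, signs) {
  totals <- as.vector(term_mat %*% (w * signs))
  g_nat <- totals[native_row]
  g <- totals[-native_row]
  q <- stats::quantile(g, c(0.25, 0.5), names = FALSE, type = 7)
  disp <- q[2] - q[1]
  if (disp <= 0) {
    # a constant-score table carries no information: the gap is 0 and
    # the chain wanders at Z = 0; any nonzero gap at zero dispersal is
    # treated as an invalid move
    return(if (q[2] - g_nat == 0) 0 else NA_real_)
  }
  (q[2] - g_nat) / disp
}

#' Optimize term weights by Metropolis-Hastings MCMC
#'
#' Walks the weight hypercube (0,1)^d maximizing the robust Z of the
#' native state against the cached alternative-state distribution.
#' Moves are accepted with probability 1 if Z improves and
#' `exp((Z_new - Z_old)/T)` otherwise; each proposal perturbs every
#' coordinate with a Gaussian of mean `proposal_mean` and variance
#' `proposal_var` (the positive default mean gives a biased random
#' walk, reproduced as printed; set `proposal_mean = 0` for a symmetric
#' walk). Proposals leaving (0,1) in any coordinate are rejected
#' outright but count as attempted moves. The best weight set seen is
#' retained.
#'
#' @param table (Typically rescaled) reference table.
#' @param temperature Chain temperature (default 0.1).
#' @param n_moves Attempted moves (default 100000).
#' @param proposal_mean,proposal_var Gaussian proposal parameters
#'   (defaults 0.1 and 0.1).
#' @param init Starting weights (default: all 0.5).
#' @param seed RNG seed.
#' @return Object of class `weight_chain`: list with `trajectory`
#'   (tibble: step, accepted flag, z, one column per weight), `best`
#'   (list of `weights` and `z`), `temperature`, `n_attempted`,
#'   `acceptance_rate`, `terms`, `signs`.
#' @export
optimize_weights <- function(table, temperature = 0.1, n_moves = 100000,
                             proposal_mean = 0.1, proposal_var = 0.1,
                             init = NULL, seed = 1L) {
  terms <- attr(table, "terms") %||% intersect(c(FOLD_TERMS, BIND_TERMS), names(table))
  signs <- if (all(terms %in% BIND_TERMS)) BIND_SIGNS[terms] else
    stats::setNames(rep(1, length(terms)), terms)
  term_mat <- as.matrix(table[, terms])
  native_row <- which(table$state == "native")
  stopifnot(length(native_row) == 1)
  d <- length(terms)
  w <- init %||% stats::setNames(rep(0.5, d), terms)
  w <- w[terms]
  sd_p <- sqrt(proposal_var)

  with_seed(seed, {
    z_cur <- .table_z(term_mat, native_row, w, signs)
    if (is.na(z_cur)) stop("degenerate score table: zero dispersal at start")
    best <- list(weights = w, z = z_cur)
    steps <- vector("list", n_moves + 1)
    steps[[1]] <- c(step = 0, accepted = 1, z = z_cur, w)
    n_acc <- 0L
    for (k in seq_len(n_moves)) {
      prop <- w + stats::rnorm(d, proposal_mean, sd_p)
      acc <- FALSE
      if (all(prop > 0 & prop < 1)) {
        z_new <- .table_z(term_mat, native_row, prop, signs)
        if (!is.na(z_new) && metropolis_accept(z_new - z_cur, temperature)) {
          w <- stats::setNames(prop, terms)
          z_cur <- z_new
          acc <- TRUE
          if (z_cur > best$z) best <- list(weights = w, z = z_cur)
        }
      }
      n_acc <- n_acc + acc
      steps[[k + 1]] <- c(step = k, accepted = as.numeric(acc), z = z_cur, w)
    }
    traj <- tibble::as_tibble(do.call(rbind, steps))
    out <- list(trajectory = traj, best = best, temperature = temperature,
                n_attempted = n_moves, acceptance_rate = n_acc / n_moves,
                terms = terms, signs = signs)
    class(out) <- "weight_chain"
    out
  })
}

#' Optimize binding weights for a complex
#'
#' Convenience wrapper: builds the random-partner reference table,
#' rescales it, and optimizes the three binding-term weights for
#' maximal Z of the native partner against random partner sequences.
#'
#' @inheritParams build_reference_scores_bind
#' @inheritParams optimize_weights
#' @return A `weight_chain`.
#' @export
optimize_binding_weights <- function(protein, ligand, n_seq = 1000,
                                     vary = "ligand",
                                     temperature = 0.1, n_moves = 100000,
                                     seed = 1L,
                                     thread_config = threading_config(),
                                     const = physics_constants()) {
  tab <- build_reference_scores_bind(protein, ligand, n_seq = n_seq,
                                     vary = vary, seed = seed,
                                     thread_config = thread_config,
                                     const = const)
  optimize_weights(rescale_terms(tab), temperature = temperature,
                   n_moves = n_moves, seed = seed + 1L)
}

#' @export
print.weight_chain <- function(x, ...) {
  cat("<weight_chain> ", x$n_attempted, " attempted moves, T = ",
      x$temperature, ", acceptance ", round(x$acceptance_rate, 3),
      "\n best Z = ", format(x$best$z, digits = 6), "\n", sep = "")
  print(round(x$best$weights, 4))
  invisible(x)
}

#' Tidy and summarize weight chains
#'
#' `tidy()` returns the full trajectory (one row per attempted move);
#' `glance()` a one-row summary with the best Z and weights.
#'
#' @param x A `weight_chain`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.weight_chain <- function(x, ...) x$trajectory

#' @rdname tidy.weight_chain
#' @export
glance.weight_chain <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(best_z = x$best$z, n_attempted = x$n_attempted,
                   acceptance_rate = x$acceptance_rate,
                   temperature = x$temperature),
    tibble::as_tibble(as.list(x$best$weights))
  )
}

#' Trace plot of a weight-optimization chain
#'
#' @param object A `weight_chain`.
#' @param ... Unused.
#' @return A ggplot of Z along the chain.
#' @export
autoplot.weight_chain <- function(object, ...) {
  ggplot2::ggplot(object$trajectory, ggplot2::aes(x = .data$step, y = .data$z)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::labs(x = "attempted move", y = "Z", title = "Weight-chain Z trace") +
    ggplot2::theme_minimal()
}
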
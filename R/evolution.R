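# Forward population simulation under truncation selection on folding
# stability and ligand binding: a population of organisms each carrying
# one coding DNA copy of the protein mutates, is translated, scored,
# and resampled every generation in proportion to a three-valued
# fitness (0 / 0.9 / 1).

DNA_ALPHABET <- c("A", "C", "G", "T")
.TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")

#' Mutate a DNA sequence
#'
#' Each base mutates independently with probability `mu`; conditional
#' on mutating, the transition is `ts_tv_ratio` times as probable as
#' the two transversions combined are split between them equally, so
#' the aggregate transition:transversion count ratio equals
#' `ts_tv_ratio`. Draws from the current RNG stream.
#'
#' @param dna DNA string over ACGT.
#' @param mu Per-base mutation probability per call.
#' @param ts_tv_ratio Aggregate transition/transversion ratio
#'   (default 2).
#' @return Mutated DNA string.
#' @export
mutate_dna <- function(dna, mu, ts_tv_ratio = 2) {
  bases <- strsplit(dna, "")[[1]]
  stopifnot(all(bases %in% DNA_ALPHABET))
  hit <- which(stats::runif(length(bases)) < mu)
  if (!length(hit)) return(dna)
  p_ts <- ts_tv_ratio / (1 + ts_tv_ratio)
  for (i in hit) {
    if (stats::runif(1) < p_ts) {
      bases[i] <- .TRANSITION[[bases[i]]]
    } else {
      tv <- setdiff(DNA_ALPHABET, c(bases[i], .TRANSITION[[bases[i]]]))
      bases[i] <- tv[sample.int(2, 1)]
    }
  }
  paste(bases, collapse = "")
}

# apply exactly n substitutions at distinct random positions
.mutate_fixed <- function(dna, n, ts_tv_ratio = 2) {
  bases <- strsplit(dna, "")[[1]]
  pos <- sample.int(length(bases), n)
  p_ts <- ts_tv_ratio / (1 + ts_tv_ratio)
  for (i in pos) {
    if (stats::runif(1) < p_ts) {
      bases[i] <- .TRANSITION[[bases[i]]]
    } else {
      tv <- setdiff(DNA_ALPHABET, c(bases[i], .TRANSITION[[bases[i]]]))
      bases[i] <- tv[sample.int(2, 1)]
    }
  }
  paste(bases, collapse = "")
}

#' Translate coding DNA to protein
#'
#' Standard genetic code. An internal stop codon sets the
#' `premature_stop` flag (the translation is truncated at it); a
#' terminal stop codon is allowed and trimmed.
#'
#' @param dna DNA string with length divisible by 3.
#' @return List with `protein` (amino-acid string) and
#'   `premature_stop` (logical).
#' @export
translate_dna <- function(dna) {
  n <- nchar(dna)
  if (n %% 3 != 0) stop("DNA length not divisible by 3")
  bases <- strsplit(dna, "")[[1]]
  if (!all(bases %in% DNA_ALPHABET)) stop("non-ACGT symbol in DNA")
  codons <- substring(dna, seq(1, n, 3), seq(3, n, 3))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  stops <- which(aa == "*")
  premature <- length(stops) > 0 && min(stops) < length(aa)
  if (length(stops)) aa <- aa[seq_len(min(stops) - 1)]
  list(protein = paste(aa, collapse = ""), premature_stop = premature)
}

#' Reverse-translate protein to DNA
#'
#' Chooses a synonymous codon uniformly at random per residue (seeded).
#'
#' @param protein Amino-acid string.
#' @param seed RNG seed.
#' @return DNA string of length `3 * nchar(protein)`.
#' @export
reverse_translate <- function(protein, seed = 1L) {
  gc <- Biostrings::GENETIC_CODE
  by_aa <- split(names(gc), unname(gc))
  aa <- strsplit(protein, "")[[1]]
  if (!all(aa %in% AA_ALPHABET)) stop("unknown residue letter in protein")
  with_seed(seed, {
    codons <- vapply(aa, function(a) {
      opts <- by_aa[[a]]
      opts[sample.int(length(opts), 1)]
    }, character(1))
    paste(codons, collapse = "")
  })
}

#' Decoy ligand for binding-specificity selection
#'
#' Threads the model-specific decoy sequence (variations on the
#' TIY..(VI) SH2-binding motif that do not bind the protein at the
#' simulation start) through the native ligand conformation:
#' `IWMTIYMIIIT` for the informational model and `RLPTIYICITG` for the
#' physics-based model. The ligand conformation must have 11 residues.
#'
#' @param model `"info"` or `"physics"`.
#' @param ligand_conformation The native ligand `coarse_structure`.
#' @param thread_config Threading configuration.
#' @return List with `sequence` and `structure` (the threaded decoy).
#' @export
make_decoy_ligand <- function(model = c("info", "physics"),
                              ligand_conformation,
                              thread_config = threading_config()) {
  model <- match.arg(model)
  seq <- if (model == "info") "IWMTIYMIIIT" else "RLPTIYICITG"
  if (nrow(ligand_conformation) != nchar(seq)) {
    stop("ligand conformation must have ", nchar(seq), " residues")
  }
  list(sequence = seq,
       structure = thread(seq, ligand_conformation, thread_config))
}

#' Fitness scorer bundle for evolutionary simulation
#'
#' Packages the three protein-level score functions used by the
#' truncation-selection fitness: `s_gap(protein)` (fold-score gap
#' against 100 fixed decoys, see [gap_scorer()]), `v_bind(protein)`
#' (binding score of the protein threaded onto its native conformation
#' against the native ligand) and `v_decoy(protein)` (same against the
#' decoy ligand threaded through the native ligand conformation).
#'
#' @param protein_conformation Native protein `coarse_structure`.
#' @param ligand Native ligand `coarse_structure` (complex frame).
#' @param model `"info"` or `"physics"`.
#' @param fold_weights,bind_weights Physics weight vectors.
#' @param u Contact matrix (informational model).
#' @param n_decoys Fixed decoys behind `s_gap` (default 100).
#' @param seed Decoy seed.
#' @param thread_config Threading configuration.
#' @param const Physics constants.
#' @return List of class `fitness_scorers` with elements `s_gap`,
#'   `v_bind`, `v_decoy`, `model`, `dispersal`.
#' @export
make_fitness_scorers <- function(protein_conformation, ligand,
                                 model = c("info", "physics"),
                                 fold_weights = default_weights("fold"),
                                 bind_weights = default_weights("bind"),
                                 u = contact_matrix(), n_decoys = 100L,
                                 seed = 1L,
                                 thread_config = threading_config(),
                                 const = physics_constants()) {
  model <- match.arg(model)
  decoy <- make_decoy_ligand(model, ligand, thread_config)
  sgap_model <- if (model == "info") "info" else "physics"
  sg <- gap_scorer(protein_conformation, sgap_model, weights = fold_weights,
                   u = u, n_decoys = n_decoys, seed = seed,
                   thread_config = thread_config, const = const)
  if (model == "info") {
    icm <- inter_contact_map(protein_conformation, ligand)
    lig_seq <- cs_sequence(ligand)
    v_bind <- function(protein) score_bind_info(protein, lig_seq, icm, u)
    v_decoy <- function(protein) score_bind_info(protein, decoy$sequence, icm, u)
  } else {
    v_bind <- function(protein) {
      p <- thread(protein, protein_conformation, thread_config, const = const)
      score_bind_physics(p, ligand, bind_weights, const)$total
    }
    v_decoy <- function(protein) {
      p <- thread(protein, protein_conformation, thread_config, const = const)
      score_bind_physics(p, decoy$structure, bind_weights, const)$total
    }
  }
  structure(list(s_gap = sg, v_bind = v_bind, v_decoy = v_decoy,
                 model = model, dispersal = attr(sg, "dispersal")),
            class = "fitness_scorers")
}

#' Truncation-selection fitness
#'
#' The three-way rule: fitness 0 when the fold gap falls below the
#' starting gap or the binding score rises above the starting binding
#' score; 0.9 when both thresholds are met but the decoy ligand also
#' binds (decoy score at or below the starting binding score); 1
#' otherwise. A premature stop codon gives fitness 0 (a truncated
#' protein cannot meet the fold threshold).
#'
#' @param protein Protein sequence (or `NA` for premature stop).
#' @param thresholds List with `s_gap_start` and `v_bind_start`.
#' @param scorers A `fitness_scorers` bundle.
#' @return List with `w` (0, 0.9 or 1) and the computed `s_gap`,
#'   `v_bind`, `v_decoy` scores.
#' @export
fitness <- function(protein, thresholds, scorers) {
  if (is.na(protein) || !nzchar(protein)) {
    return(list(w = 0, s_gap = NA_real_, v_bind = NA_real_, v_decoy = NA_real_))
  }
  sg <- scorers$s_gap(protein)
  vb <- scorers$v_bind(protein)
  if (sg < thresholds$s_gap_start || vb > thresholds$v_bind_start) {
    return(list(w = 0, s_gap = sg, v_bind = vb, v_decoy = NA_real_))
  }
  vd <- scorers$v_decoy(protein)
  w <- if (vd <= thresholds$v_bind_start) 0.9 else 1
  list(w = w, s_gap = sg, v_bind = vb, v_decoy = vd)
}

#' Starting-point fitness thresholds
#'
#' Freezes the fold-gap and binding scores of the starting protein
#' sequence; these thresholds never change during a run.
#'
#' @param start_protein Starting protein sequence.
#' @param scorers A `fitness_scorers` bundle.
#' @return List with `s_gap_start`, `v_bind_start`.
#' @export
fitness_thresholds <- function(start_protein, scorers) {
  list(s_gap_start = scorers$s_gap(start_protein),
       v_bind_start = scorers$v_bind(start_protein))
}

#' Simulation configuration
#'
#' Defaults reproduce the full-scale study conditions (1000 organisms,
#' 200000 generations, per-base mutation rate 1e-5 per generation,
#' transition/transversion ratio 2); tests and examples pass smaller
#' values explicitly.
#'
#' @param pop_size Population size N.
#' @param generations Number of generations.
#' @param mu Mutation probability per bp per generation.
#' @param ts_tv_ratio Transition/transversion ratio.
#' @param checkpoint_every Record a checkpoint every this many
#'   generations.
#' @param seed RNG seed for the replicate.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(pop_size = 1000L, generations = 200000L,
                              mu = 1e-5, ts_tv_ratio = 2,
                              checkpoint_every = 1000L, seed = 1L) {
  stopifnot(pop_size >= 2, generations >= 1, mu >= 0, checkpoint_every >= 1)
  structure(list(pop_size = as.integer(pop_size),
                 generations = as.integer(generations), mu = mu,
                 ts_tv_ratio = ts_tv_ratio,
                 checkpoint_every = as.integer(checkpoint_every),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Evolve a population under truncation selection
#'
#' Wright-Fisher propagation: every generation all organisms mutate,
#' fitness is recomputed only for genotypes not seen before (scores are
#' cached at the protein level), and the next generation is drawn by
#' sampling with replacement with probability proportional to fitness,
#' at constant population size. Checkpoints record the most common
#' allele, its frequency, and population-mean scores.
#'
#' @param start_dna Starting coding DNA (fitness of its protein must
#'   be 1).
#' @param scorers A `fitness_scorers` bundle (or any list with
#'   `s_gap`, `v_bind`, `v_decoy` functions).
#' @param config A [simulation_config()].
#' @param thresholds Optional precomputed [fitness_thresholds()].
#' @param init_population Optional DNA vector to resume from.
#' @param rng_state Optional saved RNG state to resume from (as stored
#'   in a previous run's `rng_state`).
#' @param generation0 Generation number of the resumed state.
#' @return Object of class `evolution_run`: list with `checkpoints`
#'   (tibble), `final_population`, `thresholds`, `config`,
#'   `rng_state` (for bitwise-identical resumption).
#' @export
evolve <- function(start_dna, scorers, config = simulation_config(),
                   thresholds = NULL, init_population = NULL,
                   rng_state = NULL, generation0 = 0L) {
  tr0 <- translate_dna(start_dna)
  if (tr0$premature_stop) stop("starting DNA contains a premature stop")
  if (is.null(thresholds)) thresholds <- fitness_thresholds(tr0$protein, scorers)
  w0 <- fitness(tr0$protein, thresholds, scorers)
  if (w0$w != 1) stop("starting sequence must have fitness 1 (got ", w0$w, ")")

  # two-level cache: DNA genotype -> result, protein -> result (so
  # synonymous genotypes share one protein-level scoring)
  pcache <- new.env(parent = emptyenv())
  dcache <- new.env(parent = emptyenv())
  assign(tr0$protein, w0, envir = pcache)
  n_prot <- nchar(tr0$protein)
  score_protein <- function(dna) {
    if (exists(dna, envir = dcache, inherits = FALSE)) {
      return(get(dna, envir = dcache, inherits = FALSE))
    }
    tr <- translate_dna(dna)
    # a stop in the final codon also truncates the protein
    res <- if (tr$premature_stop || nchar(tr$protein) != n_prot) {
      list(w = 0, s_gap = NA_real_, v_bind = NA_real_, v_decoy = NA_real_)
    } else {
      if (!exists(tr$protein, envir = pcache, inherits = FALSE)) {
        assign(tr$protein, fitness(tr$protein, thresholds, scorers),
               envir = pcache)
      }
      get(tr$protein, envir = pcache, inherits = FALSE)
    }
    assign(dna, res, envir = dcache)
    res
  }

  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
  })
  if (is.null(rng_state)) set.seed(config$seed) else
    assign(".Random.seed", rng_state, envir = globalenv())

  pop <- init_population %||% rep(start_dna, config$pop_size)
  stopifnot(length(pop) == config$pop_size)
  L <- nchar(start_dna)
  checkpoints <- list()
  for (gen in (generation0 + 1):(generation0 + config$generations)) {
    # equivalent to per-base Bernoulli(mu): draw the mutation count per
    # organism, then place that many mutations at distinct positions
    n_mut <- stats::rbinom(config$pop_size, L, config$mu)
    for (i in which(n_mut > 0)) {
      pop[i] <- .mutate_fixed(pop[i], n_mut[i], config$ts_tv_ratio)
    }
    scores <- lapply(pop, score_protein)
    w <- vapply(scores, `[[`, numeric(1), "w")
    if (all(w == 0)) stop("population extinct at generation ", gen,
                          ": all fitness zero")
    pop <- pop[sample.int(config$pop_size, config$pop_size,
                          replace = TRUE, prob = w)]
    if (gen %% config$checkpoint_every == 0 ||
        gen == generation0 + config$generations) {
      tab <- sort(table(pop), decreasing = TRUE)
      mc_dna <- names(tab)[1]
      sc <- lapply(pop, score_protein)
      checkpoints[[length(checkpoints) + 1]] <- tibble::tibble(
        generation = gen,
        most_common_dna = mc_dna,
        most_common_protein = translate_dna(mc_dna)$protein,
        allele_freq = as.numeric(tab[1]) / config$pop_size,
        n_alleles = length(tab),
        mean_fitness = mean(vapply(sc, `[[`, numeric(1), "w")),
        mean_s_gap = mean(vapply(sc, `[[`, numeric(1), "s_gap"), na.rm = TRUE),
        mean_v_bind = mean(vapply(sc, `[[`, numeric(1), "v_bind"), na.rm = TRUE)
      )
    }
  }
  out <- list(checkpoints = dplyr::bind_rows(checkpoints),
              final_population = pop, thresholds = thresholds,
              config = config,
              rng_state = get(".Random.seed", envir = globalenv()),
              start_dna = start_dna,
              final_generation = generation0 + config$generations)
  class(out) <- "evolution_run"
  out
}

#' @export
print.evolution_run <- function(x, ...) {
  cat("<evolution_run> N =", x$config$pop_size, ", generations =",
      x$final_generation, ",", nrow(x$checkpoints), "checkpoints\n")
  print(utils::tail(x$checkpoints, 3))
  invisible(x)
}

#' Tidy / summarize an evolution run
#'
#' `tidy()` returns the checkpoint table; `glance()` a one-row summary
#' of the final state.
#'
#' @param x An `evolution_run`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.evolution_run <- function(x, ...) x$checkpoints

#' @rdname tidy.evolution_run
#' @export
glance.evolution_run <- function(x, ...) {
  last <- utils::tail(x$checkpoints, 1)
  tibble::tibble(generations = x$final_generation,
                 pop_size = x$config$pop_size,
                 final_allele_freq = last$allele_freq,
                 final_mean_fitness = last$mean_fitness,
                 final_mean_s_gap = last$mean_s_gap)
}

#' Checkpoint trajectories of an evolution run
#' @param object An `evolution_run`.
#' @param ... Unused.
#' @return A ggplot of population-mean scores over generations.
#' @export
autoplot.evolution_run <- function(object, ...) {
  df <- tidyr::pivot_longer(object$checkpoints,
                            c("mean_fitness", "mean_s_gap", "mean_v_bind"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$generation, y = .data$value)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::theme_minimal()
}
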
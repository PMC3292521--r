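# Mutation model, translation, truncation-selection fitness and the
# Wright-Fisher propagator.

stub_scorers <- function(s_gap = function(p) 1, v_bind = function(p) -1,
                         v_decoy = function(p) 0) {
  structure(list(s_gap = s_gap, v_bind = v_bind, v_decoy = v_decoy,
                 model = "stub", dispersal = 1), class = "fitness_scorers")
}

test_that("the mutation kernel respects mu and the transition bias", {
  dna <- strrep("ACGT", 25)
  set.seed(1)
  expect_identical(mutate_dna(dna, 0), dna)

  # aggregate transition/transversion ratio over many mutated bases
  long <- paste(sample(c("A", "C", "G", "T"), 3e5, replace = TRUE), collapse = "")
  set.seed(2)
  mut <- mutate_dna(long, 1)   # every base mutates
  b0 <- strsplit(long, "")[[1]]; b1 <- strsplit(mut, "")[[1]]
  ts_map <- c(A = "G", G = "A", C = "T", T = "C")
  is_ts <- b1 == ts_map[b0]
  expect_true(all(b1 != b0))
  ratio <- sum(is_ts) / sum(!is_ts)
  expect_lt(abs(ratio - 2), 0.04)

  # Bernoulli mean of the mutation count
  set.seed(3)
  counts <- replicate(300, {
    m <- mutate_dna(strrep("A", 3000), 1e-3)
    sum(strsplit(m, "")[[1]] != "A")
  })
  expect_lt(abs(mean(counts) - 3), 3 * sqrt(3 / 300))
})

test_that("translation follows the standard code and flags premature stops", {
  expect_equal(translate_dna("ATGGCT")$protein, "MA")
  expect_false(translate_dna("ATGGCT")$premature_stop)
  # TAA at codon 2 of 4
  tr <- translate_dna("ATGTAAGCTGCT")
  expect_true(tr$premature_stop)
  expect_equal(tr$protein, "M")
  # terminal stop is fine
  expect_false(translate_dna("ATGGCTTAA")$premature_stop)
  expect_error(translate_dna("ATGGC"), "divisible")
  expect_error(translate_dna("ATGGCN"), "non-ACGT")
})

test_that("reverse translation is a seeded right inverse of translation", {
  prot <- "MKVLYDEWHRSTPQCING"
  dna <- reverse_translate(prot, seed = 4)
  expect_equal(nchar(dna), 3 * nchar(prot))
  expect_equal(translate_dna(dna)$protein, prot)
  expect_identical(reverse_translate(prot, seed = 4), dna)

  # synonymous codons drawn uniformly
  codons <- table(vapply(1:4000, function(i) {
    substr(reverse_translate("L", seed = i), 1, 3)
  }, character(1)))
  expect_equal(length(codons), 6)   # leucine has six codons
  expect_gt(stats::chisq.test(codons)$p.value, 0.001)
})

test_that("the three-way fitness rule is applied literally", {
  th <- list(s_gap_start = 1, v_bind_start = -1)
  sc <- stub_scorers(s_gap = function(p) 2, v_bind = function(p) -2,
                     v_decoy = function(p) 0)
  expect_equal(fitness("AAAA", th, sc)$w, 1)
  # fold gap below start: lethal
  sc0 <- stub_scorers(s_gap = function(p) 0.5)
  expect_equal(fitness("AAAA", th, sc0)$w, 0)
  # binding worse than start: lethal
  scb <- stub_scorers(v_bind = function(p) -0.5)
  expect_equal(fitness("AAAA", th, scb)$w, 0)
  # decoy binds too: mildly deleterious
  scd <- stub_scorers(s_gap = function(p) 2, v_bind = function(p) -2,
                      v_decoy = function(p) -3)
  expect_equal(fitness("AAAA", th, scd)$w, 0.9)
  # premature stop: lethal
  expect_equal(fitness(NA_character_, th, sc)$w, 0)
})

test_that("decoy ligands carry the printed sequences at ligand length", {
  cx <- make_fixture("toy_complex")
  d_info <- make_decoy_ligand("info", cx$ligand)
  d_phys <- make_decoy_ligand("physics", cx$ligand)
  expect_equal(d_info$sequence, "IWMTIYMIIIT")
  expect_equal(d_phys$sequence, "RLPTIYICITG")
  expect_equal(nrow(d_info$structure), nrow(cx$ligand))
  expect_identical(cs_ca(d_info$structure), cs_ca(cx$ligand))
  short <- make_fixture("two_domain_fold", 15)
  expect_error(make_decoy_ligand("info", short), "11 residues")
})

test_that("with mu = 0 the most common allele never changes", {
  dna <- reverse_translate(strrep("A", 10), seed = 1)
  run <- evolve(dna, stub_scorers(),
                simulation_config(pop_size = 20, generations = 50, mu = 0,
                                  checkpoint_every = 10, seed = 5))
  expect_true(all(run$checkpoints$most_common_dna == dna))
  expect_true(all(run$checkpoints$allele_freq == 1))
  expect_equal(length(run$final_population), 20)
})

test_that("population size is constant and extinction aborts", {
  dna <- reverse_translate(strrep("A", 8), seed = 2)
  run <- evolve(dna, stub_scorers(),
                simulation_config(pop_size = 37, generations = 30, mu = 1e-3,
                                  checkpoint_every = 30, seed = 6))
  expect_equal(length(run$final_population), 37)

  # all-zero fitness after the first mutation round
  dead <- stub_scorers(s_gap = function(p) -Inf)
  th_ok <- list(s_gap_start = -Inf, v_bind_start = 0)
  expect_error(
    evolve(dna, structure(list(
      s_gap = function(p) if (p == strrep("A", 8)) 1 else -1,
      v_bind = function(p) -1, v_decoy = function(p) 0), class = "fitness_scorers"),
      simulation_config(pop_size = 5, generations = 400, mu = 0.05,
                        checkpoint_every = 400, seed = 1),
      thresholds = list(s_gap_start = 1, v_bind_start = -1)),
    "extinct")
})

test_that("a fitness-zero genotype never leaves descendants", {
  # population seeded half-and-half; allele B is lethal
  dna_a <- reverse_translate("MKVL", seed = 1)
  dna_b <- reverse_translate("MKVI", seed = 1)
  sc <- structure(list(
    s_gap = function(p) if (p == "MKVI") -1 else 1,
    v_bind = function(p) -1, v_decoy = function(p) 0),
    class = "fitness_scorers")
  run <- evolve(dna_a, sc,
                simulation_config(pop_size = 20, generations = 1, mu = 0,
                                  checkpoint_every = 1, seed = 3),
                thresholds = list(s_gap_start = 0, v_bind_start = -0.5),
                init_population = rep(c(dna_a, dna_b), each = 10))
  expect_false(any(run$final_population == dna_b))
})

test_that("neutral drift fixes a unique allele at rate ~ 1/N", {
  n_pop <- 25
  dna_a <- reverse_translate("MKVL", seed = 1)
  dna_b <- reverse_translate("MKVM", seed = 2)
  fixed <- vapply(1:300, function(s) {
    run <- evolve(dna_a, stub_scorers(),
                  simulation_config(pop_size = n_pop, generations = 150,
                                    mu = 0, checkpoint_every = 150, seed = s),
                  init_population = c(rep(dna_a, n_pop - 1), dna_b))
    all(run$final_population == dna_b)
  }, logical(1))
  p_hat <- mean(fixed)
  sigma <- sqrt((1 / n_pop) * (1 - 1 / n_pop) / 300)
  expect_lt(abs(p_hat - 1 / n_pop), 3 * sigma)
})

test_that("a run resumes bitwise from its stored RNG state", {
  dna <- reverse_translate(strrep("A", 8), seed = 3)
  full <- evolve(dna, stub_scorers(),
                 simulation_config(pop_size = 15, generations = 40, mu = 1e-3,
                                   checkpoint_every = 10, seed = 9))
  first <- evolve(dna, stub_scorers(),
                  simulation_config(pop_size = 15, generations = 20, mu = 1e-3,
                                    checkpoint_every = 10, seed = 9))
  second <- evolve(dna, stub_scorers(),
                   simulation_config(pop_size = 15, generations = 20, mu = 1e-3,
                                     checkpoint_every = 10, seed = 9),
                   init_population = first$final_population,
                   rng_state = first$rng_state, generation0 = 20L)
  expect_identical(second$final_population, full$final_population)
  expect_equal(as.data.frame(rbind(first$checkpoints, second$checkpoints)),
               as.data.frame(full$checkpoints))
})

test_that("an end-to-end informational-model run keeps its thresholds", {
  cx <- make_fixture("toy_complex")
  sc <- make_fitness_scorers(cx$protein, cx$ligand, model = "info",
                             n_decoys = 50, seed = 2)
  start <- cs_sequence(cx$protein)
  th <- fitness_thresholds(start, sc)
  # the decoy ligand does not bind at the starting point
  expect_gt(sc$v_decoy(start), th$v_bind_start)
  dna <- reverse_translate(start, seed = 11)
  run <- evolve(dna, sc,
                simulation_config(pop_size = 30, generations = 120, mu = 2e-4,
                                  checkpoint_every = 40, seed = 7))
  expect_equal(nrow(run$checkpoints), 3)
  # every surviving organism satisfies the fold and binding thresholds
  final_prot <- vapply(run$final_population,
                       function(d) translate_dna(d)$protein, character(1))
  gaps <- vapply(unique(final_prot), sc$s_gap, numeric(1))
  expect_true(all(gaps >= th$s_gap_start - 1e-9))
})
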
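#' Simulate a pedigreed population with popular sires
#'
#' Generates a discrete-generation pedigree: unrelated founders followed
#' by `n_generations` rounds of mating within the previous generation.
#' As in commercial cattle breeding, only a small pool of sires
#' (`sire_pool`) serves all dams of a generation, so sire lineages
#' expand quickly -- the mechanism that lets individual founder
#' haplotypes reach appreciable population frequency, which the CNV
#' planter exploits. Every dam of the previous generation produces
#' `offspring_per_mating` offspring by one sire drawn from the pool.
#'
#' Birth order is a total order (older animals have smaller values) and
#' parents always precede their offspring, which is what the oldest-80%
#' reference/validation split and the Mendelian-consistency QC rely on.
#'
#' @param n_founders number of founder animals (>= 2; alternating
#'   male/female).
#' @param n_generations number of offspring generations (>= 0).
#' @param offspring_per_mating offspring per dam per generation.
#' @param sire_pool number of sires used per generation.
#' @param breed breed label attached to every animal.
#' @param seed integer seed.
#' @return a `data.frame` with columns `animal_id`, `sire_id`, `dam_id`
#'   (`NA` for founders), `birth_order`, `generation`, `sex`
#'   (`"M"`/`"F"`) and `breed`.
#' @export
simulate_pedigree <- function(n_founders, n_generations = 1,
                              offspring_per_mating = 2, sire_pool = 4,
                              breed = "breed1", seed = 1) {
  if (n_founders < 2) stop("need at least 2 founders to form matings")
  stopifnot(n_generations >= 0, offspring_per_mating >= 0, sire_pool >= 1)
  set.seed(seed)
  id <- function(g, i) sprintf("%s_g%d_%04d", breed, g, i)
  founders <- data.frame(
    animal_id = id(0, seq_len(n_founders)),
    sire_id = NA_character_, dam_id = NA_character_,
    birth_order = seq_len(n_founders), generation = 0L,
    sex = rep_len(c("M", "F"), n_founders),
    breed = breed, stringsAsFactors = FALSE
  )
  ped <- founders
  prev <- founders
  next_order <- n_founders + 1L
  for (g in seq_len(n_generations)) {
    males <- prev$animal_id[prev$sex == "M"]
    dams <- prev$animal_id[prev$sex == "F"]
    if (length(males) == 0 || length(dams) == 0) {
      stop("mating structure impossible: a generation lacks one sex")
    }
    sires <- sample(males, min(sire_pool, length(males)))
    n_off <- length(dams) * offspring_per_mating
    if (n_off == 0) { prev <- prev[0, ]; break }
    gen <- data.frame(
      animal_id = id(g, seq_len(n_off)),
      sire_id = sample(sires, n_off, replace = TRUE),
      dam_id = rep(dams, each = offspring_per_mating),
      birth_order = seq.int(next_order, length.out = n_off),
      generation = as.integer(g),
      sex = sample(c("M", "F"), n_off, replace = TRUE),
      breed = breed, stringsAsFactors = FALSE
    )
    ped <- rbind(ped, gen)
    prev <- gen
    next_order <- next_order + n_off
  }
  rownames(ped) <- NULL
  ped
}

#' Parent-progeny pairs of a pedigree
#'
#' One row per (parent, progeny) relation; each offspring contributes a
#' sire pair and a dam pair when the parent is known.
#'
#' @param ped pedigree data.frame.
#' @return data.frame with columns `parent_id`, `child_id`.
#' @export
parent_progeny_pairs <- function(ped) {
  s <- !is.na(ped$sire_id)
  d <- !is.na(ped$dam_id)
  rbind(
    data.frame(parent_id = ped$sire_id[s], child_id = ped$animal_id[s],
               stringsAsFactors = FALSE),
    data.frame(parent_id = ped$dam_id[d], child_id = ped$animal_id[d],
               stringsAsFactors = FALSE)
  )
}
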
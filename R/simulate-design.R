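# Population design and housing simulation for layer breeding programs:
# purebred hens individually housed on nucleus farms, crossbred paternal
# half-sibs housed in collective cages on recurrent-test farms.

#' Population design for the synthetic layer data
#'
#' Describes the family structure and housing of a simulated layer
#' population: paternal half-sib families with individually housed purebred
#' offspring and crossbred offspring grouped into cages of paternal
#' half-sibs.  Defaults follow a typical layer breeding program: on average
#' 50 purebred and 70 crossbred offspring per sire, cages of 6 to 8 hens,
#' recording between 25 and 83 weeks of age.
#'
#' @param n_sires number of base sires.
#' @param n_purebred_per_sire individually housed purebred offspring per
#'   sire.
#' @param n_crossbred_per_sire crossbred offspring per sire; divided into
#'   whole cages (remainder dropped).
#' @param cage_sizes vector of cage sizes, a subset of `c(6, 7, 8)`.
#' @param n_batches number of hatch batches (contemporary groups).
#' @param n_hatch_locations levels of the hatch-location fixed effect
#'   (hatch week x barn x corridor x row combination).
#' @param n_maternal_lines number of dam lines used in the crossbred test.
#' @param weeks age range (in weeks) covered by egg recording.
#' @param seed RNG seed for the design stage.
#' @return An object of class `population_design` (a list).
#' @export
population_design <- function(n_sires = 10,
                              n_purebred_per_sire = 50,
                              n_crossbred_per_sire = 70,
                              cage_sizes = c(6, 7),
                              n_batches = 4,
                              n_hatch_locations = 5,
                              n_maternal_lines = 5,
                              weeks = 25:83,
                              seed = 1L) {
  stopifnot(n_sires >= 1, n_purebred_per_sire >= 1,
            n_crossbred_per_sire >= 0,
            all(cage_sizes %in% c(6, 7, 8)),
            n_batches >= 1, n_hatch_locations >= 1, n_maternal_lines >= 1,
            length(weeks) >= 1)
  if (n_sires < 1) stop("empty design")
  structure(list(n_sires = as.integer(n_sires),
                 n_purebred_per_sire = as.integer(n_purebred_per_sire),
                 n_crossbred_per_sire = as.integer(n_crossbred_per_sire),
                 cage_sizes = as.integer(cage_sizes),
                 n_batches = as.integer(n_batches),
                 n_hatch_locations = as.integer(n_hatch_locations),
                 n_maternal_lines = as.integer(n_maternal_lines),
                 weeks = as.integer(weeks),
                 seed = as.integer(seed)),
            class = "population_design")
}

# Deterministic per-stage seed derived from the run seed, kept below 2^31.
stage_seed <- function(seed, stage) {
  cp <- as.numeric(utf8ToInt(stage))
  h <- sum(cp * seq_along(cp) * 2654435)
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483629)
}

#' Simulate a pedigree and housing plan
#'
#' Builds the paternal half-sib structure of a layer breeding program:
#' unrelated, non-inbred base sires and dams; purebred offspring with known
#' sire and dam, individually housed; crossbred offspring with known sire
#' only (dam lines are not pedigreed individually), grouped into cages in
#' which all cage mates share one sire.  Crossbred offspring that do not
#' fill a whole cage are dropped.  Each cage receives one maternal line and
#' one cage size; every unit is assigned to a batch and a hatch location.
#'
#' @param design a [population_design].
#' @return A list of class `layer_population` with elements
#'   \describe{
#'     \item{ped}{a [pedigree] over sires, purebred dams, purebred and
#'       crossbred offspring}
#'     \item{purebred}{data frame of individually housed hens: `unit_id`,
#'       `sire`, `batch`, `hatch_loc`}
#'     \item{cages}{data frame of crossbred cages: `unit_id`, `sire`,
#'       `cage_size`, `batch`, `hatch_loc`, `maternal_line`}
#'     \item{cage_members}{data frame `hen_id`, `unit_id` linking crossbred
#'       hens to their cage}
#'     \item{design}{the design used}
#'   }
#' @export
simulate_pedigree <- function(design) {
  stopifnot(inherits(design, "population_design"))
  if (design$n_sires < 1) stop("empty design")
  set.seed(stage_seed(design$seed, "pedigree"))
  ns <- design$n_sires
  np <- design$n_purebred_per_sire
  sires <- sprintf("S%03d", seq_len(ns))
  # purebred offspring: one base dam each (half-sib families through sires)
  pb_ids  <- sprintf("P%05d", seq_len(ns * np))
  pb_sire <- rep(sires, each = np)
  pb_dam  <- sprintf("D%05d", seq_len(ns * np))
  # crossbred offspring: whole cages of paternal half-sibs, dam unknown
  cs_each <- integer(0); cage_sire <- character(0)
  if (design$n_crossbred_per_sire > 0) {
    for (s in sires) {
      left <- design$n_crossbred_per_sire
      sz <- sample(rep(design$cage_sizes, length.out = 64))
      k <- 1L
      while (left >= sz[k]) {
        cs_each <- c(cs_each, sz[k])
        cage_sire <- c(cage_sire, s)
        left <- left - sz[k]
        k <- k + 1L
      }
    }
  }
  n_cb <- sum(cs_each)
  cb_ids  <- if (n_cb) sprintf("X%06d", seq_len(n_cb)) else character(0)
  cb_sire <- rep(cage_sire, times = cs_each)
  ped <- pedigree(
    id   = c(sires, pb_dam, pb_ids, cb_ids),
    sire = c(rep("0", ns + ns * np), pb_sire, cb_sire),
    dam  = c(rep("0", ns + ns * np), pb_dam, rep("0", n_cb)))
  batches <- sprintf("B%02d", seq_len(design$n_batches))
  hlocs   <- sprintf("H%02d", seq_len(design$n_hatch_locations))
  mlines  <- sprintf("M%02d", seq_len(design$n_maternal_lines))
  purebred <- data.frame(
    unit_id = pb_ids, sire = pb_sire,
    batch = sample(batches, length(pb_ids), replace = TRUE),
    hatch_loc = sample(hlocs, length(pb_ids), replace = TRUE),
    stringsAsFactors = FALSE)
  n_cage <- length(cs_each)
  cages <- data.frame(
    unit_id = if (n_cage) sprintf("C%05d", seq_len(n_cage)) else character(0),
    sire = cage_sire,
    cage_size = cs_each,
    batch = if (n_cage) sample(batches, n_cage, replace = TRUE) else character(0),
    hatch_loc = if (n_cage) sample(hlocs, n_cage, replace = TRUE) else character(0),
    maternal_line = if (n_cage) sample(mlines, n_cage, replace = TRUE) else character(0),
    stringsAsFactors = FALSE)
  cage_members <- data.frame(
    hen_id = cb_ids,
    unit_id = rep(cages$unit_id, times = cs_each),
    stringsAsFactors = FALSE)
  structure(list(ped = ped, purebred = purebred, cages = cages,
                 cage_members = cage_members, design = design),
            class = "layer_population")
}
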
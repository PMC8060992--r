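# Seeded synthetic metabolic networks. These drive the whole test suite:
# no real organism database is required anywhere. The generator emulates
# the structural features the explorer depends on -- multi-participant
# reactions, a mix of irreversible and reversible directionality,
# spontaneous reactions, a small currency-metabolite set, and synthetic
# EC/enzyme/gene/pathway annotations -- not the degree distribution or
# chemistry of a real metabolome.

# Run code under a private, fully specified RNG; the caller's random
# state is untouched.
with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", sample.kind = "Rejection")
  code
}

#' Specification for a synthetic network
#'
#' Defaults describe the standard test condition used throughout the
#' package: 200 metabolites and 500 reactions, 30% of reactions
#' reversible, 5% spontaneous, 5% of metabolites marked ubiquitous, and
#' up to 3 participants per reaction side. The same spec always yields
#' byte-identical serializations.
#'
#' @param n_metabolites,n_reactions Positive counts.
#' @param p_reversible,p_spontaneous,ubiquitous_fraction Probabilities in
#'   \code{[0, 1]}.
#' @param max_participants_per_side Maximum participants drawn per
#'   reaction side (both sides together must fit in `n_metabolites`).
#' @param seed Integer seed; the generator uses a private RNG stream.
#' @return An object of class `mn_fixture_spec`.
#' @export
fixture_spec <- function(n_metabolites = 200L, n_reactions = 500L,
                         p_reversible = 0.3, p_spontaneous = 0.05,
                         ubiquitous_fraction = 0.05,
                         max_participants_per_side = 3L, seed = 1L) {
  stopifnot(n_metabolites >= 1, n_reactions >= 0,
            p_reversible >= 0, p_reversible <= 1,
            p_spontaneous >= 0, p_spontaneous <= 1,
            ubiquitous_fraction >= 0, ubiquitous_fraction <= 1,
            max_participants_per_side >= 1)
  spec <- structure(
    list(n_metabolites = as.integer(n_metabolites),
         n_reactions = as.integer(n_reactions),
         p_reversible = p_reversible,
         p_spontaneous = p_spontaneous,
         ubiquitous_fraction = ubiquitous_fraction,
         max_participants_per_side = as.integer(max_participants_per_side),
         seed = as.integer(seed)),
    class = "mn_fixture_spec"
  )
  if (2L * spec$max_participants_per_side > spec$n_metabolites) {
    stop("infeasible spec: 2 * max_participants_per_side exceeds n_metabolites",
         call. = FALSE)
  }
  spec
}

NAME_SYLLABLES <- c("ala", "cit", "glu", "mal", "oxo", "ser", "thr", "pyr",
                    "fum", "ace", "lac", "gly", "arg", "asp", "lys", "rib",
                    "orn", "ket", "eno", "xyl")
NAME_SUFFIXES <- c("ate", "ine", "ose", "ol", "amide")
SMILES_FRAGMENTS <- c("C", "O", "N", "CC", "CO", "C(=O)O", "C(N)", "CCO")

#' Generate a synthetic metabolic network
#'
#' Draws reactions with 1..`max_participants_per_side` participants per
#' side, uniformly without replacement and with disjoint sides;
#' directions are `REVERSIBLE` with probability `p_reversible` and
#' `LEFT_TO_RIGHT` otherwise; reactions are spontaneous with probability
#' `p_spontaneous` (spontaneous reactions carry no enzymes or genes);
#' a `ubiquitous_fraction` of metabolites is marked ubiquitous; EC
#' numbers, enzyme/gene names and pathway memberships are synthesized
#' deterministically from the seed.
#'
#' @param spec An [fixture_spec()].
#' @return An `mn_network`.
#' @examples
#' net <- generate_network(fixture_spec(n_metabolites = 20, n_reactions = 30,
#'                                      seed = 7))
#' net
#' @export
generate_network <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "mn_fixture_spec"))
  with_local_seed(spec$seed, {
    n <- spec$n_metabolites
    ids <- sprintf("M%04d", seq_len(n))
    mets <- lapply(seq_len(n), function(i) {
      nm <- paste0(sample(NAME_SYLLABLES, 1), sample(NAME_SYLLABLES, 1),
                   sample(NAME_SUFFIXES, 1))
      smiles <- if (stats::runif(1) < 0.5) {
        paste(sample(SMILES_FRAGMENTS, sample(2:4, 1), replace = TRUE), collapse = "")
      } else NULL
      metabolite(ids[i], name = nm, smiles = smiles)
    })
    n_ubi <- round(spec$ubiquitous_fraction * n)
    ubi <- if (n_ubi > 0) sample(ids, n_ubi) else character(0)

    pw_pool <- sprintf("PWY-%03d", seq_len(max(1L, spec$n_reactions %/% 10L)))
    rxns <- lapply(seq_len(spec$n_reactions), function(j) {
      nl <- sample.int(spec$max_participants_per_side, 1)
      nr <- sample.int(spec$max_participants_per_side, 1)
      left <- sample(ids, nl)
      right <- sample(setdiff(ids, left), nr)
      coefs_l <- sample(c(1, 1, 1, 2), nl, replace = TRUE)
      coefs_r <- sample(c(1, 1, 1, 2), nr, replace = TRUE)
      direction <- if (stats::runif(1) < spec$p_reversible) "REVERSIBLE" else "LEFT_TO_RIGHT"
      spont <- stats::runif(1) < spec$p_spontaneous
      rid <- sprintf("R%04d", j)
      n_pw <- sample(0:2, 1)
      reaction(
        rid,
        left = stats::setNames(coefs_l, left),
        right = stats::setNames(coefs_r, right),
        direction = direction,
        ec_number = if (!spont && stats::runif(1) < 0.8) {
          sprintf("%d.%d.%d.%d", sample.int(6, 1), sample.int(20, 1),
                  sample.int(20, 1), sample.int(200, 1))
        } else NULL,
        enzymes = if (spont) character(0) else paste0("Enz-", rid, letters[seq_len(sample.int(2, 1))]),
        genes = if (spont) character(0) else paste0("gen", tolower(rid), letters[seq_len(sample.int(2, 1))]),
        pathways = if (n_pw > 0) sample(pw_pool, n_pw) else character(0),
        spontaneous = spont
      )
    })

    metabolic_network(
      sprintf("synthetic-m%d-r%d-s%d", n, spec$n_reactions, spec$seed),
      metabolites = mets, reactions = rxns, ubiquitous_ids = ubi
    )
  })
}
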
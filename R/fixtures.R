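# Deterministic toy-structure generators: the test substrate standing in for
# real antibody data. Chains are idealized poly-alanine backbones whose only
# purpose is to carry exactly the geometry the pipeline measures (framework
# rigidity, loop displacement, clashes, interface contacts).

# local offsets of backbone atoms relative to CA; CA-CA spacing 3.8 A along x
TOY_OFFSETS <- list(
  N  = c(-1.20,  0.80, 0),
  CA = c( 0.00,  0.00, 0),
  C  = c( 1.25,  0.60, 0),
  O  = c( 1.65, -0.55, 0)
)
TOY_CA_STEP <- 3.8

# run expr under a fixed RNG seed, restoring the caller's RNG state
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% 2147483647))
  force(expr)
}

# straight poly-alanine backbone atom table
toy_chain_atoms <- function(n_res, chain = "H", plddt = rep(90, n_res),
                            resno_start = 1L) {
  stopifnot(length(plddt) == n_res)
  rows <- vector("list", n_res)
  for (i in seq_len(n_res)) {
    ca <- c(TOY_CA_STEP * (i - 1L), 0, 0)
    xyz <- t(vapply(TOY_OFFSETS, function(o) ca + o, numeric(3)))
    rows[[i]] <- data.frame(
      eleno = 0L, elety = names(TOY_OFFSETS), resid = "ALA", chain = chain,
      resno = resno_start + i - 1L, insert = "",
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      o = 1, b = plddt[i],
      elesy = c("N", "C", "C", "O"),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  out$eleno <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Specification for the toy-ensemble generator
#'
#' Describes an antibody-like ensemble with planted cluster structure: a
#' rigid framework shared by all members, and a loop displaced by
#' `inter_conformation_shift` Angstrom per conformation along a fixed axis,
#' with seeded Gaussian noise of sd `intra_noise_sigma` on the loop atoms.
#'
#' @param seed integer seed; every generated coordinate is a pure function
#'   of the spec and this seed.
#' @param framework_len total framework residues (split evenly around the
#'   loop).
#' @param loop_len loop residues (the loop is named H3).
#' @param n_conformations number of planted conformations G.
#' @param members_per_conformation integer vector of length G.
#' @param intra_noise_sigma Gaussian coordinate noise on loop atoms (A).
#' @param inter_conformation_shift displacement between consecutive
#'   conformations (A).
#' @param plddt_profile optional per-residue confidence template of length
#'   `framework_len + loop_len`; default 92 on framework, 75 on the loop.
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1, framework_len = 20, loop_len = 8,
                         n_conformations = 3,
                         members_per_conformation = rep(10L, n_conformations),
                         intra_noise_sigma = 0.1,
                         inter_conformation_shift = 6,
                         plddt_profile = NULL) {
  if (framework_len < 8 || loop_len < 1) {
    stop("framework_len must be >= 8 and loop_len >= 1")
  }
  if (n_conformations < 1 ||
      length(members_per_conformation) != n_conformations ||
      any(members_per_conformation < 1)) {
    stop("members_per_conformation must give a positive count per conformation")
  }
  if (intra_noise_sigma < 0) stop("intra_noise_sigma must be >= 0")
  if (n_conformations > 1 && inter_conformation_shift <= 0) {
    stop("inter_conformation_shift must be positive when G > 1")
  }
  total <- framework_len + loop_len
  if (is.null(plddt_profile)) {
    fw1 <- ceiling(framework_len / 2)
    plddt_profile <- rep(92, total)
    plddt_profile[seq(fw1 + 1L, fw1 + loop_len)] <- 75
  }
  if (length(plddt_profile) != total) {
    stop("plddt_profile must have one value per residue (", total, ")")
  }
  structure(
    list(seed = as.integer(seed), framework_len = as.integer(framework_len),
         loop_len = as.integer(loop_len),
         n_conformations = as.integer(n_conformations),
         members_per_conformation = as.integer(members_per_conformation),
         intra_noise_sigma = intra_noise_sigma,
         inter_conformation_shift = inter_conformation_shift,
         plddt_profile = plddt_profile),
    class = "fixture_spec"
  )
}

fixture_regions <- function(spec, chain = "H") {
  fw1 <- ceiling(spec$framework_len / 2)
  total <- spec$framework_len + spec$loop_len
  region_definition(
    chain,
    framework = list(c(1L, fw1), c(fw1 + spec$loop_len + 1L, total)),
    loops = list(H3 = c(fw1 + 1L, fw1 + spec$loop_len))
  )
}

#' Generate one toy antibody-like chain
#'
#' Builds an idealized poly-alanine backbone whose framework is identical
#' across conformations while the loop is rigidly displaced along +y by
#' `conformation_id * inter_conformation_shift`, plus seeded Gaussian noise
#' on the loop atoms. The B-factor column carries the spec's pLDDT profile.
#'
#' @param spec a [fixture_spec()].
#' @param conformation_id 0-based conformation index, `< n_conformations`.
#' @param member_id index separating noise realisations of the same
#'   conformation (default 0).
#' @param chain chain id (default `"H"`).
#' @return list with `structure` (an `ab_structure`) and `regions` (the
#'   matching [region_definition()]).
#' @export
make_toy_chain <- function(spec, conformation_id, member_id = 0L,
                           chain = "H") {
  stopifnot(inherits(spec, "fixture_spec"))
  if (conformation_id < 0 || conformation_id >= spec$n_conformations) {
    stop("conformation_id must be in [0, ", spec$n_conformations - 1L, "]")
  }
  total <- spec$framework_len + spec$loop_len
  fw1 <- ceiling(spec$framework_len / 2)
  atoms <- toy_chain_atoms(total, chain = chain, plddt = spec$plddt_profile)
  is_loop <- atoms$resno >= fw1 + 1L & atoms$resno <= fw1 + spec$loop_len
  atoms$y[is_loop] <- atoms$y[is_loop] +
    conformation_id * spec$inter_conformation_shift
  if (spec$intra_noise_sigma > 0) {
    sub_seed <- (spec$seed * 100003 + conformation_id * 1009 + member_id) %%
      2147483647
    noise <- with_local_seed(sub_seed, {
      matrix(stats::rnorm(3L * sum(is_loop), sd = spec$intra_noise_sigma),
             ncol = 3)
    })
    atoms$x[is_loop] <- atoms$x[is_loop] + noise[, 1]
    atoms$y[is_loop] <- atoms$y[is_loop] + noise[, 2]
    atoms$z[is_loop] <- atoms$z[is_loop] + noise[, 3]
  }
  st <- new_structure(atoms,
                      model_id = sprintf("conf%d_mem%d", conformation_id,
                                         member_id),
                      source = "synthetic")
  list(structure = st, regions = fixture_regions(spec, chain))
}

#' Generate an ensemble with planted cluster structure
#'
#' `members_per_conformation[g]` noise realisations of each planted
#' conformation, shuffled deterministically by the spec seed. The returned
#' ground-truth labels make partition-recovery tests self-contained.
#'
#' @param spec a [fixture_spec()].
#' @param chain chain id (default `"H"`).
#' @return list with `ensemble` (an `ab_ensemble`), `truth` (integer vector
#'   of planted conformation ids, 1-based, aligned with ensemble order) and
#'   `regions`.
#' @export
make_planted_ensemble <- function(spec, chain = "H") {
  stopifnot(inherits(spec, "fixture_spec"))
  members <- list(); truth <- integer(0)
  for (g in seq_len(spec$n_conformations)) {
    for (j in seq_len(spec$members_per_conformation[g])) {
      members[[length(members) + 1L]] <-
        make_toy_chain(spec, g - 1L, member_id = j, chain = chain)$structure
      truth <- c(truth, g)
    }
  }
  perm <- with_local_seed(spec$seed, sample.int(length(members)))
  members <- members[perm]
  truth <- truth[perm]
  ens <- new_ensemble(members, labels = sprintf("m%03d", seq_along(members)))
  list(ensemble = ens, truth = truth, regions = fixture_regions(spec, chain))
}

# explicit O(n^2) double loop, intentionally naive: the generator's own
# verification path, independent of count_backbone_clashes
brute_force_interchain_clashes <- function(atoms_a, atoms_b, radii, fraction) {
  n_clash <- 0L
  min_margin <- Inf
  for (i in seq_len(nrow(atoms_a))) {
    for (j in seq_len(nrow(atoms_b))) {
      d <- sqrt((atoms_a$x[i] - atoms_b$x[j])^2 +
                  (atoms_a$y[i] - atoms_b$y[j])^2 +
                  (atoms_a$z[i] - atoms_b$z[j])^2)
      thr <- fraction * (radii[[atoms_a$elesy[i]]] + radii[[atoms_b$elesy[j]]])
      if (d < thr) n_clash <- n_clash + 1L
      else min_margin <- min(min_margin, d - thr)
    }
  }
  list(count = n_clash, min_clear_margin = min_margin)
}

#' Merge two chains with a planted number of backbone clashes
#'
#' Positions `partner` far from `structure`, then pulls `n_clashes` of its
#' CA atoms to within the clash threshold of well-separated framework CA
#' atoms of `structure`, so that exactly `n_clashes` inter-chain backbone
#' pairs violate the `fraction * (r_a + r_b)` rule while every other
#' inter-chain pair clears it by at least 0.2 Angstrom. The construction is
#' verified internally by an independent brute-force recount before
#' returning.
#'
#' @param structure heavy-chain `ab_structure` (becomes chain H).
#' @param partner light-chain `ab_structure` (becomes chain L).
#' @param n_clashes planted clash count, >= 0.
#' @param radii element radii table.
#' @param fraction clash fraction (default 0.63).
#' @param seed seed for the within-threshold clash depths.
#' @return merged `ab_structure` with chains H and L.
#' @export
plant_clashes <- function(structure, partner, n_clashes,
                          radii = default_vdw_radii(), fraction = 0.63,
                          seed = 1) {
  if (n_clashes < 0) stop("n_clashes must be >= 0")
  radii <- validate_radii(radii)
  merged <- merge_chains(structure, partner, heavy_id = "H", light_id = "L")
  la <- merged$atoms$chain == "L"
  merged$atoms$z[la] <- merged$atoms$z[la] + 25

  if (n_clashes > 0) {
    h_ca <- which(merged$atoms$chain == "H" & merged$atoms$elety == "CA")
    l_ca <- which(merged$atoms$chain == "L" & merged$atoms$elety == "CA")
    target_idx <- 2L + 3L * (seq_len(n_clashes) - 1L)
    if (max(target_idx) > length(h_ca) || n_clashes > length(l_ca)) {
      stop("placement infeasible: chains too short for ", n_clashes,
           " well-separated clashes")
    }
    thr_cc <- fraction * 2 * radii[["C"]]
    # depth >= 0.90 keeps every non-clashing neighbour pair clear of its
    # threshold by > 0.2 A on the idealized backbone geometry
    depth <- with_local_seed(seed, stats::runif(n_clashes, 0.90, 0.93))
    for (i in seq_len(n_clashes)) {
      tgt <- h_ca[target_idx[i]]
      mov <- l_ca[i]
      merged$atoms$x[mov] <- merged$atoms$x[tgt]
      merged$atoms$y[mov] <- merged$atoms$y[tgt]
      merged$atoms$z[mov] <- merged$atoms$z[tgt] + depth[i] * thr_cc
    }
  }

  bb <- merged$atoms[merged$atoms$elety %in% BACKBONE_ATOMS, , drop = FALSE]
  check <- brute_force_interchain_clashes(
    bb[bb$chain == "H", , drop = FALSE],
    bb[bb$chain == "L", , drop = FALSE],
    as.list(radii), fraction
  )
  if (check$count != n_clashes || check$min_clear_margin < 0.2) {
    stop("placement infeasible: self-verification found ", check$count,
         " clash(es) with clearance margin ",
         format(check$min_clear_margin, digits = 3))
  }
  merged
}

#' Generate a toy two-chain complex with a known interface
#'
#' Builds a receptor chain A and a shorter ligand chain B stacked 4.2
#' Angstrom above the receptor's middle, enumerates the reference contacts
#' by brute force, and returns a model in which the ligand has been rigidly
#' perturbed.
#'
#' @param seed integer seed (reserved for future stochastic perturbations;
#'   the construction itself is deterministic).
#' @param interface_size ligand residue count, >= 1.
#' @param translation rigid translation applied to the model ligand (A).
#' @param angle_deg rotation (degrees) applied to the model ligand about
#'   `axis` through its centroid, before translation.
#' @param axis rotation axis, length-3.
#' @param contact_cutoff heavy-atom contact cutoff (A) used for the expected
#'   contact enumeration.
#' @return list with `reference`, `model` (both `ab_structure`) and
#'   `contacts` (the expected reference `contact_set`).
#' @export
make_toy_complex <- function(seed = 1, interface_size = 6,
                             translation = c(0, 0, 0), angle_deg = 0,
                             axis = c(0, 0, 1), contact_cutoff = 5) {
  if (interface_size < 1) stop("interface_size must be >= 1")
  rec_len <- interface_size + 6L
  rec <- toy_chain_atoms(rec_len, chain = "A", plddt = rep(90, rec_len))
  lig <- toy_chain_atoms(interface_size, chain = "B",
                         plddt = rep(90, interface_size))
  lig$x <- lig$x + TOY_CA_STEP * 3
  lig$z <- lig$z + 4.2
  ref_atoms <- rbind(rec, lig)
  ref_atoms$eleno <- seq_len(nrow(ref_atoms))
  reference <- new_structure(ref_atoms, model_id = "toy_complex_ref")

  model <- reference
  model$model_id <- "toy_complex_model"
  bl <- model$atoms$chain == "B"
  xyz <- coords_matrix(model$atoms[bl, , drop = FALSE])
  if (angle_deg != 0) {
    u <- axis / sqrt(sum(axis^2))
    th <- angle_deg * pi / 180
    K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
                byrow = TRUE)
    R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
    ctr <- colMeans(xyz)
    xyz <- sweep(sweep(xyz, 2, ctr) %*% t(R), 2, ctr, "+")
  }
  xyz <- sweep(xyz, 2, translation, "+")
  model$atoms$x[bl] <- xyz[, 1]
  model$atoms$y[bl] <- xyz[, 2]
  model$atoms$z[bl] <- xyz[, 3]

  # expected contacts by explicit brute force over all heavy-atom pairs
  ra <- reference$atoms[reference$atoms$chain == "A", , drop = FALSE]
  rb <- reference$atoms[reference$atoms$chain == "B", , drop = FALSE]
  hits <- list()
  for (i in seq_len(nrow(ra))) {
    for (j in seq_len(nrow(rb))) {
      d <- sqrt((ra$x[i] - rb$x[j])^2 + (ra$y[i] - rb$y[j])^2 +
                  (ra$z[i] - rb$z[j])^2)
      if (d <= contact_cutoff) {
        hits[[length(hits) + 1L]] <- c(reskey(ra[i, ]), reskey(rb[j, ]))
      }
    }
  }
  contacts <- unique(data.frame(
    receptor = vapply(hits, `[`, "", 1),
    ligand = vapply(hits, `[`, "", 2),
    stringsAsFactors = FALSE
  ))
  contacts <- contacts[order(contacts$receptor, contacts$ligand), ,
                       drop = FALSE]
  rownames(contacts) <- NULL
  class(contacts) <- c("contact_set", class(contacts))
  list(reference = reference, model = model, contacts = contacts)
}
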
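QUALITY_LEVELS <- c("incorrect", "acceptable", "medium", "high")

split_complex <- function(x, receptor_chains, ligand_chains) {
  if (!length(receptor_chains) || !length(ligand_chains)) {
    stop("receptor and ligand chain groups must be non-empty")
  }
  if (length(intersect(receptor_chains, ligand_chains))) {
    stop("receptor and ligand chain groups must be disjoint")
  }
  present <- chain_ids(x)
  unknown <- setdiff(c(receptor_chains, ligand_chains), present)
  if (length(unknown)) {
    stop("chain id(s) not in structure: ", paste(unknown, collapse = ", "))
  }
  list(rec = x$atoms[x$atoms$chain %in% receptor_chains, , drop = FALSE],
       lig = x$atoms[x$atoms$chain %in% ligand_chains, , drop = FALSE])
}

# residue pairs (receptor, ligand) with any heavy-atom pair within cutoff
contact_pairs <- function(rec, lig, cutoff) {
  rx <- coords_matrix(rec); lx <- coords_matrix(lig)
  d2 <- outer(rowSums(rx^2), rowSums(lx^2), "+") - 2 * (rx %*% t(lx))
  hit <- which(d2 <= cutoff^2 + 1e-12, arr.ind = TRUE)
  if (!nrow(hit)) {
    return(data.frame(receptor = character(), ligand = character(),
                      stringsAsFactors = FALSE))
  }
  df <- unique(data.frame(receptor = reskey(rec)[hit[, 1]],
                          ligand = reskey(lig)[hit[, 2]],
                          stringsAsFactors = FALSE))
  df <- df[order(df$receptor, df$ligand), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Interface residue contacts of a complex
#'
#' A receptor-ligand residue pair is a contact when any heavy-atom pair
#' across the partition lies within `cutoff` (default 5 Angstrom, the CAPRI
#' convention).
#'
#' @param x an `ab_structure` holding the complex.
#' @param receptor_chains,ligand_chains disjoint chain id groups.
#' @param cutoff heavy-atom distance cutoff in Angstrom.
#' @return object of class `contact_set`: data.frame with columns
#'   `receptor`, `ligand` (residue keys `"chain:resno:icode"`).
#' @export
native_contacts <- function(x, receptor_chains, ligand_chains, cutoff = 5) {
  parts <- split_complex(x, receptor_chains, ligand_chains)
  out <- contact_pairs(parts$rec, parts$lig, cutoff)
  class(out) <- c("contact_set", class(out))
  out
}

#' Fraction of native contacts (fnat)
#'
#' Fraction of the reference complex's interface residue contacts that the
#' model reproduces.
#'
#' @param model,reference `ab_structure` complexes sharing residue
#'   identities.
#' @inheritParams native_contacts
#' @return fnat in `[0, 1]`.
#' @export
fnat <- function(model, reference, receptor_chains, ligand_chains,
                 cutoff = 5) {
  ref_c <- native_contacts(reference, receptor_chains, ligand_chains, cutoff)
  if (!nrow(ref_c)) {
    stop("reference complex has no contacts at cutoff ", cutoff,
         " A: fnat undefined")
  }
  mod_c <- native_contacts(model, receptor_chains, ligand_chains, cutoff)
  key <- function(df) paste(df$receptor, df$ligand, sep = "|")
  length(intersect(key(ref_c), key(mod_c))) / nrow(ref_c)
}

backbone_atoms_of_chains <- function(x, chains) {
  a <- x$atoms[x$atoms$chain %in% chains &
                 x$atoms$elety %in% BACKBONE_ATOMS, , drop = FALSE]
  rownames(a) <- NULL
  a
}

#' Ligand RMSD (L-RMSD)
#'
#' Superposes the model on the reference over the receptor backbone, then
#' measures RMSD over the ligand backbone without refitting — the standard
#' CAPRI measure of how far the docked ligand is from its native placement.
#'
#' @inheritParams fnat
#' @return RMSD in Angstrom.
#' @export
ligand_rmsd <- function(model, reference, receptor_chains, ligand_chains) {
  split_complex(reference, receptor_chains, ligand_chains)  # validates ids
  rec <- match_atom_tables(backbone_atoms_of_chains(model, receptor_chains),
                           backbone_atoms_of_chains(reference, receptor_chains),
                           what = "receptor backbone")
  lig <- match_atom_tables(backbone_atoms_of_chains(model, ligand_chains),
                           backbone_atoms_of_chains(reference, ligand_chains),
                           what = "ligand backbone")
  sup <- kabsch_superpose(coords_matrix(rec$model), coords_matrix(rec$ref))
  rmsd(apply_superposition(coords_matrix(lig$model), sup),
       coords_matrix(lig$ref))
}

#' Interface RMSD (i-RMSD)
#'
#' Interface residues are the reference residues (both sides) with any heavy
#' atom within `interface_cutoff` (default 10 Angstrom, the CAPRI
#' convention) of the partner. The model is superposed on the reference over
#' the backbone atoms of those residues and the RMSD is measured over the
#' same atoms.
#'
#' @inheritParams fnat
#' @param interface_cutoff heavy-atom cutoff defining the interface (A).
#' @return RMSD in Angstrom.
#' @export
interface_rmsd <- function(model, reference, receptor_chains, ligand_chains,
                           interface_cutoff = 10) {
  parts <- split_complex(reference, receptor_chains, ligand_chains)
  pairs <- contact_pairs(parts$rec, parts$lig, interface_cutoff)
  iface_keys <- unique(c(pairs$receptor, pairs$ligand))
  if (!length(iface_keys)) {
    stop("no interface residues within ", interface_cutoff,
         " A: i-RMSD undefined")
  }
  pick <- function(x) {
    a <- x$atoms[reskey(x$atoms) %in% iface_keys &
                   x$atoms$elety %in% BACKBONE_ATOMS, , drop = FALSE]
    rownames(a) <- NULL
    a
  }
  m <- match_atom_tables(pick(model), pick(reference),
                         what = "interface backbone")
  sup <- kabsch_superpose(coords_matrix(m$model), coords_matrix(m$ref))
  rmsd(apply_superposition(coords_matrix(m$model), sup),
       coords_matrix(m$ref))
}

#' Classify a docking model by CAPRI quality
#'
#' Evaluates High, then Medium, then Acceptable; the first satisfied rule
#' wins, otherwise the model is incorrect:
#' * high: fnat >= 0.5 and (L-RMSD <= 1 or i-RMSD <= 1)
#' * medium: fnat >= 0.3 and (L-RMSD <= 5 or i-RMSD <= 2)
#' * acceptable: fnat >= 0.1 and (L-RMSD <= 10 or i-RMSD <= 4)
#'
#' `rule = "consistent"` (default) defines incorrect as the complement of
#' acceptable. `rule = "printed"` instead applies the literal published
#' incorrect clause `fnat < 0.1 or (L-RMSD > 10 and i-RMSD > 2)` first; that
#' clause conflicts with the acceptable bound (i-RMSD <= 4) and is provided
#' only for comparison.
#'
#' @param fnat fraction of native contacts in `[0, 1]`.
#' @param lrmsd,irmsd ligand and interface RMSD in Angstrom.
#' @param rule `"consistent"` or `"printed"`.
#' @return one of `"high"`, `"medium"`, `"acceptable"`, `"incorrect"`.
#' @export
classify_quality <- function(fnat, lrmsd, irmsd,
                             rule = c("consistent", "printed")) {
  rule <- match.arg(rule)
  stopifnot(is.finite(fnat), is.finite(lrmsd), is.finite(irmsd))
  if (rule == "printed" && (fnat < 0.1 || (lrmsd > 10 && irmsd > 2))) {
    return("incorrect")
  }
  if (fnat >= 0.5 && (lrmsd <= 1 || irmsd <= 1)) return("high")
  if (fnat >= 0.3 && (lrmsd <= 5 || irmsd <= 2)) return("medium")
  if (fnat >= 0.1 && (lrmsd <= 10 || irmsd <= 4)) return("acceptable")
  "incorrect"
}

#' All three CAPRI metrics plus the quality class
#'
#' @inheritParams fnat
#' @inheritParams interface_rmsd
#' @inheritParams classify_quality
#' @return object of class `capri_scores`: list with `fnat`, `lrmsd`,
#'   `irmsd`, `quality`.
#' @export
capri_scores <- function(model, reference, receptor_chains, ligand_chains,
                         cutoff = 5, interface_cutoff = 10,
                         rule = "consistent") {
  fn <- fnat(model, reference, receptor_chains, ligand_chains, cutoff)
  lr <- ligand_rmsd(model, reference, receptor_chains, ligand_chains)
  ir <- interface_rmsd(model, reference, receptor_chains, ligand_chains,
                       interface_cutoff)
  structure(
    list(fnat = fn, lrmsd = lr, irmsd = ir,
         quality = classify_quality(fn, lr, ir, rule)),
    class = "capri_scores"
  )
}

#' @export
print.capri_scores <- function(x, ...) {
  cat(sprintf("capri_scores: fnat %.3f, L-RMSD %.2f A, i-RMSD %.2f A -> %s\n",
              x$fnat, x$lrmsd, x$irmsd, x$quality))
  invisible(x)
}

#' Top-N docking success rate over targets
#'
#' Fraction of targets whose best quality class within the first `top_n`
#' ranked models meets or exceeds `min_quality` (ordering incorrect <
#' acceptable < medium < high). `top_n` larger than a run uses the full run.
#'
#' @param ranked_runs list (one element per target) of character vectors of
#'   quality classes in rank order.
#' @param top_n number of top-ranked models to consider.
#' @param min_quality minimum class that counts as success.
#' @return success fraction in `[0, 1]`.
#' @export
success_rate <- function(ranked_runs, top_n = 1,
                         min_quality = "acceptable") {
  if (!length(ranked_runs)) stop("ranked_runs must be non-empty")
  if (top_n < 1) stop("top_n must be >= 1")
  min_quality <- match.arg(min_quality, QUALITY_LEVELS)
  need <- match(min_quality, QUALITY_LEVELS)
  ok <- vapply(ranked_runs, function(run) {
    run <- utils::head(run, top_n)
    lv <- match(run, QUALITY_LEVELS)
    if (anyNA(lv)) stop("unknown quality class in run: ",
                        paste(run[is.na(lv)], collapse = ", "))
    max(lv) >= need
  }, logical(1))
  mean(ok)
}
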
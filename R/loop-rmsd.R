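# Pair two atom tables by (chain, resno, icode, atom name); returns the
# tables reordered to the reference's atom order. Any mismatch is a coverage
# error: silent subsetting would change the metric.
match_atom_tables <- function(model_atoms, ref_atoms, what = "region") {
  km <- atomkey(model_atoms); kr <- atomkey(ref_atoms)
  miss_m <- setdiff(kr, km); miss_r <- setdiff(km, kr)
  if (length(miss_m) || length(miss_r)) {
    stop("model and reference disagree on ", what, " atoms; ",
         if (length(miss_m)) paste0("missing from model: ",
                                    paste(utils::head(miss_m, 5), collapse = ", "),
                                    if (length(miss_m) > 5) " ...") else "",
         if (length(miss_m) && length(miss_r)) "; " else "",
         if (length(miss_r)) paste0("missing from reference: ",
                                    paste(utils::head(miss_r, 5), collapse = ", "),
                                    if (length(miss_r) > 5) " ...") else "")
  }
  list(model = model_atoms[match(kr, km), , drop = FALSE], ref = ref_atoms)
}

#' Framework-aligned loop backbone RMSD
#'
#' Superposes `model` onto `reference` using the framework backbone atoms,
#' then measures the RMSD over the loop's backbone atoms in that frame,
#' without refitting on the loop. This is the loop accuracy metric used
#' throughout: it penalises a loop that sits in the wrong place relative to
#' the (conserved) framework, which a loop-local fit would hide.
#'
#' @param model,reference `ab_structure` objects containing the chain and all
#'   framework and loop residues named by `regions`.
#' @param regions a [region_definition()].
#' @param loop loop name present in `regions` (e.g. `"H3"`).
#' @param atom_set backbone atoms to use, default N, CA, C, O; set
#'   `c("N","CA","C")` to drop the carbonyl oxygen.
#' @return RMSD in Angstrom.
#' @export
loop_rmsd <- function(model, reference, regions, loop = "H3",
                      atom_set = BACKBONE_ATOMS) {
  fw <- match_atom_tables(
    select_region_atoms(model, regions, "framework", atom_set),
    select_region_atoms(reference, regions, "framework", atom_set),
    what = "framework"
  )
  lp <- match_atom_tables(
    select_region_atoms(model, regions, loop, atom_set),
    select_region_atoms(reference, regions, loop, atom_set),
    what = paste("loop", loop)
  )
  sup <- kabsch_superpose(coords_matrix(fw$model), coords_matrix(fw$ref))
  rmsd(apply_superposition(coords_matrix(lp$model), sup),
       coords_matrix(lp$ref))
}

#' Construct a labelled distance matrix
#' @param values symmetric non-negative matrix with zero diagonal (Angstrom).
#' @param labels member identifiers, one per row.
#' @return object of class `dist_matrix`.
#' @export
dist_matrix <- function(values, labels = NULL) {
  values <- as.matrix(values)
  n <- nrow(values)
  if (ncol(values) != n) stop("distance matrix must be square")
  if (is.null(labels)) labels <- sprintf("m%03d", seq_len(n))
  if (length(labels) != n) stop("labels length must match matrix size")
  if (any(values < 0)) stop("distance matrix has negative entries")
  if (any(abs(diag(values)) > 1e-9)) stop("distance matrix diagonal not zero")
  if (max(abs(values - t(values))) > 1e-6) {
    stop("distance matrix is not symmetric within 1e-6")
  }
  dimnames(values) <- list(labels, labels)
  structure(list(labels = labels, values = values), class = "dist_matrix")
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat("dist_matrix over", length(x$labels), "members; range [",
      format(min(x$values), digits = 4), ",",
      format(max(x$values), digits = 4), "] A\n")
  invisible(x)
}

#' Write a distance matrix as a labelled plain-text table
#' @param dist a `dist_matrix`.
#' @param path output TSV path.
#' @export
write_dist_matrix <- function(dist, path) {
  df <- as.data.frame(dist$values)
  utils::write.table(cbind(member = dist$labels, df), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pairwise framework-aligned loop RMSDs over an ensemble
#'
#' Entry (i, j) is [loop_rmsd()] of member i against member j. The matrix is
#' the distance that drives ensemble clustering.
#'
#' @param ensemble an `ab_ensemble` whose members share residue identities.
#' @param regions a [region_definition()].
#' @param loop loop name (default `"H3"`).
#' @param atom_set backbone atom subset.
#' @return a `dist_matrix`.
#' @export
pairwise_loop_distances <- function(ensemble, regions, loop = "H3",
                                    atom_set = BACKBONE_ATOMS) {
  n <- length(ensemble$members)
  # extract once per member, in a canonical atom order shared by all members
  first_fw <- select_region_atoms(ensemble$members[[1]], regions, "framework",
                                  atom_set)
  first_lp <- select_region_atoms(ensemble$members[[1]], regions, loop,
                                  atom_set)
  fw_keys <- atomkey(first_fw); lp_keys <- atomkey(first_lp)
  fw <- vector("list", n); lp <- vector("list", n)
  fw[[1]] <- coords_matrix(first_fw); lp[[1]] <- coords_matrix(first_lp)
  for (i in seq_len(n)[-1]) {
    fwi <- select_region_atoms(ensemble$members[[i]], regions, "framework",
                               atom_set)
    lpi <- select_region_atoms(ensemble$members[[i]], regions, loop, atom_set)
    if (!setequal(atomkey(fwi), fw_keys) || !setequal(atomkey(lpi), lp_keys)) {
      stop("member ", ensemble$labels[i],
           " disagrees with member ", ensemble$labels[1],
           " on framework/loop atoms")
    }
    fw[[i]] <- coords_matrix(fwi[match(fw_keys, atomkey(fwi)), , drop = FALSE])
    lp[[i]] <- coords_matrix(lpi[match(lp_keys, atomkey(lpi)), , drop = FALSE])
  }
  values <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      sup <- kabsch_superpose(fw[[i]], fw[[j]])
      d <- rmsd(apply_superposition(lp[[i]], sup), lp[[j]])
      values[i, j] <- d
      values[j, i] <- d
    }
  }
  dist_matrix(values, ensemble$labels)
}
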
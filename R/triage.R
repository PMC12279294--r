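#' Mean pLDDT over a loop
#'
#' Unweighted mean of per-residue pLDDT (CA B-factor) over the residues of
#' one loop. This is the confidence score that separates easy from difficult
#' antibody targets: a low H3 value signals that the predicted loop
#' conformation should not be trusted.
#'
#' @param x an `ab_structure`.
#' @param regions a [region_definition()].
#' @param loop loop name (default `"H3"`).
#' @return mean pLDDT in `[0, 100]`.
#' @export
loop_mean_plddt <- function(x, regions, loop = "H3") {
  rng <- region_ranges(regions, loop)[[1]]
  a <- x$atoms[x$atoms$chain == regions$chain &
                 in_ranges(x$atoms$resno, list(rng)), , drop = FALSE]
  missing_res <- setdiff(seq(rng[1], rng[2]), unique(a$resno))
  if (length(missing_res)) {
    stop("structure ", x$model_id, " is missing ", loop, " residue(s): ",
         paste(missing_res, collapse = ", "))
  }
  sub <- new_structure(a, model_id = x$model_id, source = x$source)
  vals <- residue_plddt(sub)
  if (any(vals < 0 | vals > 100)) {
    warning("pLDDT values outside [0, 100]: is the B-factor column really ",
            "a confidence?")
  }
  mean(vals)
}

#' Triage models into confident and difficult sets by loop pLDDT
#'
#' Partitions an ensemble at a loop-mean-pLDDT threshold (default 80, the
#' operating point separating trustworthy H3 predictions from the difficult
#' "LOW-80" regime). A value exactly at the threshold counts as confident:
#' difficult means strictly below.
#'
#' @param models an `ab_ensemble`.
#' @inheritParams loop_mean_plddt
#' @param threshold pLDDT cutoff (default 80). Values above 100 are allowed
#'   and mark every model difficult.
#' @return object of class `triage_result`: list with `values` (named
#'   per-model loop mean pLDDT), `threshold`, `confident` and `difficult`
#'   label vectors.
#' @export
triage_models <- function(models, regions, loop = "H3", threshold = 80) {
  if (threshold < 0) stop("threshold must be non-negative")
  vals <- vapply(models$members, loop_mean_plddt, numeric(1),
                 regions = regions, loop = loop)
  names(vals) <- models$labels
  structure(
    list(values = vals, threshold = threshold,
         confident = models$labels[vals >= threshold],
         difficult = models$labels[vals < threshold]),
    class = "triage_result"
  )
}

#' @export
print.triage_result <- function(x, ...) {
  cat("triage at loop pLDDT ", x$threshold, ": ", length(x$confident),
      " confident, ", length(x$difficult), " difficult\n", sep = "")
  invisible(x)
}

#' Split targets into right and wrong by best loop RMSD
#'
#' Divides targets whose best model has loop RMSD strictly below
#' `rmsd_threshold` ("right": the generator found the loop fold) from the
#' rest ("wrong"). The default 3.0 Angstrom is the conventional boundary for
#' a usable H3 conformation.
#'
#' @param best_rmsd named numeric vector: per-target best loop RMSD (A).
#' @param rmsd_threshold positive cutoff (default 3.0).
#' @return list with `right`, `wrong` label vectors and `threshold`.
#' @export
split_by_accuracy <- function(best_rmsd, rmsd_threshold = 3.0) {
  if (rmsd_threshold <= 0) stop("rmsd_threshold must be positive")
  labs <- names(best_rmsd)
  if (is.null(labs)) labs <- as.character(seq_along(best_rmsd))
  list(right = labs[best_rmsd < rmsd_threshold],
       wrong = labs[best_rmsd >= rmsd_threshold],
       threshold = rmsd_threshold)
}

#' Pearson correlation between loop pLDDT and loop RMSD
#'
#' The diagnostic linking predicted confidence to realised accuracy; on real
#' antibody sets the two are strongly anti-correlated, which is what
#' justifies pLDDT triage in the first place.
#'
#' @param plddt numeric vector of loop mean pLDDT values.
#' @param rmsd numeric vector of loop RMSDs, paired with `plddt`.
#' @return Pearson product-moment coefficient in `[-1, 1]`.
#' @export
plddt_rmsd_correlation <- function(plddt, rmsd) {
  if (length(plddt) != length(rmsd)) stop("inputs must be paired")
  if (length(plddt) < 3L) stop("need at least 3 pairs")
  if (stats::sd(plddt) == 0 || stats::sd(rmsd) == 0) {
    stop("undefined correlation: zero variance in one coordinate")
  }
  stats::cor(plddt, rmsd, method = "pearson")
}
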
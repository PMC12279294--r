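#' Default van der Waals radii table
#'
#' Element radii (Angstrom) used by the backbone clash criterion: a pair of
#' atoms clashes when their distance is strictly below
#' `fraction * (r_a + r_b)`. A standard vdW set; fully overridable.
#'
#' @return named numeric vector of radii.
#' @export
default_vdw_radii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)
}

validate_radii <- function(radii) {
  if (is.null(names(radii)) || any(!nzchar(names(radii)))) {
    stop("radii table must be a named numeric vector")
  }
  if (any(!is.finite(radii)) || any(radii <= 0)) {
    stop("all radii must be positive and finite")
  }
  need <- c("C", "N", "O", "S")
  miss <- setdiff(need, names(radii))
  if (length(miss)) {
    stop("radii table must cover at least C, N, O, S; missing: ",
         paste(miss, collapse = ", "))
  }
  radii
}

#' Merge a heavy and a light chain into one antibody model
#'
#' Takes one chain from each source structure, relabels them, and
#' concatenates them into a single two-chain model. Coordinates, residue
#' numbering and B-factors are untouched.
#'
#' @param heavy,light `ab_structure` sources.
#' @param heavy_chain,light_chain chain id to take from each source
#'   (default: the first chain).
#' @param heavy_id,light_id chain ids in the merged structure (default H, L).
#' @return an `ab_structure` with chains `heavy_id` then `light_id`.
#' @export
merge_chains <- function(heavy, light, heavy_chain = NULL, light_chain = NULL,
                         heavy_id = "H", light_id = "L") {
  if (identical(heavy_id, light_id)) {
    stop("heavy_id and light_id must differ (chain id collision)")
  }
  if (is.null(heavy_chain)) heavy_chain <- chain_ids(heavy)[1]
  if (is.null(light_chain)) light_chain <- chain_ids(light)[1]
  ha <- get_chain(heavy, heavy_chain)$atoms
  la <- get_chain(light, light_chain)$atoms
  ha$chain <- heavy_id
  la$chain <- light_id
  new_structure(rbind(ha, la),
                model_id = paste0(heavy$model_id, "+", light$model_id),
                source = "merged")
}

# residue ordinal within each chain, in order of first appearance; used to
# exclude sequence-adjacent residue pairs from clash counting
residue_ordinal <- function(atoms) {
  rk <- reskey(atoms)
  match(rk, unique(rk))
}

#' Count backbone clashes in a structure
#'
#' A clash is an unordered pair of backbone heavy atoms (N, CA, C, O) whose
#' distance is strictly lower than `fraction` times the sum of their element
#' radii (default fraction 0.63). Pairs within the same residue and between
#' residues adjacent in sequence on the same chain are excluded, so covalent
#' geometry is never counted. With `chain_pair` given, only pairs between
#' those two chains are tested — the assembly use case, where a generated H3
#' loop may run into the light chain.
#'
#' @param x an `ab_structure`.
#' @param radii named element radii table, see [default_vdw_radii()].
#' @param fraction clash threshold as a fraction of the radii sum, in (0, 1].
#' @param chain_pair optional length-2 character vector of chain ids; only
#'   inter-chain pairs between the two are tested.
#' @return object of class `clash_report`: list with `model_label`,
#'   `clashes` (data.frame: `atom_a`, `atom_b`, `distance`, `threshold`) and
#'   `count`.
#' @export
count_backbone_clashes <- function(x, radii = default_vdw_radii(),
                                   fraction = 0.63, chain_pair = NULL) {
  radii <- validate_radii(radii)
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  bb <- x$atoms[x$atoms$elety %in% BACKBONE_ATOMS, , drop = FALSE]
  unknown <- setdiff(unique(bb$elesy), names(radii))
  if (length(unknown)) {
    stop("element(s) missing from radii table: ",
         paste(unknown, collapse = ", "))
  }
  r <- radii[bb$elesy]
  ids <- atomkey(bb)
  xyz <- coords_matrix(bb)
  ordn <- residue_ordinal(bb)

  if (!is.null(chain_pair)) {
    if (length(chain_pair) != 2L) stop("chain_pair must name two chains")
    ia <- which(bb$chain == chain_pair[1])
    ib <- which(bb$chain == chain_pair[2])
    if (!length(ia) || !length(ib)) {
      stop("chain_pair chains not both present: ",
           paste(chain_pair, collapse = ", "))
    }
    pairs <- expand.grid(a = ia, b = ib, KEEP.OUT.ATTRS = FALSE)
  } else {
    n <- nrow(bb)
    if (n < 2L) {
      pairs <- data.frame(a = integer(), b = integer())
    } else {
      pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
      pairs <- data.frame(a = pairs[, 1], b = pairs[, 2])
      same_chain <- bb$chain[pairs$a] == bb$chain[pairs$b]
      near_seq <- abs(ordn[pairs$a] - ordn[pairs$b]) <= 1L
      pairs <- pairs[!(same_chain & near_seq), , drop = FALSE]
    }
  }

  if (nrow(pairs)) {
    dvec <- sqrt(rowSums((xyz[pairs$a, , drop = FALSE] -
                            xyz[pairs$b, , drop = FALSE])^2))
    thr <- fraction * (r[pairs$a] + r[pairs$b])
    hit <- dvec < thr                       # strict: "lower than"
  } else {
    dvec <- numeric(0); thr <- numeric(0); hit <- logical(0)
  }
  clashes <- data.frame(
    atom_a = ids[pairs$a[hit]],
    atom_b = ids[pairs$b[hit]],
    distance = dvec[hit],
    threshold = unname(thr[hit]),
    stringsAsFactors = FALSE
  )
  structure(list(model_label = x$model_id, clashes = clashes,
                 count = nrow(clashes)),
            class = "clash_report")
}

#' @export
print.clash_report <- function(x, ...) {
  cat("clash_report '", x$model_label, "': ", x$count, " clash(es)\n",
      sep = "")
  if (x$count) print(x$clashes)
  invisible(x)
}

#' Filter clashed members out of an ensemble
#'
#' Removes members showing more than `max_clashes` backbone clashes (default
#' 1: members with 0 or 1 clash are kept, 2 or more are removed). Survivors
#' keep their original order; the report covers every member, kept or not.
#'
#' @param ensemble an `ab_ensemble`.
#' @inheritParams count_backbone_clashes
#' @param max_clashes members with a clash count above this are removed.
#' @return list with `ensemble` (surviving members; `NULL` if none survive,
#'   with a warning), `reports` (per-member `clash_report` list) and `kept`
#'   (named logical vector).
#' @export
filter_clashed <- function(ensemble, radii = default_vdw_radii(),
                           fraction = 0.63, max_clashes = 1,
                           chain_pair = NULL) {
  reports <- lapply(seq_along(ensemble$members), function(i) {
    rep <- count_backbone_clashes(ensemble$members[[i]], radii, fraction,
                                  chain_pair)
    rep$model_label <- ensemble$labels[i]
    rep
  })
  counts <- vapply(reports, `[[`, integer(1), "count")
  kept <- counts <= max_clashes
  names(kept) <- ensemble$labels
  out <- if (any(kept)) ensemble[which(kept)] else {
    warning("all ", length(kept), " members exceed max_clashes = ",
            max_clashes, "; returning empty ensemble")
    NULL
  }
  list(ensemble = out, reports = reports, kept = kept)
}
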
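LOOP_NAMES <- c("H1", "H2", "H3", "L1", "L2", "L3")

as_range_list <- function(x, what) {
  if (is.matrix(x)) x <- lapply(seq_len(nrow(x)), function(i) x[i, ])
  if (is.numeric(x) && length(x) == 2L) x <- list(x)
  lapply(x, function(r) {
    r <- as.integer(r)
    if (length(r) != 2L || anyNA(r) || r[1] > r[2]) {
      stop(what, " ranges must be (start, end) pairs with start <= end")
    }
    r
  })
}

ranges_overlap <- function(a, b) a[1] <= b[2] && b[1] <= a[2]

#' Define framework and CDR loop regions on a chain
#'
#' A region definition partitions a chain, by author residue numbering, into
#' the structurally conserved framework (the superposition anchor) and named
#' CDR loops. Ranges are inclusive `(start, end)` residue-number pairs.
#'
#' @param chain single chain id the ranges refer to.
#' @param framework list of `(start, end)` ranges covering the framework.
#' @param loops named list mapping loop names (subset of H1, H2, H3, L1, L2,
#'   L3) to one `(start, end)` range each.
#' @return object of class `region_definition`.
#' @export
region_definition <- function(chain, framework, loops) {
  framework <- as_range_list(framework, "framework")
  if (!length(framework)) stop("framework must contain at least one range")
  if (is.null(names(loops)) || any(!nzchar(names(loops)))) {
    stop("loops must be a named list")
  }
  bad <- setdiff(names(loops), LOOP_NAMES)
  if (length(bad)) {
    stop("unknown loop name(s): ", paste(bad, collapse = ", "))
  }
  loops <- lapply(loops, function(r) as_range_list(r, "loop")[[1]])
  all_ranges <- c(framework, unname(loops))
  if (length(all_ranges) > 1L) {
    for (i in seq_len(length(all_ranges) - 1L)) {
      for (j in seq(i + 1L, length(all_ranges))) {
        if (ranges_overlap(all_ranges[[i]], all_ranges[[j]])) {
          stop("framework and loop ranges must be disjoint")
        }
      }
    }
  }
  structure(list(chain = chain, framework = framework, loops = loops),
            class = "region_definition")
}

#' @export
print.region_definition <- function(x, ...) {
  fmt <- function(r) paste0("[", r[1], "-", r[2], "]")
  cat("region_definition chain", x$chain, "\n")
  cat("  framework:", paste(vapply(x$framework, fmt, ""), collapse = " "), "\n")
  for (nm in names(x$loops)) cat("  ", nm, ": ", fmt(x$loops[[nm]]), "\n", sep = "")
  invisible(x)
}

#' Read a region definition from a YAML config
#'
#' Expected layout:
#' ```yaml
#' chain: H
#' framework:
#'   - [1, 20]
#'   - [33, 52]
#' loops:
#'   H3: [21, 32]
#' ```
#' @param path YAML file path.
#' @return a `region_definition`.
#' @export
read_region_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$chain) || is.null(cfg$framework) || is.null(cfg$loops)) {
    stop("region config must define 'chain', 'framework' and 'loops'")
  }
  region_definition(as.character(cfg$chain), cfg$framework, cfg$loops)
}

#' Write a region definition to a YAML config
#' @param regions a `region_definition`.
#' @param path output file path.
#' @export
write_region_config <- function(regions, path) {
  yaml::write_yaml(
    list(chain = regions$chain,
         framework = lapply(regions$framework, as.integer),
         loops = lapply(regions$loops, as.integer)),
    path
  )
  invisible(path)
}

in_ranges <- function(resno, ranges) {
  hit <- rep(FALSE, length(resno))
  for (r in ranges) hit <- hit | (resno >= r[1] & resno <= r[2])
  hit
}

region_ranges <- function(regions, part) {
  if (identical(part, "framework")) return(regions$framework)
  if (is.null(regions$loops[[part]])) {
    stop("loop '", part, "' not present in region definition")
  }
  list(regions$loops[[part]])
}

# Select backbone atoms of a region, in residue order then N, CA, C, O.
# Every selected residue must carry the full atom_set (silent skips would
# change the RMSD); loop ranges must additionally be fully populated.
select_region_atoms <- function(x, regions, part,
                                atom_set = BACKBONE_ATOMS) {
  ranges <- region_ranges(regions, part)
  a <- x$atoms[x$atoms$chain == regions$chain, , drop = FALSE]
  if (nrow(a) == 0L) {
    stop("chain '", regions$chain, "' absent from structure ", x$model_id)
  }
  sel <- a[in_ranges(a$resno, ranges), , drop = FALSE]
  if (part != "framework") {
    want <- seq(ranges[[1]][1], ranges[[1]][2])
    missing_res <- setdiff(want, unique(sel$resno))
    if (length(missing_res)) {
      stop("structure ", x$model_id, " is missing ", part, " residue(s): ",
           paste(missing_res, collapse = ", "))
    }
  }
  if (nrow(sel) == 0L) {
    stop("no residues of structure ", x$model_id, " fall in the ", part,
         " region")
  }
  bb <- sel[sel$elety %in% atom_set, , drop = FALSE]
  rk <- reskey(bb)
  per_res <- split(bb$elety, rk)
  incomplete <- names(per_res)[vapply(per_res, function(e) {
    !all(atom_set %in% e)
  }, logical(1))]
  if (length(incomplete)) {
    stop("residue(s) ", paste(incomplete, collapse = ", "),
         " lack backbone atom(s) {", paste(atom_set, collapse = ","),
         "} required for the ", part, " region")
  }
  res_order <- match(rk, unique(reskey(sel)))
  bb <- bb[order(res_order, match(bb$elety, BACKBONE_ATOMS)), , drop = FALSE]
  rownames(bb) <- NULL
  bb
}
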
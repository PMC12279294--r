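#' @keywords internal
"_PACKAGE"

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

#' Construct a structure object
#'
#' A structure is an atom table plus identifiers. The atom table follows the
#' familiar PDB column layout: one row per heavy atom with chain id, author
#' residue number, insertion code, residue name, atom name, coordinates in
#' Angstrom, occupancy and B-factor. For predicted models the B-factor column
#' carries per-residue pLDDT (0-100), the universal predictor convention.
#'
#' @param atoms data.frame with columns `eleno`, `elety`, `resid`, `chain`,
#'   `resno`, `insert`, `x`, `y`, `z`, `o`, `b`, `elesy`.
#' @param model_id identifier for the model.
#' @param source file path the structure came from, or `"synthetic"`.
#' @return object of class `ab_structure`.
#' @export
new_structure <- function(atoms, model_id = "model", source = "synthetic") {
  needed <- c("eleno", "elety", "resid", "chain", "resno", "insert",
              "x", "y", "z", "o", "b", "elesy")
  missing_cols <- setdiff(needed, names(atoms))
  if (length(missing_cols)) {
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(atoms) == 0L) stop("structure must contain at least one residue")
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    stop("non-finite coordinates in atom table")
  }
  if (any(!nzchar(atoms$elety))) stop("empty atom names in atom table")
  rownames(atoms) <- NULL
  structure(
    list(model_id = model_id, atoms = atoms, source = source),
    class = "ab_structure"
  )
}

#' @export
print.ab_structure <- function(x, ...) {
  ch <- chain_ids(x)
  nres <- vapply(ch, function(cc) {
    length(unique(reskey(x$atoms[x$atoms$chain == cc, , drop = FALSE])))
  }, integer(1))
  cat("ab_structure '", x$model_id, "' (", x$source, ")\n", sep = "")
  cat("  chains: ", paste0(ch, " (", nres, " res)", collapse = ", "),
      "; ", nrow(x$atoms), " atoms\n", sep = "")
  invisible(x)
}

#' Chain identifiers of a structure
#' @param x an `ab_structure`.
#' @return character vector of chain ids in order of first appearance.
#' @export
chain_ids <- function(x) unique(x$atoms$chain)

#' Extract one chain as a new structure
#' @param x an `ab_structure`.
#' @param chain single chain id.
#' @export
get_chain <- function(x, chain) {
  sel <- x$atoms$chain == chain
  if (!any(sel)) stop("chain '", chain, "' not present in structure")
  new_structure(x$atoms[sel, , drop = FALSE], model_id = x$model_id,
                source = x$source)
}

# residue key "chain:resno:icode"; the unit of identity everywhere
reskey <- function(atoms) paste(atoms$chain, atoms$resno, atoms$insert, sep = ":")

# atom key "chain:resno:icode:name"; used to pair atoms across structures
atomkey <- function(atoms) {
  paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety, sep = ":")
}

coords_matrix <- function(atoms) {
  as.matrix(atoms[, c("x", "y", "z"), drop = FALSE])
}

#' Backbone atoms of a structure
#'
#' Returns the backbone heavy atoms, residue by residue, each residue's atoms
#' in the fixed order N, CA, C, O (subset of that order if some are absent).
#'
#' @param x an `ab_structure`.
#' @param chain optional chain id filter.
#' @param atom_set backbone atom names to keep, a subset of N, CA, C, O.
#' @return atom data.frame (same columns as `x$atoms`).
#' @export
backbone <- function(x, chain = NULL, atom_set = BACKBONE_ATOMS) {
  atom_set <- match.arg(atom_set, BACKBONE_ATOMS, several.ok = TRUE)
  a <- x$atoms
  if (!is.null(chain)) a <- a[a$chain %in% chain, , drop = FALSE]
  a <- a[a$elety %in% atom_set, , drop = FALSE]
  res_order <- match(reskey(a), unique(reskey(x$atoms)))
  a <- a[order(res_order, match(a$elety, BACKBONE_ATOMS)), , drop = FALSE]
  rownames(a) <- NULL
  a
}

#' Per-residue pLDDT of a structure
#'
#' The confidence of a residue is the B-factor of its CA atom; if CA is
#' absent, the mean B-factor over the residue's atoms.
#'
#' @param x an `ab_structure`.
#' @param chain optional chain id filter.
#' @return named numeric vector, one entry per residue in structure order,
#'   names `"chain:resno:icode"`.
#' @export
residue_plddt <- function(x, chain = NULL) {
  a <- x$atoms
  if (!is.null(chain)) a <- a[a$chain %in% chain, , drop = FALSE]
  if (nrow(a) == 0L) stop("no atoms: cannot compute residue pLDDT")
  rk <- reskey(a)
  keys <- unique(rk)
  out <- vapply(keys, function(k) {
    rows <- a[rk == k, , drop = FALSE]
    ca <- rows$b[rows$elety == "CA"]
    if (length(ca)) ca[1] else mean(rows$b)
  }, numeric(1))
  names(out) <- keys
  out
}

# ---- PDB parsing -----------------------------------------------------------

pdb_substr_num <- function(lines, from, to) {
  suppressWarnings(as.numeric(substr(lines, from, to)))
}

# parse ATOM/HETATM records from a character vector of PDB lines;
# `lineno` carries original file line numbers for error messages
parse_pdb_atoms <- function(lines, lineno, hetero = FALSE) {
  rec <- substr(lines, 1, 6)
  keep <- rec == "ATOM  " | (hetero & rec == "HETATM")
  ln <- lines[keep]
  lno <- lineno[keep]
  if (!length(ln)) {
    return(data.frame(eleno = integer(), elety = character(),
                      resid = character(), chain = character(),
                      resno = integer(), insert = character(),
                      x = numeric(), y = numeric(), z = numeric(),
                      o = numeric(), b = numeric(), elesy = character(),
                      stringsAsFactors = FALSE))
  }
  df <- data.frame(
    eleno  = as.integer(pdb_substr_num(ln, 7, 11)),
    elety  = trimws(substr(ln, 13, 16)),
    alt    = trimws(substr(ln, 17, 17)),
    resid  = trimws(substr(ln, 18, 20)),
    chain  = substr(ln, 22, 22),
    resno  = as.integer(pdb_substr_num(ln, 23, 26)),
    insert = trimws(substr(ln, 27, 27)),
    x      = pdb_substr_num(ln, 31, 38),
    y      = pdb_substr_num(ln, 39, 46),
    z      = pdb_substr_num(ln, 47, 54),
    o      = pdb_substr_num(ln, 55, 60),
    b      = pdb_substr_num(ln, 61, 66),
    elesy  = toupper(trimws(substr(ln, 77, 78))),
    stringsAsFactors = FALSE
  )
  bad <- which(!is.finite(df$x) | !is.finite(df$y) | !is.finite(df$z) |
                 is.na(df$resno))
  if (length(bad)) {
    stop("unparseable ATOM record at line ", lno[bad[1]], ": ",
         substr(ln[bad[1]], 1, 30))
  }
  df$o[is.na(df$o)] <- 1
  df$b[is.na(df$b)] <- 0
  # element fallback: first letter of the digit-stripped atom name
  noel <- !nzchar(df$elesy)
  df$elesy[noel] <- substr(gsub("[0-9']", "", df$elety[noel]), 1, 1)
  # hydrogens/deuterium dropped everywhere: predictions lack them and all
  # metrics (RMSD, clashes, contacts) are heavy-atom only
  df <- df[!(df$elesy %in% c("H", "D")), , drop = FALSE]
  # altloc: keep highest occupancy per atom identity, ties by altloc letter
  key <- atomkey(df)
  ord <- order(key, -df$o, df$alt)
  keep_rows <- sort(ord[!duplicated(key[ord])])
  df <- df[keep_rows, , drop = FALSE]
  df$alt <- NULL
  rownames(df) <- NULL
  df
}

# split PDB lines into per-model line index lists
pdb_model_blocks <- function(lines) {
  starts <- grep("^MODEL", lines)
  ends <- grep("^ENDMDL", lines)
  if (!length(starts)) return(list(seq_along(lines)))
  if (length(ends) < length(starts)) ends <- c(ends, length(lines) + 1L)
  mapply(function(s, e) seq(s, e), starts, ends, SIMPLIFY = FALSE)
}

#' Read a structure from a PDB file
#'
#' Reads one MODEL of a (possibly multi-model) PDB file. Hetero and solvent
#' records are excluded by default, hydrogens always. Insertion codes are
#' preserved; alternate locations are reduced to the highest-occupancy
#' conformer (ties broken by altloc letter).
#'
#' @param path PDB file path.
#' @param model_index 1-based MODEL to read (default: first).
#' @param hetero include HETATM records.
#' @return an `ab_structure`.
#' @export
read_structure <- function(path, model_index = NULL, hetero = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  blocks <- pdb_model_blocks(lines)
  if (is.null(model_index)) model_index <- 1L
  if (model_index < 1L || model_index > length(blocks)) {
    stop("model_index ", model_index, " out of range: file has ",
         length(blocks), " model(s)")
  }
  idx <- blocks[[model_index]]
  atoms <- parse_pdb_atoms(lines[idx], idx, hetero = hetero)
  if (nrow(atoms) == 0L) {
    stop("no ATOM records parsed from ", path, " (model ", model_index, ")")
  }
  new_structure(atoms, model_id = paste0("model", model_index), source = path)
}

#' Construct an ensemble of structures
#'
#' Members must share residue identities (chain, residue number, insertion
#' code) so that loop RMSDs across the ensemble are well defined.
#'
#' @param members list of `ab_structure`.
#' @param labels per-member identifiers (default `m001`, `m002`, ...).
#' @return object of class `ab_ensemble`.
#' @export
new_ensemble <- function(members, labels = NULL) {
  if (!length(members)) stop("ensemble must have at least one member")
  if (is.null(labels)) labels <- sprintf("m%03d", seq_along(members))
  if (length(labels) != length(members)) {
    stop("labels length must match member count")
  }
  if (anyDuplicated(labels)) stop("ensemble labels must be unique")
  ref_keys <- sort(reskey(members[[1]]$atoms))
  for (i in seq_along(members)[-1]) {
    if (!identical(sort(reskey(members[[i]]$atoms)), ref_keys)) {
      stop("ensemble member ", labels[i],
           " has residue identities inconsistent with member ", labels[1])
    }
  }
  structure(list(members = members, labels = labels), class = "ab_ensemble")
}

#' @export
print.ab_ensemble <- function(x, ...) {
  cat("ab_ensemble of", length(x$members), "members;",
      "chains:", paste(chain_ids(x$members[[1]]), collapse = ","), "\n")
  invisible(x)
}

#' @export
length.ab_ensemble <- function(x) length(x$members)

#' Subset an ensemble by member index
#' @param x an `ab_ensemble`.
#' @param i integer or logical index.
#' @param ... unused.
#' @export
`[.ab_ensemble` <- function(x, i, ...) {
  new_ensemble(x$members[i], labels = x$labels[i])
}

#' Read all models of a PDB file as an ensemble
#' @inheritParams read_structure
#' @return an `ab_ensemble`, one member per MODEL.
#' @export
read_ensemble <- function(path, hetero = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  blocks <- pdb_model_blocks(lines)
  members <- lapply(seq_along(blocks), function(i) {
    idx <- blocks[[i]]
    atoms <- parse_pdb_atoms(lines[idx], idx, hetero = hetero)
    if (nrow(atoms) == 0L) stop("model ", i, " of ", path, " has no atoms")
    new_structure(atoms, model_id = paste0("model", i), source = path)
  })
  new_ensemble(members, labels = sprintf("m%03d", seq_along(members)))
}

# ---- PDB writing -----------------------------------------------------------

format_atom_records <- function(atoms) {
  name_field <- ifelse(nchar(atoms$elety) >= 4L,
                       substr(atoms$elety, 1, 4),
                       sprintf(" %-3s", atoms$elety))
  sprintf("ATOM  %5d %4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          seq_len(nrow(atoms)) %% 100000L, name_field, atoms$resid,
          atoms$chain, atoms$resno,
          ifelse(nzchar(atoms$insert), atoms$insert, " "),
          atoms$x, atoms$y, atoms$z, atoms$o, atoms$b, atoms$elesy)
}

structure_lines <- function(x) {
  out <- character(0)
  for (cc in chain_ids(x)) {
    a <- x$atoms[x$atoms$chain == cc, , drop = FALSE]
    out <- c(out, format_atom_records(a), "TER")
  }
  out
}

#' Write a single structure to a PDB file
#' @param x an `ab_structure`.
#' @param path output file path.
#' @export
write_structure <- function(x, path) {
  writeLines(c(structure_lines(x), "END"), path)
  invisible(path)
}

#' Write an ensemble as a multi-model PDB file
#'
#' One MODEL/ENDMDL block per member, member order preserved; the B-factor
#' column carries each member's stored values (pLDDT for predictions), so the
#' file is exactly what an ensemble-docking engine consumes.
#'
#' @param ensemble an `ab_ensemble` (a single `ab_structure` is accepted and
#'   wrapped).
#' @param path output file path.
#' @export
write_ensemble <- function(ensemble, path) {
  if (inherits(ensemble, "ab_structure")) {
    ensemble <- new_ensemble(list(ensemble))
  }
  if (!inherits(ensemble, "ab_ensemble")) {
    stop("write_ensemble expects an ab_ensemble")
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(ensemble$members)) {
    writeLines(sprintf("MODEL %8d", i), con)
    writeLines(structure_lines(ensemble$members[[i]]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
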
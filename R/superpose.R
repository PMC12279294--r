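#' Root-mean-square deviation between paired coordinate sets
#' @param a,b n x 3 coordinate matrices, rows paired.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) stop("coordinate sets differ in size")
  sqrt(mean(rowSums((a - b)^2)))
}

#' Least-squares rigid superposition (Kabsch algorithm)
#'
#' Finds the proper rotation `R` and translation `t` minimising the RMSD
#' between `R %*% x + t` over the mobile points and the reference points.
#' Reflections are corrected via the sign of the determinant, so the result
#' is always a proper rotation (det +1).
#'
#' @param mobile n x 3 matrix of coordinates to move.
#' @param reference n x 3 matrix of target coordinates, rows paired with
#'   `mobile`.
#' @return object of class `superposition`: list with `rotation` (3 x 3),
#'   `translation` (length 3) and `fit_rmsd` (Angstrom over the fit atoms).
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference))) {
    stop("mobile and reference must have equal point counts")
  }
  if (nrow(mobile) < 3L) {
    stop("degenerate superposition: need at least 3 points")
  }
  if (any(!is.finite(mobile)) || any(!is.finite(reference))) {
    stop("non-finite coordinates in superposition input")
  }
  mc <- colMeans(mobile); rc <- colMeans(reference)
  M <- sweep(mobile, 2, mc); R0 <- sweep(reference, 2, rc)
  sm <- svd(M)$d
  if (sm[2] < 1e-8 * max(sm[1], 1e-12)) {
    warning("collinear point set: superposition is not unique, ",
            "returning a best-effort fit")
  }
  H <- crossprod(M, R0)            # 3x3 covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  U <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- as.numeric(rc - U %*% mc)
  fitted <- sweep(mobile %*% t(U), 2, tr, "+")
  structure(
    list(rotation = U, translation = tr, fit_rmsd = rmsd(fitted, reference)),
    class = "superposition"
  )
}

#' Apply a superposition transform to coordinates
#' @param coords n x 3 matrix.
#' @param sup a `superposition`.
#' @return transformed n x 3 matrix.
#' @export
apply_superposition <- function(coords, sup) {
  sweep(as.matrix(coords) %*% t(sup$rotation), 2, sup$translation, "+")
}

#' @export
print.superposition <- function(x, ...) {
  cat("superposition: fit RMSD", format(x$fit_rmsd, digits = 6), "A\n")
  invisible(x)
}
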
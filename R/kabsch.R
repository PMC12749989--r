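## Rigid transforms and Kabsch superposition -----------------------------

#' Rigid transform
#'
#' A proper rotation plus translation acting as `x -> R x + t` on column
#' 3-vectors (rows of a coordinate matrix are transformed as
#' `X %*% t(R) + t`).
#'
#' @param R 3x3 proper orthogonal matrix.
#' @param t Length-3 translation (Angstrom).
#' @param tol Orthogonality/determinant tolerance.
#' @return A list of class `rigid_transform`.
#' @export
rigid_transform <- function(R = diag(3), t = c(0, 0, 0), tol = 1e-9) {
  R <- unname(as.matrix(R)); t <- as.numeric(t)
  if (any(abs(crossprod(R) - diag(3)) > 1e-6))
    abort("rotation is not orthogonal", class = "rnd_geometry_error")
  if (det(R) < 0)
    abort("rotation is improper (det < 0)", class = "rnd_geometry_error")
  structure(list(R = R, t = t), class = "rigid_transform")
}

#' Apply a rigid transform to coordinates
#'
#' @param xyz n x 3 matrix (or a `struct_tbl`).
#' @param tf A `rigid_transform`.
#' @return Transformed coordinates (same type as input).
#' @export
apply_transform <- function(xyz, tf) {
  if (inherits(xyz, "struct_tbl"))
    return(set_coords(xyz, apply_transform(coords(xyz), tf)))
  sweep(xyz %*% t(tf$R), 2, tf$t, "+")
}

#' Invert a rigid transform
#' @param tf A `rigid_transform`.
#' @return The inverse transform.
#' @export
invert_transform <- function(tf)
  rigid_transform(t(tf$R), -as.numeric(t(tf$R) %*% tf$t))

#' Compose rigid transforms
#' @param a,b Transforms; the result applies `b` first, then `a`.
#' @return A `rigid_transform`.
#' @export
compose_transform <- function(a, b)
  rigid_transform(a$R %*% b$R, as.numeric(a$R %*% b$t) + a$t)

#' Rotation angle of a rotation matrix
#'
#' Trace formula with the argument clamped to `[-1, 1]` for numerical
#' safety.
#'
#' @param R 3x3 rotation matrix.
#' @return Angle in degrees, in `[0, 180]`.
#' @export
rotation_angle <- function(R) {
  ct <- (sum(diag(R)) - 1) / 2
  acos(min(1, max(-1, ct))) * 180 / pi
}

#' Rotation axis of a rotation matrix
#'
#' Unit axis oriented so the rotation is by a positive angle (right-hand
#' rule) about the returned direction.
#'
#' @param R 3x3 rotation matrix.
#' @return Unit 3-vector.
#' @export
rotation_axis <- function(R) {
  v <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  n <- sqrt(sum(v^2))
  if (n > 1e-8) return(v / n)
  ## angle near 0 or 180: take the eigenvector of eigenvalue +1
  e <- eigen(R)
  i <- which.min(abs(e$values - 1))
  ax <- Re(e$vectors[, i])
  ax / sqrt(sum(ax^2))
}

#' Rotation matrix about an axis (Rodrigues)
#'
#' @param axis Direction 3-vector (normalised internally).
#' @param angle_deg Angle in degrees (right-hand rule).
#' @return 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

## matrix-level Kabsch: least-squares proper rotation + translation taking
## mobile P onto target Q (both n x 3); returns list(R, t, rmsd)
kabsch_mats <- function(P, Q) {
  pc <- colMeans(P); qc <- colMeans(Q)
  Pc <- sweep(P, 2, pc); Qc <- sweep(Q, 2, qc)
  H <- crossprod(Pc, Qc)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t <- qc - as.numeric(R %*% pc)
  D <- Pc %*% t(R) - Qc
  list(R = R, t = t, rmsd = sqrt(mean(rowSums(D^2))))
}

## deterministic atom correspondence between two structures
## policy "calpha": shared CA by (mapped chain, resno, insert)
## policy "all":    shared heavy atoms by (mapped chain, resno, insert, atom)
correspondence <- function(mobile, target, selection = "calpha",
                           chain_map = NULL) {
  m <- heavy(mobile); t <- heavy(target)
  if (selection == "calpha") {
    m <- m[m$atom == "CA", , drop = FALSE]
    t <- t[t$atom == "CA", , drop = FALSE]
  }
  if (is.null(chain_map)) {
    mc <- unique(m$chain); tc <- unique(t$chain)
    chain_map <- if (length(mc) == 1 && length(tc) == 1) setNames(tc, mc)
                 else setNames(intersect(mc, tc), intersect(mc, tc))
  }
  m <- m[m$chain %in% names(chain_map), , drop = FALSE]
  m$.tchain <- unname(chain_map[m$chain])
  keym <- if (selection == "calpha") paste(m$.tchain, m$resno, m$insert)
          else paste(m$.tchain, m$resno, m$insert, m$atom)
  keyt <- if (selection == "calpha") paste(t$chain, t$resno, t$insert)
          else paste(t$chain, t$resno, t$insert, t$atom)
  i <- match(keyt, keym)
  keep <- which(!is.na(i))
  ord <- order(keyt[keep])
  list(mobile = coords(m)[i[keep][ord], , drop = FALSE],
       target = coords(t)[keep[ord], , drop = FALSE],
       n = length(keep))
}

#' Kabsch superposition of two structures
#'
#' Finds the least-squares proper rotation and translation mapping the
#' mobile structure onto the target over a deterministic atom
#' correspondence, and reports the post-fit RMSD. The default policy pairs
#' shared C-alpha atoms by residue number (with an optional chain mapping);
#' `"all"` pairs all shared heavy atoms. No improper (mirror) fit is ever
#' returned.
#'
#' @param mobile,target Structure tables.
#' @param selection `"calpha"` (default) or `"all"`.
#' @param chain_map Named character vector mapping mobile chain ids to
#'   target chain ids; defaults to the identity (or the single chain pair).
#' @return A list of class `kabsch_fit`: `transform` (a
#'   [rigid_transform()]), `rmsd` (Angstrom), `n_atoms`.
#' @export
kabsch_superpose <- function(mobile, target, selection = c("calpha", "all"),
                             chain_map = NULL) {
  selection <- match.arg(selection)
  cp <- correspondence(mobile, target, selection, chain_map)
  if (cp$n < 3)
    abort(paste0("insufficient correspondences (", cp$n, " < 3)"),
          class = "rnd_correspondence_error")
  k <- kabsch_mats(cp$mobile, cp$target)
  structure(list(transform = rigid_transform(k$R, k$t), rmsd = k$rmsd,
                 n_atoms = cp$n, selection = selection),
            class = "kabsch_fit")
}

#' @export
print.kabsch_fit <- function(x, ...) {
  cat(sprintf("# Kabsch fit (%s): rmsd %.4f A over %d atoms, rotation %.2f deg\n",
              x$selection, x$rmsd, x$n_atoms, rotation_angle(x$transform$R)))
  invisible(x)
}
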
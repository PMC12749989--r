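## C3 axis estimation and symmetry expansion -----------------------------

#' Estimate the pseudo-C3 symmetry axis of a trimer
#'
#' The axis direction is the rotation axis of the best proper rotation
#' (Kabsch) mapping the first chain onto the second, oriented so that the
#' chain-1 to chain-2 rotation is by a positive angle (right-hand rule);
#' with that convention the three chains appear in counter-clockwise order
#' viewed down the +axis. The axis point is the centroid of the three chain
#' centroids over their shared atoms. If the chain-to-chain rotation angle
#' deviates from 360/order degrees by more than `tol` degrees, a
#' pseudo-symmetry-violation warning is attached to the result.
#'
#' @param trimer Structure table containing the three chains.
#' @param chains Character vector of three chain ids, in symmetry order.
#' @param order Symmetry order (3).
#' @param tol Pseudo-symmetry angle tolerance, degrees.
#' @return A list of class `symmetry_frame`: `axis_point`,
#'   `axis_direction` (unit vector), `order`, `angle` (chain 1 to 2
#'   rotation, degrees), `warning` (`NULL` or a message).
#' @export
estimate_symmetry_axis <- function(trimer, chains, order = 3L, tol = 15) {
  if (length(chains) != order)
    abort(paste0("need ", order, " chain ids"), class = "rnd_arity_error")
  sub <- lapply(chains, function(ch) {
    s <- heavy(trimer[trimer$chain == ch, , drop = FALSE])
    if (!nrow(s)) abort(paste0("chain not found: ", ch), class = "rnd_geometry_error")
    s
  })
  ## shared (resno, insert, atom) across all chains
  keys <- lapply(sub, function(s) paste(s$resno, s$insert, s$atom))
  shared <- Reduce(intersect, keys)
  if (length(shared) < 3)
    abort("chains share fewer than 3 (residue, atom) pairs",
          class = "rnd_correspondence_error")
  shared <- sort(shared)
  mats <- Map(function(s, k) coords(s)[match(shared, k), , drop = FALSE], sub, keys)
  k <- kabsch_mats(mats[[1]], mats[[2]])
  axis <- rotation_axis(k$R)
  angle <- rotation_angle(k$R)
  centroids <- vapply(mats, colMeans, numeric(3))
  point <- unname(rowMeans(centroids))
  warning_msg <- NULL
  if (abs(angle - 360 / order) > tol) {
    warning_msg <- sprintf(
      "pseudo-symmetry violation: chain 1 to 2 rotation is %.1f deg (expected %.1f +/- %.1f)",
      angle, 360 / order, tol)
    warn(warning_msg)
  }
  structure(list(axis_point = point, axis_direction = axis,
                 order = as.integer(order), angle = angle,
                 warning = warning_msg),
            class = "symmetry_frame")
}

#' @export
print.symmetry_frame <- function(x, ...) {
  cat(sprintf("# C%d symmetry frame: axis (%.3f, %.3f, %.3f) through (%.2f, %.2f, %.2f), chain rotation %.2f deg\n",
              x$order, x$axis_direction[1], x$axis_direction[2],
              x$axis_direction[3], x$axis_point[1], x$axis_point[2],
              x$axis_point[3], x$angle))
  if (!is.null(x$warning)) cat("#  warning:", x$warning, "\n")
  invisible(x)
}

#' Symmetry-expand a trimer into aligned monomers
#'
#' Rotates chain k (k = 0, 1, 2) by `-k * 360/order` degrees about the
#' symmetry axis so that all three monomers land at the same position (the
#' coordinate-space analogue of symmetry expansion of particles). For an
#' exactly symmetric trimer the three outputs coincide.
#'
#' @param trimer Structure table.
#' @param frame A `symmetry_frame` from [estimate_symmetry_axis()].
#' @param chains Three chain ids in symmetry order (chain k has copy index
#'   k).
#' @param particle_id Identifier tagged onto the output; defaults to the
#'   trimer's model id.
#' @return A tibble of atom records with additional columns `particle_id`
#'   and `copy_index` (0, 1, 2); each copy keeps its source chain id in
#'   `source_chain` and is re-chained to `"A"` for downstream comparison.
#' @export
symmetry_expand <- function(trimer, frame, chains,
                            particle_id = attr(trimer, "model_id") %||% "particle") {
  if (frame$order != length(chains))
    abort(paste0("frame order ", frame$order, " != ", length(chains),
                 " chains supplied"), class = "rnd_arity_error")
  step <- 360 / frame$order
  out <- purrr::imap(chains, function(ch, i) {
    k <- i - 1L
    s <- trimer[trimer$chain == ch, , drop = FALSE]
    if (!nrow(s)) abort(paste0("chain not found: ", ch), class = "rnd_geometry_error")
    R <- rotation_about_axis(frame$axis_direction, -k * step)
    xyz <- sweep(coords(s), 2, frame$axis_point)
    xyz <- sweep(xyz %*% t(R), 2, frame$axis_point, "+")
    s <- set_coords(s, xyz)
    s$particle_id <- particle_id
    s$copy_index <- k
    s$source_chain <- s$chain
    s$chain <- "A"
    s
  })
  dplyr::bind_rows(out)
}

#' Split expanded monomers into a list of structures
#'
#' @param expanded Output of [symmetry_expand()].
#' @return Named list (by copy index) of `struct_tbl`.
#' @export
expanded_monomers <- function(expanded) {
  ks <- sort(unique(expanded$copy_index))
  setNames(lapply(ks, function(k) {
    s <- expanded[expanded$copy_index == k, , drop = FALSE]
    pid <- s$particle_id[1]
    s$particle_id <- NULL; s$copy_index <- NULL; s$source_chain <- NULL
    as_structure(s, model_id = paste0(pid, "_", k))
  }), as.character(ks))
}
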
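## Synthetic data generation ---------------------------------------------
##
## Stand-in for the cryo-EM particle stacks: abstract labelled point-cloud
## templates per state (not real protein geometry), trimer particles drawn
## from a known composition distribution with optional coordinate noise, a
## label-misclassification channel, and analytic channel fixtures. All
## generators are pure functions of (spec, seed).

#' Template geometry parameters
#'
#' The synthetic monomer is a labelled point cloud: a 30-atom helical core
#' (the superposition anchor, standing in for the transmembrane domain),
#' four 12-atom porter subdomain clusters (PN1/PN2/PC1/PC2) at 16 Angstrom
#' above the core, and optionally an engineered blind exit pore (a capped
#' tube of wall atoms) whose clear radius is known by construction. States
#' differ by rigid subdomain shifts of 4-5 Angstrom, giving pairwise
#' porter C-alpha RMSDs of 2.8-4.3 Angstrom; O* equals O plus a
#' constriction ring narrowing the pore below the O* threshold.
#'
#' @param core_n Core atom count.
#' @param cluster_n Atoms per porter subdomain cluster.
#' @param state_shifts Named list (state -> named list of subdomain shift
#'   3-vectors, Angstrom). `L` is the unshifted base.
#' @param with_exit_pore Attach the engineered exit pore (forced on when an
#'   `O*` template is requested).
#' @param pore_radius Clear radius of the open exit pore, Angstrom.
#' @param constrict_radius Clear radius of the O* constriction, Angstrom.
#' @param placement_radius Distance of each monomer from the trimer axis.
#' @return A list of class `template_geometry`.
#' @export
template_geometry <- function(core_n = 30L, cluster_n = 12L,
                              state_shifts = list(
                                L = list(),
                                T = list(PN2 = c(4, 0, 0), PC2 = c(0, 4, 0)),
                                O = list(PN1 = c(0, 0, 5), PC1 = c(3, 3, 0))),
                              with_exit_pore = FALSE,
                              pore_radius = 2.5, constrict_radius = 1.2,
                              placement_radius = 14) {
  structure(list(core_n = as.integer(core_n), cluster_n = as.integer(cluster_n),
                 state_shifts = state_shifts, with_exit_pore = with_exit_pore,
                 pore_radius = pore_radius, constrict_radius = constrict_radius,
                 placement_radius = placement_radius),
            class = "template_geometry")
}

#' Synthetic dataset specification
#'
#' @param composition Named probabilities over canonical composition names
#'   (aliases accepted), summing to 1 within 1e-9.
#' @param n_particles Number of trimer particles (>= 1).
#' @param coord_noise_sd I.i.d. Gaussian noise per coordinate, Angstrom.
#' @param label_confusion Optional square row-stochastic matrix over states
#'   (rows: true state, columns: reported label).
#' @param seed Integer seed; generators are pure functions of (spec, seed).
#' @param template A [template_geometry()].
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(composition, n_particles,
                           coord_noise_sd = 0, label_confusion = NULL,
                           seed = 1L, template = template_geometry()) {
  p <- unlist(composition)
  names(p) <- vapply(names(p), canonical_composition, character(1))
  if (anyDuplicated(names(p))) {
    merged <- tapply(p, names(p), sum)
    p <- setNames(as.numeric(merged), names(merged))
  }
  if (abs(sum(p) - 1) > 1e-9)
    abort("composition probabilities must sum to 1", class = "rnd_config_error")
  if (any(p < 0)) abort("negative composition probability", class = "rnd_config_error")
  if (n_particles < 1) abort("n_particles must be >= 1", class = "rnd_config_error")
  if (coord_noise_sd < 0) abort("coord_noise_sd must be >= 0", class = "rnd_config_error")
  if (!is.null(label_confusion)) {
    if (nrow(label_confusion) != ncol(label_confusion) ||
        is.null(rownames(label_confusion)) ||
        !identical(rownames(label_confusion), colnames(label_confusion)) ||
        any(abs(rowSums(label_confusion) - 1) > 1e-9))
      abort("label_confusion must be square, named and row-stochastic",
            class = "rnd_config_error")
  }
  structure(list(composition = p, n_particles = as.integer(n_particles),
                 coord_noise_sd = coord_noise_sd,
                 label_confusion = label_confusion,
                 seed = as.integer(seed), template = template),
            class = "synthetic_spec")
}

## subdomain scheme matching the synthetic template numbering
synthetic_scheme <- function(template = template_geometry()) {
  cn <- template$core_n; kn <- template$cluster_n
  starts <- cn + 1L + kn * (0:3)
  subdomain_scheme(
    core = seq_len(cn),
    PN1 = seq(starts[1], length.out = kn),
    PN2 = seq(starts[2], length.out = kn),
    PC1 = seq(starts[3], length.out = kn),
    PC2 = seq(starts[4], length.out = kn),
    exit_seed = cn + 4L * kn + (2:4))
}

## a small cluster of points centred at `centre`
point_cluster <- function(n, centre, spacing = 1.5) {
  g <- as.matrix(expand.grid(x = 0:2, y = 0:1, z = 0:1)) * spacing
  g <- g[seq_len(n), , drop = FALSE]
  sweep(g, 2, colMeans(g)) + matrix(centre, n, 3, byrow = TRUE)
}

## ring of atoms at radius r in the plane z = z0
shell_ring <- function(z0, r, step = 0.9) {
  m <- max(6L, ceiling(2 * pi * r / step))
  th <- 2 * pi * (seq_len(m) - 1) / m
  cbind(r * cos(th), r * sin(th), z0)
}

## filled disk of atoms at height z0 out to r_max
floor_disk <- function(z0, r_max, step = 0.8) {
  rows <- list(cbind(0, 0, z0))
  for (r in seq(step, r_max, by = step)) rows <- c(rows, list(shell_ring(z0, r, step)))
  do.call(rbind, rows)
}

## capped (blind) tube of wall atoms: shell from z0 to z1 plus a floor at
## z0; clear radius on the axis is r_clear. vdW carbon radius 1.7 A.
blind_tube <- function(r_clear, z0, z1, rvdw = 1.7) {
  shell <- do.call(rbind, lapply(seq(z0, z1, by = 0.5), shell_ring,
                                 r = r_clear + rvdw))
  rbind(shell, floor_disk(z0, r_clear + rvdw - 0.4))
}

## base monomer template for one state: returns a struct_tbl
state_template <- function(state, template) {
  cn <- template$core_n; kn <- template$cluster_n
  th <- 2 * pi * 3 * (seq_len(cn) - 1) / cn
  core <- cbind(4 * cos(th), 4 * sin(th), 10 * (seq_len(cn) - 1) / (cn - 1))
  centres <- list(PN1 = c(6, 0, 16), PN2 = c(-6, 0, 16),
                  PC1 = c(0, 6, 16), PC2 = c(0, -6, 16))
  shifts <- template$state_shifts[[if (state == "O*") "O" else state]] %||% list()
  clusters <- lapply(names(centres), function(nm) {
    sh <- shifts[[nm]] %||% c(0, 0, 0)
    point_cluster(kn, centres[[nm]] + sh)
  })
  xyz <- rbind(core, do.call(rbind, clusters))
  resno <- c(seq_len(cn), cn + seq_len(4L * kn))
  resname <- c(rep("COR", cn),
               rep(c("PN1", "PN2", "PC1", "PC2"), each = kn))
  need_pore <- template$with_exit_pore || state == "O*"
  if (need_pore) {
    rs <- template$pore_radius + 1.7
    gate <- cbind(rs * cos(c(pi / 2, pi / 2 + 2 * pi / 3, pi / 2 + 4 * pi / 3)),
                  rs * sin(c(pi / 2, pi / 2 + 2 * pi / 3, pi / 2 + 4 * pi / 3)),
                  29)
    wall <- blind_tube(template$pore_radius, 24, 34)
    if (state == "O*")
      wall <- rbind(wall, shell_ring(31.5, template$constrict_radius + 1.7))
    gate_res <- cn + 4L * kn + (2:4)
    xyz <- rbind(xyz, gate, wall)
    resno <- c(resno, gate_res, max(gate_res) + 20L + seq_len(nrow(wall)))
    resname <- c(resname, rep("GAT", 3), rep("WAL", nrow(wall)))
  }
  as_structure(tibble(chain = "A", resno = resno, resname = resname,
                      atom = "CA", element = "C",
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      occ = 1, b = 0),
               model_id = paste0("template_", state))
}

#' Build a synthetic reference-state library
#'
#' Generates the L/T/O (and, when needed, O*) template structures defined
#' by the spec's template geometry, together with the matching subdomain
#' scheme. Deterministic under the spec seed (the geometry itself is
#' seed-free). If the inter-state porter RMSD falls below four times the
#' expected noise RMSD (`coord_noise_sd * sqrt(6)`) a separability warning
#' is raised.
#'
#' @param spec A [synthetic_spec()] (or a bare [template_geometry()]).
#' @param states States to include; defaults to the states appearing in
#'   the spec composition plus the classification references L, T, O.
#' @return A [reference_library()] with a `porter_rmsd` attribute (pairwise
#'   matrix for L/T/O).
#' @export
make_reference_library <- function(spec = synthetic_spec(c(LTO = 1), 1),
                                   states = NULL) {
  template <- if (inherits(spec, "template_geometry")) spec else spec$template
  comp_states <- if (inherits(spec, "synthetic_spec"))
    unique(unlist(lapply(names(spec$composition), comp_tokens))) else character()
  states <- states %||% union(c("L", "T", "O"), comp_states)
  states <- states[order(match(states, STATES))]
  refs <- setNames(lapply(states, state_template, template = template), states)
  lib <- reference_library(refs, synthetic_scheme(template))
  base <- intersect(c("L", "T", "O"), states)
  pr <- matrix(0, length(base), length(base), dimnames = list(base, base))
  sch <- lib$scheme
  for (i in seq_along(base)) for (j in seq_along(base)) if (i < j) {
    a <- ca_by_resno(refs[[base[i]]], porter_residues(sch))$xyz
    b <- ca_by_resno(refs[[base[j]]], porter_residues(sch))$xyz
    pr[i, j] <- pr[j, i] <- sqrt(mean(rowSums((a - b)^2)))
  }
  noise <- if (inherits(spec, "synthetic_spec")) spec$coord_noise_sd else 0
  offdiag <- pr[upper.tri(pr)]
  if (length(offdiag) && noise > 0 && min(offdiag) < 4 * noise * sqrt(6))
    warn(sprintf("states not separable at requested noise: min porter RMSD %.2f < 4 * %.2f",
                 min(offdiag), noise * sqrt(6)))
  attr(lib, "porter_rmsd") <- pr
  lib
}

## random proper rotations via normalised quaternions
rand_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Simulate trimer particles with known composition truth
#'
#' Per particle: draws a composition from the spec distribution, assigns
#' its three states to copy indices 0/1/2 uniformly at random, places each
#' state template at 0/120/240 degrees about a common z axis (offset by the
#' template placement radius), applies a random global rigid transform, and
#' adds i.i.d. Gaussian coordinate noise. The truth table records the
#' generating labels. Reproducible under the spec seed.
#'
#' @param spec A [synthetic_spec()].
#' @param library Optional [reference_library()]; defaults to
#'   `make_reference_library(spec)`. Every state in the composition must
#'   have a template.
#' @return A list: `structures` (one atom tibble with `particle_id` and
#'   `chain` A/B/C = copy 0/1/2) and `truth` (a label table).
#' @export
simulate_particles <- function(spec, library = make_reference_library(spec)) {
  set.seed(spec$seed)
  comp_states_all <- unique(unlist(lapply(names(spec$composition), comp_tokens)))
  missing_states <- setdiff(comp_states_all, names(library$states))
  if (length(missing_states))
    abort(paste0("composition references state(s) absent from library: ",
                 paste(missing_states, collapse = ", ")),
          class = "rnd_config_error")
  n <- spec$n_particles
  comp_draw <- sample(names(spec$composition), n, replace = TRUE,
                      prob = spec$composition)
  ## state of (particle, copy): composition multiset in random copy order
  state_mat <- t(vapply(comp_draw, function(cm) sample(comp_tokens(cm)),
                        character(3)))
  dimnames(state_mat) <- NULL
  pid <- sprintf("P%06d", seq_len(n))
  ## stacked template coordinates/metadata, indexed per state
  used_states <- sort(unique(as.vector(state_mat)))
  temps <- lapply(setNames(used_states, used_states),
                  function(s) library$states[[s]])
  tsize <- vapply(temps, nrow, integer(1))
  toffset <- c(0L, cumsum(tsize))[seq_along(tsize)]
  names(toffset) <- used_states
  meta_all <- dplyr::bind_rows(lapply(temps, function(s) {
    s[, c("resno", "resname", "atom", "element")]
  }))
  txyz <- lapply(temps, coords)
  off <- spec$template$placement_radius
  rot120 <- lapply(0:2, function(k) rotation_about_axis(c(0, 0, 1), 120 * k))
  ## per-copy template rows and transformed coordinates
  state_seq <- as.vector(t(state_mat))              # particle-major, copy 0..2
  copy_rows <- tsize[state_seq]
  total <- sum(copy_rows)
  xyz <- matrix(0, total, 3)
  idx <- integer(total)
  pos <- 0L
  for (i in seq_len(n)) {
    Rg <- rand_rotation()
    tg <- runif(3, -20, 20)
    for (k in 0:2) {
      s <- state_mat[i, k + 1]
      m <- tsize[s]
      base <- txyz[[s]]
      placed <- sweep(base, 2, c(off, 0, 0), "+") %*% t(rot120[[k + 1]])
      placed <- sweep(placed %*% t(Rg), 2, tg, "+")
      xyz[pos + seq_len(m), ] <- placed
      idx[pos + seq_len(m)] <- toffset[s] + seq_len(m)
      pos <- pos + m
    }
  }
  if (spec$coord_noise_sd > 0)
    xyz <- xyz + rnorm(length(xyz), sd = spec$coord_noise_sd)
  structures <- meta_all[idx, ]
  structures$x <- xyz[, 1]; structures$y <- xyz[, 2]; structures$z <- xyz[, 3]
  structures$occ <- 1; structures$b <- 0
  structures$particle_id <- rep(rep(pid, each = 3), times = copy_rows)
  structures$chain <- rep(rep(c("A", "B", "C"), times = n), times = copy_rows)
  structures <- structures[, c("particle_id", "chain", "resno", "resname",
                               "atom", "element", "x", "y", "z", "occ", "b")]
  truth <- validate_labels(tibble(
    particle_id = rep(pid, each = 3),
    copy_index = rep(0:2, times = n),
    state_label = as.vector(t(state_mat))))
  list(structures = as_tibble(structures), truth = truth)
}

#' One particle's trimer as a structure table
#'
#' @param structures The `structures` tibble from [simulate_particles()].
#' @param particle_id Particle to extract.
#' @return A `struct_tbl` with chains A/B/C.
#' @export
particle_structure <- function(structures, particle_id) {
  s <- structures[structures$particle_id == particle_id, , drop = FALSE]
  if (!nrow(s)) abort(paste0("unknown particle: ", particle_id),
                      class = "rnd_io_error")
  s$particle_id <- NULL
  as_structure(s, model_id = particle_id)
}

#' Corrupt truth labels through a confusion channel
#'
#' Each label is independently resampled from its row of the confusion
#' matrix; the identity matrix returns the input unchanged. Reproducible
#' under the seed.
#'
#' @param truth A label table.
#' @param confusion Square row-stochastic matrix with identical row and
#'   column names (states).
#' @param seed Integer seed.
#' @return A label table of the same shape.
#' @export
corrupt_labels <- function(truth, confusion, seed = 1L) {
  truth <- validate_labels(truth)
  if (any(abs(rowSums(confusion) - 1) > 1e-9) ||
      !identical(rownames(confusion), colnames(confusion)))
    abort("confusion matrix must be row-stochastic with matching dimnames",
          class = "rnd_config_error")
  set.seed(seed)
  out <- truth$state_label
  for (s in rownames(confusion)) {
    i <- which(truth$state_label == s)
    if (length(i))
      out[i] <- sample(colnames(confusion), length(i), replace = TRUE,
                       prob = confusion[s, ])
  }
  truth$state_label <- out
  truth
}

#' Analytic channel fixtures
#'
#' Engineered wall-atom geometries with a known clear radius, for
#' validating the channel search: a through `"cylinder"` (constant clear
#' radius), a blind `"cone"` (sealed at the wide end so the widest escape
#' runs through the narrow end, whose radius is the analytic bottleneck),
#' and a `"sealed"` cavity with no exit. The documented seed point is
#' attached as the `"seed_point"` attribute.
#'
#' @param kind `"cylinder"`, `"cone"` or `"sealed"`.
#' @param radius Clear radius, Angstrom (the narrow-end radius for
#'   `"cone"`).
#' @param radius_wide Wide-end clear radius for `"cone"`.
#' @param length Tube length, Angstrom.
#' @return A `struct_tbl` of wall atoms with attribute `seed_point`.
#' @export
make_channel_fixture <- function(kind = c("cylinder", "cone", "sealed"),
                                 radius = 3, radius_wide = 4, length = 10) {
  kind <- match.arg(kind)
  if (kind != "sealed" && radius <= 0)
    abort("radius must be > 0 for open fixtures", class = "rnd_config_error")
  if (radius < 0.8)
    warn("fixture radius below the default grid spacing; bottleneck may not resolve")
  rv <- 1.7
  if (kind == "cylinder") {
    xyz <- do.call(rbind, lapply(seq(0, length, by = 0.5), shell_ring,
                                 r = radius + rv))
    seed <- c(0, 0, length / 2)
  } else if (kind == "cone") {
    len <- max(length, 14)
    zs <- seq(0, len, by = 0.5)
    rz <- radius_wide + (radius - radius_wide) * zs / len
    xyz <- do.call(rbind, Map(function(z, r) shell_ring(z, r + rv), zs, rz))
    xyz <- rbind(xyz, floor_disk(0, radius_wide + rv - 0.4))
    seed <- c(0, 0, 4)
  } else {
    xyz <- blind_tube(max(radius, 2), 0, length)
    xyz <- rbind(xyz, floor_disk(length, max(radius, 2) + rv - 0.4))
    seed <- c(0, 0, length / 2)
  }
  s <- as_structure(tibble(chain = "W", resno = seq_len(nrow(xyz)),
                           resname = "WAL", atom = "C", element = "C",
                           x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                           occ = 1, b = 0),
                    model_id = paste0("fixture_", kind))
  attr(s, "seed_point") <- seed
  s
}
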
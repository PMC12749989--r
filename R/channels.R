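## Clearance grids and maximin channel search ----------------------------
##
## Simplified channel finding: a regular grid of clearance values
## (distance to the nearest atom surface), an exterior mask (solvent
## connected to the box boundary), and a widest-path search from an
## interior seed to the exterior. The bottleneck objective matches the
## notion of a channel bottleneck radius; it is a deliberate
## simplification of Voronoi-based channel finders.

#' Build a clearance grid over a structure
#'
#' Clearance at a grid node is `min over atoms of (distance - r_vdw)`,
#' computed exactly (block-wise evaluation; the result is independent of
#' the blocking). The grid covers the atom bounding box plus `padding` on
#' every side. Exterior nodes are those connected to the box boundary
#' through nodes with clearance at least `probe`; boundary nodes are always
#' exterior.
#'
#' @param structure Structure table (hydrogens are ignored).
#' @param spacing Grid spacing, Angstrom, in (0.2, 2].
#' @param radius_table Named element-to-radius vector (see [vdw_radii()]).
#' @param padding Bounding-box padding, Angstrom.
#' @param probe Probe radius for exterior connectivity, Angstrom.
#' @return A list of class `clearance_grid`: `origin`, `spacing`, `dims`,
#'   `clearance` (3d array, Angstrom), `exterior` (3d logical array),
#'   `probe`.
#' @export
build_clearance_grid <- function(structure, spacing = 0.8,
                                 radius_table = vdw_radii(),
                                 padding = 6, probe = 3.0) {
  s <- heavy(structure)
  if (!nrow(s)) abort("empty structure", class = "rnd_empty_structure")
  if (spacing <= 0.2 || spacing > 2)
    abort("spacing must be in (0.2, 2] Angstrom", class = "rnd_config_error")
  at <- coords(s)
  rv <- lookup_radii(s$element, radius_table)
  lo <- apply(at, 2, min) - padding
  hi <- apply(at, 2, max) + padding
  dims <- pmax(2L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  ax <- lapply(1:3, function(d) lo[d] + spacing * (seq_len(dims[d]) - 1))
  clearance <- array(NA_real_, dims)
  ## node coordinates, blocked along z-slabs to bound memory
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  xy <- cbind(rep(ax[[1]], times = ny), rep(ax[[2]], each = nx))
  zblock <- max(1L, as.integer(2e6 / (nx * ny)))
  for (z0 in seq(1L, nz, by = zblock)) {
    zi <- z0:min(nz, z0 + zblock - 1L)
    px <- rep(xy[, 1], times = length(zi))
    py <- rep(xy[, 2], times = length(zi))
    pz <- rep(ax[[3]][zi], each = nx * ny)
    mind <- rep(Inf, length(px))
    for (j in seq_len(nrow(at))) {
      d <- sqrt((px - at[j, 1])^2 + (py - at[j, 2])^2 + (pz - at[j, 3])^2) - rv[j]
      mind <- pmin(mind, d)
    }
    clearance[, , zi] <- mind
  }
  ## exterior: flood from the box boundary through clearance >= probe
  passable <- clearance >= probe
  boundary <- array(FALSE, dims)
  boundary[c(1, nx), , ] <- TRUE
  boundary[, c(1, ny), ] <- TRUE
  boundary[, , c(1, nz)] <- TRUE
  seeds <- which(boundary & passable)
  exterior <- flood_fill(dims, passable, seeds)
  exterior[boundary] <- TRUE
  structure(list(origin = lo, spacing = spacing, dims = dims,
                 clearance = clearance, exterior = exterior, probe = probe),
            class = "clearance_grid")
}

#' @export
print.clearance_grid <- function(x, ...) {
  cat(sprintf("# clearance grid %d x %d x %d, spacing %.2f A, %.1f%% exterior\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing,
              100 * mean(x$exterior)))
  invisible(x)
}

## 26-connected flood fill over `passable` from linear-index seeds;
## returns logical array of reached nodes
flood_fill <- function(dims, passable, seeds) {
  visited <- array(FALSE, dims)
  if (!length(seeds)) return(visited)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  visited[seeds] <- TRUE
  frontier <- seeds
  nx <- dims[1]; ny <- dims[2]
  while (length(frontier)) {
    ijk <- arrayInd(frontier, dims)
    cand_i <- rep(ijk[, 1], times = 26) + rep(offs[, 1], each = length(frontier))
    cand_j <- rep(ijk[, 2], times = 26) + rep(offs[, 2], each = length(frontier))
    cand_k <- rep(ijk[, 3], times = 26) + rep(offs[, 3], each = length(frontier))
    ok <- cand_i >= 1 & cand_i <= dims[1] & cand_j >= 1 & cand_j <= dims[2] &
      cand_k >= 1 & cand_k <= dims[3]
    lin <- (cand_k[ok] - 1L) * (nx * ny) + (cand_j[ok] - 1L) * nx + cand_i[ok]
    lin <- unique(lin[passable[lin] & !visited[lin]])
    visited[lin] <- TRUE
    frontier <- lin
  }
  visited
}

## nearest grid node (linear index) to a point; error if outside the box
node_at <- function(grid, point) {
  ijk <- round((point - grid$origin) / grid$spacing) + 1
  if (any(ijk < 1) || any(ijk > grid$dims))
    abort("seed point outside the clearance grid", class = "rnd_geometry_error")
  as.integer((ijk[3] - 1) * grid$dims[1] * grid$dims[2] +
               (ijk[2] - 1) * grid$dims[1] + ijk[1])
}

node_coords <- function(grid, lin) {
  ijk <- arrayInd(lin, grid$dims)
  sweep((ijk - 1) * grid$spacing, 2, grid$origin, "+")
}

#' Find the widest channel from a seed to the exterior
#'
#' Maximin (widest-path) search: among all 26-connected grid paths from the
#' seed node to any exterior node, returns one maximising the minimum
#' clearance along the path (the bottleneck radius); among equal-bottleneck
#' paths the node count is minimised and remaining ties are broken by node
#' index order, so the result is fully deterministic. If the exterior
#' cannot be reached with strictly positive clearance everywhere, the best
#' achievable bottleneck is still reported with `reached_exterior = FALSE`.
#'
#' @param grid A `clearance_grid`.
#' @param seed Length-3 coordinate (Angstrom) inside the grid.
#' @return A list of class `channel_result`: `path` (n x 3 node positions),
#'   `clearance` (per path node, Angstrom), `bottleneck_radius`, `seed`,
#'   `reached_exterior`.
#' @export
find_channel <- function(grid, seed) {
  seed <- as.numeric(seed)
  seed_node <- node_at(grid, seed)
  cl <- grid$clearance
  ext <- grid$exterior
  if (ext[seed_node]) {
    pos <- node_coords(grid, seed_node)
    return(structure(list(path = pos, clearance = cl[seed_node],
                          bottleneck_radius = cl[seed_node], seed = seed,
                          reached_exterior = cl[seed_node] > 0),
                     class = "channel_result"))
  }
  ## maximin value by bisection over the sorted unique clearance values:
  ## feasible(t) = exterior reachable through nodes with clearance >= t
  vals <- sort(unique(as.numeric(cl)))
  vals <- vals[vals <= cl[seed_node]]
  feasible <- function(t) {
    if (cl[seed_node] < t) return(FALSE)
    reach <- flood_fill(grid$dims, cl >= t, seed_node)
    any(reach & ext)
  }
  lo <- 1L; hi <- length(vals)
  if (!feasible(vals[lo]))
    abort("no exterior nodes in grid", class = "rnd_geometry_error")
  while (lo < hi) {            # invariant: feasible(vals[lo]), maybe not hi
    mid <- as.integer(ceiling((lo + hi) / 2))
    if (feasible(vals[mid])) lo <- mid else hi <- mid - 1L
  }
  bottleneck <- vals[lo]
  ## shortest path within the >= bottleneck subgraph (BFS, deterministic:
  ## frontier expanded in increasing node-index order, first parent kept)
  passable <- cl >= bottleneck
  path <- bfs_path(grid$dims, passable, seed_node, ext)
  pos <- node_coords(grid, path)
  structure(list(path = pos, clearance = as.numeric(cl[path]),
                 bottleneck_radius = bottleneck, seed = seed,
                 reached_exterior = bottleneck > 0),
            class = "channel_result")
}

## BFS from seed to the first exterior node; returns the node path
bfs_path <- function(dims, passable, seed, ext) {
  nx <- dims[1]; ny <- dims[2]
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  parent <- integer(prod(dims))      # 0 = unvisited
  parent[seed] <- seed
  frontier <- seed
  goal <- 0L
  while (length(frontier) && !goal) {
    frontier <- sort(frontier)
    ijk <- arrayInd(frontier, dims)
    from <- rep(frontier, times = 26)
    cand_i <- rep(ijk[, 1], times = 26) + rep(offs[, 1], each = length(frontier))
    cand_j <- rep(ijk[, 2], times = 26) + rep(offs[, 2], each = length(frontier))
    cand_k <- rep(ijk[, 3], times = 26) + rep(offs[, 3], each = length(frontier))
    ok <- cand_i >= 1 & cand_i <= dims[1] & cand_j >= 1 & cand_j <= dims[2] &
      cand_k >= 1 & cand_k <= dims[3]
    lin <- (cand_k[ok] - 1L) * (nx * ny) + (cand_j[ok] - 1L) * nx + cand_i[ok]
    from <- from[ok]
    keep <- passable[lin] & parent[lin] == 0L
    lin <- lin[keep]; from <- from[keep]
    if (length(lin)) {
      ord <- order(lin, from)          # smallest parent wins duplicates
      lin <- lin[ord]; from <- from[ord]
      first <- !duplicated(lin)
      lin <- lin[first]; from <- from[first]
      parent[lin] <- from
      hit <- lin[ext[lin]]
      if (length(hit)) goal <- min(hit)
    }
    frontier <- lin
  }
  if (!goal) return(seed)              # no path: degenerate single node
  path <- goal
  while (path[1] != seed) path <- c(parent[path[1]], path)
  path
}

#' @export
print.channel_result <- function(x, ...) {
  cat(sprintf("# channel: %d nodes, bottleneck %.3f A, exterior %s\n",
              nrow(x$path), x$bottleneck_radius,
              if (x$reached_exterior) "reached" else "NOT reached"))
  invisible(x)
}

#' Along-channel clearance profile
#'
#' @param result A `channel_result`.
#' @return Tibble with `arc_length` (cumulative path length from the seed,
#'   Angstrom; strictly increasing from 0) and `clearance`; the profile
#'   minimum equals the bottleneck radius exactly.
#' @export
channel_profile <- function(result) {
  if (!nrow(result$path)) abort("empty channel path", class = "rnd_geometry_error")
  seg <- if (nrow(result$path) > 1)
    sqrt(rowSums(diff(result$path)^2)) else numeric()
  tibble(arc_length = c(0, cumsum(seg)), clearance = result$clearance)
}

#' Write a channel path as PDB pseudo-atoms
#'
#' One pseudo-atom per path node with the local clearance in the B-factor
#' column, for rendering channels coloured by radius.
#'
#' @param result A `channel_result`.
#' @param path Output PDB path.
#' @return Invisibly, `path`.
#' @export
write_channel_pdb <- function(result, path) {
  n <- nrow(result$path)
  s <- as_structure(tibble(
    chain = "X", resno = seq_len(n), resname = "CHN", atom = "C",
    element = "C", x = result$path[, 1], y = result$path[, 2],
    z = result$path[, 3], occ = 1, b = result$clearance),
    model_id = "channel")
  write_structure(s, path)
}
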
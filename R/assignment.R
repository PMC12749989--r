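## Monomer state assignment ----------------------------------------------
##
## A monomer is classified L / T / O by core-anchored superposition onto
## each reference protomer followed by porter-domain C-alpha RMSD; the
## winner is the minimum-RMSD state, with fixed precedence on ties. An O
## winner can be re-examined for a closed exit channel and relabelled O*.

#' Reference state library
#'
#' Bundles reference monomer structures per state with the subdomain scheme
#' that defines the superposition core and porter subdomains.
#'
#' @param states Named list of structure tables; names from
#'   `c("L","T","O","O*")`, at least two distinct states.
#' @param scheme A [subdomain_scheme()].
#' @param accession Optional named character vector recording the source of
#'   each reference (e.g. a PDB accession).
#' @return A list of class `reference_library`.
#' @export
reference_library <- function(states, scheme, accession = NULL) {
  if (length(states) < 2)
    abort("reference library needs at least 2 states", class = "rnd_config_error")
  bad <- setdiff(names(states), STATES)
  if (length(bad))
    abort(paste0("unknown reference state(s): ", paste(bad, collapse = ", ")),
          class = "rnd_config_error")
  structure(list(states = states, scheme = scheme,
                 accession = accession %||%
                   setNames(rep("synthetic", length(states)), names(states))),
            class = "reference_library")
}

#' @export
print.reference_library <- function(x, ...) {
  cat(sprintf("# reference library: states %s; core %d res, porter %d res\n",
              paste(names(x$states), collapse = ", "),
              length(x$scheme$core), length(porter_residues(x$scheme))))
  invisible(x)
}

## C-alpha coordinates of given residues keyed by resno (single chain)
ca_by_resno <- function(s, resnos) {
  ca <- s[s$atom == "CA" & s$element != "H", , drop = FALSE]
  i <- match(resnos, ca$resno)
  list(xyz = coords(ca)[i[!is.na(i)], , drop = FALSE],
       found = resnos[!is.na(i)], idx = i)
}

## precompute per-reference core/porter CA matrices for fast assignment
prepare_library <- function(library, statistic = "porter") {
  scheme <- library$scheme
  refs <- library$states[setdiff(names(library$states), "O*")]
  core_res <- scheme$core
  stat_res <- if (statistic == "porter") porter_residues(scheme)
              else sort(c(scheme$core, porter_residues(scheme)))
  lapply(refs, function(ref) {
    co <- ca_by_resno(ref, core_res)
    po <- ca_by_resno(ref, stat_res)
    list(core_res = co$found, core = co$xyz,
         stat_res = po$found, stat = po$xyz)
  })
}

## assignment core working on one monomer's CA table (resno -> xyz)
assign_one <- function(mono_resno, mono_xyz, prep, config) {
  rmsds <- vapply(prep, function(p) {
    ic <- match(p$core_res, mono_resno)
    is <- match(p$stat_res, mono_resno)
    okc <- !is.na(ic); oks <- !is.na(is)
    if (sum(okc) < 3 || sum(oks) < 1) return(NA_real_)
    k <- kabsch_mats(mono_xyz[ic[okc], , drop = FALSE],
                     p$core[okc, , drop = FALSE])
    moved <- sweep(mono_xyz[is[oks], , drop = FALSE] %*% t(k$R), 2, k$t, "+")
    sqrt(mean(rowSums((moved - p$stat[oks, , drop = FALSE])^2)))
  }, numeric(1))
  if (all(is.na(rmsds))) return(list(label = UNASSIGNED, rmsds = rmsds,
                                     margin = NA_real_, tie = FALSE))
  ## precedence-ordered argmin: first state in precedence order among the
  ## minima (equality at numerical tolerance counts as an exact tie)
  ord <- order(match(names(rmsds), config$precedence))
  r <- rmsds[ord]
  m <- min(r, na.rm = TRUE)
  w <- which(!is.na(r) & r <= m + 1e-9)[1]
  label <- names(r)[w]
  margin <- if (sum(!is.na(r)) > 1) max(0, sort(r)[2] - r[w]) else Inf
  list(label = label, rmsds = rmsds, margin = margin,
       tie = is.finite(margin) && margin < config$tie_margin)
}

#' Assign the conformational state of a monomer
#'
#' Superposes the monomer onto each reference over the core (TMD) anchor
#' and computes the classification RMSD per state (porter-domain C-alpha by
#' default); the winning state is the RMSD minimum, with exact ties broken
#' by the configured precedence order (default L < T < O < O*) and a tie
#' flag raised when the margin is below `config$tie_margin`. When the
#' winner is O and `config$check_o_star` is `TRUE`, the exit channel is
#' searched and the monomer is relabelled `O*` if the bottleneck radius
#' falls below `config$o_star_threshold`. Monomers sharing less than
#' `config$min_coverage` of the library correspondence atoms are returned
#' `UNASSIGNED`.
#'
#' @param monomer Structure table (single chain).
#' @param library A [reference_library()].
#' @param config A [run_config()].
#' @param particle_id,copy_index Identifiers copied into the result.
#' @return A one-row tibble (`particle_assignment`): `particle_id`,
#'   `copy_index`, `state_label`, one `rmsd_<state>` column per reference
#'   state, `margin`, `tie`, `o_star_checked`, `bottleneck`, `reason`.
#' @export
assign_state <- function(monomer, library, config = run_config(),
                         particle_id = attr(monomer, "model_id") %||% "particle",
                         copy_index = 0L) {
  prep <- prepare_library(library, config$statistic)
  all_res <- sort(unique(unlist(lapply(prep, function(p) c(p$core_res, p$stat_res)))))
  ca <- monomer[monomer$atom == "CA" & monomer$element != "H", , drop = FALSE]
  coverage <- mean(all_res %in% ca$resno)
  base <- tibble(particle_id = particle_id, copy_index = as.integer(copy_index))
  if (coverage < config$min_coverage) {
    res <- dplyr::bind_cols(base, tibble(state_label = UNASSIGNED))
    for (nm in names(prep)) res[[paste0("rmsd_", nm)]] <- NA_real_
    res$margin <- NA_real_; res$tie <- FALSE
    res$o_star_checked <- FALSE; res$bottleneck <- NA_real_
    res$reason <- sprintf("coverage %.2f below %.2f", coverage, config$min_coverage)
    return(res)
  }
  a <- assign_one(ca$resno, coords(ca), prep, config)
  label <- a$label
  o_star_checked <- FALSE
  bottleneck <- NA_real_
  if (label == "O" && isTRUE(config$check_o_star)) {
    det <- detect_O_star(monomer, library$scheme, config)
    o_star_checked <- TRUE
    bottleneck <- det$bottleneck
    if (det$is_o_star) label <- "O*"
  }
  res <- dplyr::bind_cols(base, tibble(state_label = label))
  for (nm in names(prep)) res[[paste0("rmsd_", nm)]] <- unname(a$rmsds[nm])
  res$margin <- a$margin; res$tie <- a$tie
  res$o_star_checked <- o_star_checked; res$bottleneck <- bottleneck
  res$reason <- NA_character_
  res
}

#' Assign states for a set of expanded monomers
#'
#' Batch wrapper over [assign_state()] for the output of
#' [symmetry_expand()] (or any atom table with `particle_id` and
#' `copy_index` columns).
#'
#' @param monomers Atom tibble with `particle_id` and `copy_index`.
#' @param library A [reference_library()].
#' @param config A [run_config()].
#' @return A label-table-compatible tibble, one row per monomer.
#' @export
assign_monomers <- function(monomers, library, config = run_config()) {
  groups <- dplyr::group_split(dplyr::group_by(monomers, .data$particle_id,
                                               .data$copy_index))
  purrr::list_rbind(purrr::map(groups, function(g) {
    pid <- g$particle_id[1]; k <- g$copy_index[1]
    g$particle_id <- NULL; g$copy_index <- NULL; g$source_chain <- NULL
    assign_state(as_structure(g, model_id = paste0(pid, "_", k)),
                 library, config, particle_id = pid, copy_index = k)
  }))
}

#' Per-subdomain rigid-body displacements
#'
#' After core superposition of the monomer onto the reference, fits a
#' per-subdomain rigid transform (Kabsch on that subdomain's C-alpha) and
#' reports the centroid translation magnitude and the rotation angle. A
#' subdomain missing from either model is flagged and the others are still
#' reported.
#'
#' @param monomer,reference Structure tables.
#' @param scheme A [subdomain_scheme()].
#' @return Tibble with `subdomain`, `translation` (Angstrom),
#'   `rotation_angle` (degrees), `n_atoms`, `missing`.
#' @export
subdomain_displacements <- function(monomer, reference, scheme) {
  mca <- monomer[monomer$atom == "CA" & monomer$element != "H", , drop = FALSE]
  rca <- reference[reference$atom == "CA" & reference$element != "H", , drop = FALSE]
  ic <- match(scheme$core, mca$resno); jc <- match(scheme$core, rca$resno)
  ok <- !is.na(ic) & !is.na(jc)
  if (sum(ok) < 3)
    abort("core residues missing from monomer or reference",
          class = "rnd_correspondence_error")
  k <- kabsch_mats(coords(mca)[ic[ok], , drop = FALSE],
                   coords(rca)[jc[ok], , drop = FALSE])
  mxyz <- sweep(coords(mca) %*% t(k$R), 2, k$t, "+")
  rxyz <- coords(rca)
  purrr::list_rbind(purrr::map(scheme_subdomains(scheme), function(nm) {
    res <- scheme[[nm]]
    i <- match(res, mca$resno); j <- match(res, rca$resno)
    ok <- !is.na(i) & !is.na(j)
    if (sum(ok) < 3)
      return(tibble(subdomain = nm, translation = NA_real_,
                    rotation_angle = NA_real_, n_atoms = sum(ok),
                    missing = TRUE))
    P <- mxyz[i[ok], , drop = FALSE]; Q <- rxyz[j[ok], , drop = FALSE]
    ks <- kabsch_mats(Q, P)   # reference subdomain -> monomer subdomain
    tibble(subdomain = nm,
           translation = sqrt(sum((colMeans(P) - colMeans(Q))^2)),
           rotation_angle = rotation_angle(ks$R),
           n_atoms = sum(ok), missing = FALSE)
  }))
}

#' Detect the closed-exit O* state
#'
#' Runs the channel search from the exit-channel seed point (centroid of
#' the scheme's seed residues) to the exterior and compares the bottleneck
#' radius with the O* threshold (default 1.5 Angstrom, motivated by the
#' 1.1-1.5 Angstrom bottlenecks of closed exit channels). If no path with
#' positive clearance exists, the monomer is O* with the best achievable
#' clearance reported and `no_path = TRUE`.
#'
#' @param monomer Structure table.
#' @param scheme A [subdomain_scheme()] with `exit_seed` residues.
#' @param config A [run_config()].
#' @return A list: `is_o_star`, `bottleneck` (Angstrom), `no_path`.
#' @export
detect_O_star <- function(monomer, scheme, config = run_config()) {
  if (!length(scheme$exit_seed))
    abort("scheme has no exit-channel seed residues", class = "rnd_config_error")
  present <- scheme$exit_seed %in% monomer$resno
  if (!all(present))
    abort(paste0("exit-channel seed residue(s) missing from monomer: ",
                 paste(scheme$exit_seed[!present], collapse = ", ")),
          class = "rnd_precondition_error")
  seed_atoms <- monomer[monomer$resno %in% scheme$exit_seed &
                          monomer$element != "H", , drop = FALSE]
  seed <- colMeans(coords(seed_atoms))
  grid <- build_clearance_grid(monomer, spacing = config$spacing,
                               radius_table = vdw_radii(config$radius_table),
                               padding = config$padding, probe = config$probe)
  ch <- find_channel(grid, seed)
  list(is_o_star = !ch$reached_exterior ||
         ch$bottleneck_radius < config$o_star_threshold,
       bottleneck = ch$bottleneck_radius,
       no_path = !ch$reached_exterior)
}

#' Proton-network side-chain orientation feature
#'
#' Measures whether the central lysine of the proton translocation network
#' is flipped towards the neighbouring asparagine and away from the
#' titratable aspartates: the distance from the lysine terminal nitrogen
#' (NZ) to the nearest asparagine side-chain O/N (OD1/ND2) and to the
#' nearest aspartate carboxylate oxygen (OD1/OD2), with
#' `flipped = d_to_asn < d_to_asp_min` (strict). Truncated side chains
#' yield a missing-feature result, not an error.
#'
#' @param monomer Structure table.
#' @param lys,asn Residue numbers of the lysine and asparagine.
#' @param asp Integer vector of aspartate residue numbers.
#' @return A one-row tibble: `d_to_asn`, `d_to_asp_min`, `flipped`,
#'   `missing`.
#' @export
sidechain_orientation_feature <- function(monomer, lys, asn, asp) {
  get_atoms <- function(resno, atoms) {
    s <- monomer[monomer$resno %in% resno & monomer$atom %in% atoms, ,
                 drop = FALSE]
    if (!nrow(s)) NULL else coords(s)
  }
  nz <- get_atoms(lys, "NZ")
  asn_xyz <- get_atoms(asn, c("OD1", "ND2"))
  asp_xyz <- get_atoms(asp, c("OD1", "OD2"))
  if (is.null(nz) || is.null(asn_xyz) || is.null(asp_xyz))
    return(tibble(d_to_asn = NA_real_, d_to_asp_min = NA_real_,
                  flipped = NA, missing = TRUE))
  dmin <- function(a, b) min(sqrt(outer(rowSums(a^2), rowSums(b^2), "+") -
                                    2 * a %*% t(b)))
  d_asn <- dmin(nz, asn_xyz)
  d_asp <- dmin(nz, asp_xyz)
  tibble(d_to_asn = d_asn, d_to_asp_min = d_asp,
         flipped = d_asn < d_asp, missing = FALSE)
}
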
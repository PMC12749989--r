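## Shared fixtures and independent oracles for the test suite.

## -- minimal coordinate fixtures ----------------------------------------

write_mini_pdb <- function(path, altloc = FALSE, tie = FALSE) {
  lines <- c(
    "ATOM      1  N   ALA A   1       1.000   2.000   3.000  1.00 10.00           N",
    "ATOM      2  CA  ALA A   1       2.000   2.500   3.500  1.00 11.00           C",
    "ATOM      3  C   ALA A   1       3.000   3.000   4.000  1.00 12.00           C")
  if (altloc) {
    occA <- if (tie) 0.50 else 0.40
    occB <- if (tie) 0.50 else 0.60
    lines <- c(lines, sprintf(
      "ATOM      4  CB A%s A   1       4.000   4.000   4.000  %.2f 10.00           C",
      "ALA", occA), sprintf(
      "ATOM      5  CB B%s A   1       5.000   5.000   5.000  %.2f 10.00           C",
      "ALA", occB))
  }
  writeLines(c(lines, "END"), path)
  path
}

write_mini_cif <- function(path) {
  writeLines(c(
    "data_mini", "loop_",
    paste0("_atom_site.", c(
      "group_PDB", "id", "type_symbol", "label_atom_id", "label_alt_id",
      "label_comp_id", "label_asym_id", "label_entity_id", "label_seq_id",
      "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
      "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id", "auth_comp_id",
      "auth_asym_id", "auth_atom_id", "pdbx_PDB_model_num")),
    "ATOM 1 N N . ALA A 1 1 ? 1.000 2.000 3.000 1.00 10.00 ? 1 ALA A N 1",
    "ATOM 2 C CA . ALA A 1 1 ? 2.000 2.500 3.500 1.00 11.00 ? 1 ALA A CA 1",
    "ATOM 3 C C . ALA A 1 1 ? 3.000 3.000 4.000 1.00 12.00 ? 1 ALA A C 1",
    "#"), path)
  path
}

## a 50-atom single-chain blob (deterministic), as a struct_tbl
blob_monomer <- function(n = 50, seed = 7, chain = "A") {
  set.seed(seed)
  as_structure(tibble::tibble(
    chain = chain, resno = seq_len(n), resname = "GLY", atom = "CA",
    element = "C", x = stats::rnorm(n, sd = 5), y = stats::rnorm(n, sd = 5),
    z = stats::rnorm(n, sd = 5), occ = 1, b = 0),
    model_id = paste0("blob", chain))
}

## exact C3 trimer about the z axis from a template monomer
c3_trimer <- function(template = blob_monomer(), offset = c(12, 0, 0),
                      noise_sd = 0, seed = 1) {
  pieces <- lapply(0:2, function(k) {
    R <- rotation_about_axis(c(0, 0, 1), 120 * k)
    s <- template
    xyz <- sweep(coords(s), 2, offset, "+") %*% t(R)
    if (noise_sd > 0) {
      set.seed(seed + k)
      xyz <- xyz + stats::rnorm(length(xyz), sd = noise_sd)
    }
    s <- set_coords(s, xyz)
    s$chain <- c("A", "B", "C")[k + 1]
    s
  })
  as_structure(dplyr::bind_rows(pieces), model_id = "trimer")
}

random_rigid <- function(seed) {
  set.seed(seed)
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  rigid_transform(rotation_about_axis(ax, stats::runif(1, 10, 350)),
                  stats::rnorm(3, sd = 10))
}

## labels for n_comp particles of each composition name
labels_from_comps <- function(comps) {
  n <- length(comps)
  tibble::tibble(
    particle_id = rep(sprintf("p%05d", seq_len(n)), each = 3),
    copy_index = rep(0:2, times = n),
    state_label = unlist(lapply(comps, function(cm)
      strsplit(gsub("(O\\*|[LTO])", "\\1,", cm), ",")[[1]])))
}

## PDA growth matrix for one variant vs wildtype
pda_tab <- function(v_steps, wt_steps = c(5, 5, 5), drug = "CHL") {
  tibble::tibble(
    variant = rep(c("V612F", "wt"), each = length(v_steps)),
    drug = drug,
    replicate = rep(seq_along(v_steps), 2),
    last_growth_step = c(v_steps, wt_steps))
}

## -- independent oracles -------------------------------------------------

## exhaustive census oracle: base-R enumeration, no shared code path
census_oracle <- function(labels) {
  parts <- split(labels$state_label, labels$particle_id)
  comps <- character(); dropped <- 0L
  for (p in parts) {
    if (length(p) == 3 && !any(p == "UNASSIGNED")) {
      ord <- order(match(p, c("L", "T", "O", "O*")))
      comps <- c(comps, paste(p[ord], collapse = ""))
    } else dropped <- dropped + 1L
  }
  mono <- unlist(lapply(comps, function(cm)
    strsplit(gsub("(O\\*|[LTO])", "\\1,", cm), ",")[[1]]))
  list(trimer = table(comps), dropped = dropped,
       monomer = table(factor(mono, levels = c("L", "T", "O", "O*"))))
}

## maximin channel-value oracle: naive Dijkstra-style widest path with
## linear scans (independent of the package's bisection + flood fill)
maximin_oracle <- function(grid, seed_node) {
  dims <- grid$dims
  nnode <- prod(dims)
  cl <- as.numeric(grid$clearance)
  ext <- as.logical(grid$exterior)
  value <- rep(-Inf, nnode)
  done <- rep(FALSE, nnode)
  value[seed_node] <- cl[seed_node]
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  repeat {
    u <- which.max(ifelse(done, -Inf, value))
    if (!is.finite(value[u]) || done[u]) break
    done[u] <- TRUE
    ijk <- arrayInd(u, dims)
    for (r in seq_len(nrow(offs))) {
      v <- ijk + offs[r, ]
      if (any(v < 1) || any(v > dims)) next
      lin <- (v[3] - 1) * dims[1] * dims[2] + (v[2] - 1) * dims[1] + v[1]
      nv <- min(value[u], cl[lin])
      if (nv > value[lin]) value[lin] <- nv
    }
    if (all(done | !is.finite(value))) break
  }
  max(value[ext])
}
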
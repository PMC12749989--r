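## Run configuration and curated data tables -----------------------------

#' Pipeline configuration
#'
#' Collects the tunable parameters shared across extraction, assignment and
#' channel analysis. Defaults follow the package's documented choices: the
#' classification statistic is porter-domain C-alpha RMSD after core
#' (transmembrane-domain) superposition; the O* override threshold is a
#' 1.5 Angstrom exit-channel bottleneck; the clearance grid uses 0.8 Angstrom
#' spacing, 6 Angstrom padding and a 3.0 Angstrom solvent probe.
#'
#' @param atom_selection Correspondence policy for superposition:
#'   `"calpha"` (default) or `"all"` heavy atoms.
#' @param statistic Classification statistic: `"porter"` (porter-domain
#'   C-alpha RMSD after core superposition) or `"whole"` (all shared
#'   C-alpha, own superposition).
#' @param min_coverage Minimum fraction of library correspondence atoms a
#'   monomer must share to be assignable (else `UNASSIGNED`).
#' @param check_o_star Run the exit-channel bottleneck check on `O` winners
#'   and relabel `O*` when the channel is closed.
#' @param o_star_threshold Bottleneck radius (Angstrom) below which an `O`
#'   monomer is relabelled `O*`.
#' @param tie_margin Margin (Angstrom) below which the tie flag is raised.
#' @param precedence State precedence order (permutation of
#'   `c("L","T","O","O*")`); first in order wins exact ties.
#' @param spacing,padding,probe Clearance-grid spacing, bounding-box padding
#'   and exterior-connectivity probe radius, all in Angstrom.
#' @param radius_table Name of the van der Waals radius table (`"bondi"`).
#' @param pseudo_tol Tolerated deviation (degrees) of the chain-to-chain
#'   rotation from 360/order before a pseudo-symmetry warning is attached.
#' @param seed Random seed recorded with results.
#' @param out_dir Output directory used by the command-line interface.
#' @return A list of class `run_config`.
#' @export
run_config <- function(atom_selection = c("calpha", "all"),
                       statistic = c("porter", "whole"),
                       min_coverage = 0.5,
                       check_o_star = FALSE,
                       o_star_threshold = 1.5,
                       tie_margin = 0.05,
                       precedence = STATES,
                       spacing = 0.8, padding = 6, probe = 3.0,
                       radius_table = "bondi",
                       pseudo_tol = 15,
                       seed = 1L, out_dir = ".") {
  atom_selection <- match.arg(atom_selection)
  statistic <- match.arg(statistic)
  if (spacing <= 0) abort("grid spacing must be > 0", class = "rnd_config_error")
  if (o_star_threshold <= 0)
    abort("O* bottleneck threshold must be > 0", class = "rnd_config_error")
  if (!setequal(precedence, STATES) || length(precedence) != length(STATES))
    abort("precedence must be a permutation of L, T, O, O*",
          class = "rnd_config_error")
  structure(list(
    atom_selection = atom_selection, statistic = statistic,
    min_coverage = min_coverage, check_o_star = check_o_star,
    o_star_threshold = o_star_threshold, tie_margin = tie_margin,
    precedence = precedence, spacing = spacing, padding = padding,
    probe = probe, radius_table = radius_table, pseudo_tol = pseudo_tol,
    seed = as.integer(seed), out_dir = out_dir), class = "run_config")
}

#' Van der Waals radii by element
#'
#' Loads the elemental radius table shipped with the package (Bondi radii,
#' Angstrom). Unknown elements fall back to 1.7 Angstrom with a warning.
#'
#' @param name Table name; only `"bondi"` ships.
#' @return Named numeric vector, element symbol to radius.
#' @export
vdw_radii <- function(name = "bondi") {
  path <- system.file("extdata", paste0("vdw_radii_", name, ".tsv"),
                      package = "rndcensus")
  if (!nzchar(path))
    abort(paste0("unknown radius table: ", name), class = "rnd_config_error")
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  setNames(tab$radius, tab$element)
}

## radius lookup with 1.7 A fallback for unknown elements
lookup_radii <- function(elements, table) {
  r <- unname(table[elements])
  if (anyNA(r)) {
    unk <- unique(elements[is.na(r)])
    warn(paste0("unknown element(s) ", paste(unk, collapse = ", "),
                "; using fallback van der Waals radius 1.7 A"))
    r[is.na(r)] <- 1.7
  }
  r
}

#' Subdomain scheme
#'
#' Named residue sets defining the superposition core (transmembrane
#' domain), the porter subdomains PN1/PN2/PC1/PC2 (and optionally TM2),
#' exit-channel seed residues and the proton-translocation-network triplet
#' (lysine, asparagine, aspartates). Residue numbers are author numbers.
#'
#' @param core,PN1,PN2,PC1,PC2 Integer vectors of residue numbers; `core`
#'   must be disjoint from the porter subdomains.
#' @param TM2 Optional integer vector (transmembrane helix 2).
#' @param exit_seed Residue numbers whose C-alpha centroid seeds the
#'   exit-channel search.
#' @param proton_network List with elements `lys`, `asn`, `asp` (residue
#'   numbers).
#' @return A list of class `subdomain_scheme`.
#' @export
subdomain_scheme <- function(core, PN1, PN2, PC1, PC2, TM2 = integer(),
                             exit_seed = integer(),
                             proton_network = list(lys = integer(),
                                                   asn = integer(),
                                                   asp = integer())) {
  porter <- c(PN1, PN2, PC1, PC2)
  if (length(intersect(core, porter)))
    abort("core residues overlap porter subdomains", class = "rnd_config_error")
  structure(list(core = as.integer(core), PN1 = as.integer(PN1),
                 PN2 = as.integer(PN2), PC1 = as.integer(PC1),
                 PC2 = as.integer(PC2), TM2 = as.integer(TM2),
                 exit_seed = as.integer(exit_seed),
                 proton_network = proton_network),
            class = "subdomain_scheme")
}

## subdomains reported by subdomain_displacements
scheme_subdomains <- function(scheme) {
  nm <- c("PN1", "PN2", "PC1", "PC2", "TM2")
  nm[vapply(nm, function(n) length(scheme[[n]]) > 0, logical(1))]
}

porter_residues <- function(scheme)
  c(scheme$PN1, scheme$PN2, scheme$PC1, scheme$PC2)

#' Read a subdomain scheme from a range file
#'
#' The file is TSV with columns `set`, `start`, `end` where `set` is one of
#' `core`, `PN1`, `PN2`, `PC1`, `PC2`, `TM2`, `exit_seed`, `lys`, `asn`,
#' `asp`; rows with equal start and end give single residues. The curated
#' AcrB/OqxB range files shipped under `extdata/schemes/` are editable
#' approximations, not ground truth: the subdomain boundaries are this
#' package's curation.
#'
#' @param path TSV file path.
#' @return A `subdomain_scheme`.
#' @export
read_scheme <- function(path) {
  if (!file.exists(path))
    abort(paste0("file not found: ", path), class = "rnd_io_error")
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         comment = "#")
  pull <- function(set) {
    rows <- tab[tab$set == set, , drop = FALSE]
    if (!nrow(rows)) return(integer())
    unlist(Map(seq.int, rows$start, rows$end), use.names = FALSE)
  }
  subdomain_scheme(core = pull("core"), PN1 = pull("PN1"), PN2 = pull("PN2"),
                   PC1 = pull("PC1"), PC2 = pull("PC2"), TM2 = pull("TM2"),
                   exit_seed = pull("exit_seed"),
                   proton_network = list(lys = pull("lys"), asn = pull("asn"),
                                         asp = pull("asp")))
}

#' Shipped curated scheme for AcrB or OqxB numbering
#'
#' @param which `"acrb"`, `"oqxb"`, or `"synthetic"` (the generator's
#'   template numbering).
#' @return A `subdomain_scheme`.
#' @export
default_scheme <- function(which = c("acrb", "oqxb", "synthetic")) {
  which <- match.arg(which)
  if (which == "synthetic") return(synthetic_scheme())
  read_scheme(system.file("extdata", "schemes",
                          paste0(which, "_subdomains.tsv"),
                          package = "rndcensus"))
}
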
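## Atomic-structure tables -----------------------------------------------
##
## A structure is a tidy atom-record tibble, one row per atom, with columns
##   chain   character  chain identifier
##   resno   integer    author residue number (1-based, gaps allowed)
##   resname character  3-letter residue code
##   insert  character  insertion code ("" when absent)
##   atom    character  atom name (e.g. "CA", "NZ")
##   element character  element symbol, upper case
##   x, y, z double     position, Angstrom
##   occ     double     occupancy
##   b       double     isotropic B-factor, Angstrom^2
## plus a "model_id" attribute. Residues are never renumbered: the paper's
## residue citations (V612, K946, ...) are author numbers.

#' Build a structure table from atom records
#'
#' Validates and classes a data frame of atom records as a structure table.
#' Positions must be finite and the (chain, resno, insert, atom) key unique
#' (i.e. after any alternate-location resolution).
#'
#' @param df Data frame with columns `chain`, `resno`, `atom`, `x`, `y`, `z`;
#'   missing `resname`, `insert`, `element`, `occ`, `b` columns are filled
#'   with defaults.
#' @param model_id Identifier stored as an attribute.
#' @return A tibble of class `struct_tbl`.
#' @export
as_structure <- function(df, model_id = "model") {
  df <- as_tibble(df)
  if (!nrow(df)) abort("empty structure: no atom records", class = "rnd_empty_structure")
  if (!"resname" %in% names(df)) df$resname <- "UNK"
  if (!"insert" %in% names(df)) df$insert <- ""
  if (!"element" %in% names(df)) df$element <- guess_element(df$atom)
  if (!"occ" %in% names(df)) df$occ <- 1
  if (!"b" %in% names(df)) df$b <- 0
  df$insert[is.na(df$insert)] <- ""
  df$resno <- as.integer(df$resno)
  keep <- c("chain", "resno", "resname", "insert", "atom", "element",
            "x", "y", "z", "occ", "b")
  extra <- setdiff(names(df), keep)
  df <- df[, c(keep, extra)]
  if (!all(is.finite(df$x) & is.finite(df$y) & is.finite(df$z)))
    abort("non-finite atom positions", class = "rnd_invalid_structure")
  key <- paste(df$chain, df$resno, df$insert, df$atom)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    abort(paste0("duplicate atom key (chain resno insert atom): ", dup),
          class = "rnd_invalid_structure")
  }
  attr(df, "model_id") <- model_id
  class(df) <- unique(c("struct_tbl", class(df)))
  df
}

guess_element <- function(atom) {
  e <- toupper(substr(gsub("[0-9'\"]", "", atom), 1, 1))
  e[e == ""] <- "C"
  e
}

#' @export
print.struct_tbl <- function(x, ...) {
  cat(sprintf("# structure '%s': %d atoms, %d chain(s), %d residue(s)\n",
              attr(x, "model_id") %||% "?", nrow(x),
              length(unique(x$chain)),
              nrow(unique(x[, c("chain", "resno", "insert")]))))
  NextMethod()
}

#' Coordinates of a structure as a matrix
#'
#' @param s Structure table.
#' @return An n x 3 numeric matrix.
#' @export
coords <- function(s) cbind(x = s$x, y = s$y, z = s$z)

#' Replace the coordinates of a structure
#'
#' @param s Structure table.
#' @param xyz An n x 3 matrix.
#' @return The structure with new coordinates.
#' @export
set_coords <- function(s, xyz) {
  stopifnot(nrow(xyz) == nrow(s))
  s$x <- xyz[, 1]; s$y <- xyz[, 2]; s$z <- xyz[, 3]
  s
}

## heavy atoms only: deposited models are heavy-atom, all geometry ignores H
heavy <- function(s) s[s$element != "H" & s$element != "D", , drop = FALSE]

#' Read an atomic structure from PDB or mmCIF
#'
#' Parses coordinate records via bio3d and returns a tidy atom table.
#' Alternate locations are resolved to a single conformer: the highest
#' occupancy wins, ties broken by altloc identifier order (so 'A' beats 'B').
#' Insertion codes are preserved and residues keep their author numbers.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"pdb"` or `"mmcif"`.
#' @param keep_waters Keep HOH/WAT records (default drops them).
#' @param model_id Identifier for the returned structure; defaults to the
#'   file base name.
#' @return A `struct_tbl` tibble.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           keep_waters = FALSE, model_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path))
    abort(paste0("file not found: ", path), class = "rnd_io_error")
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  raw <- tryCatch(
    suppressWarnings(
      if (format == "pdb") bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
      else bio3d::read.cif(path, rm.alt = FALSE, verbose = FALSE)),
    error = function(e) abort(
      paste0("cannot parse ", format, " file '", path, "': ", conditionMessage(e)),
      class = "rnd_format_error"))
  at <- as_tibble(raw$atom)
  if (!nrow(at)) {
    ## distinguish a coordinate-free but valid file from junk text: with no
    ## recognisable PDB record types, report the offending line instead
    if (format == "pdb") {
      lines <- readLines(path, warn = FALSE)
      rec <- "^(ATOM|HETATM|HEADER|TITLE|REMARK|CRYST1|SEQRES|MODEL|ENDMDL|TER|END|ANISOU|CONECT|MASTER|COMPND|SOURCE|EXPDTA|AUTHOR|JRNL|HELIX|SHEET|SCALE|ORIGX|DBREF|MODRES|HET|FORMUL|SSBOND|LINK|SITE|NUMMDL|SPLIT|CAVEAT|OBSLTE|REVDAT|SPRSDE|KEYWDS|MTRIX|SEQADV|CISPEP)"
      bad <- lines[nzchar(trimws(lines)) & !grepl(rec, lines)]
      if (length(bad))
        abort(paste0("cannot parse pdb file '", path,
                     "': unrecognised record \"", bad[1], "\""),
              class = "rnd_format_error")
    }
    abort(paste0("empty coordinate set in ", path), class = "rnd_empty_structure")
  }
  if (!keep_waters) at <- at[!at$resid %in% c("HOH", "WAT", "DOD"), , drop = FALSE]
  if (!nrow(at))
    abort(paste0("empty coordinate set in ", path, " after water removal"),
          class = "rnd_empty_structure")
  at$chain[is.na(at$chain)] <- " "
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  at$b[is.na(at$b)] <- 0
  elesy <- if ("elesy" %in% names(at)) toupper(trimws(at$elesy)) else ""
  miss <- is.na(elesy) | elesy == ""
  elesy[miss] <- guess_element(at$elety[miss])
  df <- tibble(
    chain = at$chain, resno = as.integer(at$resno), resname = at$resid,
    insert = at$insert, atom = at$elety, element = elesy,
    x = at$x, y = at$y, z = at$z, occ = at$o, b = at$b, altloc = at$alt)
  df <- resolve_altloc(df)
  df$altloc <- NULL
  as_structure(df, model_id = model_id %||% sub("\\.[^.]+$", "", basename(path)))
}

## keep one conformer per atom: highest occupancy, ties by altloc order
resolve_altloc <- function(df) {
  key <- paste(df$chain, df$resno, df$insert, df$atom)
  if (!anyDuplicated(key)) return(df)
  ord <- order(key, -df$occ, df$altloc)
  df <- df[ord, , drop = FALSE]
  df <- df[!duplicated(paste(df$chain, df$resno, df$insert, df$atom)), , drop = FALSE]
  ## restore file order
  df[order(match(paste(df$chain, df$resno, df$insert, df$atom), unique(key))), ,
     drop = FALSE]
}

#' Write a structure to a PDB file
#'
#' Coordinate payload only (ATOM records); coordinates are written at PDB
#' text precision (0.001 Angstrom).
#'
#' @param s Structure table.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_structure <- function(s, path) {
  bio3d::write.pdb(
    pdb = NULL, file = path,
    xyz = as.numeric(t(coords(s))),
    resno = s$resno, resid = s$resname, chain = ifelse(s$chain == "", " ", s$chain),
    insert = ifelse(s$insert == "", "", s$insert),
    elety = s$atom, eleno = seq_len(nrow(s)), o = s$occ, b = s$b,
    elesy = s$element)
  invisible(path)
}
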
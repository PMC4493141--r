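# Reading, validating and writing protonated protein structures.

#' Construct a structure object from an atom table
#'
#' Low-level constructor shared by [read_pdb()] and the fixture generators.
#' Residues are re-indexed sequentially (1-based, gap-free) in order of
#' appearance; the author residue numbering is kept as metadata.
#'
#' @param atoms data frame with columns `serial`, `name`, `element`,
#'   `residue_name`, `chain_id`, `author_resno`, `x`, `y`, `z`.
#' @return An object of class `cna_structure`: a list with `atoms` (one row
#'   per atom, with `residue_index`, `is_hydrogen` and `vdw_radius` filled
#'   in), `residues` (one row per residue with backbone atom row indices
#'   `N`, `CA`, `C`, `O`, `NA` where missing) and `sequence_length`.
#' @export
make_structure <- function(atoms) {
  required <- c("serial", "name", "element", "residue_name", "chain_id",
                "author_resno", "x", "y", "z")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0)
    stop("atom table lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(atoms) == 0) stop("structure has no atoms")
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(coords)))
    stop("non-finite coordinates for atom serial(s) ",
         paste(atoms$serial[!stats::complete.cases(coords)], collapse = ", "))
  if (any(!nzchar(atoms$element)))
    stop("empty element symbol for atom serial(s) ",
         paste(atoms$serial[!nzchar(atoms$element)], collapse = ", "))

  res_key <- paste(atoms$chain_id, atoms$author_resno, atoms$residue_name, sep = "|")
  atoms$residue_index <- match(res_key, unique(res_key))
  atoms$is_hydrogen <- atoms$element == "H"
  atoms$vdw_radius <- .vdw_radius(atoms$element)
  rownames(atoms) <- NULL

  n_res <- max(atoms$residue_index)
  backbone_id <- function(res, at) {
    hit <- which(atoms$residue_index == res & atoms$name == at)
    if (length(hit) == 0) NA_integer_ else hit[1]
  }
  residues <- data.frame(
    index = seq_len(n_res),
    name = atoms$residue_name[match(seq_len(n_res), atoms$residue_index)],
    chain_id = atoms$chain_id[match(seq_len(n_res), atoms$residue_index)],
    author_resno = atoms$author_resno[match(seq_len(n_res), atoms$residue_index)],
    n_atoms = as.vector(table(factor(atoms$residue_index, levels = seq_len(n_res)))),
    stringsAsFactors = FALSE
  )
  for (at in c("N", "CA", "C", "O"))
    residues[[at]] <- vapply(seq_len(n_res), backbone_id, integer(1), at = at)

  structure(list(atoms = atoms, residues = residues, sequence_length = n_res),
            class = "cna_structure")
}

#' Read a protonated protein structure from a PDB file
#'
#' Parses fixed-column ATOM records (first model only), keeping protein
#' chains and dropping waters, buffer ions, and HETATM ligands. Hydrogens
#' are retained; elements are taken from columns 77-78 when present and
#' inferred from the atom name otherwise. Alternate locations other than
#' blank or 'A' are discarded, and all protein chains are merged into one
#' sequentially indexed chain of residues.
#'
#' @param path path to a PDB file.
#' @return A [make_structure()] object of class `cna_structure`.
#' @examples
#' pdb <- system.file("extdata", "gly.pdb", package = "cnar")
#' s <- read_pdb(pdb)
#' s$sequence_length
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("cannot parse PDB file ", path, ": ",
                             conditionMessage(e)))
  a <- pdb$atom
  a <- a[a$type == "ATOM", , drop = FALSE]
  if (nrow(a) == 0) stop("no ATOM records in ", path)
  a <- a[is.na(a$alt) | a$alt %in% c("", "A"), , drop = FALSE]
  a <- a[a$resid %in% .PROTEIN_RESIDUES, , drop = FALSE]
  if (nrow(a) == 0) stop("no protein ATOM records in ", path)

  bad <- !is.finite(a$x) | !is.finite(a$y) | !is.finite(a$z)
  if (any(bad))
    stop("malformed coordinate field in ", path, " (ATOM serial ",
         paste(a$eleno[bad], collapse = ", "), ")")

  element <- a$elesy
  element[is.na(element)] <- ""
  element <- trimws(element)
  need <- !nzchar(element)
  element[need] <- infer_element(a$elety[need])
  element <- toupper(element)

  chain <- a$chain
  chain[is.na(chain)] <- " "
  make_structure(data.frame(
    serial = a$eleno, name = a$elety, element = element,
    residue_name = a$resid, chain_id = chain, author_resno = a$resno,
    x = a$x, y = a$y, z = a$z, stringsAsFactors = FALSE))
}

#' Infer element symbols from PDB atom names
#'
#' Fallback for files without element columns: digits and primes are
#' stripped and the leading letter is used, so `1HB2`, `HG21` map to H and
#' `SD`, `CA` map to S and C (protein atoms only; ions are filtered before
#' this is called).
#'
#' @param name character vector of atom names.
#' @return character vector of element symbols.
#' @export
infer_element <- function(name) {
  stripped <- gsub("[0-9' ]", "", trimws(name))
  if (any(!nzchar(stripped))) stop("cannot infer element from atom name(s): ",
                                   paste(name[!nzchar(stripped)], collapse = ", "))
  toupper(substr(stripped, 1, 1))
}

#' Write a structure to a PDB file
#'
#' @param s a `cna_structure`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(s, path) {
  stopifnot(inherits(s, "cna_structure"))
  a <- s$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = rep("ATOM", nrow(a)),
                   resno = a$author_resno, resid = a$residue_name,
                   eleno = a$serial, elety = a$name, chain = a$chain_id,
                   elesy = a$element)
  invisible(path)
}

#' Check that a structure is protonated
#'
#' Hydrogen-bond detection requires explicit hydrogens; structures are
#' expected to be protonated before analysis. This reports hydrogen counts
#' and flags structures with none.
#'
#' @param s a `cna_structure`.
#' @return list with `n_hydrogens`, `n_heavy`, `hydrogen_ratio` and the flag
#'   `missing_hydrogens`.
#' @export
validate_protonation <- function(s) {
  stopifnot(inherits(s, "cna_structure"))
  n_h <- sum(s$atoms$is_hydrogen)
  n_heavy <- sum(!s$atoms$is_hydrogen)
  list(n_hydrogens = n_h,
       n_heavy = n_heavy,
       hydrogen_ratio = if (n_heavy > 0) n_h / n_heavy else NA_real_,
       missing_hydrogens = n_h == 0)
}

#' @export
print.cna_structure <- function(x, ...) {
  cat("cna_structure:", nrow(x$atoms), "atoms,", x$sequence_length,
      "residues,", sum(x$atoms$is_hydrogen), "hydrogens\n")
  invisible(x)
}

# coordinates as an n x 3 matrix
.coords <- function(s) as.matrix(s$atoms[, c("x", "y", "z")])
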
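#' Read a PDB file into an atomic system
#'
#' Reads ATOM/HETATM records (via bio3d), infers the element from the element
#' column with a fallback to the atom name, and retains residue/atom-name
#' metadata in `info` for downstream selections (for example backbone phi/psi
#' dihedrals). PDB is read-only in this package; all writing goes through
#' [write_extxyz()].
#'
#' @param path Path to a PDB file.
#' @param charge,spin Total charge and spin to attach (a PDB file carries
#'   neither).
#' @return An [atomic_system()] whose `info` holds `atom_names`, `res_names`,
#'   `res_ids` and `chain`.
#' @export
read_pdb <- function(path, charge = 0, spin = 0) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  elem <- trimws(at$elesy)
  fallback <- !nzchar(elem) | is.na(elem)
  if (any(fallback)) {
    # first alphabetic character(s) of the atom name; two-letter Cl handled
    nm <- toupper(gsub("[^A-Za-z].*$", "", trimws(at$elety[fallback])))
    elem[fallback] <- ifelse(substr(nm, 1, 2) == "CL", "Cl", substr(nm, 1, 1))
  }
  elem <- ifelse(toupper(elem) == "CL", "Cl", paste0(
    toupper(substr(elem, 1, 1)), tolower(substr(elem, 2, 10))))
  z <- element_number(elem)   # errors listing the 8 supported elements
  atomic_system(cbind(at$x, at$y, at$z), z, charge = charge, spin = spin,
                info = list(atom_names = trimws(at$elety),
                            res_names = trimws(at$resid),
                            res_ids = at$resno,
                            chain = at$chain))
}
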
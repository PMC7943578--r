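#' Assign heptad register letters along each chain
#'
#' Coiled-coil sequences repeat with a seven-residue period whose positions
#' are conventionally labelled `a`-`g`. Register is purely a function of
#' residue number and the chosen frame: residue `i` receives letter
#' `letters_heptad[((i - 1 + register_offset) mod 7) + 1]`, independently of
#' coordinates (the assignment is invariant to any rigid motion). With the
#' builder's default peptide (a 4x `KEIGQAL` repeat, `register_offset = 1`)
#' residue 13 (Ala) sits at `g` and the Gly positions at `e`, matching the
#' interface layout of the studied switchable hexamer.
#'
#' @param structure a `cc_structure`.
#' @param register_offset integer in `0..6`; `0` places residue 1 at `a`.
#' @return A data frame with one row per residue (`chain`, `resno`,
#'   `resname`, `register`), of class `heptad_assignment` with the offset
#'   stored as attribute `register_offset`.
#' @export
assign_register <- function(structure, register_offset = 0L) {
  register_offset <- as.integer(register_offset)
  if (register_offset < 0L || register_offset > 6L) {
    stop("register_offset must be in 0..6")
  }
  atom <- structure$atom
  res <- unique(atom[, c("chain", "resno", "resname")])
  res <- res[order(match(res$chain, chains(structure)), res$resno), ]
  rownames(res) <- NULL
  res$register <- letters[1:7][((res$resno - 1L + register_offset) %% 7L) + 1L]
  attr(res, "register_offset") <- register_offset
  class(res) <- c("heptad_assignment", class(res))
  res
}

#' Register letter of one residue
#'
#' @param assignment result of [assign_register()].
#' @param chain chain identifier.
#' @param resno residue number.
#' @return Single register letter.
#' @export
register_of <- function(assignment, chain, resno) {
  hit <- assignment$register[assignment$chain == chain & assignment$resno == resno]
  if (length(hit) != 1L) stop("residue ", chain, ":", resno, " not found")
  hit
}
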
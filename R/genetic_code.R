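#' @importFrom Biostrings GENETIC_CODE
NULL

# Standard genetic code, partitioned once at load time.  All codon-level
# statistics in the package use these tables: the 61 sense codons, the
# synonymous families keyed by amino acid, and Wright's degeneracy classes
# (2 single-codon families Met/Trp, 9 two-fold, 1 three-fold, 5 four-fold,
# 3 six-fold).
.code_env <- new.env(parent = emptyenv())

.init_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  stops <- names(gc)[gc == "*"]
  sense <- names(gc)[gc != "*"]
  fam <- split(sense, gc[sense])            # amino acid -> codons
  fam_size <- vapply(fam, length, integer(1))
  assign("genetic_code", gc, envir = .code_env)
  assign("stop_codons", stops, envir = .code_env)
  assign("sense_codons", sense, envir = .code_env)
  assign("families", fam, envir = .code_env)
  assign("family_size", fam_size, envir = .code_env)
  assign("aa_of_codon", gc[sense], envir = .code_env)
}

.onLoad <- function(libname, pkgname) .init_code()

.code <- function(what) {
  if (!length(ls(.code_env))) .init_code()
  get(what, envir = .code_env)
}

#' Stop codons of the standard genetic code
#' @return Character vector `c("TAA", "TAG", "TGA")`.
#' @export
stop_codons <- function() .code("stop_codons")

#' The 61 sense codons of the standard genetic code
#' @return Character vector of length 61, alphabetical.
#' @export
sense_codons <- function() sort(.code("sense_codons"))

#' Synonymous codon families
#'
#' @return Named list mapping each one-letter amino acid to its synonymous
#'   codons under the standard genetic code (stop codons excluded).
#' @export
codon_families <- function() .code("families")

#' Translate a vector of codons
#'
#' @param codons character vector of codon strings; codons containing
#'   characters outside ACGT translate to `NA`.
#' @return Character vector of one-letter amino acids (`"*"` for stops).
#' @export
translate_codons <- function(codons) {
  gc <- .code("genetic_code")
  unname(gc[codons])
}
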
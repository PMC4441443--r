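# Amino-acid constants: names, class pooling, max-ASA scale, composition.

#' Standard amino acids
#'
#' Three-letter codes of the 20 standard amino acids, alphabetically ordered.
#'
#' @return Character vector of length 20.
#' @export
amino_acids <- function() {
  c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
    "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")
}

# one-letter -> three-letter lookup (DSSP uses one-letter codes)
.AA1TO3 <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
  E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
  M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
  Y = "TYR", V = "VAL"
)

#' Amino-acid classes
#'
#' The five-class pooling used throughout: hydrophobic, aromatic, charged,
#' polar and other. The charged + polar classes together form the reference
#' pool used for reference correction.
#'
#' @return Named list mapping class name to a character vector of members.
#' @export
aa_classes <- function() {
  list(
    hydrophobic = c("ALA", "ILE", "LEU", "MET", "VAL"),
    aromatic    = c("HIS", "PHE", "TRP", "TYR"),
    charged     = c("ARG", "ASP", "GLU", "LYS"),
    polar       = c("ASN", "GLN", "SER", "THR"),
    other       = c("CYS", "GLY", "PRO")
  )
}

#' Maximum accessible surface area per residue type
#'
#' Theoretical maximum solvent-accessible surface area of residue X in an
#' extended Gly-X-Gly tripeptide (Tien et al. 2013, PLOS ONE 8:e80635),
#' in squared Angstrom. Used to normalise observed accessible areas into
#' exposure fractions; any other scale can be passed wherever a
#' \code{max_asa} argument is accepted.
#'
#' @return Named numeric vector over the 20 standard amino acids.
#' @export
default_max_asa <- function() {
  c(ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167,
    GLN = 225, GLU = 223, GLY = 104, HIS = 224, ILE = 197,
    LEU = 201, LYS = 236, MET = 224, PHE = 240, PRO = 159,
    SER = 155, THR = 172, TRP = 285, TYR = 263, VAL = 174)
}

#' Background amino-acid composition
#'
#' Average residue frequencies of globular proteins (UniProtKB/Swiss-Prot
#' averages), renormalised to sum to one. Used as the default residue
#' composition of the synthetic-chain generator.
#'
#' @return Named numeric vector over the 20 standard amino acids, summing to 1.
#' @export
default_composition <- function() {
  x <- c(ALA = 8.25, ARG = 5.53, ASN = 4.06, ASP = 5.45, CYS = 1.37,
         GLN = 3.93, GLU = 6.75, GLY = 7.07, HIS = 2.27, ILE = 5.96,
         LEU = 9.66, LYS = 5.84, MET = 2.42, PHE = 3.86, PRO = 4.70,
         SER = 6.56, THR = 5.34, TRP = 1.08, TYR = 2.92, VAL = 6.87)
  x / sum(x)
}

#' Resolve an entity name to its member residue types
#'
#' An entity is either a single residue type (\code{"LEU"}), a class name
#' from \code{\link{aa_classes}} (\code{"hydrophobic"}), the special pool
#' \code{"reference"} (charged + polar, the reference-correction pool) or
#' \code{"all"}.
#'
#' A character vector of several residue types is passed through unchanged,
#' so ad-hoc pools can be used wherever an entity is accepted.
#'
#' @param entity Character scalar (entity name) or vector of residue types.
#' @return Character vector of residue types in the pool.
#' @export
entity_types <- function(entity) {
  stopifnot(is.character(entity))
  if (length(entity) > 1L) {
    bad <- setdiff(entity, amino_acids())
    if (length(bad) > 0L)
      stop("UnknownClass: not residue types: ", paste(bad, collapse = ", "),
           call. = FALSE)
    return(unique(entity))
  }
  cls <- aa_classes()
  if (entity %in% amino_acids()) return(entity)
  if (entity %in% names(cls)) return(cls[[entity]])
  if (entity == "reference") return(c(cls$charged, cls$polar))
  if (entity == "all") return(amino_acids())
  stop("UnknownClass: '", entity, "' is neither a residue type nor a class",
       call. = FALSE)
}
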
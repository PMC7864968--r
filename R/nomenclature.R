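# Lipid shorthand nomenclature at sum-composition resolution.
#
# Names follow the common shorthand CLASS(C:D), where C is the total number
# of acyl/alkyl carbons and D the total number of double bonds, e.g.
# TG(52:5).  Composition-free classes (e.g. Chol) carry no parenthesis.
# Ether/plasmalogen classes carry an "-O" suffix on the class code
# (PC-O, PE-O).  A trailing "(PW)" marks measurements from petrol-washed
# adipose and is provenance, not identity.

#' Lipid classes recognised by the parser
#'
#' Abbreviations for the lipid classes handled throughout the package:
#' Cer (ceramide), Chol (cholesterol), DG (diglyceride), LPC/LPE/LPG
#' (lyso-phospholipids), PA, PC, PC-O (phosphatidylcholine plasmalogen),
#' PE, PE-O, PG, PI, PS, SM (sphingomyelin) and TG (triglyceride).
#'
#' @return Character vector of known class codes.
#' @export
lipid_classes <- function() {
  c("Cer", "Chol", "DG", "LPC", "LPE", "LPG", "PA", "PC", "PC-O",
    "PE", "PE-O", "PG", "PI", "PS", "SM", "TG")
}

#' Parse a lipid shorthand name
#'
#' Parses names of the form \code{CLASS} or \code{CLASS(C:D)}, with an
#' optional \code{-O} suffix on the class (ether/plasmalogen lipids) and an
#' optional trailing \code{(PW)} annotation (petrol-washed adipose), which is
#' stripped into a provenance flag.  Unknown class codes are preserved
#' verbatim and flagged with a warning.
#'
#' @param name Character scalar, e.g. \code{"TG(52:5)"}, \code{"PC-O(34:1)"},
#'   \code{"Chol"}.
#' @return An object of class \code{lipid_species} with fields
#'   \code{raw_name}, \code{lipid_class}, \code{total_carbons},
#'   \code{double_bonds} (both \code{NA} for composition-free classes),
#'   \code{ether}, \code{petrol_washed} and \code{known_class}.
#' @examples
#' parse_lipid_name("TG(52:5)")
#' parse_lipid_name("Chol")
#' @seealso [format_lipid_name()], [is_odd_chain()]
#' @export
parse_lipid_name <- function(name) {
  stopifnot(is.character(name), length(name) == 1L, !is.na(name))
  raw <- name
  s <- trimws(name)

  pw <- grepl("\\(PW\\)\\s*$", s)
  if (pw) s <- trimws(sub("\\(PW\\)\\s*$", "", s))

  # CLASS with optional -O suffix, optional (C:D) composition
  m <- regmatches(s, regexec(
    "^([A-Za-z][A-Za-z0-9]*(?:-O)?)\\s*(\\(.*\\))?$", s))[[1]]
  if (length(m) == 0L || m[2] == "") {
    stop("malformed lipid name '", raw, "': no class code found")
  }
  cls <- m[2]
  comp <- m[3]

  carbons <- NA_integer_
  dbonds <- NA_integer_
  if (!is.na(comp) && nzchar(comp)) {
    cm <- regmatches(comp, regexec(
      "^\\(\\s*([0-9]+)\\s*:\\s*([0-9]+)\\s*\\)$", comp))[[1]]
    if (length(cm) == 0L) {
      stop("malformed composition token '", comp, "' in '", raw,
           "': expected (C:D) with integer C and D")
    }
    carbons <- as.integer(cm[2])
    dbonds <- as.integer(cm[3])
  } else if (grepl("\\(", s) && (is.na(comp) || !nzchar(comp))) {
    stop("malformed lipid name '", raw, "': unbalanced parenthesis")
  }

  known <- cls %in% lipid_classes()
  if (!known) {
    warning("unknown lipid class code '", cls, "' in '", raw,
            "'; preserved verbatim", call. = FALSE)
  }

  structure(
    list(
      raw_name = raw,
      lipid_class = cls,
      total_carbons = carbons,
      double_bonds = dbonds,
      ether = grepl("-O$", cls),
      petrol_washed = pw,
      known_class = known
    ),
    class = "lipid_species"
  )
}

#' Canonical shorthand name of a parsed lipid species
#'
#' @param species A \code{lipid_species}.
#' @return Character scalar \code{CLASS} or \code{CLASS(C:D)}.  The
#'   petrol-washed provenance flag is not part of the canonical name.
#' @export
format_lipid_name <- function(species) {
  stopifnot(inherits(species, "lipid_species"))
  if (is.na(species$total_carbons)) {
    species$lipid_class
  } else {
    sprintf("%s(%d:%d)", species$lipid_class,
            species$total_carbons, species$double_bonds)
  }
}

#' @export
format.lipid_species <- function(x, ...) format_lipid_name(x)

#' @export
print.lipid_species <- function(x, ...) {
  cat("<lipid_species> ", format_lipid_name(x),
      if (x$ether) " [ether]" else "",
      if (x$petrol_washed) " [petrol-washed]" else "",
      if (!x$known_class) " [unknown class]" else "",
      "\n", sep = "")
  invisible(x)
}

#' Does a species contain an odd-numbered fatty-acid chain?
#'
#' An odd total carbon count forces at least one odd-numbered chain, so the
#' test is simply whether \code{total_carbons} is odd.
#'
#' @param species A \code{lipid_species} (or a name, which is parsed).
#' @return \code{TRUE}/\code{FALSE}, or \code{NA} for composition-free
#'   classes such as Chol (with a warning).
#' @examples
#' is_odd_chain(parse_lipid_name("PC(43:2)"))  # TRUE
#' @export
is_odd_chain <- function(species) {
  if (is.character(species)) species <- parse_lipid_name(species)
  stopifnot(inherits(species, "lipid_species"))
  if (is.na(species$total_carbons)) {
    warning("odd-chain test not applicable to composition-free class '",
            species$lipid_class, "'", call. = FALSE)
    return(NA)
  }
  species$total_carbons %% 2L == 1L
}

#' Tag species that are markers of de novo lipogenesis
#'
#' Matches each species against a user-supplied list of marker names by
#' exact canonical-name comparison.  The marker set itself is study-specific
#' configuration; the package ships no default list.
#'
#' @param species_list List of \code{lipid_species} objects, or a character
#'   vector of names.
#' @param marker_names Character vector of canonical marker names.
#' @return Logical vector, one element per species, named by canonical name.
#'   Markers that match no species are reported in the \code{"unmatched"}
#'   attribute (with a warning).
#' @export
tag_dnl_markers <- function(species_list, marker_names) {
  if (is.character(species_list)) {
    species_list <- lapply(species_list, parse_lipid_name)
  }
  canon <- vapply(species_list, format_lipid_name, character(1))
  if (length(marker_names) == 0L) {
    warning("empty marker list: no species tagged", call. = FALSE)
    return(stats::setNames(rep(FALSE, length(canon)), canon))
  }
  tags <- canon %in% marker_names
  unmatched <- setdiff(marker_names, canon)
  if (length(unmatched) > 0L) {
    warning("markers not found among species: ",
            paste(unmatched, collapse = ", "), call. = FALSE)
  }
  structure(stats::setNames(tags, canon), unmatched = unmatched)
}
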
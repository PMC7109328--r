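#' Three-class physicochemical partitions of the amino-acid alphabet
#'
#' The 188D encoder describes each sequence under eight physicochemical
#' attributes. For each attribute the 20 standard amino acids are partitioned
#' into three disjoint classes (e.g. for charge: positive KR, neutral, and
#' negative DE). Composition, transition and distribution descriptors are then
#' computed per class.
#'
#' @return A named list of 8 property schemes, in the frozen encoder order
#'   (hydrophobicity, normalized van der Waals volume, polarity,
#'   polarizability, charge, surface tension, secondary structure, solvent
#'   accessibility). Each scheme is a list with elements `name` and `classes`,
#'   the latter a list of three character vectors of one-letter codes.
#' @examples
#' s <- property_schemes()
#' names(s)
#' s$charge$classes
#' @export
property_schemes <- function() {
  build <- function(name, c1, c2, c3) {
    cls <- lapply(c(c1, c2, c3), function(x) strsplit(x, "")[[1]])
    scheme <- list(name = name, classes = cls)
    class(scheme) <- "property_scheme"
    scheme
  }
  schemes <- list(
    hydrophobicity        = build("hydrophobicity",        "RKEDQN",   "GASTPHY",          "CVLIMFW"),
    normalized_vdw_volume = build("normalized_vdw_volume", "GASCTPD",  "NVEQIL",           "MHKFRYW"),
    polarity              = build("polarity",              "LIFWCMVY", "PATGS",            "HQRKNED"),
    polarizability        = build("polarizability",        "GASDT",    "CPNVEQIL",         "KMHFRYW"),
    charge                = build("charge",                "KR",       "ANCQGHILMFPSTWYV", "DE"),
    surface_tension       = build("surface_tension",       "GQDNAHR",  "KTSEC",            "ILMFPWYV"),
    secondary_structure   = build("secondary_structure",   "EALMQKRH", "VIYCWFT",          "GNPSD"),
    solvent_accessibility = build("solvent_accessibility", "ALFCGIVW", "RKQEND",           "MPSTHY")
  )
  for (s in schemes) validate_scheme(s)
  schemes
}

#' Validate a property scheme
#'
#' Checks that the three classes are disjoint and together cover the 20-letter
#' alphabet exactly.
#'
#' @param scheme a `property_scheme` (list with `name` and `classes`)
#' @return the scheme, invisibly; errors if invalid
#' @export
validate_scheme <- function(scheme) {
  if (is.null(scheme$name) || !nzchar(scheme$name))
    stop_validation("property scheme must be named")
  cls <- scheme$classes
  if (length(cls) != 3L)
    stop_validation("scheme '%s': expected exactly 3 classes, got %d",
                    scheme$name, length(cls))
  all_letters <- sort(unlist(cls))
  if (anyDuplicated(all_letters))
    stop_validation("scheme '%s': classes overlap", scheme$name)
  if (!identical(all_letters, sort(AA_ALPHABET)))
    stop_validation("scheme '%s': classes do not partition the 20-letter alphabet",
                    scheme$name)
  invisible(scheme)
}

#' Read property schemes from a YAML config file
#'
#' Allows users to override or extend the built-in partitions. The file maps
#' scheme names to a list of three strings of one-letter codes, e.g.
#' `charge: [KR, ANCQGHILMFPSTWYV, DE]`.
#'
#' @param path path to a YAML file
#' @return a named list of validated schemes
#' @export
read_schemes <- function(path) {
  raw <- yaml::read_yaml(path)
  if (length(raw) == 0L) stop_validation("no schemes found in '%s'", path)
  out <- lapply(names(raw), function(nm) {
    cls <- lapply(as.character(raw[[nm]]), function(x) strsplit(x, "")[[1]])
    scheme <- list(name = nm, classes = cls)
    class(scheme) <- "property_scheme"
    validate_scheme(scheme)
    scheme
  })
  names(out) <- names(raw)
  out
}

# residue index (1..20) -> class index (1..3), per scheme; cached lookups
scheme_lookup <- function(schemes) {
  lapply(schemes, function(s) {
    lut <- integer(20)
    for (i in 1:3) lut[match(s$classes[[i]], AA_ALPHABET)] <- i
    lut
  })
}
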
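# GC-FAME mole-percent compositions and unsaturation summaries.

parse_fatty_acid_id <- function(id) {
  m <- regmatches(id, regexec("^\\s*(\\d+):(\\d+)", id))
  bad <- vapply(m, length, 0L) != 3L
  if (any(bad)) {
    stop("unparseable fatty-acid identifier(s): ",
         paste(id[bad], collapse = ", "),
         " (expected carbons:double_bonds, e.g. '18:1 d9cis')")
  }
  data.frame(carbons = vapply(m, function(x) as.integer(x[2L]), 0L),
             double_bonds = vapply(m, function(x) as.integer(x[3L]), 0L))
}

#' Fatty-acid mole-percent profile
#'
#' Builds a validated profile from identifiers such as `"16:0"`,
#' `"18:1 d9cis"` or `"18:3 n3"` (the `carbons:double_bonds` prefix is
#' parsed; positional tags are kept but ignored for saturation
#' classification). The literal value `"<LOD"` (below limit of detection,
#' any case) contributes 0 and is recorded in `lod_flags`; it never aborts a
#' downstream ratio. A total mole percent outside [95, 105] triggers an
#' audit warning.
#'
#' @param fatty_acid Character vector of fatty-acid identifiers.
#' @param mol_percent Numeric vector, or character where below-detection
#'   cells are `"<LOD"`.
#' @return An object of class `fatty_acid_profile`: a list with `entries`
#'   (named numeric mole percents), `double_bonds` (named integer),
#'   `lod_flags` (character vector of below-detection identifiers).
#' @examples
#' p <- fatty_acid_profile(c("16:0", "18:1", "18:3"), c(20, 10, 70))
#' unsaturation_ratio(p)
#' @export
fatty_acid_profile <- function(fatty_acid, mol_percent) {
  fatty_acid <- as.character(fatty_acid)
  if (length(fatty_acid) != length(mol_percent)) {
    stop("fatty_acid and mol_percent must have equal length")
  }
  if (anyDuplicated(fatty_acid)) stop("duplicate fatty-acid identifiers")
  lod <- character(0)
  if (is.character(mol_percent) || is.factor(mol_percent)) {
    mol_percent <- trimws(as.character(mol_percent))
    is_lod <- toupper(mol_percent) == "<LOD"
    lod <- fatty_acid[is_lod]
    mol_percent[is_lod] <- "0"
    mol_percent <- as.numeric(mol_percent)
    if (anyNA(mol_percent)) stop("non-numeric mole-percent values (other than '<LOD')")
  }
  if (any(mol_percent < 0)) stop("mole percents must be >= 0")
  parsed <- parse_fatty_acid_id(fatty_acid)
  total <- sum(mol_percent)
  if (total < 95 || total > 105) {
    warning(sprintf("total mole percent %.2f outside [95, 105]; check the table", total))
  }
  structure(list(entries = stats::setNames(mol_percent, fatty_acid),
                 double_bonds = stats::setNames(parsed$double_bonds, fatty_acid),
                 lod_flags = lod),
            class = "fatty_acid_profile")
}

#' @export
print.fatty_acid_profile <- function(x, ...) {
  cat(sprintf("<fatty_acid_profile> %d species, total %.2f %%mol",
              length(x$entries), sum(x$entries)))
  if (length(x$lod_flags)) {
    cat(sprintf(" (<LOD: %s)", paste(x$lod_flags, collapse = ", ")))
  }
  cat("\n")
  invisible(x)
}

#' Unsaturated-to-saturated fatty-acid ratio (U/S)
#'
#' Total mole percent of fatty acids with at least one double bond over the
#' total with none. Below-detection entries contribute 0. A membrane-fluidity
#' proxy; invariant under uniform rescaling of the profile.
#'
#' @param profile A [fatty_acid_profile()].
#' @return The dimensionless U/S ratio.
#' @export
unsaturation_ratio <- function(profile) {
  stopifnot(inherits(profile, "fatty_acid_profile"))
  u <- sum(profile$entries[profile$double_bonds >= 1L])
  s <- sum(profile$entries[profile$double_bonds == 0L])
  if (s == 0) stop("no saturated fatty acid with positive value; U/S undefined")
  u / s
}

#' Trienoic-to-dienoic ratio (18:3/18:2)
#'
#' Mole percent of 18:3 species over 18:2 species (summed over positional
#' isomers). A below-detection 18:3 gives 0; an absent or zero 18:2 is an
#' error.
#'
#' @param profile A [fatty_acid_profile()].
#' @return The dimensionless 18:3/18:2 ratio.
#' @export
trienoic_dienoic_ratio <- function(profile) {
  stopifnot(inherits(profile, "fatty_acid_profile"))
  parsed <- parse_fatty_acid_id(names(profile$entries))
  v183 <- sum(profile$entries[parsed$carbons == 18L & parsed$double_bonds == 3L])
  v182 <- sum(profile$entries[parsed$carbons == 18L & parsed$double_bonds == 2L])
  if (v182 <= 0) stop("18:2 absent or zero; 18:3/18:2 undefined")
  v183 / v182
}

#' Read a fatty-acid composition table
#'
#' Two CSV dialects are understood. `"wide"`: a `fatty_acid` column plus one
#' column per sample (cells numeric or `"<LOD"`). `"long"`: columns
#' `sample`, `fatty_acid`, `mol_percent`.
#'
#' @param path CSV file path.
#' @param format `"wide"` or `"long"`.
#' @return A named list of [fatty_acid_profile()] objects, one per sample.
#' @export
read_fatty_acid_table <- function(path, format = c("wide", "long")) {
  format <- match.arg(format)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (format == "wide") {
    if (!"fatty_acid" %in% names(df)) stop("wide table needs a 'fatty_acid' column")
    samples <- setdiff(names(df), "fatty_acid")
    profiles <- lapply(samples, function(s) fatty_acid_profile(df$fatty_acid, df[[s]]))
    stats::setNames(profiles, samples)
  } else {
    need <- c("sample", "fatty_acid", "mol_percent")
    if (!all(need %in% names(df))) {
      stop("long table needs columns: ", paste(need, collapse = ", "))
    }
    lapply(split(df, df$sample),
           function(d) fatty_acid_profile(d$fatty_acid, d$mol_percent))
  }
}

#' Chloroplast-membrane fatty-acid compositions for barley Delisa and 522DK
#'
#' Published GC-FAME mole-percent compositions of chloroplast membranes from
#' the barley cultivar Delisa (wild type) and its brassinosteroid-deficient
#' mutant 522DK grown at 20, 5 and 27 degrees C; shipped as a plain-text
#' table for the unsaturation-ratio computations.
#'
#' @return A named list of six [fatty_acid_profile()] objects
#'   (`Delisa_20C`, `522DK_20C`, `Delisa_5C`, `522DK_5C`, `Delisa_27C`,
#'   `522DK_27C`).
#' @examples
#' sapply(barley_fatty_acids(), unsaturation_ratio)
#' @export
barley_fatty_acids <- function() {
  path <- system.file("extdata", "barley_chloroplast_fatty_acids.csv",
                      package = "eprdyn", mustWork = TRUE)
  read_fatty_acid_table(path, "wide")
}

#' Unsaturation summaries for a set of fatty-acid profiles
#'
#' @param profiles A named list of [fatty_acid_profile()] objects.
#' @return A data frame with one row per profile: `sample`, `U_S`,
#'   `ratio_18_3_18_2`.
#' @export
fatty_acid_ratios <- function(profiles) {
  stopifnot(is.list(profiles), length(profiles) > 0)
  data.frame(sample = names(profiles),
             U_S = vapply(profiles, unsaturation_ratio, 0),
             ratio_18_3_18_2 = vapply(profiles, trienoic_dienoic_ratio, 0),
             row.names = NULL)
}
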
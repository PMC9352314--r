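# Fatty-acid nomenclature: trivial names, C:D(n-x) shorthand, FAME atom counts.

.trivial_names <- list(
  LIN = list(carbons = 18L, double_bonds = 2L, omega = 6L),
  ALA = list(carbons = 18L, double_bonds = 3L, omega = 3L),
  SDA = list(carbons = 18L, double_bonds = 4L, omega = 3L),
  ARA = list(carbons = 20L, double_bonds = 4L, omega = 6L),
  ETA = list(carbons = 20L, double_bonds = 4L, omega = 3L),
  EPA = list(carbons = 20L, double_bonds = 5L, omega = 3L),
  DPA = list(carbons = 22L, double_bonds = 5L, omega = 3L),
  DHA = list(carbons = 22L, double_bonds = 6L, omega = 3L)
)

#' Register or override the structure of the brain-only fatty acid HTA
#'
#' The identity of "HTA", a fatty acid quantified only in brain tissue, is not
#' standardized; its structural formula must be supplied explicitly before HTA
#' peaks can be methylation-corrected. Until registered, [parse_fa_name()]
#' returns HTA with `NA` atom counts and the mass-balance correction refuses
#' to process it.
#'
#' @param carbons Integer number of acyl carbons.
#' @param double_bonds Integer number of double bonds.
#' @param omega Integer omega position of the first double bond (e.g. `3`),
#'   or `NA` for saturated/other.
#' @return Invisibly, the registered structure as a list.
#' @export
register_hta <- function(carbons, double_bonds, omega = NA_integer_) {
  stopifnot(is.numeric(carbons), is.numeric(double_bonds),
            carbons > double_bonds, carbons > 0, double_bonds >= 0)
  structure_list <- list(carbons = as.integer(carbons),
                         double_bonds = as.integer(double_bonds),
                         omega = as.integer(omega))
  options(isocompass.hta = structure_list)
  invisible(structure_list)
}

.omega_class <- function(double_bonds, omega) {
  if (double_bonds == 0L) return("saturated")
  if (is.na(omega)) return("other")
  if (omega == 3L) return("n-3")
  if (omega == 6L) return("n-6")
  if (omega == 9L) return("n-9")
  "other"
}

#' Parse a fatty-acid name into a structural description
#'
#' Accepts shorthand (`"16:0"`, `"18:1"`, `"20:3n-3"`) or a registered trivial
#' name (LIN, ALA, SDA, ARA, ETA, EPA, DPA, DHA, and HTA if configured via
#' [register_hta()]). Atom counts refer to the methyl ester (FAME): the ester
#' has one carbon more than the acyl chain, and `2*carbons - 2*double_bonds +
#' 2` hydrogens (the carboxyl hydrogen is replaced by a methyl group).
#'
#' @param code Character scalar fatty-acid name.
#' @return An object of class `fatty_acid`: a list with `code`, `carbons`,
#'   `double_bonds`, `omega_class`, `c_count_fame`, `h_count_fame`.
#' @examples
#' parse_fa_name("16:0")   # palmitic acid, FAME C17H34O2
#' parse_fa_name("DHA")
#' @export
parse_fa_name <- function(code) {
  stopifnot(is.character(code), length(code) == 1L, !is.na(code))
  code <- trimws(code)
  up <- toupper(code)
  if (up %in% names(.trivial_names)) {
    s <- .trivial_names[[up]]
    return(.new_fatty_acid(up, s$carbons, s$double_bonds, s$omega))
  }
  if (up == "HTA") {
    s <- getOption("isocompass.hta", NULL)
    if (is.null(s)) {
      return(.new_fatty_acid("HTA", NA_integer_, NA_integer_, NA_integer_))
    }
    return(.new_fatty_acid("HTA", s$carbons, s$double_bonds, s$omega))
  }
  m <- regmatches(code, regexec("^([0-9]{1,2}):([0-9]{1,2})(?:n-([0-9]{1,2}))?$",
                                code))[[1]]
  if (length(m) == 0L) {
    stop("Unknown fatty acid '", code, "'. Use C:D / C:Dn-x shorthand or one of: ",
         paste(c(names(.trivial_names), "HTA"), collapse = ", "), call. = FALSE)
  }
  carbons <- as.integer(m[2])
  dbl <- as.integer(m[3])
  omega <- if (nzchar(m[4])) as.integer(m[4]) else NA_integer_
  if (carbons <= dbl * 2L || carbons < 2L) {
    stop("Malformed fatty acid shorthand '", code, "'", call. = FALSE)
  }
  .new_fatty_acid(code, carbons, dbl, omega)
}

.new_fatty_acid <- function(code, carbons, double_bonds, omega) {
  structure(list(
    code = code,
    carbons = carbons,
    double_bonds = double_bonds,
    omega_class = if (is.na(carbons)) NA_character_ else
      .omega_class(double_bonds, omega),
    c_count_fame = carbons + 1L,
    h_count_fame = 2L * carbons - 2L * double_bonds + 2L
  ), class = "fatty_acid")
}

#' @export
format.fatty_acid <- function(x, ...) x$code

#' @export
print.fatty_acid <- function(x, ...) {
  if (is.na(x$carbons)) {
    cat(sprintf("<fatty_acid> %s (structure unregistered)\n", x$code))
  } else {
    cat(sprintf("<fatty_acid> %s: %d:%d (%s), FAME C%dH%dO2\n",
                x$code, x$carbons, x$double_bonds, x$omega_class,
                x$c_count_fame, x$h_count_fame))
  }
  invisible(x)
}

#' The core 11-fatty-acid panel measured in all tissues
#'
#' Paired delta-13C and delta-2H data for these fatty acids are available in
#' every sample, so they form the default feature panel (22 features). Brain
#' samples additionally carry HTA; pass `core_panel(brain = TRUE)` for the
#' 12-FA brain panel.
#'
#' @param brain If `TRUE`, append HTA for brain-only comparisons.
#' @return Character vector of fatty-acid codes.
#' @export
core_panel <- function(brain = FALSE) {
  panel <- c("14:0", "16:0", "16:1", "18:0", "18:1",
             "LIN", "ALA", "ARA", "EPA", "DPA", "DHA")
  if (brain) panel <- c(panel, "HTA")
  panel
}
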
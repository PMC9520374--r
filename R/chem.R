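# Chemical-formula arithmetic and the modification-reaction registry.

# Monoisotopic masses of the most abundant isotope (CODATA/NIST), Da.
.ISOTOPE_MASS <- c(
  H  = 1.00782503207,
  C  = 12.0,
  N  = 14.0030740048,
  O  = 15.9949146196,
  S  = 31.97207100,
  P  = 30.97376163,
  F  = 18.99840322,
  Cl = 34.96885268,
  Br = 78.9183371,
  I  = 126.904473,
  Na = 22.9897692809,
  K  = 38.96370668
)

# Mass of H2, used for ring-opening (+/-2H) adjusted matches.
.MASS_2H <- 2 * .ISOTOPE_MASS[["H"]]

#' Parse a molecular formula into element counts
#'
#' Accepts Hill-style formula strings of element symbols with optional integer
#' counts, e.g. `"C6H10O5"`. Repeated element tokens (as in `"CH3NH2"` or
#' `"COO"`) are summed. Only elements present in the packaged isotope-mass
#' table are accepted.
#'
#' @param formula A single formula string.
#' @return A named integer vector of element counts (all counts > 0), in Hill
#'   order (C, H, then alphabetical).
#' @examples
#' parse_formula("C6H10O5")
#' parse_formula("CH3NH2")  # == CH5N
#' @export
parse_formula <- function(formula) {
  if (!is.character(formula) || length(formula) != 1L || is.na(formula))
    stop("`formula` must be a single string")
  formula <- trimws(formula)
  if (!nzchar(formula)) stop("empty formula string")
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula, perl = TRUE)[[1]]
  tokens <- regmatches(formula, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(formula))
    stop("malformed formula: ", formula)
  counts <- integer(0)
  for (tok in tokens) {
    sym <- sub("[0-9]*$", "", tok)
    num <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(num)) as.integer(num) else 1L
    if (!sym %in% names(.ISOTOPE_MASS))
      stop("unknown element symbol '", sym, "' in formula ", formula)
    if (n == 0L) stop("malformed formula (zero count): ", formula)
    counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0L) + n
  }
  hill_order(counts)
}

# Order element counts in Hill convention: C first, H second, rest alphabetical.
hill_order <- function(counts) {
  syms <- names(counts)
  rest <- sort(setdiff(syms, c("C", "H")))
  ord <- c(intersect(c("C", "H"), syms), rest)
  counts[ord]
}

#' Write element counts back to a canonical formula string
#'
#' Inverse of [parse_formula()] (round-trips through Hill ordering).
#'
#' @param counts Named integer vector of element counts.
#' @return A single formula string.
#' @export
format_formula <- function(counts) {
  counts <- hill_order(counts)
  paste0(names(counts), ifelse(counts == 1L, "", counts), collapse = "")
}

#' Monoisotopic mass of a formula
#'
#' Sum of element count times the most-abundant-isotope mass, from a small
#' internal CODATA/NIST table (H, C, N, O, S, P, halogens, Na, K).
#'
#' @param counts Named integer vector as returned by [parse_formula()], or a
#'   formula string.
#' @return Mass in Da. The empty formula has mass 0.
#' @examples
#' monoisotopic_mass(parse_formula("CH2O"))  # 30.010565
#' @export
monoisotopic_mass <- function(counts) {
  if (is.character(counts)) counts <- parse_formula(counts)
  if (length(counts) == 0L) return(0)
  missing <- setdiff(names(counts), names(.ISOTOPE_MASS))
  if (length(missing))
    stop("element(s) absent from isotope table: ", paste(missing, collapse = ", "))
  sum(.ISOTOPE_MASS[names(counts)] * as.numeric(counts))
}

.MOD_CATEGORIES <- c("generic", "specific")
.MOD_SUBCATEGORIES <- c("none", "amine-conjugation", "hydroxycinnamoyl-conjugation",
                        "acid-conjugation", "alcohol-conjugation", "isoprenylation")

#' Load a modification-reaction registry
#'
#' Reads a CSV with columns `name,formula,category,subcategory` describing
#' modification reactions observed as neutral losses. The monoisotopic mass of
#' each formula is computed on load. The packaged default registry
#' (`system.file("extdata", "modification_registry.csv", package = "pathprobe")`)
#' holds 61 phenylpropanoid-pathway modifications: 11 generic (methylation,
#' glycosylations, ...) and 50 pathway-specific (amine, hydroxycinnamoyl, acid
#' and alcohol conjugations plus isoprenylation).
#'
#' @param path Path to the registry CSV. Defaults to the packaged registry.
#' @return A `modification_registry`: a data.frame with columns `name`,
#'   `formula`, `category`, `subcategory`, `mass` (Da), ordered as in the file.
#' @export
load_modification_registry <- function(path = default_registry_path()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("name", "formula", "category", "subcategory")
  if (!all(required %in% names(df)))
    stop("registry file must have columns ", paste(required, collapse = ", "))
  if (nrow(df) == 0L) {
    warning("empty modification registry: ", path)
    df$mass <- numeric(0)
    return(structure(df[, c(required, "mass"), drop = FALSE],
                     class = c("modification_registry", "data.frame")))
  }
  if (anyDuplicated(df$name))
    stop("duplicate modification name(s): ",
         paste(unique(df$name[duplicated(df$name)]), collapse = ", "))
  bad_cat <- setdiff(unique(df$category), .MOD_CATEGORIES)
  if (length(bad_cat)) stop("unknown category: ", paste(bad_cat, collapse = ", "))
  bad_sub <- setdiff(unique(df$subcategory), .MOD_SUBCATEGORIES)
  if (length(bad_sub)) stop("unknown subcategory: ", paste(bad_sub, collapse = ", "))
  if (any(df$category == "generic" & df$subcategory != "none") ||
      any(df$category == "specific" & df$subcategory == "none"))
    stop("category/subcategory mismatch: generic entries must have subcategory 'none', specific must not")
  df$mass <- vapply(df$formula, function(f) monoisotopic_mass(parse_formula(f)), numeric(1))
  if (any(df$mass <= 0)) stop("non-positive modification mass")
  rownames(df) <- NULL
  structure(df[, c(required, "mass")],
            class = c("modification_registry", "data.frame"))
}

#' @rdname load_modification_registry
#' @export
default_registry_path <- function() {
  system.file("extdata", "modification_registry.csv", package = "pathprobe",
              mustWork = TRUE)
}

#' @export
print.modification_registry <- function(x, ...) {
  cat("Modification registry:", nrow(x), "reaction types (",
      sum(x$category == "generic"), "generic /",
      sum(x$category == "specific"), "specific )\n")
  print.data.frame(utils::head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more rows\n")
  invisible(x)
}

#' Match an observed mass difference against the modification registry
#'
#' Returns every registry entry whose neutral-loss mass lies within `tol_ppm`
#' of the observed delta. With `allow_h2_adjustment = TRUE`, references shifted
#' by plus or minus one H2 (2 x 1.00782503 Da; e.g. ring opening with loss of
#' two hydrogens) are also tested; adjusted matches are reported explicitly and
#' never merged with exact ones.
#'
#' @param delta Observed mass difference in Da (> 0).
#' @param registry A `modification_registry`.
#' @param tol_ppm Relative tolerance in ppm; the ppm error is computed against
#'   the (possibly H2-adjusted) reference mass:
#'   `1e6 * (observed - reference) / reference`.
#' @param allow_h2_adjustment Also test references at mass +/- 2H.
#' @return A data.frame with one row per match: `name`, `formula`, `category`,
#'   `subcategory`, `ref_mass` (after adjustment), `observed_delta`,
#'   `ppm_error`, `adjustment` (one of `"0"`, `"-2H"`, `"+2H"`), sorted by
#'   absolute ppm error. Zero rows when nothing matches.
#' @examples
#' reg <- load_modification_registry()
#' match_mass_delta(210.0917, reg, tol_ppm = 15)
#' @export
match_mass_delta <- function(delta, registry, tol_ppm = 15,
                             allow_h2_adjustment = FALSE) {
  stopifnot(is.numeric(delta), length(delta) == 1L, delta > 0, tol_ppm > 0)
  adjustments <- if (allow_h2_adjustment) c(0, -.MASS_2H, .MASS_2H) else 0
  adj_labels <- if (allow_h2_adjustment) c("0", "-2H", "+2H") else "0"
  out <- vector("list", length(adjustments))
  for (k in seq_along(adjustments)) {
    ref <- registry$mass + adjustments[k]
    ok <- ref > 0 & abs(delta - ref) / ref * 1e6 <= tol_ppm
    if (!any(ok)) next
    out[[k]] <- data.frame(
      name = registry$name[ok],
      formula = registry$formula[ok],
      category = registry$category[ok],
      subcategory = registry$subcategory[ok],
      ref_mass = ref[ok],
      observed_delta = delta,
      ppm_error = (delta - ref[ok]) / ref[ok] * 1e6,
      adjustment = adj_labels[k],
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out))
    return(data.frame(name = character(0), formula = character(0),
                      category = character(0), subcategory = character(0),
                      ref_mass = numeric(0), observed_delta = numeric(0),
                      ppm_error = numeric(0), adjustment = character(0),
                      stringsAsFactors = FALSE))
  out <- out[order(abs(out$ppm_error), out$name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Load the packaged characteristic-ion table
#'
#' Diagnostic fragment ions indicating a specific substructure (e.g. the
#' coumaric acid ion at m/z 163.0377 in negative mode). The table is metadata
#' supplied with the package and user-extensible via `path`.
#'
#' @param path CSV with columns `name,mz,polarity`.
#' @return data.frame with those columns.
#' @export
load_characteristic_ions <- function(path = system.file(
  "extdata", "characteristic_ions.csv", package = "pathprobe", mustWork = TRUE)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "mz", "polarity") %in% names(df)))
  if (nrow(df) && any(df$mz <= 0)) stop("characteristic ion m/z must be > 0")
  df
}
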
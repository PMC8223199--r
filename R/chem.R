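# Exact-mass arithmetic: molecular formulas, monoisotopic masses, and the
# adduct registry from which every mass difference used elsewhere derives.

# Monoisotopic masses (Da) of the most abundant isotope of each element,
# plus named isotopes addressable as bracketed symbols such as "[13C]".
# Values from the IUPAC/AME compilations, >= 6 decimals.
.isotope_masses <- c(
  H  = 1.00782503207, C  = 12.0,          N  = 14.0030740048,
  O  = 15.9949146196, F  = 18.99840322,   Na = 22.9897692809,
  Mg = 23.98504170,   Si = 27.9769265325, P  = 30.97376163,
  S  = 31.97207100,   Cl = 34.96885268,   K  = 38.96370668,
  Ca = 39.96259098,   Mn = 54.93804510,   Fe = 55.93493750,
  Cu = 62.92959750,   Zn = 63.92914220,   Se = 79.91652130,
  Br = 78.91833710,   Ag = 106.90509700,  I  = 126.90447300,
  `2H` = 2.0141017778, `13C` = 13.0033548378, `15N` = 15.0001088982,
  `18O` = 17.99916100, `34S` = 33.96786690,   `37Cl` = 36.96590259,
  `41K` = 40.96182576, `107Ag` = 106.90509160, `109Ag` = 108.90475200
)

.electron_mass <- 0.00054857990946

#' Mass of the proton
#'
#' Monoisotopic mass of the hydrogen atom minus the electron mass, i.e. the
#' mass added by protonation of a neutral molecule to form `[M+H]+`.
#'
#' @return Proton mass in Da.
#' @export
proton_mass <- function() .isotope_masses[["H"]] - .electron_mass

.formula_token_re <-
  "(\\[[0-9]+[A-Z][a-z]?\\]|[A-Z][a-z]?)(-?[0-9]+)?"

#' Parse a molecular formula
#'
#' Formulas use element symbols with optional counts (`"C7H4O3"`), optional
#' bracketed isotope labels (`"[13C]"`, `"[107Ag]"`), and signed counts for
#' net composition changes: a minus sign before the count marks a loss, so
#' `"NaH-1"` means one Na gained and one H lost.  Whitespace is ignored.
#'
#' @param text A single formula string; `""` is the empty formula (mass 0).
#' @return A `mol_formula`: named numeric vector of signed integer element
#'   counts.  Zero counts are dropped.
#' @examples
#' parse_formula("C7H4O3")
#' parse_formula("NaH-1")
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop("'text' must be a single formula string")
  text <- gsub("[[:space:]]+", "", text)
  counts <- numeric(0)
  if (nzchar(text)) {
    m <- gregexpr(.formula_token_re, text, perl = TRUE)[[1]]
    toks <- regmatches(text, list(m))[[1]]
    # every character must belong to some token, in order
    consumed <- paste0(toks, collapse = "")
    if (!identical(consumed, text) || m[1] != 1L) {
      # locate first unparsed position
      pos <- 1L
      for (k in seq_along(toks)) {
        if (m[k] != pos) break
        pos <- pos + nchar(toks[k])
      }
      stop(sprintf("malformed formula '%s': cannot parse at position %d ('%s')",
                   text, pos, substr(text, pos, nchar(text))))
    }
    parts <- regmatches(toks, regexec(.formula_token_re, toks, perl = TRUE))
    for (p in parts) {
      sym <- p[2]
      key <- gsub("\\[|\\]", "", sym)
      if (!key %in% names(.isotope_masses))
        stop(sprintf("unknown element or isotope symbol '%s'", sym))
      n <- if (nzchar(p[3])) as.numeric(p[3]) else 1
      counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0) + n
    }
  }
  counts <- counts[counts != 0]
  structure(counts, class = "mol_formula")
}

.as_formula <- function(f) {
  if (inherits(f, "mol_formula")) return(f)
  if (is.character(f)) return(parse_formula(f))
  if (is.numeric(f) && (length(f) == 0L || !is.null(names(f))))
    return(structure(f[f != 0], class = "mol_formula"))
  stop("cannot interpret object as a molecular formula")
}

# canonical (Hill) ordering: C, H, then remaining symbols alphabetically;
# bracketed isotopes sort with their element, after the plain symbol
.formula_order <- function(syms) {
  elem <- gsub("\\[[0-9]+|\\]", "", syms)
  iso <- rep(0, length(syms))
  br <- grepl("^\\[", syms)
  iso[br] <- as.numeric(sub("^\\[([0-9]+).*", "\\1", syms[br]))
  rank <- match(elem, c("C", "H"), nomatch = 3L)
  order(rank, elem, iso)
}

#' @export
format.mol_formula <- function(x, ...) {
  if (length(x) == 0L) return("")
  x <- x[.formula_order(names(x))]
  paste0(names(x), ifelse(x == 1, "", x), collapse = "")
}

#' @export
print.mol_formula <- function(x, ...) {
  cat("<formula> ", format(x), "  (", sprintf("%.5f", monoisotopic_mass(x)),
      " Da)\n", sep = "")
  invisible(x)
}

#' @export
Ops.mol_formula <- function(e1, e2) {
  if (!.Generic %in% c("+", "-"))
    stop(sprintf("operation '%s' not defined for formulas", .Generic))
  if (missing(e2)) {  # unary minus
    return(structure(-unclass(e1), class = "mol_formula"))
  }
  a <- unclass(.as_formula(e1)); b <- unclass(.as_formula(e2))
  if (.Generic == "-") b <- -b
  syms <- union(names(a), names(b))
  out <- numeric(length(syms)); names(out) <- syms
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] + b
  structure(out[out != 0], class = "mol_formula")
}

#' Monoisotopic mass of a composition
#'
#' Sum of signed element counts times the mass of the most abundant isotope
#' (or the named isotope for bracketed symbols such as `[13C]`).
#'
#' @param f A `mol_formula` or a formula string.
#' @return Mass in Da (can be negative for a net-loss composition).
#' @examples
#' monoisotopic_mass("C7H4O3")  # 136.016, the DHB-H2O adduct mass shift
#' @export
monoisotopic_mass <- function(f) {
  f <- .as_formula(f)
  if (length(f) == 0L) return(0)
  keys <- gsub("\\[|\\]", "", names(f))
  missing <- setdiff(keys, names(.isotope_masses))
  if (length(missing))
    stop(sprintf("no monoisotopic mass tabulated for symbol(s): %s",
                 paste(missing, collapse = ", ")))
  sum(unclass(f) * .isotope_masses[keys])
}

#' m/z of a singly protonated ion
#'
#' `[M+H]+` m/z of a neutral composition: monoisotopic mass plus the proton
#' mass (H atom minus electron).  Only singly charged positive ions are
#' supported.
#'
#' @param neutral Neutral molecule, as `mol_formula` or formula string.
#' @param charge Must be `1`.
#' @return m/z in Da.
#' @examples
#' ion_mz("C44H86NO8P")  # PC(36:1) [M+H]+ = 788.616
#' @export
ion_mz <- function(neutral, charge = 1L) {
  if (!identical(as.integer(charge), 1L))
    stop("only singly charged positive ions (charge = +1) are supported")
  f <- .as_formula(neutral)
  if (any(unclass(f) < 0))
    stop("a neutral molecule must have non-negative element counts")
  monoisotopic_mass(f) + proton_mass()
}

.adduct_categories <- c("isotope", "alkali", "matrix", "control", "custom")

#' Build an adduct registry
#'
#' An adduct registry is an ordered table of named mass-difference
#' hypotheses.  Each entry's `delta_mass` is derived from its net formula
#' change via [monoisotopic_mass()]; it is never hand-entered.
#'
#' @param name Character vector of unique entry names.
#' @param formula Net composition change of the adduct ion relative to the
#'   parent ion (both singly charged), as formula strings with signed counts
#'   (e.g. `"NaH-1"` for Na-for-H gain).
#' @param category One of `"isotope"`, `"alkali"`, `"matrix"`, `"control"`,
#'   `"custom"` per entry (recycled).
#' @param source Provenance label.
#' @return An `adduct_registry` data frame with columns `name`, `formula`,
#'   `delta_mass`, `category`.
#' @export
adduct_registry <- function(name, formula, category = "custom",
                            source = "user") {
  name <- as.character(name); formula <- as.character(formula)
  category <- rep_len(as.character(category), length(name))
  stopifnot(length(formula) == length(name))
  bad <- setdiff(unique(category), .adduct_categories)
  if (length(bad))
    stop("unknown adduct category: ", paste(bad, collapse = ", "))
  if (anyDuplicated(name))
    stop("duplicate adduct names: ",
         paste(unique(name[duplicated(name)]), collapse = ", "))
  delta <- vapply(formula, function(f) monoisotopic_mass(parse_formula(f)),
                  numeric(1), USE.NAMES = FALSE)
  if (length(delta) > 1L) {
    d <- sort(delta)
    close <- which(diff(d) < 1e-4)
    if (length(close))
      warning(sprintf(
        "registry entries closer than 1e-4 Da (near %.5f Da) are not resolvable",
        d[close[1]]))
  }
  structure(
    data.frame(name = name, formula = formula, delta_mass = delta,
               category = category, stringsAsFactors = FALSE),
    class = c("adduct_registry", "data.frame"),
    source = source)
}

#' Built-in adduct registry
#'
#' The default mass-difference hypotheses: the 13C isotope companion, the
#' alkali exchanges Na-H and K-H, an implausible-control entry (107Ag-H,
#' silver having no biological role), and matrix adducts for the chosen
#' MALDI matrix -- DHB (2,5-dihydroxybenzoic acid, C7H6O4) as the intact
#' molecule, its water-loss form C7H4O3 and the 2x/3x water-loss oligomers,
#' or CHCA (alpha-cyano-4-hydroxycinnamic acid, C10H7NO3) intact and with an
#' additional sodium.  All shifts are relative to the singly charged parent
#' ion, so e.g. `[M+Na]+` vs `[M+H]+` is the net change `NaH-1`.
#'
#' @param matrix MALDI matrix whose adduct entries to include: `"DHB"`,
#'   `"CHCA"`, or `"none"` (isotope/alkali/control entries only).
#' @param include_water_loss Also include the in-source water loss entry
#'   (`delta_mass` -18.011 Da); off by default because all default entries
#'   are required to be heavier than the parent.
#' @return An [adduct_registry()].
#' @examples
#' default_registry("DHB")
#' @export
default_registry <- function(matrix = c("DHB", "CHCA", "none"),
                             include_water_loss = FALSE) {
  matrix <- match.arg(matrix)
  name <- c("13C", "Na-H", "K-H", "Ag107-H")
  formula <- c("[13C]C-1", "NaH-1", "KH-1", "[107Ag]H-1")
  category <- c("isotope", "alkali", "alkali", "control")
  if (matrix == "DHB") {
    name <- c(name, "DHB-H2O", "DHB", "2(DHB-H2O)", "3(DHB-H2O)")
    formula <- c(formula, "C7H4O3", "C7H6O4", "C14H8O6", "C21H12O9")
    category <- c(category, rep("matrix", 4))
  } else if (matrix == "CHCA") {
    name <- c(name, "CHCA", "CHCA+Na")
    formula <- c(formula, "C10H7NO3", "C10H7NO3Na")
    category <- c(category, rep("matrix", 2))
  }
  if (include_water_loss) {
    name <- c(name, "-H2O")
    formula <- c(formula, "H-2O-1")
    category <- c(category, "custom")
  }
  adduct_registry(name, formula, category, source = "built-in")
}

#' Load an adduct registry from CSV
#'
#' The CSV has header `name,formula,category`; lines starting with `#` are
#' comments.  Mass shifts are derived from the formulas on load.
#'
#' @param path CSV file path.
#' @param base Optional registry to extend; file entries whose name
#'   duplicates a `base` entry replace it with a warning.
#' @return An [adduct_registry()].
#' @export
load_registry <- function(path, base = NULL) {
  if (!file.exists(path)) stop("registry file not found: ", path)
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("name", "formula", "category")
  if (!all(need %in% names(tab)))
    stop("registry CSV must have columns: ", paste(need, collapse = ", "))
  if (nrow(tab)) {
    for (i in seq_len(nrow(tab))) {
      ok <- tryCatch({ parse_formula(tab$formula[i]); TRUE },
                     error = function(e) e)
      if (!isTRUE(ok))
        stop(sprintf("registry row %d ('%s'): %s", i, tab$name[i],
                     conditionMessage(ok)))
    }
  }
  loaded <- if (nrow(tab))
    adduct_registry(tab$name, tab$formula, tab$category,
                    source = paste0("file:", path))
  else
    structure(
      data.frame(name = character(), formula = character(),
                 delta_mass = numeric(), category = character(),
                 stringsAsFactors = FALSE),
      class = c("adduct_registry", "data.frame"),
      source = paste0("file:", path))
  if (is.null(base)) return(loaded)
  dup <- intersect(loaded$name, base$name)
  if (length(dup)) {
    warning("replacing registry entries: ", paste(dup, collapse = ", "))
    base <- base[!base$name %in% dup, , drop = FALSE]
  }
  out <- rbind(as.data.frame(base), as.data.frame(loaded))
  rownames(out) <- NULL
  structure(out, class = c("adduct_registry", "data.frame"),
            source = "combined")
}

#' @export
print.adduct_registry <- function(x, ...) {
  cat(sprintf("Adduct registry (%d entries, %s)\n", nrow(x),
              attr(x, "source") %||% "unknown"))
  df <- as.data.frame(x)
  df$delta_mass <- sprintf("%+.5f", df$delta_mass)
  print(df, row.names = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
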
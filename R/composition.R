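# Elemental compositions are named integer vectors: names are nuclide keys
# ("C", "H", "[2]H", ...), values are signed counts.  A physical molecule has
# all counts >= 0; a modification delta may carry negative counts.

#' Build an elemental composition
#'
#' @param ... named integer counts, e.g. `comp(C = 5, H = 15, N = 1, O = 4, P = 1)`.
#' @return named integer vector of class `lf_comp`.
#' @export
#' @examples
#' comp(C = 2, H = 4, O = 2)
comp <- function(...) {
  x <- c(...)
  if (is.null(x)) x <- integer(0)
  if (is.null(names(x)) && length(x) > 0)
    stop("composition counts must be named by nuclide", call. = FALSE)
  bad <- setdiff(names(x), rownames(.NUCLIDES))
  if (length(bad))
    stop("unknown nuclide(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (any(x != round(x))) stop("counts must be integers", call. = FALSE)
  x <- x[x != 0]
  structure(as.integer(round(x)), names = names(x), class = "lf_comp")
}

.as_comp <- function(x) {
  structure(as.integer(x), names = names(x), class = "lf_comp")
}

#' Sum of elemental compositions
#'
#' @param ... compositions (named integer vectors).
#' @return combined composition; counts add, zeros are dropped.
#' @export
comp_add <- function(...) {
  parts <- list(...)
  keys <- unique(unlist(lapply(parts, names)))
  if (is.null(keys)) return(comp())
  tot <- vapply(keys, function(k) {
    sum(vapply(parts, function(p) {
      v <- p[k]
      if (is.na(v)) 0L else as.integer(v)
    }, integer(1)))
  }, integer(1))
  tot <- tot[tot != 0L]
  .as_comp(tot)
}

#' Difference of elemental compositions (a - b)
#' @param a,b compositions.
#' @export
comp_diff <- function(a, b) comp_add(a, comp_scale(b, -1L))

#' Scale a composition by an integer factor
#' @param x composition.
#' @param k integer factor.
#' @export
comp_scale <- function(x, k) {
  y <- as.integer(x) * as.integer(k)
  names(y) <- names(x)
  .as_comp(y[y != 0L])
}

.comp_is_physical <- function(x) all(as.integer(x) >= 0L)

# after merging, heavy counts must not exceed element totals; a physical
# composition holds the light and heavy nuclides as separate entries, so this
# is just non-negativity of each entry (checked by .comp_is_physical).

#' @export
print.lf_comp <- function(x, ...) {
  cat(format_formula(x), "\n")
  invisible(x)
}

#' @export
format.lf_comp <- function(x, ...) format_formula(x)

# ---------------------------------------------------------------------------
# Parsing

.FORMULA_TOKEN <- "(\\[[0-9]+\\])?([A-Z][a-z]?)([0-9]*)"

#' Parse a Hill-style chemical formula
#'
#' Accepts formulas such as `"C5H15NO4P"`, bracketed heavy nuclides such as
#' `"[2]H3"` and an optional leading `"+"` or `"-"` that marks the whole
#' formula as a positive or negated modification delta.
#'
#' @param text formula string; `""` yields the empty composition.
#' @return an `lf_comp` composition.
#' @export
#' @examples
#' parse_formula("C5H15NO4P")
#' parse_formula("-H2O")
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  text <- gsub("[[:space:]]", "", text)
  sign <- 1L
  if (grepl("^[+-]", text)) {
    if (substr(text, 1, 1) == "-") sign <- -1L
    text <- substring(text, 2)
  }
  if (text == "") return(comp())
  counts <- integer(0)
  pos <- 1L
  n <- nchar(text)
  while (pos <= n) {
    m <- regexpr(paste0("^", .FORMULA_TOKEN), substring(text, pos), perl = TRUE)
    if (m == -1L || attr(m, "match.length") == 0L)
      stop("malformed formula at '", substring(text, pos), "'", call. = FALSE)
    tok <- regmatches(substring(text, pos), m)
    parts <- regmatches(tok, regexec(paste0("^", .FORMULA_TOKEN, "$"), tok, perl = TRUE))[[1]]
    key <- paste0(parts[2], parts[3])
    if (!key %in% rownames(.NUCLIDES))
      stop("unknown element symbol '", key, "' in formula '", text, "'", call. = FALSE)
    cnt <- if (parts[4] == "") 1L else as.integer(parts[4])
    counts[key] <- (if (key %in% names(counts)) counts[key] else 0L) + cnt
    pos <- pos + attr(m, "match.length")
  }
  comp_scale(.as_comp(counts), sign)
}

# ---------------------------------------------------------------------------
# Formatting

# Canonical order: Hill (C first, H second, remaining alphabetical), with the
# metal adduct atoms (Na, K, Li) moved last so printed fragment names match
# the field's convention "(+ONa)".  Heavy nuclides render inline at the
# position of their element, after the light entry: "C2[13]C2H4".
.comp_order <- function(keys) {
  el <- .nuclide_element(keys)
  heavy <- .is_heavy(keys)
  has_c <- any(el == "C")
  rank <- function(e) {
    if (e %in% .METALS) return(paste0("zz", match(e, .METALS)))
    if (has_c && e == "C") return("0")
    if (has_c && e == "H") return("1")
    paste0("m", e)
  }
  keys[order(vapply(el, rank, character(1)), heavy, method = "radix")]
}

.format_counts <- function(x) {
  keys <- .comp_order(names(x))
  paste0(vapply(keys, function(k) {
    n <- x[k]
    paste0(k, if (n == 1L) "" else n)
  }, character(1)), collapse = "")
}

#' Format an elemental composition as a Hill-style formula
#'
#' @param x composition (`lf_comp` or named integer vector).
#' @param delta if `TRUE`, render as a signed modification delta, grouping
#'   added atoms under a leading `"+"` and removed atoms under `"-"`,
#'   e.g. `"+O -C7H15"`.
#' @return formula string (empty string for the empty composition).
#' @export
#' @examples
#' format_formula(comp(C = 5, H = 15, N = 1, O = 4, P = 1))
#' format_formula(comp(O = 1, C = -7, H = -15), delta = TRUE)
format_formula <- function(x, delta = FALSE) {
  x <- x[as.integer(x) != 0L]
  if (length(x) == 0) return("")
  if (!delta) {
    if (any(as.integer(x) < 0L))
      stop("negative counts: format with delta = TRUE", call. = FALSE)
    return(.format_counts(x))
  }
  pos <- x[as.integer(x) > 0L]
  neg <- x[as.integer(x) < 0L]
  out <- character(0)
  if (length(pos)) out <- c(out, paste0("+", .format_counts(pos)))
  if (length(neg)) out <- c(out, paste0("-", .format_counts(comp_scale(.as_comp(neg), -1L))))
  paste(out, collapse = " ")
}

#' Parse a signed modification delta
#'
#' Accepts mixed-sign deltas in the notation used inside fragment-name
#' parentheses, e.g. `"+O -C7H15"`, `"-H"`, `"+HONa"`, `"+[2]H3"`.
#'
#' @param text delta string; `""` yields the empty composition.
#' @return an `lf_comp` composition with signed counts.
#' @export
parse_delta <- function(text) {
  text <- trimws(text)
  if (text == "") return(comp())
  squeezed <- gsub("[[:space:]]", "", text)
  toks <- regmatches(squeezed, gregexpr("[+-][^+-]+", squeezed))[[1]]
  if (!length(toks) || nchar(paste(toks, collapse = "")) != nchar(squeezed))
    stop("malformed delta '", text, "': each group must be signed", call. = FALSE)
  Reduce(comp_add, lapply(toks, parse_formula))
}

# ---------------------------------------------------------------------------
# Masses

#' Monoisotopic mass of a composition
#'
#' Linear in the composition: heavy nuclides contribute their exact isotope
#' mass.  Negative counts are allowed for modification deltas, in which case
#' the result is a (possibly negative) mass difference.
#'
#' @param x composition.
#' @return mass in Da.
#' @export
#' @examples
#' monoisotopic_mass(parse_formula("NH3"))   # 17.0265
monoisotopic_mass <- function(x) {
  if (length(x) == 0) return(0)
  sum(.NUCLIDES[names(x), "mono"] * as.integer(x))
}

#' Nominal (integer) mass of a composition
#'
#' Sums mass numbers, so heavy hydrogen counts 2, heavy carbon 13 etc.  Used
#' for the parenthesized labels of lipid class-selective fragments, e.g.
#' `PC(184)`.
#'
#' @param x composition.
#' @return integer mass in Da.
#' @export
nominal_mass <- function(x) {
  if (length(x) == 0) return(0L)
  as.integer(sum(.NUCLIDES[names(x), "nominal"] * as.integer(x)))
}

#' m/z of an ion
#'
#' The composition must contain the full atom inventory of the ion (adduct
#' atoms merged in); the charge only adjusts the electron bookkeeping:
#' m/z = (mass - z * m_e) / |z|.
#'
#' @param x ion composition.
#' @param z signed integer charge (non-zero).
#' @return m/z value.
#' @export
#' @examples
#' ion_mz(parse_formula("C5H15NO4P"), 1)  # 184.0733, the phosphocholine cation
ion_mz <- function(x, z) {
  z <- as.integer(z)
  if (length(z) != 1 || z == 0L) stop("charge must be a non-zero integer", call. = FALSE)
  (monoisotopic_mass(x) - z * .ELECTRON_MASS) / abs(z)
}

# ---------------------------------------------------------------------------
# Stable isotope labels

#' Parse an isotope label specification
#'
#' @param text label such as `"[2]H13"` or `"[13]C2[15]N"`, optionally with a
#'   leading `"+"`.  `""` yields the empty label.
#' @return named integer vector of heavy-nuclide counts (all > 0).
#' @export
parse_label <- function(text) {
  text <- sub("^\\+", "", trimws(text))
  x <- parse_formula(text)
  if (length(x) && !all(.is_heavy(names(x))))
    stop("label may contain only bracketed heavy nuclides: '", text, "'", call. = FALSE)
  if (any(as.integer(x) < 0L)) stop("label counts must be positive", call. = FALSE)
  x
}

#' Format an isotope label
#'
#' Heavy nuclides are ordered by their element in Hill order, matching names
#' like `"(+[13]C2[15]N)"`.
#'
#' @param label named integer vector of heavy-nuclide counts.
#' @param sign prepend `"+"` (default `TRUE`).
#' @return label string, `""` for the empty label.
#' @export
format_label <- function(label, sign = TRUE) {
  if (is.null(label) || length(label) == 0) return("")
  paste0(if (sign) "+" else "", .format_counts(.as_comp(label)))
}

#' Substitute heavy nuclides into a composition
#'
#' Replaces `n` light atoms of each labeled element by `n` heavy nuclides; the
#' monoisotopic mass increases by exactly the per-nuclide mass differences.
#'
#' @param x composition (light atoms available for substitution).
#' @param label heavy-nuclide counts, e.g. `parse_label("[2]H13")`.
#' @return labeled composition.
#' @export
#' @examples
#' apply_label(parse_formula("C5H15NO4P"), parse_label("[2]H13"))
apply_label <- function(x, label) {
  if (is.null(label) || length(label) == 0) return(x)
  for (k in names(label)) {
    el <- .nuclide_element(k)
    have <- if (el %in% names(x)) as.integer(x[el]) else 0L
    need <- as.integer(label[k])
    if (have < need)
      stop("over-substitution: label needs ", need, " ", el,
           " but composition has ", have, call. = FALSE)
    x <- comp_add(x, .as_comp(structure(need, names = k)),
                  .as_comp(structure(-need, names = el)))
  }
  x
}
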
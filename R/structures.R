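# Lipid class structural templates: elemental composition of intact lipids,
# of minimal hydrocarbon chain-based attributes (HCAs), and precursor ions.

# Chain contribution to the intact molecule, by slot linkage chemistry.
# Ester/amide slots condense a free fatty acid with loss of water; ether
# slots attach an alkyl/alkenyl chain to a backbone oxygen (the displayed
# double-bond count of an alkenyl "p" chain includes the vinyl-ether double
# bond, so alkyl and alkenyl share one formula); the lcb slot contributes the
# free long-chain base; the sterol slot the intact sterol.
.chain_contribution <- function(ch, linkage) {
  c <- ch$carbons; db <- ch$db; oh <- ch$oh
  base <- switch(linkage,
    ester = comp(C = c, H = 2 * c - 2 - 2 * db, O = 1 + oh),
    amide = comp(C = c, H = 2 * c - 2 - 2 * db, O = 1 + oh),
    ether = comp(C = c, H = 2 * c - 2 * db, O = oh),
    lcb   = comp(C = c, H = 2 * c + 3 - 2 * db, N = 1, O = oh),
    sterol = comp(C = c, H = 2 * c - 6 - 2 * db, O = 1 + oh),
    stop("unknown linkage '", linkage, "'", call. = FALSE)
  )
  if (!is.null(ch$label)) base <- apply_label(base, ch$label)
  base
}

# Reference composition of an HCA for fragment naming.  The FA base is the
# acylium reference C_c H_(2c-1-2db) O_(1+oh): base + O is the carboxylate,
# base + HO the free fatty acid, base - H the ketene.
.hca_base <- function(ch, hca = ch$hca, labeled = TRUE) {
  c <- ch$carbons; db <- ch$db; oh <- ch$oh
  base <- switch(hca,
    FA  = comp(C = c, H = 2 * c - 1 - 2 * db, O = 1 + oh),
    LCB = comp(C = c, H = 2 * c + 3 - 2 * db, N = 1, O = oh),
    ST  = comp(C = c, H = 2 * c - 6 - 2 * db, O = 1 + oh),
    ETH = comp(C = c, H = 2 * c + 1 - 2 * db, O = 1 + oh),
    stop("unknown HCA class '", hca, "'", call. = FALSE)
  )
  if (labeled && !is.null(ch$label)) base <- apply_label(base, ch$label)
  base
}

#' Composition of an HCA-derived fragment part
#'
#' Reference HCA base of a chain plus a modification delta.  The fatty-acyl
#' base is the acylium reference, so `hca_composition(ch, parse_delta("+O"))`
#' is the carboxylate, `"+HO"` the free fatty acid and `"-H"` the ketene.
#'
#' @param ch a chain from a parsed [parse_lipid()] name (needs fields
#'   `carbons`, `db`, `oh`, `hca` and optionally `label`).
#' @param modification delta composition (default empty).
#' @return `lf_comp` composition.
#' @export
hca_composition <- function(ch, modification = comp()) {
  out <- comp_add(.hca_base(ch), modification)
  if (!.comp_is_physical(out))
    stop("negative atom counts for chain modification", call. = FALSE)
  out
}

#' Elemental composition of an intact lipid
#'
#' Backbone plus linkage-adjusted chain contributions; isotope labels on the
#' class symbol and on chains are propagated into the composition.
#'
#' @param n a molecular- or sn-level `lipid_name`.
#' @return neutral-molecule composition.
#' @export
#' @examples
#' format_formula(intact_composition(parse_lipid("PC 18:3-18:3")))  # C44H76NO8P
intact_composition <- function(n) {
  stopifnot(inherits(n, "lipid_name"))
  if (n$level == "species")
    stop("intact composition needs per-chain information (molecular or sn level)",
         call. = FALSE)
  tmpl <- .class_template(n$class)
  parts <- lapply(seq_along(n$chains), function(i)
    .chain_contribution(n$chains[[i]], tmpl$slots[[i]]$linkage))
  out <- Reduce(comp_add, parts, tmpl$backbone)
  if (!is.null(n$class_label)) out <- apply_label(out, n$class_label)
  if (!.comp_is_physical(out))
    stop("non-physical composition for ", format_lipid(n), call. = FALSE)
  out
}

#' Build a precursor ion
#'
#' @param n a molecular- or sn-level `lipid_name` (parsed or a string).
#' @param adduct adduct symbol (e.g. `"+NH4"`) or an [adduct_spec()] list.
#' @return object of class `precursor_ion`: list with the intact lipid, ion
#'   composition (adduct atoms merged), charge, m/z and the bracketed display
#'   name, e.g. `"[PC 36:6+CH3COO]-"` (precursors display at species level).
#' @export
#' @examples
#' precursor_ion("TAG 16:0-18:0-18:2", "+NH4")
precursor_ion <- function(n, adduct) {
  if (is.character(n)) n <- parse_lipid(n)
  if (is.character(adduct)) adduct <- adduct_spec(adduct)
  tmpl <- .class_template(n$class)
  supported <- if (adduct$z > 0) tmpl$adducts_pos else tmpl$adducts_neg
  if (!adduct$symbol %in% supported)
    stop("adduct ", adduct$symbol, " not supported for class ", n$class,
         call. = FALSE)
  intact <- intact_composition(n)
  ion <- comp_add(intact, adduct$delta)
  if (!.comp_is_physical(ion))
    stop("adduct ", adduct$symbol, " removes atoms ", format_lipid(n),
         " does not have", call. = FALSE)
  z <- adduct$z
  zsuf <- paste0(if (abs(z) > 1) abs(z) else "", if (z > 0) "+" else "-")
  display <- paste0("[", format_lipid(species_of(n)), adduct$symbol, "]", zsuf)
  structure(list(lipid = n, adduct = adduct, intact = intact, comp = ion,
                 z = z, mz = ion_mz(ion, z), display = display),
            class = "precursor_ion")
}

#' @export
print.precursor_ion <- function(x, ...) {
  cat(sprintf("%s  m/z %.4f  (%s, z=%+d)\n", x$display, x$mz,
              format_formula(x$comp), x$z))
  invisible(x)
}
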
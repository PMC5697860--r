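# Shorthand notation for fragment parts, the prioritization decision tree,
# and the dual "PRIORITIZED | other" rendering.
#
# Naming rules:
#   * neutral fragments are prefixed "-", charged fragments are not;
#   * LCFs: class abbreviation + nominal mass in parentheses, "PC(184)",
#     with an isotope label inline: "PC(+[2]H13)(197)";
#   * MLFs/iMLFs/DBFs: HCA class + C:DB(;OH) (+label) + signed Hill delta in
#     parentheses: "FA 18:3(+C7H16NO6P)", "-FA 16:0(+[2]H3)(-H)",
#     "DAG 28:2(+C6H11O9P2)", "FA 18:1(9)(+O -C7H15)".

.FRAG_PRIORITY <- c(DBF = 1L, MLF = 2L, LCF = 3L, iMLF = 4L)

.hca_symbol <- function(hca) switch(hca, FA = "FA", LCB = "LCB", ST = "ST",
                                    ETH = "O-", hca)

.name_lcf <- function(comp, label_class, label = NULL) {
  paste0(label_class,
         if (!is.null(label) && length(label)) paste0("(", format_label(label), ")") else "",
         "(", nominal_mass(comp), ")")
}

.name_hca_part <- function(ch, delta) {
  sym <- .hca_symbol(ch$hca)
  tok <- .format_chain_token(ch)
  head <- if (sym == "O-") paste0(sym, tok) else paste(sym, tok)
  d <- format_formula(delta, delta = TRUE)
  paste0(head, if (nzchar(d)) paste0("(", d, ")") else "")
}

# species-style name of a multi-chain remainder: "<class> C:DB(;OH)(+label)(delta)"
.name_multichain <- function(rem_class, chains, delta) {
  tot <- .chain_totals(chains)
  labels <- Filter(Negate(is.null), lapply(chains, `[[`, "label"))
  lab <- if (length(labels)) Reduce(comp_add, labels) else NULL
  d <- format_formula(delta, delta = TRUE)
  paste0(.class_prefix(rem_class),
         tot[["carbons"]], ":", tot[["db"]],
         if (tot[["oh"]] > 0) paste0(";", tot[["oh"]]) else "",
         if (!is.null(lab)) paste0("(", format_label(lab), ")") else "",
         if (nzchar(d)) paste0("(", d, ")") else "")
}

#' Shorthand name of a single fragment part
#'
#' @param part a fragment part from an enumerated reaction (see
#'   [enumerate_fragments()]); has fields `name`, `type`, `charged`.
#' @param neutral_prefix prefix neutral parts with `"-"` (default `TRUE`).
#' @return the shorthand string.
#' @export
name_part <- function(part, neutral_prefix = TRUE) {
  paste0(if (neutral_prefix && !isTRUE(part$charged)) "-" else "", part$name)
}

# ---------------------------------------------------------------------------
# Prioritization (decision tree)

#' Prioritize the shorthand notation of a fragment reaction
#'
#' Applies the decision tree: fragment types rank DBF > MLF > LCF > iMLF; the
#' side (charged fragment vs composite of neutral fragments) containing the
#' highest-priority type wins.  On a type tie the side whose total fragment
#' mass (not m/z) is lower wins; an exact mass tie goes to the charged side.
#'
#' @param rx a `fragment_reaction`.
#' @return the reaction with `$prioritized` set to `"charged"` or `"neutral"`.
#' @export
prioritize <- function(rx) {
  stopifnot(inherits(rx, "fragment_reaction"))
  neutrals <- rx$neutrals
  if (length(neutrals) == 0) {
    rx$prioritized <- "charged"
    return(rx)
  }
  # when the complement of the charged fragment is itself an ion (charge
  # splitting of a multiply charged precursor), the charged side describes
  # this m/z and always wins
  if (any(vapply(neutrals, function(p) !identical(p$z, 0L), logical(1)))) {
    rx$prioritized <- "charged"
    return(rx)
  }
  rank_c <- .FRAG_PRIORITY[[rx$charged$type]]
  rank_n <- min(vapply(neutrals, function(p) .FRAG_PRIORITY[[p$type]], integer(1)))
  if (rank_c < rank_n) {
    rx$prioritized <- "charged"
  } else if (rank_n < rank_c) {
    rx$prioritized <- "neutral"
  } else {
    mass_c <- monoisotopic_mass(rx$charged$comp)
    mass_n <- sum(vapply(neutrals, function(p) monoisotopic_mass(p$comp), numeric(1)))
    rx$prioritized <- if (mass_n < mass_c) "neutral" else "charged"
  }
  rx
}

.neutral_composite <- function(rx) {
  if (length(rx$neutrals) == 0) return("")
  # fixed term order: chain-derived parts first, then head-group/fixed parts,
  # then the remainder -- matching printed composites like "-FA 18:3(-H) -PC(74)"
  ord <- order(vapply(rx$neutrals, function(p)
    switch(p$kind, hca = 1L, dbf = 1L, pair = 2L, lcf = 3L, rem = 4L), integer(1)),
    method = "radix")
  paste(vapply(rx$neutrals[ord], name_part, character(1)), collapse = " ")
}

#' Dual shorthand notation of a reaction
#'
#' Renders `"PRIORITIZED | other"`; if the reaction has a single side (no
#' neutral fragments) only that side is printed, without `"|"`.
#'
#' @param rx a `fragment_reaction` (prioritization applied automatically if
#'   not yet set).
#' @return annotation string.
#' @export
render_dual <- function(rx) {
  if (is.null(rx$prioritized)) rx <- prioritize(rx)
  charged <- name_part(rx$charged)
  neutral <- .neutral_composite(rx)
  if (!nzchar(neutral)) return(charged)
  if (rx$prioritized == "charged") paste(charged, "|", neutral)
  else paste(neutral, "|", charged)
}

#' Prioritized shorthand of a reaction
#'
#' @param rx a `fragment_reaction`.
#' @return the winning side only (neutral composites keep their `"-"` prefixes).
#' @export
prioritized_name <- function(rx) {
  if (is.null(rx$prioritized)) rx <- prioritize(rx)
  if (rx$prioritized == "charged") name_part(rx$charged) else .neutral_composite(rx)
}

# ---------------------------------------------------------------------------
# Name -> composition (round-trip support)

#' Recover the elemental composition of a fragment name
#'
#' Inverse of the naming rules for a single fragment part: accepts LCF names
#' (`"PS(153)"`, `"PC(+[2]H13)(197)"`), HCA-based names
#' (`"FA 18:3(+C7H16NO6P)"`, `"-FA 16:0(+[2]H3)(-H)"`, `"O-18:1p"`), names of
#' multi-chain fragments (`"Cer 35:1;2(-H2O)"`) and parenthesized plain
#' formulas (`"-(C7H15)"`).  A leading `"-"` (neutral marker) is ignored for
#' the composition.
#'
#' @param text fragment name.
#' @param rules rule table used to resolve LCF formulas from their nominal
#'   masses (default: the packaged rules).
#' @return `lf_comp` composition.
#' @export
parse_fragment_name <- function(text, rules = fragmentation_rules()) {
  name <- sub("^-", "", trimws(text))

  # plain formula: "(C7H15)"
  m <- regmatches(name, regexec("^\\(([A-Za-z0-9\\[\\]]*)\\)$", name,
                                perl = TRUE))[[1]]
  if (length(m)) return(parse_formula(m[2]))

  # trailing parenthesized groups (label / delta / nominal), innermost last
  groups <- character(0)
  while (grepl("\\)$", name)) {
    i <- nchar(name) - 1L; depth <- 1L
    while (i > 0 && depth > 0) {
      ch <- substr(name, i, i)
      if (ch == ")") depth <- depth + 1L
      if (ch == "(") depth <- depth - 1L
      i <- i - 1L
    }
    groups <- c(substr(name, i + 2L, nchar(name) - 1L), groups)
    name <- substr(name, 1L, i)
  }
  name <- trimws(name)

  is_label_group <- function(g) grepl("^\\+\\[", g) &&
    !inherits(try(parse_label(g), silent = TRUE), "try-error")

  # LCF: remaining head is a bare class symbol, last group a nominal mass
  if (length(groups) && grepl("^[0-9]+$", groups[length(groups)]) &&
      trimws(name) %in% lipid_classes()$class) {
    nominal <- as.integer(groups[length(groups)])
    label <- if (length(groups) > 1 && is_label_group(groups[1])) parse_label(groups[1]) else NULL
    cands <- .lcf_formula_lookup(rules)
    for (f in cands) {
      cmp <- parse_formula(f)
      cmp_lab <- tryCatch(apply_label(cmp, label), error = function(e) NULL)
      if (!is.null(cmp_lab) && nominal_mass(cmp_lab) == nominal) return(cmp_lab)
    }
    stop("no curated LCF with nominal mass ", nominal, " for '", text, "'",
         call. = FALSE)
  }

  # HCA or multi-chain: "<sym> <C:DB(;OH)(pos)p?>"
  sym_m <- regmatches(name, regexec("^(O-|[A-Za-z]+ ?O-|[A-Za-z]+) ?([0-9].*)$", name))[[1]]
  if (!length(sym_m)) stop("unparseable fragment name '", text, "'", call. = FALSE)
  sym <- trimws(sym_m[2]); tok <- sym_m[3]

  label <- NULL; delta <- comp()
  for (g in groups) {
    if (grepl("^[0-9]+(,[0-9]+)*$", g)) {
      # double-bond positions stripped off the chain token: reinsert
      tok <- if (endsWith(tok, "p"))
        paste0(substr(tok, 1, nchar(tok) - 1), "(", g, ")p")
      else paste0(tok, "(", g, ")")
    } else if (is_label_group(g)) {
      label <- parse_label(g)
    } else {
      delta <- comp_add(delta, parse_delta(g))
    }
  }
  ch <- .parse_chain_token(tok, text)
  ch$label <- label

  if (sym %in% c("FA", "LCB", "ST", "O-")) {
    hca <- c(FA = "FA", LCB = "LCB", ST = "ST", "O-" = "ETH")[[sym]]
    ch$hca <- hca
    return(comp_add(.hca_base(ch), delta))
  }

  # multi-chain fragment named after a sub-lipid class: rebuild from totals
  tmpl <- .class_template(sym)
  cmp <- tmpl$backbone
  for (i in seq_along(tmpl$slots)) {
    cc <- if (i == 1) ch$carbons else 0L
    dd <- if (i == 1) ch$db else 0L
    hh <- if (i == 1) ch$oh else 0L
    cmp <- comp_add(cmp, .chain_contribution(list(carbons = cc, db = dd, oh = hh,
                                                  label = NULL),
                                             tmpl$slots[[i]]$linkage))
  }
  if (!is.null(label)) cmp <- apply_label(cmp, label)
  comp_add(cmp, delta)
}

# all distinct lcf formulas in a rule table (label classes resolved lazily)
.lcf_formula_lookup <- function(rules) {
  specs <- unlist(c(rules$charged, strsplit(rules$neutrals, ";", fixed = TRUE)))
  lcf <- grep("^lcf:", specs, value = TRUE)
  unique(vapply(strsplit(lcf, ":", fixed = TRUE), `[[`, character(1), 2))
}
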
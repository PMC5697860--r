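# Rule-driven enumeration of CID fragments as mass-balanced reactions.
#
# Every reaction satisfies, by construction, the module's central invariant:
# charged-fragment atoms + all neutral-fragment atoms = precursor-ion atoms
# exactly, hence mass balance to numerical precision.  The one free part per
# rule ("rem") is defined as the precursor minus all explicit parts.

# heavy-aware delta application: positive counts add light atoms; negative
# counts remove light atoms first and fall back on heavy nuclides of the same
# element only when requested (heavy_first) or when no light atoms remain.
.apply_delta <- function(base, delta, heavy_first = FALSE) {
  out <- base
  for (k in names(delta)) {
    n <- as.integer(delta[k])
    if (n >= 0L || .is_heavy(k)) {
      out <- comp_add(out, .as_comp(structure(n, names = k)))
      next
    }
    need <- -n
    el <- k
    heavies <- names(out)[.is_heavy(names(out)) & .nuclide_element(names(out)) == el]
    pools <- if (heavy_first) c(heavies, el) else c(el, heavies)
    for (p in pools) {
      have <- if (p %in% names(out)) as.integer(out[p]) else 0L
      take <- min(have, need)
      if (take > 0L) {
        out <- comp_add(out, .as_comp(structure(-take, names = p)))
        need <- need - take
      }
    }
    if (need > 0L)
      out <- comp_add(out, .as_comp(structure(-need, names = el)))
  }
  out
}

# build one concrete fragment part from a template
.make_part <- function(tpl, prec, chain_idx = NULL, charged = FALSE, z = 0L) {
  lipid <- prec$lipid
  tmpl <- .class_template(lipid$class)
  part <- list(kind = tpl$kind, charged = charged, z = if (charged) z else 0L)

  if (tpl$kind == "lcf") {
    cmp <- tpl$comp
    label <- NULL
    if (isTRUE(tpl$use_class_label) && !is.null(lipid$class_label)) {
      cmp <- apply_label(cmp, lipid$class_label)
      label <- lipid$class_label
    }
    label_class <- if (tpl$label == "*") lipid$class else tpl$label
    part$comp <- cmp
    part$name <- .name_lcf(cmp, label_class, label)
    part$type <- "LCF"
    part$chains <- integer(0)
  } else if (tpl$kind %in% c("hca", "dbf")) {
    ch <- prec$chains[[chain_idx]]
    delta <- tpl$delta
    if (tpl$kind == "dbf") {
      kdist <- ch$carbons - ch$db_pos[length(ch$db_pos)] - 2L
      delta <- comp_add(delta, comp(C = -kdist, H = -(2L * kdist + 1L)))
    }
    base <- .hca_base(ch)
    cmp <- .apply_delta(base, delta, heavy_first = isTRUE(tpl$heavy_first))
    # displayed delta: what was actually removed/added relative to the
    # labeled base (so heavy-aware removal prints "(-[13]CH8[15]NO)")
    shown_delta <- comp_diff(cmp, base)
    part$comp <- cmp
    part$name <- .name_hca_part(ch, shown_delta)
    part$type <- if (tpl$kind == "dbf") "DBF" else "MLF"
    part$chains <- chain_idx
  } else if (tpl$kind == "pair") {
    idx <- chain_idx  # two indices
    chains <- prec$chains[idx]
    sub <- .sub_lipid(tmpl$rem_classes[[2]], chains)
    cmp <- comp_add(intact_composition(sub), tpl$delta)
    part$comp <- cmp
    part$name <- .name_multichain(tmpl$rem_classes[[2]], chains, tpl$delta)
    part$type <- "iMLF"
    part$chains <- idx
  } else stop("internal: rem parts are built separately")
  if (!.comp_is_physical(part$comp))
    stop("part '", part$name, "' has negative atom counts", call. = FALSE)
  part
}

# remainder part: precursor minus the explicit parts; a non-zero z on a
# "neutral" remainder marks the leftover charge when a multiply charged
# precursor splits into two ions (e.g. doubly deprotonated cardiolipin)
.make_rem <- function(prec, parts, charged = FALSE, z = 0L) {
  cmp <- prec$comp
  consumed <- integer(0)
  for (p in parts) {
    cmp <- comp_diff(cmp, p$comp)
    consumed <- c(consumed, p$chains)
  }
  remaining <- setdiff(seq_along(prec$chains), consumed)
  if (!.comp_is_physical(cmp))
    stop("remainder has negative atom counts (",
         format_formula(cmp, delta = TRUE), ")", call. = FALSE)
  part <- list(kind = "rem", charged = charged, z = z,
               comp = cmp, chains = remaining)
  k <- length(remaining)
  lipid <- prec$lipid
  tmpl <- .class_template(lipid$class)
  if (k == 0) {
    part$name <- paste0("(", format_formula(cmp), ")")
    part$type <- "LCF"
  } else if (k == 1) {
    ch <- prec$chains[[remaining]]
    delta <- comp_diff(cmp, .hca_base(ch))
    part$name <- .name_hca_part(ch, delta)
    part$type <- "MLF"
  } else {
    rem_class <- tmpl$rem_classes[[min(k, length(tmpl$rem_classes))]]
    chains <- prec$chains[remaining]
    sub <- .sub_lipid(rem_class, chains)
    delta <- comp_diff(cmp, intact_composition(sub))
    part$name <- .name_multichain(rem_class, chains, delta)
    part$type <- "iMLF"
  }
  part
}

# pseudo-lipid of a sub-class filled with a chain subset (remainder naming)
.sub_lipid <- function(rem_class, chains) {
  structure(list(class = rem_class, level = "molecular", chains = chains,
                 totals = .chain_totals(chains), class_label = NULL,
                 molecule_label = NULL),
            class = "lipid_name")
}

# iteration domain of a rule over a precursor's chains
.rule_instances <- function(parts, prec) {
  tpls <- c(list(parts$charged), parts$neutrals)
  hca_tpl <- Filter(function(p) p$kind %in% c("hca", "dbf"), tpls)
  pair_tpl <- Filter(function(p) p$kind == "pair", tpls)
  if (length(hca_tpl) > 1 || length(pair_tpl) > 1 ||
      (length(hca_tpl) && length(pair_tpl)))
    stop("a rule may contain at most one chain-iterated part", call. = FALSE)
  if (length(hca_tpl)) {
    tpl <- hca_tpl[[1]]
    idx <- which(vapply(prec$chains, function(ch)
      identical(ch$hca, tpl$hca), logical(1)))
    if (tpl$kind == "dbf")
      idx <- idx[vapply(prec$chains[idx], function(ch)
        !is.null(ch$db_pos) &&
          (ch$carbons - ch$db_pos[length(ch$db_pos)] - 2L) >= 1L, logical(1))]
    return(lapply(idx, identity))
  }
  if (length(pair_tpl)) {
    n <- length(prec$chains)
    if (n < 3) return(list())  # a pair fragment needs chains left over
    out <- list()
    for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) out <- c(out, list(c(i, j)))
    return(out)
  }
  list(NULL)  # single instantiation, no chain binding
}

.instantiate_rule <- function(rule, prec, strict = FALSE) {
  parts <- .rule_parts(rule)
  # annotate templates with rule-level flags
  decorate <- function(tpl) {
    if (tpl$kind == "lcf") tpl$use_class_label <- isTRUE(rule$label_lcf)
    tpl
  }
  parts$charged <- decorate(parts$charged)
  parts$neutrals <- lapply(parts$neutrals, decorate)
  product_z <- if (is.null(rule$product_z) || is.na(rule$product_z) ||
                   !nzchar(as.character(rule$product_z))) prec$z
               else as.integer(rule$product_z)

  out <- list()
  for (binding in .rule_instances(parts, prec)) {
    rx <- tryCatch({
      build <- function(tpl, charged) {
        if (tpl$kind == "rem") return(NULL)
        .make_part(tpl, prec,
                   chain_idx = if (tpl$kind %in% c("hca", "dbf", "pair")) binding,
                   charged = charged, z = if (charged) product_z else 0L)
      }
      charged_part <- build(parts$charged, TRUE)
      neutral_parts <- Filter(Negate(is.null),
                              lapply(parts$neutrals, build, charged = FALSE))
      explicit <- Filter(Negate(is.null), c(list(charged_part), neutral_parts))
      if (is.null(charged_part)) {
        charged_part <- .make_rem(prec, explicit, charged = TRUE, z = product_z)
      } else if (length(neutral_parts) < length(parts$neutrals)) {
        neutral_parts <- c(neutral_parts,
                           list(.make_rem(prec, explicit, charged = FALSE,
                                          z = prec$z - product_z)))
      }
      charged_part$mz <- ion_mz(charged_part$comp, charged_part$z)
      neutral_parts <- Filter(function(p) length(p$comp) > 0, neutral_parts)
      for (i in seq_along(neutral_parts))
        neutral_parts[[i]]$mass <- monoisotopic_mass(neutral_parts[[i]]$comp)
      all_parts <- c(list(charged_part), neutral_parts)
      structure(list(precursor = prec, charged = charged_part,
                     neutrals = neutral_parts, ms_level = rule$ms_level,
                     rule_id = rule$id,
                     chain_slots = sort(unique(unlist(lapply(all_parts, `[[`,
                                                             "chains")))),
                     # slots with direct single-chain evidence (MLF/DBF parts)
                     mlf_slots = sort(unique(unlist(lapply(all_parts, function(p)
                       if (p$kind %in% c("hca", "dbf")) p$chains
                       else integer(0)))))),
                class = "fragment_reaction")
    }, error = function(e) e)
    if (inherits(rx, "error")) {
      # a rule that cannot instantiate on this lipid (e.g. not enough atoms)
      # is skipped unless strict; validate_rules() runs in strict mode
      if (strict) stop("rule '", rule$id, "': ", conditionMessage(rx),
                       call. = FALSE)
      next
    }
    out <- c(out, list(prioritize(rx)))
  }
  out
}

#' Enumerate CID fragments of a precursor ion
#'
#' One mass-balanced reaction per applicable rule and chain instantiation.
#' Duplicate reactions -- identical charged composition and identical neutral
#' multiset, arising from identical chains -- are collapsed to one, with the
#' chain-slot evidence of the duplicates merged.
#'
#' @param precursor a [precursor_ion()] (or a lipid name string plus `adduct`).
#' @param rules rule table (default: packaged rules).
#' @param ms_level 2 for MS2 rules (default).
#' @param adduct adduct symbol, used when `precursor` is a lipid name string.
#' @param warn_empty warn when no rule covers the (class, adduct) combination.
#' @return list of `fragment_reaction` objects, prioritized and in
#'   deterministic (rule then slot) order.
#' @export
#' @examples
#' rxs <- enumerate_fragments(precursor_ion("PE 17:0-17:0", "-H"))
#' sapply(rxs, render_dual)
enumerate_fragments <- function(precursor, rules = fragmentation_rules(),
                                ms_level = 2, adduct = NULL,
                                warn_empty = TRUE, strict = FALSE) {
  if (is.character(precursor)) {
    if (is.null(adduct)) stop("supply an adduct with a lipid name", call. = FALSE)
    precursor <- precursor_ion(precursor, adduct)
  }
  prec <- .as_engine_precursor(precursor)
  hits <- which(vapply(seq_len(nrow(rules)), function(i)
    .rule_matches(as.list(rules[i, , drop = FALSE]), prec$lipid$class,
                  prec$adduct_symbol, ms_level) &&
      !nzchar(trimws(rules$parent[i])), logical(1)))
  out <- list()
  for (i in hits)
    out <- c(out, .instantiate_rule(as.list(rules[i, , drop = FALSE]), prec,
                                    strict = strict))
  if (!length(out) && warn_empty)
    warning("no fragmentation rules for (", prec$lipid$class, ", ",
            prec$adduct_symbol, ", MS", ms_level, ")", call. = FALSE)
  .dedup_reactions(out)
}

#' Enumerate MS3 fragments of an MS2 fragment
#'
#' The parent reaction's charged fragment becomes the new precursor; MS3
#' rules whose parent selector names the parent's rule id are instantiated
#' over the chains the charged fragment retained, balanced against it.
#'
#' @param parent_rx a `fragment_reaction` from [enumerate_fragments()].
#' @param rules rule table.
#' @return list of `fragment_reaction` objects (empty if no rule applies).
#' @export
enumerate_ms3 <- function(parent_rx, rules = fragmentation_rules()) {
  stopifnot(inherits(parent_rx, "fragment_reaction"))
  prec0 <- parent_rx$precursor
  prec <- list(
    lipid = prec0$lipid,
    adduct_symbol = prec0$adduct_symbol,
    comp = parent_rx$charged$comp,
    z = parent_rx$charged$z,
    mz = parent_rx$charged$mz,
    display = name_part(parent_rx$charged),
    chains = prec0$chains[parent_rx$charged$chains]
  )
  out <- list()
  for (i in seq_len(nrow(rules))) {
    rule <- as.list(rules[i, , drop = FALSE])
    if (rule$ms_level != 3) next
    parents <- trimws(strsplit(rule$parent, ",", fixed = TRUE)[[1]])
    if (!parent_rx$rule_id %in% parents) next
    if (!.rule_matches(rule, prec$lipid$class, prec$adduct_symbol, 3)) next
    out <- c(out, .instantiate_rule(rule, prec))
  }
  for (i in seq_along(out)) out[[i]]$parent <- parent_rx
  .dedup_reactions(out)
}

.as_engine_precursor <- function(p) {
  stopifnot(inherits(p, "precursor_ion"))
  if (p$lipid$level == "species")
    stop("fragment enumeration needs per-chain information; parse the name ",
         "at the molecular species level", call. = FALSE)
  list(lipid = p$lipid, adduct_symbol = p$adduct$symbol, comp = p$comp,
       z = p$z, mz = p$mz, display = p$display, chains = p$lipid$chains)
}

.dedup_reactions <- function(rxs) {
  if (length(rxs) < 2) return(rxs)
  key <- vapply(rxs, function(rx) {
    paste(rx$rule_id, format_formula(rx$charged$comp), rx$charged$z,
          paste(sort(vapply(rx$neutrals, function(p) format_formula(p$comp),
                            character(1))), collapse = "+"))
  }, character(1))
  ukeys <- unique(key)
  lapply(ukeys, function(k) {
    dups <- which(key == k)
    rx <- rxs[[dups[1]]]
    rx$chain_slots <- sort(unique(unlist(lapply(rxs[dups], `[[`, "chain_slots"))))
    rx$mlf_slots <- sort(unique(unlist(lapply(rxs[dups], `[[`, "mlf_slots"))))
    rx
  })
}

#' @export
print.fragment_reaction <- function(x, ...) {
  cat(sprintf("m/z %.4f  %s\n", x$charged$mz, render_dual(x)))
  invisible(x)
}

#' Tabulate enumerated reactions
#'
#' @param rxs list of `fragment_reaction` objects.
#' @return data.frame with theoretical m/z, prioritized and dual shorthand,
#'   fragment type of the prioritized side, whether the reaction carries
#'   single-chain (MLF) evidence, MS level and rule id.
#' @export
fragment_table <- function(rxs) {
  if (!length(rxs))
    return(data.frame(mz = numeric(0), name = character(0), dual = character(0),
                      type = character(0), mlf = logical(0),
                      ms_level = integer(0), rule = character(0)))
  best_type <- function(rx) {
    parts <- if (rx$prioritized == "charged") list(rx$charged) else rx$neutrals
    names(.FRAG_PRIORITY)[min(vapply(parts, function(p)
      .FRAG_PRIORITY[[p$type]], integer(1)))]
  }
  data.frame(
    mz = vapply(rxs, function(rx) rx$charged$mz, numeric(1)),
    name = vapply(rxs, prioritized_name, character(1)),
    dual = vapply(rxs, render_dual, character(1)),
    type = vapply(rxs, best_type, character(1)),
    mlf = vapply(rxs, function(rx)
      any(vapply(c(list(rx$charged), rx$neutrals), function(p)
        p$kind == "hca", logical(1))), logical(1)),
    ms_level = vapply(rxs, function(rx) as.integer(rx$ms_level), integer(1)),
    rule = vapply(rxs, function(rx) rx$rule_id, character(1)),
    stringsAsFactors = FALSE
  )
}
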
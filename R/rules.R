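# Fragmentation-rule table: loading, part-spec parsing, validation.

#' Load a fragmentation-rule table
#'
#' Rules are data, not code: each row is a mass-balanced reaction template
#' scoped to lipid classes, adducts and MS level.  The part vocabulary is
#' documented at the top of the packaged table
#' (`system.file("extdata", "fragmentation_rules.tsv", package = "lipidfrags")`).
#'
#' @param path optional path to a user rule table (same columns).
#' @return data.frame of rules; parse errors in part specs are raised on use.
#' @export
fragmentation_rules <- function(path = NULL) {
  if (is.null(path)) {
    if (is.null(.lf_cache$rules))
      .lf_cache$rules <- .load_rules(.extdata("fragmentation_rules.tsv"))
    return(.lf_cache$rules)
  }
  .load_rules(path)
}

.load_rules <- function(path) {
  tab <- .read_tsv(path)
  need <- c("id", "classes", "adducts", "ms_level", "parent", "charged",
            "neutrals", "product_z", "label_lcf")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("rule table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(tab$id))
    stop("duplicate rule id(s): ",
         paste(unique(tab$id[duplicated(tab$id)]), collapse = ", "),
         call. = FALSE)
  tab$ms_level <- as.integer(tab$ms_level)
  tab$label_lcf <- as.logical(tab$label_lcf)
  tab
}

# parse one part spec string into a template
.parse_part_spec <- function(spec) {
  spec <- trimws(spec)
  if (spec == "rem") return(list(kind = "rem"))
  bits <- strsplit(spec, ":", fixed = TRUE)[[1]]
  kind <- bits[1]
  if (kind == "lcf") {
    if (length(bits) < 3) stop("lcf part needs formula and label: '", spec, "'",
                               call. = FALSE)
    return(list(kind = "lcf", comp = parse_formula(bits[2]), label = bits[3]))
  }
  if (kind %in% c("hca", "dbf")) {
    delta <- if (length(bits) >= 3) bits[3] else ""
    # optional 4th field "heavy": removal draws on heavy nuclides first (for
    # fragments that lose the labeled end of a chain)
    return(list(kind = kind, hca = bits[2], delta = parse_delta(delta),
                heavy_first = length(bits) >= 4 && bits[4] == "heavy"))
  }
  if (kind == "pair") {
    delta <- if (length(bits) >= 2) bits[2] else ""
    return(list(kind = "pair", delta = parse_delta(delta)))
  }
  stop("unknown part kind in spec '", spec, "'", call. = FALSE)
}

.rule_parts <- function(rule) {
  neutrals <- trimws(strsplit(rule$neutrals, ";", fixed = TRUE)[[1]])
  neutrals <- neutrals[nzchar(neutrals)]
  parts <- list(charged = .parse_part_spec(rule$charged),
                neutrals = lapply(neutrals, .parse_part_spec))
  n_rem <- sum(parts$charged$kind == "rem") +
    sum(vapply(parts$neutrals, function(p) p$kind == "rem", logical(1)))
  if (n_rem != 1)
    stop("rule '", rule$id, "' must contain exactly one 'rem' part", call. = FALSE)
  parts
}

.rule_row <- function(rules, id) {
  i <- match(id, rules$id)
  if (is.na(i)) stop("unknown rule id '", id, "'", call. = FALSE)
  as.list(rules[i, , drop = FALSE])
}

.rule_matches <- function(rule, class, adduct_symbol, ms_level) {
  classes <- trimws(strsplit(rule$classes, ",", fixed = TRUE)[[1]])
  adducts <- trimws(strsplit(rule$adducts, ",", fixed = TRUE)[[1]])
  (class %in% classes) &&
    (identical(adducts, "*") || adduct_symbol %in% adducts) &&
    rule$ms_level == ms_level
}

#' Validate a rule table against the class registry
#'
#' Instantiates every rule on a probe lipid of each class it covers and
#' checks the central invariant: the atoms of the charged fragment plus all
#' neutral fragments equal the precursor ion exactly, and every fragment
#' composition is physically valid (non-negative counts).
#'
#' @param rules rule table (default packaged).
#' @param probes named character vector mapping class symbols to probe lipid
#'   names; defaults to a built-in probe per curated class.
#' @return data.frame report with one row per (rule, probe) instantiation
#'   problem; zero rows means the table is clean.
#' @export
validate_rules <- function(rules = fragmentation_rules(), probes = NULL) {
  if (is.null(probes)) probes <- .default_probes()
  report <- list()
  for (i in seq_len(nrow(rules))) {
    rule <- as.list(rules[i, , drop = FALSE])
    classes <- trimws(strsplit(rule$classes, ",", fixed = TRUE)[[1]])
    for (cl in intersect(classes, names(probes))) {
      res <- tryCatch({
        prec <- .probe_precursor(probes[[cl]], rule)
        rxs <- if (rule$ms_level == 2)
          enumerate_fragments(prec, rules = rules[i, , drop = FALSE],
                              ms_level = 2, warn_empty = FALSE, strict = TRUE)
        else .probe_ms3(probes[[cl]], rule, rules)
        for (rx in rxs) .check_balance(rx)
        NULL
      }, error = function(e) conditionMessage(e))
      if (!is.null(res))
        report[[length(report) + 1]] <- data.frame(rule = rule$id, class = cl,
                                                   problem = res)
    }
  }
  if (length(report)) do.call(rbind, report)
  else data.frame(rule = character(0), class = character(0),
                  problem = character(0))
}

.default_probes <- function() {
  c(PC = "PC 16:0-18:1(9)", LPC = "LPC 16:0", "PC O-" = "PC O-16:0/18:1",
    PE = "PE 17:0-17:0", "PE O-" = "PE O-18:1p/20:4", PS = "PS 20:4-22:6",
    PI = "PI 16:0-18:1", PA = "PA 16:0-18:1", CL = "CL 14:1-14:1-14:1-15:1",
    DAG = "DAG 18:0-20:0", TAG = "TAG 16:0-18:0-18:2",
    SM = "SM 18:1;2/17:0", Cer = "Cer 18:1;2/17:0",
    SE = "SE 27:1/19:0", ACar = "ACar 18:2", ACoA = "ACoA 19:0",
    FA = "FA 18:1(9)")
}

.probe_precursor <- function(lipid, rule) {
  adducts <- trimws(strsplit(rule$adducts, ",", fixed = TRUE)[[1]])
  n <- parse_lipid(lipid)
  tmpl <- .class_template(n$class)
  if (identical(adducts, "*"))
    adducts <- c(tmpl$adducts_pos, tmpl$adducts_neg)
  adducts <- intersect(adducts, c(tmpl$adducts_pos, tmpl$adducts_neg))
  if (!length(adducts))
    stop("no supported probe adduct for class ", n$class, call. = FALSE)
  precursor_ion(n, adducts[[1]])
}

# run an ms3 rule through its parent(s) on the probe
.probe_ms3 <- function(lipid, rule, rules) {
  parents <- trimws(strsplit(rule$parent, ",", fixed = TRUE)[[1]])
  parents <- parents[parents %in% rules$id]
  out <- list()
  for (pid in parents) {
    prule <- rules[rules$id == pid, , drop = FALSE]
    prec <- tryCatch(.probe_precursor(lipid, as.list(prule)), error = function(e) NULL)
    if (is.null(prec)) next
    for (parent_rx in enumerate_fragments(prec, rules = prule, ms_level = 2,
                                          warn_empty = FALSE)) {
      out <- c(out, enumerate_ms3(parent_rx,
                                  rules = rules[rules$id == rule$id, , drop = FALSE]))
    }
  }
  out
}

.check_balance <- function(rx, tol = 1e-9) {
  total <- rx$charged$comp
  for (p in rx$neutrals) total <- comp_add(total, p$comp)
  resid <- comp_diff(total, rx$precursor$comp)
  if (length(resid) != 0)
    stop("atom balance violated: residual ", format_formula(resid, delta = TRUE),
         call. = FALSE)
  dm <- abs(monoisotopic_mass(total) - monoisotopic_mass(rx$precursor$comp))
  if (dm > tol) stop("mass balance violated by ", dm, " Da", call. = FALSE)
  if (!.comp_is_physical(rx$charged$comp))
    stop("charged fragment has negative atom counts", call. = FALSE)
  for (p in rx$neutrals) if (!.comp_is_physical(p$comp))
    stop("neutral fragment has negative atom counts", call. = FALSE)
  invisible(TRUE)
}
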
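# Data-driven lipid class registry and adduct table.  Both ship as TSV under
# inst/extdata and may be replaced by the user to register new classes
# without code changes.

.lf_cache <- new.env(parent = emptyenv())

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "lipidfrags")
  if (path == "") {
    # allow running from a source checkout (tests during development)
    path <- file.path("inst", "extdata", file)
  }
  if (!file.exists(path)) stop("packaged table not found: ", file, call. = FALSE)
  path
}

.read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    quote = "", comment.char = "#", na.strings = NULL,
                    check.names = FALSE)
}

#' Lipid class registry
#'
#' Structural templates for the curated lipid classes: backbone composition,
#' chain-slot linkage chemistry, allowed hydrocarbon chain attribute (HCA)
#' classes, supported adducts per polarity and the sub-lipid classes used to
#' name multi-chain remainder fragments.
#'
#' @param path optional path to a user-supplied registry TSV with the same
#'   columns as the packaged one.
#' @return data.frame, one row per class.
#' @export
lipid_classes <- function(path = NULL) {
  if (is.null(path)) {
    if (is.null(.lf_cache$classes))
      .lf_cache$classes <- .read_tsv(.extdata("lipid_classes.tsv"))
    return(.lf_cache$classes)
  }
  .read_tsv(path)
}

#' Adduct definitions
#'
#' @param path optional path to a user-supplied adduct TSV.
#' @return data.frame with columns `symbol`, `delta` (formula) and `z`.
#' @export
adducts <- function(path = NULL) {
  if (is.null(path)) {
    if (is.null(.lf_cache$adducts))
      .lf_cache$adducts <- .read_tsv(.extdata("adducts.tsv"))
    return(.lf_cache$adducts)
  }
  .read_tsv(path)
}

#' Look up one adduct
#'
#' @param symbol adduct symbol such as `"+H"`, `"-H"`, `"+CH3COO"`, `"-2H"`.
#' @return list with `symbol`, `delta` composition and signed charge `z`.
#' @export
adduct_spec <- function(symbol) {
  tab <- adducts()
  i <- match(symbol, tab$symbol)
  if (is.na(i)) stop("unknown adduct '", symbol, "'", call. = FALSE)
  list(symbol = symbol, delta = parse_formula(tab$delta[i]), z = as.integer(tab$z[i]))
}

# parsed template for one class (cached)
.class_template <- function(cl) {
  key <- paste0("tmpl:", cl)
  if (!is.null(.lf_cache[[key]])) return(.lf_cache[[key]])
  tab <- lipid_classes()
  i <- match(cl, tab$class)
  if (is.na(i)) stop("unregistered lipid class '", cl, "'", call. = FALSE)
  slots <- lapply(strsplit(tab$slots[i], ",", fixed = TRUE)[[1]], function(s) {
    p <- strsplit(trimws(s), "/", fixed = TRUE)[[1]]
    list(linkage = p[1], hca = p[2])
  })
  tmpl <- list(
    class = cl,
    category = tab$category[i],
    backbone = parse_formula(trimws(tab$backbone[i])),
    slots = slots,
    rem_classes = trimws(strsplit(tab$rem_classes[i], ",", fixed = TRUE)[[1]]),
    adducts_pos = trimws(strsplit(tab$adducts_pos[i], ",", fixed = TRUE)[[1]]),
    adducts_neg = trimws(strsplit(tab$adducts_neg[i], ",", fixed = TRUE)[[1]])
  )
  .lf_cache[[key]] <- tmpl
  tmpl
}
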
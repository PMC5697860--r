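# Materialized fragment database over configurable chain-enumeration ranges,
# with m/z search and a versioned single-file TSV store.

.FRAGDB_VERSION <- "lipidfrags-db-1"
.FRAGDB_COLS <- c("category", "class", "species", "molecular_species", "adduct",
                  "charge", "polarity", "ms_level", "formula", "fragment_name",
                  "fragment_type", "mz")

#' Build a fragment database
#'
#' Enumerates molecular species of the given classes over chain ranges,
#' ionizes them with each supported requested adduct and materializes one
#' record per precursor ion and per enumerated fragment reaction.
#'
#' @param classes character vector of registered class symbols.
#' @param chain_carbons integer vector of allowed carbons per chain,
#'   e.g. `seq(16, 22, by = 2)`.
#' @param chain_db integer vector of allowed double bonds per chain; values
#'   exceeding carbons/2 are dropped per chain.
#' @param chain_oh integer vector of allowed hydroxyl counts (default 0).
#' @param adducts adduct symbols to use; defaults to every adduct the class
#'   registry supports for each class.
#' @param rules rule table.
#' @return data.frame of class `fragment_db` with columns
#'   category, class, species, molecular_species, adduct, charge, polarity,
#'   ms_level, formula, fragment_name, fragment_type, mz.  Deterministic
#'   row order.
#' @export
#' @examples
#' db <- build_fragment_db("PS", chain_carbons = c(16, 18), chain_db = 0:1)
#' head(db)
build_fragment_db <- function(classes, chain_carbons, chain_db = 0L,
                              chain_oh = 0L, adducts = NULL,
                              rules = fragmentation_rules()) {
  if (!length(classes)) stop("empty class list", call. = FALSE)
  if (!length(chain_carbons) || !length(chain_db))
    return(.empty_fragdb())
  recs <- list()
  for (cl in classes) {
    tmpl <- .class_template(cl)
    cl_adducts <- c(tmpl$adducts_pos, tmpl$adducts_neg)
    if (!is.null(adducts)) cl_adducts <- intersect(adducts, cl_adducts)
    chain_types <- .enumerate_chain_types(chain_carbons, chain_db, chain_oh, tmpl)
    fills <- .enumerate_fills(chain_types, length(tmpl$slots))
    for (fill in fills) {
      name <- .fill_to_lipid(cl, fill, tmpl)
      for (ad in cl_adducts) {
        prec <- tryCatch(precursor_ion(name, ad), error = function(e) NULL)
        if (is.null(prec)) next
        recs[[length(recs) + 1]] <- .db_records(prec, rules)
      }
    }
  }
  out <- if (length(recs)) do.call(rbind, recs) else .empty_fragdb()
  rownames(out) <- NULL
  class(out) <- c("fragment_db", "data.frame")
  out
}

.enumerate_chain_types <- function(carbons, db, oh, tmpl) {
  grid <- expand.grid(carbons = as.integer(sort(carbons)),
                      db = as.integer(sort(db)), oh = as.integer(sort(oh)))
  grid <- grid[grid$db <= grid$carbons %/% 2, , drop = FALSE]
  grid[order(grid$carbons, grid$db, grid$oh), , drop = FALSE]
}

# unordered multisets of chain-type row indices for n slots
.enumerate_fills <- function(types, nslots) {
  idx <- seq_len(nrow(types))
  fills <- list(integer(0))
  for (s in seq_len(nslots)) {
    fills <- unlist(lapply(fills, function(f) {
      lo <- if (length(f)) f[length(f)] else 1L
      lapply(idx[idx >= lo], function(i) c(f, i))
    }), recursive = FALSE)
  }
  lapply(fills, function(f) types[f, , drop = FALSE])
}

.fill_to_lipid <- function(cl, fill, tmpl) {
  toks <- paste0(fill$carbons, ":", fill$db,
                 ifelse(fill$oh > 0, paste0(";", fill$oh), ""))
  paste0(.class_prefix(cl), paste(toks, collapse = "-"))
}

.db_records <- function(prec, rules) {
  lip <- prec$lipid
  tmpl <- .class_template(lip$class)
  species <- format_lipid(species_of(lip))
  molecular <- format_lipid(lip)
  polarity <- if (prec$z > 0) "+" else "-"
  base <- data.frame(
    category = tmpl$category, class = lip$class, species = species,
    molecular_species = molecular, adduct = prec$adduct$symbol,
    charge = prec$z, polarity = polarity, ms_level = 1L,
    formula = format_formula(prec$comp), fragment_name = prec$display,
    fragment_type = "precursor", mz = prec$mz, stringsAsFactors = FALSE)
  rxs <- enumerate_fragments(prec, rules = rules, warn_empty = FALSE)
  if (!length(rxs)) return(base)
  ft <- fragment_table(rxs)
  frag <- data.frame(
    category = tmpl$category, class = lip$class, species = species,
    molecular_species = molecular, adduct = prec$adduct$symbol,
    charge = vapply(rxs, function(rx) rx$charged$z, integer(1)),
    polarity = polarity, ms_level = ft$ms_level,
    formula = vapply(rxs, function(rx) format_formula(rx$charged$comp),
                     character(1)),
    fragment_name = ft$name, fragment_type = ft$type, mz = ft$mz,
    stringsAsFactors = FALSE)
  rbind(base, frag)
}

.empty_fragdb <- function() {
  out <- data.frame(category = character(0), class = character(0),
                    species = character(0), molecular_species = character(0),
                    adduct = character(0), charge = integer(0),
                    polarity = character(0), ms_level = integer(0),
                    formula = character(0), fragment_name = character(0),
                    fragment_type = character(0), mz = numeric(0),
                    stringsAsFactors = FALSE)
  class(out) <- c("fragment_db", "data.frame")
  out
}

#' Search a fragment database by m/z
#'
#' @param db a `fragment_db`.
#' @param mz query m/z.
#' @param tol_ppm tolerance in ppm (default 5).
#' @param tol_da absolute tolerance in Da, overrides `tol_ppm`.
#' @param polarity `"+"`, `"-"` or `NULL` (both).
#' @param ms_level restrict to an MS level (1 = precursors), `NULL` for all.
#' @return the matching records (all and only records within tolerance).
#' @export
search_mz <- function(db, mz, tol_ppm = 5, tol_da = NULL, polarity = NULL,
                      ms_level = NULL) {
  if (!is.null(tol_da)) { if (tol_da <= 0) stop("tolerance must be > 0", call. = FALSE) }
  else if (tol_ppm <= 0) stop("tolerance must be > 0", call. = FALSE)
  tol <- if (!is.null(tol_da)) tol_da else tol_ppm * 1e-6 * mz
  keep <- abs(db$mz - mz) <= tol
  if (!is.null(polarity)) keep <- keep & db$polarity == polarity
  if (!is.null(ms_level)) keep <- keep & db$ms_level == ms_level
  out <- db[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a fragment database to its single-file TSV store
#'
#' @param db a `fragment_db`.
#' @param path output file.
#' @export
write_fragment_db <- function(db, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", .FRAGDB_VERSION), con)
  utils::write.table(db[, .FRAGDB_COLS], con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a fragment database from its TSV store
#'
#' @param path file written by [write_fragment_db()].
#' @return a `fragment_db`.
#' @export
read_fragment_db <- function(path) {
  first <- readLines(path, n = 1)
  if (!identical(first, paste0("# ", .FRAGDB_VERSION)))
    stop("not a ", .FRAGDB_VERSION, " file: ", path, call. = FALSE)
  out <- utils::read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                           stringsAsFactors = FALSE, quote = "")
  miss <- setdiff(.FRAGDB_COLS, names(out))
  if (length(miss)) stop("database file missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  class(out) <- c("fragment_db", "data.frame")
  out
}
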
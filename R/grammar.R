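# Parser and serializer for intact-lipid shorthand names.
#
# A lipid name is "<class>[(<label>)] <chains>" where <chains> is either a
# single species-level C:DB(;OH) total or per-chain tokens joined by "-"
# (unordered, molecular species level) or "/" (sn-assigned).  Chain tokens
# carry optional double-bond positions "18:1(9)", an ether/alkenyl marker
# "p", and an isotope label "16:0(+[2]H3)".  Ether classes carry a trailing
# "O-" in the class symbol ("PE O-18:1p/20:4", species "PE O-40:7").

.CHAIN_RE <- paste0(
  "^([0-9]+):([0-9]+)",          # C:DB
  "(;[0-9]+)?",                  # ;OH
  "(\\(([0-9]+(,[0-9]+)*)\\))?", # (9) / (9,12) double-bond positions
  "(p)?",                        # alkenyl marker
  "(\\(\\+([^)]*)\\))?",         # (+[2]H3) isotope label
  "$")

.parse_chain_token <- function(tok, where) {
  m <- regexec(.CHAIN_RE, tok, perl = TRUE)
  p <- regmatches(tok, m)[[1]]
  if (length(p) == 0)
    stop("malformed chain token '", tok, "' in '", where, "'", call. = FALSE)
  carbons <- as.integer(p[2])
  db <- as.integer(p[3])
  oh <- if (p[4] == "") 0L else as.integer(sub(";", "", p[4]))
  db_pos <- if (p[6] == "") NULL else as.integer(strsplit(p[6], ",")[[1]])
  if (!is.null(db_pos) && length(db_pos) != db)
    stop("chain '", tok, "': ", length(db_pos), " double-bond positions for ",
         db, " double bonds", call. = FALSE)
  if (db > carbons %/% 2)
    stop("chain '", tok, "': ", db, " double bonds implausible for ",
         carbons, " carbons", call. = FALSE)
  label <- if (p[9] == "") NULL else parse_label(p[10])
  list(carbons = carbons, db = db, oh = oh, db_pos = db_pos,
       alkenyl = p[8] == "p", label = label)
}

.format_chain_token <- function(ch) {
  paste0(ch$carbons, ":", ch$db,
         if (ch$oh > 0) paste0(";", ch$oh) else "",
         if (!is.null(ch$db_pos)) paste0("(", paste(ch$db_pos, collapse = ","), ")") else "",
         if (isTRUE(ch$alkenyl)) "p" else "",
         if (!is.null(ch$label)) paste0("(", format_label(ch$label), ")") else "")
}

.match_class <- function(text) {
  classes <- lipid_classes()$class
  classes <- classes[order(nchar(classes), decreasing = TRUE)]
  for (cl in classes) {
    if (startsWith(text, cl)) return(cl)
  }
  stop("unknown lipid class in '", text, "'", call. = FALSE)
}

#' Parse an intact-lipid shorthand name
#'
#' Accepts names at the species level (`"SM 35:1;2"`), the molecular species
#' level (`"PS 16:0-22:6"`, en-dash or hyphen-minus) and the sn-defined level
#' (`"SE 27:1/18:2"`).  Isotope labels are accepted on the class symbol
#' (`"PC(+[2]H13) 16:1-18:1"`), on individual chains
#' (`"PC 16:0(+[2]H3)-16:0(+[2]H3)"`), and on species-level totals
#' (`"PC 34:1(+[2]H9)"`).
#'
#' @param text lipid name.
#' @return object of class `lipid_name`: a list with elements `class`,
#'   `level` (`"species"`, `"molecular"` or `"sn"`), `chains` (empty at
#'   species level), `totals` (`c(carbons, db, oh)`), `class_label`,
#'   `molecule_label`.
#' @export
#' @examples
#' parse_lipid("PS 16:0-22:6")
#' parse_lipid("PE O-18:1p/20:4")
parse_lipid <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  raw <- trimws(text)
  if (raw == "") stop("empty lipid name", call. = FALSE)
  # both ASCII hyphen-minus and the typographic en-dash separate chains
  norm <- gsub("–", "-", raw)
  cl <- .match_class(norm)
  rest <- substring(norm, nchar(cl) + 1)
  tmpl <- .class_template(cl)
  class_label <- NULL
  lab_m <- regmatches(rest, regexec("^\\(\\+([^)]*)\\)", rest))[[1]]
  if (length(lab_m)) {
    class_label <- parse_label(lab_m[2])
    rest <- substring(rest, nchar(lab_m[1]) + 1)
  }
  rest <- trimws(rest)
  if (rest == "") stop("'", raw, "': missing chain information", call. = FALSE)

  # split chains on "/" or "-", but not the "-" inside "O-" class symbols
  # (already consumed) nor inside "(...)" groups (db positions, labels)
  toks <- character(0)
  depth <- 0L; cur <- ""
  sn <- FALSE
  for (chx in strsplit(rest, "")[[1]]) {
    if (chx == "(") depth <- depth + 1L
    if (chx == ")") depth <- depth - 1L
    if (depth == 0L && chx %in% c("-", "/")) {
      if (chx == "/") sn <- TRUE
      toks <- c(toks, cur); cur <- ""
    } else cur <- paste0(cur, chx)
  }
  toks <- c(toks, cur)

  if (length(toks) == 1 && length(tmpl$slots) > 1) {
    # a single C:DB(;OH) total over several chain slots: species level
    ch <- .parse_chain_token(toks, raw)
    if (!is.null(ch$db_pos))
      stop("species-level name cannot carry double-bond positions", call. = FALSE)
    out <- list(class = cl, level = "species", chains = list(),
                totals = c(carbons = ch$carbons, db = ch$db, oh = ch$oh),
                class_label = class_label, molecule_label = ch$label)
    return(structure(out, class = "lipid_name"))
  }

  if (length(toks) != length(tmpl$slots))
    stop("'", raw, "': class ", cl, " takes ", length(tmpl$slots),
         " chains, got ", length(toks), call. = FALSE)
  chains <- lapply(toks, .parse_chain_token, where = raw)
  for (i in seq_along(chains)) {
    chains[[i]]$hca <- tmpl$slots[[i]]$hca
    if (chains[[i]]$alkenyl && tmpl$slots[[i]]$linkage != "ether")
      stop("'", raw, "': alkenyl marker on a non-ether chain slot", call. = FALSE)
  }
  level <- if (sn) "sn" else "molecular"
  has_pos <- any(vapply(chains, function(ch) !is.null(ch$db_pos), logical(1)))
  out <- list(class = cl, level = level, chains = chains,
              totals = .chain_totals(chains),
              class_label = class_label, molecule_label = NULL,
              db_defined = has_pos)
  structure(out, class = "lipid_name")
}

.chain_totals <- function(chains) {
  c(carbons = sum(vapply(chains, `[[`, integer(1), "carbons")),
    db = sum(vapply(chains, `[[`, integer(1), "db")),
    oh = sum(vapply(chains, `[[`, integer(1), "oh")))
}

.class_prefix <- function(cl) {
  # ether classes end in "O-" and join their first chain without a space
  if (endsWith(cl, "O-")) cl else paste0(cl, " ")
}

#' Serialize a lipid name
#'
#' Unordered (molecular-level) chains are sorted by increasing carbon number,
#' then increasing double-bond count; sn-assigned order is preserved.  The
#' hyphen-minus is emitted as the chain separator.
#'
#' @param n a `lipid_name`.
#' @return canonical shorthand string.
#' @export
format_lipid <- function(n) {
  stopifnot(inherits(n, "lipid_name"))
  head <- paste0(n$class,
                 if (!is.null(n$class_label)) paste0("(", format_label(n$class_label), ")") else "")
  head <- if (endsWith(n$class, "O-")) head else paste0(head, " ")
  if (n$level == "species") {
    tot <- paste0(n$totals[["carbons"]], ":", n$totals[["db"]],
                  if (n$totals[["oh"]] > 0) paste0(";", n$totals[["oh"]]) else "",
                  if (!is.null(n$molecule_label)) paste0("(", format_label(n$molecule_label), ")") else "")
    return(paste0(head, tot))
  }
  chains <- n$chains
  sep <- if (n$level == "sn") "/" else "-"
  if (n$level == "molecular") chains <- chains[.chain_order(chains)]
  paste0(head, paste(vapply(chains, .format_chain_token, character(1)), collapse = sep))
}

# stable sort by (carbons, db); duplicates keep input order
.chain_order <- function(chains) {
  order(vapply(chains, `[[`, integer(1), "carbons"),
        vapply(chains, `[[`, integer(1), "db"),
        method = "radix")
}

#' Collapse a lipid name to the species level
#'
#' Totals are element-wise sums over chains; chain and class labels are
#' merged into the molecule-level label.  Idempotent.
#'
#' @param n a `lipid_name`.
#' @return species-level `lipid_name`.
#' @export
#' @examples
#' format_lipid(species_of(parse_lipid("PS 20:4-22:6")))  # "PS 42:10"
species_of <- function(n) {
  stopifnot(inherits(n, "lipid_name"))
  if (n$level == "species") return(n)
  labels <- Filter(Negate(is.null), c(list(n$class_label),
                                      lapply(n$chains, `[[`, "label")))
  mol_label <- if (length(labels)) Reduce(comp_add, labels) else NULL
  out <- list(class = n$class, level = "species", chains = list(),
              totals = .chain_totals(n$chains),
              class_label = NULL, molecule_label = mol_label)
  structure(out, class = "lipid_name")
}

#' @export
print.lipid_name <- function(x, ...) {
  cat(format_lipid(x), " [", x$level, " level]\n", sep = "")
  invisible(x)
}

#' @export
format.lipid_name <- function(x, ...) format_lipid(x)
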
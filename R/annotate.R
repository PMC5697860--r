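# Matching theoretical reactions against observed peak lists, identification
# level assignment, and peak-list I/O (two-column TSV and MGF).

#' Read a two-column peak list
#'
#' @param path TSV/whitespace-delimited file with columns m/z and intensity
#'   (header optional).
#' @return data.frame with columns `mz` and `intensity`.
#' @export
read_peaklist <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- !grepl("^[0-9.eE+\t, -]+$", first)
  tab <- utils::read.table(path, header = has_header, sep = "",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("peak list needs two columns (m/z, intensity)",
                          call. = FALSE)
  peaks <- data.frame(mz = as.numeric(tab[[1]]), intensity = as.numeric(tab[[2]]))
  .check_peaks(peaks)
  peaks
}

#' Write a two-column peak list
#' @param peaks data.frame with `mz`, `intensity`.
#' @param path output file.
#' @export
write_peaklist <- function(peaks, path) {
  utils::write.table(peaks[, c("mz", "intensity")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

.check_peaks <- function(peaks) {
  if (nrow(peaks) && (any(!is.finite(peaks$mz)) || any(peaks$mz <= 0)))
    stop("peak m/z values must be positive numbers", call. = FALSE)
  if (nrow(peaks) && any(peaks$intensity < 0, na.rm = TRUE))
    stop("peak intensities must be >= 0", call. = FALSE)
  invisible(TRUE)
}

#' Read spectra from an MGF file
#'
#' Minimal Mascot Generic Format reader: honors TITLE, PEPMASS and CHARGE
#' headers of each BEGIN IONS/END IONS block.
#'
#' @param path MGF file.
#' @return list of spectra; each is a list with `title`, `pepmass`, `charge`
#'   and a `peaks` data.frame.
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  out <- list()
  cur <- NULL
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "" || startsWith(ln, "#")) next
    if (ln == "BEGIN IONS") {
      cur <- list(title = NA_character_, pepmass = NA_real_,
                  charge = NA_integer_, mz = numeric(0), int = numeric(0))
    } else if (ln == "END IONS") {
      out[[length(out) + 1]] <- list(
        title = cur$title, pepmass = cur$pepmass, charge = cur$charge,
        peaks = data.frame(mz = cur$mz, intensity = cur$int))
      cur <- NULL
    } else if (is.null(cur)) {
      next
    } else if (grepl("=", ln, fixed = TRUE)) {
      key <- toupper(sub("=.*", "", ln))
      val <- sub("^[^=]*=", "", ln)
      if (key == "TITLE") cur$title <- val
      if (key == "PEPMASS") cur$pepmass <- as.numeric(strsplit(val, " ")[[1]][1])
      if (key == "CHARGE") {
        z <- sub("^([0-9]+)([+-])$", "\\2\\1", trimws(val))
        cur$charge <- as.integer(z)
      }
    } else {
      xy <- as.numeric(strsplit(ln, "[ \t]+")[[1]])
      cur$mz <- c(cur$mz, xy[1])
      cur$int <- c(cur$int, if (length(xy) > 1) xy[2] else 0)
    }
  }
  out
}

#' Write spectra to an MGF file
#'
#' @param spectra one spectrum (list with `peaks`, optional `title`,
#'   `pepmass`, `charge`) or a list of them.
#' @param path output file.
#' @export
write_mgf <- function(spectra, path) {
  if (!is.null(spectra$peaks)) spectra <- list(spectra)
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in spectra) {
    writeLines("BEGIN IONS", con)
    if (!is.null(sp$title) && !is.na(sp$title))
      writeLines(paste0("TITLE=", sp$title), con)
    if (!is.null(sp$pepmass) && !is.na(sp$pepmass))
      writeLines(sprintf("PEPMASS=%.6f", sp$pepmass), con)
    if (!is.null(sp$charge) && !is.na(sp$charge))
      writeLines(paste0("CHARGE=", abs(sp$charge), if (sp$charge < 0) "-" else "+"),
                 con)
    writeLines(sprintf("%.6f %.6g", sp$peaks$mz, sp$peaks$intensity), con)
    writeLines("END IONS", con)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------

#' Annotate a peak list against candidate precursors
#'
#' Each peak is matched to the nearest theoretical fragment of each candidate
#' within the tolerance (closest match wins; one annotation per peak per
#' candidate).  Results are per candidate; a peak may annotate several
#' isomeric candidates, and no arbitration between candidates is attempted.
#'
#' @param peaks data.frame with columns `mz` (and optionally `intensity`).
#' @param candidates one candidate or a list: each either a
#'   [precursor_ion()] or a lipid name string (then `adduct` is required).
#' @param tol_ppm matching tolerance in ppm (default 5, FT-type resolution).
#' @param tol_da absolute tolerance in Da; overrides `tol_ppm` when given
#'   (e.g. 0.3 for ion-trap spectra).
#' @param ms_level 2 (default) or 3.
#' @param adduct adduct symbol for string candidates.
#' @param rules rule table.
#' @return list of `annotation_result` objects (one per candidate), each with
#'   `$precursor`, `$matches` (data.frame: observed_mz, intensity,
#'   theoretical_mz, ppm, name, dual_name, fragment_type, ms_level, rule),
#'   `$unmatched` (observed m/z values), `$identification_level` and
#'   `$chain_evidence`.
#' @export
annotate_spectrum <- function(peaks, candidates, tol_ppm = 5, tol_da = NULL,
                              ms_level = 2, adduct = NULL,
                              rules = fragmentation_rules()) {
  .check_peaks(peaks)
  if (inherits(candidates, "precursor_ion") || is.character(candidates))
    candidates <- if (is.character(candidates)) as.list(candidates) else list(candidates)
  if (!length(candidates)) stop("empty candidate set", call. = FALSE)
  if (!is.null(tol_da) && tol_da <= 0) stop("tolerance must be > 0", call. = FALSE)
  if (is.null(tol_da) && tol_ppm <= 0) stop("tolerance must be > 0", call. = FALSE)
  lapply(candidates, function(cand) {
    if (is.character(cand)) {
      if (is.null(adduct)) stop("supply an adduct with lipid-name candidates",
                                call. = FALSE)
      cand <- precursor_ion(cand, adduct)
    }
    rxs <- enumerate_fragments(cand, rules = rules, ms_level = ms_level,
                               warn_empty = FALSE)
    .annotate_one(peaks, cand, rxs, tol_ppm, tol_da)
  })
}

.annotate_one <- function(peaks, cand, rxs, tol_ppm, tol_da) {
  theo <- fragment_table(rxs)
  rows <- list()
  matched_rx <- integer(0)
  for (i in seq_len(nrow(peaks))) {
    obs <- peaks$mz[i]
    if (!nrow(theo)) break
    err <- obs - theo$mz
    tol <- if (!is.null(tol_da)) tol_da else tol_ppm * 1e-6 * theo$mz
    ok <- which(abs(err) <= tol)
    if (!length(ok)) next
    j <- ok[which.min(abs(err[ok]))]
    matched_rx <- c(matched_rx, j)
    rows[[length(rows) + 1]] <- data.frame(
      observed_mz = obs,
      intensity = if ("intensity" %in% names(peaks)) peaks$intensity[i] else NA_real_,
      theoretical_mz = theo$mz[j],
      ppm = (obs - theo$mz[j]) / theo$mz[j] * 1e6,
      name = theo$name[j], dual_name = theo$dual[j],
      fragment_type = theo$type[j], ms_level = theo$ms_level[j],
      rule = theo$rule[j], stringsAsFactors = FALSE)
  }
  matches <- if (length(rows)) do.call(rbind, rows) else
    data.frame(observed_mz = numeric(0), intensity = numeric(0),
               theoretical_mz = numeric(0), ppm = numeric(0),
               name = character(0), dual_name = character(0),
               fragment_type = character(0), ms_level = integer(0),
               rule = character(0), stringsAsFactors = FALSE)
  res <- structure(list(precursor = cand, reactions = rxs, matches = matches,
                        matched_reactions = rxs[unique(matched_rx)],
                        unmatched = setdiff(peaks$mz, matches$observed_mz)),
                   class = "annotation_result")
  res$chain_evidence <- .chain_evidence(res)
  res$identification_level <- identification_level(res)
  res
}

.chain_evidence <- function(res) {
  chains <- res$precursor$lipid$chains
  if (!length(chains)) return(data.frame())
  slots <- seq_along(chains)
  evid <- lapply(slots, function(s) {
    sum(vapply(res$matched_reactions, function(rx)
      s %in% rx$mlf_slots, logical(1)))
  })
  data.frame(slot = slots,
             chain = vapply(chains, .format_chain_token, character(1)),
             mlf_fragments = unlist(evid))
}

.has_dbf <- function(rx)
  any(vapply(c(list(rx$charged), rx$neutrals), function(p)
    identical(p$type, "DBF"), logical(1)))

#' Identification level supported by an annotation result
#'
#' Double-bond-location-defined if at least one DBF matched; molecular
#' species level if every chain slot has at least one matched single-chain
#' (MLF) fragment; species level if at least one LCF or iMLF matched;
#' otherwise none.
#'
#' @param res an `annotation_result`.
#' @return one of `"db_defined"`, `"molecular"`, `"species"`, `"none"`.
#' @export
identification_level <- function(res) {
  stopifnot(inherits(res, "annotation_result"))
  rxs <- res$matched_reactions
  if (!length(rxs)) return("none")
  if (any(vapply(rxs, .has_dbf, logical(1)))) return("db_defined")
  ev <- res$chain_evidence
  if (nrow(ev) && all(ev$mlf_fragments >= 1)) return("molecular")
  types <- unlist(lapply(rxs, function(rx)
    vapply(c(list(rx$charged), rx$neutrals), `[[`, character(1), "type")))
  if (any(types %in% c("LCF", "iMLF"))) return("species")
  # matched MLFs that do not cover every chain still pin down the class
  if (any(types == "MLF")) return("species")
  "none"
}

#' @export
print.annotation_result <- function(x, ...) {
  lvl <- x$identification_level
  name <- switch(lvl,
    molecular = , db_defined = format_lipid(x$precursor$lipid),
    format_lipid(species_of(x$precursor$lipid)))
  cat(x$precursor$display, ": ", nrow(x$matches), " matched peak(s), ",
      length(x$unmatched), " unmatched; identified as ", name,
      " [", lvl, " level]\n", sep = "")
  if (nrow(x$matches))
    print(x$matches[, c("observed_mz", "theoretical_mz", "ppm", "name")],
          digits = 7)
  invisible(x)
}

#' Write an annotation result as TSV
#'
#' @param res an `annotation_result`.
#' @param path output file.
#' @export
write_annotation <- function(res, path) {
  utils::write.table(res$matches, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
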
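# Synthetic MS2/MS3 spectra from the rule engine: ground-truth peaks with
# controllable ppm jitter, decoy peaks and a seeded intensity model, so
# annotation is testable without instrument data.

#' Simulate a fragment ion spectrum
#'
#' One peak per enumerated fragment at m/z = theoretical * (1 + e), with
#' e ~ Normal(0, jitter_ppm * 1e-6).  Decoy peaks are drawn uniformly over
#' `decoy_range`, excluding windows of `max(3 * jitter_ppm, 5)` ppm around
#' every true peak so that decoys can never force a false match at matching
#' tolerances up to that width.  Fully deterministic under `seed`.
#'
#' @param lipid lipid name (molecular/sn level) or a [precursor_ion()].
#' @param adduct adduct symbol (ignored when `lipid` is already an ion).
#' @param ms_level 2 (default); level-3 spectra are simulated by passing an
#'   MS3 reaction list via `reactions`.
#' @param jitter_ppm standard deviation of the relative mass error, in ppm.
#' @param n_decoys number of decoy peaks.
#' @param decoy_range numeric length-2 m/z range for decoys (default 100 up
#'   to the precursor m/z).
#' @param intensity `"uniform"` (all 1000) or `"rank"` (1000 / rank decay
#'   over fragments in enumeration order; decoys at the low end).
#' @param seed integer random seed fixing the full output.
#' @param reactions optional pre-enumerated reaction list overriding the
#'   engine call (e.g. output of [enumerate_ms3()]).
#' @param rules rule table.
#' @return list with `peaks` (data.frame mz, intensity, sorted by m/z) and
#'   `truth` (data.frame: theoretical and simulated m/z, name, dual name,
#'   fragment type, rule; decoys are not listed).
#' @export
#' @examples
#' sim <- simulate_spectrum("PE 17:0-17:0", "-H", jitter_ppm = 0, seed = 1)
#' sim$truth$name
simulate_spectrum <- function(lipid, adduct = NULL, ms_level = 2,
                              jitter_ppm = 0, n_decoys = 0,
                              decoy_range = NULL,
                              intensity = c("uniform", "rank"),
                              seed = 1L, reactions = NULL,
                              rules = fragmentation_rules()) {
  intensity <- match.arg(intensity)
  if (jitter_ppm < 0) stop("jitter_ppm must be >= 0", call. = FALSE)
  if (n_decoys < 0) stop("n_decoys must be >= 0", call. = FALSE)
  prec <- if (inherits(lipid, "precursor_ion")) lipid
          else precursor_ion(lipid, adduct)
  rxs <- if (!is.null(reactions)) reactions
         else enumerate_fragments(prec, rules = rules, ms_level = ms_level)
  if (!length(rxs)) stop("no fragments to simulate for ", prec$display,
                         call. = FALSE)
  ft <- fragment_table(rxs)
  if (is.null(decoy_range)) decoy_range <- c(100, prec$mz)

  set.seed(as.integer(seed))
  eps <- stats::rnorm(nrow(ft), mean = 0, sd = jitter_ppm * 1e-6)
  sim_mz <- ft$mz * (1 + eps)
  inten <- switch(intensity,
                  uniform = rep(1000, nrow(ft)),
                  rank = 1000 / seq_len(nrow(ft)))
  truth <- data.frame(theoretical_mz = ft$mz, simulated_mz = sim_mz,
                      name = ft$name, dual_name = ft$dual,
                      fragment_type = ft$type, rule = ft$rule,
                      stringsAsFactors = FALSE)

  decoys <- numeric(0)
  if (n_decoys > 0) {
    excl_ppm <- max(3 * jitter_ppm, 5)
    guard <- 0L
    while (length(decoys) < n_decoys && guard < 10000L) {
      cand <- stats::runif(n_decoys, decoy_range[1], decoy_range[2])
      ok <- vapply(cand, function(x)
        all(abs(x - ft$mz) / ft$mz * 1e6 > excl_ppm), logical(1))
      decoys <- c(decoys, cand[ok])
      guard <- guard + 1L
    }
    decoys <- decoys[seq_len(n_decoys)]
  }

  peaks <- data.frame(
    mz = c(sim_mz, decoys),
    intensity = c(inten, if (length(decoys))
      stats::runif(length(decoys), 1, 100) else numeric(0)))
  peaks <- peaks[order(peaks$mz), , drop = FALSE]
  rownames(peaks) <- NULL
  list(precursor = prec, peaks = peaks, truth = truth)
}
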
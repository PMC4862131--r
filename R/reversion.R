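## Probability model for treatment-induced genetic reversion of frameshift or
## nonsense mutations: uniform placement of induced mutations over the genome,
## with a small target window (20 bp for a compensating frameshift, the 3
## bases of a stop codon for an SNV).

#' Reversion model parameters
#'
#' @param genome_size_bp genome size G (default 3.1e9, human).
#' @param indel_window_bp window within which a compensating frameshift can
#'   restore the reading frame (default 20).
#' @param stop_codon_bp bases of a stop codon an SNV can revert (default 3).
#' @param snv_per_gb,indel_per_gb induced mutation burden per Gb per cell
#'   (defaults 800 and 130, the measured four-cycle cisplatin burden).
#' @return list of class `reversion_params`.
#' @export
reversion_params <- function(genome_size_bp = 3.1e9, indel_window_bp = 20,
                             stop_codon_bp = 3, snv_per_gb = 800,
                             indel_per_gb = 130) {
  if (indel_window_bp <= 0 || indel_window_bp >= genome_size_bp ||
      stop_codon_bp <= 0 || stop_codon_bp >= genome_size_bp) {
    stop("target windows must satisfy 0 < w < G")
  }
  if (snv_per_gb < 0 || indel_per_gb < 0) stop("burdens must be >= 0")
  structure(list(genome_size_bp = genome_size_bp,
                 indel_window_bp = indel_window_bp,
                 stop_codon_bp = stop_codon_bp,
                 snv_per_gb = snv_per_gb, indel_per_gb = indel_per_gb),
            class = "reversion_params")
}

#' Per-event hit probability under uniform placement
#'
#' @param G genome size in bp.
#' @param w target window in bp.
#' @return w / G.
#' @export
p_hit <- function(G, w) {
  if (w <= 0) {
    if (w == 0) return(0)
    stop("window must be non-negative")
  }
  if (w >= G) stop("window must be smaller than the genome")
  w / G
}

#' Events needed for a 50 % chance of at least one hit
#'
#' Smallest real N with 1 - (1 - p)^N = 0.5, i.e. log(0.5)/log(1 - p);
#' for small p this is ln 2 / p.
#'
#' @param p per-event hit probability, 0 < p < 1.
#' @return N (numeric).
#' @export
events_for_half_chance <- function(p) {
  if (p <= 0 || p >= 1) stop("p must be in (0, 1)")
  log(0.5) / log1p(-p)
}

#' Surviving cells needed for a 50 % chance of a reverting mutation
#'
#' Each cell carries `burden_per_genome` independent uniformly placed events;
#' the per-cell reversion probability is 1 - (1 - p_event)^burden, and the
#' cell count for a 50 % chance is log(0.5)/log(1 - p_cell).
#'
#' @param burden_per_genome events per cell (burden/Gb x genome size in Gb).
#' @param p_event per-event hit probability.
#' @return list `p_cell`, `n_cells` (floored at 1: a single cell suffices
#'   once its own reversion probability reaches 0.5).
#' @export
cells_for_half_chance <- function(burden_per_genome, p_event) {
  if (burden_per_genome <= 0) stop("burden must be positive")
  if (p_event <= 0 || p_event >= 1) stop("p_event must be in (0, 1)")
  p_cell <- -expm1(burden_per_genome * log1p(-p_event))
  n <- if (p_cell >= 1) 1 else max(1, log(0.5) / log1p(-p_cell))
  list(p_cell = p_cell, n_cells = n)
}

#' Full reversion summary for a parameter set
#'
#' @param params a [reversion_params()].
#' @return list of class `reversion_model` with per-mechanism event and cell
#'   requirements.
#' @export
reversion_model <- function(params = reversion_params()) {
  G <- params$genome_size_bp
  gb <- G / 1e9
  p_ind <- p_hit(G, params$indel_window_bp)
  p_snv <- p_hit(G, params$stop_codon_bp)
  ind <- cells_for_half_chance(params$indel_per_gb * gb, p_ind)
  snv <- cells_for_half_chance(params$snv_per_gb * gb, p_snv)
  structure(list(
    params = params,
    p_hit_indel = p_ind, p_hit_snv = p_snv,
    events_indel = events_for_half_chance(p_ind),
    events_snv = events_for_half_chance(p_snv),
    cells_indel = ind$n_cells, cells_snv = snv$n_cells,
    p_cell_indel = ind$p_cell, p_cell_snv = snv$p_cell
  ), class = "reversion_model")
}

#' @export
print.reversion_model <- function(x, ...) {
  p <- x$params
  cat(sprintf("Reversion model (G = %.3g bp)\n", p$genome_size_bp))
  cat(sprintf(
    "  frameshift reversion (window %d bp): p = %.3g per indel; %.2g indels, or %.2g surviving cells at %g indels/Gb, for a 50%% chance\n",
    p$indel_window_bp, x$p_hit_indel, x$events_indel, x$cells_indel,
    p$indel_per_gb))
  cat(sprintf(
    "  stop-codon reversion (%d bp): p = %.3g per SNV; %.2g SNVs, or %.2g surviving cells at %g SNVs/Gb, for a 50%% chance\n",
    p$stop_codon_bp, x$p_hit_snv, x$events_snv, x$cells_snv, p$snv_per_gb))
  invisible(x)
}

#' Monte-Carlo estimate of the per-cell reversion probability
#'
#' Places `burden` events uniformly on a genome of size `G` and scores a hit
#' when any event lands inside the `w`-bp target window (so the analytic hit
#' probability per event is exactly w/G); used as a simulation oracle for
#' [cells_for_half_chance()].
#'
#' @param G genome size. @param w window. @param burden events per cell.
#' @param n_reps replicate cells.
#' @param target window start (default G/2).
#' @return fraction of replicates with at least one hit.
#' @export
simulate_reversion_probability <- function(G, w, burden, n_reps,
                                           target = G / 2) {
  hits <- 0L
  chunk <- max(1L, floor(2e6 / burden))
  done <- 0L
  while (done < n_reps) {
    m <- min(chunk, n_reps - done)
    x <- matrix(runif(m * burden, 0, G), m, burden)
    hits <- hits + sum(rowSums(x > target & x <= target + w) > 0)
    done <- done + m
  }
  hits / n_reps
}
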
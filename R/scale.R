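#' Discrete evidence lattice
#'
#' An evidence scale with `n_levels` ordered levels. Level `j` (0-based,
#' `j = 0, ..., n_levels - 1`) carries the likelihood value `j / (n_levels - 1)`,
#' so the scale runs from 0 (full evidence against) through 0.5 (equivocal) to
#' 1 (full evidence for). Levels are indexed 0-based throughout the package;
#' descriptions of a projector "at row 66" in 1-based matrix terms correspond
#' to level 65 here.
#'
#' @param n_levels Integer number of evidence levels, at least 2.
#' @return An object of class `evidence_scale` with fields `n_levels` and
#'   `values` (the per-level likelihood values).
#' @examples
#' sc <- evidence_scale(101)
#' sc$values[66]  # level 65 -> likelihood 0.65
#' @export
evidence_scale <- function(n_levels) {
  n_levels <- as.integer(n_levels)
  if (length(n_levels) != 1L || is.na(n_levels) || n_levels < 2L)
    abort("`n_levels` must be a single integer >= 2.")
  structure(
    list(n_levels = n_levels, values = seq(0, 1, length.out = n_levels)),
    class = "evidence_scale"
  )
}

#' @export
print.evidence_scale <- function(x, ...) {
  cat("<evidence_scale> ", x$n_levels, " levels, values 0..1 (step ",
      format(1 / (x$n_levels - 1), digits = 4), ")\n", sep = "")
  invisible(x)
}

#' Response projector over a set of evidence levels
#'
#' Builds the diagonal 0/1 measurement operator selecting the given levels:
#' observing the response amounts to projecting the state onto those levels.
#'
#' @param scale An [evidence_scale()].
#' @param levels Non-empty vector of 0-based level indices.
#' @param label Optional response name (used in experiment output tables).
#' @return An object of class `response_projector` with fields `levels`,
#'   `matrix` (diagonal 0/1), and `label`.
#' @examples
#' sc <- evidence_scale(101)
#' m_present <- projector(sc, 51:100, "present")
#' m65 <- projector(sc, 65, "conf-0.65")
#' @export
projector <- function(scale, levels, label = NULL) {
  stopifnot(inherits(scale, "evidence_scale"))
  levels <- sort(unique(as.integer(levels)))
  n <- scale$n_levels
  if (length(levels) == 0L) abort("`levels` must be non-empty.")
  if (any(levels < 0L) || any(levels > n - 1L))
    abort(sprintf("`levels` must lie in 0..%d.", n - 1L))
  d <- numeric(n)
  d[levels + 1L] <- 1
  structure(
    list(levels = levels, matrix = diag(d, n), n_levels = n,
         label = label %||% paste0("levels-", levels[1], "-", levels[length(levels)])),
    class = "response_projector"
  )
}

#' @export
print.response_projector <- function(x, ...) {
  cat("<response_projector> '", x$label, "': ", length(x$levels), "/",
      x$n_levels, " levels\n", sep = "")
  invisible(x)
}

#' Complete projector partition into contiguous confidence bins
#'
#' Splits the lattice into `n_bins` contiguous, non-overlapping bins whose
#' projectors sum to the identity — the package's convention for modelling a
#' graded confidence rating as a measurement.
#'
#' @inheritParams projector
#' @param n_bins Number of bins (default 21 on a 101-level scale).
#' @return List of `response_projector`s labelled by bin midpoint likelihood.
#' @export
confidence_bins <- function(scale, n_bins = 21) {
  stopifnot(inherits(scale, "evidence_scale"))
  n <- scale$n_levels
  n_bins <- as.integer(n_bins)
  if (n_bins < 1L || n_bins > n) abort("`n_bins` must be in 1..n_levels.")
  cuts <- floor(seq(0, n, length.out = n_bins + 1))
  lapply(seq_len(n_bins), function(b) {
    lev <- seq.int(cuts[b], cuts[b + 1] - 1)
    mid <- scale$values[lev[ceiling(length(lev) / 2)] + 1L]
    projector(scale, lev, label = sprintf("conf-%0.2f", mid))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
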